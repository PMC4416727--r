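#' Annual herd growth
#'
#' Multiplies each herd by `1 + g` with `g ~ N(growth_mean, growth_sd^2)`
#' truncated below at -1 (a herd cannot become negative). One growth factor
#' is drawn per herd.
#'
#' @param herd numeric vector of herd sizes.
#' @param params a [sim_params()] object.
#' @return the grown herd vector.
#' @export
annual_growth <- function(herd, params = sim_params()) {
  stopifnot(all(herd >= 0))
  g <- pmax(stats::rnorm(length(herd), params$growth_mean, params$growth_sd), -1)
  herd * (1 + g)
}

#' Disaster herd loss
#'
#' Multiplies each herd by `1 - l` with `l ~ N(loss_mean, loss_sd^2)` clipped
#' to `[0, 1]`: a disaster removes on average 30% of the herd.
#'
#' @inheritParams annual_growth
#' @return the reduced herd vector.
#' @export
disaster_loss <- function(herd, params = sim_params()) {
  stopifnot(all(herd >= 0))
  l <- pmin(pmax(stats::rnorm(length(herd), params$loss_mean, params$loss_sd), 0), 1)
  herd * (1 - l)
}

#' All-or-nothing gift rule
#'
#' A partner gives exactly what is asked, but only if doing so leaves their
#' own herd at or above the minimum sustainable size; otherwise they give
#' nothing. Partial gifts never occur.
#'
#' @param giver_herd the asked partner's herd size (vectorized).
#' @param request the requested amount (> 0).
#' @param threshold minimum sustainable herd size.
#' @return `request` where `giver_herd - request >= threshold`, else 0.
#' @examples
#' gift_amount(100, 30, 64)  # 30: giver left at 70
#' gift_amount(90, 30, 64)   # 0: would leave the giver at 60
#' gift_amount(94, 30, 64)   # 30: giver left exactly at the threshold
#' @export
gift_amount <- function(giver_herd, request, threshold) {
  stopifnot(all(request > 0))
  ifelse(giver_herd - request >= threshold, request, 0)
}

#' Need-based request and gift round
#'
#' Executes one year's Osotua transfers. Every alive node whose herd is below
#' the minimum sustainable size asks one uniformly chosen alive network
#' neighbor for exactly the shortfall (`threshold - herd`). The partner gives
#' per [gift_amount()]: all of it (restoring the asker exactly to the
#' threshold) or nothing. Needy nodes are processed in a uniformly random
#' order; total cattle is conserved.
#'
#' @param herd numeric vector of post-disaster herd sizes.
#' @param alive logical vector of alive flags.
#' @param net a `spatial_network`; its edges define who may be asked.
#' @param params a [sim_params()] object.
#' @param adj optional precomputed [adjacency_list()] of `net`.
#' @param year year stamp recorded in the gift log.
#' @param eligible optional logical vector restricting who may ask this year
#'   (used for the loss-triggered asking rule: only nodes struck by a
#'   disaster this year ask). `NULL` means every needy node may ask.
#' @return list with the updated `herd` and a `gifts` data frame
#'   (`year`, `giver`, `receiver`, `amount`).
#' @export
process_requests <- function(herd, alive, net, params = sim_params(),
                             adj = NULL, year = NA_integer_,
                             eligible = NULL) {
  if (is.null(adj)) adj <- adjacency_list(net)
  thr <- params$threshold
  if (is.null(eligible)) eligible <- rep(TRUE, length(herd))
  needy <- which(alive & eligible & herd < thr)
  gy <- integer(0); gg <- integer(0); gr <- integer(0); ga <- numeric(0)
  if (length(needy) > 0L) {
    needy <- needy[sample.int(length(needy))]
    for (i in needy) {
      nb <- adj[[i]]
      nb <- nb[alive[nb]]
      if (length(nb) == 0L) next
      req <- thr - herd[i]
      n_try <- min(length(nb), 1L + params$retries)
      partners <- nb[sample.int(length(nb), n_try)]
      for (p in partners) {
        amt <- gift_amount(herd[p], req, thr)
        if (amt > 0) {
          herd[p] <- herd[p] - amt
          herd[i] <- thr
          gy <- c(gy, year); gg <- c(gg, p); gr <- c(gr, i); ga <- c(ga, amt)
          break
        }
      }
    }
  }
  list(herd = herd,
       gifts = data.frame(year = gy, giver = gg, receiver = gr, amount = ga))
}

#' End-of-year survival update
#'
#' Increments each alive node's consecutive-below-threshold counter if its
#' herd is below the minimum sustainable size, resets it otherwise, and
#' eliminates nodes whose counter reaches `death_lag`.
#'
#' @param herd numeric vector of end-of-year herd sizes (the herd the check
#'   applies to; by default the post-gift herd).
#' @param alive logical alive flags.
#' @param below_count integer vector of consecutive below-threshold years.
#' @param params a [sim_params()] object.
#' @return list with updated `alive` and `below_count`.
#' @export
update_survival <- function(herd, alive, below_count, params = sim_params()) {
  below <- alive & herd < params$threshold
  below_count[alive] <- ifelse(below[alive], below_count[alive] + 1L, 0L)
  dead_now <- alive & below_count >= params$death_lag
  alive[dead_now] <- FALSE
  list(alive = alive, below_count = below_count)
}

#' Run the 50-year Osotua simulation
#'
#' Simulates the herd dynamics of all agents over the horizon. Each year, in
#' order: (1) alive herds grow ([annual_growth()]); (2) alive nodes whose
#' lattice cell `(spatial position, year)` carries a disaster lose a random
#' herd fraction ([disaster_loss()]) — each such hit on a live node counts as
#' an *effective disaster*; (3) need-based requests and gifts are processed
#' ([process_requests()]; skipped when `net` is `NULL`, the isolated-node
#' benchmark); (4) survival is updated ([update_survival()]). Dead nodes are
#' frozen: they never grow, lose, give or receive.
#'
#' @param field a [generate_disaster_field()] object; its spatial extent must
#'   cover every node's ring position and its horizon the simulation horizon.
#' @param net a `spatial_network`, or `NULL` for unconnected nodes (one node
#'   per lattice location).
#' @param params a [sim_params()] object.
#' @param engine `"compiled"` (C++ year loop, the fast path) or
#'   `"reference"` (pure-R loop built from the exported one-step operations).
#'   Both implement the identical model; random-number draw order differs, so
#'   individual runs are not bitwise comparable across engines.
#' @param collect_gifts keep the full gift log (default `TRUE`).
#' @return an object of class `sim_result`: `survival_rate`,
#'   `surviving_herds`, final `herds` and `alive` flags, the
#'   `effective_disasters` count, the `gifts` log and `gifts_per_year`.
#' @examples
#' set.seed(7)
#' f <- generate_disaster_field("none")
#' net <- rewire_network(ring_lattice(100, 4), beta = 0.8)
#' run_simulation(f, net)
#' @export
run_simulation <- function(field, net = NULL, params = sim_params(),
                           engine = c("compiled", "reference"),
                           collect_gifts = TRUE) {
  stopifnot(inherits(field, "disaster_field"))
  engine <- match.arg(engine)
  if (is.null(net)) {
    n <- field$x_extent
    spatial_index <- 0:(n - 1L)
    adj <- NULL
  } else {
    stopifnot(inherits(net, "spatial_network"))
    n <- net$n
    spatial_index <- net$spatial_index
    adj <- adjacency_list(net)
  }
  if (any(spatial_index < 0L | spatial_index >= field$x_extent)) {
    stop("node ring positions do not fit the disaster lattice", call. = FALSE)
  }
  if (params$t_years > field$t_extent) {
    stop("disaster field horizon shorter than the simulation horizon",
         call. = FALSE)
  }

  if (engine == "compiled") {
    adj_flat <- if (is.null(adj)) integer(0) else unlist(adj, use.names = FALSE)
    adj_ptr <- if (is.null(adj)) integer(1) else
      cumsum(c(0L, lengths(adj)))
    res <- cpp_run_sim(n, adj_flat, as.integer(adj_ptr),
                       as.integer(spatial_index), field$occupancy,
                       params$t_years, params$initial_herd, params$threshold,
                       params$growth_mean, params$growth_sd,
                       params$loss_mean, params$loss_sd,
                       params$death_lag, params$check_pre_gift,
                       params$retries, params$ask_trigger == "need",
                       !is.null(net), collect_gifts)
    gifts <- data.frame(year = res$gift_year, giver = res$gift_giver,
                        receiver = res$gift_receiver, amount = res$gift_amount)
    return(new_sim_result(res$herd, res$alive, res$effective_disasters,
                          gifts, res$gifts_per_year, params))
  }

  herd <- rep(params$initial_herd, n)
  alive <- rep(TRUE, n)
  below <- integer(n)
  eff <- 0L
  gifts <- vector("list", params$t_years)
  gifts_per_year <- integer(params$t_years)
  occ <- field$occupancy
  for (yr in seq_len(params$t_years)) {
    herd[alive] <- annual_growth(herd[alive], params)
    hit <- alive & occ[cbind(spatial_index + 1L, yr)] == 1L
    eff <- eff + sum(hit)
    if (any(hit)) herd[hit] <- disaster_loss(herd[hit], params)
    check_herd <- herd
    if (!is.null(net)) {
      elig <- if (params$ask_trigger == "loss") hit else NULL
      pr <- process_requests(herd, alive, net, params, adj = adj, year = yr,
                             eligible = elig)
      herd <- pr$herd
      if (nrow(pr$gifts) > 0L && collect_gifts) gifts[[yr]] <- pr$gifts
      gifts_per_year[yr] <- nrow(pr$gifts)
    }
    if (!params$check_pre_gift) check_herd <- herd
    up <- update_survival(check_herd, alive, below, params)
    alive <- up$alive
    below <- up$below_count
  }
  gifts <- do.call(rbind, c(gifts[!vapply(gifts, is.null, logical(1))],
                            list(data.frame(year = integer(0),
                                            giver = integer(0),
                                            receiver = integer(0),
                                            amount = numeric(0)))))
  new_sim_result(herd, alive, eff, gifts, gifts_per_year, params)
}

new_sim_result <- function(herd, alive, eff, gifts, gifts_per_year, params) {
  alive <- as.logical(alive)
  structure(list(
    survival_rate = mean(alive),
    surviving_herds = herd[alive],
    herds = herd,
    alive = alive,
    effective_disasters = as.integer(eff),
    gifts = gifts,
    gifts_per_year = as.integer(gifts_per_year),
    params = params
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Osotua simulation over %d years, %d nodes\n",
              x$params$t_years, length(x$alive)))
  cat(sprintf("  survival rate %.3f (%d survivors)\n", x$survival_rate,
              sum(x$alive)))
  if (sum(x$alive) > 0) {
    cat(sprintf("  mean surviving herd %.1f cattle\n",
                mean(x$surviving_herds)))
  }
  cat(sprintf("  effective disasters %d, gift events %d\n",
              x$effective_disasters, sum(x$gifts_per_year)))
  invisible(x)
}

#' @export
summary.sim_result <- function(object, ...) {
  s <- list(
    n = length(object$alive),
    survival_rate = object$survival_rate,
    n_survivors = sum(object$alive),
    mean_surviving_herd = if (any(object$alive))
      mean(object$surviving_herds) else NA_real_,
    effective_disasters = object$effective_disasters,
    total_gifts = sum(object$gifts_per_year),
    total_cattle_transferred = sum(object$gifts$amount)
  )
  class(s) <- "summary.sim_result"
  s
}

#' @export
print.summary.sim_result <- function(x, ...) {
  cat("Survival rate:        ", sprintf("%.3f", x$survival_rate),
      sprintf("(%d / %d nodes)\n", x$n_survivors, x$n))
  cat("Mean surviving herd:  ", sprintf("%.1f cattle\n", x$mean_surviving_herd))
  cat("Effective disasters:  ", x$effective_disasters, "\n")
  cat("Gift events:          ", x$total_gifts,
      sprintf("(%.1f cattle transferred)\n", x$total_cattle_transferred))
  invisible(x)
}

#' Write a simulation result to disk
#'
#' Writes the gift log as CSV (`year,giver,receiver,amount`) and the summary
#' observables (survival rate, surviving herds, effective disasters, gifts
#' per year) as JSON.
#'
#' @param result a `sim_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(result, dir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$gifts, file.path(dir, "gifts.csv"),
                   row.names = FALSE)
  out <- list(survival_rate = result$survival_rate,
              surviving_herds = result$surviving_herds,
              effective_disasters = result$effective_disasters,
              gifts_per_year = result$gifts_per_year)
  jsonlite::write_json(out, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
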