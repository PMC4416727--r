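#' Correlation scenario standard deviations
#'
#' Maps a disaster-correlation scenario and a strength level to the pair of
#' Gaussian cluster standard deviations \eqn{(\sigma_x, \sigma_t)} used by the
#' disaster generator. Level \eqn{p} halves the relevant standard deviation(s)
#' relative to the weakest setting: \eqn{\sigma_x = 2^{-(p-1)} \cdot 64} on the
#' spatial axis and/or \eqn{\sigma_t = 2^{-(p-1)} \cdot 32} on the temporal
#' axis. Larger \eqn{p} means tighter clusters, i.e. stronger correlation.
#'
#' @param scenario one of `"none"`, `"spatial"`, `"temporal"`,
#'   `"spatiotemporal"`. `"none"` always uses the weakest (level-1) values.
#' @param level integer correlation-strength index \eqn{p \ge 1}.
#' @param base_sigma_x,base_sigma_t standard deviations at the weakest level,
#'   in lattice-location units and years (defaults 64 and 32).
#' @return a list with components `sigma_x` and `sigma_t`.
#' @examples
#' scenario_sigmas("spatial", 1)  # sigma_x = 64, sigma_t = 32
#' scenario_sigmas("spatial", 7)  # sigma_x = 1,  sigma_t = 32
#' @export
scenario_sigmas <- function(scenario, level = 1L,
                            base_sigma_x = 64, base_sigma_t = 32) {
  scenario <- match.arg(scenario, osotua_scenarios())
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level != round(level)) {
    stop("'level' must be a single integer >= 1", call. = FALSE)
  }
  if (base_sigma_x <= 0 || base_sigma_t <= 0 ||
      !is.finite(base_sigma_x) || !is.finite(base_sigma_t)) {
    stop("base standard deviations must be positive and finite", call. = FALSE)
  }
  f <- 2^(-(level - 1))
  sig <- switch(scenario,
    none           = list(sigma_x = base_sigma_x,     sigma_t = base_sigma_t),
    spatial        = list(sigma_x = f * base_sigma_x, sigma_t = base_sigma_t),
    temporal       = list(sigma_x = base_sigma_x,     sigma_t = f * base_sigma_t),
    spatiotemporal = list(sigma_x = f * base_sigma_x, sigma_t = f * base_sigma_t)
  )
  sig
}

#' @rdname scenario_sigmas
#' @export
osotua_scenarios <- function() {
  c("none", "spatial", "temporal", "spatiotemporal")
}

#' Sample cluster centers on the lattice
#'
#' Draws `m` cluster modes independently and uniformly over the
#' (location, year) lattice. Centers may coincide.
#'
#' @param m number of centers.
#' @param x_extent number of spatial locations (ring positions `0..x_extent-1`).
#' @param t_extent number of years (`1..t_extent`).
#' @return integer matrix with `m` rows and columns `year`, `location`.
#' @export
sample_cluster_centers <- function(m, x_extent = 100L, t_extent = 50L) {
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (x_extent < 1 || t_extent < 1) {
    stop("lattice extents must be >= 1", call. = FALSE)
  }
  cbind(year     = sample.int(t_extent, m, replace = TRUE),
        location = sample.int(x_extent, m, replace = TRUE) - 1L)
}

# Squared anisotropy-scaled distance of every lattice cell to a center,
# spatial axis wrapped on the ring. Used by the deterministic spill-out.
.cell_distances <- function(center, sigma, x_extent, t_extent) {
  sx <- max(sigma$sigma_x, 1e-9)
  st <- max(sigma$sigma_t, 1e-9)
  dx <- abs((0:(x_extent - 1L)) - center[["location"]])
  dx <- pmin(dx, x_extent - dx)
  dt <- abs((1:t_extent) - center[["year"]])
  outer(dx / sx, dt / st, function(a, b) a^2 + b^2)
}

#' Sample distinct disaster cells around a cluster center
#'
#' Draws `n_events` distinct lattice cells from a discretized bivariate
#' Gaussian centered on `center`: each coordinate is a normal deviate rounded
#' to the nearest integer, the spatial coordinate wrapped modulo `x_extent`
#' (the lattice is a ring) and the temporal coordinate redrawn when it falls
#' outside `1..t_extent`. Cells already listed in `occupied` are rejected, so
#' passing the running occupancy of previous clusters yields global sampling
#' without replacement.
#'
#' With both standard deviations exactly zero the Gaussian degenerates to a
#' point mass and the cluster collapses onto its mode: only the center cell
#' (at most) is returned. With tiny but positive standard deviations,
#' rejection sampling may fail to reach `n_events` distinct cells within
#' `max_iter` draws; the remainder is then filled deterministically with the
#' nearest unoccupied cells (anisotropy-scaled distance, ties broken by year
#' then location).
#'
#' @param center length-2 vector or 1-row matrix with named entries `year`
#'   and `location`.
#' @param sigma list with `sigma_x`, `sigma_t` (see [scenario_sigmas()]).
#' @param n_events number of distinct cells to draw.
#' @param x_extent,t_extent lattice extents.
#' @param occupied optional logical matrix (`x_extent` rows, `t_extent`
#'   columns); `TRUE` cells are excluded.
#' @param max_iter rejection-sampling iteration cap per cluster.
#' @return integer matrix with columns `year`, `location`; rows distinct.
#' @export
sample_cluster_events <- function(center, sigma, n_events,
                                  x_extent = 100L, t_extent = 50L,
                                  occupied = NULL, max_iter = 10000L) {
  if (n_events < 1) stop("'n_events' must be >= 1", call. = FALSE)
  if (n_events > x_extent * t_extent) {
    stop("'n_events' exceeds the lattice size", call. = FALSE)
  }
  center <- c(year = as.integer(center[["year"]]),
              location = as.integer(center[["location"]]))
  if (is.null(occupied)) {
    occupied <- matrix(FALSE, x_extent, t_extent)
  }

  taken <- matrix(FALSE, x_extent, t_extent)
  out_year <- integer(0)
  out_loc <- integer(0)

  if (sigma$sigma_x == 0 && sigma$sigma_t == 0) {
    # delta-distribution limit: the whole cluster sits on its mode
    if (!occupied[center[["location"]] + 1L, center[["year"]]]) {
      out_year <- center[["year"]]
      out_loc <- center[["location"]]
    }
    return(cbind(year = out_year, location = out_loc))
  }

  iter <- 0L
  while (length(out_year) < n_events && iter < max_iter) {
    # draw in blocks for speed; temporal out-of-range draws are discarded
    # (equivalent to redrawing), spatial draws wrap on the ring
    blk <- max(16L, n_events - length(out_year))
    iter <- iter + blk
    yr <- as.integer(round(stats::rnorm(blk, center[["year"]], sigma$sigma_t)))
    lc <- as.integer(round(stats::rnorm(blk, center[["location"]], sigma$sigma_x))) %% x_extent
    ok <- yr >= 1L & yr <= t_extent
    yr <- yr[ok]; lc <- lc[ok]
    for (j in seq_along(yr)) {
      if (!occupied[lc[j] + 1L, yr[j]] && !taken[lc[j] + 1L, yr[j]]) {
        taken[lc[j] + 1L, yr[j]] <- TRUE
        out_year <- c(out_year, yr[j])
        out_loc <- c(out_loc, lc[j])
        if (length(out_year) == n_events) break
      }
    }
  }

  n_missing <- n_events - length(out_year)
  if (n_missing > 0L) {
    # deterministic spill-out: nearest unoccupied cells by scaled distance
    d <- .cell_distances(center, sigma, x_extent, t_extent)
    free <- which(!occupied & !taken, arr.ind = TRUE)
    if (nrow(free) < n_missing) {
      stop("not enough unoccupied lattice cells for the requested events",
           call. = FALSE)
    }
    ord <- order(d[free], free[, 2L], free[, 1L])
    pick <- free[ord[seq_len(n_missing)], , drop = FALSE]
    out_year <- c(out_year, pick[, 2L])
    out_loc <- c(out_loc, pick[, 1L] - 1L)
  }

  cbind(year = as.integer(out_year), location = as.integer(out_loc))
}

#' Generate a correlated disaster field
#'
#' Builds the binary occupancy of disaster events on the
#' (location \eqn{\times} year) lattice. `m_clusters` cluster modes are placed
#' uniformly at random; each cluster receives a Gaussian event count with mean
#' `n_total / m_clusters` and variance 1 (rounded, floored at zero) and that
#' many distinct cells are sampled from a discretized bivariate Gaussian
#' around its mode. Sampling is without replacement across the whole field, so
#' the expected realized event count equals `n_total`.
#'
#' @param scenario correlation scenario label (see [scenario_sigmas()]).
#' @param level correlation-strength index \eqn{p \ge 1}.
#' @param n_total mean total number of events (default 500).
#' @param m_clusters number of Gaussian clusters (default 40).
#' @param x_extent,t_extent lattice extents (defaults 100 locations, 50 years).
#' @param sigma optional explicit `list(sigma_x =, sigma_t =)` overriding the
#'   scenario/level mapping.
#' @return an object of class `disaster_field`: a list with the 0/1
#'   `occupancy` matrix (`x_extent` rows, `t_extent` columns), the realized
#'   `events` (matrix `year`, `location`), the cluster `centers`, and the
#'   generating configuration.
#' @examples
#' set.seed(1)
#' f <- generate_disaster_field("spatial", level = 4)
#' realized_event_count(f)
#' @export
generate_disaster_field <- function(scenario = "none", level = 1L,
                                    n_total = 500L, m_clusters = 40L,
                                    x_extent = 100L, t_extent = 50L,
                                    sigma = NULL) {
  if (m_clusters < 1) stop("'m_clusters' must be >= 1", call. = FALSE)
  if (n_total < m_clusters) {
    stop("'n_total' must be >= 'm_clusters'", call. = FALSE)
  }
  scenario <- match.arg(scenario, osotua_scenarios())
  if (is.null(sigma)) sigma <- scenario_sigmas(scenario, level)

  centers <- sample_cluster_centers(m_clusters, x_extent, t_extent)
  counts <- pmax(0L, as.integer(round(stats::rnorm(m_clusters,
                                                   n_total / m_clusters, 1))))
  occupied <- matrix(FALSE, x_extent, t_extent)
  ev_year <- integer(0)
  ev_loc <- integer(0)
  for (i in seq_len(m_clusters)) {
    if (counts[i] == 0L) next
    n_i <- min(counts[i], sum(!occupied))
    if (n_i == 0L) break
    ev <- sample_cluster_events(centers[i, ], sigma, n_i,
                                x_extent, t_extent, occupied = occupied)
    if (nrow(ev) > 0L) {
      occupied[cbind(ev[, "location"] + 1L, ev[, "year"])] <- TRUE
      ev_year <- c(ev_year, ev[, "year"])
      ev_loc <- c(ev_loc, ev[, "location"])
    }
  }

  structure(list(
    occupancy = matrix(as.integer(occupied), x_extent, t_extent,
                       dimnames = list(NULL, paste0("y", seq_len(t_extent)))),
    events = cbind(year = ev_year, location = ev_loc),
    centers = centers,
    scenario = scenario,
    level = as.integer(level),
    sigma = sigma,
    n_total = as.integer(n_total),
    m_clusters = as.integer(m_clusters),
    x_extent = as.integer(x_extent),
    t_extent = as.integer(t_extent)
  ), class = "disaster_field")
}

#' Number of realized disaster events
#'
#' @param field a `disaster_field`.
#' @return the number of occupied lattice cells (equals the number of rows of
#'   the events list).
#' @export
realized_event_count <- function(field) {
  stopifnot(inherits(field, "disaster_field"))
  nrow(field$events)
}

#' @export
print.disaster_field <- function(x, ...) {
  cat("Disaster field:", x$x_extent, "locations x", x$t_extent, "years\n")
  cat(sprintf("  scenario %s (level %d), sigma_x = %g, sigma_t = %g\n",
              x$scenario, x$level, x$sigma$sigma_x, x$sigma$sigma_t))
  cat(sprintf("  %d events in %d clusters (target N = %d)\n",
              realized_event_count(x), x$m_clusters, x$n_total))
  invisible(x)
}

#' @export
as.matrix.disaster_field <- function(x, ...) x$occupancy

#' Write a disaster field to CSV + JSON sidecar
#'
#' Writes `occupancy.csv` (one row per location, one column per year, 0/1),
#' `events.csv` (`year,location`) and `field.json` (scenario, level, sigmas,
#' N, M, extents).
#'
#' @param field a `disaster_field`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_disaster_field <- function(field, dir) {
  stopifnot(inherits(field, "disaster_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(field$occupancy, file.path(dir, "occupancy.csv"),
                     sep = ",", row.names = FALSE, col.names = TRUE)
  utils::write.csv(as.data.frame(field$events), file.path(dir, "events.csv"),
                   row.names = FALSE)
  meta <- list(scenario = field$scenario, level = field$level,
               sigma_x = field$sigma$sigma_x, sigma_t = field$sigma$sigma_t,
               n_total = field$n_total, m_clusters = field$m_clusters,
               x_extent = field$x_extent, t_extent = field$t_extent)
  jsonlite::write_json(meta, file.path(dir, "field.json"), auto_unbox = TRUE)
  invisible(dir)
}
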