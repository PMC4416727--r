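#' Experiment configuration
#'
#' Bundles everything a sweep needs: which disaster scenarios and
#' correlation-strength levels to run, which rewiring fractions, the network
#' and replicate budgets, the dynamics parameters, the disaster-generator
#' parameters and the master seed. All randomness in a sweep is derived from
#' the master seed, so identical configurations give identical results.
#'
#' @param scenarios character vector of scenario labels (see
#'   [osotua_scenarios()]). The `"none"` scenario is always run at level 1
#'   only.
#' @param levels integer vector of correlation-strength indices (default
#'   `1:7`: sigma_x halves from 64 down to 1).
#' @param beta rewiring fractions (default `c(0.2, 0.8)`).
#' @param n_nodes network size; one node per lattice location (default 100).
#' @param k ring-lattice degree (default 4).
#' @param n_networks random network realizations per cell (default 100).
#' @param n_reps simulation repetitions per network (default 1000).
#' @param params a [sim_params()] object.
#' @param n_total,m_clusters disaster-generator totals (defaults 500 and 40).
#' @param network_type `"ws"` (ring-rewired) or `"powerlaw"`.
#' @param regenerate_field draw a fresh disaster field for every repetition
#'   (default `TRUE`), or keep one field per network.
#' @param seed master seed.
#' @param preset `"paper"` (100 networks x 1000 reps) or `"ci"`
#'   (20 networks x 100 reps); overrides `n_networks`/`n_reps`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(scenarios = osotua_scenarios(),
                              levels = 1:7, beta = c(0.2, 0.8),
                              n_nodes = 100L, k = 4L,
                              n_networks = 100L, n_reps = 1000L,
                              params = sim_params(),
                              n_total = 500L, m_clusters = 40L,
                              network_type = c("ws", "powerlaw"),
                              regenerate_field = TRUE,
                              seed = 1L, preset = NULL) {
  scenarios <- match.arg(scenarios, osotua_scenarios(), several.ok = TRUE)
  network_type <- match.arg(network_type)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "ci"))
    if (preset == "paper") { n_networks <- 100L; n_reps <- 1000L }
    else                   { n_networks <- 20L;  n_reps <- 100L }
  }
  stopifnot(all(levels >= 1), n_nodes >= 10, n_networks >= 1, n_reps >= 1,
            n_total >= m_clusters, m_clusters >= 1)
  structure(list(scenarios = scenarios, levels = as.integer(levels),
                 beta = beta, n_nodes = as.integer(n_nodes),
                 k = as.integer(k), n_networks = as.integer(n_networks),
                 n_reps = as.integer(n_reps), params = params,
                 n_total = as.integer(n_total),
                 m_clusters = as.integer(m_clusters),
                 network_type = network_type,
                 regenerate_field = isTRUE(regenerate_field),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# (scenario, level) cells of a config; "none" collapses to level 1
.config_cells <- function(config, beta = config$beta) {
  cells <- expand.grid(scenario = config$scenarios, level = config$levels,
                       beta = beta, stringsAsFactors = FALSE)
  none <- cells$scenario == "none"
  cells$level[none] <- 1L
  unique(cells)
}

.derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

# NA-safe grouping key for cell columns (isolated runs carry beta = NA)
.cell_key <- function(df, by) {
  factor(do.call(paste, c(lapply(df[by], function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "<NA>"
    x
  }), sep = "\r")))
}

.build_network <- function(config) {
  if (config$network_type == "powerlaw") {
    powerlaw_network(config$n_nodes, mean_degree = config$k)
  } else {
    ring_lattice(config$n_nodes, config$k)  # rewired per-cell by beta
  }
}

# Run one (scenario, level, beta-or-isolated) cell; returns per-network records
.run_cell <- function(config, scenario, level, beta, seeds, isolated = FALSE) {
  p <- config$params
  sig <- scenario_sigmas(scenario, level)
  recs <- vector("list", config$n_networks)
  gpy <- numeric(p$t_years)
  for (w in seq_len(config$n_networks)) {
    set.seed(seeds[w])
    if (isolated) {
      n <- config$n_nodes
      adj_flat <- integer(0); adj_ptr <- integer(n + 1L)
      spatial <- 0:(n - 1L)
    } else {
      net <- .build_network(config)
      if (config$network_type == "ws") net <- rewire_network(net, beta)
      adj <- adjacency_list(net)
      adj_flat <- unlist(adj, use.names = FALSE)
      adj_ptr <- cumsum(c(0L, lengths(adj)))
      spatial <- net$spatial_index
      n <- net$n
    }
    res <- cpp_run_reps(n, adj_flat, as.integer(adj_ptr),
                        as.integer(spatial), config$n_nodes, p$t_years,
                        config$n_total, config$m_clusters,
                        sig$sigma_x, sig$sigma_t, config$n_reps,
                        p$t_years, p$initial_herd, p$threshold,
                        p$growth_mean, p$growth_sd, p$loss_mean, p$loss_sd,
                        p$death_lag, p$check_pre_gift, p$retries,
                        p$ask_trigger == "need", !isolated,
                        config$regenerate_field)
    gpy <- gpy + res$gifts_per_year_sum
    recs[[w]] <- data.frame(
      scenario = scenario, level = level,
      beta = if (isolated) NA_real_ else beta,
      network = w,
      survival = mean(res$survival),
      survivors = sum(res$survivors),
      herd_sum = sum(res$herd_sum),
      eff_disasters = mean(res$effective_disasters),
      realized_events = mean(res$realized_events),
      gifts = sum(res$gifts_per_year_sum) / config$n_reps
    )
  }
  list(records = do.call(rbind, recs),
       gifts_per_year = gpy / (config$n_networks * config$n_reps))
}

#' Aggregate per-replicate records into cell means and standard errors
#'
#' Groups a record frame by the cell keys and returns, for every numeric
#' column, the across-record mean and its standard error (0 for a single
#' record). Used by [run_sweep()] on per-network summaries; usable on any
#' per-replicate record set.
#'
#' @param records data frame of records.
#' @param by character vector of grouping columns present in `records`.
#' @return data frame with one row per cell and `mean_*` / `se_*` columns.
#' @export
aggregate_results <- function(records,
                              by = intersect(c("scenario", "level", "beta"),
                                             names(records))) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  vals <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                  c(by, "network", "rep"))
  grp <- .cell_key(records, by)
  out <- unique(records[by])
  out <- out[order(.cell_key(out, by)), , drop = FALSE]
  for (v in vals) {
    m <- tapply(records[[v]], grp, mean)
    s <- tapply(records[[v]], grp,
                function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0)
    out[[paste0("mean_", v)]] <- as.numeric(m)
    out[[paste0("se_", v)]] <- as.numeric(s)
  }
  rownames(out) <- NULL
  out
}

#' Run the full scenario sweep
#'
#' For every (scenario, level, beta) cell, generates `n_networks` random
#' networks and runs `n_reps` simulation repetitions on each (a fresh
#' disaster field per repetition by default), then aggregates survival rate,
#' surviving herd size, effective disasters and gift counts. Sub-seeds for
#' every cell and network are derived from the master seed, so the sweep is
#' fully reproducible.
#'
#' @param config an [experiment_config()].
#' @param isolated run the unconnected-nodes baseline instead of networked
#'   cells (used by [isolated_baseline()]).
#' @param verbose print per-cell progress.
#' @return a data frame of class `osotua_results`, one row per cell, with
#'   `mean_survival`, `mean_surviving_herd` (pooled over all survivors),
#'   `mean_eff_disasters`, `mean_gifts` and standard errors across networks;
#'   per-cell mean gifts-per-year vectors in `attr(, "gifts_per_year")` and
#'   the per-network records in `attr(, "records")`.
#' @export
run_sweep <- function(config, isolated = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cells <- .config_cells(config, beta = if (isolated) NA_real_ else config$beta)
  seeds <- matrix(.derive_seeds(config$seed,
                                nrow(cells) * config$n_networks),
                  nrow = nrow(cells))
  all_recs <- vector("list", nrow(cells))
  gpy <- vector("list", nrow(cells))
  labels <- character(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]; lv <- cells$level[ci]; be <- cells$beta[ci]
    if (verbose) {
      message(sprintf("cell %d/%d: %s level %d%s", ci, nrow(cells), sc, lv,
                      if (isolated) " (isolated)" else sprintf(" beta %g", be)))
    }
    cell <- .run_cell(config, sc, lv, be, seeds[ci, ], isolated = isolated)
    all_recs[[ci]] <- cell$records
    gpy[[ci]] <- cell$gifts_per_year
    labels[ci] <- paste(sc, lv, if (isolated) "isolated" else be, sep = "_")
  }
  names(gpy) <- labels
  records <- do.call(rbind, all_recs)
  out <- aggregate_results(records)
  # pooled mean surviving herd: total surviving cattle / total survivors
  key <- .cell_key(records, c("scenario", "level", "beta"))
  pool <- tapply(records$herd_sum, key, sum) /
          tapply(records$survivors, key, sum)
  # per-network pooled means give the spread
  net_mean <- records$herd_sum / pmax(records$survivors, 1)
  se_pool <- tapply(net_mean, key,
                    function(x) if (length(x) > 1)
                      stats::sd(x) / sqrt(length(x)) else 0)
  out$mean_surviving_herd <- as.numeric(pool)
  out$se_surviving_herd <- as.numeric(se_pool)
  attr(out, "gifts_per_year") <- gpy
  attr(out, "records") <- records
  attr(out, "config") <- config
  class(out) <- c("osotua_results", "data.frame")
  out
}

#' Isolated-node baseline sweep
#'
#' The same sweep as [run_sweep()] with unconnected nodes (no gift-giving
#' scheme): one node per ring location, no network, no transfers. The
#' benchmark against which the networked survival gain is measured.
#'
#' @inheritParams run_sweep
#' @return an `osotua_results` data frame (the `beta` column is `NA`).
#' @export
isolated_baseline <- function(config, verbose = FALSE) {
  run_sweep(config, isolated = TRUE, verbose = verbose)
}

#' @export
print.osotua_results <- function(x, ...) {
  cat("Osotua sweep results (", nrow(x), "cells )\n")
  cols <- intersect(c("scenario", "level", "beta", "mean_survival",
                      "se_survival", "mean_surviving_herd",
                      "mean_eff_disasters", "mean_gifts"), names(x))
  print.data.frame(x[cols], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Flow-network metric sweep
#'
#' Runs replicate simulations per (scenario, beta) cell, builds the activated
#' gift-flow network of every run, computes its metrics, and averages across
#' replicates. Each replicate draws a fresh network and disaster field. With
#' `null_reps > 0`, clustering and cycle counts of degree-preserving
#' randomizations are averaged in as the null baseline.
#'
#' @param config an [experiment_config()]; its `scenarios` and `beta` define
#'   the cells. Scenario `"none"` runs at level 1, every other scenario at
#'   `max(config$levels)` (strong correlation), matching the four
#'   correlation cases.
#' @param n_flow_reps replicate simulations per cell (default 200).
#' @param null_reps randomized networks per replicate (default 0: skip).
#' @param method cycle-count method (see [count_cycles()]).
#' @param max_cycles enumeration cap.
#' @param verbose print progress.
#' @return data frame with one row per cell: mean `avg_path_length`,
#'   `avg_degree`, `clustering`, `n_cycles` (and `null_clustering`,
#'   `null_cycles` when `null_reps > 0`) with standard errors.
#' @export
flow_metric_sweep <- function(config, n_flow_reps = 200L, null_reps = 0L,
                              method = c("simple_directed", "cyclomatic"),
                              max_cycles = 1e5, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  method <- match.arg(method)
  lvl_strong <- max(config$levels)
  cells <- expand.grid(scenario = config$scenarios, beta = config$beta,
                       stringsAsFactors = FALSE)
  cells$level <- ifelse(cells$scenario == "none", 1L, lvl_strong)
  seeds <- matrix(.derive_seeds(config$seed, nrow(cells) * n_flow_reps),
                  nrow = nrow(cells))
  p <- config$params
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]; be <- cells$beta[ci]; lv <- cells$level[ci]
    if (verbose) message(sprintf("flow cell %s beta %g", sc, be))
    met <- matrix(NA_real_, n_flow_reps, 6)
    for (r in seq_len(n_flow_reps)) {
      set.seed(seeds[ci, r])
      net <- .build_network(config)
      if (config$network_type == "ws") net <- rewire_network(net, be)
      field <- generate_disaster_field(sc, lv, config$n_total,
                                       config$m_clusters,
                                       x_extent = config$n_nodes,
                                       t_extent = p$t_years)
      sim <- run_simulation(field, net, p, engine = "compiled")
      flow <- build_flow_network(sim$gifts, net$n, status = sim$alive)
      met[r, 1] <- average_path_length(flow)
      met[r, 2] <- average_degree(flow)
      met[r, 3] <- clustering_coefficient(flow)
      met[r, 4] <- as.numeric(count_cycles(flow, method, max_cycles))
      if (null_reps > 0) {
        nm <- null_model_metrics(flow, reps = null_reps, method = method,
                                 max_cycles = max_cycles)
        met[r, 5] <- nm$null_clustering
        met[r, 6] <- nm$null_cycles
      }
    }
    row <- data.frame(scenario = sc, level = lv, beta = be,
                      avg_path_length = mean(met[, 1]),
                      avg_degree = mean(met[, 2]),
                      clustering = mean(met[, 3]),
                      se_clustering = stats::sd(met[, 3]) / sqrt(n_flow_reps),
                      n_cycles = mean(met[, 4]),
                      se_n_cycles = stats::sd(met[, 4]) / sqrt(n_flow_reps))
    if (null_reps > 0) {
      row$null_clustering <- mean(met[, 5])
      row$null_cycles <- mean(met[, 6])
    }
    rows[[ci]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write sweep results to CSV and metadata JSON
#'
#' Writes `results.csv` (the cell table), `gifts_per_year.csv` (one row per
#' cell, one column per year) and `run_meta.json` (seed and budgets).
#'
#' @param results an `osotua_results` object from [run_sweep()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(results, dir) {
  stopifnot(inherits(results, "osotua_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(results), file.path(dir, "results.csv"),
                   row.names = FALSE)
  gpy <- attr(results, "gifts_per_year")
  if (!is.null(gpy)) {
    m <- do.call(rbind, gpy)
    colnames(m) <- paste0("year", seq_len(ncol(m)))
    utils::write.csv(data.frame(cell = names(gpy), m),
                     file.path(dir, "gifts_per_year.csv"), row.names = FALSE)
  }
  config <- attr(results, "config")
  meta <- list(seed = config$seed, n_networks = config$n_networks,
               n_reps = config$n_reps, n_nodes = config$n_nodes,
               scenarios = config$scenarios, levels = config$levels,
               beta = config$beta)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
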