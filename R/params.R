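#' Simulation parameters
#'
#' Collects the herd-dynamics parameters of the Osotua agent simulation.
#' Herds grow by a random percentage each year; a disaster removes a random
#' fraction of the herd; a herd below the minimum sustainable size may be
#' restored to exactly that size by a partner's gift; a node whose herd stays
#' below the minimum for `death_lag` consecutive years is eliminated.
#'
#' @param t_years simulation horizon in years (default 50).
#' @param initial_herd starting herd size of every agent, cattle (default 70).
#' @param threshold minimum sustainable herd size, cattle (default 64).
#' @param growth_mean mean annual herd growth fraction (default 0.03).
#' @param growth_sd standard deviation of annual growth (default 0.03);
#'   growth draws are truncated below at -1 so herds stay non-negative.
#' @param loss_mean mean fraction of the herd lost in a disaster year
#'   (default 0.30).
#' @param loss_sd standard deviation of the loss fraction (default 0.10);
#'   loss draws are clipped to `[0, 1]`.
#' @param death_lag consecutive below-threshold years before a node is
#'   eliminated (default 2).
#' @param check_pre_gift if `TRUE`, the end-of-year survival check uses the
#'   herd as it stood before gifts were received. The default (`FALSE`)
#'   checks the post-gift herd, so a gift that restores a herd to the
#'   threshold prevents a below-threshold year.
#' @param retries number of additional partners a refused asker may try in
#'   the same year (default 0: one request per needy node per year).
#' @param ask_trigger when may a node ask for cattle? `"need"` (default): any
#'   node below the threshold asks once a year, whether or not it was struck
#'   this year (a refused asker keeps asking in later years). `"loss"`: a
#'   request is made only in a year in which a disaster loss leaves the herd
#'   below the threshold — the request is part of the disaster response.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(t_years = 50L, initial_herd = 70, threshold = 64,
                       growth_mean = 0.03, growth_sd = 0.03,
                       loss_mean = 0.30, loss_sd = 0.10,
                       death_lag = 2L, check_pre_gift = FALSE,
                       retries = 0L, ask_trigger = c("need", "loss")) {
  ask_trigger <- match.arg(ask_trigger)
  stopifnot(threshold > 0, initial_herd >= threshold,
            loss_mean >= 0, loss_mean <= 1,
            growth_sd >= 0, loss_sd >= 0,
            t_years >= 1, death_lag >= 1, retries >= 0)
  structure(list(t_years = as.integer(t_years),
                 initial_herd = initial_herd, threshold = threshold,
                 growth_mean = growth_mean, growth_sd = growth_sd,
                 loss_mean = loss_mean, loss_sd = loss_sd,
                 death_lag = as.integer(death_lag),
                 check_pre_gift = isTRUE(check_pre_gift),
                 retries = as.integer(retries),
                 ask_trigger = ask_trigger),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Osotua simulation parameters: %d years, initial herd %g, threshold %g\n",
    x$t_years, x$initial_herd, x$threshold))
  cat(sprintf("  growth ~ N(%g, %g^2) (trunc. at -1), loss ~ N(%g, %g^2) (clipped to [0,1])\n",
              x$growth_mean, x$growth_sd, x$loss_mean, x$loss_sd))
  cat(sprintf("  elimination after %d consecutive below-threshold years\n",
              x$death_lag))
  invisible(x)
}
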