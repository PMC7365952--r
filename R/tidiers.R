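#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' One row per calibrated parameter with its estimate, starting value and
#' bounds.
#'
#' @param x A `stover_calibration` from [calibrate_reactor()].
#' @param ... Unused.
#'
#' @return A tibble with columns `term`, `estimate`, `start`, `lower`,
#'   `upper`, `at_bound`.
#' @export
tidy.stover_calibration <- function(x, ...) {
  est <- unname(x$fitted)
  tol <- 1e-6 * pmax(abs(est), 1)
  tibble::tibble(
    term = names(x$fitted),
    estimate = est,
    start = unname(x$start),
    lower = x$specs$lower,
    upper = x$specs$upper,
    at_bound = (est - x$specs$lower < tol) | (x$specs$upper - est < tol))
}

#' One-row summary of a calibration fit
#'
#' @param x A `stover_calibration`.
#' @param ... Unused.
#'
#' @return A tibble with the initial and final cost, iteration count,
#'   convergence flag, temperature MAE (degrees C) and dry-matter-loss
#'   relative error (percent).
#' @export
glance.stover_calibration <- function(x, ...) {
  tibble::tibble(
    cost_initial = x$cost_trajectory[1],
    cost_final = utils::tail(x$cost_trajectory, 1),
    iterations = x$iterations,
    converged = x$converged,
    mae_temperature = x$metrics$mae_temperature,
    relative_error_dml = x$metrics$relative_error_dml,
    n_residuals = length(x$residuals))
}

#' Tidy a simulation into a long heat-flow table
#'
#' @param x A `stover_simulation`.
#' @param ... Unused.
#'
#' @return A long tibble with `time_days`, `component`, `value_W`.
#' @export
tidy.stover_simulation <- function(x, ...) {
  s <- x$series[, c("time_days", "q_microbial_W", "q_conduction_W",
                    "q_convection_W", "q_evaporation_W", "q_net_W")]
  out <- tidyr::pivot_longer(s, -"time_days", names_to = "component",
                             values_to = "value_W")
  out$component <- sub("^q_", "", sub("_W$", "", out$component))
  out
}

#' One-row summary of a simulation
#'
#' @param x A `stover_simulation`.
#' @param ... Unused.
#'
#' @return A tibble with the final temperature, peak temperature, final
#'   substrate degraded, cumulative CO2 and microbial heat, and dry matter
#'   loss.
#' @export
glance.stover_simulation <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  tibble::tibble(
    duration_days = x$config$duration_days,
    final_temperature_C = s$temperature_C[n],
    peak_temperature_C = max(s$temperature_C),
    substrate_degraded_g = s$s_deg_total[n],
    co2_g = s$co2_g[n],
    microbial_heat_J = s$heat_microbial_J[n],
    dry_matter_loss_pct = dry_matter_loss(x))
}
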