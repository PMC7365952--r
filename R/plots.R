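#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated reactor run
#'
#' @param object A `stover_simulation`.
#' @param what One of `"temperature"` (biomass and jacket traces),
#'   `"substrate"` (per-phase and total cumulative substrate),
#'   `"heat"` (decomposed heat flows) or `"factors"` (dimensionless
#'   environmental factors).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.stover_simulation <- function(object,
                                       what = c("temperature", "substrate",
                                                "heat", "factors"), ...) {
  what <- match.arg(what)
  s <- object$series

  if (what == "temperature") {
    long <- tidyr::pivot_longer(
      s[, c("time_days", "temperature_C", "jacket_temp_C")],
      -"time_days", names_to = "series", values_to = "temp")
    long$series <- c(temperature_C = "stover",
                     jacket_temp_C = "jacket")[long$series]
    return(ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$temp,
                                              colour = .data$series)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "storage time (days)",
                           y = "temperature (°C)", colour = NULL))
  }
  if (what == "substrate") {
    cols <- grep("^s_deg_", names(s), value = TRUE)
    long <- tidyr::pivot_longer(s[, c("time_days", cols)], -"time_days",
                                names_to = "pool", values_to = "mass_g")
    long$pool <- sub("^s_deg_", "phase ", long$pool)
    long$pool[long$pool == "phase total"] <- "total"
    return(ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$mass_g,
                                              colour = .data$pool)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "storage time (days)",
                           y = "cumulative substrate degraded (g)",
                           colour = NULL))
  }
  if (what == "heat") {
    long <- tidy.stover_simulation(object)
    return(ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$value_W,
                                              colour = .data$component)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "storage time (days)", y = "heat flow (W)",
                           colour = NULL))
  }
  cols <- c("f_moisture", grep("^f_temperature_", names(s), value = TRUE))
  long <- tidyr::pivot_longer(s[, c("time_days", cols)], -"time_days",
                              names_to = "factor", values_to = "value")
  long$factor <- sub("^f_temperature_", "f(T) phase ", long$factor)
  long$factor[long$factor == "f_moisture"] <- "f(M)"
  ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$value,
                                     colour = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "storage time (days)", y = "dimensionless factor",
                  colour = NULL)
}

#' Plot a calibration fit against its observations
#'
#' @param object A `stover_calibration`.
#' @param what `"temperature"` or `"substrate"`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.stover_calibration <- function(object,
                                        what = c("temperature", "substrate"),
                                        ...) {
  what <- match.arg(what)
  s <- object$sim$series
  obs <- split_observed(object$observed)
  if (what == "temperature") {
    stopifnot(!is.null(obs$temperature))
    ggplot2::ggplot() +
      ggplot2::geom_point(data = obs$temperature,
                          ggplot2::aes(.data$time_days, .data$stover_temp_C),
                          size = 0.3, alpha = 0.3) +
      ggplot2::geom_line(data = s,
                         ggplot2::aes(.data$time_days, .data$temperature_C),
                         colour = "firebrick") +
      ggplot2::labs(x = "storage time (days)", y = "temperature (°C)")
  } else {
    stopifnot(!is.null(obs$substrate))
    ggplot2::ggplot() +
      ggplot2::geom_point(data = obs$substrate,
                          ggplot2::aes(.data$time_days, .data$substrate_g),
                          size = 0.3, alpha = 0.3) +
      ggplot2::geom_line(data = s,
                         ggplot2::aes(.data$time_days, .data$s_deg_total),
                         colour = "firebrick") +
      ggplot2::labs(x = "storage time (days)",
                    y = "cumulative substrate degraded (g)")
  }
}
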