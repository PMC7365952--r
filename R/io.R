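ts_columns <- c("time_days", "stover_temp_C", "jacket_temp_C", "substrate_g",
                "co2_frac", "condensate_kg")

#' Read an observation time-series table
#'
#' Comma-separated, header row, `.` decimal, UTF-8. The schema is fixed by
#' column name: `time_days` (required, strictly increasing) plus any of
#' `stover_temp_C`, `jacket_temp_C`, `substrate_g`, `co2_frac`,
#' `condensate_kg`. Unknown columns and malformed cells are rejected with
#' an error naming the offender.
#'
#' @param path File path.
#'
#' @return A tibble with the validated columns.
#' @export
read_timeseries <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_timeseries(df, context = path)
}

validate_timeseries <- function(df, context = "time series") {
  unknown <- setdiff(names(df), ts_columns)
  if (length(unknown) > 0)
    stop(context, ": unknown column(s) ", paste(unknown, collapse = ", "),
         "; expected a subset of {", paste(ts_columns, collapse = ", "), "}",
         call. = FALSE)
  if (!"time_days" %in% names(df))
    stop(context, ": required column time_days is missing", call. = FALSE)
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))[1]
      stop(context, ": column ", col, " is not numeric (first bad row: ",
           bad %||% NA, ")", call. = FALSE)
    }
  }
  if (anyNA(df$time_days))
    stop(context, ": time_days contains missing values", call. = FALSE)
  dt <- diff(df$time_days)
  if (any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1
    stop(context, ": time_days must be strictly increasing (violated at row ",
         row, ")", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write an observation time-series table
#'
#' Full-precision CSV companion to [read_timeseries()]; a write/read round
#' trip preserves values exactly.
#'
#' @param df Table with a `time_days` column.
#' @param path File path.
#'
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path) {
  validate_timeseries(df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' Assembles a fully defaulted set of model objects from a structured
#' configuration file. Recognized top-level keys: `reactor` (either the
#' scalar fields of [reactor_config()] plus a `moisture` block, or
#' `fixture: <1..4>`), `phases` (list of phase blocks with `t_min`,
#' `t_opt`, `t_max`, `k_d`, `pool_fraction`, `lag_days`), `yields`,
#' `thermal`, `controller`, `air`, `solver`, `calibration` (rows for
#' [parameter_specs()]) and `paths`. Unknown keys anywhere are rejected;
#' bound violations are reported with the calibration-box context.
#'
#' @param path File path (`.yml`, `.yaml` or `.json`).
#'
#' @return A named list of class `run_config` with elements `reactor`,
#'   `phases`, `yields`, `thermal`, `controller`, `air`, `solver`,
#'   `calibration` (tibble or `NULL`), `paths`, and `raw` (the parsed
#'   file).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build_run_config(raw, context = path)
}

take <- function(block, allowed, context) {
  if (is.null(block)) return(list())
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0)
    stop(context, ": unknown key(s) ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  block
}

build_run_config <- function(raw, context = "config") {
  top <- take(raw, c("reactor", "phases", "yields", "thermal", "controller",
                     "air", "solver", "calibration", "paths"), context)

  rb <- take(top$reactor, c("fixture", "t_initial", "t_ambient",
                            "loading_dry_matter", "airflow", "moisture",
                            "duration_days", "cross_section", "s0_fraction"),
             paste0(context, ": reactor"))
  if (!is.null(rb$fixture)) {
    fx <- reactor_fixtures()
    if (!rb$fixture %in% 1:4)
      stop(context, ": reactor fixture must be 1..4", call. = FALSE)
    reactor <- fx[[rb$fixture]]
    # scalar fields given alongside a fixture override the fixture's values
    for (f in intersect(names(rb), c("t_initial", "t_ambient",
                                     "loading_dry_matter", "airflow",
                                     "duration_days", "cross_section",
                                     "s0_fraction")))
      reactor[[f]] <- rb[[f]]
  } else {
    mb <- take(rb$moisture, c("m_initial", "m_final", "duration_days",
                              "m_half"), paste0(context, ": moisture"))
    moist <- do.call(moisture_model, mb)
    args <- rb[setdiff(names(rb), "moisture")]
    args$moisture <- moist
    reactor <- do.call(reactor_config, args)
  }

  phases <- if (is.null(top$phases)) {
    biphasic_scenario()$phases
  } else {
    lapply(seq_along(top$phases), function(i) {
      pb <- take(top$phases[[i]], c("t_min", "t_opt", "t_max", "k_d",
                                    "pool_fraction", "lag_days"),
                 paste0(context, ": phase ", i))
      growth_phase(cardinal_temperatures(pb$t_min, pb$t_opt, pb$t_max),
                   k_d = pb$k_d, pool_fraction = pb$pool_fraction %||% 1,
                   lag_days = pb$lag_days %||% 0)
    })
  }
  validate_phases(phases)

  yields <- do.call(yield_coefficients,
                    take(top$yields, c("y_co2", "y_m"),
                         paste0(context, ": yields")))
  thermal <- do.call(thermal_params,
                     take(top$thermal, c("k_cond", "area", "length", "v_ss",
                                         "rho_ss", "c_ss", "h_vap",
                                         "h_conv_override"),
                          paste0(context, ": thermal")))
  controller <- do.call(jacket_controller,
                        take(top$controller, c("offset",
                                               "activation_threshold",
                                               "floor_temperature"),
                             paste0(context, ": controller")))
  air <- do.call(air_properties,
                 take(top$air, c("k_air", "nu", "pr", "rho_air", "cp_air"),
                      paste0(context, ": air")))
  solver <- do.call(solver_options,
                    take(top$solver, c("rel_tol", "abs_tol", "max_step",
                                       "output_interval"),
                         paste0(context, ": solver")))

  calibration <- NULL
  if (!is.null(top$calibration)) {
    cal <- top$calibration
    rows <- lapply(seq_along(cal), function(i) {
      cb <- take(cal[[i]], c("name", "baseline", "lower", "upper"),
                 paste0(context, ": calibration entry ", i))
      tibble::tibble(name = cb$name, baseline = cb$baseline,
                     lower = cb$lower %||% -Inf, upper = cb$upper %||% Inf)
    })
    calibration <- do.call(rbind, rows)
    bad <- calibration$lower > calibration$baseline |
      calibration$baseline > calibration$upper
    if (any(bad))
      stop(context, ": calibration baseline outside [lower, upper] for ",
           paste(calibration$name[bad], collapse = ", "),
           " (each parameter must start inside its calibration box)",
           call. = FALSE)
    # kinetic sanity: any cardinal-temperature triple implied by the boxes
    # must remain orderable
    chk <- stats::setNames(calibration$baseline, calibration$name)
    for (nm in names(chk)) {
      if (grepl("^t_opt", nm)) {
        ph <- phases[[1]]
        if (chk[[nm]] >= ph$cardinals$t_max || chk[[nm]] <= ph$cardinals$t_min)
          stop(context, ": ", nm, " baseline ", chk[[nm]],
               " violates t_min < t_opt < t_max for the configured phases",
               call. = FALSE)
      }
    }
  }

  structure(list(reactor = reactor, phases = phases, yields = yields,
                 thermal = thermal, controller = controller, air = air,
                 solver = solver, calibration = calibration,
                 paths = top$paths, raw = raw),
            class = "run_config")
}

# Serializes the resolved configuration of a run for provenance.
resolved_config <- function(x) {
  strip <- function(o) if (is.list(o)) lapply(unclass(o), strip) else o
  list(config = strip(x$config), phases = lapply(x$phases, strip),
       yields = strip(x$yields), thermal = strip(x$thermal),
       controller = strip(x$controller))
}

#' Write a result object to disk
#'
#' Simulations are written as a CSV of the output series plus a JSON
#' sidecar (`<path>.config.json`) carrying the fully resolved
#' configuration; calibrations and validation reports are written as a
#' single structured JSON report.
#'
#' @param result A `stover_simulation`, `stover_calibration` or error
#'   report tibble.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  UseMethod("write_result")
}

#' @export
write_result.stover_simulation <- function(result, path) {
  readr::write_csv(result$series, path, progress = FALSE)
  jsonlite::write_json(resolved_config(result),
                       paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_result.stover_calibration <- function(result, path) {
  report <- list(
    fitted = as.list(result$fitted),
    start = as.list(result$start),
    bounds = list(lower = stats::setNames(as.list(result$specs$lower),
                                          result$specs$name),
                  upper = stats::setNames(as.list(result$specs$upper),
                                          result$specs$name)),
    cost_trajectory = result$cost_trajectory,
    converged = result$converged,
    message = result$message,
    iterations = result$iterations,
    metrics = as.list(result$metrics),
    resolved = resolved_config(result$sim))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_result.data.frame <- function(result, path) {
  jsonlite::write_json(as.list(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
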