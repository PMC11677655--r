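# shared config validation; every offending field is reported at once
validate_config <- function(config, required_paths) {
  problems <- character(0)
  for (field in required_paths) {
    p <- config[[field]]
    if (is.null(p)) {
      problems <- c(problems, paste0("missing field '", field, "'"))
    } else if (!file.exists(p)) {
      problems <- c(problems, paste0("'", field, "' path does not exist: ",
                                     p))
    }
  }
  num_in <- function(field, lo, hi, default) {
    v <- config[[field]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      problems <<- c(problems, paste0("'", field, "' must be a number in [",
                                      lo, ", ", hi, "]"))
      return(default)
    }
    v
  }
  config$temperature_k <- num_in("temperature_k", 1, 1e4, 298.15)
  config$min_ov_share <- num_in("min_ov_share", 0, 1, 0.001)
  config$fraction_cap <- num_in("fraction_cap", 0, 1.05, 1)
  config$max_iterations <- num_in("max_iterations", 1, 1e6, 2000)
  config$sse_tolerance <- num_in("sse_tolerance", 0, 1, 1e-10)
  config$seed <- num_in("seed", -2^31, 2^31, 1)
  if (length(problems) > 0) {
    na_stop(paste0("invalid configuration:\n  - ",
                   paste(problems, collapse = "\n  - ")),
            "invalid_config")
  }
  config
}

write_provenance <- function(dir, config, stage) {
  prov <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("nanoaroma")),
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")],
    config_hash = sum(utf8ToInt(paste(
      names(config), vapply(config, function(v) paste(format(v),
                                                      collapse = ","),
                            character(1)),
      collapse = ";"))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(dir, paste0(stage,
                                                   "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the perfumery-radar stage on files
#'
#' Reads a compound registry and a liquid composition, runs the full
#' odor-value radar chain, and writes `radar.csv`
#' (`family,odor_value,normalized_value`), `radar_exclusions.csv`, and a
#' machine-readable provenance record to the output directory.
#'
#' @param config Named list: `registry` and `composition` (paths,
#'   required), `output_dir` (default `"."`), `temperature_k` (default
#'   298.15), `min_ov_share` (default 0.001), `seed` (recorded in the
#'   provenance only; the stage is deterministic), `write_figure` (write
#'   `radar.pdf`, default `FALSE`).
#' @return The `radar_result`, invisibly.
#' @export
run_radar <- function(config) {
  config <- validate_config(config, c("registry", "composition"))
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_registry(config$registry)
  composition <- read_composition(config$composition)
  result <- radar_from_composition(composition, registry,
                                   temperature = config$temperature_k,
                                   min_ov_share = config$min_ov_share)
  radar <- data.frame(
    family = OLFACTORY_FAMILIES,
    odor_value = unname(result$family_odor_values[OLFACTORY_FAMILIES]),
    normalized_value = unname(result$profile$values[OLFACTORY_FAMILIES])
  )
  utils::write.csv(radar, file.path(out_dir, "radar.csv"),
                   row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(result$exclusions,
                   file.path(out_dir, "radar_exclusions.csv"),
                   row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(dominant_family = dominant_family(result$profile),
         degenerate = result$profile$degenerate,
         normalized = as.list(result$profile$values)),
    file.path(out_dir, "radar.json"), auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$write_figure)) {
    ggplot2::ggsave(file.path(out_dir, "radar.pdf"), plot_radar(result),
                    width = 6, height = 6)
  }
  write_provenance(out_dir, config, "radar")
  invisible(result)
}

#' Run the release-kinetics stage on files
#'
#' Reads a release series, normalizes it to fractions, fits the power-law
#' model, classifies the transport mechanism, and writes
#' `release_fit.csv`/`release_fit.json` (the six fit statistics plus the
#' mechanism label), a fitted-curve table for plotting, and a provenance
#' record.
#'
#' @param config Named list: `release` (path, required), `output_dir`,
#'   `m_infinity` (else plateau-estimated), `fraction_cap`,
#'   `max_iterations`, `sse_tolerance`, `geometry` (default `"sphere"`),
#'   `mechanism_tolerance` (default 0.01), `seed` (provenance only).
#' @return List with `fit` (a `peppas_fit`) and `mechanism` (a
#'   `mechanism_call`), invisibly.
#' @export
run_release <- function(config) {
  config <- validate_config(config, "release")
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curve <- read_release(config$release, m_infinity = config$m_infinity)
  fit <- fit_peppas(curve, fraction_cap = config$fraction_cap,
                    max_iterations = config$max_iterations,
                    sse_tolerance = config$sse_tolerance)
  geometry <- if (is.null(config$geometry)) "sphere" else config$geometry
  tol <- if (is.null(config$mechanism_tolerance)) 0.01 else
    config$mechanism_tolerance
  mech <- classify_mechanism(fit$n, geometry = geometry, tolerance = tol)
  report <- data.frame(
    k = fit$k, n = fit$n, r_squared = fit$r_squared,
    r_squared_adj = fit$r_squared_adj, sse = fit$sse, rmse = fit$rmse,
    mechanism = mech$label
  )
  utils::write.csv(report, file.path(out_dir, "release_fit.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(as.list(report),
                         list(converged = fit$converged,
                              n_points_used = fit$n_points_used,
                              m_infinity = curve$m_infinity,
                              m_infinity_provenance =
                                curve$m_infinity_provenance)),
                       file.path(out_dir, "release_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  fitted_tab <- data.frame(time_min = curve$times,
                           observed = curve$fractions,
                           fitted = peppas_predict(fit$k, fit$n,
                                                   curve$times))
  utils::write.csv(fitted_tab, file.path(out_dir, "release_curve.csv"),
                   row.names = FALSE, quote = FALSE)
  write_provenance(out_dir, config, "release")
  invisible(list(fit = fit, mechanism = mech))
}
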