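#' Simulate a power-law release curve
#'
#' Generates `fraction(t) = min(1, k * t^n * (1 + eps_t))` with i.i.d.
#' multiplicative Gaussian noise `eps_t ~ N(0, noise_sigma^2)` (the noise a
#' relative GC quantification error would impose). Default parameters are
#' the fitted essential-oil release kinetics (`k = 0.0234` per min^n,
#' `n = 0.45`) sampled at 20 log-spaced times between 1 and 2000 min with
#' 2% relative noise. Output is reproducible for a fixed seed and does not
#' disturb the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param k,n Generating power-law parameters, `> 0`.
#' @param times Explicit time grid (min); overrides the grid arguments.
#' @param n_points,t_min,t_max,spacing Grid specification: `n_points` times
#'   between `t_min` and `t_max`, `"log"` (default) or `"linear"` spacing.
#' @param noise_sigma Relative noise standard deviation, `>= 0`.
#' @return A [release_curve] (with `m_infinity = 1`, `"supplied"`).
#' @export
simulate_release <- function(seed, k = 0.0234, n = 0.45, times = NULL,
                             n_points = 20, t_min = 1, t_max = 2000,
                             spacing = c("log", "linear"),
                             noise_sigma = 0.02) {
  spacing <- match.arg(spacing)
  if (k <= 0 || n <= 0) na_stop("k and n must be > 0.", "invalid_parameter")
  if (noise_sigma < 0) na_stop("noise_sigma must be >= 0.",
                               "invalid_parameter")
  if (is.null(times)) {
    if (n_points < 1) na_stop("empty time grid.", "invalid_parameter")
    times <- if (spacing == "log") {
      exp(seq(log(t_min), log(t_max), length.out = n_points))
    } else {
      seq(t_min, t_max, length.out = n_points)
    }
  }
  if (length(times) == 0) na_stop("empty time grid.", "invalid_parameter")
  clean <- peppas_predict(k, n, times)
  fractions <- with_local_seed(seed, {
    eps <- stats::rnorm(length(times), 0, noise_sigma)
    pmin(1, pmax(0, clean * (1 + eps)))
  })
  release_curve(times, fractions, m_infinity = 1,
                m_infinity_provenance = "supplied")
}

#' Simulate a GC composition table around a base composition
#'
#' Draws the area vector from a Dirichlet distribution centered on the base
#' proportions with precision `concentration`, then rescales to the base
#' total (so the identified/unidentified split is preserved). The default
#' precision 5000 reproduces the few-percent relative replicate scatter
#' typical of triplicate GC area tables.
#'
#' @param seed Integer seed.
#' @param base A [composition_table] to perturb; defaults to the packaged
#'   steam-distilled essential-oil table.
#' @param concentration Dirichlet precision, `> 0`; larger = tighter around
#'   the base.
#' @return A [composition_table] with the same compounds and total.
#' @export
simulate_composition <- function(seed, base = NULL, concentration = 5000) {
  if (is.null(base)) {
    base <- read_composition(system.file("extdata",
                                         "table2_composition.csv",
                                         package = "nanoaroma"))
  }
  stopifnot(inherits(base, "composition_table"))
  if (!is.finite(concentration) || concentration <= 0) {
    na_stop("concentration must be > 0.", "invalid_parameter")
  }
  total <- sum(base$area_percent)
  if (total <= 0) na_stop("base areas are all zero.", "degenerate_input")
  p <- base$area_percent / total
  draws <- with_local_seed(seed, {
    g <- stats::rgamma(length(p), shape = concentration * p, rate = 1)
    g / sum(g)
  })
  composition_table(base$compound, draws * total, base$sd)
}

#' Simulate a DPPH scavenging time series
#'
#' Saturating first-order kinetics
#' `SR(day) = plateau - (plateau - initial) * exp(-rate * day)` plus
#' additive Gaussian noise, converted to absorbance pairs by inverting the
#' scavenging formula with `abs_control = 1`
#' (`abs_sample = 1 - SR / 100`). Defaults emulate a free essential oil
#' that starts near 4.5% scavenging and saturates at 80% within about
#' 20 days, read every 5 days for a month.
#'
#' @param seed Integer seed.
#' @param initial_sr,plateau_sr Initial and asymptotic scavenging, percent,
#'   `0 <= initial <= plateau <= 100`.
#' @param rate First-order approach rate, 1/day, `>= 0`.
#' @param days Sampling days.
#' @param noise_sigma Additive noise on %SR (absolute percentage points).
#' @return Data frame with `time` (days), `abs_sample`, `abs_control`,
#'   `sr_true` (noise-free), `sr` (noisy, as recoverable from the
#'   absorbances).
#' @export
simulate_dpph_series <- function(seed, initial_sr = 4.5, plateau_sr = 80,
                                 rate = 0.25,
                                 days = c(0, 5, 10, 15, 20, 25, 30),
                                 noise_sigma = 1) {
  if (initial_sr < 0 || plateau_sr > 100 || initial_sr > plateau_sr) {
    na_stop("need 0 <= initial_sr <= plateau_sr <= 100.", "invalid_bounds")
  }
  if (rate < 0) na_stop("rate must be >= 0.", "invalid_parameter")
  sr_true <- plateau_sr - (plateau_sr - initial_sr) * exp(-rate * days)
  sr <- with_local_seed(seed, {
    pmin(100, pmax(0, sr_true + stats::rnorm(length(days), 0,
                                             noise_sigma)))
  })
  data.frame(time = days,
             abs_sample = 1 - sr / 100,
             abs_control = 1,
             sr_true = sr_true,
             sr = sr)
}

#' Write a complete synthetic demo dataset
#'
#' Emits, in `dir`, the CSV dialects every ingestion path accepts: the
#' property registry, a perturbed composition table, a simulated release
#' series (in measured-value units, scaled by `m_infinity`), and a DPPH
#' assay table.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all generators.
#' @return Named list of the file paths written, invisibly.
#' @export
write_demo_dataset <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg_src <- system.file("extdata", "table6_properties.csv",
                         package = "nanoaroma")
  paths <- list(
    registry = file.path(dir, "properties.csv"),
    composition = file.path(dir, "composition.csv"),
    release = file.path(dir, "release.csv"),
    dpph = file.path(dir, "dpph.csv")
  )
  file.copy(reg_src, paths$registry, overwrite = TRUE)
  write_composition(simulate_composition(seed), paths$composition)
  curve <- simulate_release(seed)
  utils::write.csv(data.frame(time_min = curve$times,
                              value = curve$fractions),
                   paths$release, row.names = FALSE, quote = FALSE)
  dp <- simulate_dpph_series(seed)
  utils::write.csv(dp[, c("time", "abs_sample", "abs_control")],
                   paths$dpph, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
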