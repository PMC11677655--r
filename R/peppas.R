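#' Power-law (Korsmeyer-Peppas) release fraction
#'
#' `M_t / M_inf = k * t^n`. The value may exceed 1 for large `t`; clipping
#' is the caller's (or the simulator's) concern, not the model's.
#'
#' @param k Release constant, 1/min^n, `> 0`.
#' @param n Kinetic order (release exponent), `> 0`.
#' @param t Time(s), min, `>= 0`.
#' @return Predicted fractional release.
#' @export
peppas_predict <- function(k, n, t) {
  if (k <= 0 || n <= 0) na_stop("k and n must be > 0.", "invalid_parameter")
  if (any(t < 0)) na_stop("t must be >= 0.", "invalid_parameter")
  k * t^n
}

#' Release-curve container
#'
#' @param times Sampling times, min, strictly increasing, `>= 0`.
#' @param fractions Fractional release `M_t / M_inf`; values are allowed to
#'   exceed 1 by up to 5% (noise slack).
#' @param m_infinity The asymptotic normalizing amount, in the original
#'   measurement units.
#' @param m_infinity_provenance `"supplied"` or `"plateau-estimated"`.
#' @return Object of class `release_curve`.
#' @export
release_curve <- function(times, fractions, m_infinity = 1,
                          m_infinity_provenance = "supplied") {
  times <- as.numeric(times)
  fractions <- as.numeric(fractions)
  if (length(times) != length(fractions)) {
    na_stop("times and fractions lengths differ.", "bad_columns")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    na_stop("times must be >= 0 and strictly increasing.", "invalid_times")
  }
  if (any(fractions < 0) || any(fractions > 1.05)) {
    na_stop("fractions must lie in [0, 1.05].", "invalid_fraction")
  }
  structure(list(times = times, fractions = fractions,
                 m_infinity = m_infinity,
                 m_infinity_provenance = m_infinity_provenance),
            class = "release_curve")
}

#' Normalize a measured release series to fractions of the asymptote
#'
#' Divides the measured values by `m_infinity`. When `m_infinity` is not
#' supplied it is estimated from the terminal plateau: the longest trailing
#' window of at least `min_plateau_points` points whose relative spread
#' (max - min over mean) stays below `plateau_rel_spread`; the window mean
#' is used and the provenance recorded as `"plateau-estimated"`.
#'
#' @param times Sampling times, min.
#' @param values Measured amounts or concentrations, `>= 0` (any single
#'   consistent unit).
#' @param m_infinity Asymptotic value in the same unit, or `NULL` to
#'   plateau-estimate it.
#' @param plateau_rel_spread Stationarity tolerance (default 0.02, i.e. 2%).
#' @param min_plateau_points Minimum points in the plateau window.
#' @return A [release_curve]; fractions above 1 (possible with plateau noise)
#'   are capped at 1.05 by validation.
#' @export
normalize_release <- function(times, values, m_infinity = NULL,
                              plateau_rel_spread = 0.02,
                              min_plateau_points = 3) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 3) {
    na_stop("need at least 3 points to form a release curve.",
            "insufficient_data")
  }
  if (any(values < 0)) na_stop("values must be >= 0.", "invalid_value")
  if (is.null(m_infinity)) {
    n <- length(values)
    window <- 0
    for (w in seq(min_plateau_points, n)) {
      tail_vals <- values[(n - w + 1):n]
      m <- mean(tail_vals)
      if (m <= 0) break
      if ((max(tail_vals) - min(tail_vals)) / m < plateau_rel_spread) {
        window <- w
      } else {
        break
      }
    }
    if (window == 0) {
      na_stop(paste0("no stationary plateau (relative spread < ",
                     plateau_rel_spread, " over >= ", min_plateau_points,
                     " trailing points) and no m_infinity supplied."),
              "cannot_normalize")
    }
    m_infinity <- mean(values[(length(values) - window + 1):length(values)])
    provenance <- "plateau-estimated"
  } else {
    if (m_infinity <= 0) na_stop("m_infinity must be > 0.", "invalid_value")
    provenance <- "supplied"
  }
  release_curve(times, values / m_infinity, m_infinity, provenance)
}

#' Goodness-of-fit statistics for a release model
#'
#' `SSE = sum (obs - pred)^2`, `R2 = 1 - SSE / SStot`,
#' `R2adj = 1 - (1 - R2) (N - 1) / (N - p - 1)`, and
#' `RMSE = sqrt(SSE / N)` (divisor `N` by default; set
#' `rmse_divisor = "n_minus_p"` for `N - p`).
#'
#' @param observed,predicted Equal-length numeric vectors, `N >= 3`.
#' @param n_params Number of fitted parameters `p < N - 1`.
#' @param rmse_divisor `"n"` (default) or `"n_minus_p"`.
#' @return List with `r_squared`, `r_squared_adj`, `sse`, `rmse`.
#' @export
goodness_of_fit <- function(observed, predicted, n_params = 2,
                            rmse_divisor = c("n", "n_minus_p")) {
  rmse_divisor <- match.arg(rmse_divisor)
  N <- length(observed)
  if (length(predicted) != N) {
    na_stop("observed and predicted lengths differ.", "bad_columns")
  }
  if (N < 3) na_stop("need N >= 3 points.", "insufficient_data")
  if (n_params >= N - 1) {
    na_stop("n_params must be < N - 1.", "insufficient_data")
  }
  sse <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    na_stop("observed values have zero variance; R2 undefined.",
            "undefined_r2")
  }
  r2 <- 1 - sse / ss_tot
  r2_adj <- 1 - (1 - r2) * (N - 1) / (N - n_params - 1)
  denom <- if (rmse_divisor == "n") N else N - n_params
  list(r_squared = r2, r_squared_adj = r2_adj, sse = sse,
       rmse = sqrt(sse / denom))
}

# closed-form log-log OLS estimate of (k, n); requires t > 0, f > 0
loglog_ols_estimate <- function(times, fractions) {
  fit <- stats::lm.fit(cbind(1, log(times)), log(fractions))
  c(k = exp(unname(fit$coefficients[1])), n = unname(fit$coefficients[2]))
}

#' Fit the power-law release model by Nelder-Mead least squares
#'
#' Minimizes the linear-space residual sum of squares
#' `sum (f_i - k t_i^n)^2` over `(k, n)` with the Nelder-Mead simplex,
#' parameterized in `(log k, log n)` so both parameters stay positive. The
#' initial guess is the closed-form ordinary least squares line on
#' `(log t, log f)`. The fit is deterministic for fixed input and options.
#'
#' Points with `t <= 0` or `fraction <= 0` cannot enter (the log-log
#' initializer is undefined there); points with `fraction >= 1` are outside
#' the model's validity and are excluded by default. `fraction_cap = 0.6`
#' restricts fitting to the classical power-law validity window.
#'
#' @param curve A [release_curve] (or anything with `times`/`fractions`).
#' @param fraction_cap Upper fraction bound for usable points (default 1).
#' @param max_iterations Nelder-Mead iteration budget.
#' @param sse_tolerance Absolute convergence tolerance on the SSE.
#' @param rmse_divisor Passed to [goodness_of_fit()].
#' @return Object of class `peppas_fit`: `k`, `n`, `r_squared`,
#'   `r_squared_adj`, `sse`, `rmse`, `converged`, `n_points_used`.
#' @examples
#' curve <- simulate_release(seed = 1, k = 0.0234, n = 0.45,
#'                           noise_sigma = 0)
#' fit_peppas(curve)
#' @export
fit_peppas <- function(curve, fraction_cap = 1, max_iterations = 2000,
                       sse_tolerance = 1e-10,
                       rmse_divisor = c("n", "n_minus_p")) {
  rmse_divisor <- match.arg(rmse_divisor)
  times <- curve$times
  fractions <- curve$fractions
  usable <- times > 0 & fractions > 0 & fractions < fraction_cap
  t_u <- times[usable]
  f_u <- fractions[usable]
  if (length(t_u) < 3) {
    na_stop("fewer than 3 usable points (t > 0, 0 < fraction < cap).",
            "insufficient_data")
  }
  if (max(f_u) - min(f_u) == 0) {
    na_stop("all usable fractions are equal; power-law fit is degenerate.",
            "fit_failure")
  }
  sse_fn <- function(par) {
    pred <- exp(par[1]) * t_u^exp(par[2])
    sum((f_u - pred)^2)
  }
  init <- loglog_ols_estimate(t_u, f_u)
  if (!is.finite(init[["k"]]) || init[["k"]] <= 0 ||
      !is.finite(init[["n"]]) || init[["n"]] <= 0) {
    # fall back to a neutral start when the data slope away from a
    # power law (e.g. decreasing series)
    init <- c(k = max(min(f_u), 1e-6), n = 0.5)
  }
  opt <- stats::optim(log(c(init[["k"]], init[["n"]])), sse_fn,
                      method = "Nelder-Mead",
                      control = list(maxit = max_iterations,
                                     abstol = sse_tolerance,
                                     reltol = 1e-12))
  k_hat <- exp(opt$par[1])
  n_hat <- exp(opt$par[2])
  pred <- k_hat * t_u^n_hat
  gof <- goodness_of_fit(f_u, pred, n_params = 2,
                         rmse_divisor = rmse_divisor)
  structure(
    list(k = k_hat, n = n_hat,
         r_squared = gof$r_squared, r_squared_adj = gof$r_squared_adj,
         sse = gof$sse, rmse = gof$rmse,
         converged = opt$convergence == 0,
         n_points_used = length(t_u)),
    class = "peppas_fit"
  )
}

#' @export
print.peppas_fit <- function(x, ...) {
  cat("<peppas_fit> k = ", format(x$k, digits = 4), " min^-n, n = ",
      format(x$n, digits = 4), "\n  R2 = ",
      format(x$r_squared, digits = 4), ", R2adj = ",
      format(x$r_squared_adj, digits = 4), ", SSE = ",
      format(x$sse, digits = 4), ", RMSE = ", format(x$rmse, digits = 4),
      "\n  ", x$n_points_used, " points used; converged: ", x$converged,
      "\n", sep = "")
  invisible(x)
}

# Fickian reference exponent and Case II bound by particle geometry
# (sphere from the release-model literature for spherical carriers;
# slab/cylinder from the same power-law framework)
MECHANISM_BOUNDS <- list(
  sphere   = c(fickian = 0.43, case2 = 0.85),
  slab     = c(fickian = 0.50, case2 = 1.00),
  cylinder = c(fickian = 0.45, case2 = 0.89)
)

#' Classify the release transport mechanism from the fitted exponent
#'
#' For spheres the Fickian-diffusion reference exponent is `n = 0.43` and
#' the Case II (relaxation-controlled) bound `n = 0.85`. With tolerance
#' band half-width `tol` (default 0.01: exponents in this literature are
#' reported to two decimals, so only values printing 0.42-0.44 are treated
#' as Fickian):
#' \itemize{
#'   \item `n < fickian - tol`: quasi-Fickian/combined
#'   \item `|n - fickian| <= tol`: Fickian
#'   \item `fickian + tol < n < case2 - tol`: anomalous (non-Fickian)
#'   \item `|n - case2| <= tol`: Case II
#'   \item `n > case2 + tol`: super Case II
#' }
#'
#' @param n Fitted release exponent, `> 0`.
#' @param geometry `"sphere"` (default), `"slab"`, or `"cylinder"`.
#' @param tolerance Band half-width around the reference exponents.
#' @return Object of class `mechanism_call`: `label`, `geometry`, `n`,
#'   `tolerance`.
#' @export
classify_mechanism <- function(n, geometry = "sphere", tolerance = 0.01) {
  if (!geometry %in% names(MECHANISM_BOUNDS)) {
    na_stop(paste0("unsupported geometry '", geometry, "'; supported: ",
                   paste(names(MECHANISM_BOUNDS), collapse = ", ")),
            "unsupported_geometry")
  }
  if (!is.finite(n) || n <= 0) {
    na_stop("n must be > 0.", "invalid_parameter")
  }
  b <- MECHANISM_BOUNDS[[geometry]]
  label <-
    if (n < b[["fickian"]] - tolerance) "quasi-Fickian/combined"
    else if (abs(n - b[["fickian"]]) <= tolerance) "Fickian"
    else if (n < b[["case2"]] - tolerance) "anomalous (non-Fickian)"
    else if (abs(n - b[["case2"]]) <= tolerance) "Case II"
    else "super Case II"
  structure(list(label = label, geometry = geometry, n = n,
                 tolerance = tolerance),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call> n = ", format(x$n, digits = 4), " (", x$geometry,
      ", band +/-", x$tolerance, "): ", x$label, "\n", sep = "")
  invisible(x)
}

#' Read a release CSV (`time_min,value`)
#'
#' @param path Path to the CSV.
#' @param m_infinity Optional asymptote (else plateau-estimated).
#' @param ... Passed to [normalize_release()].
#' @return A [release_curve].
#' @export
read_release <- function(path, m_infinity = NULL, ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("time_min", "value") %in% names(raw))) {
    na_stop("release CSV needs columns time_min,value.", "bad_columns")
  }
  normalize_release(raw$time_min, raw$value, m_infinity = m_infinity, ...)
}

#' Plot a release curve with its fitted power law
#'
#' @param curve A [release_curve].
#' @param fit Optional `peppas_fit` overlay.
#' @return A ggplot object.
#' @export
plot_release <- function(curve, fit = NULL) {
  df <- data.frame(time = curve$times, fraction = curve$fractions)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time,
                                        y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)",
                  y = expression(M[t] / M[infinity])) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- data.frame(time = seq(min(df$time), max(df$time),
                                  length.out = 200))
    grid$fraction <- peppas_predict(fit$k, fit$n, grid$time)
    p <- p + ggplot2::geom_line(data = grid, color = "firebrick")
  }
  p
}
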