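#' Mole fractions from GC area percentages
#'
#' Area percentages are taken as mass-proportional, so
#' `x_i = (area_i / M_i) / sum_j(area_j / M_j)` with molar masses from the
#' registry. Fractions sum to 1 to within 1e-9.
#'
#' @param table A [composition_table]; every compound must be resolvable in
#'   `registry`.
#' @param registry A [compound_registry].
#' @return Data frame with `compound` and `mole_fraction`.
#' @export
mole_fractions_from_areas <- function(table, registry) {
  stopifnot(inherits(table, "composition_table"))
  if (sum(table$area_percent) <= 0) {
    na_stop("all areas are zero; mole fractions undefined.",
            "degenerate_input")
  }
  mm <- vapply(table$compound,
               function(nm) get_compound(registry, nm)$molar_mass,
               numeric(1))
  moles <- table$area_percent / mm
  data.frame(compound = table$compound,
             mole_fraction = moles / sum(moles),
             stringsAsFactors = FALSE)
}

#' Ideal (Raoult-law) headspace concentration of one compound
#'
#' At liquid mole fraction `x` the equilibrium partial pressure is
#' `p = gamma * x * Pvap` (activity coefficient `gamma = 1` by default) and
#' the ideal-gas mass concentration is `c = p * M / (R * T)`, returned in
#' mg/m3 (the unit odor thresholds are tabulated in).
#'
#' @param x Liquid mole fraction in `[0, 1]`.
#' @param compound A `compound` (from [get_compound()]) with a vapor
#'   pressure.
#' @param temperature Absolute temperature in K (default 298.15, i.e. 25 C).
#' @param activity Activity coefficient, default 1 (ideal solution).
#' @return Concentration in mg/m3.
#' @examples
#' reg <- load_registry(system.file("extdata", "table6_properties.csv",
#'                                  package = "nanoaroma"))
#' ideal_headspace_concentration(1, get_compound(reg, "α-Pinene"))
#' @export
ideal_headspace_concentration <- function(x, compound,
                                          temperature = 298.15,
                                          activity = 1) {
  stopifnot(inherits(compound, "compound"))
  if (any(x < 0 | x > 1)) {
    na_stop("mole fraction must lie in [0, 1].", "invalid_fraction")
  }
  if (temperature <= 0) {
    na_stop("temperature must be > 0 K.", "invalid_temperature")
  }
  if (is.na(compound$vapor_pressure)) {
    na_stop(paste0("compound '", compound$name,
                   "' has no vapor pressure."), "missing_property")
  }
  p <- activity * x * compound$vapor_pressure            # Pa
  1000 * p * compound$molar_mass / (GAS_CONSTANT * temperature)  # mg/m3
}

#' Predicted equilibrium headspace profile of a mixture
#'
#' Applies [mole_fractions_from_areas()] then
#' [ideal_headspace_concentration()] compound-wise. Compounds without a
#' tabulated vapor pressure are omitted with a warning.
#'
#' @param table A [composition_table].
#' @param registry A [compound_registry].
#' @param temperature Absolute temperature, K.
#' @param activity Named vector of per-compound activity coefficients
#'   (names matched case-insensitively); compounds not named get 1.
#' @return Data frame with `compound`, `mole_fraction`,
#'   `concentration_mg_m3`, and attribute `source = "predicted"`.
#' @export
headspace_profile <- function(table, registry, temperature = 298.15,
                              activity = NULL) {
  x <- mole_fractions_from_areas(table, registry)
  gamma <- rep(1, nrow(x))
  if (!is.null(activity)) {
    i <- match(normalize_name(x$compound), normalize_name(names(activity)))
    gamma[!is.na(i)] <- as.numeric(activity)[i[!is.na(i)]]
  }
  conc <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    cmp <- get_compound(registry, x$compound[i])
    if (is.na(cmp$vapor_pressure)) next
    conc[i] <- ideal_headspace_concentration(x$mole_fraction[i], cmp,
                                             temperature, gamma[i])
  }
  dropped <- x$compound[is.na(conc)]
  if (length(dropped) > 0) {
    na_warn(paste0("omitting compound(s) without vapor pressure: ",
                   paste(dropped, collapse = ", ")), "missing_property")
  }
  keep <- !is.na(conc)
  if (!any(keep)) {
    na_stop("no compound has a usable vapor pressure.", "degenerate_input")
  }
  out <- data.frame(compound = x$compound[keep],
                    mole_fraction = x$mole_fraction[keep],
                    concentration_mg_m3 = conc[keep],
                    stringsAsFactors = FALSE)
  attr(out, "source") <- "predicted"
  out
}

#' Read measured headspace concentration series
#'
#' CSV dialect `compound,time_min,port_mm,concentration_ug_per_ml`;
#' concentrations convert to the canonical mg/m3
#' (1 ug/mL = 1000 mg/m3).
#'
#' @param path Path to the CSV.
#' @return Data frame with `compound`, `time_min`, `port_mm`,
#'   `concentration_mg_m3`, attribute `source = "measured"`.
#' @export
read_headspace <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("compound", "time_min", "concentration_ug_per_ml")
  if (!all(need %in% names(raw))) {
    na_stop(paste0("headspace CSV needs columns ",
                   paste(need, collapse = ","), "."), "bad_columns")
  }
  if (any(raw$concentration_ug_per_ml < 0) || any(raw$time_min < 0)) {
    na_stop("concentrations and times must be >= 0.", "invalid_value")
  }
  out <- data.frame(
    compound = raw$compound,
    time_min = raw$time_min,
    port_mm = if ("port_mm" %in% names(raw)) raw$port_mm else NA_real_,
    concentration_mg_m3 = 1000 * raw$concentration_ug_per_ml,
    stringsAsFactors = FALSE
  )
  attr(out, "source") <- "measured"
  out
}
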