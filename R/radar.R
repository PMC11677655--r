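#' Odor value of one compound
#'
#' `OV = C / ODT`: headspace concentration over odor threshold, both in
#' mg/m3. A compound without a tabulated odor threshold cannot be scored;
#' the function returns `NA` and signals a `nanoaroma_excluded_compound`
#' message (a signal distinct from an error: downstream radar construction
#' logs and skips such compounds).
#'
#' @param concentration_mg_m3 Headspace concentration, mg/m3, `>= 0`.
#' @param compound A `compound` (from [get_compound()]).
#' @return Dimensionless odor value, or `NA` if the threshold is absent.
#' @export
odor_value <- function(concentration_mg_m3, compound) {
  stopifnot(inherits(compound, "compound"))
  if (concentration_mg_m3 < 0) {
    na_stop("concentration must be >= 0.", "invalid_value")
  }
  if (is.na(compound$odor_threshold)) {
    message(structure(
      class = c("nanoaroma_excluded_compound", "message", "condition"),
      list(message = paste0("compound '", compound$name,
                            "' has no odor threshold; excluded from",
                            " odor-value scoring.\n"))
    ))
    return(NA_real_)
  }
  concentration_mg_m3 / compound$odor_threshold
}

#' Rank weights for 1-3 olfactory families
#'
#' A compound's odor value is split over its ranked families: a single
#' family takes 100%; primary/secondary split 70%/30%; primary/secondary/
#' tertiary split 60%/30%/10%.
#'
#' @param n_families Integer in `{1, 2, 3}`.
#' @return Numeric weight vector summing to 1.
#' @export
family_weights <- function(n_families) {
  if (length(n_families) != 1 || !n_families %in% 1:3) {
    na_stop("n_families must be 1, 2, or 3.", "invalid_count")
  }
  switch(n_families, c(1.00), c(0.70, 0.30), c(0.60, 0.30, 0.10))
}

#' Per-family odor values of a mixture
#'
#' `OV_j = sum_i w_ij * OV_i`, distributing each compound's odor value over
#' its ranked families with the [family_weights()] scheme. All 8 canonical
#' families are present in the result; families receiving no contribution
#' hold 0.
#'
#' @param compound Character vector of compound names.
#' @param odor_values Numeric vector of per-compound odor values `>= 0`.
#' @param registry A [compound_registry] resolving every compound.
#' @return Named numeric vector over [OLFACTORY_FAMILIES].
#' @export
family_odor_values <- function(compound, odor_values, registry) {
  if (length(compound) != length(odor_values)) {
    na_stop("compound and odor_values lengths differ.", "bad_columns")
  }
  if (any(!is.finite(odor_values)) || any(odor_values < 0)) {
    na_stop("odor values must be finite and >= 0.", "invalid_value")
  }
  fov <- stats::setNames(numeric(length(OLFACTORY_FAMILIES)),
                         OLFACTORY_FAMILIES)
  for (i in seq_along(compound)) {
    cmp <- get_compound(registry, compound[i])
    w <- family_weights(length(cmp$families))
    fov[cmp$families] <- fov[cmp$families] + w * odor_values[i]
  }
  fov
}

#' Normalize family odor values into a radar profile
#'
#' `OV'_j = OV_j / sum_j OV_j`, making radar polygons comparable across
#' mixtures regardless of total aroma intensity. An all-zero input yields a
#' degenerate profile of zeros with the `degenerate` flag set (no error).
#'
#' @param fov Named numeric vector over [OLFACTORY_FAMILIES] (as from
#'   [family_odor_values()]).
#' @return Object of class `radar_profile`: `values` (named, summing to 1
#'   unless degenerate), `degenerate` flag.
#' @export
normalize_profile <- function(fov) {
  if (!all(OLFACTORY_FAMILIES %in% names(fov))) {
    na_stop("fov must carry all 8 canonical families.", "bad_columns")
  }
  fov <- fov[OLFACTORY_FAMILIES]
  if (any(fov < 0)) na_stop("family odor values must be >= 0.",
                            "invalid_value")
  total <- sum(fov)
  if (total == 0) {
    values <- fov
    degenerate <- TRUE
  } else {
    values <- fov / total
    degenerate <- FALSE
  }
  structure(list(values = values, degenerate = degenerate),
            class = "radar_profile")
}

#' Polar coordinates of the 8-axis radar polygon
#'
#' Axes are laid out in the fixed order citrus, fruity, floral, green,
#' herbal, musk, oriental, woody, equally spaced every 45 degrees starting
#' at 90 degrees (citrus at the top) and proceeding clockwise; the radius on
#' each axis is the normalized odor value.
#'
#' @param profile A non-degenerate `radar_profile`.
#' @return Data frame with `family`, `angle_deg`, `radius`.
#' @export
radar_coordinates <- function(profile) {
  stopifnot(inherits(profile, "radar_profile"))
  if (profile$degenerate) {
    na_stop("degenerate (all-zero) profile has no radar polygon.",
            "degenerate_profile")
  }
  idx <- seq_along(OLFACTORY_FAMILIES)
  data.frame(
    family = OLFACTORY_FAMILIES,
    angle_deg = (90 - 45 * (idx - 1)) %% 360,
    radius = unname(profile$values[OLFACTORY_FAMILIES]),
    stringsAsFactors = FALSE
  )
}

#' Dominant olfactory family of a profile
#'
#' @param profile A `radar_profile`.
#' @return Character vector of the arg-max family; length > 1 reports a tie
#'   explicitly rather than breaking it.
#' @export
dominant_family <- function(profile) {
  stopifnot(inherits(profile, "radar_profile"))
  if (profile$degenerate) {
    na_stop("degenerate profile has no dominant family.",
            "degenerate_profile")
  }
  v <- profile$values
  names(v)[v == max(v)]
}

#' Full perfumery-radar chain from a liquid composition
#'
#' Runs the complete scoring pipeline: restrict the composition to
#' registry-known compounds, predict equilibrium headspace concentrations
#' under the ideal (Raoult) model, score odor values for compounds with a
#' tabulated odor threshold, drop "non-expressive" compounds whose share of
#' the total odor value falls below `min_ov_share`, distribute over ranked
#' families, and normalize. Exclusions (unknown to the registry, no vapor
#' pressure, no odor threshold, below the intensity floor) are logged in the
#' `exclusions` element.
#'
#' @param table A [composition_table].
#' @param registry A [compound_registry].
#' @param temperature Absolute temperature, K.
#' @param min_ov_share Minimum fraction of the summed odor value a compound
#'   must contribute to enter the radar (default 0.001, i.e. 0.1%).
#' @param activity Optional named activity-coefficient vector (see
#'   [headspace_profile()]).
#' @return List of class `radar_result`: `profile` (a `radar_profile`),
#'   `family_odor_values`, `odor_values` (per retained compound),
#'   `exclusions` (data frame of compound/reason).
#' @examples
#' reg <- load_registry(system.file("extdata", "table6_properties.csv",
#'                                  package = "nanoaroma"))
#' tab <- read_composition(system.file("extdata", "table2_composition.csv",
#'                                     package = "nanoaroma"))
#' res <- radar_from_composition(tab, reg)
#' dominant_family(res$profile)
#' @export
radar_from_composition <- function(table, registry, temperature = 298.15,
                                   min_ov_share = 0.001, activity = NULL) {
  stopifnot(inherits(table, "composition_table"))
  keys <- normalize_name(registry$compounds$name)
  known <- normalize_name(table$compound) %in% keys
  exclusions <- data.frame(compound = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (any(!known)) {
    exclusions <- rbind(exclusions, data.frame(
      compound = table$compound[!known], reason = "not in registry",
      stringsAsFactors = FALSE))
  }
  sub <- table[known, , drop = FALSE]
  class(sub) <- c("composition_table", "data.frame")
  if (nrow(sub) == 0) {
    na_stop("no compound of the composition is in the registry.",
            "degenerate_input")
  }
  prof <- withCallingHandlers(
    headspace_profile(sub, registry, temperature, activity),
    nanoaroma_missing_property = function(w) invokeRestart("muffleWarning")
  )
  no_pvap <- setdiff(sub$compound, prof$compound)
  if (length(no_pvap) > 0) {
    exclusions <- rbind(exclusions, data.frame(
      compound = no_pvap, reason = "no vapor pressure",
      stringsAsFactors = FALSE))
  }
  ov <- rep(NA_real_, nrow(prof))
  for (i in seq_len(nrow(prof))) {
    cmp <- get_compound(registry, prof$compound[i])
    ov[i] <- suppressMessages(
      odor_value(prof$concentration_mg_m3[i], cmp))
  }
  no_odt <- prof$compound[is.na(ov)]
  if (length(no_odt) > 0) {
    exclusions <- rbind(exclusions, data.frame(
      compound = no_odt, reason = "no odor threshold",
      stringsAsFactors = FALSE))
  }
  scored <- !is.na(ov)
  compounds <- prof$compound[scored]
  ov <- ov[scored]
  if (length(ov) == 0 || sum(ov) == 0) {
    fov <- stats::setNames(numeric(8), OLFACTORY_FAMILIES)
    return(structure(list(profile = normalize_profile(fov),
                          family_odor_values = fov,
                          odor_values = stats::setNames(numeric(0),
                                                        character(0)),
                          exclusions = exclusions),
                     class = "radar_result"))
  }
  share <- ov / sum(ov)
  faint <- share < min_ov_share
  if (any(faint)) {
    exclusions <- rbind(exclusions, data.frame(
      compound = compounds[faint],
      reason = sprintf("odor-value share below %g", min_ov_share),
      stringsAsFactors = FALSE))
  }
  compounds <- compounds[!faint]
  ov <- ov[!faint]
  fov <- family_odor_values(compounds, ov, registry)
  structure(
    list(profile = normalize_profile(fov),
         family_odor_values = fov,
         odor_values = stats::setNames(ov, compounds),
         exclusions = exclusions),
    class = "radar_result"
  )
}

#' @export
print.radar_profile <- function(x, ...) {
  if (x$degenerate) {
    cat("<radar_profile> degenerate (all families zero)\n")
  } else {
    cat("<radar_profile>\n")
    print(round(x$values, 4))
  }
  invisible(x)
}

#' @export
print.radar_result <- function(x, ...) {
  print(x$profile)
  if (!x$profile$degenerate) {
    cat("dominant:", paste(dominant_family(x$profile), collapse = ", "),
        "\n")
  }
  if (nrow(x$exclusions) > 0) {
    cat(nrow(x$exclusions), "compound(s) excluded; see $exclusions\n")
  }
  invisible(x)
}

#' Plot a perfumery radar polygon
#'
#' @param result A `radar_result` or `radar_profile`.
#' @return A ggplot object (8 fixed axes, radius = normalized odor value).
#' @export
plot_radar <- function(result) {
  profile <- if (inherits(result, "radar_result")) result$profile else
    result
  coords <- radar_coordinates(profile)
  coords$family <- factor(coords$family, levels = OLFACTORY_FAMILIES)
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = .data$family, y = .data$radius,
                               group = 1)) +
    ggplot2::geom_polygon(fill = "forestgreen", alpha = 0.3,
                          color = "forestgreen") +
    ggplot2::coord_polar(start = -pi / 8) +
    ggplot2::ylim(0, max(coords$radius)) +
    ggplot2::labs(x = NULL, y = "normalized odor value") +
    ggplot2::theme_minimal()
}
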