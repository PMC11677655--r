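#' Compound property registry
#'
#' A registry holds the physicochemical and olfactory properties needed to
#' score a headspace mixture: molar mass (g/mol), pure-component vapor
#' pressure (Pa, at the registry's reference temperature), odor threshold
#' (mg/m3, the minimum gas concentration perceivable by the human nose; may
#' be absent), liquid density (kg/m3, may be absent), and an ordered list of
#' one to three olfactory families (rank 1 = primary). Family tokens must
#' belong to [OLFACTORY_FAMILIES]; a parenthetical nuance such as
#' `woody(pine)` is stored as a note and does not create a family.
#'
#' @param compounds Data frame with one row per compound (see
#'   [load_registry()] for the column contract).
#' @param source Provenance text for the table.
#' @param temperature_c Reference temperature of the vapor pressures, Celsius.
#' @return An object of class `compound_registry`.
#' @seealso [load_registry()], [get_compound()], [write_registry()]
#' @export
compound_registry <- function(compounds, source = "in-memory",
                              temperature_c = 25) {
  required <- c("name", "formula", "molar_mass_g_mol", "vapor_pressure_pa",
                "odor_threshold_mg_m3", "density_kg_m3", "families",
                "nuances", "retention_index")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols) > 0) {
    na_stop(paste0("registry is missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "bad_columns")
  }
  if (nrow(compounds) > 0) {
    keys <- normalize_name(compounds$name)
    dup <- keys[duplicated(keys)]
    if (length(dup) > 0) {
      rows <- which(keys %in% dup)
      na_stop(paste0("duplicate compound name(s) after case folding: ",
                     paste(unique(compounds$name[rows]), collapse = ", "),
                     " (rows ", paste(rows, collapse = ", "), ")"),
              "duplicate_name")
    }
    if (any(!is.finite(compounds$molar_mass_g_mol) |
            compounds$molar_mass_g_mol <= 0)) {
      na_stop("molar_mass_g_mol must be > 0 for every compound.",
              "invalid_property")
    }
    vp <- compounds$vapor_pressure_pa
    if (any(!is.na(vp) & vp < 0)) {
      na_stop("vapor_pressure_pa must be >= 0 when present.",
              "invalid_property")
    }
    odt <- compounds$odor_threshold_mg_m3
    if (any(!is.na(odt) & odt <= 0)) {
      na_stop("odor_threshold_mg_m3 must be > 0 when present.",
              "invalid_property")
    }
    for (i in seq_len(nrow(compounds))) {
      fams <- compounds$families[[i]]
      if (length(fams) < 1 || length(fams) > 3) {
        na_stop(paste0("compound '", compounds$name[i],
                       "' must carry 1-3 olfactory families."),
                "invalid_families")
      }
      bad <- setdiff(fams, OLFACTORY_FAMILIES)
      if (length(bad) > 0) {
        na_stop(paste0("unknown olfactory family token(s) for '",
                       compounds$name[i], "': ",
                       paste(bad, collapse = ", ")), "unknown_family")
      }
      if (anyDuplicated(fams)) {
        na_stop(paste0("compound '", compounds$name[i],
                       "' lists a duplicated family."), "invalid_families")
      }
    }
  }
  structure(
    list(compounds = compounds, source = source,
         temperature_c = temperature_c),
    class = "compound_registry"
  )
}

# "woody(pine)|oriental" -> families c("woody","oriental"),
# nuances c("pine", NA)
parse_family_field <- function(x) {
  tokens <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  fams <- character(0)
  nuances <- character(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([^()]+)(?:\\(([^()]*)\\))?$", tok))[[1]]
    if (length(m) == 0) {
      na_stop(paste0("cannot parse family token '", tok, "'"),
              "unknown_family")
    }
    fams <- c(fams, tolower(trimws(m[2])))
    nuances <- c(nuances, if (nzchar(m[3])) trimws(m[3]) else NA_character_)
  }
  list(families = fams, nuances = nuances)
}

#' Load a compound property table
#'
#' Reads a UTF-8 CSV with header
#' `name,formula,molar_mass_g_mol,vapor_pressure_pa,odor_threshold_mg_m3,density_kg_m3,families,retention_index`.
#' The `families` field encodes ranked families pipe-separated
#' (`primary|secondary|tertiary`), each optionally carrying a parenthetical
#' nuance, e.g. `woody(pine)|oriental`. Empty cells and `-` denote absent
#' values: an absent odor threshold marks the compound as non-scoreable
#' downstream (it is never treated as a threshold of zero).
#'
#' @param path Path to the property CSV.
#' @param source Provenance label; defaults to the file path.
#' @param temperature_c Reference temperature of the vapor pressures, Celsius.
#' @return A [compound_registry] object (empty file with header gives an
#'   empty registry).
#' @examples
#' reg <- load_registry(system.file("extdata", "table6_properties.csv",
#'                                  package = "nanoaroma"))
#' nrow(reg$compounds)
#' @export
load_registry <- function(path, source = path, temperature_c = 25) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8",
                         check.names = FALSE)
  expected <- c("name", "formula", "molar_mass_g_mol", "vapor_pressure_pa",
                "odor_threshold_mg_m3", "density_kg_m3", "families",
                "retention_index")
  missing_cols <- setdiff(expected, names(raw))
  if (length(missing_cols) > 0) {
    na_stop(paste0("property table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")), "bad_columns")
  }
  num_or_na <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "-", "NA")] <- NA_character_
    as.numeric(x)
  }
  parsed <- lapply(raw$families, parse_family_field)
  compounds <- data.frame(
    name = trimws(raw$name),
    formula = trimws(raw$formula),
    molar_mass_g_mol = num_or_na(raw$molar_mass_g_mol),
    vapor_pressure_pa = num_or_na(raw$vapor_pressure_pa),
    odor_threshold_mg_m3 = num_or_na(raw$odor_threshold_mg_m3),
    density_kg_m3 = num_or_na(raw$density_kg_m3),
    retention_index = num_or_na(raw$retention_index),
    stringsAsFactors = FALSE
  )
  compounds$families <- lapply(parsed, `[[`, "families")
  compounds$nuances <- lapply(parsed, `[[`, "nuances")
  compound_registry(compounds, source = source,
                    temperature_c = temperature_c)
}

#' Write a registry back to the property-table CSV dialect
#'
#' Inverse of [load_registry()]: numeric fields and family order round-trip
#' exactly.
#'
#' @param registry A [compound_registry].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "compound_registry"))
  cmp <- registry$compounds
  fmt <- function(x) ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE)
  }, character(1)))
  fam_field <- vapply(seq_len(nrow(cmp)), function(i) {
    fams <- cmp$families[[i]]
    nuan <- cmp$nuances[[i]]
    paste(ifelse(is.na(nuan), fams, paste0(fams, "(", nuan, ")")),
          collapse = "|")
  }, character(1))
  out <- data.frame(
    name = cmp$name, formula = cmp$formula,
    molar_mass_g_mol = fmt(cmp$molar_mass_g_mol),
    vapor_pressure_pa = fmt(cmp$vapor_pressure_pa),
    odor_threshold_mg_m3 = fmt(cmp$odor_threshold_mg_m3),
    density_kg_m3 = fmt(cmp$density_kg_m3),
    families = fam_field,
    retention_index = fmt(cmp$retention_index),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up a compound by name
#'
#' Lookup is case-insensitive and whitespace-normalized, and spelled-out
#' Greek prefixes fold to their letters (`"ALPHA-PINENE"` finds
#' `"α-Pinene"`). An explicit alias map extends matching further.
#'
#' @param registry A [compound_registry].
#' @param name Compound name.
#' @param aliases Optional named character vector mapping alias to
#'   canonical registry name.
#' @return A list of class `compound` with fields `name`, `formula`,
#'   `molar_mass` (g/mol), `vapor_pressure` (Pa), `odor_threshold` (mg/m3 or
#'   `NA`), `density` (kg/m3 or `NA`), `families` (ordered), `nuances`,
#'   `retention_index`.
#' @export
get_compound <- function(registry, name, aliases = NULL) {
  stopifnot(inherits(registry, "compound_registry"))
  if (!is.null(aliases)) {
    j <- match(normalize_name(name), normalize_name(names(aliases)))
    if (!is.na(j)) name <- unname(aliases[j])
  }
  keys <- normalize_name(registry$compounds$name)
  i <- match(normalize_name(name), keys)
  if (is.na(i)) {
    na_stop(paste0("compound '", name, "' not found in registry (",
                   registry$source, ")"), "not_found")
  }
  cmp <- registry$compounds
  structure(
    list(
      name = cmp$name[i],
      formula = cmp$formula[i],
      molar_mass = cmp$molar_mass_g_mol[i],
      vapor_pressure = cmp$vapor_pressure_pa[i],
      odor_threshold = cmp$odor_threshold_mg_m3[i],
      density = cmp$density_kg_m3[i],
      families = cmp$families[[i]],
      nuances = cmp$nuances[[i]],
      retention_index = cmp$retention_index[i]
    ),
    class = "compound"
  )
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("<compound_registry> ", nrow(x$compounds), " compounds (",
      x$source, "), vapor pressures at ", x$temperature_c, " degC\n",
      sep = "")
  invisible(x)
}

#' @export
print.compound <- function(x, ...) {
  odt <- if (is.na(x$odor_threshold)) "absent" else
    paste0(x$odor_threshold, " mg/m3")
  cat("<compound> ", x$name, " (", x$formula, "), M = ", x$molar_mass,
      " g/mol, Pvap = ", x$vapor_pressure, " Pa, ODT = ", odt,
      ", families: ", paste(x$families, collapse = " > "), "\n", sep = "")
  invisible(x)
}
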