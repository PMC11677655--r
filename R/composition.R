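# slack allowed on the 100% total for rounded published tables
AREA_SUM_SLACK <- 0.5

#' Construct a GC-MS composition table
#'
#' Area percentages are percentages of the total detected chromatogram area;
#' they must be non-negative and may sum to less than 100 (the remainder is
#' the unidentified fraction).
#'
#' @param compound Character vector of compound names.
#' @param area_percent Numeric vector, percent of total detected area.
#' @param sd Optional numeric vector of replicate standard deviations
#'   (percent), `NA` when absent.
#' @return Data frame of class `composition_table`.
#' @export
composition_table <- function(compound, area_percent, sd = NA_real_) {
  area_percent <- as.numeric(area_percent)
  if (length(compound) != length(area_percent)) {
    na_stop("compound and area_percent lengths differ.", "bad_columns")
  }
  if (any(!is.finite(area_percent)) || any(area_percent < 0)) {
    na_stop("every area_percent must be finite and >= 0.", "invalid_area")
  }
  if (sum(area_percent) > 100 + AREA_SUM_SLACK) {
    na_stop(paste0("area percentages sum to ",
                   format(sum(area_percent)), " > 100 + ", AREA_SUM_SLACK,
                   " slack."), "inconsistent_total")
  }
  out <- data.frame(compound = as.character(compound),
                    area_percent = area_percent,
                    sd = rep_len(as.numeric(sd), length(area_percent)),
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Read a composition CSV (`compound,area_percent,sd`)
#'
#' @param path Path to the CSV.
#' @return A [composition_table].
#' @export
read_composition <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("compound", "area_percent") %in% names(raw))) {
    na_stop("composition CSV needs columns compound,area_percent[,sd].",
            "bad_columns")
  }
  composition_table(raw$compound, raw$area_percent,
                    if ("sd" %in% names(raw)) raw$sd else NA_real_)
}

#' Write a composition table to CSV
#'
#' @param table A [composition_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(table, path) {
  stopifnot(inherits(table, "composition_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize raw peak areas to percentages of the total
#'
#' `area_percent_i = 100 * raw_i / sum(raw)`; the output always sums to 100
#' (to within 1e-9).
#'
#' @param compound Character vector of names.
#' @param raw_area Numeric vector of raw integrated areas, `>= 0`, at least
#'   one positive.
#' @return A [composition_table].
#' @export
normalize_areas <- function(compound, raw_area) {
  raw_area <- as.numeric(raw_area)
  if (any(!is.finite(raw_area)) || any(raw_area < 0)) {
    na_stop("raw areas must be finite and >= 0.", "invalid_area")
  }
  total <- sum(raw_area)
  if (total <= 0) {
    na_stop("all raw areas are zero; cannot normalize.", "degenerate_input")
  }
  composition_table(compound, 100 * raw_area / total)
}

#' Identified and unidentified totals of a composition table
#'
#' Sums the identified area percentages; the unidentified remainder is
#' `100 - identified`.
#'
#' @param table A [composition_table] whose rows are the identified
#'   compounds, areas as percent of total detected area.
#' @return List with `identified_percent` and `unidentified_percent`.
#' @examples
#' tab <- read_composition(system.file("extdata", "table2_composition.csv",
#'                                     package = "nanoaroma"))
#' identified_total(tab)
#' @export
identified_total <- function(table) {
  stopifnot(inherits(table, "composition_table"))
  s <- sum(table$area_percent)
  if (s > 100 + AREA_SUM_SLACK) {
    na_stop("identified areas exceed 100% beyond rounding slack.",
            "inconsistent_total")
  }
  list(identified_percent = s, unidentified_percent = 100 - s)
}
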