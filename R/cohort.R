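#' The packaged 13-patient sICH cohort
#'
#' Per-patient clinical, radiological and neutrophil measurements of the
#' pilot cohort: demographics, ICU course, admission ICH score, 90-day mRS,
#' same-day Glasgow Coma Scale, intraparenchymal hemorrhage (IPH) and
#' perihematomal edema (PHE) volumes, modified Graeb score (mGS),
#' neutrophil-to-lymphocyte ratio (NLR), and DEspR+CD11b+ ("rogue") and
#' NET-forming neutrophil counts in cells/microliter.
#'
#' @param derived if `TRUE` (default), add the derived flags and K/uL counts
#'   via [derive_fields()].
#' @return a `cohort_table` data frame with 13 rows.
#' @examples
#' co <- ich_cohort()
#' nrow(co)        # 13
#' sum(co$ivh)     # 11 patients with intraventricular extension
#' @export
ich_cohort <- function(derived = TRUE) {
  path <- system.file("extdata", "table1_cohort.csv", package = "ichneutro")
  co <- load_cohort(path)
  if (derived) co <- derive_fields(co)
  co
}

.cohort_required <- c(
  "id", "sex", "age", "pmhx", "ich_site", "icu_days", "cmo_day", "death_day",
  "ich_score", "mrs_90d", "fcm_day", "gcs", "iph_vol", "phe_vol", "mgs",
  "nlr", "rogue_n_count", "net_n_count")

.cohort_optional <- c("il6", "mpo", "sc5b9", "et1", "mt_ndna_ratio")

.cohort_numeric <- setdiff(.cohort_required, c("id", "sex", "pmhx", "ich_site"))

#' Load and validate a cohort CSV
#'
#' One row per patient, lower_snake_case headers, missing values as empty
#' cells (RFC 4180, UTF-8). Numeric parsing is locale-independent (period
#' decimal separator). Counts are stored in cells/uL as printed.
#'
#' @param path path to a CSV file.
#' @return a validated `cohort_table` data frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop_ich(paste0("cohort file not found: ", path), "ich_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.cohort_required, names(raw))
  if (length(missing_cols) > 0)
    stop_ich(paste0("cohort schema error: missing required column(s): ",
                    paste(missing_cols, collapse = ", ")), "ich_schema_error")
  co <- raw[, intersect(c(.cohort_required, .cohort_optional), names(raw)), drop = FALSE]
  num_cols <- c(.cohort_numeric, intersect(.cohort_optional, names(co)))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(co[[col]]))
    bad <- !is.na(co[[col]]) & is.na(v)
    if (any(bad))
      stop_ich(paste0("cohort validation error: non-numeric value in '", col,
                      "' for row id ", co$id[which(bad)[1]]), "ich_validation_error")
    co[[col]] <- v
  }
  validate_cohort(co)
  class(co) <- c("cohort_table", "data.frame")
  co
}

validate_cohort <- function(co) {
  if (nrow(co) == 0) return(invisible(co))
  if (anyDuplicated(co$id))
    stop_ich("cohort validation error: duplicate patient ids", "ich_validation_error")
  check <- function(cond, what) {
    bad <- which(!(cond | is.na(cond)))
    if (length(bad) > 0)
      stop_ich(paste0("cohort validation error: ", what, " out of range for row id ",
                      co$id[bad[1]]), "ich_validation_error")
  }
  check(co$gcs >= 3 & co$gcs <= 15, "gcs")
  check(co$mrs_90d >= 0 & co$mrs_90d <= 6, "mrs_90d")
  check(co$ich_score >= 0 & co$ich_score <= 6, "ich_score")
  check(co$mgs >= 0 & co$mgs <= 32, "mgs")
  check(co$iph_vol >= 0, "iph_vol")
  check(co$phe_vol >= 0, "phe_vol")
  check(co$rogue_n_count >= 0, "rogue_n_count")
  check(co$net_n_count >= 0, "net_n_count")
  check(co$nlr > 0, "nlr")
  bad_sex <- !co$sex %in% c("F", "M")
  if (any(bad_sex))
    stop_ich(paste0("cohort validation error: sex must be F or M for row id ",
                    co$id[which(bad_sex)[1]]), "ich_validation_error")
  invisible(co)
}

#' Write a cohort back to CSV
#'
#' Inverse of [load_cohort()]: a save/load round trip reproduces every cell.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  drop <- c("survivor", "ivh", "cmo", "rogue_n_count_k", "net_n_count_k")
  out <- cohort[, setdiff(names(cohort), drop), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Add derived per-patient fields
#'
#' Adds `survivor` (no death day recorded), `ivh` (intraventricular
#' hemorrhage, operationalized as modified Graeb score > 0 — the only printed
#' IVH indicator), `cmo` (comfort-measures-only designation recorded), and
#' the neutrophil counts rescaled to thousands per microliter
#' (`rogue_n_count_k`, `net_n_count_k`), the scale used by the composite
#' severity markers. Original columns are unchanged.
#'
#' @param cohort a `cohort_table`.
#' @return the cohort with derived columns appended.
#' @export
derive_fields <- function(cohort) {
  cohort$survivor <- is.na(cohort$death_day)
  cohort$ivh <- cohort$mgs > 0
  cohort$cmo <- !is.na(cohort$cmo_day)
  cohort$rogue_n_count_k <- counts_to_k(cohort$rogue_n_count)
  cohort$net_n_count_k <- counts_to_k(cohort$net_n_count)
  cohort
}

#' Convert cell counts between cells/uL and K/uL
#'
#' @param x counts in cells/uL (`counts_to_k`) or K/uL (`counts_from_k`).
#' @return rescaled counts (exact factor of 1000).
#' @export
counts_to_k <- function(x) x / 1000

#' @rdname counts_to_k
#' @export
counts_from_k <- function(x) x * 1000

#' Neutrophil-to-lymphocyte ratio
#'
#' Quotient of the absolute neutrophil and lymphocyte counts from a
#' same-day CBC differential, both in K/uL.
#'
#' @param neutrophils absolute neutrophil count, K/uL.
#' @param lymphocytes absolute lymphocyte count, K/uL; must be > 0.
#' @return the dimensionless ratio.
#' @export
nlr <- function(neutrophils, lymphocytes) {
  if (any(lymphocytes <= 0))
    stop_ich("nlr undefined: lymphocyte count must be > 0", "ich_domain_error")
  neutrophils / lymphocytes
}
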