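# Readers and writers for the two supplementary-style CSV formats.
#
# Column names in the wild vary, so both readers take a `dialect`: a named
# character vector mapping canonical field names to the file's column
# headers. Defaults follow the clinical-file column list (patient
# identifier, age, grade, event, overall survival, Heng class, MSKCC
# class) in snake_case; "Heng class" is accepted as a synonym for the
# IMDC class throughout.

#' Default column dialects
#'
#' @return named character vector mapping canonical names to CSV headers.
#' @export
clinical_dialect <- function() {
  c(patient_id = "patient_id", age = "age", grade = "grade",
    event = "event", os_months = "overall_survival",
    imdc_class = "heng_class", mskcc_class = "mskcc_class",
    cohort = "cohort", treatment_exposed = "treatment_exposed")
}

#' @rdname clinical_dialect
#' @export
sample_dialect <- function() {
  c(patient_id = "patient_id", sample_id = "sample_id", grade = "grade")
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

.require_cols <- function(df, dialect, path) {
  miss <- setdiff(unname(dialect), names(df))
  if (length(miss) > 0) {
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
}

#' Read a multiregion RPPA sample table
#'
#' One row per (patient, sample); metadata columns named by the dialect,
#' every remaining column a protein with log2-normalised expression
#' values. Non-numeric or blank expression cells are rejected with the
#' offending row and column named.
#'
#' @param path CSV file.
#' @param dialect column mapping, see [sample_dialect()]. The grade entry
#'   is optional in the file.
#' @return data.frame with columns \code{patient_id}, \code{sample_id},
#'   \code{grade} (NA when absent) and one numeric column per protein.
#' @export
read_sample_table <- function(path, dialect = sample_dialect()) {
  df <- .read_csv(path)
  .require_cols(df, dialect[c("patient_id", "sample_id")], path)
  meta_file_cols <- intersect(unname(dialect), names(df))
  prot <- setdiff(names(df), meta_file_cols)
  if (length(prot) == 0) stop("format error in ", path, ": no protein columns")
  out <- data.frame(
    patient_id = as.character(df[[dialect[["patient_id"]]]]),
    sample_id = as.character(df[[dialect[["sample_id"]]]]),
    stringsAsFactors = FALSE
  )
  gcol <- dialect[["grade"]]
  out$grade <- if (!is.null(gcol) && gcol %in% names(df)) {
    suppressWarnings(as.integer(df[[gcol]]))
  } else {
    NA_integer_
  }
  for (p in prot) {
    raw <- df[[p]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0) {
      stop("format error in ", path, ": non-numeric expression at row ",
           bad[1], ", column '", p, "'")
    }
    out[[p]] <- num
  }
  validate_samples(out)
  out
}

# Format doubles at 17 significant digits so read(write(x)) == x exactly.
.fmt_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a sample table
#'
#' Inverse of [read_sample_table()] under the same dialect; doubles are
#' written at full precision so the round-trip is lossless.
#'
#' @param samples sample table.
#' @param path output CSV file.
#' @param dialect column mapping.
#' @export
write_sample_table <- function(samples, path, dialect = sample_dialect()) {
  validate_samples(samples)
  out <- samples
  names(out)[match(.sample_meta_cols, names(out))] <-
    dialect[.sample_meta_cols]
  utils::write.csv(.fmt_full(out), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.parse_class <- function(x, levels, col, synonyms = character()) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | tolower(x) == "na"] <- "unavailable"
  x <- tolower(x)
  x <- gsub("[ /-]+", "_", x)
  for (s in names(synonyms)) x[x == s] <- synonyms[[s]]
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop("format error: unknown ", col, " label(s): ", paste(bad, collapse = ", "))
  }
  x
}

#' Read a clinical table
#'
#' Class labels are mapped onto controlled vocabularies
#' (IMDC/Heng: favourable, intermediate, poor; MSKCC:
#' favourable_intermediate, poor); blanks become \code{"unavailable"} and
#' are never imputed. Optional columns \code{cohort} (default
#' \code{"validation"}) and \code{treatment_exposed} (default
#' \code{FALSE}) extend the minimal supplementary format.
#'
#' @param path CSV file.
#' @param dialect column mapping, see [clinical_dialect()].
#' @return data.frame with canonical clinical columns.
#' @export
read_clinical_table <- function(path, dialect = clinical_dialect()) {
  df <- .read_csv(path)
  core <- dialect[c("patient_id", "age", "grade", "event", "os_months")]
  .require_cols(df, core, path)
  get <- function(field, default = NULL) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(df)) df[[col]] else default
  }
  out <- data.frame(
    patient_id = as.character(df[[dialect[["patient_id"]]]]),
    age = as.numeric(df[[dialect[["age"]]]]),
    grade = suppressWarnings(as.integer(df[[dialect[["grade"]]]])),
    event = as.integer(df[[dialect[["event"]]]]),
    os_months = as.numeric(df[[dialect[["os_months"]]]]),
    stringsAsFactors = FALSE
  )
  out$imdc_class <- .parse_class(
    get("imdc_class", "unavailable"), .imdc_levels, "IMDC class",
    synonyms = c(favorable = "favourable")
  )
  out$mskcc_class <- .parse_class(
    get("mskcc_class", "unavailable"), .mskcc_levels, "MSKCC class",
    synonyms = c(favourable_intermediate = "favourable_intermediate",
                 favorable_intermediate = "favourable_intermediate")
  )
  out$cohort <- .parse_class(get("cohort", "validation"), .cohort_levels, "cohort")
  te <- get("treatment_exposed", FALSE)
  out$treatment_exposed <- as.logical(te)
  if (any(!is.finite(out$os_months) | out$os_months <= 0)) {
    bad <- which(!is.finite(out$os_months) | out$os_months <= 0)[1]
    stop("integrity error in ", path, ": os_months <= 0 at row ", bad)
  }
  validate_clinical(out)
  out
}

#' Write a clinical table
#'
#' Inverse of [read_clinical_table()] under the same dialect.
#'
#' @param patients clinical table.
#' @param path output CSV file.
#' @param dialect column mapping.
#' @export
write_clinical_table <- function(patients, path, dialect = clinical_dialect()) {
  validate_clinical(patients)
  out <- patients
  canon <- intersect(names(dialect), names(out))
  names(out)[match(canon, names(out))] <- dialect[canon]
  utils::write.csv(.fmt_full(out), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
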