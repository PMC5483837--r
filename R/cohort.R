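#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for the clinico-pathological classes.
.imdc_levels <- c("favourable", "intermediate", "poor", "unavailable")
.mskcc_levels <- c("favourable_intermediate", "poor", "unavailable")
.cohort_levels <- c("development", "validation")

# Columns of a sample table that are not protein measurements.
.sample_meta_cols <- c("patient_id", "sample_id", "grade")

#' Protein columns of a sample table
#'
#' @param samples a sample table as returned by [read_sample_table()].
#' @return character vector of protein names.
#' @export
protein_names <- function(samples) {
  setdiff(names(samples), .sample_meta_cols)
}

#' Bundle clinical and sample tables into a cohort
#'
#' A cohort couples a per-patient clinical table with the per-sample
#' multiregion expression table. Every sample must belong to a listed
#' patient; patients without samples are allowed (they are excluded from
#' expression analyses, which require at least one sample each).
#'
#' @param patients clinical table, see [read_clinical_table()].
#' @param samples sample table, see [read_sample_table()].
#' @return an object of class \code{ith_cohort}: a list with elements
#'   \code{patients} and \code{samples}.
#' @export
cohort <- function(patients, samples) {
  validate_clinical(patients)
  validate_samples(samples)
  orphans <- setdiff(samples$patient_id, patients$patient_id)
  if (length(orphans) > 0) {
    stop("samples reference unknown patients: ", paste(orphans, collapse = ", "))
  }
  structure(list(patients = patients, samples = samples), class = "ith_cohort")
}

#' @export
print.ith_cohort <- function(x, ...) {
  cat(sprintf(
    "<ith_cohort> %d patients, %d samples, %d proteins\n",
    nrow(x$patients), nrow(x$samples), length(protein_names(x$samples))
  ))
  tab <- table(factor(x$patients$cohort, levels = .cohort_levels))
  cat("  cohorts:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a cohort to one arm
#'
#' @param x an \code{ith_cohort}.
#' @param arm \code{"development"} or \code{"validation"}.
#' @return an \code{ith_cohort} containing only that arm's patients and samples.
#' @export
cohort_arm <- function(x, arm = .cohort_levels) {
  arm <- match.arg(arm)
  keep <- x$patients$cohort == arm
  pats <- x$patients[keep, , drop = FALSE]
  samp <- x$samples[x$samples$patient_id %in% pats$patient_id, , drop = FALSE]
  rownames(pats) <- rownames(samp) <- NULL
  structure(list(patients = pats, samples = samp), class = "ith_cohort")
}

validate_samples <- function(samples) {
  need <- c("patient_id", "sample_id")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  prot <- protein_names(samples)
  if (length(prot) == 0) stop("sample table has no protein columns")
  for (p in prot) {
    v <- samples[[p]]
    if (!is.numeric(v)) stop("protein column '", p, "' is not numeric")
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop("non-finite expression for protein '", p, "' at row ", bad)
    }
  }
  key <- paste(samples$patient_id, samples$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (patient_id, sample_id): ", gsub("\r", "/", dup))
  }
  if ("grade" %in% names(samples)) {
    g <- samples$grade
    if (any(!is.na(g) & !(g %in% 1:4))) stop("grade must be in 1..4 or NA")
  }
  invisible(samples)
}

validate_clinical <- function(patients) {
  need <- c("patient_id", "age", "grade", "event", "os_months",
            "imdc_class", "mskcc_class", "cohort", "treatment_exposed")
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient_id in clinical table")
  if (any(!(patients$event %in% c(0, 1)))) stop("event must be 0 or 1")
  if (any(!is.finite(patients$os_months) | patients$os_months <= 0)) {
    stop("os_months must be finite and > 0")
  }
  if (any(!is.finite(patients$age) | patients$age <= 0)) stop("age must be finite and > 0")
  chk <- function(col, levels) {
    bad <- setdiff(unique(patients[[col]]), levels)
    if (length(bad) > 0) {
      stop("unknown ", col, " label(s): ", paste(bad, collapse = ", "))
    }
  }
  chk("imdc_class", .imdc_levels)
  chk("mskcc_class", .mskcc_levels)
  chk("cohort", .cohort_levels)
  invisible(patients)
}
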