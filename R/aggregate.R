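#' Aggregate multiregion expression to one value per patient
#'
#' Collapses the per-sample expression table to a per-patient table by
#' taking, for each protein, the median over the selected samples. The
#' median is the aggregation used for risk scoring; the mean is available
#' behind an explicit flag for sensitivity analysis only.
#'
#' @param samples sample table.
#' @param subset optional named list: patient_id -> character vector of
#'   sample_ids to use. Patients absent from the list use all their
#'   samples. Selecting a sample that does not exist is an error.
#' @param fun \code{"median"} (default) or \code{"mean"}.
#' @param patients optional character vector of patient ids that must all
#'   be represented; defaults to the patients present in \code{samples}.
#' @return data.frame with \code{patient_id} and one numeric column per
#'   protein, ordered by \code{patients}.
#' @export
aggregate_patient_expression <- function(samples, subset = NULL,
                                         fun = c("median", "mean"),
                                         patients = NULL) {
  fun <- match.arg(fun)
  agg <- if (fun == "median") stats::median else mean
  if (is.null(patients)) patients <- unique(samples$patient_id)
  prot <- protein_names(samples)
  if (!is.null(subset)) {
    unknown <- setdiff(names(subset), samples$patient_id)
    if (length(unknown) > 0) {
      stop("subset names unknown patient(s): ", paste(unknown, collapse = ", "))
    }
  }
  rows <- lapply(patients, function(pid) {
    sub <- samples[samples$patient_id == pid, , drop = FALSE]
    if (!is.null(subset) && pid %in% names(subset)) {
      want <- subset[[pid]]
      miss <- setdiff(want, sub$sample_id)
      if (length(miss) > 0) {
        stop("patient ", pid, ": selected sample(s) not found: ",
             paste(miss, collapse = ", "))
      }
      sub <- sub[sub$sample_id %in% want, , drop = FALSE]
    }
    if (nrow(sub) == 0) stop("patient with zero selected samples: ", pid)
    vapply(prot, function(p) agg(sub[[p]]), numeric(1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- prot
  cbind(data.frame(patient_id = patients, stringsAsFactors = FALSE), out)
}

#' Compare clinical characteristics between two cohorts
#'
#' Continuous characteristics are compared by the two-sided
#' Mann--Whitney (Wilcoxon rank-sum) test, categorical ones by Fisher's
#' exact test on the cross-tabulation, and proportion-type ones by a
#' two-sided binomial test of the first cohort's success count against
#' the second cohort's observed rate. Raw p-values are
#' Benjamini--Hochberg adjusted across the tested set. Values recorded
#' as \code{"unavailable"} or \code{NA} are dropped per characteristic,
#' shrinking that comparison's n.
#'
#' @param patients_a,patients_b clinical tables for the two cohorts.
#' @param characteristics data.frame with columns \code{name} (a column
#'   of the clinical tables) and \code{type} (\code{"continuous"},
#'   \code{"categorical"} or \code{"binomial"}).
#' @return data.frame: name, type, test, n_a, n_b, p, p_adj.
#' @export
compare_cohorts <- function(patients_a, patients_b, characteristics) {
  stopifnot(nrow(patients_a) >= 2, nrow(patients_b) >= 2)
  res <- lapply(seq_len(nrow(characteristics)), function(i) {
    nm <- characteristics$name[i]
    ty <- characteristics$type[i]
    if (!nm %in% names(patients_a) || !nm %in% names(patients_b)) {
      stop("characteristic absent from records: ", nm)
    }
    a <- patients_a[[nm]]
    b <- patients_b[[nm]]
    drop_u <- function(x) x[!is.na(x) & x != "unavailable"]
    if (ty == "continuous") {
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
      test <- "mann_whitney"
    } else if (ty == "categorical") {
      a <- drop_u(as.character(a)); b <- drop_u(as.character(b))
      tab <- table(
        cohort = rep(c("a", "b"), c(length(a), length(b))),
        value = c(a, b)
      )
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher_exact"
    } else if (ty == "binomial") {
      a <- drop_u(a); b <- drop_u(b)
      pb <- mean(as.numeric(b))
      pb <- min(max(pb, 1e-12), 1 - 1e-12)
      p <- stats::binom.test(sum(as.numeric(a)), length(a), p = pb)$p.value
      test <- "binomial"
    } else {
      stop("unknown characteristic type: ", ty)
    }
    data.frame(name = nm, type = ty, test = test,
               n_a = length(a), n_b = length(b), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
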