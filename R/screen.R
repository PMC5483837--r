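# Intratumoural variance screen: which proteins show inflated
# within-tumour expression variance in treatment-exposed tumours?
#
# Within-tumour variance per cohort is the pooled within-group mean
# square of a one-way ANOVA with tumours as groups; cohorts are compared
# per protein by the ratio of these mean squares (an F statistic on the
# pooled degrees of freedom), gated on distributional assumptions.

#' Per-tumour variance and pooled within-tumour mean square
#'
#' @param samples sample table for one cohort.
#' @param protein protein name.
#' @return list with \code{per_patient} (named vector of unbiased
#'   per-tumour variances, patients with >= 2 samples), \code{pooled_mse}
#'   (within-group mean square) and \code{df} (sum of n_i - 1).
#' @export
per_tumour_variance <- function(samples, protein) {
  if (!protein %in% protein_names(samples)) stop("unknown protein: ", protein)
  sp <- split(samples[[protein]], samples$patient_id)
  sp <- sp[vapply(sp, length, integer(1)) >= 2]
  if (length(sp) == 0) stop("no patient has >= 2 samples")
  vars <- vapply(sp, stats::var, numeric(1))
  ss <- vapply(sp, function(x) sum((x - mean(x))^2), numeric(1))
  df <- sum(vapply(sp, length, integer(1)) - 1L)
  list(per_patient = vars, pooled_mse = sum(ss) / df, df = df)
}

#' Variance-ratio F test between cohorts for one protein
#'
#' Two-tailed p from the F distribution as twice the smaller tail of
#' \code{exposed_mse / naive_mse}. The p-value is only reported when the
#' assumptions hold: Lilliefors normality of the per-tumour-centred
#' residuals (both cohorts) and Fligner--Killeen homogeneity of variance
#' across tumours (within each cohort), all at alpha = 0.05. When the
#' gate fails the log-ratio is still returned and p is \code{NA}.
#'
#' @param exposed_mse,naive_mse pooled within-tumour mean squares.
#' @param df_exposed,df_naive their degrees of freedom.
#' @param assumptions_ok logical from [screen_assumptions()]; \code{TRUE}
#'   when testing pre-gated values directly.
#' @return list: log_ratio (natural log), f, df1, df2, p, assumptions_ok.
#' @export
variance_ratio_test <- function(exposed_mse, naive_mse, df_exposed, df_naive,
                                assumptions_ok = TRUE) {
  stopifnot(df_exposed >= 1, df_naive >= 1)
  if (naive_mse <= 0 || exposed_mse < 0) {
    stop("non-positive mean square in variance ratio")
  }
  f <- exposed_mse / naive_mse
  p <- if (assumptions_ok) {
    min(1, 2 * min(stats::pf(f, df_exposed, df_naive),
                   stats::pf(f, df_exposed, df_naive, lower.tail = FALSE)))
  } else {
    NA_real_
  }
  list(log_ratio = log(f), f = f, df1 = df_exposed, df2 = df_naive,
       p = p, assumptions_ok = assumptions_ok)
}

#' Assumption gate for the variance screen
#'
#' @param exposed,naive numeric expression vectors for one protein.
#' @param exposed_id,naive_id matching patient ids.
#' @param alpha gate level.
#' @return list: ok, lilliefors_p (min over cohorts), fligner_p (min).
#' @export
screen_assumptions <- function(exposed, naive, exposed_id, naive_id,
                               alpha = 0.05) {
  one <- function(x, id) {
    sp <- split(x, id)
    sp <- sp[vapply(sp, length, integer(1)) >= 2]
    resid <- unlist(lapply(sp, function(v) v - mean(v)), use.names = FALSE)
    lp <- tryCatch(nortest::lillie.test(resid)$p.value, error = function(e) NA_real_)
    fp <- tryCatch(
      stats::fligner.test(unlist(sp, use.names = FALSE),
                          factor(rep(names(sp), lengths(sp))))$p.value,
      error = function(e) NA_real_
    )
    c(lillie = lp, fligner = fp)
  }
  pe <- one(exposed, exposed_id)
  pn <- one(naive, naive_id)
  ps <- c(pe, pn)
  list(
    ok = all(!is.na(ps)) && all(ps > alpha),
    lilliefors_p = min(pe[["lillie"]], pn[["lillie"]]),
    fligner_p = min(pe[["fligner"]], pn[["fligner"]])
  )
}

#' Run the variance screen over a protein panel
#'
#' Splits the cohort into treatment-exposed and naive arms via the
#' clinical \code{treatment_exposed} flag and applies
#' [per_tumour_variance()], [screen_assumptions()] and
#' [variance_ratio_test()] per protein.
#'
#' @param x an \code{ith_cohort}.
#' @param proteins panel to screen; defaults to all proteins.
#' @param alpha significance level for the F test and the gate.
#' @param adjust apply Benjamini--Hochberg across the panel (off by
#'   default; selection uses raw p).
#' @return data.frame: protein, log_ratio, f, df1, df2, p, p_adj (if
#'   requested), assumptions_ok, selected; rows in input panel order.
#' @export
screen_ith <- function(x, proteins = NULL, alpha = 0.05, adjust = FALSE) {
  exposed_ids <- x$patients$patient_id[x$patients$treatment_exposed]
  naive_ids <- x$patients$patient_id[!x$patients$treatment_exposed]
  se <- x$samples[x$samples$patient_id %in% exposed_ids, , drop = FALSE]
  sn <- x$samples[x$samples$patient_id %in% naive_ids, , drop = FALSE]
  if (nrow(se) == 0 || nrow(sn) == 0) {
    stop("screen needs both a treatment-exposed and a naive arm")
  }
  if (is.null(proteins)) proteins <- protein_names(x$samples)
  rows <- lapply(proteins, function(p) {
    ve <- per_tumour_variance(se, p)
    vn <- per_tumour_variance(sn, p)
    gate <- screen_assumptions(se[[p]], sn[[p]], se$patient_id, sn$patient_id,
                               alpha = alpha)
    vt <- variance_ratio_test(ve$pooled_mse, vn$pooled_mse, ve$df, vn$df,
                              assumptions_ok = gate$ok)
    data.frame(protein = p, log_ratio = vt$log_ratio, f = vt$f,
               df1 = vt$df1, df2 = vt$df2, p = vt$p,
               assumptions_ok = vt$assumptions_ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$selected <- out$protein %in% select_candidates(out, alpha = alpha)
  out
}

#' Select candidate proteins from screen results
#'
#' Candidates are (1) proteins passing the assumption gate with raw
#' F-test p below \code{alpha} and positive log-ratio (variance higher in
#' the exposed arm), plus (2) gate-failing proteins whose log-ratio
#' exceeds the smallest log-ratio among set (1). Returned in descending
#' log-ratio order; an empty significant set yields an empty list with a
#' warning, since the ranking rule is then undefined.
#'
#' @param screen data.frame from [screen_ith()].
#' @param alpha significance level.
#' @return character vector of candidate proteins.
#' @export
select_candidates <- function(screen, alpha = 0.05) {
  sig <- !is.na(screen$p) & screen$assumptions_ok &
    screen$p < alpha & screen$log_ratio > 0
  if (!any(sig)) {
    warning("no protein met the significance rule; no candidates selected")
    return(character(0))
  }
  floor_lr <- min(screen$log_ratio[sig])
  ranked <- !screen$assumptions_ok & screen$log_ratio > floor_lr
  cand <- screen[sig | ranked, , drop = FALSE]
  cand$protein[order(cand$log_ratio, decreasing = TRUE)]
}
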