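# Survival stratification metrics: Kaplan-Meier, log-rank, group hazard
# ratio, Harrell's concordance, 2-year classification, net
# reclassification improvement, and mixture-model clustering of overall
# survival.

#' Kaplan--Meier estimate
#'
#' Product-limit estimator (right-continuous step function).
#'
#' @param os_months,event outcome vectors.
#' @return list of class \code{km_fit}: \code{fit} (the
#'   \code{survfit} object), \code{surv_at(times)} closure evaluating
#'   S(t).
#' @export
kaplan_meier <- function(os_months, event) {
  stopifnot(length(os_months) >= 1)
  fit <- survival::survfit(survival::Surv(os_months, event) ~ 1)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(fit = fit, surv_at = function(times) sf(times)),
            class = "km_fit")
}

#' Two-group log-rank test
#'
#' @param groups two-level group labels.
#' @param os_months,event outcome vectors.
#' @return list: chisq, p (chi-square with 1 df).
#' @export
log_rank <- function(groups, os_months, event) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2) stop("log_rank needs exactly 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(os_months, event) ~ g)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Group hazard ratio (high vs low) with Wald CI
#'
#' Cox fit on a single binary group indicator. A monotone partial
#' likelihood (e.g. all events in one group) is flagged:
#' the point estimate from the final iterate is still returned but the
#' CI is unreliable.
#'
#' @param groups labels; \code{reference} names the low-risk level.
#' @param os_months,event outcome vectors.
#' @param reference reference (denominator) group label.
#' @param conf_level confidence level.
#' @return list: hr, loghr, se, ci (length-2), p, flagged.
#' @export
group_hazard_ratio <- function(groups, os_months, event, reference = "low",
                               conf_level = 0.95) {
  stopifnot(sum(event) >= 1)
  ind <- as.numeric(groups != reference)
  if (length(unique(ind)) != 2) stop("need both groups represented")
  fit <- fit_cox(data.frame(group = ind), os_months, event)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coef[["group"]]; s <- fit$se[["group"]]
  list(hr = exp(b), loghr = b, se = s,
       ci = exp(c(b - z * s, b + z * s)),
       p = fit$wald_p[["group"]], flagged = fit$monotone)
}

#' Harrell's concordance index with bootstrap CI
#'
#' All-pairs count: a pair is usable when the ordering of failure is
#' determined under censoring (the earlier time is an observed event, or
#' the times are equal with exactly one event). Score ties count 0.5.
#' CI by nonparametric percentile bootstrap over patients.
#'
#' @param scores risk scores (higher = worse prognosis); binary groups
#'   may be passed as 0/1.
#' @param os_months,event outcome vectors.
#' @param n_boot bootstrap resamples (0 disables the CI).
#' @param conf_level confidence level.
#' @param seed seed for the bootstrap.
#' @return list: c, n_pairs, ci.
#' @export
concordance_index <- function(scores, os_months, event, n_boot = 2000,
                              conf_level = 0.95, seed = 1) {
  point <- .cindex(scores, os_months, event)
  if (point$n_pairs == 0) stop("no usable pairs for concordance")
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    rng <- .new_rng(seed)
    on.exit(rng$restore())
    n <- length(scores)
    cs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      r <- .cindex(scores[i], os_months[i], event[i])
      if (r$n_pairs == 0) NA_real_ else r$c
    }, numeric(1))
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(cs, c(a, 1 - a), na.rm = TRUE))
  }
  list(c = point$c, n_pairs = point$n_pairs, ci = ci)
}

.cindex <- function(scores, os_months, event) {
  n <- length(scores)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- os_months[i]; tj <- os_months[j]
      di <- event[i]; dj <- event[j]
      # determine which subject demonstrably fails first
      if (ti < tj && di == 1) {
        worse <- i
      } else if (tj < ti && dj == 1) {
        worse <- j
      } else if (ti == tj && di + dj == 1) {
        worse <- if (di == 1) i else j
      } else {
        next
      }
      usable <- usable + 1
      si <- scores[worse]; sj <- scores[c(i, j)[c(i, j) != worse]]
      conc <- conc + if (si > sj) 1 else if (si == sj) 0.5 else 0
    }
  }
  list(c = if (usable > 0) conc / usable else NA_real_, n_pairs = usable)
}

#' Classification metrics at a survival horizon
#'
#' The positive class is death before the horizon (event observed and
#' os < horizon); everyone else -- alive at the horizon or censored
#' before it -- counts as negative, an optimistic labelling that is
#' flagged in the output. Predicted positive is the high-risk group.
#'
#' @param groups \code{"high"}/\code{"low"} risk labels.
#' @param os_months,event outcome vectors.
#' @param horizon months (default 24).
#' @return list: confusion (2x2 matrix), precision, recall, specificity,
#'   accuracy, mcc, mcc_undefined flag, n_censored_before_horizon.
#' @export
two_year_classification <- function(groups, os_months, event, horizon = 24) {
  stopifnot(horizon > 0)
  truth <- event == 1 & os_months < horizon
  pred <- groups == "high"
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc_undef <- denom == 0
  mcc <- if (mcc_undef) 0 else (tp * tn - fp * fn) / denom
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(predicted = c("high", "low"),
                                       actual = c("death", "no_death"))),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = (tp + tn) / length(groups),
    mcc = mcc, mcc_undefined = mcc_undef,
    n_censored_before_horizon = sum(event == 0 & os_months < horizon)
  )
}

#' Net reclassification improvement with bootstrap CI
#'
#' \code{NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#' P(up|nonevent)]} where "up" is reference-low reclassified new-high.
#' The outcome is death before the horizon as in
#' [two_year_classification()]. Patients lacking either classification
#' (\code{"unavailable"} or NA) are excluded and the analysed n
#' reported.
#'
#' @param reference,new risk labels (\code{"high"}/\code{"low"};
#'   \code{"unavailable"} excluded).
#' @param os_months,event outcome vectors.
#' @param horizon months.
#' @param n_boot bootstrap resamples (percentile CI).
#' @param conf_level confidence level.
#' @param seed seed for the bootstrap.
#' @return list: nri (proportion), ci, n, n_events.
#' @export
net_reclassification_improvement <- function(reference, new, os_months, event,
                                             horizon = 24, n_boot = 2000,
                                             conf_level = 0.95, seed = 1) {
  ok <- !is.na(reference) & !is.na(new) &
    reference != "unavailable" & new != "unavailable"
  reference <- reference[ok]; new <- new[ok]
  os_months <- os_months[ok]; event <- event[ok]
  outcome <- event == 1 & os_months < horizon
  if (sum(outcome) == 0 || sum(!outcome) == 0) {
    stop("NRI needs both events and non-events among classified patients")
  }
  nri_of <- function(ref, nw, out) {
    up <- ref == "low" & nw == "high"
    down <- ref == "high" & nw == "low"
    (mean(up[out]) - mean(down[out])) + (mean(down[!out]) - mean(up[!out]))
  }
  point <- nri_of(reference, new, outcome)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    rng <- .new_rng(seed)
    on.exit(rng$restore())
    n <- length(outcome)
    vals <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (sum(outcome[i]) == 0 || sum(!outcome[i]) == 0) return(NA_real_)
      nri_of(reference[i], new[i], outcome[i])
    }, numeric(1))
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(vals, c(a, 1 - a), na.rm = TRUE))
  }
  list(nri = point, ci = ci, n = length(outcome), n_events = sum(outcome))
}

#' Mixture-model clustering of overall survival
#'
#' Fits univariate Gaussian mixtures with 1..k_max components by EM and
#' selects the cardinality by BIC (via \pkg{mclust}, unequal-variance
#' models). Censored times enter as observed values. Modes are the
#' component means of the selected model; patients are assigned by
#' maximum responsibility and per-cluster median OS is reported.
#'
#' @param os_months survival times of all patients, censored included.
#' @param k_max largest component count considered.
#' @return list: k, modes (sorted component means), weights, cluster
#'   (assignments), cluster_median_os, bic_table.
#' @importFrom mclust Mclust mclustBIC
#' @export
os_mixture_modes <- function(os_months, k_max = 5) {
  stopifnot(length(os_months) >= 4)
  fit <- mclust::Mclust(os_months, G = seq_len(k_max),
                        modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fitting failed for every cardinality")
  ord <- order(fit$parameters$mean)
  med <- vapply(seq_len(fit$G), function(k) {
    stats::median(os_months[fit$classification == ord[k]])
  }, numeric(1))
  list(
    k = fit$G,
    modes = unname(fit$parameters$mean[ord]),
    weights = unname(fit$parameters$pro[ord]),
    cluster = match(fit$classification, ord),
    cluster_median_os = med,
    bic_table = fit$BIC
  )
}
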