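# Cox proportional-hazards estimation and BIC-regularised backward
# elimination. Fitting is delegated to survival::coxph (Efron ties by
# default); the wrapper adds the covariate-mean bookkeeping, BIC, and a
# monotone-likelihood flag so selection never consumes a silently
# diverged fit.

#' Fit a Cox proportional hazards model
#'
#' @param features data.frame or matrix of numeric covariates (one row
#'   per patient; no missing values).
#' @param os_months survival times.
#' @param event death indicator (1 = observed).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return object of class \code{cox_fit}: feature_names, coef,
#'   covariate_means, se, wald_p, loglik (at the optimum), null_loglik,
#'   lrt_stat, lrt_p, n, n_events, converged, monotone (TRUE when the
#'   partial likelihood is monotone in some coefficient, e.g. perfect
#'   risk separation), and the underlying \code{coxph} object.
#' @export
fit_cox <- function(features, os_months, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(os_months), length(os_months) == length(event))
  if (sum(event) < 2) stop("fit_cox needs at least 2 events")
  if (anyNA(features)) stop("fit_cox does not accept missing covariates")
  y <- survival::Surv(os_months, event)
  monotone <- FALSE
  if (ncol(features) == 0) {
    fit <- survival::coxph(y ~ 1, ties = ties)
    ll <- fit$loglik[1]
    out <- list(feature_names = character(0), coef = numeric(0),
                covariate_means = numeric(0), se = numeric(0),
                wald_p = numeric(0), loglik = ll, null_loglik = ll,
                lrt_stat = 0, lrt_p = 1, n = length(event),
                n_events = sum(event), converged = TRUE, monotone = FALSE,
                ties = ties, model = fit)
    class(out) <- "cox_fit"
    return(out)
  }
  xm <- as.matrix(features)
  fit <- withCallingHandlers(
    survival::coxph(y ~ xm, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite|Loglik converged",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- unname(stats::coef(fit))
  names(coefs) <- colnames(features)
  se <- sqrt(diag(fit$var))
  names(se) <- colnames(features)
  out <- list(
    feature_names = colnames(features),
    coef = coefs,
    covariate_means = colMeans(xm),
    se = se,
    wald_p = 2 * stats::pnorm(-abs(coefs / se)),
    loglik = fit$loglik[2],
    null_loglik = fit$loglik[1],
    lrt_stat = 2 * (fit$loglik[2] - fit$loglik[1]),
    lrt_p = stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]),
                          df = ncol(features), lower.tail = FALSE),
    n = length(event),
    n_events = sum(event),
    converged = is.null(fit$info) || fit$iter < 100,
    monotone = monotone,
    ties = ties,
    model = fit
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d features, n=%d (%d events), logPL=%.3f\n",
              length(x$coef), x$n, x$n_events, x$loglik))
  if (length(x$coef) > 0) {
    print(data.frame(coef = x$coef, HR = exp(x$coef), se = x$se, p = x$wald_p))
  }
  if (x$monotone) cat("  ! monotone partial likelihood (flagged)\n")
  invisible(x)
}

#' BIC of a Cox fit
#'
#' \code{-2 logPL + p log(m)} with \code{m} the effective sample size:
#' the number of events by default (the usual choice for censored data),
#' or the number of patients.
#'
#' @param fit a \code{cox_fit}.
#' @param effective_n \code{"events"} or \code{"patients"}.
#' @return numeric BIC value.
#' @export
bic <- function(fit, effective_n = c("events", "patients")) {
  effective_n <- match.arg(effective_n)
  m <- if (effective_n == "events") fit$n_events else fit$n
  -2 * fit$loglik + length(fit$coef) * log(m)
}

#' Backward elimination regularised by BIC
#'
#' Starting from the model with all candidates, each step refits every
#' single-feature-removal submodel (including, from a one-feature model,
#' the null model) and removes the feature whose removal gives the
#' lowest BIC, provided that BIC strictly improves on the current
#' model's. Ties are broken in favour of the earliest feature in input
#' order and logged in the trace. Submodels whose fit fails are skipped
#' with a warning recorded.
#'
#' @param features candidate covariate data.frame.
#' @param os_months,event survival outcome.
#' @param effective_n BIC sample-size convention, see [bic()].
#' @param ties tie handling passed to [fit_cox()].
#' @return list: \code{fit} (the selected \code{cox_fit}),
#'   \code{selected} (feature names), \code{trace} (data.frame of every
#'   candidate removal at every step with its BIC and whether it was
#'   accepted).
#' @export
backward_eliminate <- function(features, os_months, event,
                               effective_n = c("events", "patients"),
                               ties = "efron") {
  effective_n <- match.arg(effective_n)
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 1)
  current <- names(features)
  cur_fit <- fit_cox(features[current], os_months, event, ties = ties)
  cur_bic <- bic(cur_fit, effective_n)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- lapply(seq_along(current), function(i) {
      keep <- current[-i]
      f <- tryCatch(
        fit_cox(features[keep], os_months, event, ties = ties),
        error = function(e) {
          warning("submodel dropping '", current[i], "' failed: ",
                  conditionMessage(e))
          NULL
        }
      )
      list(drop = current[i],
           bic = if (is.null(f)) NA_real_ else bic(f, effective_n),
           fit = f)
    })
    bics <- vapply(cand, `[[`, numeric(1), "bic")
    best <- which(bics == min(bics, na.rm = TRUE))[1]  # first-in-order tie-break
    tied <- sum(bics == bics[best], na.rm = TRUE) > 1
    accepted <- is.finite(bics[best]) && bics[best] < cur_bic
    trace[[step]] <- data.frame(
      step = step, drop = vapply(cand, `[[`, character(1), "drop"),
      bic = bics, current_bic = cur_bic,
      accepted = accepted & seq_along(cand) == best,
      tie = tied, stringsAsFactors = FALSE
    )
    if (!accepted) break
    current <- setdiff(current, cand[[best]]$drop)
    cur_fit <- cand[[best]]$fit
    cur_bic <- bics[best]
    if (length(current) == 0) break
  }
  list(fit = cur_fit, selected = current, bic = cur_bic,
       trace = do.call(rbind, trace))
}

#' Grambsch--Therneau test of proportional hazards
#'
#' Score test on scaled Schoenfeld residuals via
#' \code{survival::cox.zph}.
#'
#' @param fit a \code{cox_fit} with at least 3 events.
#' @param transform time transform: \code{"identity"} (default) or
#'   \code{"km"}.
#' @return data.frame: feature (\code{"GLOBAL"} for the omnibus row),
#'   chisq, df, p.
#' @export
test_proportional_hazards <- function(fit, transform = c("identity", "km")) {
  transform <- match.arg(transform)
  if (fit$n_events < 3) stop("proportional-hazards test needs >= 3 events")
  if (length(fit$coef) == 0) stop("null model has no hazards to test")
  z <- survival::cox.zph(fit$model, transform = transform, global = TRUE)
  tab <- as.data.frame(z$table)
  feature <- rownames(tab)
  feature[seq_along(fit$feature_names)] <- fit$feature_names
  data.frame(feature = feature, chisq = tab$chisq, df = tab$df, p = tab$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- fast single-binary-covariate machinery -------------------------------
#
# The subsampling experiment refits the same two-group Cox model and
# log-rank test for tens of thousands of group labelings over a fixed
# (time, event) vector. Both statistics depend on the labeling only
# through per-death-time group counts, so all datasets are processed
# together with matrix arithmetic: `groups` is an n_datasets x n 0/1
# matrix and a Newton iteration runs on all rows at once.

# Preprocess the shared outcome: order by time, locate death times.
.surv_layout <- function(os_months, event) {
  ord <- order(os_months)
  t_s <- os_months[ord]
  d_s <- event[ord]
  ut <- unique(t_s[d_s == 1])
  list(ord = ord, t = t_s, d = d_s, death_times = ut)
}

# Per-dataset log-rank chi-square (two groups), vectorised over rows of
# `groups` (already ordered to match layout$ord).
.fast_logrank <- function(g, layout) {
  tt <- layout$t; dd <- layout$d; ut <- layout$death_times
  n_data <- nrow(g)
  o_minus_e <- numeric(n_data); v <- numeric(n_data)
  for (k in seq_along(ut)) {
    at <- tt >= ut[k]
    dk <- dd == 1 & tt == ut[k]
    n_tot <- sum(at)
    d_tot <- sum(dk)
    n1 <- as.numeric(g[, at, drop = FALSE] %*% rep(1, n_tot))
    d1 <- as.numeric(g[, dk, drop = FALSE] %*% rep(1, d_tot))
    e1 <- d_tot * n1 / n_tot
    vk <- if (n_tot > 1) {
      d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1)
    } else {
      rep(0, n_data)
    }
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + vk
  }
  chisq <- ifelse(v > 0, o_minus_e^2 / v, 0)
  p <- ifelse(v > 0, stats::pchisq(chisq, 1, lower.tail = FALSE), 1)
  list(chisq = chisq, p = p)
}

# Efron-tie Newton solver for the single binary covariate, vectorised
# over datasets. Returns beta (logHR of group 1 vs 0) with divergence
# flagged; degenerate labelings (a group empty) are flagged and skipped.
.fast_binary_cox <- function(g, layout, max_iter = 40, tol = 1e-9,
                             beta_cap = 15) {
  tt <- layout$t; dd <- layout$d; ut <- layout$death_times
  n_data <- nrow(g)
  K <- length(ut)
  # per-death-time count matrices (n_data x K)
  N1 <- matrix(0, n_data, K); Ntot <- numeric(K)
  D1 <- matrix(0, n_data, K); Dtot <- numeric(K)
  for (k in seq_len(K)) {
    at <- tt >= ut[k]
    dk <- dd == 1 & tt == ut[k]
    Ntot[k] <- sum(at); Dtot[k] <- sum(dk)
    N1[, k] <- as.numeric(g[, at, drop = FALSE] %*% rep(1, Ntot[k]))
    D1[, k] <- as.numeric(g[, dk, drop = FALSE] %*% rep(1, Dtot[k]))
  }
  d1_total <- rowSums(D1)
  degenerate <- rowSums(g) == 0 | rowSums(g) == ncol(g)
  beta <- numeric(n_data)
  active <- !degenerate
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eb <- exp(beta)
    grad <- d1_total
    hess <- numeric(n_data)
    for (k in seq_len(K)) {
      n1 <- N1[, k]; n0 <- Ntot[k] - n1
      d1 <- D1[, k]; d0 <- Dtot[k] - d1
      dk <- Dtot[k]
      for (l in seq_len(dk)) {
        w <- (l - 1) / dk
        a1 <- (n1 - w * d1) * eb      # group-1 weighted risk mass
        a0 <- n0 - w * d0
        denom <- a0 + a1
        mu <- a1 / denom              # expected covariate value
        grad <- grad - mu
        hess <- hess + mu * (1 - mu)
      }
    }
    step <- ifelse(hess > 1e-12, grad / pmax(hess, 1e-12), 0)
    step <- pmin(pmax(step, -2), 2)
    beta[active] <- beta[active] + step[active]
    beta <- pmin(pmax(beta, -beta_cap), beta_cap)
    conv <- abs(grad) < tol | abs(beta) >= beta_cap
    active <- active & !conv
  }
  diverged <- abs(beta) >= beta_cap & !degenerate
  beta[degenerate] <- 0
  list(beta = beta, degenerate = degenerate, diverged = diverged)
}
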