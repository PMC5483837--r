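# Tumour-subsampling experiment: how does limiting the number of
# samples analysed per tumour (MNTS) degrade risk stratification?
#
# A "dataset" is one choice, for every patient, of min(mnts, available)
# of that patient's samples. The combination space is the product of the
# per-patient binomial counts; datasets are drawn without replacement
# from it by mapping a Sobol low-discrepancy point (one dimension per
# patient) to per-patient combination indices, or enumerated
# exhaustively when the space is small.

#' Per-patient combination counts for an MNTS level
#'
#' @param samples sample table.
#' @param mnts maximum number of tumour samples per patient.
#' @return list: \code{per_patient} (data.frame patient_id, n_samples,
#'   k, n_combinations) and \code{total} (product, as double).
#' @export
combination_space <- function(samples, mnts) {
  stopifnot(mnts >= 1)
  n_i <- table(samples$patient_id)
  pp <- data.frame(
    patient_id = names(n_i),
    n_samples = as.integer(n_i),
    stringsAsFactors = FALSE
  )
  pp$k <- pmin(mnts, pp$n_samples)
  pp$n_combinations <- choose(pp$n_samples, pp$k)
  list(per_patient = pp, total = prod(pp$n_combinations))
}

# All k-subsets of one patient's sample ids, lexicographic, as a list.
.patient_combos <- function(sample_ids, k) {
  n <- length(sample_ids)
  if (k >= n) return(list(sample_ids))
  cols <- utils::combn(n, k)
  lapply(seq_len(ncol(cols)), function(j) sample_ids[cols[, j]])
}

#' Draw unique sample-combination datasets by Sobol sampling
#'
#' Each Sobol coordinate u_i (one dimension per patient, digital shift
#' derived from \code{seed}) maps to combination index
#' \code{floor(u_i * C_i) + 1} with combinations in lexicographic
#' sample-id order; duplicate datasets are discarded and further Sobol
#' points consumed until \code{n_datasets} unique ones exist. When
#' \code{n_datasets} equals the full combination space the exhaustive
#' enumeration is returned instead.
#'
#' @param samples sample table.
#' @param mnts maximum samples per patient.
#' @param n_datasets number of unique datasets required.
#' @param seed integer seed (digital shift of the Sobol stream).
#' @return integer matrix (n_datasets x n_patients) of 1-based
#'   combination indices, columns named by patient_id; attribute
#'   \code{"space"} carries the [combination_space()] result.
#' @export
sobol_dataset_draw <- function(samples, mnts, n_datasets, seed = 1) {
  space <- combination_space(samples, mnts)
  pp <- space$per_patient
  if (n_datasets > space$total) {
    stop("n_datasets (", n_datasets, ") exceeds the combination space (",
         format(space$total), "); use exhaustive mode")
  }
  d <- nrow(pp)
  if (n_datasets == space$total) {
    idx <- as.matrix(do.call(expand.grid, lapply(pp$n_combinations, seq_len)))
    idx <- matrix(as.integer(idx), nrow(idx), d)
  } else {
    rng <- .new_rng(seed)
    shift <- as.integer(floor(stats::runif(d) * 2^30))
    rng$restore()
    have <- matrix(integer(0), 0, d)
    keys <- character(0)
    offset <- 0L
    budget <- max(1e5, 50 * n_datasets)
    while (nrow(have) < n_datasets) {
      take <- min(max(2 * (n_datasets - nrow(have)), 1024), 2^17)
      if (offset + take > budget) stop("could not reach ", n_datasets,
                                       " unique datasets; space too small, use exhaustive mode")
      u <- .sobol_block(take, d, shift, offset)
      offset <- offset + take
      blk <- floor(sweep(u, 2, pp$n_combinations, `*`)) + 1
      blk <- matrix(as.integer(pmin(blk, rep(pp$n_combinations, each = nrow(blk)))),
                    nrow(blk), d)
      k <- apply(blk, 1, paste, collapse = ",")
      new <- !(k %in% keys) & !duplicated(k)
      have <- rbind(have, blk[new, , drop = FALSE])
      keys <- c(keys, k[new])
    }
    idx <- have[seq_len(n_datasets), , drop = FALSE]
  }
  colnames(idx) <- pp$patient_id
  attr(idx, "space") <- space
  idx
}

# Sobol points `offset + 1 .. offset + n` of the shifted stream.
.sobol_block <- function(n, d, shift, offset) {
  pts <- sobol_points(offset + n, d, shift = shift)
  pts[(offset + 1):(offset + n), , drop = FALSE]
}

# Per-patient logHR lookup tables: for each patient, the NEAT logHR of
# every combination at the given mnts (lexicographic order).
.patient_loghr_tables <- function(x, model, mnts) {
  coefs <- model$coefficients
  prot <- setdiff(names(coefs), "age")
  centre_const <- sum(coefs * model$centering_means)
  ages <- stats::setNames(x$patients$age, x$patients$patient_id)
  sp <- split(x$samples, x$samples$patient_id)
  lapply(sp, function(sub) {
    k <- min(mnts, nrow(sub))
    combos <- .patient_combos(seq_len(nrow(sub)), k)
    em <- as.matrix(sub[prot])
    age_term <- if ("age" %in% names(coefs)) {
      coefs[["age"]] * ages[[sub$patient_id[1]]]
    } else {
      0
    }
    vapply(combos, function(rows) {
      med <- apply(em[rows, , drop = FALSE], 2, stats::median)
      sum(coefs[prot] * med) + age_term - centre_const
    }, numeric(1))
  })
}

#' Subsampling experiment at one MNTS level
#'
#' For every drawn dataset: aggregate the selected samples per patient
#' (median), compute NEAT logHR, assign risk groups, and record the
#' cohort-level group log hazard ratio (Efron-tie Cox fit on the group
#' indicator) and the log-rank p. Datasets where one risk group is empty
#' are flagged degenerate and score logHR = 0, p = 1 -- dropping them
#' would bias the summaries upward.
#'
#' @param x an \code{ith_cohort}.
#' @param model a \code{neat_model}.
#' @param mnts maximum samples per patient.
#' @param n_datasets unique datasets to evaluate; capped at (and
#'   enumerated exhaustively when it reaches) the combination space.
#' @param seed Sobol stream seed.
#' @param chunk_size datasets processed per block (memory control; the
#'   result is independent of the chunking).
#' @return list of class \code{subsampling_result}: mnts, n_datasets,
#'   loghr, logrank_p, degenerate (logical), diverged (logical),
#'   median_loghr, median_p, n_degenerate, space.
#' @export
subsampling_experiment <- function(x, model, mnts, n_datasets = 1e4,
                                   seed = 1, chunk_size = 5e4) {
  space <- combination_space(x$samples, mnts)
  n_datasets <- min(n_datasets, space$total)
  draw <- sobol_dataset_draw(x$samples, mnts, n_datasets, seed = seed)
  tables <- .patient_loghr_tables(x, model, mnts)
  pids <- colnames(draw)
  clin <- x$patients[match(pids, x$patients$patient_id), ]
  layout <- .surv_layout(clin$os_months, clin$event)
  loghr <- numeric(n_datasets); lr_p <- numeric(n_datasets)
  degen <- logical(n_datasets); dive <- logical(n_datasets)
  for (start in seq(1, n_datasets, by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1, n_datasets)
    # per-patient logHR for each dataset in the chunk
    lhr <- vapply(seq_along(pids), function(j) {
      tables[[pids[j]]][draw[rows, j]]
    }, numeric(length(rows)))
    if (length(rows) == 1) lhr <- matrix(lhr, 1)
    g <- (lhr > model$threshold) * 1
    g <- g[, layout$ord, drop = FALSE]
    cox <- .fast_binary_cox(g, layout)
    lr <- .fast_logrank(g, layout)
    loghr[rows] <- ifelse(cox$degenerate, 0, cox$beta)
    lr_p[rows] <- ifelse(cox$degenerate, 1, lr$p)
    degen[rows] <- cox$degenerate
    dive[rows] <- cox$diverged
  }
  structure(list(
    mnts = mnts, n_datasets = n_datasets, loghr = loghr, logrank_p = lr_p,
    degenerate = degen, diverged = dive,
    median_loghr = stats::median(loghr), median_p = stats::median(lr_p),
    n_degenerate = sum(degen), space = space
  ), class = "subsampling_result")
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat(sprintf(
    "<subsampling_result> MNTS=%d: %d datasets (space %.3g), median logHR %.3f, median log-rank p %.3g, %d degenerate\n",
    x$mnts, x$n_datasets, x$space$total, x$median_loghr, x$median_p,
    x$n_degenerate
  ))
  invisible(x)
}

#' Compare logHR distributions of two MNTS levels
#'
#' Two-sided Mann--Whitney test on the per-dataset logHR distributions.
#'
#' @param result_a,result_b \code{subsampling_result} objects.
#' @return list: statistic, p, median_a, median_b.
#' @export
compare_mnts_distributions <- function(result_a, result_b) {
  stopifnot(length(result_a$loghr) > 0, length(result_b$loghr) > 0)
  wt <- suppressWarnings(stats::wilcox.test(result_a$loghr, result_b$loghr))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_a = result_a$median_loghr, median_b = result_b$median_loghr)
}

#' Test stratification against random expectation
#'
#' Two-sided binomial test of the number of datasets with positive logHR
#' against Binomial(n, 1/2).
#'
#' @param result a \code{subsampling_result}.
#' @return list: n_positive, n, p.
#' @export
random_expectation_test <- function(result) {
  n <- length(result$loghr)
  npos <- sum(result$loghr > 0)
  list(n_positive = npos, n = n,
       p = stats::binom.test(npos, n, 0.5)$p.value)
}

#' Exhaustive per-patient logHR range over sample subsets
#'
#' Enumerates every k-subset of one patient's samples for each k from 1
#' to the number available, computes the NEAT logHR of each subset, and
#' reports the range and whether it spans the classification threshold.
#'
#' @param x an \code{ith_cohort}.
#' @param model a \code{neat_model}.
#' @param patient_id one patient.
#' @return list: loghr_by_k (list of numeric vectors), min, max,
#'   spans_threshold.
#' @export
per_patient_loghr_range <- function(x, model, patient_id) {
  sub <- x$samples[x$samples$patient_id == patient_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("patient has no samples: ", patient_id)
  coefs <- model$coefficients
  prot <- setdiff(names(coefs), "age")
  em <- as.matrix(sub[prot])
  age_term <- if ("age" %in% names(coefs)) {
    coefs[["age"]] * x$patients$age[x$patients$patient_id == patient_id]
  } else {
    0
  }
  centre_const <- sum(coefs * model$centering_means)
  by_k <- lapply(seq_len(nrow(sub)), function(k) {
    vapply(.patient_combos(seq_len(nrow(sub)), k), function(rows) {
      med <- apply(em[rows, , drop = FALSE], 2, stats::median)
      sum(coefs[prot] * med) + age_term - centre_const
    }, numeric(1))
  })
  names(by_k) <- paste0("k", seq_along(by_k))
  all_v <- unlist(by_k, use.names = FALSE)
  list(loghr_by_k = by_k, min = min(all_v), max = max(all_v),
       spans_threshold = min(all_v) <= model$threshold &
         max(all_v) >= model$threshold)
}

#' Fraction of patients whose logHR range spans the threshold
#'
#' @param x an \code{ith_cohort}.
#' @param model a \code{neat_model}.
#' @return list: fraction, flagged (patient ids), n.
#' @export
risk_flip_fraction <- function(x, model) {
  pids <- unique(x$samples$patient_id)
  flags <- vapply(pids, function(p) {
    per_patient_loghr_range(x, model, p)$spans_threshold
  }, logical(1))
  list(fraction = mean(flags), flagged = pids[flags], n = length(pids))
}

#' Grade dependence of per-patient risk variability
#'
#' For each patient and grade class (low = Fuhrman 1--2, high = 3--4),
#' the variance of the single-sample NEAT logHRs over that patient's
#' samples of that class (patients contribute a class only with >= 2
#' graded samples in it). Classes are compared by the fold ratio of the
#' per-class medians and a two-sided Mann--Whitney test on the two sets
#' of per-patient variances.
#'
#' @param x an \code{ith_cohort} with per-sample grades.
#' @param model a \code{neat_model}.
#' @param low_grades Fuhrman grades defining the low class.
#' @return list: median_low, median_high, fold (median_low /
#'   median_high; NaN with \code{fold_undefined} when both medians are
#'   0), p, per_patient (data.frame patient_id, grade_class, variance).
#' @export
grade_variance_analysis <- function(x, model, low_grades = c(1, 2)) {
  samples <- x$samples[!is.na(x$samples$grade), , drop = FALSE]
  if (nrow(samples) == 0) stop("no graded samples available")
  rows <- list()
  for (pid in unique(samples$patient_id)) {
    rng <- per_patient_loghr_range(x, model, pid)
    sub <- x$samples[x$samples$patient_id == pid, , drop = FALSE]
    single <- rng$loghr_by_k$k1   # one value per sample, sample order
    for (cls in c("low", "high")) {
      in_cls <- !is.na(sub$grade) &
        (sub$grade %in% low_grades) == (cls == "low")
      if (sum(in_cls) >= 2) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pid, grade_class = cls,
          variance = stats::var(single[in_cls]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  pp <- do.call(rbind, rows)
  for (cls in c("low", "high")) {
    if (is.null(pp) || !any(pp$grade_class == cls)) {
      stop("no patient qualifies for grade class: ", cls)
    }
  }
  v_low <- pp$variance[pp$grade_class == "low"]
  v_high <- pp$variance[pp$grade_class == "high"]
  m_low <- stats::median(v_low); m_high <- stats::median(v_high)
  undef <- m_high == 0
  list(
    median_low = m_low, median_high = m_high,
    fold = if (undef) NaN else m_low / m_high, fold_undefined = undef,
    p = stats::wilcox.test(v_low, v_high, exact = FALSE)$p.value,
    per_patient = pp
  )
}

#' Does full-data aggregation beat the best single sample?
#'
#' Empirical exceedance p-value of the full-data cohort logHR within the
#' MNTS = 1 distribution: \code{(1 + #\{logHR >= full\}) / (n + 1)}.
#'
#' @param result_mnts1 \code{subsampling_result} at MNTS = 1.
#' @param full_loghr cohort logHR using all available samples.
#' @return list: p, full_loghr, n_datasets.
#' @export
full_vs_best_single_sample <- function(result_mnts1, full_loghr) {
  stopifnot(result_mnts1$mnts == 1)
  n <- length(result_mnts1$loghr)
  list(p = (1 + sum(result_mnts1$loghr >= full_loghr)) / (n + 1),
       full_loghr = full_loghr, n_datasets = n)
}
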