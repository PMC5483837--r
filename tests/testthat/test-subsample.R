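test_that("combination space counts follow the binomial coefficients", {
  s <- toy_samples()  # P1: 2 samples, P2: 2, P3: 1
  sp <- combination_space(s, 2)
  expect_equal(sp$per_patient$n_combinations, c(1, 1, 1))
  expect_equal(sp$total, 1)

  sp1 <- combination_space(s, 1)
  expect_equal(sp1$per_patient$n_combinations, c(2, 2, 1))
  expect_equal(sp1$total, 4)

  four <- data.frame(patient_id = "A", sample_id = paste0("S", 1:4),
                     grade = NA_integer_, P = rnorm(4))
  expect_equal(combination_space(four, 2)$per_patient$n_combinations, 6)

  # three patients with four samples each, one sample taken: 4^3 datasets
  trip <- data.frame(patient_id = rep(c("A", "B", "C"), each = 4),
                     sample_id = rep(paste0("S", 1:4), 3),
                     grade = NA_integer_, P = rnorm(12))
  expect_equal(combination_space(trip, 1)$total, 64)
})

test_that("requesting the whole space enumerates it exactly once", {
  trip <- data.frame(patient_id = rep(c("A", "B", "C"), each = 4),
                     sample_id = rep(paste0("S", 1:4), 3),
                     grade = NA_integer_, P = rnorm(12))
  draw <- sobol_dataset_draw(trip, 1, 64)
  expect_equal(nrow(draw), 64)
  keys <- apply(draw, 1, paste, collapse = ",")
  expect_equal(sort(keys),
               sort(apply(expand.grid(1:4, 1:4, 1:4), 1, paste, collapse = ",")))
  expect_error(sobol_dataset_draw(trip, 1, 65), "exceeds")
})

test_that("drawn datasets are unique and per-patient marginals are uniform", {
  co <- cached_cohort(11)
  val <- cohort_arm(co, "validation")
  draw <- sobol_dataset_draw(val$samples, 2, 1e4, seed = 5)
  keys <- apply(draw, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0)
  space <- attr(draw, "space")
  for (j in which(space$per_patient$n_combinations >= 4)[1:5]) {
    cj <- space$per_patient$n_combinations[j]
    counts <- tabulate(draw[, j], nbins = cj)
    gof <- chisq.test(counts, p = rep(1 / cj, cj))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("the Sobol stream is deterministic given the seed", {
  co <- cached_cohort(11)
  val <- cohort_arm(co, "validation")
  a <- sobol_dataset_draw(val$samples, 1, 500, seed = 9)
  b <- sobol_dataset_draw(val$samples, 1, 500, seed = 9)
  d <- sobol_dataset_draw(val$samples, 1, 500, seed = 10)
  expect_identical(a, b)
  expect_false(identical(unclass(a), unclass(d)))
})

test_that("vanishing intratumoural noise collapses every dataset to the full result", {
  cfg <- simulation_config(n_patients = 12, n_proteins = 6,
                           within_tumour_sd = 1e-6,
                           grade_sd_multiplier = c(low = 1, high = 1),
                           region_outlier_factor = 1)
  co <- generate_cohort(cfg, seed = 2)
  val <- cohort_arm(co, "validation")
  m <- neat_from_cohort(cohort_arm(co, "development"))
  res <- subsampling_experiment(val, m, 1, 200, seed = 3)
  expect_lt(diff(range(res$loghr)), 1e-3)
  # per-patient ranges are point masses as well
  rng <- per_patient_loghr_range(val, m, val$patients$patient_id[1])
  expect_lt(rng$max - rng$min, 1e-3)
})

test_that("the experiment over the whole space equals a brute-force survival run", {
  cfg <- simulation_config(n_patients = 6, n_proteins = 6,
                           sample_count_probs = c(0, 1))  # 2 samples each
  co <- generate_cohort(cfg, seed = 13)
  val <- cohort_arm(co, "validation")
  m <- neat_from_cohort(cohort_arm(co, "development"))
  space <- combination_space(val$samples, 1)
  expect_equal(space$total, 2^6)
  res <- subsampling_experiment(val, m, 1, space$total, seed = 1)
  expect_equal(res$n_datasets, 64)

  # oracle: enumerate all combinations in the same lexicographic order,
  # re-aggregate, and use the survival package directly for the group
  # Cox fit and log-rank test
  combos <- expand.grid(lapply(seq_len(6), function(i) 1:2))
  pids <- space$per_patient$patient_id
  ref <- t(vapply(seq_len(nrow(combos)), function(r) {
    subset <- lapply(seq_along(pids), function(i) {
      sub <- val$samples[val$samples$patient_id == pids[i], ]
      sub$sample_id[combos[r, i]]
    })
    names(subset) <- pids
    sc <- neat_score_cohort(val, m, subset = subset)
    if (length(unique(sc$risk_group)) == 1) return(c(0, 1))
    y <- survival::Surv(sc$os_months, sc$event)
    cx <- suppressWarnings(
      survival::coxph(y ~ I(sc$risk_group == "high"))
    )
    sd <- survival::survdiff(y ~ sc$risk_group)
    c(unname(coef(cx)), pchisq(sd$chisq, 1, lower.tail = FALSE))
  }, numeric(2)))

  usable <- !res$degenerate & !res$diverged & abs(ref[, 1]) < 14
  expect_gt(mean(usable), 0.5)
  expect_equal(res$loghr[usable], ref[usable, 1], tolerance = 1e-6)
  expect_equal(res$logrank_p, ref[, 2], tolerance = 1e-9)
})

test_that("distribution comparisons match their exact small-sample oracles", {
  a <- structure(list(loghr = c(0.1, 0.5, 0.9, 1.3, 1.7, 2.1),
                      median_loghr = 1.1), class = "subsampling_result")
  b <- structure(list(loghr = c(-0.2, 0.2, 0.6, 1.0, 1.4, 1.8),
                      median_loghr = 0.8), class = "subsampling_result")
  r <- compare_mnts_distributions(a, b)
  # exact rank-sum enumeration over all 6-of-12 assignments
  pool <- c(a$loghr, b$loghr)
  w_obs <- sum(rank(pool)[1:6]) - 6 * 7 / 2
  combos <- combn(12, 6)
  ws <- apply(combos, 2, function(i) sum(rank(pool)[i]) - 21)
  p_exact <- mean(abs(ws - 18) >= abs(w_obs - 18))
  expect_equal(r$p, p_exact, tolerance = 1e-10)

  same <- compare_mnts_distributions(a, a)
  expect_gt(same$p, 0.99)
})

test_that("the sign test against random expectation is two-sided binomial", {
  res <- structure(list(loghr = c(rep(1, 5), rep(-1, 5))),
                   class = "subsampling_result")
  r <- random_expectation_test(res)
  expect_equal(r$p, 1)
  res2 <- structure(list(loghr = rep(1, 12)), class = "subsampling_result")
  expect_equal(random_expectation_test(res2)$p, binom.test(12, 12, 0.5)$p.value)
})

test_that("per-patient ranges span the threshold exactly when signs straddle", {
  samples <- data.frame(
    patient_id = c("A", "A", "B"),
    sample_id = c("S1", "S2", "S1"),
    grade = c(2L, 3L, 2L),
    CDH2 = c(-0.2, 0.3, 0.5) / 8.927,
    EPCAM = 0, MTOR = 0
  )
  clinical <- data.frame(
    patient_id = c("A", "B"), age = c(60, 60), grade = 2L, event = 1L,
    os_months = 12, imdc_class = "unavailable", mskcc_class = "unavailable",
    cohort = "validation", treatment_exposed = FALSE
  )
  co <- cohort(clinical, samples)
  m <- neat_model(c(CDH2 = 0, EPCAM = 0, age = 60, MTOR = 0))
  ra <- per_patient_loghr_range(co, m, "A")
  expect_true(ra$spans_threshold)
  expect_equal(ra$min, -0.2, tolerance = 1e-9)
  expect_equal(ra$max, 0.3, tolerance = 1e-9)
  # k = 2 median (mean of the two) is included
  expect_equal(ra$loghr_by_k$k2, 0.05, tolerance = 1e-9)

  single <- per_patient_loghr_range(co, m, "B")
  expect_equal(single$max - single$min, 0)
  expect_false(single$spans_threshold)

  rf <- risk_flip_fraction(co, m)
  expect_equal(rf$fraction, 0.5)
  expect_equal(rf$flagged, "A")
})

test_that("grade-linked variance recovery approximates the configured fold", {
  folds <- vapply(1:50, function(s) {
    co <- generate_cohort(
      simulation_config(n_proteins = 6, region_outlier_factor = 1),
      seed = s + 900
    )
    val <- cohort_arm(co, "validation")
    m <- neat_from_cohort(cohort_arm(co, "development"))
    r <- tryCatch(grade_variance_analysis(val, m),
                  error = function(e) list(fold = NA_real_))
    r$fold
  }, numeric(1))
  expect_equal(median(folds, na.rm = TRUE), 3.5, tolerance = 0.2)
})

test_that("identical samples give zero variance in both grade classes", {
  samples <- data.frame(
    patient_id = rep(c("A", "B"), each = 4),
    sample_id = rep(paste0("S", 1:4), 2),
    grade = rep(c(1L, 1L, 4L, 4L), 2),
    CDH2 = -7, EPCAM = -6, MTOR = -7.5
  )
  clinical <- data.frame(
    patient_id = c("A", "B"), age = 60, grade = 3L, event = 1L,
    os_months = c(12, 20), imdc_class = "unavailable",
    mskcc_class = "unavailable", cohort = "validation",
    treatment_exposed = FALSE
  )
  co <- cohort(clinical, samples)
  m <- neat_model(c(CDH2 = -7, EPCAM = -6, age = 60, MTOR = -7.5))
  r <- grade_variance_analysis(co, m)
  expect_equal(r$median_low, 0)
  expect_equal(r$median_high, 0)
  expect_true(r$fold_undefined)
  expect_true(is.nan(r$fold))
})

test_that("full-data exceedance p behaves at the extremes", {
  res <- structure(list(mnts = 1, loghr = rep(2, 10)),
                   class = "subsampling_result")
  expect_equal(full_vs_best_single_sample(res, 2)$p, 1)     # point mass
  expect_equal(full_vs_best_single_sample(res, 3)$p, 1 / 11)
  low <- structure(list(mnts = 1, loghr = c(rep(3, 9), 1)),
                   class = "subsampling_result")
  expect_gt(full_vs_best_single_sample(low, 2)$p, 0.5)
})

test_that("experiment summaries are stable across Sobol seeds", {
  co <- cached_cohort(11)
  val <- cohort_arm(co, "validation")
  m <- neat_from_cohort(cohort_arm(co, "development"))
  meds <- vapply(1:5, function(s) {
    subsampling_experiment(val, m, 2, 2000, seed = s)$median_loghr
  }, numeric(1))
  expect_lt(max(meds) - min(meds), 0.1)
})
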