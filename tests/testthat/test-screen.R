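test_that("pooled within-tumour mean square matches hand ANOVA values", {
  s <- data.frame(
    patient_id = rep(c("A", "B"), each = 2),
    sample_id = rep(c("S1", "S2"), 2),
    grade = NA_integer_,
    PROT = c(0, 2, 1, 3)
  )
  v <- per_tumour_variance(s, "PROT")
  expect_equal(v$pooled_mse, 2)       # each group variance 2
  expect_equal(unname(v$per_patient), c(2, 2))
  expect_equal(v$df, 2)

  s$PROT <- rep(5, 4)
  expect_equal(per_tumour_variance(s, "PROT")$pooled_mse, 0)

  one_each <- data.frame(patient_id = c("A", "B"), sample_id = c("S1", "S1"),
                         grade = NA_integer_, PROT = c(1, 2))
  expect_error(per_tumour_variance(one_each, "PROT"), ">= 2 samples")
})

test_that("pooled MSE equals the within-group mean square of one-way ANOVA", {
  set.seed(31)
  s <- data.frame(
    patient_id = rep(paste0("P", 1:6), times = c(2, 3, 4, 2, 5, 3)),
    sample_id = unlist(lapply(c(2, 3, 4, 2, 5, 3), function(k) paste0("S", 1:k))),
    grade = NA_integer_,
    PROT = rnorm(19)
  )
  v <- per_tumour_variance(s, "PROT")
  fit <- anova(lm(PROT ~ patient_id, data = s))
  expect_equal(v$pooled_mse, fit["Residuals", "Mean Sq"], tolerance = 1e-12)
  expect_equal(v$df, fit["Residuals", "Df"])
})

test_that("equal mean squares give log-ratio 0, F 1 and two-tailed p 1", {
  r <- variance_ratio_test(0.5, 0.5, 20, 20)
  expect_equal(r$log_ratio, 0)
  expect_equal(r$f, 1)
  expect_equal(r$p, 1)
})

test_that("the variance-ratio test is antisymmetric under cohort swap", {
  a <- variance_ratio_test(0.8, 0.3, 15, 22)
  b <- variance_ratio_test(0.3, 0.8, 22, 15)
  expect_equal(a$log_ratio, -b$log_ratio)
  expect_equal(a$p, b$p)
})

test_that("the F tail probability matches a Monte-Carlo oracle at small df", {
  set.seed(77)
  n1 <- 5; n2 <- 7   # df 4 and 6
  reps <- 1e5
  v1 <- apply(matrix(rnorm(reps * n1), reps), 1, var)
  v2 <- apply(matrix(rnorm(reps * n2), reps), 1, var)
  ratio <- v1 / v2
  f_obs <- 2.7
  mc_tail <- mean(ratio >= f_obs)
  mc_sd <- sqrt(mc_tail * (1 - mc_tail) / reps)
  analytic_tail <- pf(f_obs, n1 - 1, n2 - 1, lower.tail = FALSE)
  expect_lt(abs(mc_tail - analytic_tail), 3 * mc_sd + 1e-12)
  r <- variance_ratio_test(f_obs, 1, n1 - 1, n2 - 1)
  expect_equal(r$p, 2 * min(analytic_tail, 1 - analytic_tail), tolerance = 1e-12)
})

test_that("gate-failing proteins report no p but keep their log-ratio", {
  r <- variance_ratio_test(0.9, 0.3, 10, 10, assumptions_ok = FALSE)
  expect_true(is.na(r$p))
  expect_equal(r$log_ratio, log(3))
  expect_error(variance_ratio_test(0.5, 0, 10, 10), "non-positive")
})

test_that("candidate selection applies the significance-plus-ranking rule", {
  scr <- data.frame(
    protein = c("A", "B", "C", "D", "E"),
    log_ratio = c(1.5, 0.8, 1.1, 0.5, -0.4),
    p = c(0.01, 0.03, NA, 0.2, 0.01),
    assumptions_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  # A, B significant (floor 0.8); C fails the gate but exceeds the floor
  expect_equal(select_candidates(scr), c("A", "C", "B"))

  none <- data.frame(protein = "A", log_ratio = 1.2, p = 0.2,
                     assumptions_ok = TRUE)
  expect_warning(out <- select_candidates(none), "no protein")
  expect_equal(out, character(0))

  # negative log-ratios never qualify, however small their p
  neg <- data.frame(protein = c("A", "B"), log_ratio = c(-1.2, 0.9),
                    p = c(0.001, 0.01), assumptions_ok = TRUE)
  expect_equal(select_candidates(neg), "B")
})

test_that("inflated proteins dominate the log-ratio ranking on synthetic truth", {
  inflated <- c("CA9", "CDH2", "EPCAM", "MTOR")
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(
      simulation_config(n_proteins = 12, inflated_proteins = inflated,
                        variance_inflation = 2, region_outlier_factor = 1),
      seed = s + 100
    )
    scr_exp <- co$samples[co$samples$patient_id %in%
                            co$patients$patient_id[co$patients$treatment_exposed], ]
    scr_nai <- co$samples[!co$samples$patient_id %in% scr_exp$patient_id, ]
    lr <- vapply(protein_names(co$samples), function(p) {
      log(per_tumour_variance(scr_exp, p)$pooled_mse /
            per_tumour_variance(scr_nai, p)$pooled_mse)
    }, numeric(1))
    setequal(names(sort(lr, decreasing = TRUE))[1:4], inflated)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the full screen selects inflated proteins on a typical cohort", {
  co <- generate_cohort(
    simulation_config(n_proteins = 12,
                      inflated_proteins = c("CA9", "CDH2", "EPCAM", "MTOR"),
                      variance_inflation = 2, region_outlier_factor = 1),
    seed = 42
  )
  scr <- screen_ith(co)
  expect_true(all(c("protein", "log_ratio", "f", "p", "assumptions_ok",
                    "selected") %in% names(scr)))
  top4 <- scr$protein[order(-scr$log_ratio)][1:4]
  expect_setequal(top4, c("CA9", "CDH2", "EPCAM", "MTOR"))
  expect_true(all(top4 %in% scr$protein[scr$selected]))
})

test_that("under the null the gated F test rejects at the nominal rate", {
  # Gaussian generator, no inflation: exposed and naive arms exchangeable
  res <- lapply(1:200, function(s) {
    co <- generate_cohort(
      simulation_config(n_patients = 11, n_proteins = 8,
                        region_outlier_factor = 1,
                        grade_sd_multiplier = c(low = 1, high = 1)),
      seed = s + 500
    )
    scr <- suppressWarnings(screen_ith(co))
    scr[scr$assumptions_ok, "p"]
  })
  p <- unlist(res)
  n <- length(p)
  rate <- mean(p < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_gt(n, 200)  # the gate passes most Gaussian panels
  expect_lt(abs(rate - 0.05), bound + 1e-12)
})
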