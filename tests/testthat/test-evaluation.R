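test_that("Kaplan-Meier matches hand product-limit values", {
  km_all_censored <- kaplan_meier(c(4, 9, 12), c(0, 0, 0))
  expect_equal(km_all_censored$surv_at(c(1, 5, 20)), c(1, 1, 1))

  km <- kaplan_meier(c(5, 10, 15), c(0, 1, 1))
  expect_equal(km$surv_at(10), 0.5)
  expect_equal(km$surv_at(12), 0.5)
  expect_equal(km$surv_at(15), 0)
  expect_equal(km$surv_at(9.99), 1)
})

test_that("log-rank agrees with the hand O-E/V oracle and is symmetric", {
  time <- c(3, 5, 8, 10, 12, 15, 17, 20)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  grp <- c("a", "a", "a", "a", "b", "b", "b", "b")
  r <- log_rank(grp, time, event)
  hand <- hand_logrank(grp, time, event)
  expect_equal(r$chisq, hand$chisq, tolerance = 1e-10)
  expect_equal(r$p, hand$p, tolerance = 1e-10)
  # label swap
  swapped <- log_rank(ifelse(grp == "a", "b", "a"), time, event)
  expect_equal(swapped$chisq, r$chisq, tolerance = 1e-12)
  # monotone time rescaling
  rescaled <- log_rank(grp, sqrt(time), event)
  expect_equal(rescaled$chisq, r$chisq, tolerance = 1e-12)
})

test_that("log-rank on interleaved identical survival is near zero", {
  time <- rep(c(2, 4, 6, 8), each = 2)
  event <- rep(1, 8)
  grp <- rep(c("a", "b"), 4)
  r <- log_rank(grp, time, event)
  expect_lt(r$chisq, 1e-10)
  expect_gt(r$p, 0.999)
  expect_error(log_rank(rep("a", 8), time, event), "2 non-empty groups")
})

test_that("group hazard ratio recovers exchangeability and flags separation", {
  time <- rep(c(2, 4, 6, 8, 11, 13), each = 2)
  event <- rep(1, 12)
  r <- group_hazard_ratio(rep(c("low", "high"), 6), time, event)
  expect_equal(r$hr, 1, tolerance = 0.15)
  expect_true(r$ci[1] < 1 & r$ci[2] > 1)

  sep <- group_hazard_ratio(rep(c("high", "low"), each = 4),
                            c(1, 2, 3, 4, 20, 21, 22, 23), rep(1, 8))
  expect_true(sep$flagged)
})

test_that("concordance counts pairs like the exhaustive hand oracle", {
  # perfect ordering, no censoring
  r <- concordance_index(c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5), rep(1, 5),
                         n_boot = 0)
  expect_equal(r$c, 1)
  expect_equal(r$n_pairs, 10)

  # 5-subject toy with a score tie and censoring, counted by hand:
  scores <- c(3, 3, 2, 1, 5)
  time <- c(2, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1)
  # usable pairs (earlier time has event): (1,2),(1,3),(1,4),(1,5),
  # (2,3),(2,4),(2,5),(4,5); concordant: (1,3) 3>2,(1,4) 3>1,(2,3),(2,4);
  # tie (1,2) scores 3,3 -> 0.5; (1,5),(2,5),(4,5): lower score died first -> 0
  r <- concordance_index(scores, time, event, n_boot = 0)
  expect_equal(r$n_pairs, 8)
  expect_equal(r$c, (4 + 0.5) / 8)
})

test_that("negating the scores reflects concordance around one half", {
  co <- cached_cohort(11)
  val <- cohort_arm(co, "validation")
  sc <- neat_score_cohort(val, neat_from_cohort(cohort_arm(co, "development")))
  a <- concordance_index(sc$loghr, sc$os_months, sc$event, n_boot = 0)
  b <- concordance_index(-sc$loghr, sc$os_months, sc$event, n_boot = 0)
  expect_equal(a$c, 1 - b$c, tolerance = 1e-12)
  ci <- concordance_index(sc$loghr, sc$os_months, sc$event,
                          n_boot = 200, seed = 9)
  expect_true(ci$ci[1] <= ci$c && ci$c <= ci$ci[2])
})

test_that("two-year classification reproduces reconstructed confusion matrices", {
  # validation-style: TP=4 FP=0 FN=4 TN=14
  groups <- rep(c("high", "low"), c(4, 18))
  os <- c(rep(5, 4), rep(6, 4), rep(30, 14))
  event <- c(rep(1, 4), rep(1, 4), rep(0, 14))
  r <- two_year_classification(groups, os, event)
  expect_equal(unname(r$confusion["high", "death"]), 4)
  expect_equal(r$accuracy, 18 / 22, tolerance = 1e-12)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$specificity, 1)
  expect_equal(r$mcc, 0.62, tolerance = 0.01)

  # development-style: TP=8 FP=6 FN=0 TN=8
  groups <- rep(c("high", "low"), c(14, 8))
  os <- c(rep(4, 8), rep(40, 6), rep(40, 8))
  event <- c(rep(1, 8), rep(0, 6), rep(0, 8))
  r <- two_year_classification(groups, os, event)
  expect_equal(r$accuracy, 16 / 22, tolerance = 1e-12)
  expect_equal(r$mcc, 0.57, tolerance = 0.01)
})

test_that("metrics are mutually consistent with the emitted confusion matrix", {
  set.seed(12)
  for (i in 1:20) {
    n <- 25
    groups <- sample(c("high", "low"), n, replace = TRUE)
    os <- rexp(n, 1 / 20)
    event <- rbinom(n, 1, 0.6)
    r <- two_year_classification(groups, os, event)
    cm <- r$confusion
    tp <- cm["high", "death"]; fp <- cm["high", "no_death"]
    fn <- cm["low", "death"]; tn <- cm["low", "no_death"]
    expect_equal(r$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(r$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(r$recall, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(r$specificity, tn / (tn + fp))
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (den > 0) expect_equal(r$mcc, (tp * tn - fp * fn) / den)
  }
})

test_that("an all-negative predictor yields recall 0 and flagged MCC", {
  r <- two_year_classification(rep("low", 6), c(3, 5, 30, 30, 30, 30),
                               c(1, 1, 0, 0, 0, 0))
  expect_equal(r$recall, 0)
  expect_true(r$mcc_undefined)
  expect_equal(r$mcc, 0)
})

test_that("NRI matches hand arithmetic and is antisymmetric", {
  # 10 patients: 2 events reclassified up, 1 non-event up, rest static
  ref <- c("low", "low", "high", "low", "low", "low", "low", "low", "low", "low")
  new <- c("high", "high", "high", "high", "low", "low", "low", "low", "low", "low")
  os <- c(5, 8, 10, 30, 30, 30, 30, 30, 30, 30)
  event <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  r <- net_reclassification_improvement(ref, new, os, event, n_boot = 0)
  expect_equal(r$nri, 2 / 2 - 0 + (0 - 1 / 8), tolerance = 1e-12)

  expect_equal(net_reclassification_improvement(ref, ref, os, event,
                                                n_boot = 0)$nri, 0)
  fwd <- net_reclassification_improvement(ref, new, os, event, n_boot = 0)$nri
  bwd <- net_reclassification_improvement(new, ref, os, event, n_boot = 0)$nri
  expect_equal(fwd, -bwd)
})

test_that("NRI excludes unclassified patients and requires both outcomes", {
  ref <- c("low", "unavailable", "high", "low")
  new <- c("high", "high", "low", "low")
  os <- c(5, 6, 30, 30); event <- c(1, 1, 0, 0)
  r <- net_reclassification_improvement(ref, new, os, event, n_boot = 0)
  expect_equal(r$n, 3)
  expect_error(
    net_reclassification_improvement(c("low", "high"), c("high", "low"),
                                     c(30, 31), c(0, 0), n_boot = 0),
    "events"
  )
})

test_that("mixture clustering selects one component for unimodal data", {
  hits <- vapply(1:20, function(s) {
    set.seed(s + 6000)
    os_mixture_modes(rnorm(200, 20, 4))$k == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mixture clustering recovers two well-separated modes", {
  set.seed(8)
  x <- c(rnorm(120, 10, 1.5), rnorm(80, 27, 2))
  r <- os_mixture_modes(x)
  expect_equal(r$k, 2)
  expect_equal(r$modes[1], 10, tolerance = 0.5)
  expect_equal(r$modes[2], 27, tolerance = 0.5)
  expect_equal(length(r$cluster), 200)
  expect_equal(length(r$cluster_median_os), 2)
})
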