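test_that("a covariate identical across exchangeable groups has no effect", {
  # tied death times, one subject per group at each: fully symmetric
  time <- rep(c(3, 5, 7, 9), each = 2)
  event <- rep(1, 8)
  x <- rep(c(0, 1), 4)
  fit <- fit_cox(data.frame(x = x), time, event)
  expect_lt(abs(fit$coef[["x"]]), 1e-8)
  expect_gt(fit$wald_p[["x"]], 0.99)
})

test_that("the fitter maximises the hand-written Efron partial likelihood", {
  cases <- list(
    list(time = c(4, 7, 7, 10, 12, 15), event = c(1, 1, 1, 0, 1, 1),
         x = c(0.3, -0.2, 0.8, -0.5, 0.1, -0.9)),
    list(time = c(2, 2, 5, 6, 8, 9), event = c(1, 1, 0, 1, 1, 0),
         x = c(1.2, 0.4, -0.3, 0.9, -1.1, 0.2)),
    list(time = c(1, 3, 3, 3, 7, 9, 11, 14), event = c(1, 1, 1, 1, 0, 1, 0, 1),
         x = c(0.5, 1.5, -0.5, 0.2, -1.2, 0.7, 0.1, -0.8))
  )
  for (cs in cases) {
    fit <- fit_cox(data.frame(x = cs$x), cs$time, cs$event)
    brute <- optimize(
      function(b) efron_loglik_1cov(b, cs$x, cs$time, cs$event),
      interval = c(-10, 10), maximum = TRUE, tol = 1e-9
    )
    expect_equal(fit$coef[["x"]], brute$maximum, tolerance = 1e-4)
    expect_equal(fit$loglik, brute$objective, tolerance = 1e-6)
  }
})

test_that("the linear predictor at mean covariates is zero by construction", {
  co <- cached_cohort(11)
  val <- cohort_arm(co, "validation")
  covar <- neat_covariates(val)
  fit <- fit_cox(covar[c("CDH2", "EPCAM", "MTOR", "age")],
                 val$patients$os_months, val$patients$event)
  lp_mean <- sum(fit$coef * (fit$covariate_means - fit$covariate_means))
  expect_equal(lp_mean, 0)
  expect_gte(fit$lrt_stat, 0)
})

test_that("BIC follows -2 logPL + p log(events) and its null/increment identities", {
  fake <- structure(
    list(loglik = -20, n_events = 12, n = 30, coef = rep(0, 4)),
    class = "cox_fit"
  )
  expect_equal(bic(fake), 40 + 4 * log(12), tolerance = 1e-12)
  expect_equal(bic(fake), 49.938, tolerance = 1e-3)
  expect_equal(bic(fake, effective_n = "patients"), 40 + 4 * log(30))

  null_fit <- structure(
    list(loglik = -20, n_events = 12, n = 30, coef = numeric(0)),
    class = "cox_fit"
  )
  expect_equal(bic(null_fit), 40)
  # a zero-contribution extra feature costs exactly ln(m)
  plus_one <- structure(
    list(loglik = -20, n_events = 12, n = 30, coef = rep(0, 5)),
    class = "cox_fit"
  )
  expect_equal(bic(plus_one) - bic(fake), log(12))
})

test_that("a single candidate that worsens BIC yields the null model", {
  set.seed(4)
  n <- 30
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7)
  noise <- rnorm(n)
  res <- backward_eliminate(data.frame(noise = noise), time, event)
  expect_equal(res$selected, character(0))
  expect_equal(length(res$fit$coef), 0)
})

test_that("greedy elimination matches an independent walk over all submodel BICs", {
  set.seed(7)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  lp <- 1.2 * x1 + 0.8 * x2
  time <- -log(runif(n)) / (0.05 * exp(lp))
  cens <- rexp(n, 0.03)
  event <- as.integer(time <= cens)
  os <- pmin(time, cens)
  feats <- data.frame(x1 = x1, x2 = x2, x3 = x3)

  res <- backward_eliminate(feats, os, event)

  # oracle: exhaustively precompute the BIC of every subset, then walk
  # the backward-greedy path over that table
  subset_bic <- function(vars) {
    bic(fit_cox(feats[vars], os, event))
  }
  all_subsets <- unlist(lapply(0:3, function(k) {
    combn(names(feats), k, simplify = FALSE)
  }), recursive = FALSE)
  tab <- sapply(all_subsets, function(v) subset_bic(v))
  names(tab) <- sapply(all_subsets, paste, collapse = "+")
  key <- function(v) paste(v, collapse = "+")
  cur <- names(feats)
  repeat {
    if (length(cur) == 0) break
    subs <- lapply(seq_along(cur), function(i) cur[-i])
    bics <- sapply(subs, function(v) tab[[key(v)]])
    if (min(bics) < tab[[key(cur)]]) cur <- subs[[which.min(bics)]] else break
  }
  expect_setequal(res$selected, cur)
  expect_equal(res$bic, tab[[key(cur)]], tolerance = 1e-10)
})

test_that("accepted elimination steps strictly decrease BIC and are fully traced", {
  co <- cached_cohort(11)
  dev <- cohort_arm(co, "development")
  feats <- aggregate_patient_expression(dev$samples,
                                        patients = dev$patients$patient_id)
  feats <- feats[c("CA9", "CDH2", "EPCAM", "MTOR", "MLH1", "BCL2")]
  feats$age <- dev$patients$age
  res <- backward_eliminate(feats, dev$patients$os_months, dev$patients$event)
  tr <- res$trace
  accepted <- tr[tr$accepted, ]
  if (nrow(accepted) > 1) {
    expect_true(all(diff(accepted$bic) < 0))
  }
  # every step records one candidate row per remaining feature
  expect_equal(unname(table(tr$step)[1]), ncol(feats))
  expect_true(all(accepted$bic < accepted$current_bic))
})

test_that("perfectly separated risk groups are flagged, not silently returned", {
  time <- c(1, 2, 3, 4, 20, 21, 22, 23)
  event <- rep(1, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- fit_cox(data.frame(x = x), time, event)
  expect_true(fit$monotone)
})

test_that("the proportional-hazards score test is calibrated under the null", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s + 3000)
    n <- 60
    x <- rnorm(n)
    time <- -log(runif(n)) / (0.08 * exp(0.5 * x))
    cens <- rexp(n, 0.04)
    fit <- fit_cox(data.frame(x = pmin(x, Inf)),
                   pmin(time, cens), as.integer(time <= cens))
    test_proportional_hazards(fit)$p[2]  # global row
  }, numeric(1))
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong time-varying effect is detected", {
  detect <- vapply(1:20, function(s) {
    set.seed(s + 4000)
    n <- 300
    x <- rbinom(n, 1, 0.5)
    # piecewise hazard: effect +b before tau, -b after
    b <- 1.2; lam <- 0.08; tau <- 9
    u <- runif(n)
    t1 <- -log(u) / (lam * exp(b * x))            # candidate first-phase time
    need_second <- t1 > tau
    u2 <- runif(n)
    t2 <- tau - log(u2) / (lam * exp(-b * x))
    time <- ifelse(need_second, t2, t1)
    fit <- fit_cox(data.frame(x = x), time, rep(1L, n))
    test_proportional_hazards(fit)$p[2] < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.9)
})
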