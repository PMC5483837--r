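# Small in-code fixtures and independent oracles shared across tests.

# Three patients, two proteins, known values.
toy_samples <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    sample_id = c("S1", "S2", "S1", "S2", "S1"),
    grade = c(2L, 3L, 1L, 1L, 4L),
    CDH2 = c(-7.0, -7.4, -6.5, -6.1, -8.0),
    EPCAM = c(-6.0, -6.2, -5.8, -5.6, -7.1),
    stringsAsFactors = FALSE
  )
}

toy_clinical <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    age = c(64.5, 58.0, 71.2),
    grade = c(3L, 1L, 4L),
    event = c(1L, 0L, 1L),
    os_months = c(23.5, 30.1, 8.2),
    imdc_class = c("intermediate", "poor", "unavailable"),
    mskcc_class = c("favourable_intermediate", "poor", "unavailable"),
    cohort = c("development", "development", "validation"),
    treatment_exposed = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Hand-written Efron partial log-likelihood for a single covariate;
# independent of the fitting code (direct formula evaluation).
efron_loglik_1cov <- function(beta, x, time, event) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    deaths <- which(event == 1 & time == t)
    risk <- which(time >= t)
    d <- length(deaths)
    ll <- ll + beta * sum(x[deaths])
    rs <- sum(exp(beta * x[risk]))
    ds <- sum(exp(beta * x[deaths]))
    for (l in seq_len(d)) {
      ll <- ll - log(rs - (l - 1) / d * ds)
    }
  }
  ll
}

# Hand log-rank: O-E and hypergeometric variance accumulated per death time.
hand_logrank <- function(groups, time, event) {
  g <- as.integer(groups == sort(unique(groups))[2])
  o_minus_e <- 0; v <- 0
  for (t in unique(time[event == 1])) {
    at <- time >= t
    dk <- event == 1 & time == t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(dk); d1 <- sum(dk & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# A deterministic NEAT model for toy cohorts (zero centering).
toy_neat_model <- function(means = c(CDH2 = 0, EPCAM = 0, age = 0, MTOR = 0)) {
  neat_model(means)
}

# Default-condition synthetic cohort, memoised per seed so multiple
# tests can share the generation cost.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  co <- generate_cohort(simulation_config(...), seed = seed)
  .cohort_cache[[key]] <- co
  co
}
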