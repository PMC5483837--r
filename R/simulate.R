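# Synthetic two-cohort multiregion RPPA + survival generator.
#
# Each patient carries a latent per-protein tumour mean; spatially
# separated samples scatter around it with grade- and
# treatment-dependent within-tumour noise. Survival follows a
# proportional-hazards model on the *latent* covariates, so per-sample
# noise degrades any risk score computed from observed samples -- the
# mechanism by which intratumoural heterogeneity limits prognostication.

#' Default NEAT coefficient vector
#'
#' Log-hazard slopes of the four-variable prognostic model on
#' N-cadherin (CDH2), EPCAM, age in years and mTOR (MTOR); protein
#' values are log2-normalised RPPA intensities.
#'
#' @return named numeric vector.
#' @export
neat_coefficients <- function() {
  c(CDH2 = 8.927, EPCAM = 3.800, age = 0.129, MTOR = -18.385)
}

#' Simulation configuration
#'
#' Builds the parameter list consumed by [generate_cohort()]. Defaults
#' describe a two-arm metastatic ccRCC study: 22 patients per cohort,
#' 1--10 spatially separated samples per tumour (median 4), a 55-protein
#' RPPA panel whose log2 intensities lie around -9 to -5.2, within-tumour
#' noise comparable to the between-patient signal, larger within-tumour
#' variance in low-grade tissue, and overall survival with modes near 11
#' and 27 months linked to the NEAT linear predictor.
#'
#' @param n_patients patients per cohort.
#' @param sample_count_probs probability weights on 1..10 samples per
#'   tumour (median 4 under the default).
#' @param n_proteins total panel size including the six candidates
#'   CA9, CDH2, EPCAM, MTOR, MLH1, BCL2.
#' @param expression_centre_range log2 range over which per-protein
#'   panel centres are spread.
#' @param between_patient_sd SD of latent tumour means around the
#'   protein centre (log2 units).
#' @param within_tumour_sd baseline SD of samples around the tumour mean
#'   (log2 units), before grade/treatment multipliers.
#' @param inflated_proteins proteins whose within-tumour SD is multiplied
#'   by \code{variance_inflation} in the treatment-exposed
#'   (development) arm.
#' @param variance_inflation multiplicative factor (>= 1) on
#'   within-tumour SD for \code{inflated_proteins}.
#' @param grade_probs per-sample Fuhrman grade distribution on 1..4.
#' @param grade_sd_multiplier length-2 vector (low = grades 1--2,
#'   high = 3--4) multiplying within-tumour SD; the default gives
#'   low-grade tissue 3.5-fold the high-grade variance.
#' @param region_outlier_prob probability that a sampled region deviates
#'   coherently (across the whole panel) from the tumour mean with
#'   \code{region_outlier_factor} times the usual SD, emulating discrete
#'   divergent regions rather than pure Gaussian scatter; the factor is
#'   renormalised so the total within-tumour variance stays at the
#'   configured SD squared. Set the factor to 1 for plain Gaussian
#'   intratumoural noise.
#' @param true_coef named log-hazard coefficients on latent covariates;
#'   names must be proteins plus optionally \code{age}.
#' @param baseline_weights,baseline_modes,baseline_sdlog two-component
#'   lognormal mixture baseline; modes in months.
#' @param censor_rate exponential censoring rate (per month), calibrated
#'   to roughly half the validation-like arm censored.
#' @param age_range uniform age-at-diagnosis range (years).
#' @return a list of class \code{sim_config}.
#' @export
simulation_config <- function(
    n_patients = 22,
    sample_count_probs = c(0.06, 0.12, 0.18, 0.28, 0.14, 0.09, 0.06, 0.04, 0.02, 0.01),
    n_proteins = 55,
    expression_centre_range = c(-8.6, -5.6),
    between_patient_sd = 0.06,
    within_tumour_sd = 0.12,
    inflated_proteins = character(0),
    variance_inflation = 1,
    grade_probs = c(0.10, 0.30, 0.40, 0.20),
    grade_sd_multiplier = c(low = sqrt(3.5), high = 1),
    region_outlier_prob = 0.2,
    region_outlier_factor = 3,
    true_coef = neat_coefficients(),
    baseline_weights = c(0.55, 0.45),
    baseline_modes = c(11, 27),
    baseline_sdlog = c(0.18, 0.15),
    censor_rate = 0.030,
    age_range = c(38, 79)) {
  cfg <- list(
    n_patients = n_patients,
    sample_count_probs = sample_count_probs,
    n_proteins = n_proteins,
    expression_centre_range = expression_centre_range,
    between_patient_sd = between_patient_sd,
    within_tumour_sd = within_tumour_sd,
    inflated_proteins = inflated_proteins,
    variance_inflation = variance_inflation,
    grade_probs = grade_probs,
    grade_sd_multiplier = grade_sd_multiplier,
    region_outlier_prob = region_outlier_prob,
    region_outlier_factor = region_outlier_factor,
    true_coef = true_coef,
    baseline_weights = baseline_weights / sum(baseline_weights),
    baseline_modes = baseline_modes,
    baseline_sdlog = baseline_sdlog,
    censor_rate = censor_rate,
    age_range = age_range
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$sample_count_probs) > 10 || sum(cfg$sample_count_probs) <= 0) {
    stop("sample_count_probs must be a positive law on at most 1..10 samples")
  }
  if (cfg$n_proteins < length(.candidate_proteins)) {
    stop("n_proteins must be at least ", length(.candidate_proteins))
  }
  if (cfg$between_patient_sd <= 0 || cfg$within_tumour_sd <= 0) {
    stop("all sd values must be > 0")
  }
  if (cfg$variance_inflation < 1) stop("variance_inflation must be >= 1")
  if (any(cfg$grade_sd_multiplier <= 0)) stop("grade multipliers must be > 0")
  if (cfg$region_outlier_prob < 0 || cfg$region_outlier_prob >= 1) {
    stop("region_outlier_prob must be in [0, 1)")
  }
  if (cfg$region_outlier_factor < 1) stop("region_outlier_factor must be >= 1")
  if (cfg$censor_rate < 0) stop("censor_rate must be >= 0")
  invisible(cfg)
}

.candidate_proteins <- c("CA9", "CDH2", "EPCAM", "MTOR", "MLH1", "BCL2")

#' Protein panel of a simulation configuration
#'
#' The six candidate markers followed by numbered nuisance proteins.
#'
#' @param cfg a \code{sim_config}.
#' @return character vector of protein names.
#' @export
sim_protein_panel <- function(cfg) {
  extra <- cfg$n_proteins - length(.candidate_proteins)
  c(.candidate_proteins,
    if (extra > 0) sprintf("NUIS%02d", seq_len(extra)))
}

# Baseline survival of the lognormal-mixture model; component meanlog is
# set so that each component's density mode sits at the requested month.
.baseline_survival <- function(cfg) {
  mu <- log(cfg$baseline_modes) + cfg$baseline_sdlog^2
  w <- cfg$baseline_weights
  sdl <- cfg$baseline_sdlog
  function(t) {
    w[1] * stats::plnorm(t, mu[1], sdl[1], lower.tail = FALSE) +
      w[2] * stats::plnorm(t, mu[2], sdl[2], lower.tail = FALSE)
  }
}

# Inverse-transform draw from S(t | lp) = S0(t)^exp(lp) on a log-time
# grid; monotone interpolation keeps the draw deterministic and smooth.
.draw_survival_times <- function(cfg, lp, u) {
  s0 <- .baseline_survival(cfg)
  grid <- exp(seq(log(0.01), log(2000), length.out = 4096))
  sgrid <- s0(grid)
  # target: S0(t) = u^exp(-lp)  (u uniform)
  target <- u^exp(-lp)
  # keep the strictly decreasing stretch (S0 saturates in the far tails)
  keep <- c(TRUE, diff(sgrid) < 0)
  sgrid <- sgrid[keep]; grid <- grid[keep]
  target <- pmin(pmax(target, min(sgrid) + 1e-12), max(sgrid) - 1e-12)
  lt <- stats::approx(x = sgrid, y = log(grid), xout = target, rule = 2)$y
  exp(lt)
}

#' Generate a synthetic two-arm multiregion cohort
#'
#' Draws a development (treatment-exposed) and a validation arm under a
#' [simulation_config()]. Per patient: a latent tumour mean per protein
#' \eqn{\sim N(centre, between\_patient\_sd^2)}; per sample: latent mean
#' plus Gaussian within-tumour noise whose SD carries the grade
#' multiplier and, for inflated proteins in the exposed arm, the variance
#' inflation factor. Age is uniform on \code{age_range}. Survival is
#' drawn by inverse transform from the proportional-hazards model on the
#' centred latent covariates over the bimodal baseline; censoring is
#' independent exponential. Deterministic given \code{seed}.
#'
#' @param cfg a \code{sim_config}.
#' @param seed integer seed.
#' @param arms which arms to generate.
#' @return an [cohort()] object; the latent per-patient covariates used
#'   for survival are attached as attribute \code{"latent"} for
#'   parameter-recovery studies.
#' @export
generate_cohort <- function(cfg = simulation_config(), seed = 1,
                            arms = c("development", "validation")) {
  validate_sim_config(cfg)
  arms <- match.arg(arms, several.ok = TRUE)
  rng <- .new_rng(seed)
  panel <- sim_protein_panel(cfg)
  centres <- seq(cfg$expression_centre_range[1], cfg$expression_centre_range[2],
                 length.out = length(panel))
  names(centres) <- panel
  coef_prot <- cfg$true_coef[setdiff(names(cfg$true_coef), "age")]
  if (!all(names(coef_prot) %in% panel)) {
    stop("true_coef names a protein outside the panel")
  }
  pats <- list(); samps <- list(); latents <- list()
  for (arm in arms) {
    exposed <- arm == "development"
    for (i in seq_len(cfg$n_patients)) {
      pid <- sprintf("%s%02d", if (exposed) "DEV" else "VAL", i)
      n_samp <- sample(seq_along(cfg$sample_count_probs), 1,
                       prob = cfg$sample_count_probs)
      latent <- centres + stats::rnorm(length(panel), 0, cfg$between_patient_sd)
      age <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
      grades <- sample(1:4, n_samp, replace = TRUE, prob = cfg$grade_probs)
      sdvec <- rep(cfg$within_tumour_sd, length(panel))
      names(sdvec) <- panel
      if (exposed && length(cfg$inflated_proteins) > 0) {
        sdvec[cfg$inflated_proteins] <-
          sdvec[cfg$inflated_proteins] * cfg$variance_inflation
      }
      gmult <- ifelse(grades <= 2, cfg$grade_sd_multiplier[["low"]],
                      cfg$grade_sd_multiplier[["high"]])
      # divergent regions: occasional samples scatter more, coherently
      # across the panel; normalised to keep total variance at sd^2
      po <- cfg$region_outlier_prob; fo <- cfg$region_outlier_factor
      region_fac <- ifelse(stats::runif(n_samp) < po, fo, 1) /
        sqrt(po * fo^2 + 1 - po)
      expr <- matrix(
        stats::rnorm(n_samp * length(panel)), n_samp, length(panel)
      ) * outer(gmult * region_fac, sdvec) +
        matrix(latent, n_samp, length(panel), byrow = TRUE)
      colnames(expr) <- panel
      # centred linear predictor on latent covariates
      lp <- sum(coef_prot * (latent[names(coef_prot)] - centres[names(coef_prot)]))
      if ("age" %in% names(cfg$true_coef)) {
        lp <- lp + cfg$true_coef[["age"]] * (age - mean(cfg$age_range))
      }
      tt <- .draw_survival_times(cfg, lp, stats::runif(1))
      cc <- if (cfg$censor_rate > 0) stats::rexp(1, cfg$censor_rate) else Inf
      # clinico-pathological classes: risk-correlated with realistic
      # missingness, so score comparisons (C-index, NRI) are meaningful
      imdc <- if (stats::runif(1) < 0.09) {
        "unavailable"
      } else if (stats::runif(1) < stats::plogis(-0.4 + 0.6 * lp)) {
        "poor"
      } else {
        "intermediate"
      }
      mskcc <- if (stats::runif(1) < 0.15) {
        "unavailable"
      } else if (stats::runif(1) < stats::plogis(-1.2 + 0.6 * lp)) {
        "poor"
      } else {
        "favourable_intermediate"
      }
      pats[[pid]] <- data.frame(
        patient_id = pid, age = age, grade = max(grades),
        event = as.integer(tt <= cc), os_months = min(tt, cc),
        imdc_class = imdc, mskcc_class = mskcc,
        cohort = arm, treatment_exposed = exposed,
        stringsAsFactors = FALSE
      )
      samps[[pid]] <- data.frame(
        patient_id = pid,
        sample_id = sprintf("S%02d", seq_len(n_samp)),
        grade = grades, expr,
        stringsAsFactors = FALSE, check.names = FALSE
      )
      latents[[pid]] <- c(latent, age = age, lp = lp)
    }
  }
  on.exit(rng$restore())
  out <- cohort(do.call(rbind, c(pats, list(make.row.names = FALSE))),
                do.call(rbind, c(samps, list(make.row.names = FALSE))))
  attr(out, "latent") <- do.call(rbind, latents)
  out
}

# Scoped RNG: seed without disturbing the caller's random state.
.new_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Write a cohort as a fixture directory
#'
#' Emits \code{samples.csv} and \code{clinical.csv} in the formats of
#' [read_sample_table()] and [read_clinical_table()]; the round-trip is
#' lossless and byte-stable for a fixed cohort.
#'
#' @param x an \code{ith_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_fixture <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fs <- c(samples = file.path(dir, "samples.csv"),
          clinical = file.path(dir, "clinical.csv"))
  write_sample_table(x$samples, fs[["samples"]])
  write_clinical_table(x$patients, fs[["clinical"]])
  invisible(fs)
}

#' Read a fixture directory back into a cohort
#'
#' @param dir directory written by [write_fixture()].
#' @return an \code{ith_cohort}.
#' @export
read_fixture <- function(dir) {
  cohort(
    read_clinical_table(file.path(dir, "clinical.csv")),
    read_sample_table(file.path(dir, "samples.csv"))
  )
}
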