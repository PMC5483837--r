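# End-to-end pipeline: simulate (or load) -> screen -> select -> score
# -> evaluate -> subsample, driven by a YAML/list config with one root
# seed feeding named per-stage substreams.

.pipeline_stages <- c("simulate", "screen", "select", "score", "evaluate",
                      "subsample")

.config_error <- function(...) {
  stop(structure(class = c("ithstrat_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# Per-stage seeds derived from the root seed; kept within 32-bit range.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000L * match(stage, .pipeline_stages)) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on either a simulated cohort or
#' CSV inputs. Stage outputs (CSV/JSON) are written under \code{out};
#' the returned report carries every stage's key results, the config
#' digest and the seeds used.
#'
#' Config keys: \code{seed} (root seed); \code{stages} (named logical
#' toggles); \code{input} (\code{samples}/\code{clinical} CSV paths, or
#' absent to simulate); \code{simulate} (overrides for
#' [simulation_config()]); \code{evaluate} (\code{horizon},
#' \code{n_boot}); \code{subsample} (\code{mnts} vector,
#' \code{n_datasets}).
#'
#' @param config a list or path to a YAML file.
#' @param out output directory.
#' @return the report, invisibly (also written to \code{out/report.json}).
#' @export
run_pipeline <- function(config, out = "ithstrat_out") {
  if (is.character(config)) {
    if (!file.exists(config)) .config_error("config file not found: ", config)
    cfg_digest <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    tf <- tempfile(); yaml::write_yaml(config, tf)
    cfg_digest <- unname(tools::md5sum(tf)); unlink(tf)
  }
  if (!is.list(config)) .config_error("config must be a mapping")
  unknown <- setdiff(names(config), c("seed", "stages", "input", "simulate",
                                      "evaluate", "subsample"))
  if (length(unknown) > 0) {
    .config_error("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  stages <- stats::setNames(rep(TRUE, length(.pipeline_stages)), .pipeline_stages)
  for (s in names(config$stages %||% list())) {
    if (!s %in% .pipeline_stages) .config_error("unknown stage: ", s)
    stages[s] <- isTRUE(config$stages[[s]])
  }
  for (s in c("evaluate", "subsample")) {
    if (stages[[s]] && !stages[["score"]]) {
      .config_error("stage '", s, "' requires stage 'score' to be enabled")
    }
  }
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  report <- list(config_digest = cfg_digest, seed = seed,
                 stages = as.list(stages))

  # ---- data: simulate or load ----
  if (!is.null(config$input)) {
    co <- cohort(read_clinical_table(config$input$clinical),
                 read_sample_table(config$input$samples))
  } else if (stages[["simulate"]]) {
    sim_args <- config$simulate %||% list()
    sim_cfg <- do.call(simulation_config, sim_args)
    co <- generate_cohort(sim_cfg, seed = .stage_seed(seed, "simulate"))
    write_fixture(co, file.path(out, "cohort"))
  } else {
    .config_error("no input files given and stage 'simulate' is disabled")
  }
  dev <- cohort_arm(co, "development")
  val <- cohort_arm(co, "validation")
  report$data <- list(n_patients = nrow(co$patients),
                      n_samples = nrow(co$samples),
                      n_proteins = length(protein_names(co$samples)))

  if (stages[["screen"]]) {
    scr <- suppressWarnings(screen_ith(co))  # an empty candidate set is valid here
    utils::write.csv(scr, file.path(out, "screen.csv"), row.names = FALSE)
    report$screen <- list(
      candidates = scr$protein[scr$selected],
      n_significant = sum(scr$assumptions_ok & !is.na(scr$p) &
                            scr$p < 0.05 & scr$log_ratio > 0)
    )
  }

  if (stages[["select"]]) {
    cand <- if (!is.null(report$screen) && length(report$screen$candidates) > 0) {
      report$screen$candidates
    } else {
      intersect(.candidate_proteins, protein_names(co$samples))
    }
    feats <- aggregate_patient_expression(dev$samples,
                                          patients = dev$patients$patient_id)
    feats <- feats[cand]
    feats$age <- dev$patients$age
    sel <- backward_eliminate(feats, dev$patients$os_months, dev$patients$event)
    utils::write.csv(sel$trace, file.path(out, "selection_trace.csv"),
                     row.names = FALSE)
    report$select <- list(selected = sel$selected, bic = sel$bic)
  }

  model <- neat_from_cohort(dev)
  if (stages[["score"]]) {
    write_neat_model(model, file.path(out, "neat_model.json"))
    scores <- neat_score_cohort(val, model)
    utils::write.csv(scores, file.path(out, "risk_scores.csv"), row.names = FALSE)
    report$score <- list(
      n_high = sum(scores$risk_group == "high"),
      n_low = sum(scores$risk_group == "low")
    )
  }

  if (stages[["evaluate"]]) {
    ev <- config$evaluate %||% list()
    horizon <- ev$horizon %||% 24
    n_boot <- ev$n_boot %||% 2000
    scores <- neat_score_cohort(val, model)
    mets <- stratification_metrics(
      scores$risk_group, scores$os_months, scores$event,
      horizon = horizon, n_boot = n_boot,
      seed = .stage_seed(seed, "evaluate")
    )
    mix <- os_mixture_modes(co$patients$os_months)
    report$evaluate <- c(mets, list(os_modes = mix$modes, os_k = mix$k))
  }

  if (stages[["subsample"]]) {
    sb <- config$subsample %||% list()
    mnts_levels <- sb$mnts %||% c(1, 2, 3)
    n_datasets <- sb$n_datasets %||% 1e4
    res <- lapply(mnts_levels, function(m) {
      subsampling_experiment(val, model, m, n_datasets,
                             seed = .stage_seed(seed, "subsample"))
    })
    names(res) <- paste0("mnts", mnts_levels)
    flips <- risk_flip_fraction(val, model)
    report$subsample <- list(
      median_loghr = vapply(res, `[[`, numeric(1), "median_loghr"),
      median_logrank_p = vapply(res, `[[`, numeric(1), "median_p"),
      n_datasets = vapply(res, `[[`, numeric(1), "n_datasets"),
      risk_flip_fraction = flips$fraction
    )
    for (nm in names(res)) {
      utils::write.csv(
        data.frame(loghr = res[[nm]]$loghr, logrank_p = res[[nm]]$logrank_p,
                   degenerate = res[[nm]]$degenerate),
        file.path(out, paste0("subsample_", nm, ".csv")), row.names = FALSE
      )
    }
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Stratification metric bundle for one risk grouping
#'
#' Log-rank test, group hazard ratio, Harrell's concordance of the
#' binary groups, and classification metrics at the horizon.
#'
#' @param groups \code{"high"}/\code{"low"} labels.
#' @param os_months,event outcome vectors.
#' @param horizon classification horizon (months).
#' @param n_boot bootstrap resamples for the concordance CI.
#' @param seed bootstrap seed.
#' @return list of metric values.
#' @export
stratification_metrics <- function(groups, os_months, event, horizon = 24,
                                   n_boot = 2000, seed = 1) {
  lr <- log_rank(groups, os_months, event)
  hr <- group_hazard_ratio(groups, os_months, event)
  cc <- concordance_index(as.numeric(groups == "high"), os_months, event,
                          n_boot = n_boot, seed = seed)
  cls <- two_year_classification(groups, os_months, event, horizon = horizon)
  list(
    logrank_p = lr$p, hr = hr$hr, loghr = hr$loghr, hr_ci = hr$ci,
    hr_flagged = hr$flagged, c_index = cc$c, c_index_ci = cc$ci,
    accuracy = cls$accuracy, mcc = cls$mcc, precision = cls$precision,
    recall = cls$recall, specificity = cls$specificity
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
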