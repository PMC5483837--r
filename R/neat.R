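# The NEAT prognostic score: a fixed-coefficient Cox linear predictor on
# N-cadherin (CDH2), EPCAM, age and mTOR (MTOR). The printed coefficient
# vector defines relative hazards; the predictor is centred at the
# development-cohort covariate means so that logHR = 0 is average risk,
# the predetermined classification threshold.

#' Construct a NEAT model
#'
#' @param centering_means named numeric vector of means for
#'   \code{CDH2}, \code{EPCAM}, \code{age}, \code{MTOR} -- normally the
#'   development-cohort means, see [neat_from_cohort()].
#' @param coefficients log-hazard slopes, default [neat_coefficients()].
#' @param threshold risk-group threshold on logHR.
#' @return object of class \code{neat_model}.
#' @export
neat_model <- function(centering_means,
                       coefficients = neat_coefficients(),
                       threshold = 0) {
  miss <- setdiff(names(coefficients), names(centering_means))
  if (length(miss) > 0) {
    stop("centering_means lacks variable(s): ", paste(miss, collapse = ", "))
  }
  structure(
    list(coefficients = coefficients,
         centering_means = centering_means[names(coefficients)],
         threshold = threshold),
    class = "neat_model"
  )
}

#' @export
print.neat_model <- function(x, ...) {
  cat("<neat_model> logHR = sum(coef * (value - mean)), threshold",
      x$threshold, "\n")
  print(data.frame(coef = x$coefficients, HR = exp(x$coefficients),
                   centering_mean = x$centering_means))
  invisible(x)
}

#' Build a NEAT model centred on a cohort
#'
#' Aggregates the cohort's expression (median per patient), joins age,
#' and uses the resulting covariate means as the centering constants.
#'
#' @param x an \code{ith_cohort} (typically the development arm).
#' @param coefficients log-hazard slopes.
#' @return a \code{neat_model}.
#' @export
neat_from_cohort <- function(x, coefficients = neat_coefficients()) {
  covar <- neat_covariates(x)
  neat_model(colMeans(covar[names(coefficients)]), coefficients)
}

#' Per-patient NEAT covariate table
#'
#' @param x an \code{ith_cohort}.
#' @param subset optional per-patient sample selection, as in
#'   [aggregate_patient_expression()].
#' @return data.frame: patient_id, CDH2, EPCAM, MTOR, age (patients in
#'   clinical-table order; every patient needs >= 1 sample).
#' @export
neat_covariates <- function(x, subset = NULL) {
  agg <- aggregate_patient_expression(x$samples, subset = subset,
                                      patients = x$patients$patient_id)
  need <- c("CDH2", "EPCAM", "MTOR")
  miss <- setdiff(need, names(agg))
  if (length(miss) > 0) {
    stop("expression table lacks NEAT protein(s): ", paste(miss, collapse = ", "))
  }
  out <- agg[c("patient_id", need)]
  out$age <- x$patients$age[match(out$patient_id, x$patients$patient_id)]
  out
}

#' NEAT log hazard ratio
#'
#' \code{logHR = sum(coef * (value - centering_mean))} over the model's
#' variables.
#'
#' @param values data.frame with one column per model variable (extra
#'   columns ignored), or a named numeric vector for a single patient.
#' @param model a \code{neat_model}.
#' @return numeric vector of per-patient logHR (named by
#'   \code{patient_id} when present).
#' @export
neat_loghr <- function(values, model) {
  if (is.numeric(values) && !is.null(names(values))) {
    values <- as.data.frame(as.list(values))
  }
  vars <- names(model$coefficients)
  miss <- vars[!vars %in% names(values)]
  if (length(miss) > 0) {
    stop("missing NEAT input variable(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(values[vars])
  if (anyNA(m)) {
    bad <- vars[apply(is.na(m), 2, any)]
    stop("missing value(s) in NEAT variable(s): ", paste(bad, collapse = ", "))
  }
  lhr <- as.numeric(m %*% model$coefficients -
                      sum(model$coefficients * model$centering_means))
  if ("patient_id" %in% names(values)) names(lhr) <- values$patient_id
  lhr
}

#' Assign high/low risk groups from logHR
#'
#' Boundary convention: \code{logHR > threshold} is high risk; a patient
#' exactly at the threshold is low risk.
#'
#' @param loghr numeric vector of log hazard ratios.
#' @param threshold classification threshold (default 0).
#' @return character vector \code{"high"}/\code{"low"}.
#' @export
assign_risk_groups <- function(loghr, threshold = 0) {
  ifelse(loghr > threshold, "high", "low")
}

#' Score a cohort with a NEAT model
#'
#' @param x an \code{ith_cohort}.
#' @param model a \code{neat_model}.
#' @param subset optional per-patient sample selection.
#' @return data.frame: patient_id, loghr, risk_group, os_months, event.
#' @export
neat_score_cohort <- function(x, model, subset = NULL) {
  covar <- neat_covariates(x, subset = subset)
  lhr <- neat_loghr(covar, model)
  data.frame(
    patient_id = covar$patient_id,
    loghr = unname(lhr),
    risk_group = assign_risk_groups(unname(lhr), model$threshold),
    os_months = x$patients$os_months[match(covar$patient_id, x$patients$patient_id)],
    event = x$patients$event[match(covar$patient_id, x$patients$patient_id)],
    stringsAsFactors = FALSE
  )
}

#' Write / read a NEAT model as JSON
#'
#' @param model a \code{neat_model}.
#' @param path JSON file.
#' @return \code{path} (write) or a \code{neat_model} (read).
#' @export
write_neat_model <- function(model, path) {
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients),
         centering_means = as.list(model$centering_means),
         threshold = model$threshold),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_neat_model
#' @export
read_neat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  neat_model(unlist(x$centering_means),
             coefficients = unlist(x$coefficients),
             threshold = x$threshold)
}
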