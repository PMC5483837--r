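# Clinico-pathological risk scores for metastatic RCC.
#
# Both scores count adverse prognostic factors; a factor recorded as NA
# is "unavailable" and the class is only reported when the determinable
# count already forces it (e.g. three adverse factors present force
# "poor" regardless of what the missing factors would add).

# Count-based class with missing-data dominance logic.
.factor_count_class <- function(factors, breaks, labels) {
  stopifnot(is.logical(factors))
  lo <- sum(factors, na.rm = TRUE)          # adverse factors known present
  hi <- lo + sum(is.na(factors))            # if every unknown were adverse
  cls <- function(k) labels[findInterval(k, breaks) + 1L]
  if (cls(lo) == cls(hi)) cls(lo) else "unavailable"
}

#' IMDC (Heng) risk class
#'
#' Counts the six IMDC adverse factors: Karnofsky performance status
#' < 80, time from diagnosis to treatment < 1 year, anaemia,
#' hypercalcaemia, neutrophilia and thrombocytosis. 0 factors is
#' favourable, 1--2 intermediate, >= 3 poor. Unknown factors (NA) give
#' class \code{"unavailable"} unless the known count already forces the
#' class.
#'
#' @param kps_lt80,dx_to_treat_lt1yr,anaemia,hypercalcaemia,neutrophilia,thrombocytosis
#'   logical adverse-factor indicators (NA = unavailable).
#' @return one of \code{"favourable"}, \code{"intermediate"},
#'   \code{"poor"}, \code{"unavailable"}.
#' @export
imdc_class <- function(kps_lt80, dx_to_treat_lt1yr, anaemia,
                       hypercalcaemia, neutrophilia, thrombocytosis) {
  f <- c(kps_lt80, dx_to_treat_lt1yr, anaemia, hypercalcaemia,
         neutrophilia, thrombocytosis)
  stopifnot(length(f) == 6)
  .factor_count_class(f, breaks = c(1, 3),
                      labels = c("favourable", "intermediate", "poor"))
}

#' MSKCC prognosis group (binarised)
#'
#' Counts the five MSKCC adverse factors: Karnofsky performance status
#' < 80, time from diagnosis to treatment < 1 year, anaemia, elevated
#' lactate dehydrogenase and hypercalcaemia, and groups patients into
#' favourable/intermediate (0--2 factors) versus poor (>= 3). Borderline
#' patients whose class depends on unavailable factors are
#' \code{"unavailable"}; clinical overrides for individual patients are
#' data-entry annotations supplied via \code{override}, never inferred.
#'
#' @param kps_lt80,dx_to_treat_lt1yr,anaemia,high_ldh,hypercalcaemia
#'   logical adverse-factor indicators (NA = unavailable).
#' @param override optional class to force
#'   (\code{"favourable_intermediate"} or \code{"poor"}).
#' @return one of \code{"favourable_intermediate"}, \code{"poor"},
#'   \code{"unavailable"}.
#' @export
mskcc_group <- function(kps_lt80, dx_to_treat_lt1yr, anaemia, high_ldh,
                        hypercalcaemia, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override %in% c("favourable_intermediate", "poor"))
    return(override)
  }
  f <- c(kps_lt80, dx_to_treat_lt1yr, anaemia, high_ldh, hypercalcaemia)
  stopifnot(length(f) == 5)
  .factor_count_class(f, breaks = 3,
                      labels = c("favourable_intermediate", "poor"))
}
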