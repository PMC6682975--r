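# State-space vocabulary shared by every module. Order matters: all matrices,
# arrays and traces index BMI categories as NORMAL, OVERWEIGHT, OBESE, DEAD.

#' BMI category labels, in canonical matrix order
#'
#' `NORMAL` folds in underweight; `DEAD` is the unique absorbing state.
#' @export
BMI_CATEGORIES <- c("NORMAL", "OVERWEIGHT", "OBESE", "DEAD")

#' Live (non-absorbing) BMI categories
#' @export
LIVE_CATEGORIES <- c("NORMAL", "OVERWEIGHT", "OBESE")

#' Sex labels, in canonical array order
#' @export
SEXES <- c("MALE", "FEMALE")

#' Childhood-history labels for the adult cohort split
#'
#' `EVER_OWOB` marks individuals who occupied overweight or obese at least
#' once; the flag is sticky and drives history-dependent adult mortality.
#' @export
HISTORIES <- c("NEVER_OWOB", "EVER_OWOB")

#' Arm tags for the two infant-feeding strategies
#' @export
ARMS <- c("LP", "HP")

#' Cost components
#' @export
COST_COMPONENTS <- c("DIRECT", "INDIRECT")

#' Classify a child's BMI percentile into a BMI category
#'
#' Uses the German reference-percentile convention for children and
#' adolescents: normal weight at or below the 90th percentile (underweight is
#' folded into normal), overweight above the 90th up to and including the
#' 97th, obese above the 97th. Boundaries are right-closed.
#'
#' @param bmi_percentile numeric vector of percentiles in \[0, 100\].
#' @return character vector of category labels (never `"DEAD"`).
#' @examples
#' classify_child(c(50, 90, 95, 97.1))
#' @export
classify_child <- function(bmi_percentile) {
  if (!is.numeric(bmi_percentile) || anyNA(bmi_percentile) ||
      any(!is.finite(bmi_percentile))) {
    stop("bmi_percentile must be finite numeric", call. = FALSE)
  }
  if (any(bmi_percentile < 0 | bmi_percentile > 100)) {
    stop("bmi_percentile must lie in [0, 100]", call. = FALSE)
  }
  ifelse(bmi_percentile <= 90, "NORMAL",
         ifelse(bmi_percentile <= 97, "OVERWEIGHT", "OBESE"))
}

#' Classify an adult BMI (kg/m^2) into a BMI category
#'
#' WHO adult cut-points, left-closed as conventionally printed:
#' normal below 25, overweight in \[25, 30), obese at 30 and above.
#'
#' @param bmi numeric vector of positive BMI values in kg/m^2.
#' @return character vector of category labels (never `"DEAD"`).
#' @examples
#' classify_adult(c(24.9, 25, 29.9, 30))
#' @export
classify_adult <- function(bmi) {
  if (!is.numeric(bmi) || anyNA(bmi) || any(!is.finite(bmi))) {
    stop("bmi must be finite numeric", call. = FALSE)
  }
  if (any(bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  ifelse(bmi < 25, "NORMAL", ifelse(bmi < 30, "OVERWEIGHT", "OBESE"))
}
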