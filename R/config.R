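# Run configuration: a validated list of scalars steering the whole pipeline.
# Stored on disk as JSON; unknown keys are rejected so typos fail loudly.

.config_defaults <- function() {
  list(
    discount_rate      = 0.03,
    wtp_grid           = c(0, 1000, 2000, 5000, 10000, 20000, 50000),
    psa_draws          = 4000L,
    seed               = 1L,
    formula_fed_share  = 0.19,
    birth_cohort_size  = 700000L,
    sex_mix            = c(MALE = 0.512, FEMALE = 0.488),
    horizon_age        = 100L,
    child_qaly_start_age = 18L,
    accrue_child_costs = TRUE
  )
}

#' Build a validated run configuration
#'
#' @param ... named overrides of the defaults: `discount_rate` (annual, 0.03),
#'   `wtp_grid` (ascending willingness-to-pay grid in EUR/QALY), `psa_draws`
#'   (4000), `seed`, `formula_fed_share` (0.19, the share of infants fed with
#'   formula), `birth_cohort_size` (persons), `sex_mix` (named proportions
#'   summing to 1), `horizon_age` (100), `child_qaly_start_age` (18; utilities
#'   below this age are not accrued), `accrue_child_costs` (TRUE).
#' @return object of class `run_config`.
#' @examples
#' cfg <- run_config(discount_rate = 0, psa_draws = 100L)
#' @export
run_config <- function(...) {
  overrides <- list(...)
  cfg <- .config_defaults()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$discount_rate), cfg$discount_rate >= 0)
  if (any(cfg$wtp_grid < 0)) stop("wtp_grid must be non-negative", call. = FALSE)
  if (is.unsorted(cfg$wtp_grid)) {
    stop("wtp_grid must be sorted ascending", call. = FALSE)
  }
  cfg$psa_draws <- as.integer(cfg$psa_draws)
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$psa_draws >= 1L)
  if (cfg$formula_fed_share < 0 || cfg$formula_fed_share > 1) {
    stop("formula_fed_share must lie in [0, 1]", call. = FALSE)
  }
  cfg$birth_cohort_size <- as.numeric(cfg$birth_cohort_size)
  stopifnot(cfg$birth_cohort_size > 0)
  mix <- cfg$sex_mix
  if (is.null(names(mix)) || !setequal(names(mix), SEXES)) {
    stop("sex_mix must be named with MALE and FEMALE", call. = FALSE)
  }
  mix <- mix[SEXES]
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("sex_mix proportions must sum to 1", call. = FALSE)
  }
  cfg$sex_mix <- mix
  cfg$horizon_age <- as.integer(cfg$horizon_age)
  cfg$child_qaly_start_age <- as.integer(cfg$child_qaly_start_age)
  stopifnot(cfg$horizon_age >= 1L, cfg$horizon_age <= 100L,
            cfg$child_qaly_start_age >= 0L,
            is.logical(cfg$accrue_child_costs))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; all documented keys are optional and fall back
#' to defaults.
#'
#' @param path path to a JSON file.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sex_mix)) raw$sex_mix <- unlist(raw$sex_mix)
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$sex_mix <- as.list(out$sex_mix)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  discount_rate: %g  horizon_age: %d  seed: %d\n",
              x$discount_rate, x$horizon_age, x$seed))
  cat(sprintf("  psa_draws: %d  wtp_grid: %s\n", x$psa_draws,
              paste(x$wtp_grid, collapse = ", ")))
  cat(sprintf("  formula_fed_share: %g  birth_cohort_size: %g\n",
              x$formula_fed_share, x$birth_cohort_size))
  cat(sprintf("  sex_mix: MALE %.3f / FEMALE %.3f\n",
              x$sex_mix[["MALE"]], x$sex_mix[["FEMALE"]]))
  invisible(x)
}
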