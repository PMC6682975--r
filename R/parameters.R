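# ParameterSet: the complete calibrated model input. Internally everything is
# dense arrays indexed [age+1, sex, ...] with age 0..99 (the transition /
# accrual ages; occupancy extends one year further, to horizon_age).
#
# CSV bundle schemas (UTF-8, header row, "." decimal):
#   transitions.csv   age, sex, arm, from_state, to_state, prob
#   mortality.csv     age, sex, qx
#   mortality_rr.csv  context, rr, ci_low, ci_high
#   costs.csv         age, sex, state, component, mean, se
#   utilities.csv     age, sex, state, mean, se
#   intervention.csv  outcome, rr, ci_low, ci_high, duration_years
#   initial.csv       sex, state, share

N_AGES <- 100L          # transition ages 0..99
ARM_AGE_MAX <- 5L       # arm-specific matrices exist for ages 0..5

.age_dn  <- function() as.character(0:(N_AGES - 1L))
.arm_dn  <- function() as.character(0:ARM_AGE_MAX)

MORTALITY_CONTEXTS <- c("ADULT_OW", "ADULT_OB", "CHILDHOOD_HISTORY")

#' Construct and validate a ParameterSet
#'
#' @param transitions list with elements `common` (array
#'   `[100, 2, 4, 4]`: age 0-99, sex, from, to), `lp` and `hp` (arrays
#'   `[6, 2, 4, 4]`: ages 0-5 of the intervention-effect window). All rows
#'   must be row-stochastic; the DEAD row is (0, 0, 0, 1).
#' @param mortality list with `qx` (matrix `[100, 2]` of annual death
#'   probabilities), `rr` (named vector `ADULT_OW`, `ADULT_OB`,
#'   `CHILDHOOD_HISTORY`) and `rr_ci` (matrix `[3, 2]`, columns low/high).
#' @param costs list with `mean` and `se`, arrays `[100, 2, 3, 2]` (age, sex,
#'   live state, component DIRECT/INDIRECT), EUR at 2015 prices, per year.
#' @param utilities list with `mean` and `se`, arrays `[100, 2, 3]`; values in
#'   \[-0.594, 1\] (EQ-5D tariff range).
#' @param intervention list with `rr_overweight`, `rr_obese`, each with
#'   `ci_low_*`/`ci_high_*`, and `duration_years` (default 6): the relative
#'   risk of becoming overweight/obese under LP vs HP formula.
#' @param initial matrix `[2, 3]` (sex by live state) of age-0 occupancy
#'   shares; each row sums to 1.
#' @return object of class `parameter_set`. A `validation` attribute lists any
#'   clamped or imputed cells.
#' @export
parameter_set <- function(transitions, mortality, costs, utilities,
                          intervention, initial) {
  ps <- structure(
    list(transitions = transitions, mortality = mortality, costs = costs,
         utilities = utilities, intervention = intervention,
         initial = initial),
    class = "parameter_set")
  validate_parameter_set(ps)
}

.check_stochastic <- function(arr, what, ages) {
  # arr: [n_age, 2, 4, 4]
  for (si in 1:2) {
    for (ai in seq_along(ages)) {
      M <- arr[ai, si, , ]
      if (any(M < -1e-12 | M > 1 + 1e-12)) {
        stop(sprintf("%s: probability outside [0,1] at age %s sex %s",
                     what, ages[ai], SEXES[si]), call. = FALSE)
      }
      rs <- rowSums(M)
      bad <- which(abs(rs - 1) > 1e-9)
      if (length(bad)) {
        stop(sprintf(
          "%s: row for state %s sums to %.12g (age %s, sex %s)",
          what, BMI_CATEGORIES[bad[1]], rs[bad[1]], ages[ai], SEXES[si]),
          call. = FALSE)
      }
      if (any(abs(M[4, ] - c(0, 0, 0, 1)) > 1e-12)) {
        stop(sprintf("%s: DEAD row must be (0,0,0,1) at age %s sex %s",
                     what, ages[ai], SEXES[si]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Validate a ParameterSet against all type invariants
#'
#' @param ps a `parameter_set` (or a bare list with the same shape).
#' @return the validated `parameter_set`, invisibly usable; errors name the
#'   offending cell.
#' @export
validate_parameter_set <- function(ps) {
  tr <- ps$transitions
  if (!identical(dim(tr$common), c(N_AGES, 2L, 4L, 4L))) {
    stop("transitions$common must be a [100, 2, 4, 4] array", call. = FALSE)
  }
  for (arm in c("lp", "hp")) {
    if (!identical(dim(tr[[arm]]), c(ARM_AGE_MAX + 1L, 2L, 4L, 4L))) {
      stop(sprintf("transitions$%s must be a [6, 2, 4, 4] array", arm),
           call. = FALSE)
    }
  }
  .check_na_cell(tr$common, "transitions (COMMON)", .age_dn())
  .check_na_cell(tr$lp, "transitions (LP)", .arm_dn())
  .check_na_cell(tr$hp, "transitions (HP)", .arm_dn())
  .check_stochastic(tr$common, "transitions (COMMON)", .age_dn())
  .check_stochastic(tr$lp, "transitions (LP)", .arm_dn())
  .check_stochastic(tr$hp, "transitions (HP)", .arm_dn())

  mo <- ps$mortality
  if (!identical(dim(mo$qx), c(N_AGES, 2L))) {
    stop("mortality$qx must be a [100, 2] matrix", call. = FALSE)
  }
  if (anyNA(mo$qx)) {
    idx <- which(is.na(mo$qx), arr.ind = TRUE)[1, ]
    stop(sprintf("missing mortality qx for age %d sex %s",
                 idx[1] - 1L, SEXES[idx[2]]), call. = FALSE)
  }
  if (any(mo$qx < 0 | mo$qx > 1)) {
    stop("mortality qx must lie in [0, 1]", call. = FALSE)
  }
  if (!all(MORTALITY_CONTEXTS %in% names(mo$rr))) {
    stop("mortality rr must name ", paste(MORTALITY_CONTEXTS, collapse = ", "),
         call. = FALSE)
  }
  if (any(mo$rr <= 0)) stop("mortality relative risks must be positive",
                            call. = FALSE)

  co <- ps$costs
  if (!identical(dim(co$mean), c(N_AGES, 2L, 3L, 2L))) {
    stop("costs$mean must be a [100, 2, 3, 2] array", call. = FALSE)
  }
  .check_na_cost(co$mean, "costs")
  if (any(co$mean < 0)) stop("costs must be non-negative", call. = FALSE)
  if (any(co$se < 0)) stop("cost standard errors must be non-negative",
                           call. = FALSE)

  ut <- ps$utilities
  if (!identical(dim(ut$mean), c(N_AGES, 2L, 3L))) {
    stop("utilities$mean must be a [100, 2, 3] array", call. = FALSE)
  }
  if (anyNA(ut$mean)) {
    idx <- which(is.na(ut$mean), arr.ind = TRUE)[1, ]
    stop(sprintf("missing utility for age %d sex %s state %s",
                 idx[1] - 1L, SEXES[idx[2]], LIVE_CATEGORIES[idx[3]]),
         call. = FALSE)
  }
  if (any(ut$mean < -0.594 - 1e-12 | ut$mean > 1 + 1e-12)) {
    stop("utilities must lie in [-0.594, 1]", call. = FALSE)
  }

  iv <- ps$intervention
  for (oc in c("overweight", "obese")) {
    rr <- iv[[paste0("rr_", oc)]]
    lo <- iv[[paste0("ci_low_", oc)]]
    hi <- iv[[paste0("ci_high_", oc)]]
    if (!(is.numeric(rr) && rr > 0 && lo > 0 && lo <= rr + 1e-12 &&
          rr <= hi + 1e-12)) {
      stop(sprintf("intervention %s: need 0 < ci_low <= rr <= ci_high", oc),
           call. = FALSE)
    }
  }
  if (iv$duration_years < 0) stop("duration_years must be >= 0", call. = FALSE)

  ini <- ps$initial
  if (!identical(dim(ini), c(2L, 3L))) {
    stop("initial must be a [2, 3] matrix (sex by live state)", call. = FALSE)
  }
  if (any(abs(rowSums(ini) - 1) > 1e-9) || any(ini < 0)) {
    stop("initial shares must be non-negative and sum to 1 per sex",
         call. = FALSE)
  }
  ps
}

.check_na_cell <- function(arr, what, ages) {
  if (anyNA(arr)) {
    idx <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: missing probability at age %s sex %s (%s -> %s)",
                 what, ages[idx[1]], SEXES[idx[2]],
                 BMI_CATEGORIES[idx[3]], BMI_CATEGORIES[idx[4]]),
         call. = FALSE)
  }
}

.check_na_cost <- function(arr, what) {
  if (anyNA(arr)) {
    idx <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: missing value at age %d sex %s state %s component %s",
                 what, idx[1] - 1L, SEXES[idx[2]], LIVE_CATEGORIES[idx[3]],
                 COST_COMPONENTS[idx[4]]), call. = FALSE)
  }
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  transitions: COMMON ages 0-%d, LP/HP ages 0-%d\n",
              N_AGES - 1L, ARM_AGE_MAX))
  cat(sprintf("  intervention RR: overweight %.3f [%.3f, %.3f], obese %.3f [%.3f, %.3f], %d-year window\n",
              x$intervention$rr_overweight, x$intervention$ci_low_overweight,
              x$intervention$ci_high_overweight, x$intervention$rr_obese,
              x$intervention$ci_low_obese, x$intervention$ci_high_obese,
              x$intervention$duration_years))
  cat(sprintf("  mortality RR: adult OW %.2f, adult OB %.2f, childhood history %.2f\n",
              x$mortality$rr[["ADULT_OW"]], x$mortality$rr[["ADULT_OB"]],
              x$mortality$rr[["CHILDHOOD_HISTORY"]]))
  invisible(x)
}

# ---- CSV bundle I/O ---------------------------------------------------------

.fmt <- function(x) sprintf("%.17g", x)

.read_table <- function(dir, name) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop("parameter bundle is missing table: ", name, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.sex_index <- function(sex) {
  i <- match(sex, SEXES)
  if (anyNA(i)) stop("invalid sex label: ", sex[which(is.na(i))[1]],
                     call. = FALSE)
  i
}
.cat_index <- function(state, live_only = FALSE) {
  lev <- if (live_only) LIVE_CATEGORIES else BMI_CATEGORIES
  i <- match(state, lev)
  if (anyNA(i)) stop("invalid state label: ", state[which(is.na(i))[1]],
                     call. = FALSE)
  i
}

#' Load a parameter bundle from a directory of CSV tables
#'
#' Reads the documented CSV schemas and assembles a validated
#' [parameter_set()]. Every (age, sex) lookup needed by the engine must
#' resolve; missing cells raise an error naming the cell.
#'
#' @param dir directory containing `transitions.csv`, `mortality.csv`,
#'   `mortality_rr.csv`, `costs.csv`, `utilities.csv`, `intervention.csv`,
#'   `initial.csv`.
#' @return a `parameter_set`.
#' @seealso [write_parameters()], [write_bundle()]
#' @export
load_parameters <- function(dir) {
  tr <- .read_table(dir, "transitions.csv")
  need <- c("age", "sex", "arm", "from_state", "to_state", "prob")
  if (!all(need %in% names(tr))) {
    stop("transitions.csv must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  common <- array(NA_real_, dim = c(N_AGES, 2L, 4L, 4L))
  lp <- array(NA_real_, dim = c(ARM_AGE_MAX + 1L, 2L, 4L, 4L))
  hp <- lp
  bad_age <- tr$age[tr$arm == "COMMON" & (tr$age < 0 | tr$age >= N_AGES)]
  if (length(bad_age)) stop("transitions.csv: COMMON age out of 0-99: ",
                            bad_age[1], call. = FALSE)
  bad_age <- tr$age[tr$arm != "COMMON" & (tr$age < 0 | tr$age > ARM_AGE_MAX)]
  if (length(bad_age)) {
    stop("transitions.csv: arm-specific entries only allowed for ages 0-",
         ARM_AGE_MAX, " (got ", bad_age[1], ")", call. = FALSE)
  }
  si <- .sex_index(tr$sex); fi <- .cat_index(tr$from_state)
  ti <- .cat_index(tr$to_state)
  for (k in seq_len(nrow(tr))) {
    idx <- cbind(tr$age[k] + 1L, si[k], fi[k], ti[k])
    switch(tr$arm[k],
           COMMON = { common[idx] <- tr$prob[k] },
           LP = { lp[idx] <- tr$prob[k] },
           HP = { hp[idx] <- tr$prob[k] },
           stop("invalid arm tag in transitions.csv: ", tr$arm[k],
                call. = FALSE))
  }

  mo <- .read_table(dir, "mortality.csv")
  qx <- matrix(NA_real_, N_AGES, 2L)
  qx[cbind(mo$age + 1L, .sex_index(mo$sex))] <- mo$qx

  mr <- .read_table(dir, "mortality_rr.csv")
  rr <- stats::setNames(mr$rr, mr$context)
  missing_ctx <- setdiff(MORTALITY_CONTEXTS, mr$context)
  if (length(missing_ctx)) {
    stop("mortality_rr.csv missing context: ", missing_ctx[1], call. = FALSE)
  }
  rr_ci <- cbind(low = mr$ci_low, high = mr$ci_high)
  rownames(rr_ci) <- mr$context

  co <- .read_table(dir, "costs.csv")
  cmean <- array(NA_real_, dim = c(N_AGES, 2L, 3L, 2L))
  cse <- cmean
  ci_idx <- cbind(co$age + 1L, .sex_index(co$sex),
                  .cat_index(co$state, live_only = TRUE),
                  match(co$component, COST_COMPONENTS))
  cmean[ci_idx] <- co$mean
  cse[ci_idx] <- co$se

  ut <- .read_table(dir, "utilities.csv")
  umean <- array(NA_real_, dim = c(N_AGES, 2L, 3L))
  use <- umean
  ui_idx <- cbind(ut$age + 1L, .sex_index(ut$sex),
                  .cat_index(ut$state, live_only = TRUE))
  umean[ui_idx] <- ut$mean
  use[ui_idx] <- ut$se

  iv <- .read_table(dir, "intervention.csv")
  row_of <- function(outcome) {
    r <- iv[iv$outcome == outcome, ]
    if (nrow(r) != 1) stop("intervention.csv needs one row for outcome ",
                           outcome, call. = FALSE)
    r
  }
  ow <- row_of("OVERWEIGHT"); ob <- row_of("OBESE")
  intervention <- list(
    rr_overweight = ow$rr, ci_low_overweight = ow$ci_low,
    ci_high_overweight = ow$ci_high,
    rr_obese = ob$rr, ci_low_obese = ob$ci_low, ci_high_obese = ob$ci_high,
    duration_years = as.integer(ow$duration_years))

  ini_df <- .read_table(dir, "initial.csv")
  ini <- matrix(NA_real_, 2L, 3L)
  ini[cbind(.sex_index(ini_df$sex),
            .cat_index(ini_df$state, live_only = TRUE))] <- ini_df$share

  parameter_set(
    transitions = list(common = common, lp = lp, hp = hp),
    mortality = list(qx = qx, rr = rr[MORTALITY_CONTEXTS],
                     rr_ci = rr_ci[MORTALITY_CONTEXTS, , drop = FALSE]),
    costs = list(mean = cmean, se = cse),
    utilities = list(mean = umean, se = use),
    intervention = intervention,
    initial = ini)
}

.long_transitions <- function(arr, arm, ages) {
  grid <- expand.grid(to = 1:4, from = 1:4, sex = 1:2, age = seq_along(ages),
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    age = ages[grid$age],
    sex = SEXES[grid$sex],
    arm = arm,
    from_state = BMI_CATEGORIES[grid$from],
    to_state = BMI_CATEGORIES[grid$to],
    prob = arr[cbind(grid$age, grid$sex, grid$from, grid$to)],
    stringsAsFactors = FALSE)
}

#' Write a parameter bundle to a directory of CSV tables
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(ps, d))`
#' reproduces every numeric cell exactly (values are serialized at full
#' double precision).
#'
#' @param ps a `parameter_set`.
#' @param dir output directory (created if absent).
#' @return character vector of written file paths, invisibly.
#' @export
write_parameters <- function(ps, dir) {
  stopifnot(inherits(ps, "parameter_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, numcols) {
    for (cn in numcols) df[[cn]] <- .fmt(df[[cn]])
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
    file.path(dir, name)
  }
  tr <- rbind(
    .long_transitions(ps$transitions$common, "COMMON", 0:(N_AGES - 1L)),
    .long_transitions(ps$transitions$lp, "LP", 0:ARM_AGE_MAX),
    .long_transitions(ps$transitions$hp, "HP", 0:ARM_AGE_MAX))
  paths <- c(w(tr, "transitions.csv", "prob"))

  mo <- expand.grid(age = 0:(N_AGES - 1L), sex = SEXES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mo$qx <- ps$mortality$qx[cbind(mo$age + 1L, match(mo$sex, SEXES))]
  paths <- c(paths, w(mo, "mortality.csv", "qx"))

  mr <- data.frame(context = MORTALITY_CONTEXTS,
                   rr = as.numeric(ps$mortality$rr[MORTALITY_CONTEXTS]),
                   ci_low = ps$mortality$rr_ci[MORTALITY_CONTEXTS, "low"],
                   ci_high = ps$mortality$rr_ci[MORTALITY_CONTEXTS, "high"])
  paths <- c(paths, w(mr, "mortality_rr.csv", c("rr", "ci_low", "ci_high")))

  co <- expand.grid(age = 0:(N_AGES - 1L), sex = SEXES,
                    state = LIVE_CATEGORIES, component = COST_COMPONENTS,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(co$age + 1L, match(co$sex, SEXES),
               match(co$state, LIVE_CATEGORIES),
               match(co$component, COST_COMPONENTS))
  co$mean <- ps$costs$mean[idx]; co$se <- ps$costs$se[idx]
  paths <- c(paths, w(co, "costs.csv", c("mean", "se")))

  ut <- expand.grid(age = 0:(N_AGES - 1L), sex = SEXES,
                    state = LIVE_CATEGORIES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  uidx <- cbind(ut$age + 1L, match(ut$sex, SEXES),
                match(ut$state, LIVE_CATEGORIES))
  ut$mean <- ps$utilities$mean[uidx]; ut$se <- ps$utilities$se[uidx]
  paths <- c(paths, w(ut, "utilities.csv", c("mean", "se")))

  iv <- ps$intervention
  ivdf <- data.frame(
    outcome = c("OVERWEIGHT", "OBESE"),
    rr = c(iv$rr_overweight, iv$rr_obese),
    ci_low = c(iv$ci_low_overweight, iv$ci_low_obese),
    ci_high = c(iv$ci_high_overweight, iv$ci_high_obese),
    duration_years = iv$duration_years)
  paths <- c(paths, w(ivdf, "intervention.csv", c("rr", "ci_low", "ci_high")))

  ini <- expand.grid(sex = SEXES, state = LIVE_CATEGORIES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ini$share <- ps$initial[cbind(match(ini$sex, SEXES),
                                match(ini$state, LIVE_CATEGORIES))]
  paths <- c(paths, w(ini, "initial.csv", "share"))
  invisible(paths)
}
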