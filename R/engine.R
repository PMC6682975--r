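# Two-part cohort engine.
#
# Occupancy lives on a 4 x 2 grid: BMI category (NORMAL, OVERWEIGHT, OBESE,
# DEAD) by childhood history (NEVER_OWOB, EVER_OWOB). Mass entering OVERWEIGHT
# or OBESE is moved to the EVER_OWOB column at the same instant, so the
# (OW, NEVER) and (OB, NEVER) cells are always empty between cycles. DEAD
# retains its history column for bookkeeping but accrues nothing.
#
# Cycle order (no half-cycle correction): rewards are accrued on the cycle-
# start occupancy for the full year, then mortality is applied, then the
# survivors move between BMI categories. Discounting is referenced to birth:
# the reward of the cycle starting at age a is divided by (1+r)^a.

#' Discount an amount back to cycle 0
#'
#' @param amount numeric amount.
#' @param cycle non-negative integer cycle index (cycle 0 is undiscounted).
#' @param rate annual discount rate, `>= 0`.
#' @return `amount / (1 + rate)^cycle`.
#' @examples
#' discount(100, 1, 0.03)
#' @export
discount <- function(amount, cycle, rate) {
  stopifnot(is.numeric(amount), is.numeric(rate), rate >= 0)
  if (any(cycle < 0)) stop("cycle must be non-negative", call. = FALSE)
  amount / (1 + rate)^cycle
}

# 3x3 live-state movement matrix conditional on survival for one (age, sex,
# arm). Any death mass in the stored matrix is removed by renormalization.
.live_matrix <- function(ps, age, sex_i, arm) {
  in_window <- age <= ARM_AGE_MAX && age < ps$intervention$duration_years
  M <- if (arm != "COMMON" && in_window) {
    ps$transitions[[tolower(arm)]][age + 1L, sex_i, , ]
  } else {
    ps$transitions$common[age + 1L, sex_i, , ]
  }
  live <- M[1:3, 1:3]
  rs <- rowSums(live)
  if (any(rs <= 0)) {
    stop(sprintf("no live transition mass for age %d sex %s", age,
                 SEXES[sex_i]), call. = FALSE)
  }
  live / rs
}

# Core propagation over a contiguous age range. Returns a cohort_trace.
.propagate <- function(ps, arm, sex, age_from, age_to, occ, config,
                       adult_from = 18L) {
  sex_i <- .sex_index(sex)
  n_cyc <- age_to - age_from
  ages <- age_from:age_to
  occupancy <- array(0, dim = c(n_cyc + 1L, 4L, 2L),
                     dimnames = list(ages, BMI_CATEGORIES, HISTORIES))
  disc_cost <- disc_qaly <- py_owob <- py_alive <- numeric(n_cyc)
  r <- config$discount_rate
  qstart <- config$child_qaly_start_age
  cost_by_cat <- ps$costs$mean[, sex_i, , 1] + ps$costs$mean[, sex_i, , 2]
  util_by_cat <- ps$utilities$mean[, sex_i, ]
  rr <- ps$mortality$rr
  cat_rr <- c(1, rr[["ADULT_OW"]], rr[["ADULT_OB"]])
  hist_rr <- c(1, rr[["CHILDHOOD_HISTORY"]])
  n_clamped <- 0L

  occupancy[1, , ] <- occ
  for (k in seq_len(n_cyc)) {
    age <- ages[k]
    lv <- rowSums(occ[1:3, , drop = FALSE])      # live occupancy by category
    df <- (1 + r)^(-age)
    accrue_cost <- age >= adult_from || config$accrue_child_costs
    disc_cost[k] <- if (accrue_cost) sum(lv * cost_by_cat[age + 1L, ]) * df else 0
    disc_qaly[k] <- if (age >= qstart) sum(lv * util_by_cat[age + 1L, ]) * df else 0
    py_owob[k] <- lv[2] + lv[3]
    py_alive[k] <- sum(lv)

    qx <- ps$mortality$qx[age + 1L, sex_i]
    if (age < adult_from) {
      q <- matrix(qx, 3L, 2L)                     # uniform childhood mortality
    } else {
      q <- outer(cat_rr, hist_rr) * qx
      over <- q > 1
      if (any(over)) { n_clamped <- n_clamped + sum(over); q[over] <- 1 }
    }
    dead_new <- colSums(occ[1:3, , drop = FALSE] * q)
    surv <- occ[1:3, , drop = FALSE] * (1 - q)
    P <- .live_matrix(ps, age, sex_i, arm)
    moved <- crossprod(P, surv)                   # t(P) %*% surv: 3 x 2
    moved[2:3, 2] <- moved[2:3, 2] + moved[2:3, 1]
    moved[2:3, 1] <- 0
    occ[1:3, ] <- moved
    occ[4, ] <- occ[4, ] + dead_new
    occupancy[k + 1L, , ] <- occ
  }
  structure(
    list(arm = arm, sex = sex, ages = ages, occupancy = occupancy,
         disc_cost = disc_cost, disc_qaly = disc_qaly,
         py_owob = py_owob, py_alive = py_alive, n_clamped = n_clamped),
    class = "cohort_trace")
}

#' Run the childhood-to-adolescence model (M1)
#'
#' Propagates the birth cohort from age 0 to age 18 using arm-specific
#' matrices inside the intervention-effect window (ages 0 to
#' `duration_years - 1`) and COMMON matrices afterwards. Childhood mortality
#' comes from the life table, applied uniformly across BMI states. Mass in
#' OVERWEIGHT or OBESE at age 0 (and any mass entering later) carries the
#' EVER_OWOB history flag.
#'
#' @param ps a `parameter_set`.
#' @param arm `"LP"` or `"HP"`.
#' @param sex `"MALE"` or `"FEMALE"`.
#' @param config a [run_config()].
#' @return a `cohort_trace` covering ages 0-18; the final occupancy row is
#'   the handoff distribution for [run_m2()].
#' @export
run_m1 <- function(ps, arm, sex, config = run_config()) {
  stopifnot(inherits(ps, "parameter_set"), arm %in% ARMS)
  sex_i <- .sex_index(sex)
  init <- ps$initial[sex_i, ]
  occ <- matrix(0, 4L, 2L)
  occ[1, 1] <- init[1]
  occ[2, 2] <- init[2]           # starting in OW/OB counts as history
  occ[3, 2] <- init[3]
  .propagate(ps, arm, sex, 0L, 18L, occ, config)
}

#' Run the adulthood model (M2)
#'
#' Propagates the age-18 handoff distribution to the horizon using COMMON
#' matrices. The per-cycle death probability is the life-table `qx`
#' multiplied by the adult overweight/obese relative risk for the current
#' category and, for the EVER_OWOB cohort, the childhood-history relative
#' risk; products above 1 are clamped (the number of clamped cells is
#' reported in the trace). Costs accrue per (age, sex, category); utilities
#' accrue from `child_qaly_start_age`; both discounted to birth.
#'
#' @param ps a `parameter_set`.
#' @param handoff 4 x 2 occupancy matrix (category by history) summing to 1.
#' @param sex `"MALE"` or `"FEMALE"`.
#' @param config a [run_config()].
#' @param arm arm tag recorded in the trace (matrices are COMMON regardless).
#' @return a `cohort_trace` covering ages 18 to `config$horizon_age`.
#' @export
run_m2 <- function(ps, handoff, sex, config = run_config(), arm = "COMMON") {
  stopifnot(inherits(ps, "parameter_set"))
  if (!is.matrix(handoff) || !identical(dim(handoff), c(4L, 2L)) ||
      abs(sum(handoff) - 1) > 1e-9) {
    stop("handoff must be a 4x2 occupancy matrix summing to 1", call. = FALSE)
  }
  .propagate(ps, arm, sex, 18L, config$horizon_age, handoff, config)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> arm %s, sex %s, ages %d-%d\n",
              x$arm, x$sex, x$ages[1], x$ages[length(x$ages)]))
  cat(sprintf("  final dead mass: %.4f; discounted cost so far: %.2f\n",
              sum(x$occupancy[dim(x$occupancy)[1], 4, ]), sum(x$disc_cost)))
  invisible(x)
}

#' Summarize M1 + M2 traces into lifetime per-person totals
#'
#' @param m1,m2 `cohort_trace`s from [run_m1()] and [run_m2()]; `m2` must
#'   start at the age where `m1` ends.
#' @param config a [run_config()].
#' @return an `arm_result` with `lifetime_cost_pp`, `lifetime_qaly_pp`
#'   (discounted EUR and QALYs per person), `person_years_owob` and
#'   `life_expectancy` (undiscounted years), and `decade_costs` (10 bins that
#'   sum to the lifetime cost).
#' @export
summarize_arm <- function(m1, m2, config = run_config()) {
  stopifnot(inherits(m1, "cohort_trace"), inherits(m2, "cohort_trace"))
  if (m1$ages[length(m1$ages)] != m2$ages[1]) {
    stop("age gap between traces: M1 ends at ", m1$ages[length(m1$ages)],
         ", M2 starts at ", m2$ages[1], call. = FALSE)
  }
  ages <- c(m1$ages[-length(m1$ages)], m2$ages[-length(m2$ages)])
  disc_cost <- c(m1$disc_cost, m2$disc_cost)
  disc_qaly <- c(m1$disc_qaly, m2$disc_qaly)
  py_owob <- c(m1$py_owob, m2$py_owob)
  py_alive <- c(m1$py_alive, m2$py_alive)
  decade <- pmin(ages %/% 10L, 9L)
  decade_costs <- vapply(0:9, function(d) sum(disc_cost[decade == d]),
                         numeric(1))
  names(decade_costs) <- paste0("D", 1:10)
  structure(
    list(arm = m1$arm, sex = m1$sex,
         lifetime_cost_pp = sum(disc_cost),
         lifetime_qaly_pp = sum(disc_qaly),
         person_years_owob = sum(py_owob),
         life_expectancy = sum(py_alive),
         decade_costs = decade_costs,
         n_clamped = m1$n_clamped + m2$n_clamped),
    class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> arm %s, sex %s\n", x$arm, x$sex))
  cat(sprintf("  lifetime cost/person (disc.): EUR %.2f\n", x$lifetime_cost_pp))
  cat(sprintf("  lifetime QALYs/person (disc.): %.4f\n", x$lifetime_qaly_pp))
  cat(sprintf("  years with OW/OB: %.2f; life expectancy: %.2f\n",
              x$person_years_owob, x$life_expectancy))
  invisible(x)
}

# Weighted average of per-sex arm_results (sex_mix weights).
.pool_arm_results <- function(by_sex, weights) {
  w <- weights / sum(weights)
  agg <- function(field) sum(vapply(seq_along(by_sex),
                                    function(i) by_sex[[i]][[field]] * w[i],
                                    numeric(1)))
  dec <- Reduce(`+`, lapply(seq_along(by_sex),
                            function(i) by_sex[[i]]$decade_costs * w[i]))
  structure(
    list(arm = by_sex[[1]]$arm, sex = "POOLED",
         lifetime_cost_pp = agg("lifetime_cost_pp"),
         lifetime_qaly_pp = agg("lifetime_qaly_pp"),
         person_years_owob = agg("person_years_owob"),
         life_expectancy = agg("life_expectancy"),
         decade_costs = dec,
         n_clamped = sum(vapply(by_sex, `[[`, integer(1), "n_clamped")),
         by_sex = by_sex),
    class = "arm_result")
}

#' Run one strategy end to end for one sex
#'
#' Convenience wrapper: [run_m1()], handoff, [run_m2()], [summarize_arm()].
#'
#' @inheritParams run_m1
#' @param keep_traces if TRUE, attach the M1/M2 traces to the result.
#' @return an `arm_result`.
#' @export
run_arm_sex <- function(ps, arm, sex, config = run_config(),
                        keep_traces = FALSE) {
  m1 <- run_m1(ps, arm, sex, config)
  handoff <- m1$occupancy[dim(m1$occupancy)[1], , ]
  m2 <- run_m2(ps, handoff, sex, config, arm = arm)
  res <- summarize_arm(m1, m2, config)
  if (keep_traces) res$traces <- list(m1 = m1, m2 = m2)
  res
}

#' Run one strategy for both sexes and pool by the configured sex mix
#'
#' @inheritParams run_m1
#' @param keep_traces if TRUE, per-sex traces are attached.
#' @return a pooled `arm_result` with a `by_sex` list of per-sex results.
#' @export
run_arm <- function(ps, arm, config = run_config(), keep_traces = FALSE) {
  by_sex <- lapply(SEXES, function(s)
    run_arm_sex(ps, arm, s, config, keep_traces = keep_traces))
  names(by_sex) <- SEXES
  .pool_arm_results(by_sex, config$sex_mix[SEXES])
}

#' Run both strategies
#'
#' @param ps a `parameter_set`.
#' @param config a [run_config()].
#' @param keep_traces if TRUE, per-sex traces are attached to each arm.
#' @return list with elements `LP` and `HP`, each a pooled `arm_result`.
#' @export
run_strategies <- function(ps, config = run_config(), keep_traces = FALSE) {
  list(LP = run_arm(ps, "LP", config, keep_traces),
       HP = run_arm(ps, "HP", config, keep_traces))
}

#' Export a cohort trace as a long data frame
#'
#' One row per (age, state, history) with occupancy, plus per-age discounted
#' cost and QALY increments (repeated across states of that age, zero for the
#' final recorded age).
#'
#' @param trace a `cohort_trace`.
#' @return data.frame with columns arm, sex, age, state, history, occupancy,
#'   disc_cost, disc_qaly.
#' @export
trace_to_df <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- length(trace$ages)
  grid <- expand.grid(history = HISTORIES, state = BMI_CATEGORIES,
                      age = trace$ages, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  occ <- aperm(trace$occupancy, c(3, 2, 1))
  inc_cost <- c(trace$disc_cost, 0)[match(grid$age, trace$ages)]
  inc_qaly <- c(trace$disc_qaly, 0)[match(grid$age, trace$ages)]
  data.frame(arm = trace$arm, sex = trace$sex, age = grid$age,
             state = grid$state, history = grid$history,
             occupancy = as.vector(occ),
             disc_cost = inc_cost, disc_qaly = inc_qaly,
             stringsAsFactors = FALSE)
}
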