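# Individual-level microsimulation used to cross-validate the cohort engine.
# This is a deliberately separate code path: persons are simulated one cycle
# at a time by sampling categorical transitions and Bernoulli deaths, and
# per-person lifetime totals provide Monte-Carlo standard errors against
# which the deterministic cohort expectations are checked.

#' Individual-level microsimulation of one strategy and sex
#'
#' Simulates `n` persons from birth to the horizon under the same cycle
#' order as the cohort engine (accrue on cycle-start state, then mortality,
#' then category movement) and returns per-person lifetime totals with
#' Monte-Carlo standard errors of their means.
#'
#' @param ps a `parameter_set`.
#' @param arm `"LP"` or `"HP"`.
#' @param sex `"MALE"` or `"FEMALE"`.
#' @param n number of simulated persons.
#' @param config a [run_config()].
#' @param seed RNG seed (the function seeds locally and restores nothing).
#' @return list with means and standard errors of `lifetime_cost_pp`,
#'   `lifetime_qaly_pp`, `person_years_owob`, plus `life_expectancy` and `n`.
#' @export
run_microsim <- function(ps, arm, sex, n, config = run_config(), seed = 1L) {
  stopifnot(inherits(ps, "parameter_set"), arm %in% ARMS, n >= 1)
  sex_i <- .sex_index(sex)
  set.seed(seed)
  r <- config$discount_rate
  qstart <- config$child_qaly_start_age
  horizon <- config$horizon_age
  cost_by_cat <- ps$costs$mean[, sex_i, , 1] + ps$costs$mean[, sex_i, , 2]
  util_by_cat <- ps$utilities$mean[, sex_i, ]
  rr <- ps$mortality$rr
  cat_rr <- c(1, rr[["ADULT_OW"]], rr[["ADULT_OB"]])
  hist_rr <- c(1, rr[["CHILDHOOD_HISTORY"]])

  init <- ps$initial[sex_i, ]
  cat <- sample.int(3L, n, replace = TRUE, prob = init)
  ever <- cat >= 2L
  alive <- rep(TRUE, n)
  cost <- qaly <- owob <- yrs <- numeric(n)

  for (age in 0:(horizon - 1L)) {
    idx_alive <- which(alive)
    if (!length(idx_alive)) break
    ac <- cat[idx_alive]
    df <- (1 + r)^(-age)
    accrue_cost <- age >= 18L || config$accrue_child_costs
    if (accrue_cost) {
      cost[idx_alive] <- cost[idx_alive] + cost_by_cat[age + 1L, ac] * df
    }
    if (age >= qstart) {
      qaly[idx_alive] <- qaly[idx_alive] + util_by_cat[age + 1L, ac] * df
    }
    owob[idx_alive] <- owob[idx_alive] + (ac >= 2L)
    yrs[idx_alive] <- yrs[idx_alive] + 1

    qx <- ps$mortality$qx[age + 1L, sex_i]
    q <- if (age < 18L) rep(qx, length(idx_alive))
         else pmin(1, qx * cat_rr[ac] * ifelse(ever[idx_alive], hist_rr[2], 1))
    dies <- stats::runif(length(idx_alive)) < q
    alive[idx_alive[dies]] <- FALSE
    surv <- idx_alive[!dies]
    if (!length(surv)) next
    P <- .live_matrix(ps, age, sex_i, arm)
    cp <- t(apply(P, 1, cumsum))
    u <- stats::runif(length(surv))
    sc <- cat[surv]
    nxt <- integer(length(surv))
    for (c0 in 1:3) {
      m <- sc == c0
      if (any(m)) {
        nxt[m] <- pmin(findInterval(u[m], cp[c0, ], left.open = TRUE) + 1L, 3L)
      }
    }
    cat[surv] <- nxt
    ever[surv] <- ever[surv] | nxt >= 2L
  }
  se <- function(x) stats::sd(x) / sqrt(n)
  list(lifetime_cost_pp = mean(cost), se_cost = se(cost),
       lifetime_qaly_pp = mean(qaly), se_qaly = se(qaly),
       person_years_owob = mean(owob), se_owob = se(owob),
       life_expectancy = mean(yrs), n = n)
}
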