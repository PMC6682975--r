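# Incremental cost-effectiveness layer. Sign convention throughout: all
# increments are LP minus HP, so a cost saving under LP appears as a negative
# delta_cost and a positive NMB at WTP = 0.

#' Incremental comparison of two strategies
#'
#' @param lp,hp `arm_result`s (or any lists with `lifetime_cost_pp` and
#'   `lifetime_qaly_pp`) produced under the same configuration.
#' @return list with `delta_cost`, `delta_qaly` (LP - HP), `icer`
#'   (`NA` and `icer_defined = FALSE` when `|delta_qaly| < 1e-12`), and a
#'   `dominance` tag (`"LP_DOMINANT"`, `"HP_DOMINANT"` or `"NONE"`).
#' @examples
#' incremental(list(lifetime_cost_pp = 12535, lifetime_qaly_pp = 47.72),
#'             list(lifetime_cost_pp = 13285, lifetime_qaly_pp = 47.42))
#' @export
incremental <- function(lp, hp) {
  delta_cost <- lp$lifetime_cost_pp - hp$lifetime_cost_pp
  delta_qaly <- lp$lifetime_qaly_pp - hp$lifetime_qaly_pp
  defined <- abs(delta_qaly) >= 1e-12
  icer <- if (defined) delta_cost / delta_qaly else NA_real_
  dominance <- if (delta_cost < 0 && delta_qaly > 0) "LP_DOMINANT"
               else if (delta_cost > 0 && delta_qaly < 0) "HP_DOMINANT"
               else "NONE"
  list(delta_cost = delta_cost, delta_qaly = delta_qaly,
       icer = icer, icer_defined = defined, dominance = dominance)
}

#' Net monetary benefit
#'
#' `NMB(w) = delta_qaly * w - delta_cost`: the health gain valued at the
#' willingness to pay, net of the incremental cost.
#'
#' @param delta_qaly incremental QALYs (LP - HP).
#' @param delta_cost incremental cost in EUR (LP - HP).
#' @param wtp willingness to pay in EUR per QALY, `>= 0` (vectorized).
#' @return NMB in EUR per person.
#' @examples
#' nmb(0.2976, -750, c(0, 1000, 5000))
#' @export
nmb <- function(delta_qaly, delta_cost, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  delta_qaly * wtp - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with strictly positive NMB at each willingness-to-
#' pay value. Ties (NMB exactly 0) count as not cost-effective.
#'
#' @param psa a `psa_result` from [run_psa()] (or any list with a `draws`
#'   data.frame holding `delta_cost` and `delta_qaly`).
#' @param wtp_grid non-negative WTP values.
#' @return data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  d <- psa$draws
  if (is.null(d) || !nrow(d)) stop("psa draws are empty", call. = FALSE)
  if (any(wtp_grid < 0)) stop("wtp must be non-negative", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(d$delta_qaly * w - d$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Averted person-years with overweight/obesity
#'
#' Years with overweight or obesity averted by each arm relative to a
#' reference scenario, and the LP-vs-HP difference. The difference is
#' algebraically independent of the reference:
#' `averted_lp - averted_hp = py_owob(HP) - py_owob(LP)`.
#'
#' @param lp,hp `arm_result`s.
#' @param reference an `arm_result` for the reference scenario; if `NULL`
#'   only the (reference-free) difference is returned and the per-arm
#'   averted values are `NA`.
#' @return list with `averted_lp`, `averted_hp`, `difference`.
#' @export
averted_years <- function(lp, hp, reference = NULL) {
  difference <- hp$person_years_owob - lp$person_years_owob
  if (is.null(reference)) {
    return(list(averted_lp = NA_real_, averted_hp = NA_real_,
                difference = difference))
  }
  list(averted_lp = reference$person_years_owob - lp$person_years_owob,
       averted_hp = reference$person_years_owob - hp$person_years_owob,
       difference = difference)
}

#' Scale per-person savings to the population level
#'
#' @param savings_pp savings per formula-fed person in EUR.
#' @param formula_fed_share share of the birth cohort fed with formula.
#' @param cohort_size birth cohort size in persons.
#' @return total savings in EUR: `savings_pp * formula_fed_share * cohort_size`.
#' @examples
#' population_savings(750, 0.19, 1e6)
#' @export
population_savings <- function(savings_pp, formula_fed_share, cohort_size) {
  if (any(c(savings_pp, formula_fed_share, cohort_size) < 0)) {
    stop("population_savings inputs must be non-negative", call. = FALSE)
  }
  savings_pp * formula_fed_share * cohort_size
}

#' Full incremental cost-effectiveness comparison
#'
#' Builds the complete comparison of LP vs HP: increments and ICER (pooled
#' and per sex), the NMB curve on the configured WTP grid, the averted
#' years-with-overweight/obesity difference, population savings, and - when
#' a `psa_result` is supplied - the CEAC and 2.5/97.5 percentile intervals.
#'
#' @param lp,hp pooled `arm_result`s from [run_arm()].
#' @param config a [run_config()].
#' @param psa optional `psa_result`.
#' @return object of class `cea_result`.
#' @export
cea_compare <- function(lp, hp, config = run_config(), psa = NULL) {
  inc <- incremental(lp, hp)
  nmb_curve <- data.frame(
    wtp = config$wtp_grid,
    nmb = nmb(inc$delta_qaly, inc$delta_cost, config$wtp_grid))
  by_sex <- NULL
  if (!is.null(lp$by_sex) && !is.null(hp$by_sex)) {
    by_sex <- lapply(SEXES, function(s) {
      inc_s <- incremental(lp$by_sex[[s]], hp$by_sex[[s]])
      inc_s$nmb_curve <- data.frame(
        wtp = config$wtp_grid,
        nmb = nmb(inc_s$delta_qaly, inc_s$delta_cost, config$wtp_grid))
      inc_s
    })
    names(by_sex) <- SEXES
  }
  av <- averted_years(lp, hp)
  savings <- population_savings(max(0, -inc$delta_cost),
                                config$formula_fed_share,
                                config$birth_cohort_size)
  res <- list(incremental = inc, nmb_curve = nmb_curve, by_sex = by_sex,
              averted_years_diff = av$difference,
              population_savings = savings,
              lp = lp, hp = hp, config = config)
  if (!is.null(psa)) {
    res$ceac <- ceac(psa, config$wtp_grid)
    res$psa_summaries <- psa$summaries
  }
  structure(res, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  inc <- x$incremental
  cat("<cea_result> LP vs HP\n")
  cat(sprintf("  delta cost/person: EUR %.2f; delta QALYs/person: %.4f\n",
              inc$delta_cost, inc$delta_qaly))
  if (inc$icer_defined) {
    cat(sprintf("  ICER: EUR %.2f per QALY (%s)\n", inc$icer, inc$dominance))
  } else {
    cat("  ICER: undefined (delta QALY ~ 0)\n")
  }
  cat(sprintf("  averted OW/OB years (LP vs HP): %.2f\n",
              x$averted_years_diff))
  cat(sprintf("  population savings: EUR %.0f\n", x$population_savings))
  invisible(x)
}
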