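# Interval-to-annual probability conversion and panel-based estimation of
# age/sex-specific transition rows.
#
# The annualization follows the constant-rate convention: an interval
# probability p over t years corresponds to rate r = -ln(1 - p)/t and annual
# probability 1 - exp(-r). For a single destination this inverts t-fold
# composition exactly; for competing destinations the per-destination
# conversion is only approximate and the residual goes to the diagonal.

#' Convert an interval probability to an annual probability
#'
#' Constant-rate conversion: `1 - (1 - p)^(1/t)`. Composing the annual
#' probability over `t` years reproduces the interval probability exactly.
#'
#' @param p_interval probability observed over the interval, in \[0, 1).
#' @param interval_years positive integer interval length.
#' @return annual probability in \[0, 1).
#' @examples
#' annualize_two_state(0.19, 2) # 0.10
#' @export
annualize_two_state <- function(p_interval, interval_years) {
  stopifnot(is.numeric(p_interval), is.numeric(interval_years),
            interval_years >= 1)
  if (any(p_interval < 0 | p_interval >= 1)) {
    stop("p_interval must lie in [0, 1); p = 1 implies an infinite rate",
         call. = FALSE)
  }
  1 - (1 - p_interval)^(1 / interval_years)
}

#' Convert a multi-destination interval row to an annual row
#'
#' Each off-diagonal interval probability is converted independently to a
#' rate and back to an annual probability; the residual mass is assigned to
#' the diagonal (stay) entry. If competing destinations are so large that the
#' residual is negative, off-diagonal annual probabilities are rescaled
#' proportionally and a warning is issued. For competing risks the t-fold
#' composition of the annual row only approximates the interval row; the
#' approximation error grows with the off-diagonal mass.
#'
#' @param row named or unnamed probability vector over destination states,
#'   summing to 1.
#' @param from_index index of the origin (stay) state within `row`.
#' @param interval_years positive integer interval length.
#' @return annual probability row over the same states, summing to 1.
#' @export
annualize_multistate <- function(row, from_index, interval_years) {
  stopifnot(is.numeric(row), length(row) >= 2,
            from_index >= 1, from_index <= length(row), interval_years >= 1)
  if (abs(sum(row) - 1) > 1e-9) {
    stop("interval row must sum to 1", call. = FALSE)
  }
  off <- setdiff(seq_along(row), from_index)
  if (any(row[off] >= 1)) {
    stop("off-diagonal interval probability of 1 implies an infinite rate",
         call. = FALSE)
  }
  annual <- row
  annual[off] <- annualize_two_state(row[off], interval_years)
  resid <- 1 - sum(annual[off])
  if (resid < 0) {
    warning("negative stay residual after annualization; rescaling ",
            "off-diagonal probabilities proportionally", call. = FALSE)
    annual[off] <- annual[off] / sum(annual[off])
    resid <- 0
  }
  annual[from_index] <- resid
  annual
}

#' Estimate annual transition rows from a longitudinal category panel
#'
#' Maximum-likelihood estimation by transition counting: for each (age, sex)
#' the row leaving each category is the observed one-year transition counts
#' normalized by the row total. Only consecutive integer-age observation
#' pairs contribute. Cells whose row total is zero are filled from the
#' nearest observed age of the same sex and origin state (or uniformly over
#' the live states if no age has data) and flagged in the `filled` attribute.
#'
#' @param panel data.frame with columns `subject_id`, `sex`, `age`,
#'   `category` (labels from [BMI_CATEGORIES]). An optional `arm` column is
#'   ignored here; subset the panel per arm before calling.
#' @param ages integer ages for which to return rows (default: all ages with
#'   at least one observed transition).
#' @param fill `"nearest"` (default) or `"uniform"` for zero-count rows.
#' @return array `[length(ages), 2, 4, 4]` of row-stochastic matrices with an
#'   `ages` attribute and a logical `filled` array flagging imputed rows.
#' @export
estimate_from_panel <- function(panel, ages = NULL, fill = c("nearest", "uniform")) {
  fill <- match.arg(fill)
  need <- c("subject_id", "sex", "age", "category")
  if (!is.data.frame(panel) || !all(need %in% names(panel)) || !nrow(panel)) {
    stop("panel must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  si <- .sex_index(panel$sex)
  ci <- .cat_index(panel$category)
  ord <- order(panel$subject_id, panel$age)
  panel <- panel[ord, ]; si <- si[ord]; ci <- ci[ord]
  same <- panel$subject_id[-1] == panel$subject_id[-nrow(panel)]
  dage <- diff(panel$age)
  if (any(same & dage <= 0)) {
    stop("panel has a subject with non-increasing age", call. = FALSE)
  }
  pair <- which(same & dage == 1)
  if (!length(pair)) stop("panel contains no one-year transitions",
                          call. = FALSE)
  from_age <- panel$age[pair]
  if (is.null(ages)) ages <- sort(unique(from_age))
  counts <- array(0, dim = c(length(ages), 2L, 4L, 4L))
  keep <- from_age %in% ages
  idx <- cbind(match(from_age[keep], ages), si[pair][keep],
               ci[pair][keep], ci[pair + 1L][keep])
  for (k in seq_len(nrow(idx))) {
    counts[idx[k, , drop = FALSE]] <- counts[idx[k, , drop = FALSE]] + 1
  }
  est <- array(NA_real_, dim = dim(counts))
  filled <- array(FALSE, dim = c(length(ages), 2L, 4L))
  for (s in 1:2) {
    for (f in 1:3) {
      tot <- apply(counts[, s, f, , drop = FALSE], 1, sum)
      has <- which(tot > 0)
      for (a in seq_along(ages)) {
        if (tot[a] > 0) {
          est[a, s, f, ] <- counts[a, s, f, ] / tot[a]
        } else {
          filled[a, s, f] <- TRUE
          if (fill == "nearest" && length(has)) {
            nb <- has[which.min(abs(ages[has] - ages[a]))]
            est[a, s, f, ] <- counts[nb, s, f, ] / tot[nb]
          } else {
            est[a, s, f, ] <- c(rep(1 / 3, 3), 0)
          }
        }
      }
    }
    for (a in seq_along(ages)) est[a, s, 4, ] <- c(0, 0, 0, 1)
  }
  structure(est, ages = ages, filled = filled,
            counts = counts)
}

#' Apply intervention relative risks to a row leaving NORMAL
#'
#' Multiplies the probabilities of moving to OVERWEIGHT and OBESE by their
#' relative risks and absorbs the total change into the stay-NORMAL entry.
#' The death probability is untouched and the row sum is preserved exactly.
#'
#' @param row length-4 probability row in [BMI_CATEGORIES] order, from NORMAL.
#' @param rr_overweight,rr_obese positive relative risks (LP vs HP).
#' @return modified row-stochastic row.
#' @examples
#' apply_relative_risk(c(0.90, 0.08, 0.02, 0), 0.5, 0.5)
#' @export
apply_relative_risk <- function(row, rr_overweight, rr_obese) {
  stopifnot(length(row) == 4, rr_overweight >= 0, rr_obese >= 0)
  if (abs(sum(row) - 1) > 1e-9) stop("row must sum to 1", call. = FALSE)
  new_ow <- row[2] * rr_overweight
  new_ob <- row[3] * rr_obese
  if (new_ow > 1 || new_ob > 1) {
    stop("relative risk pushes a transition probability above 1",
         call. = FALSE)
  }
  stay <- row[1] + (row[2] - new_ow) + (row[3] - new_ob)
  if (stay < 0) {
    stop("relative risk leaves a negative stay probability", call. = FALSE)
  }
  c(stay, new_ow, new_ob, row[4])
}

#' Derive the LP-arm matrices from the HP-arm matrices and the intervention
#' relative risks
#'
#' For each age in the effect window (0 to `duration_years - 1`, capped at
#' the arm-table range) the NORMAL row of the HP matrix is modified with
#' [apply_relative_risk()]; all other rows are copied. With `scope =
#' "all_incidence"` the OVERWEIGHT row's transition to OBESE is additionally
#' scaled by `rr_obese` (alternative effect scope; off by default).
#'
#' @param hp array `[6, 2, 4, 4]` of HP-arm matrices (ages 0-5).
#' @param effect intervention list as in [parameter_set()].
#' @param scope `"normal_only"` (default) or `"all_incidence"`.
#' @return array of the same shape for the LP arm.
#' @export
derive_lp_matrices <- function(hp, effect, scope = c("normal_only", "all_incidence")) {
  scope <- match.arg(scope)
  lp <- hp
  n_eff <- min(dim(hp)[1], effect$duration_years)
  if (n_eff < 1) return(lp)
  for (a in seq_len(n_eff)) {
    for (s in 1:2) {
      lp[a, s, 1, ] <- apply_relative_risk(hp[a, s, 1, ],
                                           effect$rr_overweight,
                                           effect$rr_obese)
      if (scope == "all_incidence") {
        row <- hp[a, s, 2, ]
        new_ob <- row[3] * effect$rr_obese
        row[2] <- row[2] + (row[3] - new_ob)
        row[3] <- new_ob
        lp[a, s, 2, ] <- row
      }
    }
  }
  lp
}
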