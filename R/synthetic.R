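# Synthetic ground truth standing in for the trial panel, the child/adolescent
# cross-sections, the adult prevalence data and the literature-derived cost,
# utility and mortality schedules. Every generated bundle satisfies the full
# ParameterSet contract; regeneration from the same seed is bitwise identical.
#
# Shapes are chosen to be epidemiologically plausible for a central-European
# setting: childhood overweight/obesity incidence rises with age, adult
# overweight prevalence drifts upward to mid-life, mortality is
# Gompertz-Makeham with an infant-mortality bump, costs rise with age and are
# strictly ordered OBESE > OVERWEIGHT > NORMAL, utilities fall with age and
# category. The seed jitters a few global scale factors (+-5%) so that
# property tests range over distinct but valid worlds.

.truth_profiles <- c("baseline", "strong-effect", "null-effect")

.child_row_n <- function(a, sf, j) {
  inc_ow <- j * sf * (0.015 + 0.0025 * a)
  inc_ob <- j * sf * (0.004 + 0.0012 * a)
  c(1 - inc_ow - inc_ob, inc_ow, inc_ob, 0)
}

.make_common <- function(j_inc) {
  common <- array(0, dim = c(N_AGES, 2L, 4L, 4L))
  for (s in 1:2) {
    sf <- c(1.05, 0.95)[s]
    for (a in 0:(N_AGES - 1L)) {
      i <- a + 1L
      if (a < 18) {
        common[i, s, 1, ] <- .child_row_n(a, sf, j_inc)
        rem <- max(0.05, 0.25 - 0.008 * a)
        ow_ob <- 0.06 + 0.003 * a
        common[i, s, 2, ] <- c(rem, 1 - rem - ow_ob, ow_ob, 0)
        ob_ow <- max(0.02, 0.12 - 0.003 * a)
        common[i, s, 3, ] <- c(0.03, ob_ow, 1 - 0.03 - ob_ow, 0)
      } else {
        inc_ow <- j_inc * sf * (0.035 + 0.0005 * (min(a, 60) - 18))
        inc_ob <- j_inc * sf * 0.006
        common[i, s, 1, ] <- c(1 - inc_ow - inc_ob, inc_ow, inc_ob, 0)
        common[i, s, 2, ] <- c(0.06, 1 - 0.06 - 0.04, 0.04, 0)
        common[i, s, 3, ] <- c(0.005, 0.05, 1 - 0.005 - 0.05, 0)
      }
      common[i, s, 4, ] <- c(0, 0, 0, 1)
    }
  }
  common
}

#' Generate a synthetic ground truth
#'
#' @param profile `"baseline"` (moderate protective effect of LP formula),
#'   `"strong-effect"` (larger effect and higher HP incidence) or
#'   `"null-effect"` (both relative risks 1 and identical arm matrices).
#' @param seed integer seed; jitters global scale factors so different seeds
#'   give different valid parameter worlds. Same seed, same truth, bitwise.
#' @return object of class `synthetic_truth`: `params` (a `parameter_set`),
#'   `profile`, `seed`.
#' @export
make_truth <- function(profile = "baseline", seed = 42L) {
  if (!profile %in% .truth_profiles) {
    stop("unknown profile: ", profile, " (expected one of ",
         paste(.truth_profiles, collapse = ", "), ")", call. = FALSE)
  }
  set.seed(as.integer(seed))
  j_inc <- stats::runif(1, 0.95, 1.05)
  j_cost <- stats::runif(1, 0.95, 1.05)
  j_mort <- stats::runif(1, 0.95, 1.05)

  common <- .make_common(j_inc)

  eff <- switch(profile,
    "baseline" = list(rr_overweight = 0.80, ci_low_overweight = 0.66,
                      ci_high_overweight = 0.97,
                      rr_obese = 0.70, ci_low_obese = 0.53,
                      ci_high_obese = 0.92, duration_years = 6L),
    "strong-effect" = list(rr_overweight = 0.50, ci_low_overweight = 0.35,
                           ci_high_overweight = 0.70,
                           rr_obese = 0.40, ci_low_obese = 0.25,
                           ci_high_obese = 0.65, duration_years = 6L),
    "null-effect" = list(rr_overweight = 1, ci_low_overweight = 1,
                         ci_high_overweight = 1,
                         rr_obese = 1, ci_low_obese = 1, ci_high_obese = 1,
                         duration_years = 6L))
  hp_shift <- switch(profile, "baseline" = 1.25, "strong-effect" = 1.6,
                     "null-effect" = 1)
  hp <- common[1:(ARM_AGE_MAX + 1L), , , , drop = FALSE]
  for (a in 0:ARM_AGE_MAX) {
    for (s in 1:2) {
      row <- hp[a + 1L, s, 1, ]
      row[2:3] <- row[2:3] * hp_shift
      row[1] <- 1 - sum(row[2:4])
      hp[a + 1L, s, 1, ] <- row
    }
  }
  lp <- derive_lp_matrices(hp, eff)

  ages <- 0:(N_AGES - 1L)
  qx <- matrix(0, N_AGES, 2L)
  for (s in 1:2) {
    mf <- c(1, 0.75)[s]
    haz <- j_mort * mf * (2.5e-4 + 2e-5 * exp(0.095 * ages))
    haz[1] <- haz[1] + 0.0025
    qx[, s] <- pmin(0.99, 1 - exp(-haz))
  }
  mortality <- list(
    qx = qx,
    rr = c(ADULT_OW = 1.10, ADULT_OB = 1.45, CHILDHOOD_HISTORY = 1.12),
    rr_ci = matrix(c(1.00, 1.21, 1.25, 1.68, 1.00, 1.25), nrow = 3,
                   byrow = TRUE,
                   dimnames = list(MORTALITY_CONTEXTS, c("low", "high"))))

  cmean <- array(0, dim = c(N_AGES, 2L, 3L, 2L))
  aw <- pmax(0, pmin(ages, 66) - 18)
  working <- ages >= 18 & ages < 67
  for (s in 1:2) {
    sf <- c(1, 1.04)[s]
    cmean[, s, 1, 1] <- j_cost * sf * 30
    cmean[, s, 2, 1] <- j_cost * sf * (150 + 6 * ages)
    cmean[, s, 3, 1] <- j_cost * sf * (500 + 14 * ages)
    cmean[, s, 1, 2] <- j_cost * sf * ifelse(working, 10, 5)
    cmean[, s, 2, 2] <- j_cost * sf * ifelse(working, 60 + 3 * aw, 20)
    cmean[, s, 3, 2] <- j_cost * sf * ifelse(working, 250 + 7 * aw, 60)
  }
  cse <- 0.25 * cmean

  umean <- array(0, dim = c(N_AGES, 2L, 3L))
  base_u <- pmax(0.3, 0.95 - 0.0018 * pmax(0, ages - 18))
  for (s in 1:2) {
    umean[, s, 1] <- base_u
    umean[, s, 2] <- pmax(0.3, base_u - 0.02)
    umean[, s, 3] <- pmax(0.3, base_u - 0.07)
  }
  use <- array(0.02, dim = dim(umean))

  initial <- matrix(rep(c(0.96, 0.028, 0.012), each = 2), 2L, 3L)

  params <- parameter_set(
    transitions = list(common = common, lp = lp, hp = hp),
    mortality = mortality,
    costs = list(mean = cmean, se = cse),
    utilities = list(mean = umean, se = use),
    intervention = eff,
    initial = initial)
  structure(list(params = params, profile = profile, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> profile %s, seed %d\n", x$profile, x$seed))
  print(x$params)
  invisible(x)
}

#' Simulate a trial-like longitudinal category panel
#'
#' Subjects are assigned an arm and sex, drawn from the truth's initial
#' distribution at age 0, and evolved through the truth's arm-specific annual
#' matrices over the requested ages (the trial follow-up window; no deaths -
#' the child life-table risk is negligible and kept out of the panel).
#' Optional dropout removes all visits of a subject after a geometric number
#' of years.
#'
#' @param truth a `synthetic_truth`.
#' @param n_per_arm subjects per arm.
#' @param ages integer visit ages, default `0:6`.
#' @param seed RNG seed.
#' @param dropout per-year probability of permanent dropout after age 0.
#' @return data.frame with columns `subject_id`, `arm`, `sex`, `age`,
#'   `category` (the `panel.csv` schema).
#' @export
simulate_panel <- function(truth, n_per_arm, ages = 0:6, seed = 1L,
                           dropout = 0) {
  stopifnot(inherits(truth, "synthetic_truth"), n_per_arm >= 1,
            dropout >= 0, dropout <= 1)
  ps <- truth$params
  set.seed(as.integer(seed))
  recs <- vector("list", 2L * n_per_arm)
  sid <- 0L
  for (arm in ARMS) {
    for (k in seq_len(n_per_arm)) {
      sid <- sid + 1L
      sex_i <- sample.int(2L, 1L)
      cat <- sample.int(3L, 1L, prob = ps$initial[sex_i, ])
      last_age <- ages[length(ages)]
      if (dropout > 0) {
        drops <- stats::runif(length(ages) - 1L) < dropout
        if (any(drops)) last_age <- ages[which(drops)[1]]
      }
      keep <- ages[ages <= last_age]
      cats <- integer(length(keep))
      for (j in seq_along(keep)) {
        cats[j] <- cat
        if (j < length(keep)) {
          P <- .live_matrix(ps, keep[j], sex_i, arm)
          cat <- sample.int(3L, 1L, prob = P[cat, ])
        }
      }
      recs[[sid]] <- data.frame(
        subject_id = sid, arm = arm, sex = SEXES[sex_i], age = keep,
        category = LIVE_CATEGORIES[cats], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Write the full synthetic input bundle
#'
#' Emits the CSV parameter bundle consumable by [load_parameters()] plus the
#' default PSA spec table and a small provenance file. Round trip is exact:
#' `load_parameters(dir)` reproduces every numeric cell of
#' `truth$params`.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_bundle <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_parameters(truth$params, dir)
  spec_path <- file.path(dir, "psa_specs.csv")
  utils::write.csv(default_psa_specs(), spec_path, row.names = FALSE,
                   quote = FALSE)
  meta_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(profile = truth$profile, seed = truth$seed,
                            generator = "feedcea synthetic bundle"),
                       meta_path, auto_unbox = TRUE)
  invisible(c(paths, spec_path, meta_path))
}
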