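# Shared fixtures. Truths are cached per (profile, seed) because several test
# files reuse the same generated world.

.truths <- new.env(parent = emptyenv())

get_truth <- function(profile = "baseline", seed = 42L) {
  key <- paste(profile, seed, sep = "/")
  if (is.null(.truths[[key]])) .truths[[key]] <- make_truth(profile, seed)
  .truths[[key]]
}

# Baseline parameter set with all mortality zeroed out.
zero_mortality <- function(ps) {
  ps$mortality$qx[] <- 0
  ps
}

# Neutralize every history/category mortality multiplier.
all_rr_one <- function(ps) {
  ps$mortality$rr[] <- 1
  ps
}

# Replace every live transition row (all ages, sexes, arms) with the same
# 3-state row `rows` (3x4 matrix over NORMAL/OVERWEIGHT/OBESE origins).
set_uniform_transitions <- function(ps, rows) {
  stopifnot(identical(dim(rows), c(3L, 4L)))
  for (s in 1:2) {
    for (f in 1:3) {
      for (a in 1:100) ps$transitions$common[a, s, f, ] <- rows[f, ]
      for (a in 1:6) {
        ps$transitions$lp[a, s, f, ] <- rows[f, ]
        ps$transitions$hp[a, s, f, ] <- rows[f, ]
      }
    }
  }
  ps
}

identity_rows <- function() {
  rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
}

# Parameter-recovery scoring: per-cell |z| of the estimate against the
# generating probability, over well-populated cells (expected success and
# failure counts both >= 5). With 100+ cells a few |z| slightly above 3 are
# expected by chance (P(|z| > 3) ~ 0.0027 per cell), so the documented
# confidence is enforced on the exceedance count at its own 99.9% binomial
# bound, with a hard 4.5-SE cap on any single cell.
recovery_score <- function(est, counts, tmat, ages) {
  n_checked <- 0L; n_exceed <- 0L; max_z <- 0
  for (a in seq_along(ages)) for (s in 1:2) for (f in 1:3) {
    tot <- sum(counts[a, s, f, ])
    for (to in 1:3) {
      p <- tmat[a, s, f, to]
      if (tot * p >= 5 && tot * (1 - p) >= 5) {
        z <- abs(est[a, s, f, to] - p) / sqrt(p * (1 - p) / tot)
        n_checked <- n_checked + 1L
        if (z > 3) n_exceed <- n_exceed + 1L
        max_z <- max(max_z, z)
      }
    }
  }
  list(n_checked = n_checked, n_exceed = n_exceed, max_z = max_z)
}

expect_recovery <- function(truth, panel, arm) {
  est <- estimate_from_panel(panel[panel$arm == arm, ])
  sc <- recovery_score(est, attr(est, "counts"),
                       truth$params$transitions[[tolower(arm)]],
                       attr(est, "ages"))
  testthat::expect_gt(sc$n_checked, 20L)
  allowance <- stats::qbinom(0.999, sc$n_checked, 2 * stats::pnorm(-3))
  testthat::expect_lte(sc$n_exceed, max(1L, allowance))
  testthat::expect_lt(sc$max_z, 4.5)
}
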