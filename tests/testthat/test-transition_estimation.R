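test_that("two-state annualization matches the closed form and inverts composition", {
  expect_equal(annualize_two_state(0, 5), 0)
  expect_equal(annualize_two_state(0.19, 2), 0.1)
  expect_equal(annualize_two_state(0.5, 1), 0.5)
  expect_error(annualize_two_state(1, 2), "infinite rate")
  set.seed(21)
  for (i in 1:50) {
    p <- runif(1, 0, 0.99)
    t <- sample(1:10, 1)
    p1 <- annualize_two_state(p, t)
    expect_equal(1 - (1 - p1)^t, p, tolerance = 1e-12)
  }
})

test_that("multistate annualization: identity, two-state reduction, composition oracle", {
  row <- c(1, 0, 0, 0)
  expect_equal(annualize_multistate(row, 1, 7), row)

  row <- c(0.81, 0.19, 0, 0)
  expect_equal(annualize_multistate(row, 1, 2), c(0.90, 0.10, 0, 0))

  # Brute-force composition oracle: destinations absorb, so composing the
  # annual row t times gives destination mass p_j * (1 + s + ... + s^(t-1))
  # with s the annual stay probability. Exact agreement is NOT expected for
  # competing risks; the documented tolerance bounds the approximation error.
  row <- c(0.70, 0.15, 0.10, 0.05)
  t <- 3
  ann <- annualize_multistate(row, 1, t)
  expect_equal(sum(ann), 1, tolerance = 1e-12)
  M <- diag(4)
  M[1, ] <- ann
  comp <- diag(4)
  for (k in seq_len(t)) comp <- comp %*% M
  expect_lt(max(abs(comp[1, 2:4] - row[2:4])), 0.01)  # absolute tolerance
  expect_true(any(abs(comp[1, 2:4] - row[2:4]) > 1e-6)) # genuinely approximate

  # annualization never inflates off-diagonal mass, so the stay residual of a
  # valid interval row is always non-negative (property over random rows)
  set.seed(9)
  for (i in 1:30) {
    p <- runif(4); p <- p / sum(p) * 0.999
    p[1] <- p[1] + (1 - sum(p))
    out <- annualize_multistate(p, 1, sample(1:8, 1))
    expect_gte(out[1], p[1] - 1e-12)
    expect_equal(sum(out), 1, tolerance = 1e-12)
  }
})

test_that("apply_relative_risk: arithmetic, identity, limiting case, invariants", {
  row <- c(0.90, 0.08, 0.02, 0)
  expect_equal(apply_relative_risk(row, 0.5, 0.5), c(0.95, 0.04, 0.01, 0))
  expect_equal(apply_relative_risk(row, 1, 1), row)
  row_d <- c(0.88, 0.08, 0.02, 0.02)
  expect_equal(apply_relative_risk(row_d, 0, 0), c(0.98, 0, 0, 0.02))
  set.seed(5)
  for (i in 1:50) {
    p <- runif(4); p <- p / sum(p)
    rr <- runif(2, 0, 1)   # rr <= 1 keeps every row feasible
    out <- apply_relative_risk(p, rr[1], rr[2])
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_identical(out[4], p[4])
  }
  expect_error(apply_relative_risk(c(0.05, 0.9, 0.05, 0), 1.5, 1),
               "above 1")
  expect_error(apply_relative_risk(c(0.1, 0.6, 0.3, 0), 1.5, 1.2),
               "negative stay")
})

test_that("panel estimation: count ratios, identity panels, data errors", {
  toy <- data.frame(
    subject_id = c(1, 1, 2, 2),
    sex = "MALE",
    age = c(3, 4, 3, 4),
    category = c("NORMAL", "OVERWEIGHT", "NORMAL", "NORMAL"))
  est <- estimate_from_panel(toy)
  expect_equal(est[1, 1, 1, ], c(0.5, 0.5, 0, 0))

  stay <- data.frame(
    subject_id = rep(1:3, each = 3),
    sex = "FEMALE",
    age = rep(0:2, 3),
    category = rep(c("NORMAL", "OVERWEIGHT", "OBESE"), each = 3))
  est2 <- estimate_from_panel(stay)
  for (a in 1:2) {
    expect_equal(est2[a, 2, 1, ], c(1, 0, 0, 0))
    expect_equal(est2[a, 2, 2, ], c(0, 1, 0, 0))
    expect_equal(est2[a, 2, 3, ], c(0, 0, 1, 0))
  }

  expect_error(estimate_from_panel(toy[0, ]), "non-empty")
  dup <- toy
  dup$age[2] <- 3
  expect_error(estimate_from_panel(dup), "non-increasing age")
})

test_that("panel estimation recovers a known generating matrix (n = 2000)", {
  truth <- get_truth("baseline", 42)
  pan <- simulate_panel(truth, n_per_arm = 2000, seed = 314)
  for (arm in ARMS) expect_recovery(truth, pan, arm)
})

test_that("zero-count rows are filled from the nearest age and flagged", {
  # only age-3 transitions observed: all other requested ages are imputed
  toy <- data.frame(
    subject_id = c(1, 1), sex = "MALE", age = c(3, 4),
    category = c("NORMAL", "NORMAL"))
  est <- estimate_from_panel(toy, ages = 2:4)
  filled <- attr(est, "filled")
  expect_true(all(filled[c(1, 3), 1, 1]))   # ages 2 and 4 imputed
  expect_false(filled[2, 1, 1])             # age 3 observed
  expect_equal(est[1, 1, 1, ], est[2, 1, 1, ])
})

test_that("derive_lp_matrices only modifies NORMAL rows within the window", {
  truth <- get_truth("baseline", 42)
  hp <- truth$params$transitions$hp
  eff <- truth$params$intervention
  lp <- derive_lp_matrices(hp, eff)
  for (a in 1:6) for (s in 1:2) {
    expect_equal(lp[a, s, 1, 2], hp[a, s, 1, 2] * eff$rr_overweight)
    expect_equal(lp[a, s, 1, 3], hp[a, s, 1, 3] * eff$rr_obese)
    expect_identical(lp[a, s, 2, ], hp[a, s, 2, ])
    expect_identical(lp[a, s, 3, ], hp[a, s, 3, ])
    expect_equal(sum(lp[a, s, 1, ]), 1, tolerance = 1e-12)
  }
  eff0 <- eff
  eff0$duration_years <- 0L
  expect_identical(derive_lp_matrices(hp, eff0), hp)
})
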