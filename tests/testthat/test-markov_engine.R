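test_that("discount matches the closed form", {
  expect_equal(round(discount(100, 1, 0.03), 4), 97.0874)
  expect_equal(discount(100, 5, 0), 100)
  expect_equal(discount(0, 7, 0.1), 0)
  expect_error(discount(1, -1, 0.03), "non-negative")
})

test_that("M1 identity dynamics keep all mass at (NORMAL, NEVER_OWOB)", {
  ps <- zero_mortality(get_truth("baseline", 42)$params)
  ps <- set_uniform_transitions(ps, identity_rows())
  ps$initial[] <- rep(c(1, 0, 0), each = 2)
  m1 <- run_m1(ps, "LP", "MALE")
  handoff <- m1$occupancy[19, , ]
  expect_equal(handoff[1, 1], 1)
  expect_equal(sum(handoff) - handoff[1, 1], 0)
})

test_that("M1 two-cycle hand example: occupancy and history mass", {
  rows <- rbind(c(0.8, 0.2, 0, 0),
                c(0, 1, 0, 0),
                c(0, 0, 1, 0))
  ps <- zero_mortality(get_truth("baseline", 42)$params)
  ps <- set_uniform_transitions(ps, rows)
  ps$initial[] <- rep(c(1, 0, 0), each = 2)
  m1 <- run_m1(ps, "HP", "FEMALE")
  occ2 <- m1$occupancy[3, , ]   # age 2
  expect_equal(sum(occ2[1, ]), 0.64)
  expect_equal(sum(occ2[2, ]), 0.36)
  expect_equal(sum(occ2[, 2]), 0.36)   # EVER_OWOB mass
  expect_equal(occ2[2, 1], 0)          # (OW, NEVER) unreachable
})

test_that("M2 survival equals the life-table product when all RRs are 1", {
  ps <- all_rr_one(get_truth("baseline", 42)$params)
  handoff <- matrix(0, 4, 2)
  handoff[1, 1] <- 1
  cfg <- run_config()
  m2 <- run_m2(ps, handoff, "MALE", cfg)
  qx <- ps$mortality$qx[19:100, 1]
  surv <- cumprod(1 - qx)
  alive <- rowSums(m2$occupancy[, 1:3, ])
  expect_equal(unname(alive[-1]), surv, tolerance = 1e-12)
  expect_equal(sum(m2$py_alive), sum(c(1, surv[-length(surv)])),
               tolerance = 1e-12)
})

test_that("history split is inert when the history multiplier is 1", {
  ps <- get_truth("baseline", 42)$params
  ps$mortality$rr[["CHILDHOOD_HISTORY"]] <- 1
  cfg <- run_config()
  mix <- c(0.5, 0.3, 0.2)
  h1 <- matrix(0, 4, 2); h1[1:3, 1] <- mix * 0.4; h1[1:3, 2] <- mix * 0.6
  h2 <- matrix(0, 4, 2); h2[1:3, 2] <- mix
  a <- run_m2(ps, h1, "MALE", cfg)
  b <- run_m2(ps, h2, "MALE", cfg)
  expect_equal(a$disc_cost, b$disc_cost, tolerance = 1e-12)
  expect_equal(a$disc_qaly, b$disc_qaly, tolerance = 1e-12)
  expect_equal(a$py_owob, b$py_owob, tolerance = 1e-12)
})

test_that("three-age toy M2 matches a hand computation", {
  # identity category movement, single cohort in NORMAL; everything explicit
  ps <- get_truth("baseline", 42)$params
  ps <- set_uniform_transitions(zero_mortality(ps), identity_rows())
  ps <- all_rr_one(ps)
  ps$mortality$qx[19:21, 1] <- c(0.1, 0.2, 0.3)
  ps$costs$mean[] <- 0
  ps$costs$mean[19:21, 1, 1, 1] <- c(100, 110, 120)   # direct, NORMAL
  ps$utilities$mean[19:21, 1, 1] <- c(0.9, 0.8, 0.7)
  cfg <- run_config(discount_rate = 0.1, horizon_age = 21L)
  handoff <- matrix(0, 4, 2); handoff[1, 1] <- 1
  m2 <- run_m2(ps, handoff, "MALE", cfg)
  s <- c(1, 0.9, 0.9 * 0.8)                  # alive at cycle start, ages 18-20
  df <- 1.1^-(18:20)
  expect_equal(sum(m2$disc_cost), sum(s * c(100, 110, 120) * df),
               tolerance = 1e-12)
  expect_equal(sum(m2$disc_qaly), sum(s * c(0.9, 0.8, 0.7) * df),
               tolerance = 1e-12)
  expect_equal(sum(m2$py_alive), sum(s), tolerance = 1e-12)
  expect_equal(rowSums(m2$occupancy[4, , , drop = FALSE][1, , ])[["DEAD"]],
               1 - 0.9 * 0.8 * 0.7, tolerance = 1e-12)
})

test_that("utility of one, no mortality, no discounting gives 82 QALYs", {
  ps <- get_truth("baseline", 42)$params
  ps <- zero_mortality(ps)
  ps$utilities$mean[] <- 1
  ps$costs$mean[] <- 0
  cfg <- run_config(discount_rate = 0)
  res <- run_arm_sex(ps, "LP", "FEMALE", cfg)
  expect_equal(res$lifetime_qaly_pp, 82)
  expect_equal(res$lifetime_cost_pp, 0)
  expect_equal(unname(res$decade_costs), rep(0, 10))
})

test_that("conservation and monotone death hold across profiles and seeds", {
  for (profile in c("baseline", "strong-effect")) {
    for (seed in c(1, 99)) {
      ps <- get_truth(profile, seed)$params
      cfg <- run_config()
      for (arm in ARMS) {
        res <- run_arm_sex(ps, arm, "MALE", cfg, keep_traces = TRUE)
        for (tr in res$traces) {
          tot <- apply(tr$occupancy, 1, sum)
          expect_true(all(abs(tot - 1) < 1e-9))
          dead <- apply(tr$occupancy[, 4, , drop = FALSE], 1, sum)
          expect_true(all(diff(dead) >= -1e-12))
        }
        expect_equal(sum(res$decade_costs), res$lifetime_cost_pp,
                     tolerance = 1e-6)
        expect_true(res$person_years_owob <= res$life_expectancy + 1e-9)
        expect_true(res$life_expectancy <= cfg$horizon_age + 1e-9)
      }
    }
  }
})

test_that("discounted totals are non-increasing in the discount rate", {
  ps <- get_truth("baseline", 42)$params
  costs <- vapply(c(0, 0.03, 0.1), function(r)
    run_arm(ps, "HP", run_config(discount_rate = r))$lifetime_cost_pp,
    numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("summarize_arm rejects non-contiguous traces", {
  ps <- get_truth("baseline", 42)$params
  cfg <- run_config()
  m1 <- run_m1(ps, "LP", "MALE", cfg)
  h <- m1$occupancy[19, , ]
  m2 <- run_m2(ps, h, "MALE", cfg)
  m2$ages <- m2$ages + 1
  expect_error(summarize_arm(m1, m2, cfg), "age gap")
})

test_that("pooled results are the sex-mix weighted average of per-sex results", {
  ps <- get_truth("baseline", 42)$params
  cfg <- run_config()
  pooled <- run_arm(ps, "LP", cfg)
  w <- cfg$sex_mix
  manual <- w[["MALE"]] * pooled$by_sex$MALE$lifetime_cost_pp +
    w[["FEMALE"]] * pooled$by_sex$FEMALE$lifetime_cost_pp
  expect_equal(pooled$lifetime_cost_pp, manual, tolerance = 1e-12)
})

test_that("trace export has the documented long schema", {
  ps <- get_truth("baseline", 42)$params
  m1 <- run_m1(ps, "LP", "MALE")
  df <- trace_to_df(m1)
  expect_named(df, c("arm", "sex", "age", "state", "history", "occupancy",
                     "disc_cost", "disc_qaly"))
  expect_equal(nrow(df), 19 * 4 * 2)
  occ_sums <- tapply(df$occupancy, df$age, sum)
  expect_true(all(abs(occ_sums - 1) < 1e-9))
})
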