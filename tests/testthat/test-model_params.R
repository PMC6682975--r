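test_that("childhood percentile classification follows the reference cutoffs", {
  expect_equal(classify_child(c(0, 50, 90)), rep("NORMAL", 3))
  expect_equal(classify_child(c(90.0001, 95, 97)), rep("OVERWEIGHT", 3))
  expect_equal(classify_child(c(97.1, 99, 100)), rep("OBESE", 3))
  expect_error(classify_child(101), "\\[0, 100\\]")
  expect_error(classify_child(NaN), "finite")
})

test_that("adult BMI classification follows WHO cutoffs, left-closed", {
  expect_equal(classify_adult(c(15, 24.9)), rep("NORMAL", 2))
  expect_equal(classify_adult(c(25, 29.999)), rep("OVERWEIGHT", 2))
  expect_equal(classify_adult(c(30, 55)), rep("OBESE", 2))
  expect_error(classify_adult(0), "positive")
})

test_that("classifiers partition their domains", {
  set.seed(11)
  p <- runif(500, 0, 100)
  expect_true(all(classify_child(p) %in% LIVE_CATEGORIES))
  b <- runif(500, 10, 60)
  expect_true(all(classify_adult(b) %in% LIVE_CATEGORIES))
})

test_that("write/load parameter bundle round-trips every numeric cell exactly", {
  truth <- get_truth("baseline", 42)
  d <- withr::local_tempdir()
  write_parameters(truth$params, d)
  ps <- load_parameters(d)
  for (fld in c("common", "lp", "hp")) {
    expect_identical(ps$transitions[[fld]], truth$params$transitions[[fld]])
  }
  expect_identical(ps$mortality$qx, truth$params$mortality$qx)
  expect_identical(unname(ps$mortality$rr),
                   unname(truth$params$mortality$rr))
  expect_identical(ps$costs$mean, truth$params$costs$mean)
  expect_identical(ps$costs$se, truth$params$costs$se)
  expect_identical(ps$utilities$mean, truth$params$utilities$mean)
  expect_identical(ps$initial, truth$params$initial)
  expect_identical(ps$intervention$rr_overweight,
                   truth$params$intervention$rr_overweight)
})

test_that("row-sum violations are rejected with the offending cell named", {
  truth <- get_truth("baseline", 42)
  ps <- truth$params
  ps$transitions$common[8, 1, 1, 2] <-
    ps$transitions$common[8, 1, 1, 2] + 0.2   # age 7, MALE, NORMAL row
  err <- expect_error(validate_parameter_set(ps), "sums to")
  expect_match(conditionMessage(err), "age 7")
  expect_match(conditionMessage(err), "MALE")
  expect_match(conditionMessage(err), "NORMAL")
})

test_that("a corrupted transitions file fails at load with cell context", {
  truth <- get_truth("baseline", 42)
  d <- withr::local_tempdir()
  write_parameters(truth$params, d)
  tr <- read.csv(file.path(d, "transitions.csv"))
  k <- which(tr$age == 3 & tr$sex == "FEMALE" & tr$arm == "COMMON" &
               tr$from_state == "NORMAL" & tr$to_state == "OVERWEIGHT")[1]
  tr$prob[k] <- tr$prob[k] + 0.2
  write.csv(tr, file.path(d, "transitions.csv"), row.names = FALSE)
  expect_error(load_parameters(d), "age 3.*FEMALE")
})

test_that("missing cells raise a missing-parameter error naming the cell", {
  truth <- get_truth("baseline", 42)
  d <- withr::local_tempdir()
  write_parameters(truth$params, d)
  ut <- read.csv(file.path(d, "utilities.csv"))
  ut <- ut[!(ut$age == 40 & ut$sex == "MALE"), ]
  write.csv(ut, file.path(d, "utilities.csv"), row.names = FALSE)
  expect_error(load_parameters(d), "age 40 sex MALE")
})

test_that("a bundle missing a whole table names the table", {
  truth <- get_truth("baseline", 42)
  d <- withr::local_tempdir()
  write_parameters(truth$params, d)
  unlink(file.path(d, "mortality.csv"))
  expect_error(load_parameters(d), "mortality.csv")
})

test_that("DEAD rows must be absorbing and arm entries limited to the window", {
  truth <- get_truth("baseline", 42)
  ps <- truth$params
  ps$transitions$common[30, 2, 4, ] <- c(0.1, 0, 0, 0.9)
  expect_error(validate_parameter_set(ps), "DEAD row")
  d <- withr::local_tempdir()
  write_parameters(truth$params, d)
  tr <- read.csv(file.path(d, "transitions.csv"))
  extra <- tr[tr$arm == "LP" & tr$age == 5, ]
  extra$age <- 9
  write.csv(rbind(tr, extra), file.path(d, "transitions.csv"),
            row.names = FALSE)
  expect_error(load_parameters(d), "ages 0-5")
})

test_that("run_config validates and round-trips through JSON", {
  cfg <- run_config(discount_rate = 0.05, wtp_grid = c(0, 500),
                    sex_mix = c(MALE = 0.5, FEMALE = 0.5))
  p <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, p)
  cfg2 <- read_run_config(p)
  expect_equal(unclass(cfg2), unclass(cfg))
  expect_error(run_config(nonsense = 1), "unknown run_config key")
  expect_error(run_config(wtp_grid = c(5, 1)), "ascending")
  expect_error(run_config(sex_mix = c(MALE = 0.7, FEMALE = 0.5)), "sum to 1")
  expect_error(run_config(formula_fed_share = 1.2), "\\[0, 1\\]")
})
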