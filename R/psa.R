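# Probabilistic sensitivity analysis. Parameters are sampled from the
# distributions conventional in health-economic modelling: lognormal for
# relative risks (parameters backed out of the point estimate and its 95% CI),
# gamma for costs (method of moments on mean/SE), uniform where only a range
# is available, FIXED otherwise. Both arms share each draw's common
# parameters, so with the intervention effect fixed at 1 every draw has
# identical arms (common-random-numbers contract).

#' Lognormal parameters from a point estimate and 95% CI
#'
#' `mu = log(point)`; `sigma = (log(ci_high) - log(ci_low)) / (2 * z_0.975)`.
#' A degenerate CI yields `sigma = 0` (point mass).
#'
#' @param point,ci_low,ci_high positive reals with
#'   `ci_low <= point <= ci_high`.
#' @return list with `mu` and `sigma` (log scale).
#' @export
lognormal_from_ci <- function(point, ci_low, ci_high) {
  if (any(c(point, ci_low, ci_high) <= 0)) {
    stop("lognormal inputs must be positive", call. = FALSE)
  }
  if (ci_low > point + 1e-12 || point > ci_high + 1e-12) {
    stop("need ci_low <= point <= ci_high", call. = FALSE)
  }
  list(mu = log(point),
       sigma = (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975)))
}

#' Gamma parameters from a mean and standard error
#'
#' Method of moments: `shape = mean^2/se^2`, `scale = se^2/mean`. A zero SE
#' yields a point mass at the mean.
#'
#' @param mean positive mean.
#' @param se standard error, `>= 0`.
#' @return list with `shape` and `scale` (`NULL`s and `fixed = TRUE` when
#'   `se = 0`).
#' @export
gamma_from_moments <- function(mean, se) {
  if (mean <= 0) stop("gamma mean must be positive", call. = FALSE)
  if (se < 0) stop("se must be non-negative", call. = FALSE)
  if (se == 0) return(list(shape = NULL, scale = NULL, fixed = TRUE))
  list(shape = mean^2 / se^2, scale = se^2 / mean, fixed = FALSE)
}

PSA_SCALAR_TARGETS <- c("intervention.rr_overweight", "intervention.rr_obese",
                        "mortality_rr.ADULT_OW", "mortality_rr.ADULT_OB",
                        "mortality_rr.CHILDHOOD_HISTORY")
PSA_WILDCARD_TARGETS <- c("costs.*", "utilities.*")

#' Default PSA distribution specification
#'
#' Relative risks lognormal (from their stored CIs), all cost cells gamma
#' (from their stored mean/SE), utilities fixed.
#'
#' @return data.frame with columns `target`, `kind`, `p1`, `p2`.
#' @export
default_psa_specs <- function() {
  data.frame(
    target = c(PSA_SCALAR_TARGETS, "costs.*", "utilities.*"),
    kind = c(rep("LOGNORMAL", 5), "GAMMA", "FIXED"),
    p1 = NA_real_, p2 = NA_real_,
    stringsAsFactors = FALSE)
}

#' Read a PSA spec table from CSV
#'
#' @param path CSV with columns `target`, `kind`, and optional `p1`, `p2`
#'   (used by UNIFORM as absolute low/high bounds on scalar targets).
#' @return data.frame of specs.
#' @export
read_psa_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("target", "kind") %in% names(df))) {
    stop("psa spec file needs columns target, kind", call. = FALSE)
  }
  if (is.null(df$p1)) df$p1 <- NA_real_
  if (is.null(df$p2)) df$p2 <- NA_real_
  df
}

.validate_psa_specs <- function(specs) {
  ok <- c(PSA_SCALAR_TARGETS, PSA_WILDCARD_TARGETS)
  bad <- setdiff(specs$target, ok)
  if (length(bad)) {
    stop("psa spec targets a missing cell: ", bad[1], call. = FALSE)
  }
  badk <- setdiff(specs$kind, c("LOGNORMAL", "GAMMA", "UNIFORM", "FIXED"))
  if (length(badk)) stop("unknown distribution kind: ", badk[1], call. = FALSE)
  uni <- specs$kind == "UNIFORM" & specs$target %in% PSA_SCALAR_TARGETS
  if (any(uni & (is.na(specs$p1) | is.na(specs$p2) | specs$p1 > specs$p2))) {
    stop("UNIFORM on a scalar target requires p1 <= p2", call. = FALSE)
  }
  invisible(specs)
}

.sample_scalar <- function(kind, point, ci_low, ci_high, p1, p2) {
  switch(kind,
    FIXED = point,
    LOGNORMAL = {
      par <- lognormal_from_ci(point, ci_low, ci_high)
      if (par$sigma == 0) point else stats::rlnorm(1, par$mu, par$sigma)
    },
    UNIFORM = stats::runif(1, p1, p2),
    stop("unsupported kind for scalar target: ", kind, call. = FALSE))
}

#' Draw one sampled ParameterSet
#'
#' Replaces every spec-targeted cell by one sample using the current RNG
#' state, then re-derives the LP transition matrices from the (shared) HP
#' matrices and the sampled intervention relative risks whenever an
#' intervention target is present.
#'
#' @param ps base `parameter_set`.
#' @param specs spec data.frame as from [default_psa_specs()].
#' @return a sampled `parameter_set`.
#' @export
sample_parameter_set <- function(ps, specs = default_psa_specs()) {
  .validate_psa_specs(specs)
  out <- ps
  rr_touched <- FALSE
  for (k in seq_len(nrow(specs))) {
    tg <- specs$target[k]; kind <- specs$kind[k]
    if (kind == "FIXED") next
    if (tg == "intervention.rr_overweight" || tg == "intervention.rr_obese") {
      oc <- sub("intervention.rr_", "", tg, fixed = TRUE)
      out$intervention[[paste0("rr_", oc)]] <- .sample_scalar(
        kind, ps$intervention[[paste0("rr_", oc)]],
        ps$intervention[[paste0("ci_low_", oc)]],
        ps$intervention[[paste0("ci_high_", oc)]],
        specs$p1[k], specs$p2[k])
      rr_touched <- TRUE
    } else if (startsWith(tg, "mortality_rr.")) {
      ctx <- sub("mortality_rr.", "", tg, fixed = TRUE)
      out$mortality$rr[[ctx]] <- .sample_scalar(
        kind, ps$mortality$rr[[ctx]],
        ps$mortality$rr_ci[ctx, "low"], ps$mortality$rr_ci[ctx, "high"],
        specs$p1[k], specs$p2[k])
    } else if (tg == "costs.*") {
      if (kind != "GAMMA") {
        stop("costs.* supports GAMMA or FIXED only", call. = FALSE)
      }
      m <- ps$costs$mean; se <- ps$costs$se
      pos <- m > 0 & se > 0
      if (any(pos)) {
        shape <- m[pos]^2 / se[pos]^2
        out$costs$mean[pos] <- stats::rgamma(sum(pos), shape = shape,
                                             scale = se[pos]^2 / m[pos])
      }
    } else if (tg == "utilities.*") {
      if (kind != "UNIFORM") {
        stop("utilities.* supports UNIFORM or FIXED only", call. = FALSE)
      }
      # uniform matching the cell's mean and SE: half-width sqrt(3)*se
      m <- ps$utilities$mean; se <- ps$utilities$se
      pos <- se > 0
      if (any(pos)) {
        hw <- sqrt(3) * se[pos]
        out$utilities$mean[pos] <- pmax(-0.594, pmin(1, stats::runif(
          sum(pos), m[pos] - hw, m[pos] + hw)))
      }
    }
  }
  if (rr_touched) {
    out$transitions$lp <- derive_lp_matrices(out$transitions$hp,
                                             out$intervention)
  }
  out
}

# Substream seed for draw i: exact integer arithmetic below 2^53, independent
# of n_draws and of parallel scheduling.
.psa_substream_seeds <- function(master, n) {
  base <- as.numeric(master) %% 2147483647
  as.integer((base * 69069 + seq_len(n) * 104729) %% 2147483647)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each draw, all targeted parameters are sampled once (shared between
#' arms), both strategies are run for both sexes and pooled by the sex mix,
#' and lifetime totals are recorded. Summaries are empirical means and
#' 2.5/97.5 percentiles (quantile type 7). Fully reproducible given
#' `config$seed`; draw `i` uses an independent substream so results do not
#' depend on `psa_draws` for earlier draws.
#'
#' @param ps base `parameter_set`.
#' @param config a [run_config()]; `psa_draws` and `seed` are used.
#' @param specs spec data.frame (default [default_psa_specs()]).
#' @return a `psa_result`: `draws` (one row per draw with LP/HP costs, QALYs,
#'   person-years and their increments), `summaries`, `seed`, `n_draws`.
#' @export
run_psa <- function(ps, config = run_config(), specs = default_psa_specs()) {
  .validate_psa_specs(specs)
  n <- config$psa_draws
  seeds <- .psa_substream_seeds(config$seed, n)
  cols <- c("cost_lp", "qaly_lp", "py_lp", "cost_hp", "qaly_hp", "py_hp")
  draws <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    psi <- sample_parameter_set(ps, specs)
    lp <- run_arm(psi, "LP", config)
    hp <- run_arm(psi, "HP", config)
    draws[i, ] <- c(lp$lifetime_cost_pp, lp$lifetime_qaly_pp,
                    lp$person_years_owob, hp$lifetime_cost_pp,
                    hp$lifetime_qaly_pp, hp$person_years_owob)
  }
  draws <- as.data.frame(draws)
  draws$delta_cost <- draws$cost_lp - draws$cost_hp
  draws$delta_qaly <- draws$qaly_lp - draws$qaly_hp
  summ <- do.call(rbind, lapply(names(draws), function(cn) {
    x <- draws[[cn]]
    data.frame(quantity = cn, mean = mean(x),
               p2.5 = stats::quantile(x, 0.025, type = 7, names = FALSE),
               p97.5 = stats::quantile(x, 0.975, type = 7, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  structure(list(draws = draws, summaries = summ, seed = config$seed,
                 n_draws = n),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d\n", x$n_draws, x$seed))
  print(x$summaries, row.names = FALSE, digits = 6)
  invisible(x)
}
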