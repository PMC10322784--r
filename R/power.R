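#' Define a power-simulation scenario
#'
#' Bundles the parameters of the duplex-sequencing study-design simulator:
#' per-animal mutation counts are drawn as
#' `Binomial(depth_bp, plogis(qlogis(background_mf * fold) + eps))` with a
#' per-animal effect `eps ~ Normal(0, animal_sd)` on the logit scale
#' capturing between-animal overdispersion. Defaults reproduce the
#' reference study's observed conditions: control MF 1.31e-7 mutations per
#' bp, 7.98e8 duplex bp per animal, and a logit-scale animal SD of 0.062
#' estimated from the per-target mixed model.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param fold Fold increase in MF of the treated group (>= 1).
#' @param background_mf Control mutation frequency per bp.
#' @param depth_bp Duplex base pairs sequenced per animal.
#' @param animal_sd SD of the per-animal logit-scale effect (default
#'   0.062; 0.1 emulates a noisier study).
#' @param alpha Significance level of the two-sided test (default 0.05).
#' @param n_sims Monte-Carlo replicates for power estimation (>= 100).
#' @param seed Optional integer seed.
#' @return A list of class `power_scenario`.
#' @export
power_scenario <- function(n_per_group, fold = 1.5,
                           background_mf = 1.31e-7, depth_bp = 7.98e8,
                           animal_sd = 0.062, alpha = 0.05,
                           n_sims = 2000, seed = NULL) {
  stopifnot(n_per_group >= 2, fold >= 1, background_mf > 0,
            background_mf < 1, depth_bp >= 0, animal_sd >= 0,
            alpha > 0, alpha < 1, n_sims >= 100)
  structure(list(n_per_group = as.integer(n_per_group), fold = fold,
                 background_mf = background_mf, depth_bp = depth_bp,
                 animal_sd = animal_sd, alpha = alpha,
                 n_sims = as.integer(n_sims), seed = seed),
            class = "power_scenario")
}

#' Draw per-animal mutation counts for one group
#'
#' @param scenario A `power_scenario`.
#' @param group_fold Fold applied to the background MF for this group.
#' @param n Number of animals (defaults to `scenario$n_per_group`).
#' @return Integer vector of counts. Uses the current RNG state; seed
#'   management belongs to the caller.
#' @export
simulate_mf_counts <- function(scenario, group_fold = 1, n = scenario$n_per_group) {
  eps <- stats::rnorm(n, 0, scenario$animal_sd)
  p <- stats::plogis(stats::qlogis(scenario$background_mf * group_fold) + eps)
  stats::rbinom(n, round(scenario$depth_bp), p)
}

# Two-group quasibinomial logit test in closed form. Identical to
# glm(cbind(y, N - y) ~ group, family = quasibinomial()) with the t-test
# of summary.glm (Pearson dispersion, df = n0 + n1 - 2); verified against
# glm in the test suite. Returns the logit-scale contrast, its SE and the
# two-sided p.
quasibinomial_two_group_test <- function(y0, y1, denom) {
  n0 <- length(y0); n1 <- length(y1)
  t0 <- sum(y0); t1 <- sum(y1)
  if (t0 == 0 || t1 == 0 || t0 == n0 * denom || t1 == n1 * denom) {
    return(NULL)  # degenerate group; caller falls back to fit_dose_glm
  }
  p0 <- t0 / (n0 * denom); p1 <- t1 / (n1 * denom)
  pearson <- sum((y0 - denom * p0)^2) / (denom * p0 * (1 - p0)) +
    sum((y1 - denom * p1)^2) / (denom * p1 * (1 - p1))
  dfr <- n0 + n1 - 2
  phi <- pearson / dfr
  b <- stats::qlogis(p1) - stats::qlogis(p0)
  se <- sqrt(phi * (1 / (n0 * denom * p0 * (1 - p0)) +
                    1 / (n1 * denom * p1 * (1 - p1))))
  tval <- b / se
  list(logit_diff = b, se = se, t = tval, df = dfr,
       p = 2 * stats::pt(-abs(tval), df = dfr))
}

#' Monte-Carlo power of the dose-response contrast
#'
#' Simulates `n_sims` two-group experiments (control at fold 1, treated at
#' `scenario$fold`), tests each with the quasibinomial GLM contrast
#' (two-sided, on the model's t distribution) and counts a replicate as a
#' success when `p < alpha` and the estimated change is an increase.
#'
#' @param scenario A `power_scenario`.
#' @return A list of class `power_result`: `power`, `mc_se`
#'   (`sqrt(p(1-p)/n_sims)`), `n_significant`, `n_sims` and the scenario.
#' @export
estimate_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_per_group
  denom <- round(scenario$depth_bp)
  hits <- 0L
  for (i in seq_len(scenario$n_sims)) {
    y0 <- simulate_mf_counts(scenario, 1, n)
    y1 <- simulate_mf_counts(scenario, scenario$fold, n)
    tst <- quasibinomial_two_group_test(y0, y1, denom)
    if (is.null(tst)) {
      # degenerate all-zero group: fall back to the general fitter
      est <- suppressWarnings(fit_dose_glm(c(y0, y1), rep(denom, 2 * n),
                                           rep(c(0, 1), each = n)))
      if (isTRUE(est$p_raw[2] < scenario$alpha) && est$fold[2] > 1) {
        hits <- hits + 1L
      }
    } else if (isTRUE(tst$p < scenario$alpha) && tst$logit_diff > 0) {
      hits <- hits + 1L
    }
  }
  power <- hits / scenario$n_sims
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / scenario$n_sims),
                 n_significant = hits, n_sims = scenario$n_sims,
                 scenario = scenario),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power %.3f (MC SE %.3f) for fold %.3g, n = %d/group\n",
              x$power, x$mc_se, x$scenario$fold, x$scenario$n_per_group))
  invisible(x)
}

#' Minimum detectable effect size by bisection
#'
#' Finds the fold increase detectable with `target_power` by bisecting the
#' Monte-Carlo power curve over `bracket`. Every power evaluation reuses
#' the scenario seed (common random numbers), which makes the empirical
#' power curve monotone in fold and the bisection well behaved; the
#' bracket is halved until narrower than `tol` and the midpoint returned.
#'
#' @param scenario A `power_scenario`; its `fold` field is ignored.
#' @param target_power Power to achieve (default 0.8).
#' @param bracket Fold search interval (default `c(1.01, 5)`).
#' @param tol Terminal bracket width in fold units (default 0.01).
#' @return A list of class `mdes_result`: `mdes`, `power_at_mdes`,
#'   `n_evaluations`, `scenario`.
#' @export
mdes <- function(scenario, target_power = 0.8, bracket = c(1.01, 5),
                 tol = 0.01) {
  stopifnot(inherits(scenario, "power_scenario"), length(bracket) == 2,
            bracket[1] < bracket[2], tol > 0)
  if (is.null(scenario$seed)) scenario$seed <- 1L
  power_at <- function(fold) {
    s <- scenario
    s$fold <- fold
    estimate_power(s)$power   # estimate_power re-seeds: common random numbers
  }
  n_eval <- 0L
  p_hi <- power_at(bracket[2]); n_eval <- n_eval + 1L
  if (p_hi < target_power) {
    stop(sprintf(
      "power at the upper bracket (fold %.2f) is %.3f < target %.2f",
      bracket[2], p_hi, target_power))
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    p_mid <- power_at(mid); n_eval <- n_eval + 1L
    if (p_mid >= target_power) hi <- mid else lo <- mid
  }
  out_fold <- (lo + hi) / 2
  structure(list(mdes = out_fold, power_at_mdes = power_at(out_fold),
                 n_evaluations = n_eval + 1L, target_power = target_power,
                 scenario = scenario),
            class = "mdes_result")
}

#' @export
print.mdes_result <- function(x, ...) {
  cat(sprintf("MDES %.3f-fold at %.0f%% power (n = %d/group)\n",
              x$mdes, 100 * x$target_power, x$scenario$n_per_group))
  invisible(x)
}

#' Power over a grid of sample sizes and sequencing depths
#'
#' Evaluates [estimate_power()] for every combination of `n_values` and
#' `depth_values` at a fixed fold, marking which cells clear 80% power.
#'
#' @param n_values Integer vector of animals per group.
#' @param depth_values Numeric vector of duplex bp per animal.
#' @param animal_sd Logit-scale per-animal SD (default 0.062).
#' @param fold Fold increase to detect (default 1.5).
#' @param background_mf,alpha,n_sims,seed Passed to [power_scenario()].
#' @return A `data.frame` with columns `n_per_group`, `depth_bp`, `power`,
#'   `mc_se`, `meets_80`.
#' @export
depth_sweep <- function(n_values, depth_values, animal_sd = 0.062,
                        fold = 1.5, background_mf = 1.31e-7, alpha = 0.05,
                        n_sims = 2000, seed = NULL) {
  stopifnot(length(n_values) > 0, length(depth_values) > 0)
  grid <- expand.grid(n_per_group = n_values, depth_bp = depth_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- power_scenario(grid$n_per_group[i], fold = fold,
                         background_mf = background_mf,
                         depth_bp = grid$depth_bp[i],
                         animal_sd = animal_sd, alpha = alpha,
                         n_sims = n_sims, seed = seed)
    pr <- estimate_power(sc)
    data.frame(n_per_group = grid$n_per_group[i],
               depth_bp = grid$depth_bp[i],
               power = pr$power, mc_se = pr$mc_se)
  })
  out <- do.call(rbind, res)
  out$meets_80 <- out$power > 0.8
  out
}
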