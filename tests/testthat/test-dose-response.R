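test_that("Holm-Sidak step-down matches the closed form and its invariants", {
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(c(0.01, 0.02, 0.03)),
               c(1 - 0.99^3, 1 - 0.98^2, 1 - 0.98^2),
               tolerance = 1e-12)
  # spot values as decimals
  expect_equal(round(holm_sidak(c(0.01, 0.02, 0.03)), 4),
               c(0.0297, 0.0396, 0.0396))
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(sample(1:8, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # invariant to input order
    perm <- sample(seq_along(p))
    expect_equal(holm_sidak(p[perm]), adj[perm])
    # monotone in rank
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(holm_sidak(numeric(0)), numeric(0))
})

test_that("GLM group estimates equal pooled ratios under equal denominators", {
  counts <- c(100, 104, 108, 150, 156, 162)
  denom <- rep(7.98e8, 6)
  doses <- rep(c(0, 25), each = 3)
  est <- fit_dose_glm(counts, denom, doses)
  expect_equal(est$estimate[1], sum(counts[1:3]) / sum(denom[1:3]),
               tolerance = 1e-9)
  expect_equal(est$estimate[2], sum(counts[4:6]) / sum(denom[4:6]),
               tolerance = 1e-9)
  expect_equal(est$fold[2], sum(counts[4:6]) / sum(counts[1:3]),
               tolerance = 1e-9)
  expect_equal(est$fold[1], 1)
  # identical group totals with within-group spread: fold 1, p = 1
  est2 <- fit_dose_glm(c(100, 108, 116, 100, 108, 116), denom, doses)
  expect_equal(est2$fold[2], 1, tolerance = 1e-9)
  expect_gt(est2$p_raw[2], 0.999)
})

test_that("the printed control-vs-high contrast is reproduced from group counts", {
  # six animals at the group-mean counts; equal depths
  counts <- c(rep(104, 6), rep(256, 6))
  est <- fit_dose_glm(counts, rep(7.98e8, 12), rep(c(0, 25), each = 6))
  expect_equal(round(est$fold[2], 2), 2.46)
  expect_equal(est$fold[2], 256 / 104, tolerance = 1e-9)
})

test_that("dose GLM validates inputs and handles zero-count groups", {
  expect_error(fit_dose_glm(c(2, 1), c(1, 10), c(0, 5)), "exceed")
  expect_error(fit_dose_glm(c(1, 2), c(10, 10), c(0, 0)), ">= 2 dose")
  expect_error(fit_dose_glm(c(1, 2), c(10, 10), c(5, 10)), "control")
  expect_warning(
    est <- fit_dose_glm(c(0, 0, 0, 5, 6, 7), rep(1e6, 6),
                        rep(c(0, 25), each = 3)),
    "continuity")
  expect_true(is.finite(est$estimate[1]) && est$estimate[1] > 0)
  expect_true(attr(est, "continuity_adjusted"))
})

test_that("dispersion is estimated from Pearson residuals", {
  set.seed(7)
  sc <- power_scenario(6, fold = 1, animal_sd = 0.3, n_sims = 100)
  y <- simulate_mf_counts(sc, 1, 12)
  est <- fit_dose_glm(y, rep(7.98e8, 12), rep(c(0, 25), each = 6))
  # strong per-animal noise must inflate the quasibinomial dispersion
  expect_gt(attr(est, "dispersion"), 1)
})

test_that("GLMM fixed effects agree with the GLM when animal variance is zero", {
  sh <- shared_study()
  # single-target data with the animal effect switched off: refit both ways
  panel <- sh$panel
  cfg <- study_config(animal_sd = 0, germline_per_sample = 0, seed = 31)
  st <- simulate_study(cfg, panel)
  tal <- tally_cohort(st$calls, st$depth, panel, st$design)
  tid <- panel$target_id[5]
  d <- tal[tal$target_id == tid, ]
  dose <- st$design$dose[match(d$sample_id, st$design$sample_id)]
  glm_est <- fit_dose_glm(d$unique_mutations, d$duplex_bp, dose)
  glmm <- fit_target_glmm(tal, st$design, tid)
  expect_true(glmm$converged)
  # random-intercept variance collapses toward zero and estimates agree
  # (the Laplace fit keeps a small positive variance at finite counts,
  # shifting logit-scale estimates by at most a few hundredths)
  expect_lt(glmm$ranef_variance, 0.05)
  expect_equal(stats::qlogis(glmm$estimates$estimate),
               stats::qlogis(glm_est$estimate), tolerance = 5e-3)
})

test_that("per-target GLMM recovers an elevated target and the animal variance", {
  sh <- shared_study()
  glmm <- fit_target_glmm(sh$tallies, sh$study$design, sh$panel$target_id[1])
  expect_s3_class(glmm, "target_glmm")
  expect_true(is.finite(glmm$ranef_variance))
  expect_true(glmm$ranef_variance >= 0)
  # pooling by genic status returns estimates for both strata
  pooled <- fit_target_glmm(sh$tallies, sh$study$design, panel = sh$panel,
                            pool_by = "genic")
  expect_true(all(c(FALSE, TRUE) %in% pooled$estimates$genic))
  expect_equal(nrow(pooled$estimates), 8)
  # high dose significantly above control in both strata at these settings
  hi <- pooled$estimates[pooled$estimates$dose == 25, ]
  expect_true(all(hi$p_adj < 0.05))
})

test_that("assay correlation matches cor.test and validates input", {
  x <- c(1, 2, 3, 5, 8, 9)
  expect_equal(correlate_assays(x, 2 * x)$r, 1)
  y <- c(1, -1, 1, -1, 1, -1)  # orthogonal to a constant-shifted x? use residuals
  r <- correlate_assays(x, y)
  expect_equal(r$r, stats::cor(x, y))
  expect_error(correlate_assays(x, rep(1, 6)), "zero variance")
  expect_error(correlate_assays(x[1:2], x[1:2]), ">= 3")
  expect_error(correlate_assays(x, x[1:3]), "length")
})

test_that("correlated assays are detected on a shared-animal-effect cohort", {
  set.seed(91)
  n <- 24
  eps <- stats::rnorm(n, 0, 0.4)                 # shared animal effect
  dose_fold <- rep(c(1, 1.26, 1.55, 2.46), each = 6)
  ds <- stats::rbinom(n, 7.98e8, 1.31e-7 * dose_fold * exp(eps)) / 7.98e8
  lz <- stats::rbinom(n, 191000, 7.33e-5 * dose_fold^1.8 * exp(eps)) / 191000
  r <- correlate_assays(ds, lz)
  expect_gt(r$r, 0.5)
  expect_lt(r$p, 0.01)
})

test_that("spectrum heterogeneity test is calibrated under the null", {
  # equal depths, identical proportions: rejection rate stays near alpha
  set.seed(11)
  probs <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  depths <- rep(4.8e9, 2)
  n_rej <- 0L
  n_sim <- 300L
  for (i in seq_len(n_sim)) {
    counts <- rbind(stats::rmultinom(1, 600, probs)[, 1],
                    stats::rmultinom(1, 600, probs)[, 1])
    rownames(counts) <- c("0", "25")
    res <- spectrum_difference_test(counts, depths, method = "asymptotic")
    if (res$p_overall < 0.05) n_rej <- n_rej + 1L
  }
  expect_lt(n_rej / n_sim, 0.08)
})

test_that("a dose-shifted spectrum is declared heterogeneous", {
  sh <- shared_study()
  design <- sh$study$design
  dl <- design$dose[match(sh$calls$sample_id, design$sample_id)]
  counts <- t(vapply(c(0, 25), function(d) {
    spectrum_class9(sh$calls[dl == d, ])$counts
  }, numeric(9)))
  rownames(counts) <- c("0", "25")
  depths <- vapply(c(0, 25), function(d) {
    sum(sh$per_sample$duplex_bp[sh$per_sample$sample_id %in%
                                  design$sample_id[design$dose == d]])
  }, numeric(1))
  res <- spectrum_difference_test(counts, depths, seed = 1)
  expect_lt(res$p_overall, 0.05)
  expect_true(!is.null(res$per_subtype))
  # T>C transitions rise with dose in the generator's exposure spectrum
  tc <- res$per_subtype[res$per_subtype$subtype == "T>C", ]
  expect_true(all(tc$fold > 1))
  expect_error(spectrum_difference_test(counts[1, , drop = FALSE], depths[1]),
               ">= 2 groups")
})
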