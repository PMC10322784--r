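test_that("study configuration validates its probability inputs", {
  expect_error(study_config(doses = c(5, 10)), "control")
  expect_error(study_config(spectrum_by_dose = list(
    "0" = c("C>A" = 0.5), "6.25" = c("C>A" = 1), "12.5" = c("C>A" = 1),
    "25" = c("C>A" = 1))), "sum to 1")
  expect_error(study_config(fold_by_dose = c("0" = 1)), "lacks entries")
  cfg <- study_config()
  expect_s3_class(cfg, "study_config")
  expect_equal(unname(cfg$fold_by_dose[["25"]]), 2.46)
})

test_that("identical seed and config reproduce the cohort byte for byte", {
  panel <- simulate_panel(seed = 5)
  cfg <- study_config(n_per_group = 2, seed = 77)
  s1 <- simulate_study(cfg, panel)
  s2 <- simulate_study(cfg, panel)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$depth, s2$depth)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(s1, d1, panel)
  write_study(s2, d2, panel)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("zero clonal fraction makes MF_Min and MF_Max coincide", {
  panel <- simulate_panel(seed = 6)
  cfg <- study_config(n_per_group = 2,
                      clonal_fraction_by_dose = c("0" = 0, "6.25" = 0,
                                                  "12.5" = 0, "25" = 0),
                      germline_per_sample = 0, seed = 78)
  st <- simulate_study(cfg, panel)
  expect_true(all(st$calls$multiplicity == 1))
  tal <- tally_cohort(st$calls, st$depth, panel, st$design)
  expect_equal(tal$mf_min, tal$mf_max)
})

test_that("control counts match the binomial mean and folds are recovered", {
  sh <- shared_study()
  ps <- sh$per_sample
  dose <- sh$study$design$dose[match(ps$sample_id, sh$study$design$sample_id)]
  mu <- 1.31e-7 * 7.98e8
  ctrl <- ps$unique_mutations[dose == 0]
  # mean of 6 animals, animal SD 0.062 adds ~mu*sd extra spread
  se <- sqrt((mu + mu^2 * (exp(0.062^2) - 1)) / length(ctrl))
  expect_lt(abs(mean(ctrl) - mu), 4 * se)
  gt <- group_tallies(ps, sh$study$design)
  expect_equal(gt$fold_min[gt$dose == 25], 2.46, tolerance = 0.2)
  # clonality grows with dose in the defaults, so does the MF_Max fold
  expect_gt(gt$fold_max[gt$dose == 25], gt$fold_min[gt$dose == 25])
})

test_that("generated spectra converge to the configured distribution", {
  panel <- simulate_panel(seed = 8)
  target_sp <- c("C>A" = 0.30, "C>G" = 0.05, "C>T" = 0.25,
                 "T>A" = 0.10, "T>C" = 0.25, "T>G" = 0.05)
  cfg <- study_config(doses = 0, n_per_group = 6,
                      fold_by_dose = c("0" = 1),
                      clonal_fraction_by_dose = c("0" = 0),
                      spectrum_by_dose = list("0" = target_sp),
                      class_probs = c(snv = 1, mnv = 0, ins = 0, del = 0),
                      depth_per_animal = 4e9,     # ~520 mutations/animal
                      germline_per_sample = 0, animal_sd = 0, seed = 79)
  st <- simulate_study(cfg, panel)
  expect_gt(nrow(st$calls), 1500)
  sp <- spectrum_sbs6(st$calls)
  tv <- sum(abs(sp$proportions - target_sp)) / 2
  expect_lt(tv, 0.05)
})

test_that("between-animal dispersion exceeds binomial when variance is on", {
  sh <- shared_study()
  ps <- sh$per_sample
  dose <- sh$study$design$dose[match(ps$sample_id, sh$study$design$sample_id)]
  est <- fit_dose_glm(ps$unique_mutations, ps$duplex_bp, dose)
  expect_gt(attr(est, "dispersion"), 0.5)  # single-cohort check; median
  # property over replicates: median dispersion above 1
  disps <- vapply(1:7, function(i) {
    cfg <- study_config(doses = c(0, 25), n_per_group = 6,
                        fold_by_dose = c("0" = 1, "25" = 2.46),
                        clonal_fraction_by_dose = c("0" = 0, "25" = 0),
                        germline_per_sample = 0, seed = 100 + i)
    st <- simulate_study(cfg, simulate_panel(seed = 9))
    ps2 <- panel_tally(tally_cohort(st$calls, st$depth,
                                    simulate_panel(seed = 9), st$design))
    d2 <- st$design$dose[match(ps2$sample_id, st$design$sample_id)]
    attr(fit_dose_glm(ps2$unique_mutations, ps2$duplex_bp, d2), "dispersion")
  }, numeric(1))
  expect_gt(stats::median(disps), 1)
})

test_that("planted germline calls carry high VAF and are filtered out", {
  sh <- shared_study()
  st <- sh$study
  germ <- st$calls[st$calls$germline, ]
  expect_equal(nrow(germ), nrow(st$design) * st$config$germline_per_sample)
  expect_true(all(germ$vaf > 0.01))
  kept <- sh$calls
  expect_equal(nrow(kept), sum(!st$calls$germline))
})

test_that("a spectrum incompatible with the panel sequence errors", {
  seqs <- c(chrA = paste(rep("A", 50), collapse = ""))  # no C or G
  panel <- toy_panel(seqs = seqs)
  cfg <- study_config(doses = 0, n_per_group = 1, fold_by_dose = c("0" = 1),
                      clonal_fraction_by_dose = c("0" = 0),
                      spectrum_by_dose = list("0" = c("C>A" = 1)),
                      seed = 80)
  expect_error(simulate_study(cfg, panel), "compatible")
})

test_that("lacZ simulation matches binomial moments and the printed means", {
  design <- data.frame(sample_id = sprintf("a%03d", 1:500),
                       dose = rep(c(0, 25), 250))
  lz <- simulate_lacz(design, mf_by_dose = c("0" = 7.33e-5, "25" = 46.7e-5),
                      pfu_per_animal = 191000, animal_sd = 0, seed = 81)
  m0 <- lz$mutants[design$dose == 0]
  expect_lt(abs(mean(m0) - 191000 * 7.33e-5), 3 * sqrt(14 / 250))
  expect_equal(round(191000 * 7.33e-5), 14)   # the expected control count
  # zero mutant frequency yields no mutants
  lz0 <- simulate_lacz(design, mf_by_dose = c("0" = 0, "25" = 0),
                       pfu_per_animal = 1000, seed = 82)
  expect_true(all(lz0$mutants == 0))
})
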