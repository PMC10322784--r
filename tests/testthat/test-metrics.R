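test_that("germline filter removes VAF > threshold, strictly", {
  calls <- do.call(rbind, lapply(
    c(0.001, 0.005, 0.009, 0.02, 0.4),
    function(v) toy_call(pos = 103, vaf = v)))
  kept <- suppressMessages(filter_germline(calls))
  expect_equal(nrow(kept), 3)
  expect_equal(attr(kept, "n_removed"), 2L)
  # a call at exactly the threshold is retained
  boundary <- toy_call(vaf = 0.01)
  expect_equal(nrow(filter_germline(boundary)), 1)
  expect_equal(nrow(suppressMessages(filter_germline(toy_call(vaf = 0.0100001)))), 0)
})

test_that("tally separates unique events from clonal multiplicities", {
  panel <- toy_panel()
  calls <- rbind(
    toy_call(pos = 103, ref = "G", alt = "A", multiplicity = 3),
    toy_call(pos = 105, ref = "A", alt = "T", multiplicity = 1),
    toy_call(pos = 108, ref = "T", alt = "C", multiplicity = 1))
  tal <- tally_sample(calls, toy_depth("s1", panel), panel, "s1")
  expect_equal(sum(tal$unique_mutations), 3)
  expect_equal(sum(tal$total_mutations), 5)
  expect_equal(sum(tal$total_mutations) / sum(tal$unique_mutations), 5 / 3)
  # per-class breakdown
  expect_equal(sum(tal$n_snv), 3)
  # no calls: both frequencies zero
  tal0 <- tally_sample(empty <- calls[0, ], toy_depth("s1", panel), panel, "s1")
  expect_true(all(tal0$mf_min == 0) && all(tal0$mf_max == 0))
})

test_that("identical mutations within a sample are collapsed, across samples not", {
  panel <- toy_panel()
  calls <- rbind(
    toy_call(sample_id = "s1", pos = 103, multiplicity = 2),
    toy_call(sample_id = "s1", pos = 103, multiplicity = 3),  # same event
    toy_call(sample_id = "s2", pos = 103, multiplicity = 1))
  t1 <- tally_sample(calls, toy_depth(c("s1", "s2"), panel), panel, "s1")
  t2 <- tally_sample(calls, toy_depth(c("s1", "s2"), panel), panel, "s2")
  expect_equal(sum(t1$unique_mutations), 1)
  expect_equal(sum(t1$total_mutations), 5)
  expect_equal(sum(t2$unique_mutations), 1)
  expect_equal(sum(t2$total_mutations), 1)
})

test_that("a mean control animal reproduces the printed background MF", {
  # 104 unique mutations over 7.98e8 duplex bp
  panel <- toy_panel(seqs = c(chrA = paste(rep("ACGT", 60), collapse = "")))
  calls <- do.call(rbind, lapply(seq_len(104), function(i) {
    toy_call(pos = 100 + i, ref = "C", alt = "T")
  }))
  depth <- toy_depth("s1", panel, duplex_bp = 7.98e8)
  tal <- tally_sample(calls, depth, panel, "s1")
  expect_equal(sum(tal$unique_mutations) / sum(tal$duplex_bp),
               1.303e-7, tolerance = 1e-3)
})

test_that("tallies are invariant to call order and additive over targets", {
  sh <- shared_study()
  tal <- sh$tallies
  shuffled_calls <- sh$calls[sample.int(nrow(sh$calls)), ]
  tal2 <- tally_cohort(shuffled_calls, sh$study$depth, sh$panel,
                       sh$study$design)
  expect_equal(tal2[order(tal2$sample_id, tal2$target_id), ],
               tal[order(tal$sample_id, tal$target_id), ],
               ignore_attr = TRUE)
  ps <- sh$per_sample
  expect_true(all(ps$mf_max >= ps$mf_min))
  expect_true(all(tal$total_mutations >= tal$unique_mutations))
  # panel-wide counts equal the sum of per-target counts
  for (sid in ps$sample_id[1:3]) {
    expect_equal(ps$unique_mutations[ps$sample_id == sid],
                 sum(tal$unique_mutations[tal$sample_id == sid]))
  }
  # panel-wide MF is the depth-weighted mean of per-target MFs
  sid <- ps$sample_id[1]
  d <- tal[tal$sample_id == sid, ]
  expect_equal(ps$mf_min[ps$sample_id == sid],
               sum(d$mf_min * d$duplex_bp) / sum(d$duplex_bp))
})

test_that("calls in a zero-depth target raise an error", {
  panel <- toy_panel()
  depth <- toy_depth("s1", panel, duplex_bp = 0)
  expect_error(tally_sample(toy_call(), depth, panel, "s1"), "zero")
})

test_that("group pooling reproduces the printed fold changes and MF_Max estimate", {
  panel <- toy_panel(seqs = c(chrA = paste(rep("ACGT", 200), collapse = "")))
  design <- data.frame(sample_id = sprintf("s%02d", 1:12),
                       dose = rep(c(0, 25), each = 6))
  # per-animal unique counts 104 (control) and 256 (high dose); group-level
  # clonal excesses of 50 and 770 events spread over the six animals
  make_calls <- function(sids, n_unique, extra_total) {
    do.call(rbind, lapply(seq_along(sids), function(i) {
      extra <- rep(0L, n_unique)
      if (i == 1) {  # the group excess can sit on any animal; use the first
        extra <- rep(extra_total %/% n_unique, n_unique)
        extra[seq_len(extra_total %% n_unique)] <-
          extra[seq_len(extra_total %% n_unique)] + 1L
      }
      data.frame(sample_id = sids[i], target_id = "chrA", chrom = "chrA",
                 pos = 100 + seq_len(n_unique), ref = "C", alt = "T",
                 variant_class = "SNV", multiplicity = 1L + extra,
                 vaf = 0.001, stringsAsFactors = FALSE)
    }))
  }
  calls <- rbind(make_calls(design$sample_id[1:6], 104, 50),
                 make_calls(design$sample_id[7:12], 256, 770))
  depth <- toy_depth(design$sample_id, panel, duplex_bp = 7.98e8)
  tallies <- tally_cohort(calls, depth, panel, design)
  gt <- group_tallies(tallies, design)
  expect_equal(gt$fold_min[gt$dose == 25], 256 / 104, tolerance = 1e-12)
  expect_equal(round(gt$fold_min[gt$dose == 25], 2), 2.46)
  # MF_Max control: (104 + 50/6) per animal over 7.98e8 bp
  expect_equal(gt$mf_max[gt$dose == 0], (104 + 50 / 6) / 7.98e8,
               tolerance = 1e-12)
  expect_equal(round(gt$mf_max[gt$dose == 0] * 1e7, 2), 1.41)
  expect_equal(round(gt$fold_max[gt$dose == 25], 2), 3.42)
  # single group is flagged
  expect_warning(group_tallies(tallies[tallies$sample_id %in%
                                         design$sample_id[1:6], ],
                               design[1:6, ]), "undefined")
})
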