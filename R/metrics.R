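#' Remove germline-like variants by allele fraction
#'
#' Duplex consensus pipelines flag highly clonal variants as germline
#' polymorphisms: calls with a variant allele fraction strictly greater
#' than `vaf_max` are excluded from mutagenesis metrics. A call at exactly
#' `vaf_max` is retained.
#'
#' @param calls Call table.
#' @param vaf_max Exclusion threshold (default 0.01).
#' @return The retained calls; the number removed is reported via
#'   `message()` and attached as `attr(, "n_removed")`.
#' @export
filter_germline <- function(calls, vaf_max = 0.01) {
  validate_calls(calls)
  keep <- calls$vaf <= vaf_max
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message("filter_germline: removed ", n_removed,
            " call(s) with VAF > ", vaf_max)
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Per-target mutation tallies for one sample
#'
#' Counts mutations per target under both clonality conventions:
#' `unique_mutations` counts each distinct `(chrom, pos, ref, alt)` once
#' (clonal copies assumed to descend from a single mutational event; the
#' MF_Min numerator) and `total_mutations` sums clonal multiplicities
#' (every duplex molecule counted as an independent event; the MF_Max
#' numerator). Frequencies are counts divided by the duplex base pairs
#' sequenced over the target.
#'
#' @param calls Germline-filtered call table.
#' @param depth_table Depth table (see [read_depth_table()]).
#' @param panel Panel `GRanges`.
#' @param sample_id Sample to tally.
#' @return A `data.frame` with one row per panel target: `sample_id`,
#'   `target_id`, `unique_mutations`, `total_mutations`, `duplex_bp`,
#'   `mf_min`, `mf_max` and per-class counts `n_snv`, `n_mnv`, `n_ins`,
#'   `n_del` (unique-event counts).
#' @export
tally_sample <- function(calls, depth_table, panel, sample_id) {
  if (length(panel) == 0) stop("empty panel")
  x <- calls[calls$sample_id == sample_id, , drop = FALSE]
  depth <- depth_table[depth_table$sample_id == sample_id, , drop = FALSE]
  missing_depth <- setdiff(panel$target_id, depth$target_id)
  if (length(missing_depth) > 0) {
    stop("no depth recorded for sample ", sample_id, " at target(s): ",
         paste(missing_depth, collapse = ", "))
  }
  # collapse identical mutations within the sample
  key <- paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(multiplicity ~ key, data = cbind(x, key = key), sum)
    first <- x[!duplicated(key), , drop = FALSE]
    first$multiplicity <- agg$multiplicity[match(key[!duplicated(key)], agg$key)]
    x <- first
  }
  out <- data.frame(
    sample_id = sample_id,
    target_id = panel$target_id,
    stringsAsFactors = FALSE
  )
  per_target <- function(f) {
    vapply(panel$target_id, function(tid) f(x[x$target_id == tid, , drop = FALSE]),
           numeric(1))
  }
  out$unique_mutations <- per_target(nrow)
  out$total_mutations <- per_target(function(d) sum(d$multiplicity))
  out$duplex_bp <- depth$duplex_bp[match(out$target_id, depth$target_id)]
  zero_depth <- out$target_id[out$duplex_bp == 0 & out$unique_mutations > 0]
  if (length(zero_depth) > 0) {
    stop("calls observed in target(s) with zero recorded depth: ",
         paste(zero_depth, collapse = ", "))
  }
  out$mf_min <- ifelse(out$duplex_bp > 0, out$unique_mutations / out$duplex_bp, 0)
  out$mf_max <- ifelse(out$duplex_bp > 0, out$total_mutations / out$duplex_bp, 0)
  out$n_snv <- per_target(function(d) sum(d$variant_class == "SNV"))
  out$n_mnv <- per_target(function(d) sum(d$variant_class == "MNV"))
  out$n_ins <- per_target(function(d) sum(d$variant_class == "insertion"))
  out$n_del <- per_target(function(d) sum(d$variant_class == "deletion"))
  rownames(out) <- NULL
  out
}

#' Tally every sample of a cohort
#'
#' Applies [tally_sample()] to each sample in the design.
#'
#' @inheritParams tally_sample
#' @param design Study design (see [read_design()]).
#' @return Row-bound per-target tallies for all samples.
#' @export
tally_cohort <- function(calls, depth_table, panel, design) {
  out <- do.call(rbind, lapply(design$sample_id, function(sid) {
    tally_sample(calls, depth_table, panel, sid)
  }))
  rownames(out) <- NULL
  out
}

#' Panel-wide tallies per sample
#'
#' Sums per-target tallies over the panel. Panel-wide MF equals the
#' depth-weighted mean of per-target MFs exactly.
#'
#' @param tallies Per-target tallies from [tally_cohort()].
#' @return One row per sample with panel-wide counts, depth and MFs.
#' @export
panel_tally <- function(tallies) {
  out <- do.call(rbind, lapply(split(tallies, tallies$sample_id), function(d) {
    data.frame(
      sample_id = d$sample_id[1],
      unique_mutations = sum(d$unique_mutations),
      total_mutations = sum(d$total_mutations),
      duplex_bp = sum(d$duplex_bp),
      n_snv = sum(d$n_snv), n_mnv = sum(d$n_mnv),
      n_ins = sum(d$n_ins), n_del = sum(d$n_del),
      stringsAsFactors = FALSE
    )
  }))
  out$mf_min <- out$unique_mutations / out$duplex_bp
  out$mf_max <- out$total_mutations / out$duplex_bp
  rownames(out) <- NULL
  out
}

#' Pool tallies by dose group
#'
#' Sums counts and depth over the animals of each dose group and reports
#' the naive pooled frequencies and their fold change over the dose-0
#' group. These pooled ratios coincide with the model-based group
#' estimates of [fit_dose_glm()] when per-animal denominators are equal.
#'
#' @param tallies Per-target or panel-wide tallies.
#' @param design Study design mapping `sample_id` to `dose`.
#' @return A `data.frame` per dose: pooled `unique_mutations`,
#'   `total_mutations`, `duplex_bp`, `mf_min`, `mf_max`, `fold_min`,
#'   `fold_max`, `n_samples`.
#' @export
group_tallies <- function(tallies, design) {
  validate_design(design)
  dose <- design$dose[match(tallies$sample_id, design$sample_id)]
  if (anyNA(dose)) {
    stop("tallies contain sample(s) absent from the design: ",
         paste(unique(tallies$sample_id[is.na(dose)]), collapse = ", "))
  }
  missing <- setdiff(design$sample_id, tallies$sample_id)
  if (length(missing) > 0) {
    stop("design sample(s) without tallies: ", paste(missing, collapse = ", "))
  }
  out <- do.call(rbind, lapply(split(tallies, dose), function(d) {
    data.frame(
      dose = design$dose[match(d$sample_id[1], design$sample_id)],
      n_samples = length(unique(d$sample_id)),
      unique_mutations = sum(d$unique_mutations),
      total_mutations = sum(d$total_mutations),
      duplex_bp = sum(d$duplex_bp),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$dose), , drop = FALSE]
  out$mf_min <- out$unique_mutations / out$duplex_bp
  out$mf_max <- out$total_mutations / out$duplex_bp
  ctrl <- out[out$dose == 0, , drop = FALSE]
  if (nrow(out) < 2) {
    warning("single dose group: fold changes undefined")
    out$fold_min <- NA_real_
    out$fold_max <- NA_real_
  } else {
    out$fold_min <- out$mf_min / ctrl$mf_min
    out$fold_max <- out$mf_max / ctrl$mf_max
  }
  rownames(out) <- NULL
  out
}
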