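# Shared in-code fixtures: everything is built at test time, nothing on disk.

# A minimal panel with a fully known reference sequence per target.
toy_panel <- function(seqs = c(chrA = "ACGTACGTAC", chrB = "TTTCCCGGGA"),
                      start = 101, genic = NULL) {
  n <- length(seqs)
  if (is.null(genic)) genic <- rep(FALSE, n)
  panel <- GenomicRanges::GRanges(
    seqnames = names(seqs),
    ranges = IRanges::IRanges(start = start, width = nchar(seqs)),
    target_id = names(seqs), genic = genic, gc_fraction = NA_real_
  )
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  panel$seq <- ss
  panel
}

# One call row with sensible defaults; pos is the 1-based genomic position.
toy_call <- function(sample_id = "s1", target_id = "chrA", chrom = target_id,
                     pos = 103, ref = "G", alt = "A", multiplicity = 1,
                     vaf = 0.001) {
  data.frame(sample_id = sample_id, target_id = target_id, chrom = chrom,
             pos = pos, ref = ref, alt = alt,
             variant_class = duplexmut:::classify_variant(ref, alt),
             multiplicity = as.integer(multiplicity), vaf = vaf,
             stringsAsFactors = FALSE)
}

toy_depth <- function(samples, panel, duplex_bp = 1e6) {
  d <- expand.grid(sample_id = samples, target_id = panel$target_id,
                   stringsAsFactors = FALSE)
  d$duplex_bp <- duplex_bp
  d
}

# A small cohort generated once per test run and reused by several files.
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_panel(seed = 401)
      cfg <- study_config(seed = 402)
      study <- simulate_study(cfg, panel)
      calls <- suppressMessages(filter_germline(study$calls))
      tallies <- tally_cohort(calls, study$depth, panel, study$design)
      cache <<- list(panel = panel, config = cfg, study = study,
                     calls = calls, tallies = tallies,
                     per_sample = panel_tally(tallies))
    }
    cache
  }
})

# Independent SBS96 oracle: per-substitution classification by explicit
# complement tables, no shared code with the package implementation.
oracle_sbs96_label <- function(flank5, ref, alt, flank3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    lab_ref <- comp[[ref]]
    lab_alt <- comp[[alt]]
    lab_f5 <- comp[[flank3]]   # reverse complement swaps and complements flanks
    lab_f3 <- comp[[flank5]]
  } else {
    lab_ref <- ref; lab_alt <- alt; lab_f5 <- flank5; lab_f3 <- flank3
  }
  paste0(lab_f5, "[", lab_ref, ">", lab_alt, "]", lab_f3)
}

write_signature_file <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(Type = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
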