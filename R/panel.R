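#' Read a target-panel definition from BED (with optional reference FASTA)
#'
#' Loads the targeted panel over which duplex mutation frequencies are
#' computed. The BED file must have at least four columns
#' (chrom, start, end, name); a further annotation column holding
#' `genic`/`intergenic` labels is recognised when present. BED coordinates
#' (0-based half-open) are converted to the 1-based closed convention of
#' [GenomicRanges::GRanges] at the boundary.
#'
#' When `fasta_path` is given, the reference sequence of every target is
#' attached. FASTA records may either be named after a target id (and must
#' then have exactly the target's width) or after a chromosome (the target
#' interval is then extracted from it).
#'
#' @param bed_path Path to a BED file with >= 4 columns.
#' @param fasta_path Optional path to a FASTA file covering every target.
#' @return A `GRanges` with metadata columns `target_id`, `genic`,
#'   `gc_fraction` (NA without sequence) and, when a FASTA was supplied,
#'   `seq` (a `DNAStringSet`).
#' @export
read_panel <- function(bed_path, fasta_path = NULL) {
  if (!file.exists(bed_path)) {
    stop("panel BED file not found: ", bed_path)
  }
  if (length(readLines(bed_path, n = 1)) == 0) {
    return(empty_panel())
  }
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) == 1) {  # tolerate space-separated files
    bed <- utils::read.table(bed_path, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
  }
  if (nrow(bed) == 0) {
    return(empty_panel())
  }
  if (ncol(bed) < 4) {
    stop("panel BED must have >= 4 columns (chrom, start, end, name)")
  }
  genic <- rep(FALSE, nrow(bed))
  if (ncol(bed) >= 5) {
    for (j in 5:ncol(bed)) {
      vals <- tolower(as.character(bed[[j]]))
      if (all(vals %in% c("genic", "intergenic"))) {
        genic <- vals == "genic"
        break
      }
    }
  }
  panel <- GenomicRanges::GRanges(
    seqnames = as.character(bed[[1]]),
    ranges   = IRanges::IRanges(start = bed[[2]] + 1L, end = bed[[3]]),
    target_id = as.character(bed[[4]]),
    genic     = genic,
    gc_fraction = NA_real_
  )
  validate_panel(panel)
  if (!is.null(fasta_path)) {
    panel <- attach_panel_sequence(panel, fasta_path)
  }
  panel
}

empty_panel <- function() {
  GenomicRanges::GRanges(
    target_id = character(0), genic = logical(0), gc_fraction = numeric(0)
  )
}

validate_panel <- function(panel) {
  ids <- panel$target_id
  if (anyDuplicated(ids)) {
    stop("duplicated target ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  hits <- GenomicRanges::findOverlaps(panel, panel, ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  if (length(hits) > 0) {
    stop("panel intervals overlap: ",
         paste(unique(ids[S4Vectors::queryHits(hits)]), collapse = ", "))
  }
  invisible(panel)
}

attach_panel_sequence <- function(panel, fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("panel FASTA file not found: ", fasta_path)
  }
  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  seqs <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    id <- panel$target_id[i]
    chrom <- as.character(GenomicRanges::seqnames(panel))[i]
    if (id %in% names(fa)) {
      s <- fa[[id]]
      if (length(s) != GenomicRanges::width(panel)[i]) {
        stop("FASTA record for target ", id, " has length ", length(s),
             ", expected ", GenomicRanges::width(panel)[i])
      }
    } else if (chrom %in% names(fa)) {
      chrom_seq <- fa[[chrom]]
      if (GenomicRanges::end(panel)[i] > length(chrom_seq)) {
        stop("interval of target ", id, " extends past FASTA record ", chrom)
      }
      s <- Biostrings::subseq(chrom_seq, GenomicRanges::start(panel)[i],
                              GenomicRanges::end(panel)[i])
    } else {
      stop("no FASTA record covers target ", id)
    }
    seqs[[i]] <- s
  }
  seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- panel$target_id
  panel$seq <- seqs
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  panel$gc_fraction <- (freq[, "C"] + freq[, "G"]) / rowSums(freq[, 1:4, drop = FALSE])
  panel
}

#' Write a panel back to BED (and optionally FASTA)
#'
#' Inverse of [read_panel()]: coordinates are emitted 0-based half-open and
#' the genic flag as a fifth `genic`/`intergenic` column.
#'
#' @param panel A panel `GRanges` as returned by [read_panel()] or
#'   [simulate_panel()].
#' @param bed_path Output BED path.
#' @param fasta_path Optional output FASTA path (requires sequences).
#' @return Invisibly, `bed_path`.
#' @export
write_panel <- function(panel, bed_path, fasta_path = NULL) {
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(panel)),
    start = GenomicRanges::start(panel) - 1L,
    end   = GenomicRanges::end(panel),
    name  = panel$target_id,
    annot = ifelse(panel$genic, "genic", "intergenic")
  )
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(fasta_path)) {
    if (is.null(panel$seq)) stop("panel carries no sequences to write")
    Biostrings::writeXStringSet(panel$seq, fasta_path)
  }
  invisible(bed_path)
}

#' Simulate a targeted mutagenesis panel
#'
#' Builds a synthetic panel emulating a rodent duplex-sequencing mutagenesis
#' design: `n_targets` targets of equal width spread over autosomes, with one
#' target per chromosome except two on chromosome 1, a fixed number located
#' in genic regions, and random reference sequence at a given GC fraction.
#' Sequences are synthetic, not taken from any genome build.
#'
#' @param n_targets Number of targets (default 20).
#' @param target_length Width of each target in bp (default 2400).
#' @param n_genic Number of targets flagged genic (default 9).
#' @param gc Expected GC fraction of the simulated reference (default 0.42,
#'   typical of mammalian bulk sequence).
#' @param seed Optional integer seed for reproducible sequence draws.
#' @return A panel `GRanges` with sequences attached, as from [read_panel()].
#' @export
simulate_panel <- function(n_targets = 20, target_length = 2400,
                           n_genic = 9, gc = 0.42, seed = NULL) {
  stopifnot(n_targets >= 1, target_length >= 3, n_genic <= n_targets,
            gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  n_chrom <- max(1L, n_targets - 1L)
  chroms <- paste0("chr", c(1L, seq_len(n_chrom)))
  ids <- paste0("chr", c("1", "1.2", if (n_chrom >= 2) 2:n_chrom))
  ids <- ids[seq_len(n_targets)]
  chroms <- chroms[seq_len(n_targets)]
  # two targets on chr1 must not overlap
  start <- ifelse(seq_len(n_targets) == 2L, 3e6 + 2L * target_length, 3e6)
  genic <- rep(FALSE, n_targets)
  if (n_genic > 0) {
    idx <- unique(round(seq(1, n_targets, length.out = n_genic)))
    while (length(idx) < n_genic) idx <- unique(c(idx, sample.int(n_targets, 1)))
    genic[idx] <- TRUE
  }
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_targets), function(i) {
    paste(sample(names(base_prob), target_length, replace = TRUE,
                 prob = base_prob), collapse = "")
  }, character(1)))
  names(seqs) <- ids
  panel <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(start = start, width = target_length),
    target_id = ids, genic = genic, gc_fraction = NA_real_
  )
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  panel$gc_fraction <- (freq[, "C"] + freq[, "G"]) / rowSums(freq[, 1:4, drop = FALSE])
  panel$seq <- seqs
  validate_panel(panel)
  panel
}
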