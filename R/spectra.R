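#' Canonical SBS96 context ordering
#'
#' The 96 trinucleotide mutation types in COSMIC convention: six
#' pyrimidine-reference substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each
#' in 16 flanking-base contexts, substitution-major with flanks in
#' alphabetical order (`A[C>A]A`, `A[C>A]C`, ...).
#'
#' @return Character vector of length 96.
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f1, f2) {
      paste0(f1, "[", s, "]", f2)
    })))
  }))
}

SBS6_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
CLASS9_LEVELS <- c(SBS6_CLASSES, "mnv", "ins", "del")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
}

#' Collapse an SNV to pyrimidine-reference notation
#'
#' Substitutions with a purine reference (A or G) are strand-complemented
#' so every SNV is expressed as one of the six classes C>A, C>G, C>T, T>A,
#' T>C, T>G. The collapse is an involution: applying it to an
#' already-pyrimidine substitution is the identity.
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @return Character vector of substitution classes.
#' @export
pyrimidine_class <- function(ref, alt) {
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    stop("non-ACGT allele in SNV")
  }
  purine <- ref %in% c("A", "G")
  cls <- paste0(ifelse(purine, complement_base(ref), ref), ">",
                ifelse(purine, complement_base(alt), alt))
  cls
}

new_spectrum <- function(counts, kind) {
  total <- sum(counts)
  structure(list(
    kind = kind,
    counts = counts,
    proportions = if (total > 0) counts / total else counts * 0,
    total = total
  ), class = "duplex_spectrum")
}

#' @export
print.duplex_spectrum <- function(x, ...) {
  cat(sprintf("%s mutation spectrum: %d mutation(s)\n", x$kind, x$total))
  print(x$counts)
  invisible(x)
}

#' Six-class single-base-substitution spectrum
#'
#' Counts SNVs per pyrimidine-reference substitution class. Non-SNV calls
#' are ignored (they enter the nine-class spectrum of [spectrum_class9()]).
#'
#' @param calls Call table; only rows with `variant_class == "SNV"` are used.
#' @param weight `"unique"` counts each distinct mutation once (the MF_Min
#'   convention, default); `"multiplicity"` weights by clonal multiplicity
#'   (MF_Max convention).
#' @return A `duplex_spectrum` with 6 named counts.
#' @export
spectrum_sbs6 <- function(calls, weight = c("unique", "multiplicity")) {
  weight <- match.arg(weight)
  snv <- calls[calls$variant_class == "SNV", , drop = FALSE]
  w <- if (weight == "multiplicity") snv$multiplicity else rep(1L, nrow(snv))
  cls <- if (nrow(snv) > 0) pyrimidine_class(snv$ref, snv$alt) else character(0)
  counts <- vapply(SBS6_CLASSES, function(k) sum(w[cls == k]), numeric(1))
  new_spectrum(counts, "SBS6")
}

#' Nine-class mutation spectrum
#'
#' The six pyrimidine-reference SNV classes plus multi-nucleotide variants
#' (`mnv`), small insertions (`ins`) and small deletions (`del`), each
#' indel/MNV counted as one mutation event.
#'
#' @inheritParams spectrum_sbs6
#' @return A `duplex_spectrum` with 9 named counts.
#' @export
spectrum_class9 <- function(calls, weight = c("unique", "multiplicity")) {
  weight <- match.arg(weight)
  w <- if (weight == "multiplicity") calls$multiplicity else rep(1L, nrow(calls))
  is_snv <- calls$variant_class == "SNV"
  cls <- character(nrow(calls))
  cls[is_snv] <- if (any(is_snv)) {
    pyrimidine_class(calls$ref[is_snv], calls$alt[is_snv])
  } else character(0)
  cls[calls$variant_class == "MNV"] <- "mnv"
  cls[calls$variant_class == "insertion"] <- "ins"
  cls[calls$variant_class == "deletion"] <- "del"
  counts <- vapply(CLASS9_LEVELS, function(k) sum(w[cls == k]), numeric(1))
  new_spectrum(counts, "CLASS9")
}

#' Trinucleotide (SBS96) mutation spectrum
#'
#' Reads the flanking base on either side of each SNV from the panel
#' reference sequence and bins mutations into the 96 COSMIC trinucleotide
#' classes. Purine-reference sites are reverse-complemented (context and
#' alleles together). SNVs at the first or last base of a target have no
#' context and are excluded with a warning; the number excluded is
#' available as `attr(, "n_excluded")`.
#'
#' @inheritParams spectrum_sbs6
#' @param panel Panel `GRanges` with sequences attached (see [read_panel()]).
#' @return A `duplex_spectrum` with 96 counts in [sbs96_contexts()] order.
#' @export
spectrum_sbs96 <- function(calls, panel, weight = c("unique", "multiplicity")) {
  weight <- match.arg(weight)
  if (is.null(panel$seq)) {
    stop("panel carries no sequences; supply a FASTA to read_panel()")
  }
  snv <- calls[calls$variant_class == "SNV", , drop = FALSE]
  w <- if (weight == "multiplicity") snv$multiplicity else rep(1L, nrow(snv))
  contexts <- sbs96_contexts()
  counts <- stats::setNames(numeric(96), contexts)
  n_excluded <- 0L
  if (nrow(snv) > 0) {
    tidx <- match(snv$target_id, panel$target_id)
    if (anyNA(tidx)) stop("call in unknown target: ",
                          paste(unique(snv$target_id[is.na(tidx)]), collapse = ", "))
    offset <- snv$pos - GenomicRanges::start(panel)[tidx] + 1L
    widths <- GenomicRanges::width(panel)[tidx]
    has_context <- offset > 1L & offset < widths
    n_excluded <- sum(!has_context)
    if (n_excluded > 0) {
      warning(n_excluded, " SNV(s) at target boundaries excluded from SBS96")
    }
    for (i in which(has_context)) {
      tri <- as.character(Biostrings::subseq(panel$seq[[tidx[i]]],
                                             offset[i] - 1L, offset[i] + 1L))
      ref <- snv$ref[i]; alt <- snv$alt[i]
      if (substr(tri, 2, 2) != ref) {
        stop("reference mismatch at ", snv$chrom[i], ":", snv$pos[i],
             " (panel has ", substr(tri, 2, 2), ", call has ", ref, ")")
      }
      if (ref %in% c("A", "G")) {
        tri <- revcomp(tri)
        ref <- complement_base(ref)
        alt <- complement_base(alt)
      }
      lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                    substr(tri, 3, 3))
      counts[lab] <- counts[lab] + w[i]
    }
  }
  sp <- new_spectrum(counts, "SBS96")
  attr(sp, "n_excluded") <- n_excluded
  sp
}

#' Marginalise an SBS96 spectrum to six classes
#'
#' Sums the 16 contexts within each substitution class; exact by
#' construction.
#'
#' @param spectrum An SBS96 `duplex_spectrum`.
#' @return An SBS6 `duplex_spectrum`.
#' @export
sbs96_to_sbs6 <- function(spectrum) {
  stopifnot(inherits(spectrum, "duplex_spectrum"), spectrum$kind == "SBS96")
  sub_of <- substr(sbs96_contexts(), 3, 5)
  counts <- vapply(SBS6_CLASSES, function(k) {
    sum(spectrum$counts[sub_of == k])
  }, numeric(1))
  new_spectrum(counts, "SBS6")
}

#' Split C>T counts of an SBS96 spectrum by CpG context
#'
#' C>T mutations at `N[C>T]G` contexts occur at CpG dinucleotides; a shift
#' from CpG to non-CpG C>T is a hallmark of induced (rather than
#' deamination-driven) mutagenesis.
#'
#' @param spectrum An SBS96 `duplex_spectrum`.
#' @return Named numeric vector with elements `cpg` and `non_cpg`.
#' @export
cpg_split <- function(spectrum) {
  stopifnot(inherits(spectrum, "duplex_spectrum"), spectrum$kind == "SBS96")
  ctx <- sbs96_contexts()
  ct <- substr(ctx, 3, 5) == "C>T"
  cpg <- ct & substr(ctx, 7, 7) == "G"
  c(cpg = sum(spectrum$counts[cpg]), non_cpg = sum(spectrum$counts[ct & !cpg]))
}

#' Cosine similarity between two non-negative vectors
#'
#' `sum(x * y) / (||x|| * ||y||)`; scale-invariant, so counts and
#' proportions give identical values.
#'
#' @param x,y Non-negative numeric vectors of equal length (a
#'   `duplex_spectrum` is accepted and its counts used).
#' @return A value in `[0, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (inherits(x, "duplex_spectrum")) x <- x$counts
  if (inherits(y, "duplex_spectrum")) y <- y$counts
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("vectors must be non-negative")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector has no cosine similarity")
  sum(x * y) / (nx * ny)
}

#' Rank signatures by their shift in similarity between dose and control
#'
#' For each reference signature, computes the cosine similarity to the
#' exposed-group spectrum and to the control spectrum, and ranks signatures
#' by the difference (`delta = sim_dose - sim_control`, descending; ties
#' broken by signature label). The top-ranked signatures are those whose
#' resemblance increases most under exposure.
#'
#' @param control_spectrum,dose_spectrum SBS96 `duplex_spectrum` objects (or
#'   96-long non-negative vectors).
#' @param signatures 96 x k signature matrix from [read_signatures()].
#' @return A `data.frame` with columns `signature`, `sim_dose`,
#'   `sim_control`, `delta`, sorted by decreasing `delta`.
#' @export
rank_signature_shifts <- function(control_spectrum, dose_spectrum, signatures) {
  sims <- function(sp) {
    vapply(seq_len(ncol(signatures)), function(j) {
      cosine_similarity(sp, signatures[, j])
    }, numeric(1))
  }
  sim_dose <- sims(dose_spectrum)
  sim_control <- sims(control_spectrum)
  out <- data.frame(
    signature = colnames(signatures),
    sim_dose = sim_dose,
    sim_control = sim_control,
    delta = sim_dose - sim_control,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$delta, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
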