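#' Read per-sample somatic variant calls from VCF
#'
#' Parses one or more post-consensus VCF files (one per library, as emitted
#' by duplex consensus-calling pipelines) into the package's flat call
#' table. Records are assigned to their containing panel target; records
#' outside every target are dropped and the count reported via `message()`.
#' Variant classes are assigned from allele lengths: both length 1 = `SNV`,
#' equal lengths > 1 = `MNV`, longer alt = `insertion`, longer ref =
#' `deletion`.
#'
#' Per-call clonal multiplicity (the number of duplex source molecules
#' carrying the identical variant) is read from the INFO field named by
#' `multiplicity_field`; when the field is absent every call gets
#' multiplicity 1, which makes MF_Min and MF_Max coincide downstream. The
#' variant allele fraction is read from `vaf_field` and is required.
#'
#' @param vcf_paths Character vector of VCF paths.
#' @param panel Panel `GRanges` from [read_panel()].
#' @param sample_ids Sample ids, one per file; defaults to file base names.
#' @param multiplicity_field INFO key with the duplex-molecule count
#'   (default `"ALT_DEPTH"`).
#' @param vaf_field INFO key with the variant allele fraction (default
#'   `"VAF"`).
#' @return A `data.frame` with columns `sample_id`, `target_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `variant_class`, `multiplicity`, `vaf`.
#' @export
read_variants <- function(vcf_paths, panel, sample_ids = NULL,
                          multiplicity_field = "ALT_DEPTH",
                          vaf_field = "VAF") {
  if (length(panel) == 0) stop("empty panel: refusing to map variants")
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.vcf(\\.gz)?$", "", basename(vcf_paths))
  }
  stopifnot(length(sample_ids) == length(vcf_paths))
  out <- vector("list", length(vcf_paths))
  n_dropped <- 0L
  for (i in seq_along(vcf_paths)) {
    vcf <- VariantAnnotation::readVcf(vcf_paths[i])
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (length(rr) == 0) {
      out[[i]] <- empty_calls()
      next
    }
    info <- VariantAnnotation::info(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    if (!vaf_field %in% colnames(info)) {
      stop("VCF ", vcf_paths[i], " lacks the INFO field '", vaf_field,
           "' carrying the variant allele fraction")
    }
    vaf <- as.numeric(info[[vaf_field]])
    if (anyNA(vaf)) {
      bad <- which(is.na(vaf))
      stop("missing ", vaf_field, " in ", vcf_paths[i], " at record(s): ",
           paste(names(rr)[bad], collapse = ", "))
    }
    if (multiplicity_field %in% colnames(info)) {
      mult <- as.integer(info[[multiplicity_field]])
      if (anyNA(mult)) {
        bad <- which(is.na(mult))
        stop("missing ", multiplicity_field, " in ", vcf_paths[i],
             " at record(s): ", paste(names(rr)[bad], collapse = ", "))
      }
    } else {
      mult <- rep(1L, length(rr))
    }
    hits <- GenomicRanges::findOverlaps(rr, panel, ignore.strand = TRUE,
                                        select = "first")
    keep <- !is.na(hits)
    n_dropped <- n_dropped + sum(!keep)
    out[[i]] <- data.frame(
      sample_id = rep(sample_ids[i], sum(keep)),
      target_id = panel$target_id[hits[keep]],
      chrom = as.character(GenomicRanges::seqnames(rr))[keep],
      pos = GenomicRanges::start(rr)[keep],
      ref = ref[keep], alt = alt[keep],
      variant_class = classify_variant(ref[keep], alt[keep]),
      multiplicity = mult[keep],
      vaf = vaf[keep],
      stringsAsFactors = FALSE
    )
  }
  if (n_dropped > 0) {
    message("read_variants: dropped ", n_dropped,
            " record(s) outside the panel")
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  validate_calls(calls)
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(0), target_id = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), variant_class = character(0),
             multiplicity = integer(0), vaf = numeric(0),
             stringsAsFactors = FALSE)
}

classify_variant <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
    ifelse(nr == na, "MNV",
      ifelse(na > nr, "insertion", "deletion")))
}

validate_calls <- function(calls) {
  need <- c("sample_id", "target_id", "chrom", "pos", "ref", "alt",
            "variant_class", "multiplicity", "vaf")
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0) {
    stop("call table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(calls) > 0) {
    if (any(calls$multiplicity < 1)) stop("multiplicity must be >= 1")
    if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
    if (any(calls$vaf < 0 | calls$vaf > 1)) stop("vaf must lie in [0, 1]")
  }
  invisible(calls)
}

#' Write somatic variant calls to per-sample VCF files
#'
#' Emits one minimal VCF 4.2 file per sample with the call multiplicity and
#' variant allele fraction as INFO fields, readable back by
#' [read_variants()] (the round trip preserves position, alleles,
#' multiplicity and VAF exactly).
#'
#' @param calls Call table as produced by [read_variants()] or
#'   [simulate_study()].
#' @param dir Output directory (created if needed); files are named
#'   `<sample_id>.vcf`.
#' @param multiplicity_field,vaf_field INFO keys to write under.
#' @return Invisibly, the vector of file paths written.
#' @export
write_variants <- function(calls, dir, multiplicity_field = "ALT_DEPTH",
                           vaf_field = "VAF") {
  validate_calls(calls)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Number of duplex source molecules carrying the variant\">",
            multiplicity_field),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Variant allele fraction\">",
            vaf_field),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  paths <- character(0)
  for (sid in unique(calls$sample_id)) {
    x <- calls[calls$sample_id == sid, , drop = FALSE]
    x <- x[order(x$chrom, x$pos, x$ref, x$alt), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s=%d;%s=%s",
                    x$chrom, x$pos, x$ref, x$alt,
                    multiplicity_field, x$multiplicity,
                    vaf_field, format(x$vaf, digits = 10, scientific = TRUE,
                                      trim = TRUE))
    path <- file.path(dir, paste0(sid, ".vcf"))
    writeLines(c(header, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read and write per-sample, per-target duplex depth tables
#'
#' The depth table maps `(sample_id, target_id)` to the number of duplex
#' base pairs sequenced, the denominator of every mutation frequency.
#'
#' @param path TSV path with columns `sample_id`, `target_id`, `duplex_bp`.
#' @return A `data.frame` with those three columns.
#' @export
read_depth_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target_id", "duplex_bp")
  if (!all(need %in% names(d))) {
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[need]
  if (any(d$duplex_bp < 0)) stop("duplex_bp must be non-negative")
  d
}

#' @rdname read_depth_table
#' @param depth Depth `data.frame` to write.
#' @export
write_depth_table <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the study design (dose assignment)
#'
#' @param path TSV path with columns `sample_id`, `dose` (dose 0 is the
#'   vehicle control) and optionally `group` and `sampling_day`.
#' @return A `data.frame` with `sample_id`, `dose` and any extra columns.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "dose") %in% names(d))) {
    stop("design must have columns sample_id and dose")
  }
  validate_design(d)
  d
}

validate_design <- function(design) {
  if (anyDuplicated(design$sample_id)) stop("duplicated sample ids in design")
  if (!any(design$dose == 0)) stop("design has no dose-0 (vehicle control) group")
  invisible(design)
}

#' @rdname read_design
#' @param design Design `data.frame` to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a COSMIC-format SBS signature matrix
#'
#' Reads a tab-delimited signature catalogue with one row per trinucleotide
#' context in COSMIC notation (`A[C>A]A` ... `T[T>G]T`) and one column per
#' signature. Rows are reordered to the canonical context order returned by
#' [sbs96_contexts()]; each signature column is validated non-negative and
#' renormalised to sum to one (with a warning when the input deviates from
#' unit sum by more than `1e-6`).
#'
#' @param path Path to the tab-delimited signature file. The context label
#'   column is either the first column or one named `Type`.
#' @return A 96 x k numeric matrix, columns summing to 1, rows in COSMIC
#'   context order.
#' @export
read_signatures <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  label_col <- if ("Type" %in% names(d)) "Type" else names(d)[1]
  labels <- as.character(d[[label_col]])
  d <- d[setdiff(names(d), label_col)]
  contexts <- sbs96_contexts()
  if (nrow(d) != 96 || !setequal(labels, contexts)) {
    bad <- setdiff(labels, contexts)
    stop("signature file must have exactly the 96 COSMIC contexts",
         if (length(bad) > 0) paste0("; unknown label(s): ",
                                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  m <- m[match(contexts, labels), , drop = FALSE]
  rownames(m) <- contexts
  if (any(m < 0)) stop("signature entries must be non-negative")
  sums <- colSums(m)
  if (any(sums == 0)) {
    stop("signature column(s) sum to zero: ",
         paste(colnames(m)[sums == 0], collapse = ", "))
  }
  if (any(abs(sums - 1) > 1e-6)) {
    warning("renormalising signature column(s) not summing to 1: ",
            paste(colnames(m)[abs(sums - 1) > 1e-6], collapse = ", "))
  }
  sweep(m, 2, sums, "/")
}

#' Read and write lacZ plaque-count tables
#'
#' The transgenic-rodent reporter assay scores mutant plaques among total
#' plaque-forming units (pfu) per animal; the mutant frequency is
#' `mutants / pfu`.
#'
#' @param path TSV path with columns `sample_id`, `mutants`, `pfu`.
#' @return A `data.frame` with those columns.
#' @export
read_lacz <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mutants", "pfu")
  if (!all(need %in% names(d))) {
    stop("lacZ table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$pfu < 1)) stop("pfu must be >= 1")
  if (any(d$mutants < 0 | d$mutants > d$pfu)) {
    stop("mutants must lie in [0, pfu]")
  }
  d
}

#' @rdname read_lacz
#' @param lacz lacZ `data.frame` to write.
#' @export
write_lacz <- function(lacz, path) {
  utils::write.table(lacz, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
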