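#' Run the full mutagenicity analysis pipeline
#'
#' Orchestrates the stages end-to-end: load (or simulate) a cohort,
#' filter germline-like calls, tally mutation frequencies, fit
#' quasibinomial group estimates for MF_Min, MF_Max and (when plaque
#' counts are available) the reporter assay, fit per-target mixed models,
#' build dose-group spectra with signature ranking (when a signature
#' catalogue is given), and estimate model-averaged benchmark doses. Each
#' stage writes a TSV into `out_dir`; a `manifest.yaml` records the seed,
#' configuration hash and files written. A failing stage raises an error
#' naming the stage; outputs of earlier stages are left in place.
#'
#' @param config Either a path to a YAML file or a list with (optionally
#'   nested) entries:
#'   \describe{
#'     \item{out_dir}{output directory (required)}
#'     \item{simulate}{logical; generate a synthetic cohort instead of
#'       reading files (default TRUE when no `paths` given)}
#'     \item{seed}{integer seed used for simulation and bootstrap}
#'     \item{paths}{list with `panel_bed`, `panel_fasta`, `vcf_dir`,
#'       `depth`, `design`, and optionally `lacz`, `signatures`}
#'     \item{vaf_max}{germline VAF threshold (default 0.01)}
#'     \item{bmr}{benchmark response (default 0.5)}
#'     \item{n_bootstrap}{BMD bootstrap replicates (default 200)}
#'     \item{per_target_glmm}{fit per-target mixed models (default TRUE)}
#'     \item{power}{optional list with `n_per_group`, `fold`, `n_sims`
#'       to append a power section}
#'   }
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(config$out_dir)) stop("config must set out_dir")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  vaf_max <- if (is.null(config$vaf_max)) 0.01 else config$vaf_max
  simulate <- isTRUE(config$simulate) || is.null(config$paths)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# duplexmut seed=%d", seed), con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    written <<- c(written, name)
    path
  }

  if (simulate) {
    inputs <- stage("simulate", {
      panel <- simulate_panel(seed = seed)
      cfg <- do.call(study_config,
                     c(config$study %||% list(), list(seed = seed)))
      study <- simulate_study(cfg, panel)
      lacz <- simulate_lacz(study$design, seed = seed + 1L)
      list(panel = panel, calls = study$calls, depth = study$depth,
           design = study$design, lacz = lacz)
    })
  } else {
    inputs <- stage("load", {
      p <- config$paths
      panel <- read_panel(p$panel_bed, p$panel_fasta)
      vcfs <- list.files(p$vcf_dir, pattern = "\\.vcf(\\.gz)?$",
                         full.names = TRUE)
      if (length(vcfs) == 0) stop("no VCF files in ", p$vcf_dir)
      design <- read_design(p$design)
      list(panel = panel,
           calls = read_variants(vcfs, panel),
           depth = read_depth_table(p$depth),
           design = design,
           lacz = if (!is.null(p$lacz)) read_lacz(p$lacz))
    })
  }

  filtered <- stage("filter_germline", filter_germline(inputs$calls, vaf_max))
  tallies <- stage("tally", {
    t <- tally_cohort(filtered, inputs$depth, inputs$panel, inputs$design)
    emit(t, "tallies.tsv")
    t
  })
  per_sample <- panel_tally(tallies)
  emit(per_sample, "per_sample.tsv")
  dose_of <- inputs$design$dose[match(per_sample$sample_id,
                                      inputs$design$sample_id)]

  estimates <- stage("stats", {
    est_min <- fit_dose_glm(per_sample$unique_mutations,
                            per_sample$duplex_bp, dose_of)
    est_max <- fit_dose_glm(per_sample$total_mutations,
                            per_sample$duplex_bp, dose_of)
    est <- rbind(cbind(endpoint = "mf_min", est_min),
                 cbind(endpoint = "mf_max", est_max))
    if (!is.null(inputs$lacz)) {
      lz <- inputs$lacz[match(per_sample$sample_id, inputs$lacz$sample_id), ]
      est_lz <- fit_dose_glm(lz$mutants, lz$pfu, dose_of)
      est <- rbind(est, cbind(endpoint = "lacz", est_lz))
    }
    emit(est, "estimates.tsv")
    est
  })

  per_target <- NULL
  if (!identical(config$per_target_glmm, FALSE)) {
    per_target <- stage("per_target_glmm", {
      res <- lapply(inputs$panel$target_id, function(tid) {
        fit <- fit_target_glmm(tallies, inputs$design, tid)
        if (is.null(fit$estimates)) {
          return(data.frame(target_id = tid, dose = NA_real_,
                            estimate = NA_real_, sem = NA_real_,
                            fold = NA_real_, p_raw = NA_real_,
                            p_adj = NA_real_, converged = FALSE,
                            ranef_variance = NA_real_))
        }
        cbind(target_id = tid, fit$estimates,
              converged = fit$converged,
              ranef_variance = fit$ranef_variance)
      })
      res <- do.call(rbind, res)
      emit(res, "per_target.tsv")
      res
    })
  }

  spectra <- stage("spectra", {
    sp <- lapply(split(filtered, dose_label(filtered, inputs$design)),
                 function(d) spectrum_sbs96(d, inputs$panel))
    tab <- data.frame(context = sbs96_contexts())
    for (nm in names(sp)) tab[[paste0("dose_", nm)]] <- sp[[nm]]$counts
    emit(tab, "spectra_sbs96.tsv")
    sp
  })
  ranking <- NULL
  if (!is.null(config$paths$signatures)) {
    ranking <- stage("signature_ranking", {
      signatures <- read_signatures(config$paths$signatures)
      doses <- sort(unique(inputs$design$dose))
      top <- as.character(max(doses))
      r <- rank_signature_shifts(spectra[["0"]], spectra[[top]], signatures)
      emit(r, "signature_shifts.tsv")
      r
    })
  }

  bmd <- stage("bmd", {
    gt <- group_tallies(per_sample, inputs$design)
    datasets <- list(
      mf_min = data.frame(dose = gt$dose, count = gt$unique_mutations,
                          denom = gt$duplex_bp),
      mf_max = data.frame(dose = gt$dose, count = gt$total_mutations,
                          denom = gt$duplex_bp))
    if (!is.null(inputs$lacz)) {
      lz <- merge(inputs$lacz, inputs$design)
      agg <- stats::aggregate(cbind(mutants, pfu) ~ dose, lz, sum)
      datasets$lacz <- data.frame(dose = agg$dose, count = agg$mutants,
                                  denom = agg$pfu)
    }
    n_boot <- if (is.null(config$n_bootstrap)) 200 else config$n_bootstrap
    bmr <- if (is.null(config$bmr)) 0.5 else config$bmr
    res <- lapply(names(datasets), function(nm) {
      b <- model_average_bmd(datasets[[nm]], bmr = bmr,
                             n_bootstrap = n_boot, seed = seed)
      data.frame(endpoint = nm, bmd = b$bmd, bmdl = b$bmdl, bmdu = b$bmdu,
                 best_family = b$best_family, flag = b$flag)
    })
    res <- do.call(rbind, res)
    emit(res, "bmd.tsv")
    res
  })

  power <- NULL
  if (!is.null(config$power)) {
    power <- stage("power", {
      pw <- config$power
      sc <- power_scenario(
        n_per_group = pw$n_per_group %||% 3,
        fold = pw$fold %||% 1.5,
        n_sims = pw$n_sims %||% 2000,
        seed = seed)
      pr <- estimate_power(sc)
      df <- data.frame(n_per_group = sc$n_per_group, fold = sc$fold,
                       power = pr$power, mc_se = pr$mc_se)
      emit(df, "power.tsv")
      df
    })
  }

  manifest <- list(
    package = "duplexmut",
    version = as.character(utils::packageVersion("duplexmut")),
    seed = seed,
    config_hash = config_hash(config),
    files = written
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(inputs = inputs, tallies = tallies,
                 per_sample = per_sample, estimates = estimates,
                 per_target = per_target, spectra = spectra,
                 signature_ranking = ranking, bmd = bmd, power = power,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dose_label <- function(calls, design) {
  as.character(design$dose[match(calls$sample_id, design$sample_id)])
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
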