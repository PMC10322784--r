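#' Holm-Sidak step-down adjustment of p-values
#'
#' Step-down Sidak: with the p-values sorted ascending, the i-th adjusted
#' value is `max_{j <= i} (1 - (1 - p_j)^(m - j + 1))`, capped at 1, and
#' returned in the original input order. Adjusted values are always at
#' least the raw values and monotone in rank; the procedure is idempotent
#' and invariant to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
holm_sidak <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax(1 - (1 - p[ord])^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Continuity handling for a dose group with zero events: add half an event
# and one trial so the logit is finite. Estimation only; flagged upstream.
continuity_adjust <- function(counts, denominators, doses) {
  zero_groups <- unique(doses)[vapply(unique(doses), function(d) {
    sum(counts[doses == d]) == 0
  }, logical(1))]
  if (length(zero_groups) > 0) {
    warning("dose group(s) with zero events; continuity adjustment applied: ",
            paste(zero_groups, collapse = ", "))
    for (d in zero_groups) {
      i <- which(doses == d)[1]
      counts[i] <- counts[i] + 0.5
      denominators[i] <- denominators[i] + 1
    }
  }
  list(counts = counts, denominators = denominators,
       adjusted = length(zero_groups) > 0)
}

#' Quasibinomial dose-response group estimates and contrasts
#'
#' Fits a binomial-logit GLM with dose as a factor and dispersion
#' estimated from Pearson residuals (R's quasibinomial family) to
#' per-animal event counts over per-animal denominators. Group frequencies
#' are back-transformed from the logit scale with delta-method standard
#' errors; each treated group is compared with the dose-0 control by the
#' model's t-test on the logit contrast, and the family of treated-vs-
#' control p-values is Holm-Sidak adjusted. Fold changes vs control carry
#' delta-method SEs accounting for the estimate covariance.
#'
#' @param counts Integer vector of per-animal event counts (unique or
#'   multiplicity-weighted mutations, or mutant plaques).
#' @param denominators Per-animal denominators (duplex bp or pfu).
#' @param doses Per-animal dose levels; dose 0 is the control.
#' @param adjust Apply the Holm-Sidak correction to the treated-vs-control
#'   family (default TRUE).
#' @return A `data.frame` per dose: `dose`, `estimate`, `sem`, `fold`,
#'   `fold_sem`, `p_raw`, `p_adj` (`NA` for the control row), with the
#'   model dispersion as `attr(, "dispersion")`.
#' @export
fit_dose_glm <- function(counts, denominators, doses, adjust = TRUE) {
  stopifnot(length(counts) == length(denominators),
            length(counts) == length(doses))
  if (any(counts > denominators)) stop("counts exceed denominators")
  if (length(unique(doses)) < 2) stop("need >= 2 dose groups")
  if (!any(doses == 0)) stop("no dose-0 control group")
  ca <- continuity_adjust(counts, denominators, doses)
  dose_f <- factor(doses, levels = sort(unique(doses)))
  fit <- stats::glm(cbind(ca$counts, ca$denominators - ca$counts) ~ dose_f,
                    family = stats::quasibinomial())
  sm <- summary(fit)
  phi <- sm$dispersion
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  levels_d <- levels(dose_f)
  k <- length(levels_d)
  # logit-scale group means eta_g and their covariance
  L <- cbind(1, rbind(0, diag(k - 1)))           # k x k contrast matrix
  eta <- drop(L %*% beta)
  Veta <- L %*% V %*% t(L)
  p_hat <- stats::plogis(eta)
  sem <- sqrt(diag(Veta)) * p_hat * (1 - p_hat)   # delta method
  # fold vs control and its delta-method SE: fold = p_g / p_0
  fold <- p_hat / p_hat[1]
  fold_sem <- rep(NA_real_, k)
  for (g in seq_len(k)) {
    grad <- numeric(k)
    grad[g] <- fold[g] * (1 - p_hat[g])
    grad[1] <- grad[1] - fold[g] * (1 - p_hat[1])
    fold_sem[g] <- sqrt(drop(t(grad) %*% Veta %*% grad))
  }
  # treated-vs-control tests: model coefficients 2..k, t on residual df
  p_raw <- rep(NA_real_, k)
  tvals <- beta[-1] / sqrt(diag(V)[-1])
  p_raw[-1] <- 2 * stats::pt(-abs(tvals), df = fit$df.residual)
  p_adj <- rep(NA_real_, k)
  p_adj[-1] <- if (adjust) holm_sidak(p_raw[-1]) else p_raw[-1]
  out <- data.frame(
    dose = as.numeric(levels_d),
    estimate = p_hat,
    sem = sem,
    fold = fold,
    fold_sem = fold_sem,
    p_raw = p_raw,
    p_adj = p_adj
  )
  rownames(out) <- NULL
  attr(out, "dispersion") <- phi
  attr(out, "continuity_adjusted") <- ca$adjusted
  out
}

#' Binomial mixed model for per-target dose response
#'
#' Fits `events / denominator ~ dose + (1 | animal)` with a binomial error
#' distribution via [lme4::glmer()] (Laplace approximation) for one target,
#' or for targets pooled by genic status. The per-animal random intercept
#' absorbs between-animal overdispersion. Group estimates, delta-method
#' SEs, folds and Holm-Sidak-adjusted Wald contrasts vs control mirror
#' [fit_dose_glm()]; Wald tests here are z-based, as conventional for
#' mixed-model output. Non-convergence is reported in the result, not
#' raised.
#'
#' @param tallies Per-target tallies from [tally_cohort()].
#' @param design Study design.
#' @param target_id Target to fit; ignored when `pool_by = "genic"`.
#' @param panel Panel `GRanges`; required for `pool_by = "genic"`.
#' @param endpoint `"mf_min"` (unique counts, default) or `"mf_max"`.
#' @param pool_by `"none"` (single target) or `"genic"` (dose x genic
#'   model over all targets).
#' @return A list of class `target_glmm` with elements `estimates` (as in
#'   [fit_dose_glm()], plus a `genic` column when pooled), `ranef_variance`
#'   (variance of the animal intercept), `converged`, `messages` and
#'   `target_id`.
#' @export
fit_target_glmm <- function(tallies, design, target_id = NULL, panel = NULL,
                            endpoint = c("mf_min", "mf_max"),
                            pool_by = c("none", "genic")) {
  endpoint <- match.arg(endpoint)
  pool_by <- match.arg(pool_by)
  count_col <- if (endpoint == "mf_min") "unique_mutations" else "total_mutations"
  if (pool_by == "none") {
    if (is.null(target_id)) stop("target_id required when pool_by = 'none'")
    d <- tallies[tallies$target_id == target_id, , drop = FALSE]
    if (nrow(d) == 0) stop("no tallies for target ", target_id)
    agg <- d
  } else {
    if (is.null(panel)) stop("panel required when pool_by = 'genic'")
    genic <- panel$genic[match(tallies$target_id, panel$target_id)]
    agg <- stats::aggregate(
      cbind(unique_mutations, total_mutations, duplex_bp) ~ sample_id + genic,
      data = cbind(tallies, genic = genic), FUN = sum)
    target_id <- "pooled_by_genic"
  }
  agg$dose <- design$dose[match(agg$sample_id, design$sample_id)]
  n_per_group <- table(agg$dose[!duplicated(agg$sample_id)])
  if (any(n_per_group < 2)) stop("need >= 2 animals per dose group")
  agg$dose_f <- factor(agg$dose, levels = sort(unique(agg$dose)))
  agg$y <- agg[[count_col]]
  msgs <- character(0)
  form <- if (pool_by == "genic") {
    cbind(y, duplex_bp - y) ~ dose_f * genic + (1 | sample_id)
  } else {
    cbind(y, duplex_bp - y) ~ dose_f + (1 | sample_id)
  }
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(form, data = agg, family = stats::binomial()),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    return(structure(list(target_id = target_id, estimates = NULL,
                          ranef_variance = NA_real_, converged = FALSE,
                          messages = conditionMessage(fit)),
                     class = "target_glmm"))
  }
  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  vc <- lme4::VarCorr(fit)
  ranef_var <- as.numeric(vc$sample_id[1, 1])
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  levels_d <- levels(agg$dose_f)
  k <- length(levels_d)
  make_estimates <- function(sel_names, label) {
    # sel_names: coefficient combination per dose level (list of named vecs)
    eta <- vapply(sel_names, function(w) sum(beta[names(w)] * w), numeric(1))
    Lm <- t(vapply(sel_names, function(w) {
      v <- numeric(length(beta)); names(v) <- names(beta)
      v[names(w)] <- w; v
    }, numeric(length(beta))))
    Veta <- Lm %*% V %*% t(Lm)
    p_hat <- stats::plogis(eta)
    sem <- sqrt(diag(Veta)) * p_hat * (1 - p_hat)
    fold <- p_hat / p_hat[1]
    z <- (eta - eta[1]) / sqrt(pmax(diag(Veta) + Veta[1, 1] - 2 * Veta[, 1], 0))
    p_raw <- c(NA_real_, 2 * stats::pnorm(-abs(z[-1])))
    data.frame(dose = as.numeric(levels_d), estimate = p_hat, sem = sem,
               fold = fold, p_raw = p_raw,
               p_adj = c(NA_real_, holm_sidak(p_raw[-1])),
               genic = label)
  }
  coef_names <- names(beta)
  dose_coef <- function(lv) {
    nm <- paste0("dose_f", lv)
    if (nm %in% coef_names) stats::setNames(1, nm) else NULL
  }
  if (pool_by == "none") {
    sel <- lapply(levels_d, function(lv) {
      c(stats::setNames(1, "(Intercept)"), dose_coef(lv))
    })
    est <- make_estimates(sel, NA)
    est$genic <- NULL
  } else {
    sel_i <- lapply(levels_d, function(lv) {
      c(stats::setNames(1, "(Intercept)"), dose_coef(lv))
    })
    sel_g <- lapply(levels_d, function(lv) {
      w <- c(stats::setNames(1, "(Intercept)"),
             stats::setNames(1, "genicTRUE"), dose_coef(lv))
      nm_int <- paste0("dose_f", lv, ":genicTRUE")
      if (nm_int %in% coef_names) w <- c(w, stats::setNames(1, nm_int))
      w
    })
    est <- rbind(make_estimates(sel_i, FALSE), make_estimates(sel_g, TRUE))
  }
  structure(list(target_id = target_id, estimates = est,
                 ranef_variance = ranef_var, converged = converged,
                 messages = msgs),
            class = "target_glmm")
}

#' @export
print.target_glmm <- function(x, ...) {
  cat("Binomial GLMM dose-response fit for", x$target_id, "\n")
  cat("converged:", x$converged,
      " animal-intercept variance:", signif(x$ranef_variance, 4), "\n")
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Correlate duplex-sequencing MF with reporter-assay mutant frequency
#'
#' Pearson product-moment correlation between paired per-animal mutation
#' frequencies from the two assays.
#'
#' @param ds_mf Per-animal duplex-sequencing MF.
#' @param lacz_mf Per-animal reporter mutant frequency, same animals in the
#'   same order.
#' @return A list with `r`, `p` and `n`.
#' @export
correlate_assays <- function(ds_mf, lacz_mf) {
  if (length(ds_mf) != length(lacz_mf)) stop("vectors differ in length")
  if (length(ds_mf) < 3) stop("need >= 3 paired animals")
  if (stats::sd(ds_mf) == 0 || stats::sd(lacz_mf) == 0) {
    stop("zero variance in one assay; correlation undefined")
  }
  ct <- stats::cor.test(ds_mf, lacz_mf, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ds_mf))
}

#' Test for heterogeneity of mutation spectra across dose groups
#'
#' Contingency-style comparison of mutation subtype composition across
#' dose groups with unequal sequencing depths: the overall statistic is a
#' likelihood-ratio G computed against expected counts that allocate each
#' subtype total to groups in proportion to group depth. The null
#' distribution is either the asymptotic chi-square with
#' `(groups - 1) * (subtypes - 1)` degrees of freedom or, whenever any
#' expected cell is below 5 (or `method = "mc"`), a Monte-Carlo null that
#' resamples the table multinomially with cell probabilities proportional
#' to depth x pooled subtype rate.
#'
#' Per-subtype dose-vs-control comparisons run the quasibinomial machinery
#' of [fit_dose_glm()] on each subtype's counts over group depths, with
#' Holm-Sidak adjustment across subtypes within each dose.
#'
#' @param counts Groups x subtypes matrix of mutation counts (rows named
#'   by dose).
#' @param depths Per-group depths (same row order).
#' @param method `"auto"` (default), `"asymptotic"` or `"mc"`.
#' @param n_mc Monte-Carlo resamples (default 2000).
#' @param seed Optional seed for the Monte-Carlo null.
#' @return A list with `p_overall`, `statistic`, `df`, `method` and
#'   `per_subtype` (a `data.frame` of per-subtype, per-dose folds and
#'   adjusted p-values).
#' @export
spectrum_difference_test <- function(counts, depths,
                                     method = c("auto", "asymptotic", "mc"),
                                     n_mc = 2000, seed = NULL) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need >= 2 groups to compare spectra")
  if (length(depths) != nrow(counts)) stop("one depth per group required")
  keep <- colSums(counts) > 0
  if (any(!keep)) {
    warning("dropping all-zero subtype(s): ",
            paste(colnames(counts)[!keep], collapse = ", "))
    counts <- counts[, keep, drop = FALSE]
  }
  if (ncol(counts) < 2) stop("need >= 2 non-empty subtypes")
  g_stat <- function(obs) {
    rate <- colSums(obs) / sum(depths)         # pooled per-bp subtype rates
    expected <- outer(depths, rate)            # depth-proportional expectation
    nz <- obs > 0
    2 * sum(obs[nz] * log(obs[nz] / expected[nz])) -
      2 * (sum(obs) - sum(expected))           # Poisson LR with open margins
  }
  G <- g_stat(counts)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  rate <- colSums(counts) / sum(depths)
  expected <- outer(depths, rate)
  use_mc <- method == "mc" || (method == "auto" && any(expected < 5))
  if (use_mc) {
    if (!is.null(seed)) set.seed(seed)
    n_total <- sum(counts)
    prob <- expected / sum(expected)
    g_null <- vapply(seq_len(n_mc), function(i) {
      sim <- matrix(stats::rmultinom(1, n_total, as.vector(prob)),
                    nrow = nrow(counts))
      g_stat(sim)
    }, numeric(1))
    p_overall <- (1 + sum(g_null >= G)) / (1 + n_mc)
    method_used <- "mc"
  } else {
    p_overall <- stats::pchisq(G, df = df, lower.tail = FALSE)
    method_used <- "asymptotic"
  }
  doses <- suppressWarnings(as.numeric(rownames(counts)))
  if (anyNA(doses)) doses <- seq_len(nrow(counts)) - 1
  per_subtype <- NULL
  if (any(doses == 0)) {
    per_subtype <- do.call(rbind, lapply(colnames(counts), function(s) {
      est <- tryCatch(
        suppressWarnings(fit_dose_glm(counts[, s], depths, doses,
                                      adjust = FALSE)),
        error = function(e) NULL)
      if (is.null(est)) return(NULL)
      est <- est[est$dose != 0, , drop = FALSE]
      data.frame(subtype = s, dose = est$dose, fold = est$fold,
                 p_raw = est$p_raw, stringsAsFactors = FALSE)
    }))
    if (!is.null(per_subtype)) {
      per_subtype$p_adj <- NA_real_
      for (d in unique(per_subtype$dose)) {
        i <- per_subtype$dose == d
        per_subtype$p_adj[i] <- holm_sidak(per_subtype$p_raw[i])
      }
    }
  }
  list(p_overall = p_overall, statistic = G, df = df, method = method_used,
       per_subtype = per_subtype)
}
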