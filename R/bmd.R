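#' Dose-response mean functions for benchmark-dose fitting
#'
#' Four sigmoid/exponential families parameterise the mean frequency
#' `mu(dose)` on the natural scale:
#' \describe{
#'   \item{exponential}{`a * exp(b * d^c)` (unbounded increase)}
#'   \item{reverse_exponential}{`a * (m - (m - 1) * exp(-b * d))`
#'     (saturating at `a * m`)}
#'   \item{hill}{`a * (1 + (m - 1) * d^c / (k^c + d^c))` with `m` the
#'     maximal fold and `k` the half-maximal dose}
#'   \item{lognormal}{`a * (1 + (m - 1) * Phi(log(d / k) / s))`, a
#'     lognormal-CDF sigmoid}
#' }
#' `a` is always the background frequency at dose 0.
#'
#' @name bmd_families
#' @keywords internal
NULL

bmd_family_names <- function() {
  c("exponential", "reverse_exponential", "hill", "lognormal")
}

bmd_mu <- function(family, params) {
  switch(family,
    exponential = function(d) params[["a"]] * exp(params[["b"]] * d^params[["c"]]),
    reverse_exponential = function(d) {
      params[["a"]] * (params[["m"]] - (params[["m"]] - 1) * exp(-params[["b"]] * d))
    },
    hill = function(d) {
      params[["a"]] * (1 + (params[["m"]] - 1) * d^params[["c"]] /
                         (params[["k"]]^params[["c"]] + d^params[["c"]]))
    },
    lognormal = function(d) {
      params[["a"]] * (1 + (params[["m"]] - 1) *
                         stats::pnorm(log(pmax(d, 1e-300) / params[["k"]]) / params[["s"]]))
    },
    stop("unknown family: ", family))
}

# parameter transforms: optimise unconstrained, map back to natural scale
bmd_par_spec <- function(family, data) {
  a0 <- max(1e-12, sum(data$count[data$dose == 0]) /
              sum(data$denom[data$dose == 0]))
  dmax <- max(data$dose)
  fold_obs <- max(1.05, (sum(data$count[data$dose == dmax]) /
                           sum(data$denom[data$dose == dmax])) / a0)
  switch(family,
    exponential = list(
      init = c(log(a0), log(log(fold_obs) / dmax), 0),
      to_natural = function(th) c(a = exp(th[1]), b = exp(th[2]),
                                  c = exp(th[3]))),
    reverse_exponential = list(
      init = c(log(a0), log(2 / dmax), log(fold_obs)),
      to_natural = function(th) c(a = exp(th[1]), b = exp(th[2]),
                                  m = 1 + exp(th[3]))),
    hill = list(
      init = c(log(a0), log(2 * fold_obs - 1), log(dmax / 2), 0),
      to_natural = function(th) c(a = exp(th[1]), m = 1 + exp(th[2]),
                                  k = exp(th[3]), c = exp(th[4]))),
    lognormal = list(
      init = c(log(a0), log(2 * fold_obs - 1), log(dmax / 2), 0),
      to_natural = function(th) c(a = exp(th[1]), m = 1 + exp(th[2]),
                                  k = exp(th[3]), s = exp(th[4]))),
    stop("unknown family: ", family))
}

#' Fit one dose-response family by maximum likelihood
#'
#' Maximises the binomial log-likelihood of observed event counts given
#' the family's mean function on the frequency scale (see
#' [bmd_families]). Several starting points are tried; the best optimum
#' is kept. `AIC = 2k - 2 logLik`.
#'
#' @param data A `data.frame` with columns `dose`, `count`, `denom`;
#'   needs >= 3 distinct doses including 0.
#' @param family One of `"exponential"`, `"reverse_exponential"`,
#'   `"hill"`, `"lognormal"`.
#' @return A list of class `bmd_fit`: `family`, `params` (natural scale),
#'   `loglik`, `aic`, `n_params`, `converged`, `mu` (the fitted mean
#'   function), `dispersion` (Pearson), `data`.
#' @export
fit_bmd_family <- function(data, family = bmd_family_names()) {
  family <- match.arg(family)
  stopifnot(all(c("dose", "count", "denom") %in% names(data)))
  if (length(unique(data$dose)) < 3 || !any(data$dose == 0)) {
    stop("need >= 3 distinct doses including 0")
  }
  if (any(data$count > data$denom)) stop("counts exceed denominators")
  spec <- bmd_par_spec(family, data)
  negll <- function(th) {
    pars <- spec$to_natural(th)
    mu <- bmd_mu(family, pars)(data$dose)
    if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) return(1e12)
    -sum(stats::dbinom(data$count, data$denom, mu, log = TRUE))
  }
  starts <- list(spec$init)
  for (shift in c(-1, 1)) {
    s <- spec$init
    s[-1] <- s[-1] + shift * 0.7
    starts[[length(starts) + 1]] <- s
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(s, negll, control = list(iter.max = 500, rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best) || best$objective >= 1e11) {
    return(structure(list(family = family, params = NULL, loglik = NA_real_,
                          aic = NA_real_, n_params = length(spec$init),
                          converged = FALSE, mu = NULL,
                          dispersion = NA_real_, data = data),
                     class = "bmd_fit"))
  }
  pars <- spec$to_natural(best$par)
  mu_fun <- bmd_mu(family, pars)
  mu <- mu_fun(data$dose)
  pearson <- sum((data$count - data$denom * mu)^2 /
                   (data$denom * mu * (1 - mu)))
  dfr <- max(1, nrow(data) - length(spec$init))
  k <- length(spec$init)
  structure(list(family = family, params = pars, loglik = -best$objective,
                 aic = 2 * k + 2 * best$objective, n_params = k,
                 converged = best$convergence == 0 ||
                   best$objective < 1e11,
                 mu = mu_fun, dispersion = pearson / dfr, data = data),
            class = "bmd_fit")
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik %.2f, AIC %.2f, converged %s\n",
              x$family, x$loglik, x$aic, x$converged))
  if (!is.null(x$params)) print(signif(x$params, 4))
  invisible(x)
}

#' Benchmark dose from a fitted family
#'
#' The BMD is the smallest dose at which the fitted mean reaches
#' `(1 + bmr)` times the background `mu(0)`: closed-form for the
#' exponential family (`(log(1 + bmr) / b)^(1/c)`), bracketed root
#' finding (relative tolerance 1e-8) otherwise. When the family's
#' asymptote never reaches the benchmark within 10x the maximal observed
#' dose, `NA` is returned with attribute `flag = "unbounded"`.
#'
#' @param fit A `bmd_fit`.
#' @param bmr Benchmark response as a relative increase (default 0.5, a
#'   50% increase over background).
#' @return The benchmark dose (numeric), or `NA` with a `flag` attribute.
#' @export
bmd_from_fit <- function(fit, bmr = 0.5) {
  stopifnot(inherits(fit, "bmd_fit"), bmr >= 0)
  if (!fit$converged || is.null(fit$params)) {
    return(structure(NA_real_, flag = "nonconverged"))
  }
  if (bmr == 0) return(0)
  d_hi <- 10 * max(fit$data$dose)
  if (fit$family == "exponential") {
    d <- (log(1 + bmr) / fit$params[["b"]])^(1 / fit$params[["c"]])
    if (d > d_hi) return(structure(NA_real_, flag = "unbounded"))
    return(d)
  }
  target <- (1 + bmr) * fit$mu(0)
  f <- function(d) fit$mu(d) - target
  if (f(d_hi) < 0) return(structure(NA_real_, flag = "unbounded"))
  stats::uniroot(f, c(0, d_hi), tol = 1e-8 * d_hi)$root
}

#' Model-averaged benchmark dose with bootstrap confidence interval
#'
#' Fits all requested families, weights the converged ones by Akaike
#' weights `w_i` proportional to `exp(-deltaAIC_i / 2)`, and reports the
#' weighted geometric mean of the per-family BMDs as the point estimate
#' (BMDs are ratio-scale quantities, so averaging is done on the log
#' scale). The confidence interval comes from a parametric bootstrap:
#' counts are resampled from the model-averaged mean with the Pearson
#' dispersion of the best fit held fixed (normal approximation to the
#' overdispersed binomial), all families are refit per replicate, one
#' family is drawn per replicate with probability equal to its Akaike
#' weight, and the 2.5/97.5 percentiles of the replicate BMDs give
#' `bmdl`/`bmdu`.
#'
#' @param data A `data.frame` with `dose`, `count`, `denom`.
#' @param bmr Benchmark response (default 0.5).
#' @param n_bootstrap Bootstrap replicates (default 200).
#' @param families Families to average over.
#' @param seed Optional seed (recorded in the result).
#' @return A list of class `bmd_result`: `bmd`, `bmdl`, `bmdu`, `bmr`,
#'   `weights`, `fits`, `best_family`, `n_bootstrap`, `n_boot_ok`,
#'   `flag` (`"ok"`, `"unstable"` or `"nonconverged"`), `seed`.
#' @export
model_average_bmd <- function(data, bmr = 0.5, n_bootstrap = 200,
                              families = bmd_family_names(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(families, function(f) fit_bmd_family(data, f))
  names(fits) <- families
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic),
               logical(1))
  if (!any(ok)) {
    warning("no dose-response family converged; no BMD")
    return(structure(list(bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                          bmr = bmr, weights = NULL, fits = fits,
                          best_family = NA_character_,
                          n_bootstrap = n_bootstrap, n_boot_ok = 0L,
                          flag = "nonconverged", seed = seed),
                     class = "bmd_result"))
  }
  aics <- vapply(fits[ok], `[[`, numeric(1), "aic")
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)
  bmds <- vapply(fits[ok], function(f) as.numeric(bmd_from_fit(f, bmr)),
                 numeric(1))
  finite <- is.finite(bmds) & bmds > 0
  point <- if (any(finite)) {
    exp(sum(w[finite] * log(bmds[finite])) / sum(w[finite]))
  } else NA_real_
  # model-averaged mean curve for the parametric bootstrap
  mu_avg <- function(d) {
    m <- vapply(fits[ok], function(f) f$mu(d), numeric(length(d)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(d))
    drop(m %*% w)
  }
  phi <- fits[ok][[which.max(w)]]$dispersion
  phi <- max(1, phi, na.rm = TRUE)
  boot_bmds <- rep(NA_real_, n_bootstrap)
  mu0 <- mu_avg(data$dose)
  for (b in seq_len(n_bootstrap)) {
    sd_b <- sqrt(phi * data$denom * mu0 * (1 - mu0))
    y <- round(pmax(0, pmin(data$denom,
                            stats::rnorm(nrow(data), data$denom * mu0, sd_b))))
    db <- data
    db$count <- y
    bf <- lapply(families, function(f) {
      tryCatch(fit_bmd_family(db, f), error = function(e) NULL)
    })
    bok <- vapply(bf, function(f) !is.null(f) && isTRUE(f$converged) &&
                    is.finite(f$aic), logical(1))
    if (!any(bok)) next
    ba <- vapply(bf[bok], `[[`, numeric(1), "aic")
    bw <- exp(-(ba - min(ba)) / 2)
    bw <- bw / sum(bw)
    pick <- sample(which(bok), 1, prob = bw)
    bb <- as.numeric(bmd_from_fit(bf[[pick]], bmr))
    if (is.finite(bb) && bb > 0) boot_bmds[b] <- bb
  }
  n_ok <- sum(is.finite(boot_bmds))
  flag <- if (n_ok < n_bootstrap / 2) "unstable" else "ok"
  ci <- if (n_ok > 0) {
    stats::quantile(boot_bmds, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(bmd = point, bmdl = ci[1], bmdu = ci[2], bmr = bmr,
                 weights = w, fits = fits,
                 best_family = names(which.max(w)),
                 n_bootstrap = n_bootstrap, n_boot_ok = n_ok,
                 flag = flag, seed = seed),
            class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("model-averaged BMD (BMR = %g%% increase): %.3g [%.3g, %.3g] (%s)\n",
              100 * x$bmr, x$bmd, x$bmdl, x$bmdu, x$flag))
  if (!is.null(x$weights)) {
    cat("Akaike weights:\n")
    print(signif(x$weights, 3))
  }
  invisible(x)
}
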