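# GWAS-facing inference: detection threshold model, one-parameter maximum
# likelihood fit of v_s to the variances of detected loci, goodness of fit,
# target-size and detectable-fraction estimation, and discovery projections.

#' Calibration constant of the step-function power model
#'
#' The association test statistic for a locus explaining a fraction `v/V_P`
#' of the phenotypic variance in a study of `m` unrelated individuals is
#' approximately chi^2 with 1 df and noncentrality `m * v / V_P`. Under a
#' step-function approximation to power, a locus is detected when its
#' noncentrality reaches the value `c` at which power equals `power` at the
#' genome-wide significance level `alpha`; the detection threshold is then
#' `v* = c * V_P / m`. This function solves for `c`.
#'
#' @param alpha genome-wide significance level (default `5e-8`).
#' @param power power at the threshold (default 0.5).
#' @return The noncentrality `c` (about 29.7 at the defaults).
#' @export
power_constant <- function(alpha = 5e-8, power = 0.5) {
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  uniroot(function(ncp)
    pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE) - power,
    c(1e-6, crit + 100))$root
}

#' GWAS detection threshold on per-locus variance explained
#'
#' `v* = c * V_P / m`: the smallest per-locus contribution to phenotypic
#' variance a study of size `m` detects under the step-function power model.
#'
#' @param m study size (number of individuals).
#' @param V_P total phenotypic variance of the trait (same units as the
#'   per-locus variances; 1 if variances are fractions of `V_P`).
#' @param calibration the power calibration constant `c`
#'   (default [power_constant()] at genome-wide significance).
#' @return The threshold `v*`.
#' @examples
#' detection_threshold(1e5, V_P = 1, calibration = 1)  # 1e-5
#' @export
detection_threshold <- function(m, V_P = 1, calibration = power_constant()) {
  stopifnot(m > 0, V_P > 0, calibration > 0)
  calibration * V_P / m
}

# ---- truncated strong-selection families --------------------------------
# In units of v_s, write x = sqrt(v/vs). Among segregating sites in the
# strong-selection pleiotropic limit the variance-weighted density of v is
# prop. to exp(-2x) (minus the derivative of G = (1+2x)exp(-2x)), and the
# per-site (count-weighted) density carries an extra 1/v:
#   sites   : f(v) prop. exp(-2 sqrt(v/vs)) / v ;  survival 2 E1(2 sqrt(v/vs))
#   variance: f(v) prop. exp(-2 sqrt(v/vs))     ;  survival (1+2x) e^{-2x} vs/2
# The n = 1 strong regime replaces sqrt(v/vs) by v/vs.

.fam_logZ <- function(vs, v_star, mode, weighting) {
  if (mode == "strong-limit") {
    x0 <- sqrt(v_star / vs)
    if (weighting == "sites") {
      if (v_star <= 0) stop("weighting = 'sites' requires v_star > 0")
      log(2) + log(pracma::expint_E1(2 * x0))
    } else {
      if (v_star > 0) log(vs) - log(2) + log1p(2 * x0) - 2 * x0
      else log(vs) - log(2)
    }
  } else { # strong-n1
    x0 <- v_star / vs
    if (weighting == "sites") {
      if (v_star <= 0) stop("weighting = 'sites' requires v_star > 0")
      log(pracma::expint_E1(2 * x0))
    } else {
      log(vs) - log(2) - 2 * x0
    }
  }
}

.fam_logdens <- function(v, vs, v_star, mode, weighting) {
  kern <- if (mode == "strong-limit") -2 * sqrt(v / vs) else -2 * v / vs
  kern <- kern - .fam_logZ(vs, v_star, mode, weighting)
  if (weighting == "sites") kern - log(v) else kern
}

.fam_cdf <- function(v, vs, v_star, mode, weighting) {
  surv <- function(u) exp(.fam_logsurv(u, vs, mode, weighting))
  1 - surv(v) / surv(v_star)
}

.fam_logsurv <- function(v, vs, mode, weighting) {
  if (mode == "strong-limit") {
    x <- sqrt(v / vs)
    if (weighting == "sites") log(2) + log(pracma::expint_E1(2 * x))
    else log1p(2 * x) - 2 * x
  } else {
    x <- v / vs
    if (weighting == "sites") log(pracma::expint_E1(2 * x))
    else -2 * x
  }
}

.fam_sample <- function(k, vs, v_star, mode, weighting) {
  if (weighting == "variance" && mode == "strong-limit") {
    # sqrt(v/vs) ~ Gamma(2, 2) truncated below at x0
    x0 <- sqrt(v_star / vs)
    u <- runif(k, pgamma(x0, 2, 2), 1)
    return(vs * qgamma(u, 2, 2)^2)
  }
  if (weighting == "variance" && mode == "strong-n1") {
    # v/vs ~ Exp(2) shifted truncation (memoryless)
    return(v_star + vs * stats::rexp(k, 2))
  }
  # sites: numeric inverse CDF on a log-spaced grid (density has closed
  # survival via E1 but no closed inverse)
  vmax <- vs * if (mode == "strong-limit") 400 else 20   # e^{-40} tail
  grid <- exp(seq(log(v_star), log(max(vmax, v_star * 10)), length.out = 2048))
  cdf <- .fam_cdf(grid, vs, v_star, mode, weighting)
  cdf[length(cdf)] <- 1
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], grid[keep], xout = runif(k), rule = 2)$y
}

.fit_vs_mle <- function(v, v_star, mode, weighting) {
  nll <- function(lvs) -sum(.fam_logdens(v, exp(lvs), v_star, mode, weighting))
  ctr <- log(mean(v))
  opt <- optimize(nll, c(ctr - 12, ctr + 12))
  list(vs = exp(opt$minimum), logLik = -opt$objective)
}

#' Fit the strongly selected variance scale v_s to GWAS hit variances
#'
#' Maximum-likelihood fit of the one-parameter truncated family implied by
#' the stabilizing-selection architecture to the per-locus variances `v` of
#' genome-wide significant associations, given the study's detection
#' threshold `v*`. In the pleiotropic strong-selection regime (the default
#' `mode = "strong-limit"`) the per-site density of variance contributions is
#' proportional to `exp(-2*sqrt(v/v_s))/v` on `v >= v*` (its variance-weighted
#' survival is the closed curve `G(v) = (1+2*sqrt(v/v_s))*exp(-2*sqrt(v/v_s))`
#' of [G_closed()]); the fit conditions on detection, so only loci with
#' `v >= v*` enter. `weighting` selects whether the likelihood treats each
#' locus as one *site* drawn from the per-site law (default; consistent with
#' hit tables, where every segregating site above threshold is one record) or
#' as a variance-weighted draw.
#'
#' @param gwas a data.frame from [read_gwas_tsv()] / [generate_gwas_table()],
#'   or any data.frame with a `var_explained` column (or `freq` and `beta`
#'   columns from which `2*beta^2*p*q` is computed).
#' @param v_star detection threshold on the same scale as the variances
#'   (see [detection_threshold()]).
#' @param mode `"strong-limit"` (pleiotropic limit, default) or
#'   `"strong-n1"` (single-trait strong selection).
#' @param weighting `"sites"` (default) or `"variance"`.
#' @param bootstrap number of nonparametric bootstrap resamples for the 95%
#'   CI of `v_s` (0 = none).
#' @param seed integer seed for the bootstrap.
#' @param V_P phenotypic variance used to express variances as fractions
#'   (kept as metadata; variances are not rescaled).
#' @return Object of class `vs_fit`: list with `vs` (the MLE), `v_star`,
#'   `mode`, `weighting`, `v` (per-locus variances used), `n_loci`,
#'   `logLik`, `boot` (bootstrap draws of `v_s`), `ci` (percentile 95% CI),
#'   and the call.
#' @examples
#' set.seed(1)
#' tab <- data.frame(var_explained = 1e-4 * (1 + rexp(100)))
#' fit <- fit_vs(tab, v_star = 1e-4)
#' coef(fit)
#' @seealso [summary.vs_fit()], [estimate_target_size()], [project_discovery()]
#' @export
fit_vs <- function(gwas, v_star, mode = c("strong-limit", "strong-n1"),
                   weighting = c("sites", "variance"),
                   bootstrap = 0, seed = NULL, V_P = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  v <- gwas_variances(gwas)
  if (any(v < v_star)) v <- v[v >= v_star]
  if (!length(v)) stop("no loci at or above the detection threshold")
  if (length(v) < 20)
    warning("only ", length(v), " loci above threshold; the fit will be weak")
  if (!is.null(seed)) set.seed(seed)
  mle <- .fit_vs_mle(v, v_star, mode, weighting)
  boot <- NULL; ci <- NULL
  if (bootstrap > 0) {
    boot <- vapply(seq_len(bootstrap), function(b)
      .fit_vs_mle(sample(v, replace = TRUE), v_star, mode, weighting)$vs, 0)
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  structure(list(vs = mle$vs, v_star = v_star, mode = mode,
                 weighting = weighting, v = v, n_loci = length(v),
                 logLik = mle$logLik, boot = boot, ci = ci, V_P = V_P,
                 call = match.call()),
            class = "vs_fit")
}

#' Extract per-locus variances from a GWAS table
#'
#' Uses `var_explained` when present, otherwise computes `2*beta^2*p*q` from
#' the `beta` and `freq` columns.
#'
#' @param gwas a GWAS hit data.frame.
#' @return Numeric vector of per-locus variances.
#' @export
gwas_variances <- function(gwas) {
  stopifnot(is.data.frame(gwas))
  if (!is.null(gwas$var_explained)) {
    v <- gwas$var_explained
  } else if (!is.null(gwas$beta) && !is.null(gwas$freq)) {
    v <- 2 * gwas$beta^2 * gwas$freq * (1 - gwas$freq)
  } else {
    stop("GWAS table needs a 'var_explained' column or 'freq' + 'beta'")
  }
  if (any(!is.finite(v)) || any(v < 0)) stop("invalid per-locus variances")
  v
}

#' @export
print.vs_fit <- function(x, ...) {
  cat("Fit of the strongly selected variance scale v_s\n")
  cat(sprintf("  family    : %s (%s-weighted), truncated at v* = %g\n",
              x$mode, x$weighting, x$v_star))
  cat(sprintf("  loci      : %d\n", x$n_loci))
  cat(sprintf("  v_s (MLE) : %g\n", x$vs))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI    : [%g, %g]  (%d bootstrap resamples)\n",
                x$ci[1], x$ci[2], length(x$boot)))
  invisible(x)
}

#' @export
coef.vs_fit <- function(object, ...) c(vs = object$vs)

#' @export
logLik.vs_fit <- function(object, ...) {
  structure(object$logLik, df = 1L, nobs = object$n_loci, class = "logLik")
}

#' @export
confint.vs_fit <- function(object, parm = "vs", level = 0.95, ...) {
  if (is.null(object$boot))
    stop("fit has no bootstrap sample; refit with bootstrap > 0")
  a <- (1 - level) / 2
  out <- matrix(quantile(object$boot, c(a, 1 - a)), 1, 2,
                dimnames = list("vs", sprintf("%g %%", 100 * c(a, 1 - a))))
  out
}

#' @export
residuals.vs_fit <- function(object, type = c("quantile", "uniform"), ...) {
  type <- match.arg(type)
  u <- .fam_cdf(object$v, object$vs, object$v_star, object$mode, object$weighting)
  if (type == "uniform") u else qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Simulate GWAS hit tables from a fitted v_s model
#'
#' Draws `nsim` tables of `n_loci` per-locus variances from the fitted
#' truncated family (parametric simulation, used by the bootstrap
#' goodness-of-fit test).
#'
#' @param object a [fit_vs()] object.
#' @param nsim number of tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of data.frames with column `var_explained`.
#' @export
simulate.vs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    data.frame(var_explained =
      .fam_sample(object$n_loci, object$vs, object$v_star,
                  object$mode, object$weighting)))
}

#' @export
plot.vs_fit <- function(x, log = "x", ...) {
  v <- sort(x$v)
  emp <- 1 - (seq_along(v) - 0.5) / length(v)
  plot(v, emp, log = log, xlab = "per-locus variance v",
       ylab = "fraction of loci with variance > v",
       main = sprintf("truncated %s fit (v_s = %.3g)", x$mode, x$vs), ...)
  vv <- exp(seq(log(min(v)), log(max(v)), length.out = 200))
  lines(vv, 1 - .fam_cdf(vv, x$vs, x$v_star, x$mode, x$weighting), col = 2)
  legend("topright", c("empirical", "fitted"), pch = c(1, NA),
         lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Kolmogorov-Smirnov goodness of fit for a v_s fit
#'
#' KS statistic of the observed per-locus variances against the fitted
#' truncated CDF. `method = "classic"` uses the asymptotic KS p-value (which
#' ignores that `v_s` was estimated from the same data);
#' `method = "bootstrap"` re-estimates `v_s` on each parametric resample and
#' is calibrated under estimation.
#'
#' @param fit a [fit_vs()] object.
#' @param method `"classic"` or `"bootstrap"`.
#' @param n_boot parametric bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return A list with `D`, `p`, `method`.
#' @export
ks_goodness_of_fit <- function(fit, method = c("classic", "bootstrap"),
                               n_boot = 199, seed = NULL) {
  stopifnot(inherits(fit, "vs_fit"))
  method <- match.arg(method)
  cdf <- function(v, vs) .fam_cdf(v, vs, fit$v_star, fit$mode, fit$weighting)
  ks <- suppressWarnings(ks.test(fit$v, function(v) cdf(v, fit$vs)))
  if (method == "classic")
    return(list(D = unname(ks$statistic), p = ks$p.value, method = method))
  if (!is.null(seed)) set.seed(seed)
  D0 <- unname(ks$statistic)
  Db <- vapply(seq_len(n_boot), function(b) {
    vb <- .fam_sample(fit$n_loci, fit$vs, fit$v_star, fit$mode, fit$weighting)
    vsb <- .fit_vs_mle(vb, fit$v_star, fit$mode, fit$weighting)$vs
    unname(suppressWarnings(ks.test(vb, function(v) cdf(v, vsb)))$statistic)
  }, 0)
  list(D = D0, p = (1 + sum(Db >= D0)) / (n_boot + 1), method = method)
}

#' @export
summary.vs_fit <- function(object, ks_method = "classic", ...) {
  ks <- ks_goodness_of_fit(object, method = ks_method, ...)
  out <- list(fit = object, ks = ks)
  class(out) <- "summary.vs_fit"
  out
}

#' @export
print.summary.vs_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  KS D = %.4f, p = %.3f (%s)\n", x$ks$D, x$ks$p, x$ks$method))
  invisible(x)
}

#' Mutational target size and detectable variance fraction
#'
#' Given a fitted `v_s` and the detection threshold, the expected number of
#' detected loci per target site is `2 N u * C(v*/v_s)` where `C` is the
#' strong-regime count survival (see [expected_sites_above()]); equating to
#' the observed count gives the target size `L`. The fraction of heritable
#' variance arising from the detectable (intermediate/strong) selection range
#' is then `L * 2 N u * v_s / (h2 * V_P)`, using the strong-selection
#' expectation `v_s` per site.
#'
#' @param fit a [fit_vs()] object.
#' @param params a [model_params()] object supplying `N` and `u` (theta per
#'   site); its `L` is ignored here.
#' @param h2 trait heritability (for the detectable fraction).
#' @param V_P phenotypic variance on the scale of the fitted variances
#'   (default 1, i.e. variances are fractions of V_P).
#' @param S_ref reference scaled selection coefficient for the count
#'   integral; `Inf` (default) uses the S-free strong-limit form.
#' @param sites_per_mb reporting constant for the Mb conversion (default 1e6
#'   sites per Mb).
#' @param bootstrap_ci if TRUE and the fit has bootstrap draws, propagate
#'   them to `L`, together with the Poisson sampling variation of the
#'   observed hit count (the count enters `L` linearly and is one Poisson
#'   realization of the site-generating process).
#' @param seed optional seed for the Poisson count resampling.
#' @return A list of class `target_size`: `L_detectable` (sites),
#'   `L_mb`, `detectable_fraction`, `expected_per_site`, `ci_L` (when
#'   available), plus inputs.
#' @export
estimate_target_size <- function(fit, params, h2 = 0.5, V_P = 1,
                                 S_ref = Inf, sites_per_mb = 1e6,
                                 bootstrap_ci = TRUE, seed = NULL) {
  stopifnot(inherits(fit, "vs_fit"), inherits(params, "model_params"))
  if (fit$n_loci == 0) stop("no detected loci; target size undefined")
  count_per_site <- function(vs) {
    x <- fit$v_star / vs
    csur <- if (fit$mode == "strong-limit") {
      if (is.infinite(S_ref)) .count_survival_strong_limit(x)
      else expected_sites_above(x, S_ref, n = Inf, params,
                                per_new_mutation = TRUE)
    } else {
      # n = 1 strong: v = vs * y with sojourn (2/y) e^{-y}: count survival
      # int_{x}^{inf} (2/y) e^{-y} dy = 2 E1(x)
      2 * pracma::expint_E1(x)
    }
    2 * params$N * params$u * csur
  }
  eps <- count_per_site(fit$vs)
  L <- fit$n_loci / eps
  det_frac <- function(Lv, vs) min(1, Lv * 2 * params$N * params$u * vs / (h2 * V_P))
  ciL <- NULL
  if (bootstrap_ci && !is.null(fit$boot)) {
    if (!is.null(seed)) set.seed(seed)
    nb <- rpois(length(fit$boot), fit$n_loci)
    Lb <- nb / vapply(fit$boot, count_per_site, 0)
    ciL <- unname(quantile(Lb, c(0.025, 0.975)))
  }
  structure(list(L_detectable = L, L_mb = L / sites_per_mb,
                 detectable_fraction = det_frac(L, fit$vs),
                 expected_per_site = eps, ci_L = ciL,
                 h2 = h2, V_P = V_P, fit = fit),
            class = "target_size")
}

#' @export
print.target_size <- function(x, ...) {
  cat("mutational target size (detectable selection range)\n")
  cat(sprintf("  L        : %.3g sites (%.2f Mb)\n", x$L_detectable, x$L_mb))
  if (!is.null(x$ci_L))
    cat(sprintf("  95%% CI   : [%.3g, %.3g] sites\n", x$ci_L[1], x$ci_L[2]))
  cat(sprintf("  detectable fraction of heritable variance: %.2f\n",
              x$detectable_fraction))
  invisible(x)
}

#' Projected heritability explained and hit count versus study size
#'
#' For each study size `m`: the detection threshold `v*(m)`, the fraction of
#' heritable variance explained `detectable_fraction * G(v*(m)/v_s)` (where
#' `G` is the variance-weighted survival of the fitted regime, so the
#' explained fraction climbs to `detectable_fraction` as `m` grows), and the
#' expected number of genome-wide significant hits
#' `L * 2 N u * C(v*(m)/v_s)`.
#'
#' @param fit a [fit_vs()] object.
#' @param m_grid study sizes.
#' @param params a [model_params()] supplying `N`, `u`.
#' @param target a [estimate_target_size()] result (supplies `L` and
#'   `detectable_fraction`); computed from `fit`/`params` when missing.
#' @param V_P,calibration passed to [detection_threshold()].
#' @param ... passed to [estimate_target_size()] when `target` is missing.
#' @return data.frame `(m, v_star, explained_fraction, n_hits)` with, when
#'   the fit carries bootstrap draws, `explained_lo/hi` and `hits_lo/hi`
#'   95% bands.
#' @export
project_discovery <- function(fit, m_grid, params, target = NULL, V_P = 1,
                              calibration = power_constant(), ...) {
  stopifnot(inherits(fit, "vs_fit"))
  if (is.null(target)) target <- estimate_target_size(fit, params, V_P = V_P, ...)
  Gsurv <- function(x) exp(.fam_logsurv(x, 1, fit$mode, "variance"))
  countC <- function(x) {
    if (fit$mode == "strong-limit") .count_survival_strong_limit(x)
    else 2 * pracma::expint_E1(x)
  }
  one <- function(vs, L, df) {
    vstar <- detection_threshold(m_grid, V_P, calibration)
    x <- vstar / vs
    data.frame(m = m_grid, v_star = vstar,
               explained_fraction = df * Gsurv(x),
               n_hits = L * 2 * params$N * params$u * countC(x))
  }
  out <- one(fit$vs, target$L_detectable, target$detectable_fraction)
  if (!is.null(fit$boot)) {
    mats <- lapply(fit$boot, function(vsb) {
      tb <- estimate_target_size(
        structure(modifyList(unclass(fit), list(vs = vsb)), class = "vs_fit"),
        params, h2 = target$h2, V_P = target$V_P, bootstrap_ci = FALSE)
      one(vsb, tb$L_detectable, tb$detectable_fraction)
    })
    ef <- sapply(mats, `[[`, "explained_fraction")
    nh <- sapply(mats, `[[`, "n_hits")
    out$explained_lo <- apply(ef, 1, quantile, 0.025)
    out$explained_hi <- apply(ef, 1, quantile, 0.975)
    out$hits_lo <- apply(nh, 1, quantile, 0.025)
    out$hits_hi <- apply(nh, 1, quantile, 0.975)
  }
  out
}

#' @export
predict.vs_fit <- function(object, newdata, params, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$m
  project_discovery(object, m_grid = newdata, params = params, ...)
}
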