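# Architecture summaries built on the sojourn density: expected variance per
# site versus S, MAF decompositions, and the distribution of variances among
# segregating sites G(v). Internal variance bookkeeping is per new mutation;
# multiplying by the influx 2Nu converts to stationary per-site moments.
# Ratios and G(v) are normalization-free.

# E[eps * 1(eps > c)] for the effect-size factor eps:
#   limit (pleiotropic) : eps ~ chi^2_1, identity = P(chi^2_3 > c)
#   exact n > 1         : eps = n*B, B ~ Beta(1/2, (n-1)/2),
#                         identity = P(Beta(3/2, (n-1)/2) > c/n)
#   n = 1               : eps = 1
.eps_tail_mean <- function(cc, n) {
  if (is.infinite(n)) pchisq(cc, df = 3, lower.tail = FALSE)
  else if (n == 1) as.numeric(cc < 1)
  else pbeta(pmin(cc / n, 1), 3 / 2, (n - 1) / 2, lower.tail = FALSE)
}

# P(eps > c), the site-count analogue
.eps_tail_prob <- function(cc, n) {
  if (is.infinite(n)) pchisq(cc, df = 1, lower.tail = FALSE)
  else if (n == 1) as.numeric(cc < 1)
  else pbeta(pmin(cc / n, 1), 1 / 2, (n - 1) / 2, lower.tail = FALSE)
}

#' Expected per-site contribution to genetic variance, in units of v_s
#'
#' The expected time-integrated contribution of a new mutation with scaled
#' selection coefficient `S` to the additive variance of the focal trait,
#' `E(a1^2 | S) * int 2 p q t(q; S) dq`, expressed in units of
#' `v_s = 2 w^2/(n N)`. In these units the quantity depends only on `S` (and
#' weakly on `N` through the entry frequency `1/2N`): it equals `S/2` in the
#' effectively neutral range, crosses 1 near `S ~ 3`, peaks about 30% above 1
#' near `S ~ 10`, and decays back to 1 under strong selection.
#'
#' @param S scaled selection coefficient(s), `>= 0` (vectorized).
#' @param params optional [model_params()]; supplies `N` (and the raw-unit
#'   conversion when `raw = TRUE`).
#' @param N diploid size used for the diffusion entry frequency when `params`
#'   is not given.
#' @param raw if TRUE, return raw squared-trait units per new mutation
#'   (requires `params`) instead of units of `v_s`.
#' @param m quadrature grid size.
#' @return Numeric vector of expected contributions.
#' @examples
#' expected_variance_per_site(10)   # ~ 1.3
#' expected_variance_per_site(0.01) # ~ S/2 = 0.005
#' @export
expected_variance_per_site <- function(S, params = NULL, N = 10000,
                                       raw = FALSE, m = 3000) {
  if (!is.null(params)) { stopifnot(inherits(params, "model_params")); N <- params$N }
  if (raw && is.null(params)) stop("'raw = TRUE' requires 'params'")
  out <- vapply(S, function(s1) {
    if (s1 < 0) stop("'S' must be >= 0")
    # ratio = E(a1^2|S)/v_s * int 2pq t dq = (S/4) * int 2pq t dq
    if (s1 == 0) return(0)
    (s1 / 4) * .sojourn_integral(s1, N, function(q) log(2 * q * (1 - q)), m = m)
  }, 0)
  if (raw) out * vs_unit(params) else out
}

#' Expected per-site variance versus S, with crossing point and argmax
#'
#' Evaluates [expected_variance_per_site()] on a grid of scaled selection
#' coefficients and locates (i) the crossing point `S*` where the expected
#' contribution first reaches `v_s` and (ii) the argmax and peak value.
#'
#' @param S_grid positive, sorted scaled selection coefficients.
#' @inheritParams expected_variance_per_site
#' @return A data.frame with columns `S` and `ratio` (units of `v_s`) and
#'   attributes `crossing` (S where ratio = 1), `argmax`, `peak`.
#' @examples
#' vc <- variance_ratio_curve(c(1, 3, 10, 30))
#' attr(vc, "argmax")  # ~ 9
#' @export
variance_ratio_curve <- function(S_grid, params = NULL, N = 10000, m = 3000) {
  if (any(S_grid <= 0) || is.unsorted(S_grid))
    stop("'S_grid' must be positive and sorted")
  ratio <- expected_variance_per_site(S_grid, params = params, N = N, m = m)
  f <- function(lS) expected_variance_per_site(exp(lS), params = params, N = N, m = m)
  crossing <- tryCatch(
    exp(uniroot(function(lS) f(lS) - 1, c(log(0.5), log(8)))$root),
    error = function(e) NA_real_)
  opt <- optimize(function(lS) -f(lS), c(log(2), log(60)))
  out <- data.frame(S = S_grid, ratio = ratio)
  attr(out, "crossing") <- crossing
  attr(out, "argmax") <- exp(opt$minimum)
  attr(out, "peak") <- -opt$objective
  out
}

#' Fraction of genetic variance from sites with MAF above a cutoff
#'
#' The proportion of the expected additive variance at scaled selection
#' coefficient `S` that arises from sites whose minor allele frequency
#' `min(q, 1-q)` exceeds `maf0`:
#' `int_{maf0 < q < 1-maf0} 2pq t(q;S) dq / int 2pq t(q;S) dq`.
#' Folding is applied to the integration domain (the sojourn weighting itself
#' is not assumed symmetric).
#'
#' @param S scaled selection coefficient, `>= 0`.
#' @param maf0 MAF cutoff in `[0, 0.5)`.
#' @inheritParams expected_variance_per_site
#' @return Fraction in `[0, 1]`.
#' @examples
#' maf_variance_fraction(3, 0.1)   # ~ 0.72
#' maf_variance_fraction(10, 0.1)  # ~ 0.49
#' @export
maf_variance_fraction <- function(S, maf0, params = NULL, N = 10000, m = 3000) {
  if (!is.null(params)) { stopifnot(inherits(params, "model_params")); N <- params$N }
  if (!is.numeric(maf0) || maf0 < 0 || maf0 >= 0.5)
    stop("'maf0' must lie in [0, 0.5)")
  if (maf0 == 0) return(1)
  lw <- function(q) log(2 * q * (1 - q))
  num <- .sojourn_integral(S, N, lw, lo = maf0, hi = 1 - maf0, m = m)
  den <- .sojourn_integral(S, N, lw, m = m)
  num / den
}

#' Distribution of variances among segregating sites: numeric oracle
#'
#' The proportion `G(v)` of additive genetic variance arising from segregating
#' sites whose individual contribution `v = 2 a1^2 p q` (in units of `v_s`)
#' exceeds each threshold in `v_grid`, for sites with scaled selection
#' coefficient `S` and `n` traits. In `v_s` units `v = (S/2) * eps * q(1-q)`
#' where `eps` is the effect-size factor (`chi^2_1` in the pleiotropic limit,
#' `n * Beta(1/2, (n-1)/2)` for finite `n`, constant 1 for `n = 1`), and `q`
#' is weighted by the sojourn density. The default evaluates the conditional
#' tail expectation of `eps` in closed form and quadratures over `q`
#' (deterministic); `method = "mc"` draws Monte Carlo samples instead and is
#' retained as an independent cross-check.
#'
#' This function is the oracle against which the closed forms of
#' [G_closed()] are validated.
#'
#' @param v_grid nonnegative thresholds, units of `v_s`.
#' @param S scaled selection coefficient, `>= 0`.
#' @param n number of traits; `Inf` (default) is the pleiotropic limit.
#' @param params optional [model_params()] (supplies `N` and `n`).
#' @param N diploid size when `params` absent.
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param mc_size Monte Carlo sample size (warns below 1e4).
#' @param seed seed for `method = "mc"`.
#' @param m quadrature grid size.
#' @return Object of class `architecture_curve`: data.frame `(v, G)` with
#'   attributes `S`, `n`, `regime = "numeric"`.
#' @examples
#' G_numeric(c(0, 1), S = 100)$G  # ~ c(1, 0.41)
#' @export
G_numeric <- function(v_grid, S, n = Inf, params = NULL, N = 10000,
                      method = c("quadrature", "mc"), mc_size = 1e6,
                      seed = NULL, m = 3000) {
  method <- match.arg(method)
  if (any(v_grid < 0)) stop("'v_grid' must be >= 0")
  if (!is.null(params)) {
    stopifnot(inherits(params, "model_params"))
    N <- params$N
    if (missing(n)) n <- params$n
  }
  if (method == "quadrature") {
    q <- .q_grid(N, m)
    lw <- .log_sojourn(q, S, N) + log(q * (1 - q))
    M <- max(lw); w <- exp(lw - M)
    den <- sum(diff(q) * (head(w, -1) + tail(w, -1)) / 2)
    G <- vapply(v_grid, function(v0) {
      if (v0 == 0) return(1)
      h <- .eps_tail_mean(2 * v0 / (S * q * (1 - q)), n)
      wh <- w * h
      sum(diff(q) * (head(wh, -1) + tail(wh, -1)) / 2) / den
    }, 0)
  } else {
    if (mc_size < 1e4) warning("mc_size < 1e4: the Monte Carlo oracle will be noisy")
    if (!is.null(seed)) set.seed(seed)
    qs <- sample_sojourn_frequencies(mc_size, S, N, m = m)
    eps <- if (is.infinite(n)) rchisq(mc_size, 1)
           else if (n == 1) rep(1, mc_size)
           else n * rbeta(mc_size, 1 / 2, (n - 1) / 2)
    v <- (S / 2) * eps * qs * (1 - qs)
    tot <- sum(v)
    G <- vapply(v_grid, function(v0) sum(v[v > v0]) / tot, 0)
  }
  structure(data.frame(v = v_grid, G = G),
            S = S, n = n, regime = "numeric",
            class = c("architecture_curve", "data.frame"))
}

#' Closed forms for the distribution of variances among sites
#'
#' The four regime corners of `G(v)` (thresholds `v` in units of `v_s`):
#' \describe{
#'   \item{`strong-n1`}{single trait, strong selection: `G = exp(-2v)`.}
#'   \item{`neutral-n1`}{single trait, effectively neutral:
#'     `G = sqrt(1 - v/v_max)` with `v_max = S/8` (the contribution of an
#'     allele at frequency 1/2), 0 beyond `v_max`.}
#'   \item{`strong-limit`}{pleiotropic limit, strong selection:
#'     `G = (1 + 2*sqrt(v)) * exp(-2*sqrt(v))`.}
#'   \item{`neutral-limit`}{pleiotropic limit, effectively neutral:
#'     `G = exp(-4v/S)`.}
#' }
#' These forms satisfy the mean-survival identities
#' `int_0^inf G dv = 1/2, S/12, 3/2, S/4` respectively and are validated
#' against [G_numeric()] in their corners (strong: `S >~ 30`; neutral:
#' `S <~ 1`).
#'
#' @param v thresholds, units of `v_s` (vectorized).
#' @param S scaled selection coefficient (used by the neutral forms).
#' @param regime one of `"strong-n1"`, `"neutral-n1"`, `"strong-limit"`,
#'   `"neutral-limit"`.
#' @return Numeric vector `G(v)`.
#' @examples
#' G_closed(1, 100, "strong-limit")  # (1+2)*exp(-2) ~ 0.406
#' @export
G_closed <- function(v, S, regime) {
  if (length(regime) != 1L ||
      !regime %in% c("strong-n1", "neutral-n1", "strong-limit", "neutral-limit"))
    stop("unknown regime: must be one of ",
         "'strong-n1', 'neutral-n1', 'strong-limit', 'neutral-limit'")
  if (any(v < 0)) stop("'v' must be >= 0")
  switch(regime,
    "strong-n1"     = exp(-2 * v),
    "neutral-n1"    = { vmax <- S / 8
                        sqrt(pmax(1 - v / vmax, 0)) },
    "strong-limit"  = (1 + 2 * sqrt(v)) * exp(-2 * sqrt(v)),
    "neutral-limit" = exp(-4 * v / S))
}

#' Regime tag for automatic closed-form selection
#'
#' Strong selection for `S > 30`, effectively neutral for `S < 1`, otherwise
#' `"numeric"` (no closed form; use [G_numeric()]).
#'
#' @param S scaled selection coefficient.
#' @param n number of traits (`Inf` = pleiotropic limit).
#' @return A regime string usable with [G_closed()], or `"numeric"`.
#' @export
G_regime <- function(S, n = Inf) {
  tagn <- if (is.infinite(n)) "limit" else if (n == 1) "n1" else NA
  if (is.na(tagn)) return("numeric")
  if (S > 30) paste0("strong-", tagn)
  else if (S < 1) paste0("neutral-", tagn)
  else "numeric"
}

#' Expected number of segregating sites contributing more than v
#'
#' Expected number of segregating sites per target site whose contribution to
#' the focal trait's additive variance exceeds `v` (units of `v_s`):
#' `2 N u * int t(q; S) P(eps > 2v/(S q (1-q))) dq`. This is the site-count
#' analogue of `G(v)` (the same integrand without the variance weight), used
#' for mutational-target-size estimation.
#'
#' @param v threshold(s), units of `v_s`, `> 0` (the count diverges
#'   logarithmically at `v = 0` only through the entry-frequency cutoff).
#' @param S scaled selection coefficient.
#' @param n number of traits (`Inf` = limit).
#' @param params a [model_params()] object (supplies `N` and `u`).
#' @param per_new_mutation if TRUE drop the `2Nu` influx factor and return
#'   the expected sojourn time above the threshold per new mutation.
#' @param m quadrature grid size.
#' @return Expected counts (vectorized over `v`).
#' @export
expected_sites_above <- function(v, S, n = Inf, params,
                                 per_new_mutation = FALSE, m = 3000) {
  stopifnot(inherits(params, "model_params"))
  if (any(v < 0)) stop("'v' must be >= 0")
  N <- params$N
  q <- .q_grid(N, m)
  lt <- .log_sojourn(q, S, N)
  M <- max(lt); tt <- exp(lt - M)
  cnt <- vapply(v, function(v0) {
    h <- if (v0 == 0) rep(1, length(q))
         else .eps_tail_prob(2 * v0 / (S * q * (1 - q)), n)
    th <- tt * h
    exp(M) * sum(diff(q) * (head(th, -1) + tail(th, -1)) / 2)
  }, 0)
  if (per_new_mutation) cnt else 2 * N * params$u * cnt
}

# strong-limit count survival, S-free: expected sojourn (in units where the
# strong sojourn is t = (2/y) e^{-y}, y = S q) above a variance threshold x
# in v_s units: C(x) = int_0^inf (2/y) e^{-y} P(chi^2_1 > 2x/y) dy.
# Converges for x > 0 without an entry-frequency cutoff.
.count_survival_strong_limit <- function(x) {
  vapply(x, function(x0) {
    if (x0 <= 0) stop("strong-limit count survival needs v > 0")
    integrate(function(y) (2 / y) * exp(-y) *
                pchisq(2 * x0 / y, df = 1, lower.tail = FALSE),
              0, Inf, rel.tol = 1e-9)$value
  }, 0)
}

#' Sample allele frequencies from the normalized sojourn density
#'
#' Draws per-segregating-site snapshot frequencies proportional to
#' `t(q; S)` by inverse-CDF interpolation on the quadrature grid.
#'
#' @param k number of draws.
#' @param S scaled selection coefficient.
#' @param N diploid population size.
#' @param m grid size.
#' @return Numeric vector of frequencies in `(0, 1)`.
#' @export
sample_sojourn_frequencies <- function(k, S, N, m = 3000) {
  q <- .q_grid(N, m)
  lt <- .log_sojourn(q, S, N)
  M <- max(lt); tt <- exp(lt - M)
  dq <- diff(q)
  seg <- dq * (head(tt, -1) + tail(tt, -1)) / 2
  cdf <- c(0, cumsum(seg)) / sum(seg)
  # strictly increasing knots for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], q[keep], xout = runif(k), rule = 2)$y
}
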