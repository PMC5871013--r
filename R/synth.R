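# Synthetic-architecture and synthetic-GWAS generation with the model's exact
# statistical structure: frequencies from the normalized sojourn density
# (an equilibrium per-segregating-site snapshot), effect sizes from the
# selection<->effect geometry. Demography-aware tables come from forward_sim
# instead.

#' Specification for synthetic architecture / GWAS generation
#'
#' @param params a [model_params()] object.
#' @param S scaled selection coefficient(s): a single value (point mass) or a
#'   vector of grid points.
#' @param weights mixture weights over `S` (default uniform); normalized to
#'   sum to 1.
#' @param m study size (sets the detection threshold via
#'   [detection_threshold()]).
#' @param V_P phenotypic variance in the same (squared-trait) units as the
#'   generated per-locus variances.
#' @param mode effect-size mode, `"limit"` (pleiotropic limit) or `"exact"`.
#' @param n_sites optional fixed number of segregating sites; default draws
#'   `Poisson(L * weight_j * 2Nu * Tbar(S_j))` per mixture component, the
#'   equilibrium expectation for target size `L`.
#' @param noise_se optional standard error added to effect estimates
#'   (`beta_hat = beta + N(0, se^2)`); off by default.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(params, S, weights = NULL, m = 1.5e5, V_P = 1,
                       mode = c("limit", "exact"), n_sites = NULL,
                       noise_se = 0, seed = 1) {
  stopifnot(inherits(params, "model_params"), all(S >= 0), m > 0, V_P > 0)
  mode <- match.arg(mode)
  if (is.null(weights)) weights <- rep(1 / length(S), length(S))
  if (length(weights) != length(S) || any(weights < 0))
    stop("'weights' must be nonnegative and match 'S'")
  weights <- weights / sum(weights)
  structure(list(params = params, S = S, weights = weights, m = m, V_P = V_P,
                 mode = mode, n_sites = n_sites, noise_se = noise_se,
                 seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic per-site architecture table
#'
#' Draws segregating sites with the model's joint law: the selection
#' coefficient from the spec's mixture, the frequency from the normalized
#' sojourn density `t(q; S)`, and the focal-trait effect from the geometry
#' given `S`. Per-site variance contributions are `v = 2 a1^2 p q` (trait
#' units) with `v_vs = v / v_s`.
#'
#' @param spec a [synth_spec()] object.
#' @return data.frame `(S, q, a1, v, v_vs)` with attributes `spec` and
#'   `seed`.
#' @export
generate_architecture <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  p <- spec$params
  counts <- if (!is.null(spec$n_sites)) {
    drop(rmultinom(1, spec$n_sites, spec$weights))
  } else {
    vapply(seq_along(spec$S), function(j) {
      Tbar <- .sojourn_integral(spec$S[j], p$N, function(q) rep(0, length(q)))
      rpois(1, p$L * spec$weights[j] * 2 * p$N * p$u * Tbar)
    }, 0)
  }
  parts <- lapply(seq_along(spec$S), function(j) {
    k <- counts[j]
    if (k == 0) return(NULL)
    S <- spec$S[j]
    q <- sample_sojourn_frequencies(k, S, p$N)
    a1 <- sample_effect(S / (2 * p$N), p, n_draws = k, mode = spec$mode)
    data.frame(S = S, q = q, a1 = a1, v = 2 * a1^2 * q * (1 - q))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(S = numeric(), q = numeric(),
                                      a1 = numeric(), v = numeric())
  out$v_vs <- out$v / vs_unit(p)
  attr(out, "spec") <- spec
  attr(out, "seed") <- spec$seed
  out
}

#' Generate a synthetic GWAS hit table
#'
#' Applies the study's detection threshold `v* = c V_P / m` to a generated
#' architecture and formats the surviving sites as a GWAS table (`snp`,
#' `freq`, `beta`, `var_explained`, `n`). In noiseless mode (default) the
#' thresholding is exact: every emitted locus has `v >= v*`. With
#' `noise_se > 0` the reported `beta` carries estimation noise and
#' `var_explained` is recomputed from the noisy `beta`.
#'
#' @param spec a [synth_spec()] object.
#' @param calibration power calibration constant (see [power_constant()]).
#' @return data.frame GWAS table with attributes `v_star`, `spec`, `seed`,
#'   `n_sites_total`. Empty (with a warning) if nothing exceeds threshold.
#' @export
generate_gwas_table <- function(spec, calibration = power_constant()) {
  arch <- generate_architecture(spec)
  v_star <- detection_threshold(spec$m, spec$V_P, calibration)
  hit <- arch[arch$v >= v_star, , drop = FALSE]
  if (nrow(hit) == 0)
    warning("no loci exceed the detection threshold at m = ", spec$m)
  beta <- hit$a1
  if (spec$noise_se > 0) beta <- beta + rnorm(nrow(hit), 0, spec$noise_se)
  out <- data.frame(
    snp = if (nrow(hit)) sprintf("site_%06d", seq_len(nrow(hit))) else character(),
    freq = hit$q,
    beta = beta,
    var_explained = 2 * beta^2 * hit$q * (1 - hit$q),
    n = if (nrow(hit)) spec$m else numeric())
  attr(out, "v_star") <- v_star
  attr(out, "spec") <- spec
  attr(out, "seed") <- spec$seed
  attr(out, "n_sites_total") <- nrow(arch)
  out
}
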