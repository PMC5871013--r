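#' Model parameters for the stabilizing-selection architecture model
#'
#' Bundles the population-genetic and trait-space parameters: the number of
#' traits `n` (real-valued, so an effective number of traits n_e may be used
#' directly), the strength of stabilizing selection `w` (trait units per unit
#' fitness; larger `w` means weaker selection), the diploid population size
#' `N`, the per-site per-gamete mutation rate `u`, and the mutational target
#' size `L` in sites. Derived quantities: `U = L*u` (genome-wide mutation rate
#' per gamete), `theta = 4*N*u` (per-site population mutation rate) and
#' `v_s = 2*w^2/(n*N)`, the expected contribution to additive genetic variance
#' of a strongly selected site, which is the unit of variance used throughout.
#'
#' The model's approximations assume `theta << 1` and `1 >> U >> 1/(2N)`;
#' violations are reported as warnings, not errors, because the approximations
#' degrade gracefully.
#'
#' @param n number of traits (pleiotropy), real `>= 1`.
#' @param w strength of stabilizing selection, positive.
#' @param N diploid population size, positive integer.
#' @param u per-site per-gamete mutation rate, positive.
#' @param L mutational target size in sites, positive integer.
#' @return An object of class `model_params`: a list with fields `n`, `w`,
#'   `N`, `u`, `L`, `U`, `theta`, `vs`.
#' @examples
#' p <- model_params(n = 10, w = 1, N = 10000, u = 1e-8, L = 1e6)
#' vs_unit(p)
#' @seealso [vs_unit()], [selection_from_effect()], [read_model_config()]
#' @export
model_params <- function(n = 10, w = 1, N = 10000, u = 1e-8, L = 1e6) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(w), length(w) == 1L, is.finite(w),
            is.numeric(N), length(N) == 1L, is.finite(N),
            is.numeric(u), length(u) == 1L, is.finite(u),
            is.numeric(L), length(L) == 1L, is.finite(L))
  if (n < 1) stop("'n' (number of traits) must be >= 1")
  if (w <= 0) stop("'w' (selection strength) must be positive")
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer")
  if (u <= 0) stop("'u' must be positive")
  if (L < 1 || L != round(L)) stop("'L' must be a positive integer")

  theta <- 4 * N * u
  U <- L * u
  if (theta > 0.1)
    warning("theta = 4Nu = ", signif(theta, 3),
            " > 0.1: the infinite-sites assumption is strained")
  if (U >= 1 || U <= 1 / (2 * N))
    warning("U = L*u = ", signif(U, 3),
            " outside (1/2N, 1): the polygenic regime 1 >> U >> 1/2N is strained")

  structure(list(n = n, w = w, N = as.integer(N), u = u, L = L,
                 U = U, theta = theta, vs = 2 * w^2 / (n * N)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Stabilizing-selection model parameters\n")
  cat(sprintf("  n (traits)          : %g\n", x$n))
  cat(sprintf("  w (selection scale)  : %g\n", x$w))
  cat(sprintf("  N (diploid size)     : %d\n", x$N))
  cat(sprintf("  u (per-site mut rate): %g\n", x$u))
  cat(sprintf("  L (target size)      : %g sites\n", x$L))
  cat(sprintf("  U = L*u              : %g\n", x$U))
  cat(sprintf("  theta = 4Nu          : %g\n", x$theta))
  cat(sprintf("  v_s = 2w^2/(nN)      : %g\n", x$vs))
  invisible(x)
}

#' Unit of variance: expected contribution of a strongly selected site
#'
#' Returns `v_s = 2*w^2/(n*N)`, the expected contribution to additive genetic
#' variance of a site under strong selection (`S > 30` or so), which is
#' independent of the selection coefficient. All architecture statistics are
#' reported in units of `v_s` unless stated otherwise.
#'
#' @param params a [model_params()] object.
#' @return The variance unit, a positive scalar in squared trait units.
#' @examples
#' vs_unit(model_params(n = 1, w = 1, N = 1, u = 1e-8, L = 10))  # 2
#' @export
vs_unit <- function(params) {
  stopifnot(inherits(params, "model_params"))
  2 * params$w^2 / (params$n * params$N)
}

#' Selection coefficient of an effect vector
#'
#' The fitness cost of a variant is determined by the squared Euclidean size
#' of its effect vector in the n-dimensional trait space:
#' `s = |a|^2 / w^2 = sum(a_i^2) / w^2`, and in scaled units `S = 2*N*s`.
#'
#' @param a numeric vector of per-trait effects (trait units). Any length is
#'   accepted; its Euclidean norm is what matters.
#' @param params a [model_params()] object.
#' @return An object of class `selection_coef`: list with `s` (unscaled) and
#'   `S = 2Ns` (scaled).
#' @examples
#' p <- model_params(n = 4, w = 2, N = 5000, u = 1e-8, L = 1e4)
#' selection_from_effect(rep(0.1, 4), p)  # s = 0.01, S = 100
#' @export
selection_from_effect <- function(a, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(a) || any(!is.finite(a)))
    stop("effect vector 'a' must be finite numeric")
  s <- sum(a^2) / params$w^2
  if (s > 0.1)
    warning("a^2/w^2 = ", signif(s, 3),
            " > 0.1: the weak-effect approximation is strained")
  structure(list(s = s, S = 2 * params$N * s), class = "selection_coef")
}

#' @export
print.selection_coef <- function(x, ...) {
  cat(sprintf("selection coefficient: s = %g (S = 2Ns = %g)\n", x$s, x$S))
  invisible(x)
}

#' Read model parameters from a YAML or JSON config file
#'
#' The file must provide the keys `n`, `w`, `N`, `u`, `L` (extra keys are
#' ignored). Format is chosen by extension: `.json` is parsed as JSON,
#' anything else as YAML (of which JSON is a subset).
#'
#' @param path path to the config file.
#' @return A [model_params()] object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else .read_yaml_cfg(path)
  need <- c("n", "w", "N", "u", "L")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing keys: ", paste(miss, collapse = ", "))
  model_params(n = cfg$n, w = cfg$w, N = cfg$N, u = cfg$u, L = cfg$L)
}
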