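#' Density of the focal-trait effect size given the selection coefficient
#'
#' Mutations with selection coefficient `s` lie on the hypersphere of radius
#' `a = w*sqrt(s)` in the n-dimensional trait space; with isotropic mutation
#' their focal-trait effect `a1` has density proportional to the volume of the
#' (n-2)-dimensional cross section with projection `a1`:
#' `phi_n(a1 | a) = C/a * (1 - (a1/a)^2)^((n-3)/2)` on `(-a, a)`, with
#' `C = Gamma(n/2) / (Gamma((n-1)/2) * sqrt(pi))`. For `n = 3` this is
#' uniform on `(-a, a)`; as `n` grows it approaches `N(0, a^2/n)`. The
#' normalization is computed from the Gamma-function form (the second moment
#' `a^2/n` is verified against it in the test suite rather than trusted from
#' any printed constant).
#'
#' The case `n = 1` is discrete (`a1 = +/-a` with probability 1/2 each) and
#' deliberately not representable as a density; use [effect_distribution()].
#' For `n = 2` the density is integrably singular at `+/-a`; quadrature
#' against it should use the change of variables `a1 = a*sin(theta)`.
#'
#' @param a1 numeric vector of focal-trait effect sizes.
#' @param a positive scalar, the mutation size (Euclidean norm).
#' @param n number of traits, real `> 1` (use [effect_distribution()] for
#'   `n = 1`).
#' @return Density values; 0 outside `(-a, a)`.
#' @examples
#' effect_density(0.2, a = 1, n = 3)  # 1/2: uniform on (-1, 1)
#' @export
effect_density <- function(a1, a, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a real number >= 1")
  if (n == 1)
    stop("n = 1 is a two-point distribution at +/-a, not a density; ",
         "use effect_distribution()")
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("'a' must be positive")
  x <- a1 / a
  out <- numeric(length(x))
  inside <- is.finite(x) & abs(x) < 1
  logC <- lgamma(n / 2) - lgamma((n - 1) / 2) - 0.5 * log(pi)
  out[inside] <- exp(logC + ((n - 3) / 2) * log1p(-x[inside]^2)) / a
  out
}

#' Distribution object for the focal-trait effect given mutation size
#'
#' Returns a small object describing the conditional law of the focal-trait
#' effect `a1` given the mutation size `a` and the number of traits `n`:
#' discrete (`+/-a` with probability 1/2) when `n = 1`, continuous with
#' density [effect_density()] when `n > 1`.
#'
#' @param a positive mutation size.
#' @param n number of traits, real `>= 1`.
#' @return A list of class `effect_dist` with fields `type`
#'   (`"discrete"`/`"continuous"`), `a`, `n`, and for the discrete case
#'   `atoms`/`prob`.
#' @export
effect_distribution <- function(a, n) {
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  if (n == 1)
    structure(list(type = "discrete", a = a, n = 1,
                   atoms = c(-a, a), prob = c(0.5, 0.5)),
              class = "effect_dist")
  else
    structure(list(type = "continuous", a = a, n = n), class = "effect_dist")
}

#' @export
print.effect_dist <- function(x, ...) {
  if (x$type == "discrete")
    cat(sprintf("effect distribution (n = 1): a1 = +/-%g with probability 1/2\n", x$a))
  else
    cat(sprintf("effect distribution: phi_n(a1 | a = %g), n = %g traits\n", x$a, x$n))
  invisible(x)
}

#' Conditional second moment of the focal-trait effect
#'
#' `E(a1^2 | s) = a^2/n = (w^2/n) * s`, independent of whether the exact
#' finite-n law or its pleiotropic (normal) limit is used.
#'
#' @param s selection coefficient (unscaled), or a `selection_coef` object.
#' @param params a [model_params()] object.
#' @return `(w^2/n) * s`.
#' @export
conditional_second_moment <- function(s, params) {
  stopifnot(inherits(params, "model_params"))
  if (inherits(s, "selection_coef")) s <- s$s
  (params$w^2 / params$n) * s
}

#' Sample focal-trait effect sizes given a selection coefficient
#'
#' In the pleiotropic limit (`mode = "limit"`, the default) draws
#' `a1 ~ N(0, (w^2/n) s)`; equivalently `a1^2 = (w^2/n) s * eps` with
#' `eps ~ chi^2_1`, which is the canonical internal representation used by the
#' architecture calculations. In exact mode the draw follows the finite-n
#' geometry: `a1 = a * X` with `X^2 ~ Beta(1/2, (n-1)/2)` and a random sign
#' (for `n = 1` this reduces to `a1 = +/- w*sqrt(s)`).
#'
#' @param s selection coefficient (unscaled), scalar, or `selection_coef`.
#' @param params a [model_params()] object.
#' @param n_draws number of draws.
#' @param mode `"limit"` (pleiotropic limit) or `"exact"` (finite n).
#' @param seed optional integer seed (set before drawing when supplied).
#' @return Numeric vector of `n_draws` effect sizes (trait units).
#' @examples
#' p <- model_params()
#' a1 <- sample_effect(0.01, p, n_draws = 1000, seed = 1)
#' mean(a1^2)  # ~ (w^2/n) * s
#' @export
sample_effect <- function(s, params, n_draws = 1L,
                          mode = c("limit", "exact"), seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  mode <- match.arg(mode)
  if (inherits(s, "selection_coef")) s <- s$s
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (s == 0) return(numeric(n_draws))
  n <- params$n
  if (mode == "limit") {
    sqrt(params$w^2 / n * s) * rnorm(n_draws)
  } else {
    a <- params$w * sqrt(s)
    sgn <- sample(c(-1, 1), n_draws, replace = TRUE)
    if (n == 1) a * sgn
    else a * sgn * sqrt(rbeta(n_draws, 1 / 2, (n - 1) / 2))
  }
}
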