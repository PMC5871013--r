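# Diffusion sojourn-time machinery for the underdominant drift
# M(q) = s*p*q*(q - 1/2), V(q) = p*q/(2N); psi(y) = exp(S*y*(1-y)).
# Writing psi(y) = e^{S/4} exp(-S (y-1/2)^2), the e^{S/4} factors cancel in
# the sojourn density, so everything is computed from
#   J(a, b) = int_a^b exp(-S (y - 1/2)^2) dy
# which has an error-function closed form. All heavy integrands are handled
# on the log scale so arbitrarily strong selection cannot overflow.

# log of J(a,b); falls back to a midpoint rule if the pnorm difference
# underflows (deep-tail, very narrow intervals such as (0, 1/2N) at large S)
.logJ <- function(a, b, S) {
  if (S < 1e-12) return(log(b - a))
  r <- sqrt(2 * S)
  d <- pnorm((b - 0.5) * r) - pnorm((a - 0.5) * r)
  if (d > 0 && is.finite(log(d))) {
    0.5 * (log(pi) - log(S)) + log(d)
  } else {
    m <- (a + b) / 2
    log(b - a) - S * (m - 0.5)^2
  }
}

.logJ_vec <- function(a, b, S) {
  # vectorized over a (b scalar)
  if (S < 1e-12) return(log(b - a))
  r <- sqrt(2 * S)
  d <- pnorm((b - 0.5) * r) - pnorm((a - 0.5) * r)
  out <- 0.5 * (log(pi) - log(S)) + log(d)
  bad <- !is.finite(out)
  if (any(bad)) {
    m <- (a[bad] + b) / 2
    out[bad] <- log(b - a[bad]) - S * (m - 0.5)^2
  }
  out
}

# default frequency grid: log-spaced from q0 = 1/2N up to 1/2, mirrored
.q_grid <- function(N, m = 3000) {
  q0 <- 1 / (2 * N)
  g <- exp(seq(log(q0), log(0.5), length.out = m))
  sort(unique(c(g, 1 - g)))
}

# log sojourn-time density t(q) for a new mutation entering at q0 = 1/2N:
#   t(q) = 2 J(0,q0) J(q,1) / (V(q) psi~(q) J(0,1))   for q >= q0
# (mirrored for q < q0), with psi~(q) = exp(-S (q-1/2)^2); time in generations.
.log_sojourn <- function(q, S, N) {
  q0 <- 1 / (2 * N)
  lJ01 <- .logJ(0, 1, S)
  out <- numeric(length(q))
  up <- q >= q0
  if (any(up)) {
    out[up] <- log(2) + .logJ(0, q0, S) + .logJ_vec(q[up], 1, S) +
      S * (q[up] - 0.5)^2 + log(2 * N) - log(q[up] * (1 - q[up])) - lJ01
  }
  if (any(!up)) {
    # mirrored form below the entry frequency
    lo <- q[!up]
    lJq0_1 <- .logJ(q0, 1, S)
    lJ0q <- vapply(lo, function(x) .logJ(0, x, S), 0)
    out[!up] <- log(2) + lJq0_1 + lJ0q +
      S * (lo - 0.5)^2 + log(2 * N) - log(lo * (1 - lo)) - lJ01
  }
  out
}

# trapezoid integral of exp(logf) over x, stabilized by the max log
.logtrapz <- function(x, logf) {
  M <- max(logf)
  if (!is.finite(M)) return(0)
  y <- exp(logf - M)
  exp(M) * sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Sojourn-time density of a new mutation under stabilizing selection
#'
#' Expected time (generations) spent at frequency `q` per new mutation, for
#' the diffusion with drift `M(q) = s*p*q*(q - 1/2)` (underdominance with the
#' population mean at the optimum) and variance `V(q) = p*q/(2N)`, entering at
#' `q0 = 1/(2N)`. With `psi(y) = exp(S*y*(1-y))` the density for `q >= q0` is
#' `t(q) = 2 * int_0^q0 psi * int_q^1 psi / (V(q) * psi(q) * int_0^1 psi)`
#' and the mirrored form below `q0`. For `S = 0` this reduces to `t(q) = 2/q`
#' (for `q >= q0`).
#'
#' @param S scaled selection coefficient `2Ns`, `>= 0`.
#' @param N diploid population size (`>= 100`; the diffusion scaling needs
#'   a reasonably large `N`).
#' @param q_grid frequencies at which to evaluate, all within `(0, 1)`.
#'   Default: log-spaced grid from `1/2N` to `1 - 1/2N`.
#' @param m grid size used when `q_grid` is NULL.
#' @return Object of class `sojourn_density`: list with `q`, `t` (time at
#'   frequency, generations), `log_t`, `S`, `N`.
#' @examples
#' sd0 <- sojourn_density(0, N = 1000)
#' # neutral: t(q) = 2/q
#' max(abs(sd0$t * sd0$q - 2))
#' @export
sojourn_density <- function(S, N, q_grid = NULL, m = 3000) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 0)
    stop("'S' must be a single finite value >= 0")
  if (!is.numeric(N) || length(N) != 1L || N < 100)
    stop("'N' must be >= 100")
  if (is.null(q_grid)) q_grid <- .q_grid(N, m)
  if (any(q_grid <= 0 | q_grid >= 1)) stop("'q_grid' must lie within (0, 1)")
  lt <- .log_sojourn(q_grid, S, N)
  structure(list(q = q_grid, t = exp(lt), log_t = lt, S = S, N = N),
            class = "sojourn_density")
}

#' @export
print.sojourn_density <- function(x, ...) {
  cat(sprintf("sojourn-time density: S = %g, N = %d, %d grid points on (%g, %g)\n",
              x$S, as.integer(x$N), length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  total sojourn time  : %g generations\n",
              .logtrapz(x$q, x$log_t)))
  cat(sprintf("  int 2pq t(q) dq     : %g\n",
              .logtrapz(x$q, x$log_t + log(2 * x$q * (1 - x$q)))))
  invisible(x)
}

# weighted sojourn integrals int w(q) t(q) dq with w given as log-weights;
# restricted to (lo, hi) when given. Endpoints are inserted so that MAF
# cutoffs do not depend on grid placement.
.sojourn_integral <- function(S, N, log_w, lo = NULL, hi = NULL, m = 3000) {
  q <- .q_grid(N, m)
  if (!is.null(lo)) {
    q <- sort(unique(c(q[q >= lo & q <= hi], lo, hi)))
    q <- q[q > 0 & q < 1]
  }
  .logtrapz(q, .log_sojourn(q, S, N) + log_w(q))
}
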