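# Forward Wright-Fisher simulation of per-site allelic trajectories under the
# marginal underdominant drift, with arbitrary piecewise demography. The
# per-site reduction is valid at the mean-at-optimum steady state; the full
# multilocus model that justifies it lives in simulate_multilocus().

.check_s <- function(s) {
  # max |E(dq)| over q is s * max pq|q-1/2| = s/(12*sqrt(3)); guard the
  # discrete WF update well before that becomes a macroscopic jump
  if (s < 0) stop("'s' must be >= 0")
  if (s / (12 * sqrt(3)) > 0.5)
    stop("selection coefficient too large for the discrete Wright-Fisher ",
         "update: expected drift step would exceed 0.5")
}

#' Simulate per-site allelic trajectories
#'
#' Each replicate is one new mutation: it enters at frequency `1/(2N(t0))`
#' and follows `q <- Binomial(2N(t), q + s*p*q*(q - 1/2)) / (2N(t))` to loss,
#' fixation, or the present (the last generation of the demography). The
#' origin time `t0` is drawn proportional to the mutational influx `2 N(t) u`
#' (`origin_policy = "uniform-influx"`) or fixed at `origin_gen`
#' (`"fixed-time"`; with a constant demography long enough for absorption
#' this yields the per-new-mutation time-integrated statistics that the
#' diffusion predicts).
#'
#' @param s unscaled selection coefficient, `>= 0`.
#' @param demog a [demography()] object.
#' @param origin_policy `"uniform-influx"` or `"fixed-time"`.
#' @param n_reps number of replicate mutations.
#' @param seed integer seed (required for reproducibility; all randomness
#'   flows through R's RNG).
#' @param origin_gen origin generation for `"fixed-time"` (default 1).
#' @param params optional [model_params()]; when given, a per-replicate
#'   effect-size factor `eps ~ chi^2_1` (pleiotropic limit) is drawn so the
#'   ensemble carries variance contributions `2 a1^2 p q` with
#'   `a1^2 = (w^2/n) s eps`.
#' @return Object of class `trajectory_ensemble`: data.frame with columns
#'   `origin`, `q_final` (0 lost, 1 fixed), `segregating`, `sum_pq` (lifetime
#'   integrated heterozygosity `sum_t p_t q_t`), `eps`, plus attributes `s`,
#'   `demography`, `seed`.
#' @examples
#' d <- demography_constant(500, 2000)
#' te <- simulate_site(0.001, d, "fixed-time", n_reps = 200, seed = 1)
#' mean(te$segregating)
#' @export
simulate_site <- function(s, demog, origin_policy = c("uniform-influx", "fixed-time"),
                          n_reps, seed = NULL, origin_gen = 1L, params = NULL) {
  stopifnot(inherits(demog, "demography"))
  origin_policy <- match.arg(origin_policy)
  .check_s(s)
  if (!is.null(seed)) set.seed(seed)
  Nt <- demog$N
  Tt <- length(Nt)
  origin <- if (origin_policy == "uniform-influx") {
    sort(sample.int(Tt, n_reps, replace = TRUE, prob = as.numeric(Nt)))
  } else {
    if (origin_gen < 1 || origin_gen > Tt) stop("'origin_gen' out of range")
    rep(as.integer(origin_gen), n_reps)
  }
  sim <- cpp_wf_demography(s, Nt, as.integer(origin))
  eps <- rchisq(n_reps, 1)
  out <- data.frame(origin = origin,
                    q_final = sim$q_final,
                    segregating = sim$q_final > 0 & sim$q_final < 1,
                    sum_pq = sim$sum_pq,
                    eps = eps)
  structure(out, s = s, demography = demog, seed = seed, params = params,
            class = c("trajectory_ensemble", "data.frame"))
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory ensemble: s = %g, %d replicates, %d segregating, %d fixed\n",
              attr(x, "s"), nrow(x), sum(x$segregating), sum(x$q_final >= 1)))
  invisible(x)
}

#' Per-mutation time-integrated variance at constant N (simulation)
#'
#' Runs new-mutation replicates at constant `N` to absorption and returns the
#' Monte Carlo estimate of the expected time-integrated contribution to
#' additive variance per new mutation, in units of `v_s`:
#' `(S/2) * E[sum_t p_t q_t]` (the chi^2 effect factor is marginalized
#' analytically). This is the simulation counterpart of
#' [expected_variance_per_site()].
#'
#' @param S scaled selection coefficient `2Ns`.
#' @param N diploid population size.
#' @param n_reps number of replicate mutations.
#' @param seed integer seed.
#' @return A list with `estimate` (units of `v_s`), `se` (Monte Carlo
#'   standard error), `n_reps`, `n_fixed`.
#' @examples
#' r <- integrated_variance_sim(10, N = 500, n_reps = 5000, seed = 1)
#' r$estimate  # noisy ~ 1.3
#' @export
integrated_variance_sim <- function(S, N, n_reps, seed = NULL) {
  s <- S / (2 * N)
  .check_s(s)
  if (!is.null(seed)) set.seed(seed)
  agg <- cpp_wf_integrated_pq(s, as.integer(N), as.numeric(n_reps), FALSE)
  mean_acc <- agg$sum / agg$reps
  var_acc <- (agg$sumsq - agg$reps * mean_acc^2) / (agg$reps - 1)
  list(estimate = (S / 2) * mean_acc,
       se = (S / 2) * sqrt(var_acc / agg$reps),
       n_reps = n_reps, n_fixed = agg$n_fixed)
}

#' Variance by selection coefficient under a demography
#'
#' For each `s` in `s_grid`, simulates `n_reps` replicate mutations with
#' origins proportional to the influx `2 N(t) u` and summarizes the extant
#' (present-day) variance they imply. Cumulative variance per target site is
#' reported in units of `4 u w^2 / n` (the equilibrium per-site expectation
#' for a strongly selected site); per-segregating-site contributions are in
#' units of `w^2/n`. The chi^2 effect-size factor is marginalized analytically
#' (its mean is 1), so a site's expected contribution is `2 s p q` in `w^2/n`
#' units; thresholds are applied to that quantity.
#'
#' @param s_grid unscaled selection coefficients.
#' @param demog a [demography()] object.
#' @param n_reps replicates per `s`.
#' @param thresholds contribution thresholds, units of `w^2/n`.
#' @param seed integer seed.
#' @return data.frame with one row per `s`: `s`, `n_seg` (segregating
#'   replicates), `p_seg`, `cum_var` (total per-site variance, units
#'   `4 u w^2/n`), one column `cum_above_<thr>` per threshold, and
#'   `q90_contrib` (90th percentile of per-segregating-site contribution,
#'   units `w^2/n`). Attribute `origin_by_s` holds the origin generations of
#'   segregating replicates for age analyses.
#' @export
variance_by_s_under_demography <- function(s_grid, demog, n_reps,
                                           thresholds = c(1e-5, 1e-4),
                                           seed = NULL) {
  stopifnot(inherits(demog, "demography"))
  if (!is.null(seed)) set.seed(seed)
  W <- sum(as.numeric(demog$N))   # sum_t N(t); influx weight / (2u)
  origins <- list()
  rows <- lapply(s_grid, function(s) {
    te <- simulate_site(s, demog, "uniform-influx", n_reps)
    seg <- te$segregating
    qf <- te$q_final[seg]
    contrib <- 2 * s * qf * (1 - qf)          # units w^2/n, eps marginalized
    origins[[as.character(s)]] <<- te$origin[seg]
    # per-site cumulative variance / (4 u w^2/n) = s * W * mean(pq * 1(above))
    cum <- function(v0) {
      if (n_reps == 0) return(0)
      (W / n_reps) * s * sum(qf * (1 - qf) * (contrib > v0))
    }
    out <- data.frame(s = s, n_seg = sum(seg), p_seg = mean(seg),
                      cum_var = cum(-Inf))
    for (v0 in thresholds) out[[paste0("cum_above_", format(v0))]] <- cum(v0)
    out$q90_contrib <- if (any(seg)) unname(quantile(contrib, 0.9)) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "origin_by_s") <- origins
  out
}
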