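test_that("expected variance per site has the right regime behavior", {
  # effectively neutral: ratio ~ S/2
  expect_equal(expected_variance_per_site(0.01) / 0.01, 0.5, tolerance = 0.02)
  expect_equal(expected_variance_per_site(0), 0)
  # strong asymptote: ratio -> 1 (at N large enough that S << 2N)
  expect_equal(expected_variance_per_site(1000, N = 1e5), 1, tolerance = 0.02)
  # intermediate maximum ~30% above the asymptote near S ~ 10
  expect_equal(expected_variance_per_site(10), 1.3, tolerance = 0.05)
  expect_error(expected_variance_per_site(-2), "S")
})

test_that("variance-ratio curve locates the crossing and the peak", {
  vc <- variance_ratio_curve(c(0.1, 1, 3, 10, 30, 100))
  expect_equal(vc$ratio, expected_variance_per_site(vc$S))
  expect_true(attr(vc, "crossing") > 2 && attr(vc, "crossing") < 4)
  expect_true(attr(vc, "argmax") > 7 && attr(vc, "argmax") < 14)
  expect_true(attr(vc, "peak") > 1.25 && attr(vc, "peak") < 1.35)
  expect_error(variance_ratio_curve(c(3, 1)), "sorted")
})

test_that("MAF decomposition of variance matches the regime expectations", {
  expect_equal(maf_variance_fraction(3, 0), 1)
  expect_error(maf_variance_fraction(3, 0.5), "maf0")
  expect_equal(maf_variance_fraction(3, 0.1), 0.72, tolerance = 0.01)
  expect_equal(maf_variance_fraction(10, 0.1), 0.49, tolerance = 0.01)
  # almost nothing segregates at MAF > 0.1 under strong selection
  expect_lt(maf_variance_fraction(100, 0.1), 0.001)
  # monotone decreasing in the cutoff
  fr <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), maf_variance_fraction, 0, S = 3)
  expect_true(all(diff(fr) < 0))
})

test_that("closed-form G matches spot values and the survival integrals", {
  expect_equal(G_closed(0, 100, "strong-n1"), 1)
  expect_equal(G_closed(0, 0.5, "neutral-n1"), 1)
  expect_equal(G_closed(0, 100, "strong-limit"), 1)
  expect_equal(G_closed(0, 0.5, "neutral-limit"), 1)
  expect_equal(G_closed(1, 100, "strong-limit"), 3 * exp(-2))
  expect_equal(G_closed(1, 100, "strong-n1"), exp(-2))
  # neutral n = 1: support ends at v_max = S/8 (allele at frequency 1/2)
  S <- 0.4
  expect_equal(G_closed(S / 8, S, "neutral-n1"), 0)
  expect_equal(G_closed(S / 8 + 0.01, S, "neutral-n1"), 0)
  # mean-survival identities: int_0^inf G dv
  expect_equal(integrate(G_closed, 0, Inf, S = 1, regime = "strong-n1")$value,
               1 / 2, tolerance = 1e-6)
  expect_equal(integrate(G_closed, 0, 400, S = 1,
                         regime = "strong-limit")$value,
               3 / 2, tolerance = 1e-5)
  for (S in c(0.1, 0.7)) {
    expect_equal(integrate(G_closed, 0, S / 8, S = S,
                           regime = "neutral-n1")$value, S / 12,
                 tolerance = 1e-4)
    expect_equal(integrate(G_closed, 0, Inf, S = S,
                           regime = "neutral-limit")$value, S / 4,
                 tolerance = 1e-6)
  }
  expect_error(G_closed(1, 1, "strongest"), "regime")
})

test_that("automatic regime tagging follows the S thresholds", {
  expect_identical(G_regime(100, Inf), "strong-limit")
  expect_identical(G_regime(100, 1), "strong-n1")
  expect_identical(G_regime(0.5, Inf), "neutral-limit")
  expect_identical(G_regime(0.5, 1), "neutral-n1")
  expect_identical(G_regime(5, Inf), "numeric")
  expect_identical(G_regime(100, 7), "numeric")
})

test_that("numeric G is a proper survival curve and spans the regimes", {
  v <- c(0, 0.25, 0.5, 1, 2, 5)
  for (n in c(1, 2, Inf)) {
    G <- G_numeric(v, S = 5, n = n)
    expect_equal(G$G[1], 1)
    expect_true(all(diff(G$G) <= 0))
    expect_true(all(G$G >= 0 & G$G <= 1))
  }
  # at S = 5 (limit mode) the numeric curve is bracketed by the two closed
  # forms at small thresholds; in the tail the finite-S truncation of
  # per-site contributions pulls it below both, so the bound that holds
  # throughout is the neutral-limit one from above
  G5s <- G_numeric(0.25, S = 5)$G
  expect_lte(G5s, G_closed(0.25, 5, "neutral-limit"))
  expect_gte(G5s, G_closed(0.25, 5, "strong-limit"))
  G5 <- G_numeric(v[-1], S = 5)$G
  expect_true(all(G5 <= G_closed(v[-1], 5, "neutral-limit") + 1e-9))
})

test_that("Monte Carlo oracle agrees with the quadrature oracle", {
  v <- c(0.25, 0.5, 1, 2)
  gq <- G_numeric(v, S = 10, n = Inf)$G
  gmc <- G_numeric(v, S = 10, n = Inf, method = "mc", mc_size = 1e6,
                   seed = 11)$G
  expect_lt(max(abs(gmc - gq)), 0.01)
  expect_warning(G_numeric(1, S = 10, method = "mc", mc_size = 100, seed = 1),
                 "noisy")
})

test_that("pleiotropy raises G(v) at every threshold", {
  v <- c(0.25, 0.5, 1, 2)
  for (S in c(3, 10)) {
    G_by_n <- vapply(c(1, 2, 5, 20), function(n) G_numeric(v, S, n = n)$G,
                     numeric(length(v)))
    for (i in seq_along(v))
      expect_true(all(diff(G_by_n[i, ]) >= -1e-9))
    expect_true(all(G_numeric(v, S)$G >= G_by_n[, 4] - 1e-9))
  }
})
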