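test_that("generator is deterministic given its seed", {
  p <- small_params()
  sp <- synth_spec(p, S = c(1, 10), weights = c(0.3, 0.7), n_sites = 500,
                   seed = 42)
  a1 <- generate_architecture(sp)
  a2 <- generate_architecture(sp)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 500)
  expect_true(all(a1$q > 0 & a1$q < 1))
  expect_equal(a1$v, 2 * a1$a1^2 * a1$q * (1 - a1$q))
  expect_equal(a1$v_vs, a1$v / vs_unit(p))
})

test_that("generated architecture matches the strong-limit distribution", {
  p <- height_like_params()
  sp <- synth_spec(p, S = 100, n_sites = 1e5, seed = 7)
  arch <- generate_architecture(sp)
  tot <- sum(arch$v_vs)
  for (v0 in c(0.5, 1, 2)) {
    emp <- sum(arch$v_vs[arch$v_vs > v0]) / tot
    expect_lt(abs(emp - G_closed(v0, 100, "strong-limit")), 0.02)
  }
})

test_that("generated per-site variance matches the sojourn expectation", {
  p <- small_params(N = 2000)
  S <- 10
  sp <- synth_spec(p, S = S, n_sites = 1e5, seed = 9)
  arch <- generate_architecture(sp)
  # per segregating site, E v (v_s units) = (S/4) int 2pq t / int t
  num <- stabarch:::.sojourn_integral(S, p$N, function(q) log(2 * q * (1 - q)))
  den <- stabarch:::.sojourn_integral(S, p$N, function(q) rep(0, length(q)))
  expected <- (S / 4) * num / den
  se <- sd(arch$v_vs) / sqrt(nrow(arch))
  expect_lt(abs(mean(arch$v_vs) - expected), 3 * se)
})

test_that("site counts follow the equilibrium influx when L is used", {
  p <- small_params(N = 2000)  # theta large enough for a visible count
  sp <- synth_spec(p, S = 0.1, seed = 10)
  arch <- generate_architecture(sp)
  den <- stabarch:::.sojourn_integral(0.1, p$N, function(q) rep(0, length(q)))
  lambda <- p$L * 2 * p$N * p$u * den
  expect_lt(abs(nrow(arch) - lambda), 4 * sqrt(lambda))
})

test_that("GWAS tables threshold exactly in noiseless mode", {
  p <- height_like_params()
  sp <- synth_spec(p, S = 400, m = 1.5e5, seed = 12)
  tab <- generate_gwas_table(sp)
  vstar <- attr(tab, "v_star")
  expect_equal(vstar, detection_threshold(1.5e5, 1))
  expect_true(all(tab$var_explained >= vstar))
  expect_equal(tab$var_explained, 2 * tab$beta^2 * tab$freq * (1 - tab$freq))
  # an underpowered study discovers (almost) nothing
  sp_small <- synth_spec(p, S = 400, m = 2e3, n_sites = 2000, seed = 12)
  expect_warning(tab0 <- generate_gwas_table(sp_small), "no loci")
  expect_equal(nrow(tab0), 0)
})

test_that("fit round-trip on a generated table recovers the known v_s", {
  p <- height_like_params()
  sp <- synth_spec(p, S = 400, m = 1.5e5, seed = 77)
  tab <- generate_gwas_table(sp)
  f <- fit_vs(tab, attr(tab, "v_star"), bootstrap = 200, seed = 1)
  expect_true(f$ci[1] <= vs_unit(p) && vs_unit(p) <= f$ci[2])
})
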