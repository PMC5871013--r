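test_that("detection threshold scales as V_P/m with the chi-square constant", {
  expect_equal(detection_threshold(1e5, V_P = 1, calibration = 1), 1e-5)
  expect_equal(detection_threshold(2e5, V_P = 1, calibration = 1),
               detection_threshold(1e5, V_P = 1, calibration = 1) / 2)
  # the calibration constant solves the 50%-power noncentrality equation
  cc <- power_constant(alpha = 5e-8, power = 0.5)
  crit <- qchisq(5e-8, 1, lower.tail = FALSE)
  expect_equal(pchisq(crit, 1, ncp = cc, lower.tail = FALSE), 0.5,
               tolerance = 1e-6)
  expect_gt(cc, 25); expect_lt(cc, 35)
  # study size needed to reach a given threshold: m = c V_P / v*
  vstar <- detection_threshold(3e5, V_P = 2, calibration = cc)
  expect_equal(cc * 2 / vstar, 3e5)
})

test_that("the truncated family fit is a scale family and order-invariant", {
  set.seed(4)
  v <- stabarch:::.fam_sample(300, 1, 0.5, "strong-limit", "sites")
  f1 <- fit_vs(data.frame(var_explained = v), 0.5)
  f2 <- fit_vs(data.frame(var_explained = rev(v) * 1e-3), 0.5e-3)
  expect_equal(f2$vs / f1$vs, 1e-3, tolerance = 1e-6)
  # deterministic bootstrap under a fixed seed
  fa <- fit_vs(data.frame(var_explained = v), 0.5, bootstrap = 50, seed = 9)
  fb <- fit_vs(data.frame(var_explained = v), 0.5, bootstrap = 50, seed = 9)
  expect_identical(fa$ci, fb$ci)
  expect_warning(fit_vs(data.frame(var_explained = v[1:10]), 0.5), "weak")
  expect_error(fit_vs(data.frame(var_explained = v), max(v) * 2), "no loci")
})

test_that("variance-weighted family has a unimodal likelihood at v* = 0", {
  set.seed(5)
  v <- stabarch:::.fam_sample(400, 1, 0, "strong-limit", "variance")
  ll <- vapply(exp(seq(log(0.05), log(20), length.out = 80)), function(vs)
    sum(stabarch:::.fam_logdens(v, vs, 0, "strong-limit", "variance")), 0)
  peaks <- sum(diff(sign(diff(ll))) < 0)
  expect_equal(peaks, 1)
  f <- fit_vs(data.frame(var_explained = v), v_star = 0,
              weighting = "variance")
  expect_equal(f$vs, 1, tolerance = 0.2)
  # sites weighting is undefined at v* = 0 (log-divergent site count)
  expect_error(fit_vs(data.frame(var_explained = v), 0, weighting = "sites"),
               "v_star > 0")
})

test_that("per-locus variances come from var_explained or 2 beta^2 pq", {
  tab <- data.frame(freq = c(0.1, 0.4), beta = c(0.2, -0.1))
  expect_equal(gwas_variances(tab),
               2 * tab$beta^2 * tab$freq * (1 - tab$freq))
  tab$var_explained <- c(1, 2)
  expect_equal(gwas_variances(tab), c(1, 2))
  expect_error(gwas_variances(data.frame(snp = "a")), "var_explained")
})

test_that("KS test is exact on model quantiles and calibrated directions", {
  vs <- 1; vstar <- 0.4
  # loci placed at the exact model quantiles: D is as small as n allows
  u <- (seq_len(200) - 0.5) / 200
  grid <- exp(seq(log(vstar), log(500), length.out = 4096))
  cdfg <- stabarch:::.fam_cdf(grid, vs, vstar, "strong-limit", "sites")
  v <- approx(cdfg, grid, xout = u, ties = "ordered")$y
  f <- fit_vs(data.frame(var_explained = v), vstar)
  ks <- ks_goodness_of_fit(f, "classic")
  expect_lt(ks$D, 2 / 200)
  expect_gt(ks$p, 0.9)
  # a wrong-regime fit explains the same data worse than the right one
  set.seed(14)
  vlim <- stabarch:::.fam_sample(700, vs, vstar, "strong-limit", "sites")
  p_right <- ks_goodness_of_fit(
    fit_vs(data.frame(var_explained = vlim), vstar), "classic")$p
  p_wrong <- ks_goodness_of_fit(
    fit_vs(data.frame(var_explained = vlim), vstar, mode = "strong-n1"),
    "classic")$p
  expect_lt(p_wrong, p_right)
  ll_right <- fit_vs(data.frame(var_explained = vlim), vstar)$logLik
  ll_wrong <- fit_vs(data.frame(var_explained = vlim), vstar,
                     mode = "strong-n1")$logLik
  expect_lt(ll_wrong, ll_right)
})

test_that("target size scales linearly in the observed count", {
  p <- height_like_params()
  set.seed(6)
  v <- stabarch:::.fam_sample(400, vs_unit(p), 0.5 * vs_unit(p),
                              "strong-limit", "sites")
  f1 <- fit_vs(data.frame(var_explained = v), 0.5 * vs_unit(p))
  f2 <- fit_vs(data.frame(var_explained = rep(v, 2)), 0.5 * vs_unit(p))
  t1 <- estimate_target_size(f1, p, h2 = 0.8)
  t2 <- estimate_target_size(f2, p, h2 = 0.8)
  expect_equal(f1$vs, f2$vs, tolerance = 1e-8)
  expect_equal(t2$L_detectable / t1$L_detectable, 2, tolerance = 1e-6)
  expect_gte(t1$detectable_fraction, 0)
  expect_lte(t1$detectable_fraction, 1)
})

test_that("discovery projections rise to the detectable fraction", {
  p <- height_like_params()
  set.seed(16)
  v <- stabarch:::.fam_sample(450, vs_unit(p), 0.49 * vs_unit(p),
                              "strong-limit", "sites")
  f <- fit_vs(data.frame(var_explained = v), 0.49 * vs_unit(p))
  tg <- estimate_target_size(f, p, h2 = 0.8)
  m <- c(1e5, 3e5, 1e6, 1e7, 1e10)
  pr <- project_discovery(f, m, p, target = tg)
  expect_true(all(diff(pr$explained_fraction) > 0))
  expect_true(all(diff(pr$n_hits) > 0))
  expect_equal(pr$explained_fraction[5], tg$detectable_fraction,
               tolerance = 0.01)
  # predict() is the formula-object front end to the same computation
  pd <- predict(f, newdata = data.frame(m = m), params = p, target = tg)
  expect_equal(pd$explained_fraction, pr$explained_fraction)
})

test_that("fit methods expose the standard modelling surface", {
  set.seed(26)
  v <- stabarch:::.fam_sample(250, 2, 1, "strong-limit", "sites")
  f <- fit_vs(data.frame(var_explained = v), 1, bootstrap = 60, seed = 2)
  expect_named(coef(f), "vs")
  expect_equal(as.numeric(logLik(f)), f$logLik)
  expect_equal(dim(confint(f)), c(1L, 2L))
  expect_true(confint(f)[1] < coef(f) && coef(f) < confint(f)[2])
  r <- residuals(f, type = "uniform")
  expect_true(all(r >= 0 & r <= 1))
  expect_gt(suppressWarnings(ks.test(r, "punif")$p.value), 0.01)
  sims <- simulate(f, nsim = 3, seed = 8)
  expect_length(sims, 3)
  expect_true(all(sims[[1]]$var_explained >= f$v_star))
  s <- summary(f)
  expect_s3_class(s, "summary.vs_fit")
  expect_output(print(s), "KS")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
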