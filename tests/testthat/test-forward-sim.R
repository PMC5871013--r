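test_that("demography containers discretize epochs correctly", {
  d <- demography(list(list(gens = 100, N = 500),
                       list(gens = 10, N_start = 500, N_end = 5000,
                            mode = "exp")))
  expect_length(d$N, 110)
  expect_equal(d$N[1:100], rep(500L, 100))
  expect_equal(d$N[110], 5000L)
  expect_true(all(diff(d$N[101:110]) > 0))
  expect_equal(demography_constant(1000, 50)$N, rep(1000L, 50))
  expect_error(demography(list(list(gens = 0, N = 10))), "gens")
  expect_error(demography(list(list(gens = 10, N = 1))), ">= 2")
  expect_error(demography(list(list(gens = 10, N_start = 5, mode = "exp"))),
               "N_end")
})

test_that("demography files parse from YAML", {
  path <- system.file("extdata", "synthetic_bottleneck.yaml",
                      package = "stabarch")
  d <- read_demography(path)
  expect_length(d$epochs, 3)
  expect_equal(max(d$N), 100000L)
  expect_equal(d$N[1], 10000L)
})

test_that("piecewise demography with equal sizes matches constant N exactly", {
  d1 <- demography_constant(400, 300)
  d2 <- demography(list(list(gens = 120, N = 400), list(gens = 180, N = 400)))
  t1 <- simulate_site(0.002, d1, "fixed-time", n_reps = 500, seed = 99)
  t2 <- simulate_site(0.002, d2, "fixed-time", n_reps = 500, seed = 99)
  expect_identical(t1$q_final, t2$q_final)
  expect_identical(t1$sum_pq, t2$sum_pq)
})

test_that("trajectories are reproducible and absorbing at the boundaries", {
  d <- demography_constant(300, 500)
  a <- simulate_site(0.01, d, "uniform-influx", n_reps = 400, seed = 5)
  b <- simulate_site(0.01, d, "uniform-influx", n_reps = 400, seed = 5)
  expect_identical(a$q_final, b$q_final)
  expect_identical(a$origin, b$origin)
  expect_true(all(a$q_final >= 0 & a$q_final <= 1))
  expect_true(all(a$segregating == (a$q_final > 0 & a$q_final < 1)))
  expect_error(simulate_site(20, d, "fixed-time", n_reps = 1), "too large")
})

test_that("neutral fixation probability is 1/2N", {
  N <- 100
  d <- demography_constant(N, 6000)  # long enough for absorption
  te <- simulate_site(0, d, "fixed-time", n_reps = 4e4, seed = 13)
  expect_lt(mean(te$segregating), 0.01)  # essentially all absorbed
  pfix <- mean(te$q_final >= 1)
  se <- sqrt(pfix * (1 - pfix) / nrow(te))
  expect_lt(abs(pfix - 1 / (2 * N)), 3 * se + 1e-12)
})

test_that("origin times follow the mutational influx 2 N(t) u", {
  d <- demography(list(list(gens = 100, N = 1000),
                       list(gens = 100, N = 4000)))
  te <- simulate_site(0, d, "uniform-influx", n_reps = 2e4, seed = 3)
  frac_late <- mean(te$origin > 100)
  # influx weight 4000/(1000+4000) = 0.8
  expect_lt(abs(frac_late - 0.8), 3 * sqrt(0.8 * 0.2 / 2e4))
})

test_that("constant-N simulation matches the diffusion expectation", {
  # small-scale check (the deep one runs in the acceptance suite)
  r <- integrated_variance_sim(10, N = 500, n_reps = 2e5, seed = 21)
  th <- expected_variance_per_site(10, N = 500)
  expect_lt(abs(r$estimate - th), 4 * r$se)
})

test_that("demography summary table behaves at the edges", {
  d <- demography_constant(200, 400)
  out <- variance_by_s_under_demography(c(0, 0.005), d, n_reps = 2000,
                                        thresholds = 1e-4, seed = 8)
  expect_equal(nrow(out), 2)
  expect_true(all(out$cum_var >= out$`cum_above_1e-04`))
  # zero replicates -> zero variance
  out0 <- variance_by_s_under_demography(0.005, d, n_reps = 0, seed = 8)
  expect_equal(out0$cum_var, 0)
})
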