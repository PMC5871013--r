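test_that("parameter container computes derived quantities and validates", {
  p <- model_params(n = 10, w = 1, N = 10000, u = 1e-8, L = 1e6)
  expect_s3_class(p, "model_params")
  expect_equal(p$U, 1e-2)
  expect_equal(p$theta, 4e-4)
  expect_equal(p$vs, 2 / (10 * 1e4))

  expect_error(model_params(n = 0.5), "n")
  expect_error(model_params(w = -1), "w")
  expect_error(model_params(N = 10.5), "N")
  expect_error(model_params(u = 0), "u")

  # regime violations warn but do not error
  expect_warning(model_params(n = 1, w = 1, N = 1e6, u = 1e-6, L = 1e4),
                 "theta")
  expect_warning(model_params(n = 1, w = 1, N = 100, u = 1e-9, L = 10), "U")
})

test_that("v_s unit follows 2 w^2/(n N) and its scaling laws", {
  expect_equal(vs_unit(suppressWarnings(model_params(1, 1, 1, 1e-8, 10))), 2)
  expect_equal(vs_unit(model_params(10, 1, 1e4, 1e-8, 1e6)), 2e-5)
  # doubling n halves v_s; the combination vs*n*N/w^2 is exactly 2
  for (n in c(1, 2.5, 10)) for (w in c(0.5, 3)) for (N in c(500, 20000)) {
    p <- suppressWarnings(model_params(n, w, N, 1e-8, 1e6))
    expect_equal(vs_unit(p) * n * N / w^2, 2)
    p2 <- suppressWarnings(model_params(2 * n, w, N, 1e-8, 1e6))
    expect_equal(vs_unit(p2), vs_unit(p) / 2)
  }
})

test_that("selection coefficient from effect vector matches s = |a|^2/w^2", {
  p <- suppressWarnings(model_params(n = 3, w = 1, N = 5000, u = 1e-8, L = 1e4))
  expect_equal(selection_from_effect(c(0, 0, 0), p)$s, 0)
  expect_equal(selection_from_effect(c(0.1, 0, 0), p)$s, 0.01)
  p4 <- suppressWarnings(model_params(n = 4, w = 2, N = 5000, u = 1e-8, L = 1e4))
  sc <- selection_from_effect(rep(0.1, 4), p4)
  expect_equal(sc$s, 0.01)
  expect_equal(sc$S, 100)
  expect_error(selection_from_effect(c(1, NA), p), "finite")
  expect_warning(selection_from_effect(c(0.9, 0.9, 0.9), p), "0.1")
})

test_that("S is invariant under joint rescaling of w and the effect vector", {
  a <- c(0.03, -0.02, 0.01)
  for (cc in c(0.1, 2, 17)) {
    p1 <- suppressWarnings(model_params(3, 1, 1000, 1e-8, 1e4))
    p2 <- suppressWarnings(model_params(3, cc * 1, 1000, 1e-8, 1e4))
    expect_equal(selection_from_effect(cc * a, p2)$S,
                 selection_from_effect(a, p1)$S)
  }
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- list(n = 10, w = 4.5, N = 10000, u = 1e-8, L = 5e6)
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  py <- read_model_config(fy)
  expect_equal(py$vs, 2 * 4.5^2 / (10 * 1e4))

  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  pj <- read_model_config(fj)
  expect_equal(unclass(pj), unclass(py))

  yaml::write_yaml(cfg[-2], fy)
  expect_error(read_model_config(fy), "w")
})
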