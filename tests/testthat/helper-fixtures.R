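# Shared fixtures for the test suite. Everything is generated in code; the
# parameter sets mirror the worked examples in the vignette.

# a height-like trait in the pleiotropic limit: v_s ~ 4e-4 V_P, theta = 4e-4
height_like_params <- function() {
  suppressWarnings(model_params(n = 10, w = 4.5, N = 1e4, u = 1e-8, L = 5e6))
}

# small parameter set for cheap checks
small_params <- function(n = 10, w = 1, N = 1000) {
  suppressWarnings(model_params(n = n, w = w, N = N, u = 1e-6, L = 1e4))
}

# quadrature of a function against the effect-size density phi_n. The
# endpoint singularities for n < 3 are algebraic, which QAGS extrapolation
# handles directly to ~1e-10; the a1 = a*sin(theta) change of variables is an
# alternative that removes them for n >= 2.
phi_quad <- function(f, a, n) {
  integrate(function(a1) f(a1) * effect_density(a1, a, n), -a, a,
            rel.tol = 1e-10, subdivisions = 800L)$value
}
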