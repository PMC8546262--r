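# evaluation points spread over the outer sphere surface
oracle_eval_points <- function(R, n = 40, seed = 7) {
  set.seed(seed)
  p <- matrix(rnorm(n * 3), ncol = 3)
  p / sqrt(rowSums(p^2)) * R
}

test_that("equal-conductivity layers reduce to the homogeneous sphere", {
  pts <- oracle_eval_points(0.09)
  multi <- layered_sphere_model(c(0.09, 0.08, 0.07, 0.05), rep(0.33, 4),
                                n_max = 2000)
  single <- layered_sphere_model(0.09, 0.33, n_max = 2000)
  a <- layered_sphere_potential(multi, 0.06, c(0, 0, 1), 1e-4, pts)
  b <- layered_sphere_potential(single, 0.06, c(0, 0, 1), 1e-4, pts)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("series potentials are linear, antisymmetric and truncation-stable", {
  pts <- oracle_eval_points(0.09)
  m <- layered_sphere_model(c(0.09, 0.08), c(0.4, 0.1), n_max = 500)
  v <- layered_sphere_potential(m, 0.05, c(1, 0, 0), 1e-4, pts)
  v2 <- layered_sphere_potential(m, 0.05, c(1, 0, 0), 2e-4, pts)
  expect_equal(v2, 2 * v, tolerance = 1e-12)
  vm <- layered_sphere_potential(m, 0.05, c(1, 0, 0), -1e-4, pts)
  expect_equal(vm, -v, tolerance = 1e-12)
  # deep source: convergence well before n_max; doubling n_max is a no-op
  m2 <- layered_sphere_model(c(0.09, 0.08), c(0.4, 0.1), n_max = 1000)
  v3 <- layered_sphere_potential(m2, 0.05, c(1, 0, 0), 1e-4, pts)
  expect_equal(v3, v, tolerance = 1e-10)
  # shallow source with too small a truncation must error, not truncate
  m3 <- layered_sphere_model(c(0.09, 0.08), c(0.4, 0.1), n_max = 30)
  expect_error(layered_sphere_potential(m3, 0.0895, c(1, 0, 0), 1e-4, pts),
               "not converged")
})

test_that("potential is continuous across layer interfaces", {
  # the normal gradient jumps by the conductivity ratio at each interface
  # (107x at skull-CSF), so the straddling offset must be tiny for the
  # one-sided values to witness continuity of the potential itself
  m <- layered_sphere_model(c(0.092, 0.086, 0.080, 0.078),
                            c(0.414, 0.016, 1.71, 0.37), n_max = 5000)
  set.seed(3)
  dirs <- matrix(rnorm(60), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (R in c(0.086, 0.080, 0.078)) {
    vi <- layered_sphere_potential(m, 0.089, c(0, 0, 1), 1e-4,
                                   dirs * (R - 1e-11), tail_tol = 1e-10)
    vo <- layered_sphere_potential(m, 0.089, c(0, 0, 1), 1e-4,
                                   dirs * (R + 1e-11), tail_tol = 1e-10)
    expect_lte(max(abs(vi - vo)) / max(abs(vo)), 1e-8)
  }
})

test_that("homogeneous-sphere potential is reciprocal in source and sensor", {
  m <- layered_sphere_model(0.09, 0.33, n_max = 1500)
  a <- c(0.05, 0.01, 0.02)
  b <- c(-0.02, 0.04, -0.03)
  va <- layered_sphere_potential(m, sqrt(sum(a^2)), a / sqrt(sum(a^2)), 1e-4,
                                 matrix(b, 1))
  vb <- layered_sphere_potential(m, sqrt(sum(b^2)), b / sqrt(sum(b^2)), 1e-4,
                                 matrix(a, 1))
  expect_equal(va, vb, tolerance = 1e-8)
})

test_that("rdm_mag implements the standard forward-error metrics", {
  expect_equal(rdm_mag(c(1, 2, 3), c(1, 2, 3)), list(rdm = 0, mag = 1))
  m <- rdm_mag(c(1, 2, 3), 2 * c(1, 2, 3))
  expect_equal(m$rdm, 0)
  expect_equal(m$mag, 2)
  expect_equal(rdm_mag(c(1, 0), c(0, 1))$rdm, sqrt(2))
  expect_error(rdm_mag(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(rdm_mag(1:3, 1:4), "equal length")
})
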