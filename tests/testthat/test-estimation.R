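test_that("recorded potentials respond to rotation and scale with current", {
  les <- tiny_lesioned()
  pair <- tiny_pair()
  layout <- tiny_layout()
  cache <- tiny_cache()
  # rotation 0 (NULL) equals the plain optimal-pair recording of the same
  # refined model
  psi0 <- simulate_recorded(les, pair, layout, 128, NULL, cache = cache)
  direct <- lesionbem:::cache_recording(cache, 1.23, layout)
  expect_equal(lesionbem:::recording_values(psi0),
               lesionbem:::recording_values(direct), tolerance = 1e-12)
  expect_identical(attr(psi0, "provenance"), "recorded")
  # a 0.1 degree rotation changes the recording
  psi_rot <- simulate_recorded(les, pair, layout, 128,
                               rotation_spec("coronal", 0.1), cache = cache)
  expect_gt(scalp_rmsd(psi0, psi_rot), 0)
  # doubling the stimulation current doubles psi (uncached path, tiny mesh)
  p1 <- simulate_recorded(les, pair, layout, 8, NULL, current = 1e-4)
  p2 <- simulate_recorded(les, pair, layout, 8, NULL, current = 2e-4)
  expect_equal(2 * lesionbem:::recording_values(p1),
               lesionbem:::recording_values(p2), tolerance = 1e-9)
})

test_that("conductivity is recovered exactly without electrode rotation", {
  les <- tiny_lesioned()
  cache <- tiny_cache()
  truth <- set_lesion_conductivity(les, 1.23)
  psi <- simulate_recorded(truth, tiny_pair(), tiny_layout(), 64, NULL,
                           cache = cache)
  est <- estimate_lesion_conductivity(psi, les, tiny_pair(), tiny_layout(),
                                      64, cache = cache)
  expect_true(any(est$converged))
  expect_lt(abs(est$best_sigma - 1.23) / 1.23, 1e-4)
  expect_length(est$starts, 10)
  expect_true(all(est$starts >= 0.033 & est$starts <= 2))
  # lesion-free degenerate case: recover the brain conductivity
  flat <- set_lesion_conductivity(les, 0.37)
  psi_flat <- simulate_recorded(flat, tiny_pair(), tiny_layout(), 64, NULL,
                                cache = cache)
  est_flat <- estimate_lesion_conductivity(psi_flat, les, tiny_pair(),
                                           tiny_layout(), 64, cache = cache)
  expect_lt(abs(est_flat$best_sigma - 0.37) / 0.37, 0.02)
})

test_that("a fixed seed reproduces the multi-start traces bit for bit", {
  les <- tiny_lesioned()
  cache <- tiny_cache()
  psi <- simulate_recorded(set_lesion_conductivity(les, 0.74), tiny_pair(),
                           tiny_layout(), 64,
                           rotation_spec("sagittal", 0.1), cache = cache)
  cfg <- estimation_config(seed = 42)
  e1 <- estimate_lesion_conductivity(psi, les, tiny_pair(), tiny_layout(), 64,
                                     config = cfg, cache = cache)
  e2 <- estimate_lesion_conductivity(psi, les, tiny_pair(), tiny_layout(), 64,
                                     config = cfg, cache = cache)
  expect_identical(e1$starts, e2$starts)
  expect_identical(e1$traces, e2$traces)
  expect_identical(e1$best_sigma, e2$best_sigma)
  # a different seed draws different starts
  e3 <- estimate_lesion_conductivity(psi, les, tiny_pair(), tiny_layout(), 64,
                                     config = estimation_config(seed = 43),
                                     cache = cache)
  expect_false(identical(e1$starts, e3$starts))
  # estimation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(estimate_lesion_conductivity(psi, les, tiny_pair(), tiny_layout(),
                                         64, config = cfg, cache = cache))
  expect_identical(runif(1), before)
})

test_that("error metrics are the definitional absolute and relative errors", {
  fake <- structure(list(best_sigma = 0.86, converged = TRUE),
                    class = "estimation_result")
  m <- error_metrics(fake, 0.74)
  expect_equal(m$absolute, 0.12)
  expect_equal(m$relative, 0.12 / 0.74)
  fake2 <- structure(list(best_sigma = 1.48), class = "estimation_result")
  expect_equal(error_metrics(fake2, 0.74)$relative, 1)
  exact <- structure(list(best_sigma = 1.23), class = "estimation_result")
  expect_equal(error_metrics(exact, 1.23), list(absolute = 0, relative = 0))
  failed <- structure(list(best_sigma = NA_real_), class = "estimation_result")
  expect_error(error_metrics(failed, 1.23), "did not converge")
})

test_that("estimation results serialize to JSON with traces and flags", {
  les <- tiny_lesioned()
  cache <- tiny_cache()
  psi <- simulate_recorded(set_lesion_conductivity(les, 1.23), tiny_pair(),
                           tiny_layout(), 8, NULL, cache = cache)
  est <- estimate_lesion_conductivity(psi, les, tiny_pair(), tiny_layout(), 8,
                                      config = estimation_config(n_starts = 3),
                                      cache = cache)
  path <- tempfile(fileext = ".json")
  estimation_to_json(est, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$best_sigma, est$best_sigma, tolerance = 1e-12)
  expect_length(back$traces, 3)
  expect_equal(back$seed, est$seed)
  unlink(path)
})
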