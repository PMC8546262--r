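# Numeric quadrature of the linear double-layer triangle integral, the
# from-first-principles oracle for the analytic element integration.
quad_triangle_integral <- function(v1, v2, v3, obs, ngrid = 300) {
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  a2 <- sqrt(sum(nrm^2)); nrm <- nrm / a2
  acc <- c(0, 0, 0); k <- 0
  for (i in 1:ngrid) for (j in 1:(ngrid - i + 1)) {
    a <- (i - 0.5) / ngrid; b <- (j - 0.5) / ngrid
    if (a + b < 1) {
      x <- v1 * (1 - a - b) + v2 * a + v3 * b
      r <- x - obs; rn <- sqrt(sum(r^2))
      acc <- acc + sum(r * nrm) / rn^3 * c(1 - a - b, a, b)
      k <- k + 1
    }
  }
  acc * (a2 / 2) / k
}

test_that("analytic element integrals match numeric quadrature", {
  v1 <- c(1, 0.2, 0.1); v2 <- c(0.3, 1.2, -0.2); v3 <- c(-0.5, 0.3, 0.9)
  for (obs in list(c(0.1, -0.4, -0.8), c(2, 1, 1), c(-0.3, 0.5, -0.1))) {
    q <- quad_triangle_integral(v1, v2, v3, obs)
    a <- lesionbem:::.bem_collocation_matrix(rbind(v1, v2, v3),
                                             matrix(1:3, 1), matrix(obs, 1))
    expect_equal(as.numeric(a), q, tolerance = 5e-3)
  }
  # observation point in the triangle plane: kernel vanishes
  a0 <- lesionbem:::.bem_collocation_matrix(rbind(v1, v2, v3), matrix(1:3, 1),
                                            matrix(v1 + 2 * (v2 - v1), 1))
  expect_equal(as.numeric(a0), c(0, 0, 0))
})

test_that("solid angles sum to 4 pi inside and 0 outside a closed surface", {
  s <- make_icosphere(c(0, 0, 0), 1, 2)
  din <- lesionbem:::.bem_collocation_matrix(s$vertices, s$triangles,
                                             matrix(c(0.2, 0.1, -0.3), 1))
  expect_equal(sum(din), 4 * pi, tolerance = 1e-12)
  dout <- lesionbem:::.bem_collocation_matrix(s$vertices, s$triangles,
                                              matrix(c(2, 0, 0), 1))
  expect_equal(sum(dout), 0, tolerance = 1e-12)
  w <- lesionbem:::.mesh_winding_number(rbind(c(0.2, 0.1, -0.3), c(2, 0, 0)),
                                        s$vertices, s$triangles)
  expect_equal(as.numeric(w), c(1, 0), tolerance = 1e-12)
})

test_that("infinite-medium monopole potential follows the closed form", {
  src <- source_config(matrix(c(0, 0, 0), 1), 0)  # single balanced "pair"
  expect_error(source_config(matrix(0, 1, 3), 1e-4), "sum to exactly 0")
  pair <- source_config(rbind(c(0, 0, 0), c(20, 0, 0)), c(1e-4, -1e-4))
  # single monopole value isolated by superposition at distance 10 mm
  v <- infinite_medium_potential(pair, matrix(c(0, 10, 0), 1), 0.414)
  v_far <- -1e-4 / (4 * pi * 0.414 * sqrt(0.02^2 + 0.01^2))
  expect_equal(v, 1e-4 / (4 * pi * 0.414 * 0.01) + v_far, tolerance = 1e-12)
  # point equidistant from anode and cathode: zero
  v0 <- infinite_medium_potential(pair, matrix(c(10, 5, 0), 1), 0.414)
  expect_equal(v0, 0, tolerance = 1e-18)
  # linearity in current
  pair2 <- source_config(rbind(c(0, 0, 0), c(20, 0, 0)), c(2e-4, -2e-4))
  expect_equal(infinite_medium_potential(pair2, matrix(c(0, 10, 0), 1), 0.414),
               2 * v, tolerance = 1e-12)
  expect_error(infinite_medium_potential(pair, matrix(c(0, 0, 0), 1), 0.414),
               "coincides")
  expect_error(infinite_medium_potential(pair, matrix(c(1, 1, 1), 1), -1),
               "sigma")
})

test_that("stimulation monopoles sit 3 mm under the electrodes, inside scalp", {
  src <- stim_sources(tiny_head(), tiny_layout(), c("T7", "T8"))
  expect_equal(unname(sqrt(rowSums(src$positions^2))), c(89, 89),
               tolerance = 1e-9)
  expect_equal(sum(src$currents), 0)
  # a monopole inside the skull is rejected at assembly
  deep <- source_config(rbind(c(50, 0, 0), c(-50, 0, 0)), c(1e-4, -1e-4))
  expect_error(assemble_system(tiny_head(), deep), "scalp compartment")
})

test_that("collocation operator annihilates constants and solves linearly", {
  sys <- assemble_system(tiny_head(), antipodal_sources())
  ones <- rep(1, nrow(sys$D))
  cj <- sys$sig_in - sys$sig_out
  resid <- sys$a
  for (j in seq_along(sys$sig_in)) {
    cols <- (sys$offsets[j] + 1):sys$offsets[j + 1]
    resid <- resid - (sys$D[, cols] %*% ones[cols]) * cj[j] / (4 * pi)
  }
  expect_lt(max(abs(resid)) / mean(abs(sys$a)), 1e-10)

  fld <- solve_potentials(sys)
  # gauge: area-weighted mean zero
  phi_all <- unlist(fld$potentials, use.names = FALSE)
  expect_lt(abs(sum(sys$w * phi_all)), 1e-15)
  # linearity in the injected current
  sys2 <- assemble_system(tiny_head(), antipodal_sources(2e-4))
  fld2 <- solve_potentials(sys2)
  expect_equal(fld2$potentials[[1]], 2 * fld$potentials[[1]],
               tolerance = 1e-10)
  # zero current, zero field
  sys0 <- assemble_system(tiny_head(),
                          source_config(rbind(c(89, 0, 0), c(-89, 0, 0)),
                                        c(0, 0)))
  expect_equal(max(abs(solve_potentials(sys0)$potentials[[1]])), 0)
  expect_error(solve_potentials(assemble_system(tiny_head())), "without sources")
})

test_that("antipodal-pair scalp potentials are antisymmetric across the midplane", {
  sys <- assemble_system(tiny_head(), antipodal_sources())
  fld <- solve_potentials(sys)
  v <- fld$model$surfaces[[1]]$vertices
  phi <- fld$potentials[[1]]
  # pair each vertex with its x-mirror (icosphere vertices map exactly)
  key <- apply(round(cbind(-v[, 1], v[, 2], v[, 3]), 6), 1, paste,
               collapse = ",")
  own <- apply(round(v, 6), 1, paste, collapse = ",")
  mirror <- match(key, own)
  ok <- !is.na(mirror)
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(phi[ok] + phi[mirror[ok]])) / max(abs(phi)), 0.01)
})

test_that("electrode recording interpolates, re-references and excludes the pair", {
  sys <- assemble_system(tiny_head(), antipodal_sources())
  fld <- solve_potentials(sys)
  layout <- tiny_layout()
  rec <- record_at_electrodes(fld, layout, exclude = c("T7", "T8"))
  expect_s3_class(rec, "electrode_recording")
  expect_equal(nrow(rec), 127)  # 126 measurement + reference row
  expect_length(lesionbem:::recording_values(rec), 126)
  expect_equal(rec$potential_V[rec$label == "nasion"], 0)
  expect_false(any(c("T7", "T8") %in% rec$label))
  # electrodes exactly at mesh vertices reproduce the vertex potentials
  scalp <- fld$model$surfaces[[1]]
  lay2 <- electrode_layout(c("probe", "refv"),
                           scalp$vertices[c(17, 33), ], reference = "refv")
  rec2 <- record_at_electrodes(fld, lay2)
  expect_equal(rec2$potential_V[rec2$label == "probe"],
               fld$potentials[[1]][17] - fld$potentials[[1]][33],
               tolerance = 1e-12)
  # off-surface electrode beyond tolerance is rejected
  lay3 <- electrode_layout(c("far", "nasion"),
                           rbind(c(0, 0, 99), layout$positions["nasion", ]))
  expect_error(record_at_electrodes(fld, lay3), "farther than")
})

test_that("low-rank lesion re-solve equals direct re-assembly", {
  les <- tiny_lesioned()
  sys <- assemble_system(les, antipodal_sources())
  resolver <- lesion_resolver(sys)
  for (sg in c(0.5, 1.23, 1.9)) {
    direct <- unlist(solve_potentials(sys, sigma_lesion = sg)$potentials,
                     use.names = FALSE)
    expect_equal(resolver(sg), direct, tolerance = 1e-9)
  }
})
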