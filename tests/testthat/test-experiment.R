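# micro study: tiny meshes, 1 lesion, 2 conductivities, 2 axes,
# angles {0, 0.1}, 2 subsets -> 2 * (1 + 2 * 1) * 2 = 12 rows
micro_config <- function(seed = 1L) {
  study_config(elements_per_surface = 320, lesion_elements = 320,
               lesion_radii = 23, lesion_conductivities = c(0.74, 1.23),
               angles_deg = c(0, 0.1), subset_sizes = c(8, 64),
               refine = "none", seed = seed,
               estimation = estimation_config(n_starts = 4, seed = seed))
}

test_that("the study sweep has the full factorial row count and shares 0 deg", {
  tab <- fixture("micro_study", run_study(micro_config(), progress = FALSE))
  expect_equal(nrow(tab), 2 * (1 + 2 * 1) * 2)
  expect_setequal(unique(tab$axis), c("none", "coronal", "sagittal"))
  expect_true(all(tab$axis[tab$angle_deg == 0] == "none"))
  expect_true(all(tab$axis[tab$angle_deg > 0] != "none"))
  expect_true(all(tab$status == "ok"))
  # zero-rotation rows recover the conductivity to within 1%
  zero <- tab[tab$angle_deg == 0, ]
  expect_true(all(zero$converged))
  expect_true(all(zero$relative_error <= 0.01))
  # displacement recorded only for rotated rows
  expect_true(all(tab$mean_displacement_mm[tab$angle_deg == 0] == 0))
  expect_true(all(tab$mean_displacement_mm[tab$angle_deg > 0] > 0))
  expect_true(nzchar(attr(tab, "config_hash")))
})

test_that("re-running with the same seed reproduces the table exactly", {
  tab1 <- fixture("micro_study", run_study(micro_config(), progress = FALSE))
  tab2 <- run_study(micro_config(), progress = FALSE)
  expect_equal(as.data.frame(tab1), as.data.frame(tab2), tolerance = 0)
  expect_identical(attr(tab1, "config_hash"), attr(tab2, "config_hash"))
})

test_that("summaries give grouped sample statistics excluding non-convergence", {
  base_row <- function(err, conv = TRUE, axis = "coronal", angle = 0.5) {
    data.frame(lesion_radius_mm = 23, volume_ml = 50, depth_mm = 43,
               anode = "a", cathode = "b", pair_rmsd_V = 1,
               sigma_true = 0.74, axis = axis, angle_deg = angle, subset = 64,
               sigma_hat = 0.74 * (1 + err), absolute_error = 0.74 * err,
               relative_error = err, converged = conv,
               mean_displacement_mm = 1, status = "ok",
               stringsAsFactors = FALSE)
  }
  tab <- rbind(base_row(0.1), base_row(0.3),
               base_row(99, conv = FALSE),
               base_row(0.2, axis = "sagittal"))
  tab$absolute_error[3] <- NA; tab$relative_error[3] <- NA
  class(tab) <- c("study_result", "data.frame")
  s <- summarize_study(tab, group_by = c("axis"))
  cor <- s[s$axis == "coronal", ]
  expect_equal(cor$n, 3)
  expect_equal(cor$n_converged, 2)
  expect_equal(cor$n_nonconverged, 1)
  expect_equal(cor$mean_relative, 0.2)
  expect_equal(cor$sd_relative, sd(c(0.1, 0.3)))
  expect_equal(cor$sd_relative, 0.1414, tolerance = 1e-3)
  sag <- s[s$axis == "sagittal", ]
  expect_equal(sag$sd_relative, 0)  # single converged row
  expect_error(summarize_study(tab[0, ]), "empty")
})

test_that("study outputs and YAML configs round-trip on disk", {
  tab <- fixture("micro_study", run_study(micro_config(), progress = FALSE))
  dir <- tempfile("study")
  write_study_results(tab, dir)
  expect_true(file.exists(file.path(dir, "study_results.csv")))
  meta <- jsonlite::read_json(file.path(dir, "study_metadata.json"))
  expect_equal(meta$n_rows, nrow(tab))
  expect_equal(meta$config_hash, attr(tab, "config_hash"))
  unlink(dir, recursive = TRUE)

  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c("elements_per_surface: 320",
               "lesion_radii: [23]",
               "lesion_conductivities: [0.74]",
               "angles_deg: [0]",
               "subset_sizes: [8]",
               "estimation:",
               "  n_starts: 3",
               "  seed: 7"), cfg_path)
  cfg <- read_study_config(cfg_path)
  expect_equal(cfg$elements_per_surface, 320)
  expect_equal(cfg$estimation$n_starts, 3L)
  expect_equal(cfg$lesion_center, default_lesion_center())  # default kept
  writeLines("not_a_field: 1", cfg_path)
  expect_error(read_study_config(cfg_path), "unknown config")
  unlink(cfg_path)
})
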