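test_that("candidate pairs enumerate the outer-edge electrodes", {
  layout <- tiny_layout()
  pairs <- candidate_pairs(layout)
  expect_equal(nrow(pairs), 190)  # choose(20, 2)
  expect_true(all(pairs$anode != pairs$cathode))
  expect_true(all(c(pairs$anode, pairs$cathode) %in% outer_edge_labels()))
  expect_false(anyDuplicated(paste(pairs$anode, pairs$cathode)) > 0)
  # each pair leaves 126 measurement electrodes
  left <- length(setdiff(lesionbem:::measurement_labels(layout),
                         c(pairs$anode[1], pairs$cathode[1])))
  expect_equal(left, 126)
  lay2 <- electrode_layout(c("A", "nasion"), rbind(1:3, 4:6))
  expect_error(candidate_pairs(lay2), "missing candidate")
})

test_that("scalp RMSD is the root-mean-square label-matched difference", {
  fake <- function(labels, values) {
    structure(data.frame(label = c(labels, "nasion"),
                         potential_V = c(values, 0)),
              class = c("electrode_recording", "data.frame"),
              reference = "nasion", stim_pair = character(),
              provenance = "simulated")
  }
  a <- fake(c("e1", "e2"), c(0, 0))
  b <- fake(c("e1", "e2"), c(3, 4))
  expect_equal(scalp_rmsd(a, a), 0)
  expect_equal(scalp_rmsd(a, b), sqrt(12.5))
  # scaling both recordings scales the RMSD
  a2 <- fake(c("e1", "e2"), c(0, 0) * -2)
  b2 <- fake(c("e1", "e2"), c(3, 4) * -2)
  expect_equal(scalp_rmsd(a2, b2), 2 * sqrt(12.5))
  expect_error(scalp_rmsd(a, fake(c("e1", "e3"), c(1, 2))), "label sets")
})

test_that("the exhaustive search returns the argmax and flags degeneracy", {
  pt <- find_optimal_pair(tiny_lesioned(), tiny_head(), tiny_layout(),
                          refine = "none")
  opt <- attr(pt, "optimal")
  expect_equal(opt$rmsd_V, max(pt$rmsd_V))
  expect_equal(nrow(pt), 190)
  # locality: the optimal pair touches one of the 5 candidates nearest the
  # left-temporal lesion centroid
  layout <- tiny_layout()
  cand_pos <- lesionbem:::layout_positions(layout, outer_edge_labels())
  d <- sqrt(colSums((t(cand_pos) - default_lesion_center())^2))
  nearest5 <- outer_edge_labels()[order(d)][1:5]
  expect_true(any(c(opt$anode, opt$cathode) %in% nearest5))
  # recordings of the winning pair are attached
  expect_s3_class(attr(pt, "recording_lesion"), "electrode_recording")

  # zero-contrast lesion: no pair can distinguish the models
  flat <- set_lesion_conductivity(tiny_lesioned(), 0.37)
  expect_error(find_optimal_pair(flat, tiny_head(), tiny_layout(),
                                 refine = "none"),
               "degenerate")
})

test_that("a higher-contrast lesion has a larger scalp-potential footprint", {
  # same geometry, sigma 1.71 vs 0.74 against brain 0.37
  lo <- set_lesion_conductivity(tiny_lesioned(), 0.74)
  hi <- set_lesion_conductivity(tiny_lesioned(), 1.71)
  r_lo <- attr(find_optimal_pair(lo, tiny_head(), tiny_layout(),
                                 refine = "none"), "optimal")$rmsd_V
  r_hi <- attr(find_optimal_pair(hi, tiny_head(), tiny_layout(),
                                 refine = "none"), "optimal")$rmsd_V
  expect_gt(r_hi, r_lo)
})
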