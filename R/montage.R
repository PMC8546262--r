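#' All candidate stimulation pairs
#'
#' Unordered pairs of the 20 outer-edge electrodes, the candidate set for
#' transcranial stimulation; each pair leaves 126 of the 128 measurement
#' electrodes available for recording.
#'
#' @param layout an [electrode_layout()] containing all outer-edge labels.
#' @return data.frame with columns `anode`, `cathode` (190 rows for the
#'   full candidate set), ordered lexicographically.
#' @export
candidate_pairs <- function(layout) {
  cand <- outer_edge_labels()
  missing <- setdiff(cand, layout$labels)
  if (length(missing))
    stop("layout is missing candidate labels: ", paste(missing, collapse = ", "))
  cand <- sort(cand)
  cmb <- t(combn(cand, 2))
  data.frame(anode = cmb[, 1], cathode = cmb[, 2], stringsAsFactors = FALSE)
}

#' Root-mean-square difference between two recordings
#'
#' `sqrt(mean((a - b)^2))` over the shared electrodes (reference excluded),
#' the montage-selection score of the lesion's effect on scalp potentials.
#'
#' @param a,b `electrode_recording`s with identical label sets and reference.
#' @return RMSD in volts.
#' @export
scalp_rmsd <- function(a, b) {
  va <- recording_values(a)
  vb <- recording_values(b)
  if (!setequal(names(va), names(vb)))
    stop("recordings have different label sets")
  vb <- vb[names(va)]
  sqrt(mean((va - vb)^2))
}

#' Find the stimulation pair most sensitive to the lesion
#'
#' Scores every candidate pair by the RMSD between the scalp potentials of
#' the lesioned and lesion-free models at the 126 non-stimulating
#' electrodes, and returns the pair with the highest score. The potential
#' differences are average-referenced before scoring so the selection does
#' not depend on the recording reference.
#'
#' By linearity of the forward problem, the search solves each model once
#' per candidate electrode (20 single-monopole right-hand sides against one
#' factorization) and forms pair solutions by superposition. With
#' `refine = "winner"` (default) the search runs on the unrefined meshes and
#' the winning pair is re-scored on locally refined meshes; `"full"` refines
#' and re-assembles for every candidate pair; `"none"` skips refinement.
#'
#' @param model_lesion,model_nolesion [head_model()]s sharing all non-lesion
#'   surfaces and conductivities.
#' @param layout an [electrode_layout()].
#' @param current stimulation current, A.
#' @param refine refinement policy: "winner", "full" or "none".
#' @param refine_radius capture radius for local refinement, mm.
#' @return a `pair_score_table`: data.frame(anode, cathode, rmsd_V) with
#'   attributes `optimal` (list with anode, cathode, rmsd_V) and the two
#'   optimal-pair recordings.
#' @export
find_optimal_pair <- function(model_lesion, model_nolesion, layout,
                              current = 1e-4, refine = c("winner", "full", "none"),
                              refine_radius = 25) {
  refine <- match.arg(refine)
  pairs <- candidate_pairs(layout)

  if (refine == "full") {
    scores <- vapply(seq_len(nrow(pairs)), function(i) {
      pair <- c(pairs$anode[i], pairs$cathode[i])
      rl <- pair_recording(refine_head_for_pair(model_lesion, layout, pair,
                                                refine_radius),
                           layout, pair, current)
      rn <- pair_recording(refine_head_for_pair(model_nolesion, layout, pair,
                                                refine_radius),
                           layout, pair, current)
      score_rmsd(rl, rn)
    }, numeric(1))
    scale <- sqrt(mean(recording_values(
      pair_recording(refine_head_for_pair(model_lesion, layout,
                                          c(pairs$anode[1], pairs$cathode[1]),
                                          refine_radius),
                     layout, c(pairs$anode[1], pairs$cathode[1]), current))^2))
  } else {
    rec_l <- monopole_recordings(model_lesion, layout, current)
    rec_n <- monopole_recordings(model_nolesion, layout, current)
    scores <- vapply(seq_len(nrow(pairs)), function(i) {
      pair <- c(pairs$anode[i], pairs$cathode[i])
      keep <- setdiff(measurement_labels(layout), pair)
      d <- (rec_l[keep, pair[1]] - rec_l[keep, pair[2]]) -
        (rec_n[keep, pair[1]] - rec_n[keep, pair[2]])
      sqrt(mean((d - mean(d))^2))
    }, numeric(1))
    p1 <- c(pairs$anode[1], pairs$cathode[1])
    keep1 <- setdiff(measurement_labels(layout), p1)
    scale <- sqrt(mean((rec_l[keep1, p1[1]] - rec_l[keep1, p1[2]])^2))
  }

  if (max(scores) <= 1e-12 * scale)
    stop("degenerate pair search: no candidate pair distinguishes the ",
         "models (zero-contrast lesion?)")

  best <- which(scores == max(scores))
  if (length(best) > 1) best <- best[order(pairs$anode[best],
                                           pairs$cathode[best])][1]
  opt_pair <- c(pairs$anode[best], pairs$cathode[best])

  if (refine == "none") {
    rl <- pair_recording(model_lesion, layout, opt_pair, current)
    rn <- pair_recording(model_nolesion, layout, opt_pair, current)
  } else {
    rl <- pair_recording(refine_head_for_pair(model_lesion, layout, opt_pair,
                                              refine_radius),
                         layout, opt_pair, current)
    rn <- pair_recording(refine_head_for_pair(model_nolesion, layout, opt_pair,
                                              refine_radius),
                         layout, opt_pair, current)
    if (refine == "winner") scores[best] <- score_rmsd(rl, rn)
  }

  tab <- data.frame(anode = pairs$anode, cathode = pairs$cathode,
                    rmsd_V = scores, stringsAsFactors = FALSE)
  structure(tab, class = c("pair_score_table", "data.frame"),
            optimal = list(anode = opt_pair[1], cathode = opt_pair[2],
                           rmsd_V = scores[best]),
            recording_lesion = rl, recording_nolesion = rn)
}

#' @export
print.pair_score_table <- function(x, ...) {
  opt <- attr(x, "optimal")
  cat(sprintf("<pair_score_table: %d pairs; optimal %s-%s, RMSD %.3e V>\n",
              nrow(x), opt$anode, opt$cathode, opt$rmsd_V))
  invisible(x)
}

# Pair-selection score: RMSD of the average-referenced lesion-induced
# potential difference. Demeaning makes the selection independent of the
# recording reference; a nasion-referenced score would otherwise favour
# pairs stimulating next to the reference electrode, whose apparent
# sensitivity is a common-mode term carried by the reference itself.
score_rmsd <- function(a, b) {
  va <- recording_values(a)
  vb <- recording_values(b)[names(recording_values(a))]
  d <- va - vb
  sqrt(mean((d - mean(d))^2))
}

# solve one model for the full pair and record at the non-stimulating electrodes
pair_recording <- function(model, layout, pair, current) {
  sys <- assemble_system(model, stim_sources(model, layout, pair, current))
  record_at_electrodes(solve_potentials(sys), layout, exclude = pair)
}

# potentials of a unit-anode monopole under every candidate electrode,
# recorded at all measurement electrodes (columns = candidate labels).
# Pair solutions follow by subtracting columns; the unbalanced single-source
# gauge component cancels in the difference.
monopole_recordings <- function(model, layout, current) {
  cand <- sort(outer_edge_labels())
  sys <- assemble_system(model, sources = NULL)
  M <- bem_matrix(sys)
  scalp <- model$surfaces[[1]]
  V <- do.call(rbind, lapply(model$surfaces, `[[`, "vertices")) / 1000
  G <- vapply(cand, function(lb) {
    src <- stim_sources(model, layout, c(lb, lb), current)  # positions only
    d <- sqrt(colSums((t(V) - src$positions[1, ] / 1000)^2))
    current / (4 * pi * d)
  }, numeric(nrow(V)))
  PHI <- solve(M, G)
  labs <- c(measurement_labels(layout), layout$reference)
  pr <- .project_points_to_mesh(layout_positions(layout, labs),
                                scalp$vertices, scalp$triangles)
  tri <- scalp$triangles[pr$triangle, , drop = FALSE]
  vals <- pr$bary[, 1] * PHI[tri[, 1], ] + pr$bary[, 2] * PHI[tri[, 2], ] +
    pr$bary[, 3] * PHI[tri[, 3], ]
  rownames(vals) <- labs
  # re-reference each monopole solution so that pair superpositions are
  # nasion-referenced like ordinary recordings (and model-specific gauge
  # constants cancel)
  vals <- sweep(vals, 2, vals[layout$reference, ])
  vals[measurement_labels(layout), , drop = FALSE]
}
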