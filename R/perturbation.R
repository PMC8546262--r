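#' Electrode coregistration error as a rigid rotation
#'
#' Systematic electrode-placement error is modelled as a rigid rotation of
#' the whole measurement montage about a head axis through the rotation
#' center. In the head frame (x = right, y = anterior, z = superior) the
#' coronal rotation is about the left-right (x) axis and the sagittal
#' rotation about the anterior-posterior (y) axis.
#'
#' @param axis "coronal" or "sagittal".
#' @param angle_deg rotation angle in degrees, in [0, 5].
#' @param center rotation center, mm (default the head origin).
#' @return object of class `rotation_spec`.
#' @export
rotation_spec <- function(axis = c("coronal", "sagittal"), angle_deg,
                          center = c(0, 0, 0)) {
  axis <- match.arg(axis)
  if (angle_deg < 0 || angle_deg > 5)
    stop("rotation angle must be in [0, 5] degrees")
  structure(list(axis = axis, angle_deg = angle_deg,
                 center = as.numeric(center)), class = "rotation_spec")
}

rotation_matrix <- function(spec) {
  th <- spec$angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  if (spec$axis == "coronal") {        # about x
    matrix(c(1, 0, 0, 0, ct, -st, 0, st, ct), 3, byrow = TRUE)
  } else {                              # about y
    matrix(c(ct, 0, st, 0, 1, 0, -st, 0, ct), 3, byrow = TRUE)
  }
}

#' Rotate an electrode layout
#'
#' Rigidly rotates all electrode positions (including the reference) about
#' the axis through the rotation center. Positions are deliberately not
#' re-projected onto the scalp: the displaced positions are what a
#' mis-coregistered montage reports.
#'
#' @param layout an [electrode_layout()].
#' @param spec a [rotation_spec()].
#' @return the rotated [electrode_layout()].
#' @export
rotate_layout <- function(layout, spec) {
  R <- rotation_matrix(spec)
  pos <- sweep(layout$positions, 2, spec$center)
  pos <- pos %*% t(R)
  pos <- sweep(pos, 2, spec$center, "+")
  electrode_layout(layout$labels, pos, reference = layout$reference)
}

#' Mean electrode displacement between two layouts
#'
#' Mean Euclidean distance over electrodes with the same label, the
#' displacement summary corresponding to a given rotation angle.
#'
#' @param a,b [electrode_layout()]s with identical labels.
#' @return mean displacement in mm.
#' @export
mean_displacement <- function(a, b) {
  if (!setequal(a$labels, b$labels)) stop("layouts have different labels")
  pb <- b$positions[a$labels, , drop = FALSE]
  mean(sqrt(rowSums((a$positions - pb)^2)))
}

#' Electrode subsets of the full montage
#'
#' Size 8 is the fixed set of electrodes closest to Cz (Cz, FCz, CPz, C1,
#' C2, FFC1h, Fz, AFF1); size 128 is the full montage; sizes 16, 32 and 64
#' are chosen by deterministic farthest-point sampling seeded at Cz, giving
#' nested, uniformly distributed subsets. The reference electrode is always
#' retained.
#'
#' @param layout the full [electrode_layout()].
#' @param size one of 8, 16, 32, 64, 128.
#' @return the subset [electrode_layout()].
#' @export
select_subset <- function(layout, size) {
  if (!size %in% c(8, 16, 32, 64, 128))
    stop("subset size must be one of 8, 16, 32, 64, 128")
  labs <- measurement_labels(layout)
  if (size == 128) return(layout)
  if (size == 8) return(layout_subset(layout, cz8_labels()))
  ord <- farthest_point_order(layout, start = "Cz")
  layout_subset(layout, ord[seq_len(size)])
}

# deterministic farthest-point ordering of the measurement electrodes,
# by geodesic (angular) distance on the directions from the head center
farthest_point_order <- function(layout, start = "Cz") {
  labs <- measurement_labels(layout)
  dirs <- layout_positions(layout, labs)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ang_to <- function(lab, who) {
    d <- as.numeric(dirs[who, , drop = FALSE] %*% dirs[lab, ])
    setNames(acos(pmin(1, pmax(-1, d))), who)
  }
  chosen <- start
  remaining <- setdiff(labs, start)
  mind <- ang_to(start, remaining)
  while (length(remaining) > 0) {
    nxt <- remaining[order(-mind[remaining], remaining)][1]
    chosen <- c(chosen, nxt)
    remaining <- setdiff(remaining, nxt)
    if (!length(remaining)) break
    mind[remaining] <- pmin(mind[remaining], ang_to(nxt, remaining))
  }
  chosen
}
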