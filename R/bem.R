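#' Current monopole source configuration
#'
#' A transcranial stimulation electrode pair is modelled as a balanced pair
#' of current monopoles (+I at the anode, -I at the cathode) placed 3 mm
#' inside the scalp compartment. Currents must sum to zero.
#'
#' @param positions monopole positions, mm (k x 3).
#' @param currents monopole currents, A; must sum to exactly 0.
#' @return object of class `source_config`.
#' @export
source_config <- function(positions, currents) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(currents))
    stop("one current per monopole required")
  if (abs(sum(currents)) > 0)
    stop("monopole currents must sum to exactly 0")
  structure(list(positions = positions, currents = as.numeric(currents)),
            class = "source_config")
}

#' Build the monopole pair for a stimulation electrode pair
#'
#' Monopoles are inset from the anode and cathode scalp positions along the
#' inward radial direction (sphere heads) or the local inward surface normal.
#'
#' @param model a [head_model()].
#' @param layout an [electrode_layout()].
#' @param pair character vector c(anode, cathode).
#' @param current stimulation current, A (default 1e-4, i.e. 0.1 mA).
#' @param depth inset below the scalp surface, mm (default 3).
#' @return a [source_config()].
#' @export
stim_sources <- function(model, layout, pair, current = 1e-4, depth = 3) {
  scalp <- model$surfaces[[1]]
  pos <- layout_positions(layout, pair)
  if (!is.null(scalp$sphere)) {
    ctr <- scalp$sphere$center
    dirs <- sweep(pos, 2, ctr)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    inset <- sweep(dirs * (scalp$sphere$radius - depth), 2, ctr, "+")
  } else {
    pr <- .project_points_to_mesh(pos, scalp$vertices, scalp$triangles)
    tri <- scalp$triangles[pr$triangle, , drop = FALSE]
    a <- scalp$vertices[tri[, 2], , drop = FALSE] - scalp$vertices[tri[, 1], , drop = FALSE]
    b <- scalp$vertices[tri[, 3], , drop = FALSE] - scalp$vertices[tri[, 1], , drop = FALSE]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    inset <- pr$point - nrm * depth
  }
  source_config(inset, c(current, -current))
}

#' Infinite-medium potential of monopole sources
#'
#' `phi(r) = sum_k I_k / (4 pi sigma |r - r_k|)` with all lengths in mm
#' converted to meters internally.
#'
#' @param sources a [source_config()].
#' @param points evaluation points, mm (k x 3).
#' @param sigma medium conductivity, S/m.
#' @return potentials in V.
#' @export
infinite_medium_potential <- function(sources, points, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  points <- as.matrix(points)
  phi <- numeric(nrow(points))
  for (k in seq_len(nrow(sources$positions))) {
    d <- sqrt(colSums((t(points) - sources$positions[k, ])^2)) / 1000
    if (any(d == 0)) stop("evaluation point coincides with a source")
    phi <- phi + sources$currents[k] / (4 * pi * sigma * d)
  }
  phi
}

#' Refine scalp and skull meshes near a stimulation pair
#'
#' Applies [refine_near_points()] to the two outermost surfaces around the
#' stimulation electrode positions, as required by the steep potential
#' gradient near the current monopoles.
#'
#' @param model a [head_model()].
#' @param layout an [electrode_layout()].
#' @param pair character vector c(anode, cathode).
#' @param radius capture radius, mm (default 25).
#' @param levels number of refinement passes.
#' @return the refined [head_model()].
#' @export
refine_head_for_pair <- function(model, layout, pair, radius = 25, levels = 1) {
  pts <- layout_positions(layout, pair)
  for (l in seq_len(levels)) {
    for (i in 1:2) {
      model$surfaces[[i]] <- refine_near_points(model$surfaces[[i]], pts, radius)
    }
  }
  model
}

#' Assemble the boundary-element system
#'
#' Linear-collocation double-layer formulation with vertex unknowns and
#' analytically integrated elements. The geometry operator is independent of
#' the conductivities, so the assembled system can be re-solved for a new
#' lesion conductivity without re-integration (see [lesion_resolver()]).
#' The polyhedral-vertex jump coefficient is obtained from the own-surface
#' row sums (the interior solid angle at each collocation vertex), which
#' makes the operator annihilate constant potentials exactly; the resulting
#' rank-1 null space is removed by area-weighted deflation at solve time.
#'
#' @param model a [head_model()] with closed, nested surfaces.
#' @param sources optional [source_config()]; monopoles must lie inside the
#'   scalp compartment (between scalp and skull surfaces).
#' @return object of class `bem_system`.
#' @export
assemble_system <- function(model, sources = NULL) {
  ns <- length(model$surfaces)
  nv <- vapply(model$surfaces, function(s) nrow(s$vertices), integer(1))
  offsets <- c(0L, cumsum(nv))
  V <- do.call(rbind, lapply(model$surfaces, `[[`, "vertices")) / 1000  # m
  Fm <- do.call(rbind, lapply(seq_len(ns), function(i)
    model$surfaces[[i]]$triangles + offsets[i]))
  surf_of_vertex <- rep(seq_len(ns), nv)

  if (!is.null(sources)) check_sources_in_scalp(model, sources)

  D <- .bem_collocation_matrix(V, Fm, V)

  # interior solid angle at each vertex = row sum over its own surface block
  omega <- numeric(nrow(V))
  for (i in seq_len(ns)) {
    idx <- (offsets[i] + 1):offsets[i + 1]
    omega[idx] <- rowSums(D[idx, idx, drop = FALSE])
  }

  sig_in <- model$conductivities
  sig_out <- c(0, sig_in[-ns])
  a <- sig_out[surf_of_vertex] + (sig_in - sig_out)[surf_of_vertex] *
    omega / (4 * pi)

  w <- unlist(lapply(model$surfaces, vertex_areas))
  w <- w / sum(w)

  g <- if (is.null(sources)) NULL else
    rowSums(vapply(seq_along(sources$currents), function(k) {
      d <- sqrt(colSums((t(V) - sources$positions[k, ] / 1000)^2))
      sources$currents[k] / (4 * pi * d)
    }, numeric(nrow(V))))

  structure(list(D = D, a = a, omega = omega, offsets = offsets,
                 surf_of_vertex = surf_of_vertex, sig_in = sig_in,
                 sig_out = sig_out, w = w, g = g, model = model,
                 sources = sources),
            class = "bem_system")
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("<bem_system: %d vertex unknowns over %d surfaces>\n",
              nrow(x$D), length(x$model$surfaces)))
  invisible(x)
}

check_sources_in_scalp <- function(model, sources) {
  scalp <- model$surfaces[[1]]
  w_in <- .mesh_winding_number(sources$positions, scalp$vertices, scalp$triangles)
  w_out <- 0
  if (length(model$surfaces) > 1) {
    skull <- model$surfaces[[2]]
    w_out <- .mesh_winding_number(sources$positions, skull$vertices,
                                  skull$triangles)
  }
  if (any(abs(w_in - 1) > 0.01) || any(abs(w_out) > 0.01))
    stop("source monopoles must lie inside the scalp compartment ",
         "(between scalp and skull surfaces)")
  invisible(TRUE)
}

# Dense system matrix with deflation. Columns of surface j are weighted by
# the conductivity jump; the diagonal carries the vertex jump coefficient.
# Chunked updates keep peak memory at one extra matrix copy.
bem_matrix <- function(system, sigma_lesion = NULL) {
  model <- system$model
  sig_in <- system$sig_in
  if (!is.null(sigma_lesion)) {
    idx <- lesion_surface_index(model)
    sig_in[idx] <- sigma_lesion
  }
  ns <- length(model$surfaces)
  sig_out <- c(0, sig_in[-ns])
  cj <- sig_in - sig_out
  a <- sig_out[system$surf_of_vertex] +
    (sig_in - sig_out)[system$surf_of_vertex] * system$omega / (4 * pi)

  M <- system$D
  n <- nrow(M)
  s <- mean(abs(a))
  w <- system$w
  chunk <- 512L
  for (j in seq_len(ns)) {
    cols <- (system$offsets[j] + 1):system$offsets[j + 1]
    for (start in seq(1, length(cols), by = chunk)) {
      cc <- cols[start:min(start + chunk - 1L, length(cols))]
      # conductivity weighting and area-weighted deflation term
      M[, cc] <- M[, cc] * (-cj[j] / (4 * pi)) +
        rep(s * w[cc], each = n)
    }
  }
  diag(M) <- diag(M) + a
  M
}

#' Solve the assembled system for the potential field
#'
#' Dense LU solve of the deflated collocation system. The returned potentials
#' satisfy the gauge `sum(area_weights * phi) = 0` and scale linearly with
#' the injected current.
#'
#' @param system a [bem_system()] assembled with sources.
#' @param sigma_lesion optional lesion conductivity overriding the model's.
#' @return object of class `potential_field`: per-surface vertex potentials (V).
#' @export
solve_potentials <- function(system, sigma_lesion = NULL) {
  if (is.null(system$g)) stop("system was assembled without sources")
  M <- bem_matrix(system, sigma_lesion)
  phi <- tryCatch(solve(M, system$g),
                  error = function(e) stop("BEM system solve failed: ",
                                           conditionMessage(e)))
  phi <- phi - sum(system$w * phi)
  as_potential_field(phi, system)
}

as_potential_field <- function(phi, system) {
  ns <- length(system$model$surfaces)
  per_surface <- lapply(seq_len(ns), function(i)
    phi[(system$offsets[i] + 1):system$offsets[i + 1]])
  names(per_surface) <- vapply(system$model$surfaces, `[[`, character(1), "label")
  structure(list(potentials = per_surface, model = system$model,
                 sources = system$sources),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  rng <- range(x$potentials[[1]])
  cat(sprintf("<potential_field: %d surfaces, scalp range [%.3g, %.3g] V>\n",
              length(x$potentials), rng[1], rng[2]))
  invisible(x)
}

#' Cheap re-solves across lesion conductivities
#'
#' The system matrix depends on the lesion conductivity only through its
#' lesion-surface columns, which are linear in it. One factorization of the
#' deflated base matrix plus a low-rank (Woodbury) correction therefore
#' yields the potential field at any lesion conductivity at the cost of a
#' small dense solve -- this is what makes the multi-start estimator
#' tractable.
#'
#' @param system a [bem_system()] for a model with a lesion, assembled with
#'   sources.
#' @return a function `f(sigma_lesion)` returning the gauge-fixed potential
#'   vector over all vertices.
#' @export
lesion_resolver <- function(system) {
  if (is.null(system$g)) stop("system was assembled without sources")
  les <- lesion_surface_index(system$model)
  sigma_ref <- system$sig_in[les]
  lidx <- (system$offsets[les] + 1):system$offsets[les + 1]
  nl <- length(lidx)

  # d M / d sigma_lesion: lesion columns of -D/(4 pi), plus the lesion-row
  # diagonal jump coefficient derivative omega/(4 pi)
  K <- system$D[, lidx, drop = FALSE] * (-1 / (4 * pi))
  K[cbind(lidx, seq_len(nl))] <- K[cbind(lidx, seq_len(nl))] +
    system$omega[lidx] / (4 * pi)

  M <- bem_matrix(system)
  Z <- solve(M, cbind(K, system$g))
  Y <- Z[, seq_len(nl), drop = FALSE]
  z0 <- Z[, nl + 1]
  CL <- Y[lidx, , drop = FALSE]
  z0l <- z0[lidx]
  w <- system$w

  function(sigma_lesion) {
    stopifnot(sigma_lesion > 0)
    delta <- sigma_lesion - sigma_ref
    phi <- if (delta == 0) z0 else {
      small <- diag(nl) + delta * CL
      z0 - delta * as.numeric(Y %*% solve(small, z0l))
    }
    phi - sum(w * phi)
  }
}

#' Potentials at labelled electrodes
#'
#' Interpolates the scalp potential at each electrode by barycentric
#' interpolation on its containing scalp triangle (electrodes up to
#' `tolerance` mm off the surface are projected to the nearest triangle),
#' then re-references by subtracting the reference electrode's value. The
#' stimulation pair is excluded from the output.
#'
#' @param field a [potential_field()].
#' @param layout an [electrode_layout()].
#' @param exclude labels to drop (normally the stimulation pair).
#' @param tolerance maximum electrode-to-scalp distance, mm (default 2).
#' @param provenance "simulated" or "recorded".
#' @return an `electrode_recording`: data.frame(label, potential_V) with the
#'   reference at exactly 0 V.
#' @export
record_at_electrodes <- function(field, layout, exclude = character(),
                                 tolerance = 2, provenance = "simulated") {
  record_scalp_values(field$model$surfaces[[1]], field$potentials[[1]],
                      layout, exclude, tolerance, provenance)
}

# interpolation core shared by record_at_electrodes and the cached solvers
record_scalp_values <- function(scalp, phi, layout, exclude = character(),
                                tolerance = 2, provenance = "simulated") {
  pr <- .project_points_to_mesh(layout$positions, scalp$vertices,
                                scalp$triangles)
  if (any(pr$distance > tolerance))
    stop(sprintf("electrode(s) farther than %g mm from the scalp surface: %s",
                 tolerance,
                 paste(layout$labels[pr$distance > tolerance], collapse = ", ")))
  tri <- scalp$triangles[pr$triangle, , drop = FALSE]
  vals <- rowSums(pr$bary * cbind(phi[tri[, 1]], phi[tri[, 2]], phi[tri[, 3]]))
  names(vals) <- layout$labels
  vals <- vals - vals[layout$reference]
  keep <- setdiff(layout$labels, exclude)
  rec <- data.frame(label = keep, potential_V = as.numeric(vals[keep]),
                    stringsAsFactors = FALSE)
  structure(rec, class = c("electrode_recording", "data.frame"),
            reference = layout$reference, stim_pair = exclude,
            provenance = provenance)
}

# recording values excluding the reference electrode, as a named vector
recording_values <- function(recording) {
  ref <- attr(recording, "reference")
  keep <- recording$label != ref
  setNames(recording$potential_V[keep], recording$label[keep])
}
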