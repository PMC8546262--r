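#' Nested-compartment head model
#'
#' Ordered set of closed surfaces, outermost first (scalp, skull, CSF, brain,
#' and optionally a lesion), each with the conductivity of the tissue it
#' encloses. The medium outside the scalp is insulating (conductivity 0).
#' Default tissue conductivities are 0.414 (scalp), 0.016 (skull),
#' 1.71 (CSF) and 0.37 (brain) S/m.
#'
#' @param surfaces list of [triangle_surface()], outermost to innermost.
#' @param conductivities conductivity (S/m) inside each surface.
#' @param validate verify nesting of consecutive surfaces.
#' @return object of class `head_model`.
#' @export
head_model <- function(surfaces, conductivities, validate = TRUE) {
  if (length(surfaces) != length(conductivities))
    stop("need one conductivity per surface")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  if (validate && length(surfaces) > 1) {
    for (i in 2:length(surfaces)) {
      if (!surface_inside(surfaces[[i]], surfaces[[i - 1]]))
        stop("surface '", surfaces[[i]]$label,
             "' is not strictly inside '", surfaces[[i - 1]]$label, "'")
    }
  }
  structure(list(surfaces = surfaces,
                 conductivities = as.numeric(conductivities)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model>\n")
  for (i in seq_along(x$surfaces))
    cat(sprintf("  %-8s %6d triangles  sigma_in = %.3f S/m\n",
                x$surfaces[[i]]$label, n_triangles(x$surfaces[[i]]),
                x$conductivities[i]))
  invisible(x)
}

# inner strictly inside outer (analytic for concentric spheres, winding
# number + clearance otherwise)
surface_inside <- function(inner, outer, margin = 0) {
  if (!is.null(inner$sphere) && !is.null(outer$sphere)) {
    d <- sqrt(sum((inner$sphere$center - outer$sphere$center)^2))
    return(d + inner$sphere$radius + margin < outer$sphere$radius)
  }
  w <- .mesh_winding_number(inner$vertices, outer$vertices, outer$triangles)
  all(abs(w - 1) < 0.01)
}

#' Concentric 4-shell spherical head model
#'
#' Builds scalp, skull, CSF and brain compartments as concentric icospheres.
#' The subdivision level is the smallest giving at least `elements_per_surface`
#' triangles per surface (icospheres admit `20 * 4^k` triangles, so a request
#' of 3200 yields 5120, within twice the request).
#'
#' @param radii strictly decreasing surface radii in mm
#'   (default 92, 86, 80, 78).
#' @param conductivities tissue conductivities in S/m, outermost first
#'   (default 0.414, 0.016, 1.71, 0.37).
#' @param elements_per_surface requested triangle count per surface.
#' @return a [head_model()] with 4 surfaces.
#' @export
make_sphere_head <- function(radii = c(92, 86, 80, 78),
                             conductivities = c(0.414, 0.016, 1.71, 0.37),
                             elements_per_surface = 3200) {
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  subdiv <- icosphere_subdivisions(elements_per_surface)
  labels <- c("scalp", "skull", "csf", "brain")
  surfaces <- lapply(seq_along(radii), function(i)
    make_icosphere(c(0, 0, 0), radii[i], subdiv, label = labels[i]))
  head_model(surfaces, conductivities)
}

icosphere_subdivisions <- function(elements) {
  max(0L, as.integer(ceiling(log(elements / 20) / log(4) - 1e-9)))
}

#' Spherical lesion specification
#'
#' @param center lesion center, mm (length 3).
#' @param radius lesion radius, mm, > 0.
#' @param conductivity lesion conductivity, S/m, in (0, 2].
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, conductivity) {
  if (radius <= 0) stop("lesion radius must be positive")
  if (conductivity <= 0 || conductivity > 2)
    stop("lesion conductivity must be in (0, 2] S/m")
  structure(list(center = as.numeric(center), radius = radius,
                 conductivity = conductivity), class = "lesion_spec")
}

#' Add a spherical lesion compartment
#'
#' Appends a spherical lesion surface strictly inside the brain compartment
#' (at least 1 mm clearance). The original model is not modified.
#'
#' @param model a 4-surface [head_model()].
#' @param spec a [lesion_spec()].
#' @param elements requested lesion mesh triangle count.
#' @return a 5-surface [head_model()].
#' @export
add_spherical_lesion <- function(model, spec, elements = 1280) {
  if (has_lesion(model)) stop("model already has a lesion surface")
  brain <- model$surfaces[[length(model$surfaces)]]
  lesion <- make_icosphere(spec$center, spec$radius,
                           icosphere_subdivisions(elements), label = "lesion")
  if (!surface_inside(lesion, brain, margin = 1))
    stop("lesion sphere (with 1 mm margin) is not strictly inside the brain surface")
  head_model(c(model$surfaces, list(lesion)),
             c(model$conductivities, spec$conductivity), validate = FALSE)
}

has_lesion <- function(model) {
  any(vapply(model$surfaces, function(s) s$label == "lesion", logical(1)))
}

lesion_surface_index <- function(model) {
  idx <- which(vapply(model$surfaces, function(s) s$label == "lesion", logical(1)))
  if (length(idx) != 1L) stop("model has no lesion surface")
  idx
}

#' Replace the lesion conductivity
#'
#' @param model a [head_model()] with a lesion surface.
#' @param conductivity new lesion conductivity, S/m.
#' @return the model with updated lesion conductivity.
#' @export
set_lesion_conductivity <- function(model, conductivity) {
  idx <- lesion_surface_index(model)
  if (conductivity <= 0) stop("conductivity must be positive")
  model$conductivities[idx] <- conductivity
  model
}

#' Lesion volume and depth
#'
#' Volume is the divergence-theorem volume of the lesion mesh (ml); depth is
#' the distance from the area-weighted lesion centroid to the nearest vertex
#' (mesh node) of the scalp surface (mm).
#'
#' @param model a [head_model()] with a lesion surface.
#' @return list with `volume_ml` and `depth_mm`.
#' @export
lesion_metrics <- function(model) {
  idx <- lesion_surface_index(model)
  lesion <- model$surfaces[[idx]]
  scalp <- model$surfaces[[1]]
  w <- vertex_areas(lesion)
  centroid <- colSums(lesion$vertices * w) / sum(w)
  d <- sqrt(colSums((t(scalp$vertices) - centroid)^2))
  list(volume_ml = surface_volume(lesion) / 1000, depth_mm = min(d))
}
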