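#' Closed triangulated surface
#'
#' A `triangle_surface` is a closed, consistently oriented triangle mesh with
#' outward normals, used to bound one head compartment. Vertices are in mm.
#' Surfaces generated from an analytic sphere carry a `sphere` attribute
#' (center, radius) so that refinement can re-project new vertices.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices, wound
#'   counter-clockwise seen from outside.
#' @param label short name for the surface (e.g. "scalp").
#' @param sphere optional list(center, radius) if the mesh samples a sphere.
#' @param validate check closure, orientation and non-degeneracy.
#' @return object of class `triangle_surface`.
#' @export
triangle_surface <- function(vertices, triangles, label = "surface",
                             sphere = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  s <- structure(list(vertices = vertices, triangles = triangles,
                      label = as.character(label), sphere = sphere),
                 class = "triangle_surface")
  if (validate) {
    if (!is_closed_surface(s))
      stop("surface '", label, "' is not closed and consistently oriented")
    if (any(triangle_areas(s) <= 0))
      stop("surface '", label, "' contains degenerate triangles")
    if (surface_volume(s) <= 0)
      stop("surface '", label, "' is not oriented with outward normals")
  }
  s
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("<triangle_surface '%s': %d vertices, %d triangles, volume %.1f mm^3>\n",
              x$label, nrow(x$vertices), nrow(x$triangles), surface_volume(x)))
  invisible(x)
}

n_triangles <- function(surface) nrow(surface$triangles)

directed_edges <- function(surface) {
  tri <- surface$triangles
  cbind(c(tri[, 1], tri[, 2], tri[, 3]), c(tri[, 2], tri[, 3], tri[, 1]))
}

#' Test closure and consistent orientation
#'
#' A closed, consistently oriented mesh has every undirected edge shared by
#' exactly two triangles, traversed once in each direction.
#'
#' @param surface a [triangle_surface()].
#' @return logical.
#' @export
is_closed_surface <- function(surface) {
  de <- directed_edges(surface)
  key <- paste(de[, 1], de[, 2])
  if (anyDuplicated(key) > 0L) return(FALSE)  # repeated directed edge
  rev_key <- paste(de[, 2], de[, 1])
  all(key %in% rev_key)
}

#' Triangle areas of a surface (mm^2)
#' @param surface a [triangle_surface()].
#' @return numeric vector, one area per triangle.
#' @export
triangle_areas <- function(surface) {
  v <- surface$vertices
  tri <- surface$triangles
  a <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

triangle_centroids <- function(surface) {
  v <- surface$vertices
  tri <- surface$triangles
  (v[tri[, 1], , drop = FALSE] + v[tri[, 2], , drop = FALSE] +
     v[tri[, 3], , drop = FALSE]) / 3
}

#' Enclosed volume of a closed surface (mm^3)
#'
#' Signed volume by the divergence theorem; positive for outward orientation.
#'
#' @param surface a [triangle_surface()].
#' @return numeric scalar in mm^3.
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices
  tri <- surface$triangles
  p1 <- v[tri[, 1], , drop = FALSE]
  p2 <- v[tri[, 2], , drop = FALSE]
  p3 <- v[tri[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# Per-vertex area weights (one third of incident triangle areas).
vertex_areas <- function(surface) {
  ar <- triangle_areas(surface) / 3
  w <- numeric(nrow(surface$vertices))
  for (k in 1:3) {
    acc <- tapply(ar, surface$triangles[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + as.numeric(acc)
  }
  w
}

#' Triangulated sphere by icosahedron subdivision
#'
#' Recursively subdivides an icosahedron, projecting new vertices onto the
#' sphere, producing `20 * 4^subdivisions` triangles. The enclosed volume
#' converges to `4/3 pi r^3` from below as the subdivision level increases.
#'
#' @param center sphere center (mm, length 3).
#' @param radius sphere radius (mm), > 0.
#' @param subdivisions non-negative integer subdivision level.
#' @param label surface label.
#' @return a [triangle_surface()] carrying a `sphere` attribute.
#' @export
make_icosphere <- function(center = c(0, 0, 0), radius, subdivisions = 0,
                           label = "sphere") {
  if (radius <= 0) stop("radius must be positive")
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_all(v, f)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$triangles
  }
  v <- sweep(v * radius, 2, as.numeric(center), "+")
  triangle_surface(v, f, label = label,
                   sphere = list(center = as.numeric(center), radius = radius))
}

# 4-way midpoint subdivision of every triangle (shared midpoints merged).
subdivide_all <- function(vertices, triangles) {
  nv <- nrow(vertices)
  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uniq <- !duplicated(ekey)
  mid_ids <- setNames(nv + seq_len(sum(uniq)), ekey[uniq])
  mids <- (vertices[edges[uniq, 1], , drop = FALSE] +
           vertices[edges[uniq, 2], , drop = FALSE]) / 2
  m <- matrix(mid_ids[ekey], ncol = 3)  # midpoint ids: (12), (23), (31)
  newf <- rbind(cbind(triangles[, 1], m[, 1], m[, 3]),
                cbind(triangles[, 2], m[, 2], m[, 1]),
                cbind(triangles[, 3], m[, 3], m[, 2]),
                m)
  list(vertices = rbind(vertices, mids), triangles = newf)
}

#' Local red-green mesh refinement around points
#'
#' Triangles whose centroid lies within `radius` of any of `points` are
#' 4-way subdivided ("red"); neighbours are bisected ("green") as needed so
#' the result stays closed with no hanging vertices. On sphere-derived
#' surfaces new vertices are re-projected onto the analytic sphere.
#'
#' @param surface a closed [triangle_surface()].
#' @param points matrix (k x 3) of attraction points, mm.
#' @param radius capture radius in mm.
#' @return refined [triangle_surface()].
#' @export
refine_near_points <- function(surface, points, radius) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) < 1L) stop("points must be nonempty")
  if (radius <= 0) stop("radius must be positive")
  if (!is_closed_surface(surface)) stop("input surface must be closed")

  cen <- triangle_centroids(surface)
  near <- rep(FALSE, nrow(cen))
  for (i in seq_len(nrow(points)))
    near <- near | sqrt(colSums((t(cen) - points[i, ])^2)) <= radius
  if (!any(near)) return(surface)

  tri <- surface$triangles
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tri_edges <- function(f) cbind(ekey(f[, 1], f[, 2]),
                                 ekey(f[, 2], f[, 3]),
                                 ekey(f[, 3], f[, 1]))
  ek <- tri_edges(tri)

  red <- near
  repeat {  # promote triangles with >= 2 split edges to red
    split_edges <- unique(as.vector(ek[red, , drop = FALSE]))
    nsplit <- matrix(ek %in% split_edges, ncol = 3)
    promote <- !red & rowSums(nsplit) >= 2
    if (!any(promote)) break
    red <- red | promote
  }
  nsplit_count <- rowSums(matrix(ek %in% split_edges, ncol = 3))
  green <- !red & nsplit_count == 1

  v <- surface$vertices
  mid_id <- new.env(parent = emptyenv())
  vlist <- list(v)
  nv <- nrow(v)
  get_mid <- function(a, b) {
    key <- ekey(a, b)
    if (!is.null(mid_id[[key]])) return(mid_id[[key]])
    p <- (v[a, ] + v[b, ]) / 2
    if (!is.null(surface$sphere)) {
      d <- p - surface$sphere$center
      p <- surface$sphere$center + d / sqrt(sum(d^2)) * surface$sphere$radius
    }
    nv <<- nv + 1L
    vlist[[length(vlist) + 1L]] <<- matrix(p, 1)
    mid_id[[key]] <- nv
    nv
  }

  out <- vector("list", nrow(tri))
  for (i in seq_len(nrow(tri))) {
    a <- tri[i, 1]; b <- tri[i, 2]; cc <- tri[i, 3]
    if (red[i]) {
      mab <- get_mid(a, b); mbc <- get_mid(b, cc); mca <- get_mid(cc, a)
      out[[i]] <- rbind(c(a, mab, mca), c(b, mbc, mab), c(cc, mca, mbc),
                        c(mab, mbc, mca))
    } else if (green[i]) {
      which_e <- which(ek[i, ] %in% split_edges)
      # rotate so the split edge is (a, b)
      ord <- switch(which_e, c(a, b, cc), c(b, cc, a), c(cc, a, b))
      m <- get_mid(ord[1], ord[2])
      out[[i]] <- rbind(c(ord[1], m, ord[3]), c(m, ord[2], ord[3]))
    } else {
      out[[i]] <- matrix(c(a, b, cc), 1)
    }
  }
  triangle_surface(do.call(rbind, vlist), do.call(rbind, out),
                   label = surface$label, sphere = surface$sphere)
}
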