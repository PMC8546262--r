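#' Labelled electrode layout
#'
#' Measurement electrodes of the 10/5 system plus a reference electrode,
#' with positions on (or near) the scalp surface in mm. The head frame is
#' x = right, y = anterior, z = superior.
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix (n x 3), mm.
#' @param reference label of the reference electrode (default "nasion").
#' @return object of class `electrode_layout`.
#' @export
electrode_layout <- function(labels, positions, reference = "nasion") {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  if (nrow(positions) != length(labels))
    stop("one position per label required")
  if (!reference %in% labels) stop("reference label '", reference,
                                   "' not in layout")
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, positions = positions,
                 reference = reference), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout: %d electrodes (reference '%s')>\n",
              length(x$labels), x$reference))
  invisible(x)
}

#' The 20 outer-edge stimulation candidate labels
#' @return character vector of length 20.
#' @export
outer_edge_labels <- function() {
  c("Fp1", "Fp2", "F7", "F8", "FT9", "FT10", "FTT9h", "FTT10h", "T7", "T8",
    "TTP7h", "TTP8h", "TP7", "TP8", "TPP9h", "TPP10h", "P9", "P10", "I1", "I2")
}

#' The fixed 8-electrode subset around Cz
#' @return character vector of length 8.
#' @export
cz8_labels <- function() {
  c("Cz", "FCz", "CPz", "C1", "C2", "FFC1h", "Fz", "AFF1")
}

#' Canonical 10/5 unit-direction table
#'
#' 128 measurement labels plus the nasion reference as unit directions from
#' the head center (x = right, y = anterior, z = superior), derived from the
#' standard 10/5 montage and aligned so Cz is the vertex.
#'
#' @return data.frame with columns label, x, y, z.
#' @export
ten_five_table <- function() {
  path <- system.file("extdata", "ten_five_128.tsv", package = "lesionbem")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Place the 10/5 montage on a scalp surface
#'
#' Each canonical unit direction is projected onto the scalp along the ray
#' from the head center; on sphere-derived scalps the projection is exact
#' (|position| equals the scalp radius) and Cz maps to the topmost point.
#'
#' @param scalp the scalp [triangle_surface()].
#' @param canonical_layout table of unit directions as from [ten_five_table()].
#' @return an [electrode_layout()].
#' @export
place_electrodes_10_5 <- function(scalp, canonical_layout = ten_five_table()) {
  required <- c(outer_edge_labels(), cz8_labels(), "nasion")
  missing <- setdiff(required, canonical_layout$label)
  if (length(missing))
    stop("canonical layout is missing required labels: ",
         paste(missing, collapse = ", "))
  dirs <- as.matrix(canonical_layout[, c("x", "y", "z")])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  if (!is.null(scalp$sphere)) {
    pos <- sweep(dirs * scalp$sphere$radius, 2, scalp$sphere$center, "+")
  } else {
    # ray casting from the mesh centroid: scale each direction to the
    # surface by projecting candidate radii onto the mesh
    center <- colMeans(scalp$vertices)
    rmax <- max(sqrt(colSums((t(scalp$vertices) - center)^2)))
    pos <- t(vapply(seq_len(nrow(dirs)), function(i) {
      pr <- .project_points_to_mesh(matrix(center + dirs[i, ] * rmax * 1.2, 1),
                                    scalp$vertices, scalp$triangles)
      pr$point[1, ]
    }, numeric(3)))
  }
  electrode_layout(canonical_layout$label, pos, reference = "nasion")
}

#' Read / write an electrode layout as TSV
#'
#' Plain tab-separated table with header `label  x  y  z`, coordinates in mm.
#'
#' @param path file path.
#' @param reference reference label.
#' @return [read_layout_tsv()]: an [electrode_layout()].
#' @export
read_layout_tsv <- function(path, reference = "nasion") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  electrode_layout(tab$label, as.matrix(tab[, c("x", "y", "z")]),
                   reference = reference)
}

#' @param layout an [electrode_layout()].
#' @rdname read_layout_tsv
#' @export
write_layout_tsv <- function(layout, path) {
  tab <- data.frame(label = layout$labels, x = layout$positions[, 1],
                    y = layout$positions[, 2], z = layout$positions[, 3])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

# positions of given labels as a matrix
layout_positions <- function(layout, labels) {
  missing <- setdiff(labels, layout$labels)
  if (length(missing)) stop("labels not in layout: ",
                            paste(missing, collapse = ", "))
  layout$positions[labels, , drop = FALSE]
}

# layout restricted to given labels (reference always kept)
layout_subset <- function(layout, labels) {
  keep <- union(labels, layout$reference)
  keep <- layout$labels[layout$labels %in% keep]
  electrode_layout(keep, layout$positions[keep, , drop = FALSE],
                   reference = layout$reference)
}

# measurement labels (everything but the reference)
measurement_labels <- function(layout) {
  setdiff(layout$labels, layout$reference)
}
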