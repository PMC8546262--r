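#' Read a triangulated surface from PLY, STL or OFF
#'
#' Supports ASCII and binary little-endian PLY, ASCII and binary STL, and
#' ASCII OFF. STL files carry no vertex connectivity, so coincident vertices
#' are merged on read to recover a closed mesh.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of "ply", "stl", "off".
#' @param label surface label (defaults to the file name).
#' @return a [triangle_surface()].
#' @export
read_surface <- function(path, format = tools::file_ext(path), label = NULL) {
  format <- tolower(format)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    ply = read_ply(path, label),
    stl = read_stl(path, label),
    off = read_off(path, label),
    stop("unsupported mesh format: ", format))
}

#' Write a triangulated surface to PLY, STL or OFF
#'
#' @param surface a [triangle_surface()].
#' @param path output path; format inferred from the extension unless given.
#' @param format one of "ply", "stl", "off".
#' @param binary write the binary variant (PLY and STL only).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = tools::file_ext(path),
                          binary = FALSE) {
  format <- tolower(format)
  switch(format,
    ply = write_ply(surface, path, binary),
    stl = write_stl(surface, path, binary),
    off = {
      if (binary) stop("OFF is ASCII-only")
      write_off(surface, path)
    },
    stop("unsupported mesh format: ", format))
  invisible(path)
}

read_ply <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (!grepl("^ply", hdr[1])) stop("not a PLY file")
  fmt <- strsplit(hdr[grepl("^format", hdr)], " +")[[1]][2]
  nv <- as.integer(strsplit(hdr[grepl("^element vertex", hdr)], " +")[[1]][3])
  nf <- as.integer(strsplit(hdr[grepl("^element face", hdr)], " +")[[1]][3])
  if (fmt == "ascii") {
    vl <- readLines(con, nv)
    v <- matrix(as.numeric(unlist(strsplit(trimws(vl), " +"))), ncol = 3,
                byrow = TRUE)
    fl <- readLines(con, nf)
    fm <- matrix(as.integer(unlist(strsplit(trimws(fl), " +"))), ncol = 4,
                 byrow = TRUE)
    if (any(fm[, 1] != 3L)) stop("only triangle faces are supported")
    f <- fm[, 2:4] + 1L
  } else if (fmt == "binary_little_endian") {
    v <- matrix(readBin(con, "double", nv * 3, size = 4, endian = "little"),
                ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
      if (cnt != 3L) stop("only triangle faces are supported")
      f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  triangle_surface(v, f, label = label)
}

write_ply <- function(surface, path, binary) {
  v <- surface$vertices
  f <- surface$triangles - 1L
  fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
  hdr <- c("ply", paste("format", fmt),
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(3L, con, size = 1)
      writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
    }
  } else {
    lines <- c(hdr,
               apply(v, 1, function(r) paste(format(r, digits = 9), collapse = " ")),
               apply(f, 1, function(r) paste(c(3L, r), collapse = " ")))
    writeLines(lines, path)
  }
}

read_stl <- function(path, label) {
  raw5 <- readBin(path, "raw", n = 5)
  if (identical(raw5, charToRaw("solid")) && is_ascii_stl(path)) {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                              function(x) x[2:4]))),
                     ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "double", 12, size = 4, endian = "little")
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  }
  merge_soup(coords, label)
}

is_ascii_stl <- function(path) {
  # a binary STL may also start with "solid"; require a facet keyword in text
  txt <- suppressWarnings(readLines(path, n = 3))
  any(grepl("facet", txt))
}

# merge duplicated vertices of a triangle soup (3 rows per triangle)
merge_soup <- function(coords, label) {
  key <- apply(round(coords, 6), 1, paste, collapse = ",")
  ids <- match(key, key[!duplicated(key)])
  v <- coords[!duplicated(key), , drop = FALSE]
  f <- matrix(ids, ncol = 3, byrow = TRUE)
  triangle_surface(v, f, label = label)
}

write_stl <- function(surface, path, binary) {
  v <- surface$vertices
  tri <- surface$triangles
  a <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(nrow(tri), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tri))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[tri[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", surface$label), con)
    for (i in seq_len(nrow(tri))) {
      writeLines(c(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", v[tri[i, ], 1],
                           v[tri[i, ], 2], v[tri[i, ], 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines(paste("endsolid", surface$label), con)
  }
}

read_off <- function(path, label) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"))),
              ncol = 3, byrow = TRUE)
  fm <- matrix(as.integer(unlist(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]),
                                          "\\s+"))), ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop("only triangle faces are supported")
  triangle_surface(v, fm[, 2:4] + 1L, label = label)
}

write_off <- function(surface, path) {
  v <- surface$vertices
  f <- surface$triangles - 1L
  lines <- c("OFF", paste(nrow(v), nrow(f), 0),
             apply(v, 1, function(r) paste(format(r, digits = 9), collapse = " ")),
             apply(f, 1, function(r) paste(c(3L, r), collapse = " ")))
  writeLines(lines, path)
}
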