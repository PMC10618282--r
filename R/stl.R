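#' Read a triangulated surface from an STL file
#'
#' Reads binary or ASCII STL (auto-detected), welds duplicated vertices
#' within `1e-8` of the bounding-box diagonal, re-indexes the triangles and
#' computes facet geometry.  STL carries no units; `unit_scale` converts the
#' stored coordinates to meters (e.g. `1e-3` for millimeter files).  When
#' the mesh is closed but wound inward (negative signed volume) the
#' orientation is corrected with a warning.
#'
#' @param path STL file path.
#' @param unit_scale multiplicative factor applied to coordinates.
#' @return a [triangle_mesh()].
#' @export
load_stl <- function(path, unit_scale = 1) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  tri9 <- if (is_binary_stl(raw)) parse_stl_binary(raw) else
    parse_stl_ascii(rawToChar(raw))
  if (nrow(tri9) == 0) stop("no facets parsed from ", path)
  tri9 <- tri9 * unit_scale
  # weld duplicated vertices on a tolerance grid
  verts <- rbind(tri9[, 1:3], tri9[, 4:6], tri9[, 7:9])
  bbox <- apply(verts, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  tol <- max(1e-8 * diag_len, .Machine$double.xmin)
  key <- paste(round(verts[, 1] / tol), round(verts[, 2] / tol),
               round(verts[, 3] / tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  nf <- nrow(tri9)
  triangles <- cbind(idx[seq_len(nf)], idx[nf + seq_len(nf)],
                     idx[2 * nf + seq_len(nf)])
  degen <- triangles[, 1] == triangles[, 2] | triangles[, 2] == triangles[, 3] |
    triangles[, 3] == triangles[, 1]
  if (any(degen))
    stop("zero-area facets after vertex welding at indices: ",
         paste(utils::head(which(degen), 20), collapse = ", "))
  mesh <- triangle_mesh(verts[first, , drop = FALSE], triangles)
  rep_ <- validate_closed_manifold(mesh)
  if (rep_$is_closed && rep_$is_oriented && rep_$signed_volume < 0) {
    warning("mesh in ", basename(path),
            " is wound inward; flipping facet orientation")
    mesh <- triangle_mesh(mesh$vertices, mesh$triangles[, c(1, 3, 2)])
  }
  mesh
}

is_binary_stl <- function(raw) {
  if (length(raw) < 84) return(FALSE)
  n <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  length(raw) == 84 + 50 * n
}

parse_stl_binary <- function(raw) {
  n <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  body <- raw[-(1:84)]
  out <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    rec <- body[(i - 1) * 50 + seq_len(48)]
    vals <- readBin(rec, "numeric", n = 12, size = 4, endian = "little")
    out[i, ] <- vals[4:12]  # skip the stored normal; recomputed from winding
  }
  out
}

parse_stl_ascii <- function(txt) {
  lines <- strsplit(txt, "\r?\n")[[1]]
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3 != 0)
    stop("malformed ASCII STL: vertex count not a multiple of 3")
  nums <- vapply(strsplit(trimws(vlines), "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) stop("malformed ASCII STL vertex line")
    v
  }, numeric(3))
  matrix(as.vector(nums), ncol = 9, byrow = TRUE)
}

#' Write a mesh to an STL file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param ascii write ASCII STL instead of binary.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, ascii = FALSE, name = "tmsbem") {
  tri9 <- facet_matrix(mesh)
  n <- nrow(tri9)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("solid", name), con)
    for (i in seq_len(n)) {
      writeLines(c(sprintf("  facet normal %.9e %.9e %.9e",
                           mesh$normals[i, 1], mesh$normals[i, 2],
                           mesh$normals[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9e %.9e %.9e",
                           tri9[i, c(1, 4, 7)], tri9[i, c(2, 5, 8)],
                           tri9[i, c(3, 6, 9)]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(paste("endsolid", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", name))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    for (i in seq_len(n)) {
      writeBin(c(mesh$normals[i, ], tri9[i, ]), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
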