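#' Construct a triangle mesh
#'
#' Builds a `tri_mesh` from a vertex matrix and face index matrix,
#' deduplicating vertices that coincide within `tol` and computing
#' area-weighted per-vertex unit normals.  Meshes need not be watertight.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param tol vertex-merge tolerance, mm (default 1e-6).
#' @return An object of class `tri_mesh` with elements `vertices`,
#'   `faces`, `normals` (per-vertex unit normals).
#' @export
tri_mesh <- function(vertices, faces, tol = 1e-6) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  ap_check(ncol(vertices) == 3 && is.numeric(vertices),
           "tri_mesh: `vertices` must be an n x 3 numeric matrix")
  ap_check(all(is.finite(vertices)), "tri_mesh: vertices must be finite")
  ap_check(all(faces >= 1L) && all(faces <= nrow(vertices)),
           "tri_mesh: faces reference invalid vertices")
  # merge coincident vertices on a tol-grid
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  m <- structure(list(vertices = vertices, faces = faces, normals = NULL),
                 class = "tri_mesh")
  m$normals <- vertex_normals(m)
  m
}

face_normals_raw <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  # cross product; magnitude = 2 * triangle area (gives area weighting)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vertex_normals <- function(mesh) {
  fn <- face_normals_raw(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(n))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(n))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.tri_mesh <- function(x, ...) {
  r <- apply(x$vertices, 2, range)
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): x [%.3g, %.3g], y [%.3g, %.3g], z [%.3g, %.3g]\n",
              r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  invisible(x)
}

#' Read an STL file (ASCII or binary)
#'
#' Detects the variant automatically: a file is treated as binary when its
#' size matches the 84 + 50 n layout implied by its triangle-count field,
#' otherwise parsed as ASCII.  Vertices are deduplicated within 1e-6 mm
#' and per-vertex area-weighted normals recomputed (facet normals stored
#' in the file are ignored).
#'
#' @param path file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  ap_check(!is.na(sz) && sz > 0, paste0("read_stl: cannot read `", path, "`"))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = min(84, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(header[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) read_stl_binary(con, ntri) else read_stl_ascii(path)
}

read_stl_binary <- function(con, ntri) {
  rec <- readBin(con, "raw", n = 50 * ntri)
  ap_check(length(rec) == 50 * ntri,
           sprintf("read_stl: truncated binary STL at byte offset %d", 84 + length(rec)))
  m <- matrix(rec, nrow = 50)
  tri <- vapply(seq_len(ntri), function(i)
    readBin(m[1:48, i], "numeric", n = 12, size = 4, endian = "little"),
    numeric(12))
  tri <- t(tri)  # ntri x 12: normal, v1, v2, v3
  verts <- rbind(tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE],
                 tri[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3 * ntri), ntri, 3)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines)
  ap_check(length(vx) > 0 && length(vx) %% 3 == 0,
           sprintf("read_stl: malformed ASCII STL `%s` (%d vertex lines, not a multiple of 3; near byte offset %d)",
                   path, length(vx),
                   if (length(vx)) sum(nchar(lines[seq_len(max(vx[1] - 1, 0))])) else 0))
  parts <- strsplit(trimws(lines[vx]), "\\s+")
  verts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  ap_check(all(is.finite(verts)),
           sprintf("read_stl: unparseable vertex near line %d of `%s`",
                   vx[which(!stats::complete.cases(verts))[1]], path))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

#' Write a mesh as STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @param binary write binary STL (default FALSE, ASCII).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  ap_check(inherits(mesh, "tri_mesh"), "write_stl: `mesh` must be a tri_mesh")
  fn <- face_normals_raw(mesh)
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    out <- character(2 + 7 * nrow(f))
    out[1] <- "solid anisoprint"
    k <- 2
    for (i in seq_len(nrow(f))) {
      out[k] <- sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3])
      out[k + 1] <- "    outer loop"
      out[k + 2:4] <- sprintf("      vertex %.9g %.9g %.9g",
                              v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3])
      out[k + 5] <- "    endloop"
      out[k + 6] <- "  endfacet"
      k <- k + 7
    }
    out[k] <- "endsolid anisoprint"
    writeLines(out, path)
  }
  invisible(path)
}
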