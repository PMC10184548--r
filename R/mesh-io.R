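#' Read a triangle mesh from STL, OBJ or PLY
#'
#' Dispatches on the file extension (`.stl`, `.obj`, `.ply`). STL may be
#' binary or ASCII (detected from content, not the header string, since many
#' exporters write binary files beginning with "solid"). OBJ support covers
#' `v`/`f` records, with polygonal faces fan-triangulated; PLY support covers
#' the ASCII format. Coordinates are taken to be millimetres.
#'
#' STL stores vertices per facet, so duplicate vertices are welded at a
#' tolerance of 1e-6 mm (deterministically, by coordinate quantisation).
#'
#' @param path File path.
#' @param weld_tol Welding tolerance in mm for per-facet formats.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("No such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = read_stl(path, weld_tol = weld_tol),
    obj = read_obj(path),
    ply = read_ply(path),
    stop(sprintf("Unsupported mesh format '.%s' (use STL, OBJ or PLY).", ext),
         call. = FALSE)
  )
}

# weld duplicate vertices by quantising coordinates to `tol`
weld_vertices <- function(tris, tol = 1e-6) {
  key <- paste(round(tris[, 1] / tol), round(tris[, 2] / tol),
               round(tris[, 3] / tol))
  idx <- match(key, unique(key))
  verts <- tris[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Read an STL file (binary or ASCII)
#'
#' @inheritParams read_mesh
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 84)
  is_binary <- FALSE
  if (length(header) == 84) {
    n_tri <- readBin(header[81:84], "integer", 1, size = 4, endian = "little")
    # binary STL size is exactly 84 + 50 * n_tri bytes
    is_binary <- !is.na(n_tri) && size == 84 + 50 * n_tri
  }
  if (is_binary) {
    n_tri <- readBin(header[81:84], "integer", 1, size = 4, endian = "little")
    body <- readBin(con, "raw", 50 * n_tri)
    # each facet: 12 floats (normal + 3 vertices), then uint16 attribute
    m <- matrix(body, nrow = 50)
    coords <- readBin(as.vector(m[1:48, ]), "double", n = 12 * n_tri,
                      size = 4, endian = "little")
    coords <- matrix(coords, ncol = 12, byrow = TRUE)
    tris <- rbind(coords[, 4:6, drop = FALSE],
                  coords[, 7:9, drop = FALSE],
                  coords[, 10:12, drop = FALSE])
    # interleave back to per-facet vertex order
    ord <- as.vector(t(matrix(seq_len(3 * n_tri), ncol = 3)))
    tris <- tris[ord, , drop = FALSE]
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      stop("Malformed ASCII STL: vertex count is not a multiple of 3.",
           call. = FALSE)
    }
    tris <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  }
  w <- weld_vertices(tris, tol = weld_tol)
  triangle_mesh(w$vertices, w$faces,
                name = tools::file_path_sans_ext(basename(path)))
}

#' Read a Wavefront OBJ file (v/f records)
#'
#' @param path File path.
#' @return A [triangle_mesh()].
#' @export
read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (!length(vl) || !length(fl)) {
    stop("OBJ file contains no v/f records.", call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- list()
  for (line in fl) {
    toks <- strsplit(trimws(line), "\\s+")[[1]][-1]
    # indices may be v, v/vt, v//vn or v/vt/vn; keep the vertex index
    idx <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
    idx[idx < 0] <- nrow(verts) + idx[idx < 0] + 1L  # negative = relative
    if (length(idx) < 3) stop("OBJ face with fewer than 3 vertices.",
                              call. = FALSE)
    for (k in seq_len(length(idx) - 2)) {
      faces[[length(faces) + 1]] <- c(idx[1], idx[k + 1], idx[k + 2])
    }
  }
  triangle_mesh(verts, do.call(rbind, faces),
                name = tools::file_path_sans_ext(basename(path)))
}

#' Read an ASCII PLY file
#'
#' @param path File path.
#' @return A [triangle_mesh()].
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^ply", txt[1])) stop("Not a PLY file.", call. = FALSE)
  if (!any(grepl("format ascii", txt))) {
    stop("Only ASCII PLY is supported.", call. = FALSE)
  }
  end <- match("end_header", trimws(txt))
  header <- trimws(txt[seq_len(end)])
  elements <- grep("^element ", header, value = TRUE)
  counts <- lapply(strsplit(elements, "\\s+"), function(x) {
    list(name = x[2], n = as.integer(x[3]))
  })
  body <- trimws(txt[(end + 1):length(txt)])
  body <- body[nzchar(body)]
  pos <- 1L
  verts <- NULL
  faces <- NULL
  for (el in counts) {
    rows <- body[pos:(pos + el$n - 1L)]
    pos <- pos + el$n
    if (el$name == "vertex") {
      verts <- do.call(rbind, lapply(strsplit(rows, "\\s+"),
                                     function(x) as.numeric(x[1:3])))
    } else if (el$name == "face") {
      faces <- list()
      for (r in strsplit(rows, "\\s+")) {
        n <- as.integer(r[1])
        idx <- as.integer(r[2:(n + 1)]) + 1L  # PLY indices are 0-based
        for (k in seq_len(n - 2)) {
          faces[[length(faces) + 1]] <- c(idx[1], idx[k + 1], idx[k + 2])
        }
      }
      faces <- do.call(rbind, faces)
    }
  }
  if (is.null(verts) || is.null(faces)) {
    stop("PLY file lacks vertex or face elements.", call. = FALSE)
  }
  triangle_mesh(verts, faces,
                name = tools::file_path_sans_ext(basename(path)))
}

#' Write a triangle mesh as binary STL
#'
#' Facet normals are recomputed from the (assumed outward) vertex winding.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("paleoneuro binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  v0 <- v[f[, 1], , drop = FALSE]
  v1 <- v[f[, 2], , drop = FALSE]
  v2 <- v[f[, 3], , drop = FALSE]
  e1 <- v1 - v0
  e2 <- v2 - v0
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(nrm[i, ], v0[i, ], v1[i, ], v2[i, ])), con,
             size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}
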