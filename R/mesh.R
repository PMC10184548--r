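#' Triangle mesh object
#'
#' A minimal oriented triangle surface: an n-by-3 matrix of vertex coordinates
#' in millimetres and an m-by-3 integer matrix of vertex indices per face,
#' ordered so that consistently oriented faces give an outward normal by the
#' right-hand rule. Volume computation additionally requires the mesh to be
#' closed (every edge shared by exactly two faces).
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @param name Free-text label.
#'
#' @return An object of class `"triangle_mesh"`.
#' @export
#' @examples
#' m <- triangle_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' )
#' mesh_volume(m) * 1000  # mm^3 of the unit tetrahedron
triangle_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("`vertices` must have 3 columns.", call. = FALSE)
  if (ncol(faces) != 3) stop("`faces` must have 3 columns.", call. = FALSE)
  if (any(!is.finite(vertices))) {
    stop("Vertex coordinates must be finite.", call. = FALSE)
  }
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("Face indices reference non-existent vertices.", call. = FALSE)
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3])) {
    stop("Degenerate faces (repeated vertex index) are not allowed.",
         call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# directed edges as a 2-column matrix, one row per half-edge
mesh_half_edges <- function(mesh) {
  f <- mesh$faces
  rbind(cbind(f[, 1], f[, 2]),
        cbind(f[, 2], f[, 3]),
        cbind(f[, 3], f[, 1]))
}

# undirected edge keys
edge_keys <- function(e) {
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Count boundary edges of a mesh
#'
#' A boundary edge belongs to exactly one face. A closed (watertight) surface
#' has none.
#'
#' @param mesh A [triangle_mesh()].
#' @return Integer count of boundary edges.
#' @export
mesh_boundary_edges <- function(mesh) {
  tab <- table(edge_keys(mesh_half_edges(mesh)))
  sum(tab == 1L)
}

#' Is the mesh closed?
#'
#' @param mesh A [triangle_mesh()].
#' @return `TRUE` when every edge is shared by exactly two faces.
#' @export
mesh_is_closed <- function(mesh) {
  tab <- table(edge_keys(mesh_half_edges(mesh)))
  all(tab == 2L)
}

# TRUE when every undirected edge is traversed once in each direction
mesh_is_consistently_oriented <- function(mesh) {
  he <- mesh_half_edges(mesh)
  dir_keys <- paste(he[, 1], he[, 2])
  !anyDuplicated(dir_keys)
}

#' Repair face orientation by propagation
#'
#' Flips faces so that every shared edge is traversed in opposite directions
#' by its two adjacent faces, propagating deterministically outward from the
#' first face of each connected component. Surface files (STL in particular)
#' carry no orientation guarantee, so this runs before strict volume
#' computation refuses a mesh. Fails on non-orientable input.
#'
#' @param mesh A closed [triangle_mesh()].
#' @return The mesh with consistently oriented faces.
#' @export
orient_faces <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0) return(mesh)
  keys <- matrix(edge_keys(mesh_half_edges(mesh)), nrow = nf)
  # face ids adjacent over each undirected edge
  edge_faces <- split(rep(seq_len(nf), 3), as.vector(keys))
  flipped <- rep(FALSE, nf)
  visited <- rep(FALSE, nf)
  for (start in seq_len(nf)) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      fi <- if (flipped[i]) f[i, c(1, 3, 2)] else f[i, ]
      dir_i <- rbind(fi[c(1, 2)], fi[c(2, 3)], fi[c(3, 1)])
      for (k in 1:3) {
        key <- paste(min(dir_i[k, ]), max(dir_i[k, ]))
        for (j in edge_faces[[key]]) {
          if (j == i) next
          fj <- if (flipped[j]) f[j, c(1, 3, 2)] else f[j, ]
          dir_j <- rbind(fj[c(1, 2)], fj[c(2, 3)], fj[c(3, 1)])
          # consistent orientation: j must traverse the shared edge reversed
          same <- any(dir_j[, 1] == dir_i[k, 1] & dir_j[, 2] == dir_i[k, 2])
          if (!visited[j]) {
            flipped[j] <- same
            visited[j] <- TRUE
            queue <- c(queue, j)
          } else if (same) {
            stop("Mesh is non-orientable: orientation propagation failed.",
                 call. = FALSE)
          }
        }
      }
    }
  }
  if (any(flipped)) {
    f[flipped, ] <- f[flipped, c(1, 3, 2), drop = FALSE]
    mesh$faces <- f
  }
  mesh
}

# signed volume in mm^3 by the divergence theorem over signed tetrahedra
signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  v1 <- v[f[, 2], , drop = FALSE]
  v2 <- v[f[, 3], , drop = FALSE]
  dets <- v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
    v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
    v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sum(dets) / 6
}

#' Enclosed volume of a triangle mesh
#'
#' Sums signed tetrahedra `det(v0, v1, v2)/6` over all faces and returns the
#' absolute value, converted from cubic millimetres to cubic centimetres
#' (the unit comparative endocast tables are reported in). The result is
#' invariant under rigid motion and additive over disjoint closed components.
#'
#' In strict mode (default) an open mesh is an error naming the number of
#' boundary edges, and an inconsistently oriented mesh is first repaired by
#' [orient_faces()] and rejected only if non-orientable. In permissive mode
#' (`strict = FALSE`) the signed sum is computed regardless and the result
#' carries an attribute `flagged = TRUE` plus a warning; segmented fossil
#' surfaces often carry small holes, and a flagged approximation can still be
#' useful.
#'
#' @param mesh A [triangle_mesh()], vertex units mm.
#' @param strict Refuse open meshes? Default `TRUE`.
#' @return Volume in cm^3 (scalar). In permissive mode the value may carry
#'   attribute `flagged`.
#' @export
#' @examples
#' cube <- make_box_mesh(10, 10, 10)
#' mesh_volume(cube)  # 1 cm^3
mesh_volume <- function(mesh, strict = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("Mesh has no faces.", call. = FALSE)
  open_edges <- mesh_boundary_edges(mesh)
  if (open_edges > 0) {
    if (strict) {
      stop(sprintf("Mesh is not closed: %d boundary edge(s) present.",
                   open_edges), call. = FALSE)
    }
    warning(sprintf("Open mesh (%d boundary edges): volume is approximate.",
                    open_edges), call. = FALSE)
    out <- abs(signed_volume_mm3(mesh)) / 1000
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (!mesh_is_consistently_oriented(mesh)) {
    mesh <- orient_faces(mesh)  # errors if non-orientable
  }
  abs(signed_volume_mm3(mesh)) / 1000
}

#' Euclidean distance between two 3D points
#'
#' The digital-calliper primitive backing linear endocast measurements.
#'
#' @param p,q Numeric length-3 vectors, mm.
#' @return Distance in mm.
#' @export
#' @examples
#' linear_distance(c(0, 0, 0), c(3, 4, 0))  # 5
linear_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3 || length(q) != 3 || any(!is.finite(c(p, q)))) {
    stop("`p` and `q` must be finite length-3 coordinates.", call. = FALSE)
  }
  sqrt(sum((p - q)^2))
}

#' Length of a polyline
#'
#' Sum of segment lengths of an ordered point path; used for curved
#' measurements such as duct lengths along a centreline.
#'
#' @param line Numeric matrix, k x 3 (k >= 2), ordered points in mm.
#' @return Length in mm.
#' @export
#' @examples
#' polyline_length(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)))  # 17
polyline_length <- function(line) {
  line <- as.matrix(line)
  storage.mode(line) <- "double"
  if (ncol(line) != 3 || nrow(line) < 2 || any(!is.finite(line))) {
    stop("`line` must be a finite k x 3 matrix with k >= 2 points.",
         call. = FALSE)
  }
  d <- diff(line)
  sum(sqrt(rowSums(d^2)))
}
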