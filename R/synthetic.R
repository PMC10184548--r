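# base icosahedron with unit circumradius, outward-oriented faces
icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

# one 4-to-1 refinement pass, midpoints projected back to the unit sphere
subdivide_sphere <- function(m) {
  v <- m$v
  f <- m$f
  cache <- new.env(parent = emptyenv())
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    mp <- (v[i, ] + v[j, ]) / 2
    mp <- mp / sqrt(sum(mp^2))
    v <<- rbind(v, mp)
    cache[[key]] <- nrow(v)
    nrow(v)
  }
  nf <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; d <- f[k, 3]
    ab <- midpoint(a, b); bd <- midpoint(b, d); da <- midpoint(d, a)
    nf[[k]] <- rbind(c(a, ab, da), c(b, bd, ab), c(d, da, bd), c(ab, bd, da))
  }
  list(v = v, f = do.call(rbind, nf))
}

#' Synthetic ellipsoid mesh with known volume
#'
#' Builds a geodesic sphere (icosahedron refined `subdivisions` times, each
#' pass splitting every face into four and projecting new vertices to the
#' sphere) and scales it anisotropically to semi-axes `a`, `b`, `c`. The
#' analytic volume 4/3*pi*a*b*c is returned alongside; the mesh volume of an
#' inscribed polyhedron is strictly below it and converges as faces are added
#' (0.22% low at `subdivisions = 4`, i.e. 5120 faces).
#'
#' @param a,b,c Semi-axes in mm (> 0).
#' @param subdivisions Refinement passes, >= 1 (default 4).
#' @param name Mesh label.
#' @return A list with `mesh` (a [triangle_mesh()]) and `true_volume_cm3`.
#' @export
#' @examples
#' e <- make_ellipsoid_mesh(10, 10, 10, subdivisions = 3)
#' mesh_volume(e$mesh) / e$true_volume_cm3
make_ellipsoid_mesh <- function(a, b, c, subdivisions = 4,
                                name = "ellipsoid") {
  check_positive(c(a, b, c), "a, b, c")
  if (!is.numeric(subdivisions) || length(subdivisions) != 1 ||
      subdivisions < 1 || subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be an integer >= 1.", call. = FALSE)
  }
  m <- icosahedron()
  for (k in seq_len(subdivisions)) m <- subdivide_sphere(m)
  verts <- m$v %*% diag(c(a, b, c))
  list(
    mesh = triangle_mesh(verts, m$f, name = name),
    true_volume_cm3 = 4 / 3 * pi * a * b * c / 1000
  )
}

#' Synthetic tube mesh along a polyline with known centreline length
#'
#' Sweeps an inscribed regular polygon of `segments` sides and radius
#' `radius` along the path using parallel-transport frames, closing the ends
#' with flat triangle-fan caps, so the mesh is watertight and outward
#' oriented. For a straight path the enclosed volume is exactly the prism
#' volume `0.5 * segments * radius^2 * sin(2*pi/segments) * length`, a factor
#' `sin(x)/x` (x = 2*pi/segments) below the smooth cylinder `pi r^2 L` —
#' 0.64% at the default 32 segments. The reported centreline length is
#' [polyline_length()] of the path. A warning flags radii large enough to
#' self-intersect at path corners.
#'
#' @param path Numeric k x 3 matrix of centreline points, mm (k >= 2, no
#'   zero-length segments).
#' @param radius Tube radius in mm (> 0).
#' @param segments Cross-section sides, >= 3 (default 32).
#' @param name Mesh label.
#' @return A list with `mesh`, `true_length_mm`, and `self_intersecting`
#'   (logical flag).
#' @export
#' @examples
#' t <- make_tube_mesh(rbind(c(0, 0, 0), c(20, 0, 0)), radius = 1)
#' mesh_volume(t$mesh) * 1000 / (pi * 20)  # ratio to smooth cylinder
make_tube_mesh <- function(path, radius, segments = 32, name = "tube") {
  path <- as.matrix(path)
  storage.mode(path) <- "double"
  check_positive(radius, "radius")
  if (segments < 3) stop("`segments` must be >= 3.", call. = FALSE)
  if (ncol(path) != 3 || nrow(path) < 2 || any(!is.finite(path))) {
    stop("`path` must be a finite k x 3 matrix with k >= 2 points.",
         call. = FALSE)
  }
  d <- diff(path)
  seglen <- sqrt(rowSums(d^2))
  if (any(seglen == 0)) {
    stop("Degenerate path: consecutive points coincide.", call. = FALSE)
  }
  tangents <- d / seglen

  # per-vertex tangents (averaged at interior points)
  k <- nrow(path)
  vt <- rbind(tangents[1, , drop = FALSE],
              if (k > 2) (tangents[-nrow(tangents), , drop = FALSE] +
                            tangents[-1, , drop = FALSE]) / 2,
              tangents[nrow(tangents), , drop = FALSE])
  vt <- vt / sqrt(rowSums(vt^2))

  # corner self-intersection heuristic: the tube folds into itself when the
  # radius exceeds the local turning radius of the mitred joint
  self_intersecting <- FALSE
  if (k > 2) {
    cosang <- rowSums(tangents[-nrow(tangents), , drop = FALSE] *
                        tangents[-1, , drop = FALSE])
    ang <- acos(pmin(1, pmax(-1, cosang)))
    lim <- pmin(seglen[-length(seglen)], seglen[-1])
    if (any(ang > 1e-8 & radius * tan(ang / 2) > lim / 2)) {
      self_intersecting <- TRUE
      warning("Tube radius is large relative to path curvature: ",
              "the surface may self-intersect.", call. = FALSE)
    }
  }

  # parallel-transport an initial normal along the path
  ref <- c(0, 0, 1)
  if (abs(sum(ref * vt[1, ])) > 0.9) ref <- c(0, 1, 0)
  n0 <- ref - sum(ref * vt[1, ]) * vt[1, ]
  n0 <- n0 / sqrt(sum(n0^2))
  normals <- matrix(0, k, 3)
  normals[1, ] <- n0
  for (i in 2:k) {
    n <- normals[i - 1, ]
    n <- n - sum(n * vt[i, ]) * vt[i, ]
    if (sqrt(sum(n^2)) < 1e-12) {
      # fallback for a right-angle flip; pick any perpendicular
      n <- c(0, 0, 1)
      if (abs(sum(n * vt[i, ])) > 0.9) n <- c(0, 1, 0)
      n <- n - sum(n * vt[i, ]) * vt[i, ]
    }
    normals[i, ] <- n / sqrt(sum(n^2))
  }

  theta <- 2 * pi * (seq_len(segments) - 1) / segments
  verts <- matrix(0, k * segments + 2, 3)
  for (i in seq_len(k)) {
    b2 <- c(vt[i, 2] * normals[i, 3] - vt[i, 3] * normals[i, 2],
            vt[i, 3] * normals[i, 1] - vt[i, 1] * normals[i, 3],
            vt[i, 1] * normals[i, 2] - vt[i, 2] * normals[i, 1])
    ring <- outer(cos(theta), normals[i, ]) + outer(sin(theta), b2)
    verts[(i - 1) * segments + seq_len(segments), ] <-
      matrix(path[i, ], segments, 3, byrow = TRUE) + radius * ring
  }
  c_start <- k * segments + 1L
  c_end <- k * segments + 2L
  verts[c_start, ] <- path[1, ]
  verts[c_end, ] <- path[k, ]

  faces <- list()
  idx <- function(i, j) (i - 1L) * segments + ((j - 1L) %% segments) + 1L
  for (i in seq_len(k - 1)) {
    for (j in seq_len(segments)) {
      a <- idx(i, j); b <- idx(i, j + 1)
      a2 <- idx(i + 1, j); b2i <- idx(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, a2, b2i)
      faces[[length(faces) + 1]] <- c(a, b2i, b)
    }
  }
  for (j in seq_len(segments)) {  # start cap, wound against the side faces
    faces[[length(faces) + 1]] <- c(c_start, idx(1, j), idx(1, j + 1))
  }
  for (j in seq_len(segments)) {  # end cap
    faces[[length(faces) + 1]] <- c(c_end, idx(k, j + 1), idx(k, j))
  }
  mesh <- triangle_mesh(verts, do.call(rbind, faces), name = name)
  if (signed_volume_mm3(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  list(mesh = mesh, true_length_mm = polyline_length(path),
       self_intersecting = self_intersecting)
}

# log-uniform draw
runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Synthetic specimen cohort with analytically known ground truth
#'
#' Draws per-specimen measurements log-uniformly within the given ranges
#' (body-size-like quantities span orders of magnitude, so log-uniform is the
#' scale-free choice) and stores alongside them the ground-truth derived
#' values computed *inline from the closed forms* — deliberately not by
#' calling this package's pipeline functions — so that generator and pipeline
#' can be tested against each other.
#'
#' The cochlear proxy is sampled as basicranial length times a log-uniform
#' ECD:BCL ratio spanning the comparative hearing table (0.156-0.43), with
#' draws rejected until the duct length also falls inside `ecd_mm`; this
#' keeps the implied best hearing range inside the empirically observed band
#' (about 2050-4740 Hz) rather than letting independent draws produce
#' anatomically impossible ducts longer than the basicranium.
#'
#' @param n Number of specimens (>= 1).
#' @param seed Integer seed; cohorts are reproducible under a fixed seed.
#' @param ranges Named list of `c(lo, hi)` positive ordered ranges. Defaults
#'   (spanning the packaged comparative tables): `ecd_mm` 6-20, `bcl_mm`
#'   15-110, `ecd_bcl_ratio` 0.156-0.43, `endocast_volume_cm3` 90-420,
#'   `femoral_circumference_mm` 100-600, `cerebrum_diameter_mm` 20-60,
#'   `bulb_ratio` 0.25-0.7, `midbrain_medulla_ratio` 0.7-1.6,
#'   `medulla_length_mm` 20-55.
#' @param fill_fractions Fill fractions for the ground-truth REQs.
#' @return A tibble of measurements plus `true_*` ground-truth columns and
#'   the seed.
#' @export
#' @examples
#' cohort <- make_specimen_cohort(5, seed = 1)
#' cohort$true_best_hz
make_specimen_cohort <- function(n, seed,
                                 ranges = list(),
                                 fill_fractions = c(0.37, 0.50)) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1.", call. = FALSE)
  }
  defaults <- list(
    ecd_mm = c(6, 20),
    bcl_mm = c(15, 110),
    ecd_bcl_ratio = c(0.156, 0.43),
    endocast_volume_cm3 = c(90, 420),
    femoral_circumference_mm = c(100, 600),
    cerebrum_diameter_mm = c(20, 60),
    bulb_ratio = c(0.25, 0.7),
    midbrain_medulla_ratio = c(0.7, 1.6),
    medulla_length_mm = c(20, 55)
  )
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown)) {
    stop(sprintf("Unknown range name(s): %s.", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  r <- utils::modifyList(defaults, ranges)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 2 || any(!is.finite(v)) ||
        any(v <= 0) || v[1] > v[2]) {
      stop(sprintf("Range `%s` must be two positive ordered values.", nm),
           call. = FALSE)
    }
  }

  withr::with_seed(as.integer(seed), {
    bcl <- runif_log(n, r$bcl_mm[1], r$bcl_mm[2])
    ecd <- bcl * runif_log(n, r$ecd_bcl_ratio[1], r$ecd_bcl_ratio[2])
    for (iter in 1:1000) {
      bad <- ecd < r$ecd_mm[1] | ecd > r$ecd_mm[2]
      if (!any(bad)) break
      bcl[bad] <- runif_log(sum(bad), r$bcl_mm[1], r$bcl_mm[2])
      ecd[bad] <- bcl[bad] *
        runif_log(sum(bad), r$ecd_bcl_ratio[1], r$ecd_bcl_ratio[2])
    }
    if (any(bad)) {
      stop("Could not sample cochlear ducts inside `ecd_mm`; ",
           "ranges are incompatible.", call. = FALSE)
    }
    ev <- runif_log(n, r$endocast_volume_cm3[1], r$endocast_volume_cm3[2])
    fc <- runif_log(n, r$femoral_circumference_mm[1],
                    r$femoral_circumference_mm[2])
    cer <- runif_log(n, r$cerebrum_diameter_mm[1], r$cerebrum_diameter_mm[2])
    bulb <- cer * runif_log(n, r$bulb_ratio[1], r$bulb_ratio[2])
    med <- runif_log(n, r$medulla_length_mm[1], r$medulla_length_mm[2])
    mid <- med * runif_log(n, r$midbrain_medulla_ratio[1],
                           r$midbrain_medulla_ratio[2])
  })

  # ground truths: straight-line closed forms, independent of the pipeline
  x <- log10(ecd / bcl)
  mass_g <- 10^(2.749 * log10(fc * sqrt(2)) - 1.104)
  out <- tibble::tibble(
    specimen_id = sprintf("SYN-%03d", seq_len(n)),
    taxon = sprintf("Synthetheropus %03d", seq_len(n)),
    ecd_mm = ecd,
    bcl_mm = bcl,
    endocast_volume_cm3 = ev,
    femoral_circumference_mm = fc,
    bulb_length_mm = bulb,
    cerebrum_diameter_mm = cer,
    midbrain_length_mm = mid,
    medulla_length_mm = med,
    seed = as.integer(seed),
    true_body_mass_g = mass_g,
    true_best_hz = 6104.3 * x + 6975,
    true_mean_hz = 3311.3 * x + 4000.8,
    true_olfactory_pct = 100 * bulb / cer,
    true_midbrain_ratio = mid / med
  )
  for (fill in fill_fractions) {
    out[[sprintf("true_req_%g", 100 * fill)]] <-
      (ev * fill) / (0.0155 * mass_g^0.553)
  }
  out
}

#' Axis-aligned box mesh
#'
#' Twelve outward-oriented triangles; handy as an exactly-known volume
#' fixture (`lx * ly * lz` mm^3).
#'
#' @param lx,ly,lz Edge lengths in mm (> 0).
#' @param origin Length-3 corner position, mm.
#' @param name Mesh label.
#' @return A [triangle_mesh()].
#' @export
#' @examples
#' mesh_volume(make_box_mesh(10, 10, 10))  # 1 cm^3
make_box_mesh <- function(lx, ly, lz, origin = c(0, 0, 0), name = "box") {
  check_positive(c(lx, ly, lz), "lx, ly, lz")
  v <- rbind(c(0, 0, 0), c(lx, 0, 0), c(lx, ly, 0), c(0, ly, 0),
             c(0, 0, lz), c(lx, 0, lz), c(lx, ly, lz), c(0, ly, lz))
  v <- sweep(v, 2, as.numeric(origin), "+")
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),  # bottom (z = 0), outward -z
    c(5, 6, 7), c(5, 7, 8),  # top, outward +z
    c(1, 2, 6), c(1, 6, 5),  # front (y = 0)
    c(2, 3, 7), c(2, 7, 6),  # right
    c(3, 4, 8), c(3, 8, 7),  # back
    c(4, 1, 5), c(4, 5, 8)   # left
  )
  triangle_mesh(v, f, name = name)
}
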