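# shared geometry helpers built in code (no binary fixtures)

# regular tetrahedron fixture: vertices at origin and the three axis points
tetra_mesh <- function(s = 10) {
  triangle_mesh(
    vertices = rbind(c(0, 0, 0), c(s, 0, 0), c(0, s, 0), c(0, 0, s)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    name = "tetra"
  )
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform <- function(mesh, rot, shift) {
  mesh$vertices <- mesh$vertices %*% t(rot) +
    matrix(shift, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# merge two meshes into a single multi-component mesh
merge_meshes <- function(m1, m2) {
  triangle_mesh(
    rbind(m1$vertices, m2$vertices),
    rbind(m1$faces, m2$faces + nrow(m1$vertices)),
    name = "merged"
  )
}

# discretised quarter circle of radius r in the xy-plane
quarter_circle <- function(r = 10, n = 100) {
  th <- seq(0, pi / 2, length.out = n)
  cbind(r * cos(th), r * sin(th), 0)
}
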