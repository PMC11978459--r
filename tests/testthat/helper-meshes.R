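# programmatic fixtures: canonical closed meshes with known geometry

unit_tetrahedron <- function() {
  surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
    specimen_id = "tetra"
  )
}

unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front
             c(3, 4, 8), c(3, 8, 7),   # back
             c(1, 5, 8), c(1, 8, 4),   # left
             c(2, 3, 7), c(2, 7, 6))   # right
  surface_mesh(v, f, specimen_id = "cube")
}

# icosphere: subdivided icosahedron projected onto a sphere of given radius
icosphere <- function(radius = 1, subdivisions = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(0L, 0L, 3L)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c_ <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  v <- v * radius / sqrt(rowSums(v^2))
  surface_mesh(v, f, specimen_id = "icosphere")
}

# regular triangulated square patch in the z = 0 plane, n x n vertices
plane_patch <- function(n = 8) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * n + i
  f <- matrix(0L, 0L, 3L)
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      f <- rbind(f,
                 c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    }
  }
  surface_mesh(v, f, specimen_id = "plane")
}

# interior vertex ids of plane_patch(n): those not on the boundary
plane_interior <- function(n = 8) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  which(g$x > 1 & g$x < n & g$y > 1 & g$y < n)
}

# a random blob-like closed mesh: icosphere with radial perturbation
random_blob <- function(radius = 10, subdivisions = 2, wobble = 0.2) {
  m <- icosphere(radius, subdivisions)
  r <- 1 + wobble * stats::runif(nrow(m$vertices), -1, 1)
  m$vertices <- m$vertices * r
  m
}

# rotation by angle about an axis
axis_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

# independent metric oracle: plain double loop over all vertex pairs
brute_metric <- function(A, B) {
  Va <- if (is_surface_mesh(A)) A$vertices else A
  Vb <- if (is_surface_mesh(B)) B$vertices else B
  fwd <- mean(apply(Va, 1, function(a) min(colSums((t(Vb) - a)^2))))
  bwd <- mean(apply(Vb, 1, function(b) min(colSums((t(Va) - b)^2))))
  sqrt(0.5 * (fwd + bwd))
}

expect_mesh_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$vertices, b$vertices, tolerance = tol)
  expect_identical(a$faces, b$faces)
}
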