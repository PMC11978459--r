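test_that("surface_metric matches hand-computed cases", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(surface_metric(tri, tri + rep(c(0, 0, 1), each = 3)), 1.0)
  # unequal counts: forward mean square (0+4)/2 = 2, backward 0
  A <- rbind(c(0, 0, 0), c(2, 0, 0))
  B <- rbind(c(0, 0, 0))
  expect_equal(surface_metric(A, B), 1.0)
  set.seed(41)
  m <- random_blob()
  expect_equal(surface_metric(m, m), 0)
})

test_that("surface_metric equals the brute-force oracle on small meshes", {
  set.seed(42)
  for (rep in 1:10) {
    A <- matrix(rnorm(3 * sample(5:30, 1)), ncol = 3)
    B <- matrix(rnorm(3 * sample(5:30, 1)), ncol = 3)
    expect_equal(surface_metric(A, B), brute_metric(A, B), tolerance = 1e-12)
  }
})

test_that("surface_metric satisfies metric axioms and rigid invariance", {
  set.seed(43)
  for (rep in 1:20) {
    A <- matrix(rnorm(60), 20, 3)
    B <- matrix(rnorm(45), 15, 3)
    d <- surface_metric(A, B)
    expect_gte(d, 0)
    expect_equal(d, surface_metric(B, A), tolerance = 1e-12)
    R0 <- random_rotation()
    t0 <- runif(3, -5, 5)
    tf <- rigid_transform(R0, t0)
    expect_equal(surface_metric(apply_transform(A, tf), apply_transform(B, tf)),
                 d, tolerance = 1e-9)
  }
  expect_error(surface_metric(matrix(numeric(), 0, 3), matrix(0, 1, 3)), "empty")
})

test_that("homologize returns prototype-ordered nearest specimen vertices", {
  set.seed(44)
  proto <- generate_muscle_mesh(n_vertices = 200)
  expect_equal(homologize(proto, proto), proto$vertices)
  delta <- c(0.001, 0, 0)       # below half the minimum vertex spacing
  spec <- proto
  spec$vertices <- proto$vertices + rep(delta, each = nrow(proto$vertices))
  expect_equal(homologize(spec, proto),
               proto$vertices + rep(delta, each = nrow(proto$vertices)))
})

test_that("homologize breaks distance ties by the lowest vertex index", {
  # prototype vertex at the origin equidistant to specimen vertices 3 and 7
  spec <- rbind(c(5, 0, 0), c(0, 5, 0), c(1, 0, 0), c(0, 0, 5),
                c(6, 6, 6), c(7, 7, 7), c(-1, 0, 0))
  proto <- rbind(c(0, 0, 0))
  expect_equal(homologize(spec, proto), rbind(c(1, 0, 0)))
})

test_that("average_surface averages homologized rows with prototype connectivity", {
  proto <- unit_tetrahedron()
  expect_mesh_equal(average_surface(proto, list(proto$vertices)),
                    {
                      p <- proto
                      p$specimen_id <- "mean_surface"
                      p
                    })
  shift <- rep(c(1, 0, 0), each = 4)
  avg <- average_surface(proto, list(proto$vertices + shift, proto$vertices - shift))
  expect_equal(avg$vertices, proto$vertices)
  set.seed(45)
  hs <- replicate(3, proto$vertices + matrix(rnorm(12), 4, 3), simplify = FALSE)
  expect_equal(average_surface(proto, hs)$vertices, Reduce(`+`, hs) / 3)
  expect_error(average_surface(proto, list(proto$vertices[1:3, ])), "rows")
})

test_that("gpsa recovers identical shapes under random rigid nuisance", {
  set.seed(46)
  base <- generate_muscle_mesh(n_vertices = 350)
  specimens <- lapply(1:6, function(i) {
    m <- apply_transform(base, rigid_transform(random_rotation(), runif(3, -50, 50)))
    m$specimen_id <- sprintf("S%02d", i)
    m
  })
  res <- generalized_align(specimens, prototype_id = "S01")
  expect_true(all(res$distances[upper.tri(res$distances)] < 1e-6))
  # the mean surface equals the (normalized) common shape
  truth <- normalize_pose(base, unit_scale = TRUE)$mesh
  rms <- sqrt(mean(rowSums((res$mean_surface$vertices - truth$vertices)^2)))
  expect_lt(rms, 1e-3)
  # metric axioms on the result matrix
  expect_equal(res$distances, t(res$distances))
  expect_true(all(diag(res$distances) == 0))
})

test_that("gpsa mean surface is the average of the homologized rows", {
  set.seed(47)
  cfg <- population_config(n_young = 3, n_older = 3, pose_jitter = TRUE,
                           vertex_count_range = c(150, 250), seed = 47)
  pop <- generate_population(cfg)
  res <- suppressWarnings(generalized_align(population_meshes(pop)))
  expect_equal(res$mean_surface$vertices,
               Reduce(`+`, res$homologized) / length(res$homologized),
               tolerance = 1e-9)
  p <- nrow(res$mean_surface$vertices)
  expect_true(all(vapply(res$homologized, nrow, integer(1)) == p))
})

test_that("gpsa reference change decreases monotonically before the floor", {
  set.seed(48)
  cfg <- population_config(n_young = 4, n_older = 4,
                           vertex_count_range = c(250, 400), seed = 48)
  pop <- generate_population(cfg)
  res <- suppressWarnings(generalized_align(population_meshes(pop)))
  tr <- res$rms_trace
  if (length(tr) > 2L) {
    expect_true(all(diff(tr[2:length(tr)]) < 0))
  }
  expect_true(res$converged)
})

test_that("prototype_from_distances ranks by mean distance with lexical ties", {
  D <- matrix(c(0, 1, 4, 1, 0, 1, 4, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  r1 <- prototype_from_distances(D, rank = 1)
  expect_identical(r1$prototype_id, "B")          # means 2.5, 1.0, 2.5
  expect_equal(r1$table$mean_distance, c(1.0, 2.5, 2.5))
  r2 <- prototype_from_distances(D, rank = 2)
  expect_identical(r2$prototype_id, "A")          # lexical tie-break A before C
  expect_error(prototype_from_distances(D, rank = 4), "range")
})

test_that("select_prototype on identical shapes returns the lexically smallest id", {
  set.seed(49)
  base <- generate_muscle_mesh(n_vertices = 200)
  specimens <- lapply(c("S03", "S01", "S02"), function(id) {
    m <- apply_transform(base, rigid_transform(random_rotation(), runif(3, -10, 10)))
    m$specimen_id <- id
    m
  })
  sel <- select_prototype(specimens)
  expect_identical(sel$prototype_id, "S01")
  expect_s3_class(sel$table, "tbl_df")
})

test_that("prototype_sensitivity reports per-prototype variance and ranges", {
  set.seed(50)
  cfg <- population_config(n_young = 3, n_older = 3,
                           vertex_count_range = c(150, 250), seed = 50)
  pop <- generate_population(cfg)
  sens <- suppressWarnings(prototype_sensitivity(population_meshes(pop), k_pcs = 4))
  expect_equal(nrow(sens), 6L)
  expect_equal(ncol(sens), 5L)                    # id + 4 PCs
  rng <- sensitivity_ranges(sens)
  expect_length(rng, 4L)
  expect_true(all(is.finite(rng) & rng >= 0))
  # reproducibility under the seed
  set.seed(50)
  pop2 <- generate_population(cfg)
  sens2 <- suppressWarnings(prototype_sensitivity(population_meshes(pop2), k_pcs = 4))
  expect_equal(as.data.frame(sens), as.data.frame(sens2))
})

test_that("prototype_sensitivity is degenerate for identical shapes", {
  set.seed(51)
  base <- generate_muscle_mesh(n_vertices = 150)
  specimens <- lapply(1:4, function(i) {
    m <- base
    m$specimen_id <- sprintf("S%02d", i)
    m
  })
  sens <- prototype_sensitivity(specimens, k_pcs = 3)
  expect_true(all(as.matrix(sens[, -1]) == 0))
  expect_true(all(sensitivity_ranges(sens) == 0))
})

test_that("gpsa result tidiers expose distances and a summary row", {
  set.seed(52)
  base <- generate_muscle_mesh(n_vertices = 200)
  specimens <- lapply(1:3, function(i) {
    m <- apply_transform(base, rigid_transform(random_rotation(), runif(3)))
    m$specimen_id <- sprintf("S%02d", i)
    m
  })
  res <- generalized_align(specimens, prototype_id = "S01")
  td <- tidy(res)
  expect_equal(nrow(td), 3L)                      # upper triangle of 3 x 3
  expect_named(td, c("specimen_1", "specimen_2", "distance"))
  g <- glance(res)
  expect_equal(g$n_specimens, 3L)
  expect_identical(g$prototype_id, "S01")
})
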