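test_that("pcoa matches closed-form two-point and collinear configurations", {
  D2 <- matrix(c(0, 2, 2, 0), 2, 2)
  ord <- pcoa(D2)
  expect_equal(ncol(ord$scores), 1L)
  expect_equal(unname(ord$scores[, 1]), c(1, -1))
  expect_equal(ord$pct_variance, 100)
  D3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  ord3 <- pcoa(D3)
  expect_equal(length(ord3$eigenvalues), 1L)
  expect_equal(ord3$eigenvalues, 2, tolerance = 1e-12)
  expect_equal(sort(unname(ord3$scores[, 1])), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(ord3$pct_variance, 100)
})

test_that("pcoa of Euclidean distances reproduces the configuration up to rotation", {
  set.seed(61)
  for (rep in 1:10) {
    k <- sample(5:12, 1)
    X <- matrix(rnorm(3 * k), k, 3)
    ord <- pcoa(as.matrix(dist(X)))
    Xc <- scale(X, scale = FALSE)
    S <- ord$scores[, seq_len(min(3, ncol(ord$scores))), drop = FALSE]
    # orthogonal Procrustes residual between scores and centered generators
    sv <- svd(t(S) %*% Xc)
    resid <- sum(Xc^2) + sum(S^2) - 2 * sum(sv$d)
    expect_lt(abs(resid), 1e-9)
  }
})

test_that("pcoa agrees with classical scaling (independent implementation)", {
  set.seed(62)
  X <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(dist(X))
  ord <- pcoa(D)
  cs <- stats::cmdscale(D, k = 3, eig = TRUE)
  expect_equal(ord$eigenvalues[1:3], cs$eig[1:3], tolerance = 1e-9)
  for (j in 1:3) {
    expect_equal(abs(unname(ord$scores[, j])), abs(unname(cs$points[, j])),
                 tolerance = 1e-9)
  }
})

test_that("pcoa validates its input and handles degenerate matrices", {
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(pcoa(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  expect_error(pcoa(matrix(c(1, 1, 1, 1), 2, 2)), "diagonal")
  degenerate <- pcoa(matrix(0, 4, 4))
  expect_equal(length(degenerate$eigenvalues), 0L)
  expect_equal(ncol(degenerate$scores), 0L)
})

test_that("pcoa drops negative eigenvalues and records their mass", {
  # a non-Euclidean dissimilarity: violates the triangle inequality
  D <- matrix(c(0, 10, 1, 10, 0, 1, 1, 1, 0), 3, 3)
  ord <- pcoa(D)
  expect_gt(ord$negative_mass, 0)
  expect_true(all(ord$eigenvalues > 0))
  expect_equal(sum(ord$pct_variance), 100, tolerance = 1e-9)
})

test_that("score signs are deterministic and columns centered", {
  set.seed(63)
  X <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(X))
  ord1 <- pcoa(D)
  ord2 <- pcoa(D)
  expect_identical(ord1$scores, ord2$scores)
  for (j in seq_len(ncol(ord1$scores))) {
    i_star <- which.max(abs(ord1$scores[, j]))
    expect_gt(ord1$scores[i_star, j], 0)
  }
  expect_lt(max(abs(colMeans(ord1$scores))), 1e-9)
})

test_that("variance percentages are invariant to specimen relabeling", {
  set.seed(64)
  X <- matrix(rnorm(27), 9, 3)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("S", 1:9), paste0("S", 1:9))
  perm <- sample(9)
  ord1 <- pcoa(D)
  ord2 <- pcoa(D[perm, perm])
  expect_equal(ord1$pct_variance, ord2$pct_variance, tolerance = 1e-9)
})

test_that("ordination tidiers expose axes, scores and summaries", {
  set.seed(65)
  D <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  ord <- pcoa(D)
  td <- tidy(ord)
  expect_named(td, c("axis", "eigenvalue", "pct_variance", "cum_pct_variance"))
  expect_equal(td$cum_pct_variance[nrow(td)], 100, tolerance = 1e-9)
  sc <- ord_scores(ord, axes = 1:2)
  expect_named(sc, c("specimen_id", "PC1", "PC2"))
  expect_equal(nrow(sc), 10L)
  g <- glance(ord)
  expect_equal(g$n_specimens, 10L)
  p <- autoplot(ord)
  expect_s3_class(p, "ggplot")
})

test_that("reconstruction at score zero returns the mean surface exactly", {
  set.seed(66)
  cfg <- population_config(n_young = 4, n_older = 4,
                           vertex_count_range = c(200, 300), seed = 66)
  pop <- generate_population(cfg)
  res <- suppressWarnings(generalized_align(population_meshes(pop)))
  ord <- pcoa(res$distances)
  sh0 <- reconstruct_shape_at_score(res, ord, 1, 0)
  expect_equal(sh0$vertices, res$mean_surface$vertices)
  expect_identical(sh0$faces, res$mean_surface$faces)
  # linearity: shape(2s) - mean = 2 (shape(s) - mean)
  s <- 0.37
  sh1 <- reconstruct_shape_at_score(res, ord, 1, s)
  sh2 <- reconstruct_shape_at_score(res, ord, 1, 2 * s)
  expect_equal(sh2$vertices - sh0$vertices, 2 * (sh1$vertices - sh0$vertices),
               tolerance = 1e-9)
  expect_error(reconstruct_shape_at_score(res, ord, 99, 0), "retained")
})

test_that("a girth-only population reconstructs wider shapes at high scores", {
  set.seed(67)
  cfg <- population_config(n_young = 6, n_older = 6,
                           factor_sds = c(girth = 1.5, torsion = 0, elongation = 0),
                           vertex_count_range = c(300, 450),
                           vertex_noise_sd = 0.1, seed = 67)
  pop <- generate_population(cfg)
  res <- suppressWarnings(generalized_align(population_meshes(pop)))
  ord <- pcoa(res$distances)
  s <- ord$scores[, 1]
  lo <- reconstruct_shape_at_score(res, ord, 1, min(s))
  hi <- reconstruct_shape_at_score(res, ord, 1, max(s))
  # PC1 tracks girth, so the two extremes must differ in cross-sectional extent
  extent <- function(m) mean(sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2))
  r <- cor(pop$truth$girth, s[pop$truth$specimen_id])
  wide <- if (r > 0) hi else lo
  narrow <- if (r > 0) lo else hi
  expect_gt(extent(wide), extent(narrow))
})

test_that("variation heat maps measure per-vertex displacement", {
  m <- unit_cube_mesh()
  expect_equal(variation_heatmap(m, m), rep(0, 8))
  shifted <- m
  shifted$vertices <- m$vertices + rep(c(0, 0, 5), each = 8)
  expect_equal(variation_heatmap(m, shifted), rep(5, 8))
  set.seed(68)
  other <- m
  other$vertices <- m$vertices + matrix(rnorm(24), 8, 3)
  expect_equal(max(variation_heatmap(m, other, normalize = TRUE)), 1)
  bad <- unit_tetrahedron()
  expect_error(variation_heatmap(m, bad), "connectivity")
})
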