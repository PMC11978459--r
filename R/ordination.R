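#' Principal coordinates analysis (classical scaling, Gower)
#'
#' Ordination of an interspecimen distance matrix by Gower double centering:
#' `B = -1/2 * J (D o D) J` with `J = I - (1/k) 11'`, eigendecomposed; scores
#' are the eigenvectors scaled by the square roots of their eigenvalues.
#' Axes with non-positive eigenvalues are dropped (their total magnitude is
#' recorded in `negative_mass`), and percent variance is taken relative to
#' the sum of the positive eigenvalues. Each retained axis is oriented so
#' that the specimen with the largest absolute score on it is positive
#' (first such specimen on ties), which makes score signs deterministic.
#'
#' When the distances are Euclidean distances of some configuration, the
#' scores reproduce that configuration (centered, up to rotation), i.e. PCoA
#' coincides with PCA of the coordinates.
#'
#' @param D k x k symmetric nonnegative distance matrix with zero diagonal;
#'   dimnames, if present, become specimen ids.
#' @return an object of class `shape_ordination`: list with `scores`
#'   (k x m matrix, columns `PC1..PCm`), `eigenvalues` (descending),
#'   `pct_variance`, `negative_mass`, `specimen_id`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  k <- nrow(D)
  if (k != ncol(D)) stop("`D` must be square", call. = FALSE)
  if (any(D < 0)) stop("`D` must be nonnegative", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(D))) {
    stop("`D` must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(D))) > 1e-12 * max(1, max(D))) {
    stop("`D` must have a zero diagonal", call. = FALSE)
  }
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(k))
  D <- (D + t(D)) / 2
  J <- diag(k) - matrix(1 / k, k, k)
  B <- -0.5 * J %*% (D * D) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * k * .Machine$double.eps * 100
  pos <- which(eg$values > max(tol, 1e-12))
  neg_mass <- sum(abs(eg$values[eg$values < 0]))
  if (length(pos) == 0L) {
    scores <- matrix(numeric(), k, 0L, dimnames = list(ids, NULL))
    return(structure(list(scores = scores, eigenvalues = numeric(),
                          pct_variance = numeric(), negative_mass = neg_mass,
                          specimen_id = ids),
                     class = "shape_ordination"))
  }
  ev <- eg$values[pos]
  S <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), length(pos))
  # orient each axis: largest-|score| specimen positive
  for (j in seq_len(ncol(S))) {
    i_star <- which.max(abs(S[, j]))
    if (S[i_star, j] < 0) S[, j] <- -S[, j]
  }
  dimnames(S) <- list(ids, paste0("PC", seq_len(ncol(S))))
  structure(list(scores = S, eigenvalues = ev,
                 pct_variance = 100 * ev / sum(ev),
                 negative_mass = neg_mass, specimen_id = ids),
            class = "shape_ordination")
}

#' @export
print.shape_ordination <- function(x, ...) {
  cat(sprintf("<shape_ordination> %d specimens, %d positive axes\n",
              length(x$specimen_id), length(x$eigenvalues)))
  if (length(x$pct_variance) > 0L) {
    lead <- utils::head(x$pct_variance, 4L)
    cat("  % variance:", paste(sprintf("%.1f", lead), collapse = ", "),
        if (length(x$pct_variance) > 4L) "..." else "", "\n")
  }
  invisible(x)
}

#' Ordination scores as a tibble
#'
#' @param ord a [pcoa()] result.
#' @param axes which axes to return (default all).
#' @return tibble with `specimen_id` and one column per axis.
#' @export
ord_scores <- function(ord, axes = NULL) {
  stopifnot(inherits(ord, "shape_ordination"))
  S <- ord$scores
  if (!is.null(axes)) S <- S[, axes, drop = FALSE]
  dplyr::bind_cols(tibble::tibble(specimen_id = ord$specimen_id),
                   tibble::as_tibble(S))
}

#' @export
tidy.shape_ordination <- function(x, ...) {
  tibble::tibble(axis = paste0("PC", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues,
                 pct_variance = x$pct_variance,
                 cum_pct_variance = cumsum(x$pct_variance))
}

#' @export
glance.shape_ordination <- function(x, ...) {
  tibble::tibble(n_specimens = length(x$specimen_id),
                 n_axes = length(x$eigenvalues),
                 negative_mass = x$negative_mass,
                 pct_first_two = sum(utils::head(x$pct_variance, 2L)))
}

#' Ordination scatter plot
#'
#' @param object a [pcoa()] result.
#' @param axes integer pair of axes to plot (default `c(1, 2)`).
#' @param data optional tibble with `specimen_id` plus covariates to join
#'   onto the scores (e.g. for colouring).
#' @param colour optional column name (string) in `data` to map to colour.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.shape_ordination <- function(object, axes = c(1L, 2L), data = NULL,
                                      colour = NULL, ...) {
  df <- ord_scores(object, axes = axes)
  names(df)[2:3] <- c("axis_x", "axis_y")
  if (!is.null(data)) df <- dplyr::left_join(df, data, by = "specimen_id")
  labs_x <- sprintf("PC%d (%.1f%%)", axes[1], object$pct_variance[axes[1]])
  labs_y <- sprintf("PC%d (%.1f%%)", axes[2], object$pct_variance[axes[2]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis_x, y = .data$axis_y))
  p <- if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  }
  p + ggplot2::labs(x = labs_x, y = labs_y) + ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Theoretical shape at a given ordination score
#'
#' Reconstructs the surface a specimen would have at an arbitrary score on
#' one ordination axis: each homologized vertex coordinate is regressed
#' linearly on the axis scores across specimens (through the mean, since the
#' scores are centered), and the mean surface is displaced by `score` times
#' the per-vertex slopes. With the observed minimum and maximum scores this
#' yields the extreme-shape projections used to visualize what an axis means
#' anatomically.
#'
#' @param result a [generalized_align()] result.
#' @param ord the [pcoa()] of `result$distances`.
#' @param axis axis number (within the retained axes).
#' @param score score at which to reconstruct.
#' @return a [surface_mesh()] with the mean surface's connectivity.
#' @export
reconstruct_shape_at_score <- function(result, ord, axis, score) {
  stopifnot(inherits(result, "gpsa_result"), inherits(ord, "shape_ordination"))
  if (axis < 1L || axis > ncol(ord$scores)) {
    stop(sprintf("axis %d is not among the %d retained axes", axis, ncol(ord$scores)),
         call. = FALSE)
  }
  ids <- names(result$homologized)
  s <- ord$scores[ids, axis]
  ss <- sum(s^2)
  if (ss <= .Machine$double.eps) stop("degenerate axis: zero score variance", call. = FALSE)
  # scores are centered, so the through-the-mean slope is sum(s_k H_k) / sum(s^2)
  beta <- Reduce(`+`, Map(function(H, sk) sk * H, result$homologized, s)) / ss
  out <- result$mean_surface
  out$vertices <- out$vertices + score * beta
  out$specimen_id <- sprintf("PC%d_at_%.3g", axis, score)
  out
}

#' Per-vertex shape variation between two reconstructions
#'
#' The displacement magnitude of each vertex between two shapes with shared
#' connectivity (typically the reconstructions at the minimum and maximum
#' score of an axis); exported as a mesh scalar field it becomes the
#' familiar blue-to-red variation heat map.
#'
#' @param shape_min,shape_max [surface_mesh()] objects with identical vertex
#'   count and faces.
#' @param normalize scale to `[0, 1]` by the maximum (default `FALSE`).
#' @return numeric vector of per-vertex displacement magnitudes (mm, or
#'   unitless if normalized).
#' @export
variation_heatmap <- function(shape_min, shape_max, normalize = FALSE) {
  stopifnot(is_surface_mesh(shape_min), is_surface_mesh(shape_max))
  if (nrow(shape_min$vertices) != nrow(shape_max$vertices) ||
      !identical(shape_min$faces, shape_max$faces)) {
    stop("shapes must share vertex count and connectivity", call. = FALSE)
  }
  v <- sqrt(rowSums((shape_max$vertices - shape_min$vertices)^2))
  if (normalize && max(v) > 0) v <- v / max(v)
  v
}
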