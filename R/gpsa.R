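#' Symmetric Procrustes surface metric
#'
#' Root-mean-square closest-point distance between two surfaces already in a
#' common frame. Each surface contributes equal total weight regardless of
#' its vertex count, making the metric symmetric and robust to unequal point
#' counts:
#' \deqn{d(A,B) = \sqrt{\tfrac12\left[\tfrac{1}{|A|}\sum_{a} \min_b \|a-b\|^2
#'   + \tfrac{1}{|B|}\sum_{b} \min_a \|b-a\|^2\right]}}
#' No alignment is performed here; superimpose first (see [icp_align()]).
#'
#' @param A,B [surface_mesh()] objects or `n x 3` coordinate matrices.
#' @return nonnegative scalar distance, mm.
#' @export
surface_metric <- function(A, B) {
  Va <- if (is_surface_mesh(A)) A$vertices else as.matrix(A)
  Vb <- if (is_surface_mesh(B)) B$vertices else as.matrix(B)
  if (nrow(Va) == 0L || nrow(Vb) == 0L) stop("empty vertex set", call. = FALSE)
  sqrt(0.5 * (mean_min_dist2_cpp(Va, Vb) + mean_min_dist2_cpp(Vb, Va)))
}

#' Homologize a specimen against a prototype
#'
#' Constructs the point correspondence GPSA uses in place of landmarks: row
#' `i` of the result is the specimen vertex nearest to prototype vertex `i`
#' (ties broken by the lowest specimen vertex index), with rows ordered as
#' the prototype vertices. The prototype's vertex set thereby serves as the
#' common landmark set for every specimen.
#'
#' @param specimen,prototype [surface_mesh()] objects in a common frame.
#' @return a `p x 3` matrix, `p = nrow(prototype$vertices)`.
#' @export
homologize <- function(specimen, prototype) {
  Vs <- if (is_surface_mesh(specimen)) specimen$vertices else as.matrix(specimen)
  Vp <- if (is_surface_mesh(prototype)) prototype$vertices else as.matrix(prototype)
  if (nrow(Vs) == 0L) stop("empty specimen", call. = FALSE)
  idx <- nn_query_cpp(Vp, Vs)$index
  Vs[idx, , drop = FALSE]
}

#' Average surface over homologized specimens
#'
#' Rebuilds the reference surface from the current distribution of
#' homologized points: vertex `i` of the output is the mean over specimens of
#' homologized row `i`; connectivity is inherited from the prototype.
#'
#' @param prototype a [surface_mesh()] providing connectivity.
#' @param homologized list of `p x 3` matrices from [homologize()].
#' @return a [surface_mesh()] with the averaged vertices.
#' @export
average_surface <- function(prototype, homologized) {
  p <- nrow(prototype$vertices)
  if (!all(vapply(homologized, nrow, integer(1)) == p)) {
    stop("all homologized matrices must have as many rows as the prototype has vertices",
         call. = FALSE)
  }
  M <- Reduce(`+`, homologized) / length(homologized)
  out <- prototype
  out$vertices <- M
  out$specimen_id <- "mean_surface"
  out
}

#' Generalized Procrustes surface analysis
#'
#' Group-wise landmark-free superimposition: starting from a chosen prototype
#' surface, every specimen is (1) superimposed onto the current reference by
#' [icp_align()], (2) homologized against it, and (3) the reference is
#' reformed as the [average_surface()] of the homologized points; the loop
#' repeats until the reference changes by less than `tol` (RMS vertex
#' displacement, mm) or `max_outer_iter` is reached. Specimens are first
#' pose-normalized ([normalize_pose()]), with unit centroid-size scaling by
#' default so that size variation is removed once, up front. The full
#' pairwise interspecimen distance matrix ([surface_metric()]) is computed on
#' the aligned specimens.
#'
#' @param specimens list of [surface_mesh()] objects with unique
#'   `specimen_id`s (at least 3).
#' @param prototype_id `specimen_id` of the initial reference; `NULL` selects
#'   it automatically with [select_prototype()].
#' @param max_outer_iter maximum reference-update iterations (default 20).
#' @param tol RMS reference change convergence threshold in working-frame
#'   units: with `scale_normalize` the frame has unit RMS radius, so the
#'   default 1e-3 corresponds to 0.1% of the overall surface radius; for
#'   unnormalized mm-scale meshes pass an absolute mm value.
#' @param scale_normalize remove size by unit centroid-size scaling
#'   (default `TRUE`).
#' @param icp_max_iter,icp_tol ICP controls passed to [icp_align()].
#' @return an object of class `gpsa_result` with elements `prototype_id`,
#'   `mean_surface`, `aligned` (named list of aligned meshes), `distances`
#'   (k x k symmetric matrix), `homologized` (named list of `p x 3`
#'   matrices), and the outer-loop record: `n_outer_iter`, `converged`,
#'   `rms_trace`.
#' @export
generalized_align <- function(specimens, prototype_id = NULL,
                              max_outer_iter = 20L, tol = 1e-3,
                              scale_normalize = TRUE,
                              icp_max_iter = 100L, icp_tol = 1e-6) {
  ids <- vapply(specimens, function(m) m$specimen_id, character(1))
  if (anyDuplicated(ids)) stop("specimen_ids must be unique", call. = FALSE)
  names(specimens) <- ids
  k <- length(specimens)
  if (k < 3L) stop("need at least 3 specimens", call. = FALSE)
  if (is.null(prototype_id)) {
    prototype_id <- select_prototype(specimens, scale_normalize = scale_normalize)$prototype_id
  }
  if (!prototype_id %in% ids) {
    stop(sprintf("prototype_id '%s' not among the specimens", prototype_id), call. = FALSE)
  }
  normed <- lapply(specimens, function(m) normalize_pose(m, unit_scale = scale_normalize)$mesh)
  prototype <- normed[[prototype_id]]
  reference <- prototype
  rms_trace <- numeric()
  converged <- FALSE
  homologized <- NULL
  aligned <- normed
  n_outer <- 0L
  for (outer in seq_len(max_outer_iter)) {
    n_outer <- outer
    aligned <- lapply(normed, function(m) {
      fit <- icp_align(m, reference, max_iter = icp_max_iter, tol = icp_tol)
      apply_transform(m, fit$transform)
    })
    homologized <- lapply(aligned, homologize, prototype = reference)
    new_ref <- average_surface(prototype, homologized)
    rms <- sqrt(mean(rowSums((new_ref$vertices - reference$vertices)^2)))
    rms_trace <- c(rms_trace, rms)
    reference <- new_ref
    if (rms < tol) {
      converged <- TRUE
      break
    }
    # stagnation: correspondence flips keep the reference jittering at a
    # noise floor it cannot descend below; treat a <10% improvement as
    # converged-to-floor rather than iterating to max_outer_iter
    if (outer >= 3L && rms > 0.9 * rms_trace[outer - 1L]) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("GPSA did not converge in %d outer iterations (last RMS change %.3g mm)",
                    max_outer_iter, rms_trace[length(rms_trace)]))
  }
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      D[i, j] <- D[j, i] <- surface_metric(aligned[[i]], aligned[[j]])
    }
  }
  structure(
    list(prototype_id = prototype_id, mean_surface = reference,
         aligned = aligned, distances = D, homologized = homologized,
         n_outer_iter = n_outer, converged = converged, rms_trace = rms_trace),
    class = "gpsa_result"
  )
}

#' @export
print.gpsa_result <- function(x, ...) {
  cat(sprintf("<gpsa_result> %d specimens, prototype '%s', %d landmark points, %d outer iterations (%s)\n",
              length(x$aligned), x$prototype_id, nrow(x$mean_surface$vertices),
              x$n_outer_iter, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy interspecimen distances of a GPSA result
#'
#' @param x a `gpsa_result`.
#' @param ... unused.
#' @return tibble with columns `specimen_1`, `specimen_2`, `distance`
#'   (upper triangle of the distance matrix).
#' @export
tidy.gpsa_result <- function(x, ...) {
  D <- x$distances
  ij <- which(upper.tri(D), arr.ind = TRUE)
  tibble::tibble(specimen_1 = rownames(D)[ij[, 1]],
                 specimen_2 = colnames(D)[ij[, 2]],
                 distance = D[ij])
}

#' @rdname tidy.gpsa_result
#' @export
glance.gpsa_result <- function(x, ...) {
  tibble::tibble(n_specimens = length(x$aligned),
                 n_landmarks = nrow(x$mean_surface$vertices),
                 prototype_id = x$prototype_id,
                 n_outer_iter = x$n_outer_iter,
                 converged = x$converged,
                 mean_distance = mean(x$distances[upper.tri(x$distances)]))
}

#' Prototype choice from a precomputed distance matrix
#'
#' Ranks specimens by their mean off-diagonal interspecimen distance (the
#' most "average" shape ranks first) and returns the `rank`-th smallest; ties
#' are broken by lexical `specimen_id` order.
#'
#' @param D k x k symmetric distance matrix with specimen ids as dimnames.
#' @param rank which rank to return (1 = most average).
#' @return list with `prototype_id` and `table` (tibble of `specimen_id`,
#'   `mean_distance`, `rank`).
#' @export
prototype_from_distances <- function(D, rank = 1L) {
  D <- as.matrix(D)
  k <- nrow(D)
  if (rank < 1L || rank > k) stop("`rank` out of range", call. = FALSE)
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(k))
  means <- unname(rowSums(D)) / (k - 1L)
  ord <- order(means, ids)
  tab <- tibble::tibble(specimen_id = ids[ord], mean_distance = means[ord],
                        rank = seq_len(k))
  list(prototype_id = tab$specimen_id[rank], table = tab)
}

#' Select the prototype surface
#'
#' The prototype should be the most "average" specimen: the one with the
#' lowest mean interspecimen Procrustes surface metric distance to all other
#' surfaces. By default each ordered pair of pose-normalized specimens is
#' superimposed once with [icp_align()] (a single pairwise pass, no prototype
#' averaging) and the resulting matrix symmetrized; `method = "full"` instead
#' runs a complete [generalized_align()] per candidate (much more expensive;
#' used by [prototype_sensitivity()]). `rank = 2` supports falling back to
#' the second most average specimen when the first is visually anomalous.
#'
#' @param specimens list of [surface_mesh()] objects.
#' @param rank which rank to return (1 = most average).
#' @param method `"pairwise"` (default) or `"full"`.
#' @param scale_normalize remove size before comparison (default `TRUE`).
#' @return list with `prototype_id` and `table` as in
#'   [prototype_from_distances()].
#' @export
select_prototype <- function(specimens, rank = 1L,
                             method = c("pairwise", "full"),
                             scale_normalize = TRUE) {
  method <- match.arg(method)
  ids <- vapply(specimens, function(m) m$specimen_id, character(1))
  names(specimens) <- ids
  k <- length(specimens)
  if (k < 3L) stop("need at least 3 specimens", call. = FALSE)
  if (method == "pairwise") {
    normed <- lapply(specimens, function(m) normalize_pose(m, unit_scale = scale_normalize)$mesh)
    D <- matrix(0, k, k, dimnames = list(ids, ids))
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) next
        fit <- icp_align(normed[[i]], normed[[j]])
        D[i, j] <- fit$final_metric
      }
    }
    D <- (D + t(D)) / 2
  } else {
    D <- matrix(0, k, k, dimnames = list(ids, ids))
    for (i in seq_len(k)) {
      res <- generalized_align(specimens, prototype_id = ids[i],
                               scale_normalize = scale_normalize)
      D[i, ] <- rowSums(res$distances) / (k - 1L)
    }
    # per-candidate mean distances live on the rows; collapse to one score
    D <- (D + t(D)) / 2
  }
  prototype_from_distances(D, rank = rank)
}

#' Prototype sensitivity analysis
#'
#' Repeats the whole GPSA + ordination pipeline once per specimen used as the
#' prototype and tabulates the percent variance explained by the first
#' `k_pcs` principal coordinates, quantifying how strongly the results depend
#' on the prototype choice. The per-PC max-minus-min range across prototypes
#' is attached as the `"pc_ranges"` attribute (see [sensitivity_ranges()]).
#' Failures for individual prototypes are recorded as `NA` rows without
#' aborting the sweep.
#'
#' @param specimens list of [surface_mesh()] objects.
#' @param k_pcs number of leading axes to tabulate (default 4).
#' @param ... passed to [generalized_align()].
#' @return tibble with `k` rows and `k_pcs + 1` columns: `prototype_id` and
#'   `PC1 .. PCk_pcs` percent variance.
#' @export
prototype_sensitivity <- function(specimens, k_pcs = 4L, ...) {
  if (k_pcs < 1L) stop("`k_pcs` must be >= 1", call. = FALSE)
  ids <- vapply(specimens, function(m) m$specimen_id, character(1))
  rows <- lapply(ids, function(id) {
    pct <- tryCatch({
      res <- generalized_align(specimens, prototype_id = id, ...)
      ord <- pcoa(res$distances)
      p <- ord$pct_variance
      if (length(p) == 0L) rep(0, k_pcs) else c(p, rep(0, k_pcs))[seq_len(k_pcs)]
    }, error = function(e) {
      warning(sprintf("prototype '%s' failed: %s", id, conditionMessage(e)))
      rep(NA_real_, k_pcs)
    })
    stats::setNames(c(list(id), as.list(pct)),
                    c("prototype_id", paste0("PC", seq_len(k_pcs))))
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  ranges <- vapply(paste0("PC", seq_len(k_pcs)), function(cn) {
    v <- out[[cn]]
    if (all(is.na(v))) NA_real_ else diff(range(v, na.rm = TRUE))
  }, numeric(1))
  attr(out, "pc_ranges") <- ranges
  out
}

#' @rdname prototype_sensitivity
#' @param sensitivity output of [prototype_sensitivity()].
#' @return `sensitivity_ranges()`: named numeric vector of per-PC
#'   max-minus-min percent-variance ranges.
#' @export
sensitivity_ranges <- function(sensitivity) {
  attr(sensitivity, "pc_ranges")
}
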