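#' Resolved configuration of a pipeline run
#'
#' Collects every knob of the end-to-end analysis in one serializable
#' object. A config written with [write_run_config()] and read back with
#' [read_run_config()] reproduces all fields exactly, and every pipeline run
#' writes its fully resolved config beside its outputs.
#'
#' @param simulate generate the inputs with [generate_population()] instead
#'   of reading meshes from disk.
#' @param population list of [population_config()] arguments (when
#'   `simulate`).
#' @param mesh_dir directory of mesh files (`""` when simulating); all
#'   PLY/STL/OBJ/VTK files in it are read, or `manifest` lists them.
#' @param manifest optional CSV with columns `specimen_id`, `path`, `side`.
#' @param covariates_csv covariate table CSV (`""` when simulating).
#' @param smooth_sigma Gaussian-equivalent smoothing scale, mm (0 disables).
#' @param smooth_method `"taubin"` or `"laplacian"`.
#' @param scale_normalize remove size by unit centroid-size scaling.
#' @param prototype `"auto"`, `"auto_rank_<k>"`, or an explicit specimen id.
#' @param icp_tol,icp_max_iter ICP convergence controls.
#' @param outer_tol,outer_max_iter GPSA outer-loop controls.
#' @param axes ordination axes to model.
#' @param stepwise_criterion `"aic"` or `"alpha"`.
#' @param alpha significance level for the alpha criterion.
#' @param sensitivity run the prototype sensitivity sweep.
#' @param sensitivity_pcs leading axes tabulated by the sweep.
#' @param out_dir output directory.
#' @param seed integer seed governing all randomness of the run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, population = list(),
                       mesh_dir = "", manifest = "", covariates_csv = "",
                       smooth_sigma = 0, smooth_method = "taubin",
                       scale_normalize = TRUE, prototype = "auto",
                       icp_tol = 1e-6, icp_max_iter = 100L,
                       outer_tol = 1e-3, outer_max_iter = 20L,
                       axes = c(1L, 2L), stepwise_criterion = "aic",
                       alpha = 0.05, sensitivity = FALSE,
                       sensitivity_pcs = 4L, out_dir = "surfmorph_run",
                       seed = 1L) {
  stopifnot(smooth_method %in% c("taubin", "laplacian"),
            stepwise_criterion %in% c("aic", "alpha"))
  structure(list(simulate = isTRUE(simulate),
                 population = lapply(population, function(x) x),
                 mesh_dir = as.character(mesh_dir),
                 manifest = as.character(manifest),
                 covariates_csv = as.character(covariates_csv),
                 smooth_sigma = as.numeric(smooth_sigma),
                 smooth_method = smooth_method,
                 scale_normalize = isTRUE(scale_normalize),
                 prototype = as.character(prototype),
                 icp_tol = as.numeric(icp_tol),
                 icp_max_iter = as.integer(icp_max_iter),
                 outer_tol = as.numeric(outer_tol),
                 outer_max_iter = as.integer(outer_max_iter),
                 axes = as.integer(unlist(axes)),
                 stepwise_criterion = stepwise_criterion,
                 alpha = as.numeric(alpha),
                 sensitivity = isTRUE(sensitivity),
                 sensitivity_pcs = as.integer(sensitivity_pcs),
                 out_dir = as.character(out_dir),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (is.null(lst$population)) lst$population <- list()
  do.call(run_config, lst)
}

.load_inputs <- function(config, log) {
  if (config$simulate) {
    pop_args <- config$population
    pop_args$seed <- config$seed     # the run seed governs the simulation
    pop <- generate_population(do.call(population_config, pop_args))
    list(meshes = population_meshes(pop),
         covariates = pop$covariates, truth = pop$truth, log = log)
  } else {
    if (nzchar(config$manifest)) {
      man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    } else {
      files <- list.files(config$mesh_dir, pattern = "\\.(ply|stl|obj|vtk)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (length(files) == 0L) stop("no mesh files found in ", config$mesh_dir, call. = FALSE)
      man <- data.frame(specimen_id = tools::file_path_sans_ext(basename(files)),
                        path = files, side = "unknown", stringsAsFactors = FALSE)
    }
    meshes <- lapply(seq_len(nrow(man)), function(i) {
      m <- read_mesh(man$path[i])
      m$specimen_id <- man$specimen_id[i]
      if (!is.null(man$side)) m$side <- man$side[i]
      m
    })
    names(meshes) <- man$specimen_id
    for (i in seq_along(meshes)) {
      if (meshes[[i]]$side == "left") {
        meshes[[i]] <- reflect_sagittal(meshes[[i]])
        log <- c(log, sprintf("specimen %s: left side, reflected about the sagittal plane",
                              names(meshes)[i]))
      }
    }
    covars <- utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
    list(meshes = meshes, covariates = tibble::as_tibble(covars),
         truth = NULL, log = log)
  }
}

.write_matrix_csv <- function(M, path) {
  df <- data.frame(specimen_id = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full shape-analysis pipeline
#'
#' Orchestrates every stage: input acquisition (synthetic population or mesh
#' files plus covariate CSV, with left-side surfaces reflected), optional
#' smoothing, prototype selection, generalized Procrustes surface analysis,
#' principal coordinates ordination, extreme-shape reconstruction with
#' variation heat maps, GLM fitting with backward stepwise reduction per
#' modelled axis, and (optionally) the prototype sensitivity sweep. All
#' tabular artifacts are CSV; meshes are written as legacy VTK with the
#' heat map as a per-vertex scalar. A run with the same config and seed is
#' bit-reproducible in its CSV outputs.
#'
#' Artifacts written to `config$out_dir`: `distances.csv`, `scores.csv`,
#' `variance.csv`, `model_summary.csv`, `aic_path.csv`, `mean_surface.vtk`,
#' `PC<k>_min.vtk` / `PC<k>_max.vtk` per modelled axis, `truth.csv` (when
#' simulating), `sensitivity.csv` (when requested), `config_resolved.yaml`,
#' and `log.txt`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `gpsa` (the [generalized_align()] result),
#'   `ordination`, `fits` (final `shape_glm` per axis), `covariates`, and
#'   `artifacts` (paths written).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- c(sprintf("surfmorph %s on R %s", as.character(utils::packageVersion("surfmorph")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %d", config$seed))
  stage <- "input"
  artifacts <- character()
  res <- tryCatch({
    inp <- .load_inputs(config, log)
    log <- inp$log
    meshes <- inp$meshes
    if (config$smooth_sigma > 0) {
      stage <- "smoothing"
      meshes <- lapply(meshes, smooth_mesh, sigma_mm = config$smooth_sigma,
                       method = config$smooth_method)
      log <- c(log, sprintf("smoothed all meshes (%s, sigma %.3g mm)",
                            config$smooth_method, config$smooth_sigma))
    }
    stage <- "prototype selection"
    proto_id <- if (config$prototype == "auto") {
      select_prototype(meshes, scale_normalize = config$scale_normalize)$prototype_id
    } else if (grepl("^auto_rank_", config$prototype)) {
      rk <- as.integer(sub("^auto_rank_", "", config$prototype))
      select_prototype(meshes, rank = rk,
                       scale_normalize = config$scale_normalize)$prototype_id
    } else {
      config$prototype
    }
    log <- c(log, sprintf("prototype: %s", proto_id))
    stage <- "generalized alignment"
    gpsa_res <- generalized_align(meshes, prototype_id = proto_id,
                                  max_outer_iter = config$outer_max_iter,
                                  tol = config$outer_tol,
                                  scale_normalize = config$scale_normalize,
                                  icp_max_iter = config$icp_max_iter,
                                  icp_tol = config$icp_tol)
    log <- c(log, sprintf("GPSA converged: %s after %d outer iterations",
                          gpsa_res$converged, gpsa_res$n_outer_iter))
    stage <- "ordination"
    ord <- pcoa(gpsa_res$distances)
    log <- c(log, sprintf("PCoA: %d positive axes, negative eigenvalue mass %.3g",
                          length(ord$eigenvalues), ord$negative_mass))
    stage <- "artifact export"
    p <- file.path(out, "distances.csv")
    .write_matrix_csv(gpsa_res$distances, p); artifacts <- c(artifacts, p)
    p <- file.path(out, "scores.csv")
    utils::write.csv(ord_scores(ord), p, row.names = FALSE); artifacts <- c(artifacts, p)
    p <- file.path(out, "variance.csv")
    utils::write.csv(tidy(ord), p, row.names = FALSE); artifacts <- c(artifacts, p)
    if (!is.null(inp$truth)) {
      p <- file.path(out, "truth.csv")
      utils::write.csv(inp$truth, p, row.names = FALSE); artifacts <- c(artifacts, p)
    }
    axes <- intersect(config$axes, seq_len(ncol(ord$scores)))
    for (ax in axes) {
      s <- ord$scores[, ax]
      sh_min <- reconstruct_shape_at_score(gpsa_res, ord, ax, min(s))
      sh_max <- reconstruct_shape_at_score(gpsa_res, ord, ax, max(s))
      hm <- variation_heatmap(sh_min, sh_max)
      p1 <- file.path(out, sprintf("PC%d_min.vtk", ax))
      p2 <- file.path(out, sprintf("PC%d_max.vtk", ax))
      write_mesh(sh_min, p1, scalar_field = hm)
      write_mesh(sh_max, p2, scalar_field = hm)
      artifacts <- c(artifacts, p1, p2)
      if (ax == axes[1]) {
        p <- file.path(out, "mean_surface.vtk")
        write_mesh(gpsa_res$mean_surface, p, scalar_field = hm)
        artifacts <- c(artifacts, p)
      }
    }
    stage <- "shape-covariate modelling"
    fits <- list()
    model_rows <- list()
    path_rows <- list()
    if (nrow(inp$covariates) > 0L) {
      sc <- ord_scores(ord)
      # keep only as many model terms as the sample size can estimate
      n_obs <- nrow(inp$covariates)
      terms_used <- shape_model_terms(n_obs)
      if (length(terms_used) < length(shape_model_terms(1000L))) {
        log <- c(log, sprintf("n = %d supports only %d model terms: %s",
                              n_obs, length(terms_used),
                              paste(terms_used, collapse = ", ")))
      }
      for (ax in axes) {
        axis_name <- sprintf("PC%d", ax)
        full <- fit_shape_glm(sc, inp$covariates, axis = axis_name,
                              terms = terms_used)
        red <- backward_stepwise(full, criterion = config$stepwise_criterion,
                                 alpha = config$alpha)
        fits[[axis_name]] <- red
        model_rows[[axis_name]] <- dplyr::mutate(tidy(red), axis = axis_name,
                                                 .before = 1L)
        path_rows[[axis_name]] <- dplyr::mutate(red$step_path, axis = axis_name,
                                                .before = 1L)
      }
      p <- file.path(out, "model_summary.csv")
      utils::write.csv(dplyr::bind_rows(model_rows), p, row.names = FALSE)
      artifacts <- c(artifacts, p)
      p <- file.path(out, "aic_path.csv")
      utils::write.csv(dplyr::bind_rows(path_rows), p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
    if (config$sensitivity) {
      stage <- "prototype sensitivity"
      sens <- prototype_sensitivity(meshes, k_pcs = config$sensitivity_pcs,
                                    max_outer_iter = config$outer_max_iter,
                                    tol = config$outer_tol,
                                    scale_normalize = config$scale_normalize)
      rng <- sensitivity_ranges(sens)
      sens_out <- dplyr::bind_rows(
        sens,
        tibble::as_tibble(c(list(prototype_id = "range_max_minus_min"),
                            as.list(rng)))
      )
      p <- file.path(out, "sensitivity.csv")
      utils::write.csv(sens_out, p, row.names = FALSE)
      artifacts <- c(artifacts, p)
    }
    list(gpsa = gpsa_res, ordination = ord, fits = fits,
         covariates = inp$covariates, artifacts = artifacts, log = log)
  }, error = function(e) {
    writeLines(c(log, sprintf("ERROR in stage '%s': %s (partial outputs flagged)",
                              stage, conditionMessage(e))),
               file.path(out, "log.txt"))
    stop(sprintf("pipeline failed in stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  p <- file.path(out, "config_resolved.yaml")
  write_run_config(config, p)
  res$artifacts <- c(res$artifacts, p)
  writeLines(res$log, file.path(out, "log.txt"))
  res$artifacts <- c(res$artifacts, file.path(out, "log.txt"))
  invisible(res)
}
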