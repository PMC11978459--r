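#' Validate a participant covariate table
#'
#' The covariate table carries one row per participant: `specimen_id`,
#' `age_group` (young/older), `sex` (female/male), `height` (cm), `mass`
#' (kg), `volume` (muscle volume, cm^3) and `metmin` (MET-minutes of
#' physical activity per week). Ids must be unique; numeric fields finite
#' and positive.
#'
#' @param covars data frame of covariates.
#' @return the validated tibble with `age_group` and `sex` as factors
#'   (reference levels `young` and `female`).
#' @export
validate_covariates <- function(covars) {
  covars <- tibble::as_tibble(covars)
  need <- c("specimen_id", "age_group", "sex", "height", "mass", "volume", "metmin")
  miss <- setdiff(need, names(covars))
  if (length(miss) > 0L) {
    stop("covariate table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(covars$specimen_id)) stop("specimen_id must be unique", call. = FALSE)
  for (cn in c("height", "mass", "volume", "metmin")) {
    v <- covars[[cn]]
    if (!all(is.finite(v)) || any(v <= 0)) {
      stop(sprintf("covariate '%s' must be finite and positive", cn), call. = FALSE)
    }
  }
  covars$age_group <- factor(as.character(covars$age_group), levels = c("young", "older"))
  covars$sex <- factor(as.character(covars$sex), levels = c("female", "male"))
  if (anyNA(covars$age_group) || anyNA(covars$sex)) {
    stop("age_group must be young/older and sex female/male", call. = FALSE)
  }
  covars
}

# model terms recognised by fit_shape_glm; log_mass is derived from mass
.default_terms <- c("log_mass", "age_group", "sex", "volume", "metmin",
                    "height", "age_group:sex")

#' Default model terms supported by a given sample size
#'
#' The full covariate model — log(mass), age group, sex, volume, MET-minutes,
#' height and the age-by-sex interaction — estimates 8 coefficients. For
#' small samples this returns the leading subset of those terms that still
#' leaves at least two residual degrees of freedom.
#'
#' @param n number of specimens with covariates.
#' @return character vector of model terms.
#' @export
shape_model_terms <- function(n) {
  .default_terms[seq_len(min(length(.default_terms), max(1L, n - 3L)))]
}

#' Fit a general linear model of shape scores on covariates
#'
#' Ordinary least squares of one ordination axis on participant covariates.
#' Body mass enters as its natural log (`log_mass`); `age_group` and `sex`
#' are dummy-coded with `young` and `female` as reference levels; the
#' `age_group:sex` interaction is available as a term. Specimens are matched
#' to covariates by `specimen_id` (inner join; dropped specimens are
#' messaged).
#'
#' @param scores tibble with `specimen_id` and score columns (from
#'   [ord_scores()]).
#' @param covars covariate table (see [validate_covariates()]).
#' @param axis name of the score column to model (default `"PC1"`).
#' @param terms character vector of model terms; any of `log_mass`,
#'   `age_group`, `sex`, `volume`, `metmin`, `height`, `age_group:sex`.
#' @return an object of class `shape_glm` wrapping the `lm` fit, with
#'   per-term partial r-squared; supports [tidy()], [glance()],
#'   [backward_stepwise()], [effect_plot_data()].
#' @export
fit_shape_glm <- function(scores, covars, axis = "PC1", terms = .default_terms) {
  covars <- validate_covariates(covars)
  scores <- tibble::as_tibble(scores)
  if (!axis %in% names(scores)) {
    stop(sprintf("axis '%s' not found in scores", axis), call. = FALSE)
  }
  dat <- dplyr::inner_join(scores[, c("specimen_id", axis)], covars, by = "specimen_id")
  dropped <- setdiff(scores$specimen_id, dat$specimen_id)
  if (length(dropped) > 0L) {
    message(sprintf("%d specimen(s) without covariates dropped: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  dat$log_mass <- log(dat$mass)
  dat$.response <- dat[[axis]]
  bad <- setdiff(unique(unlist(strsplit(terms, ":"))),
                 c("log_mass", "age_group", "sex", "volume", "metmin", "height"))
  if (length(bad) > 0L) {
    stop("unknown model terms: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(terms, response = ".response")
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    na_terms <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model; collinear terms: ", paste(na_terms, collapse = ", "),
         call. = FALSE)
  }
  .as_shape_glm(fit, axis = axis, data = dat)
}

.as_shape_glm <- function(fit, axis, data, step_path = NULL) {
  structure(list(fit = fit, axis = axis, data = data, step_path = step_path,
                 note = "no multiple-testing correction applied across axes or muscles"),
            class = "shape_glm")
}

#' @export
print.shape_glm <- function(x, ...) {
  cat(sprintf("<shape_glm> %s ~ %s\n", x$axis,
              paste(attr(stats::terms(x$fit), "term.labels"), collapse = " + ")))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted shape GLM
#'
#' @param x a [fit_shape_glm()] result.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `partial.r2`.
#' @export
tidy.shape_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  df <- x$fit$df.residual
  tibble::tibble(term = rownames(sm),
                 estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
                 statistic = unname(sm[, 3]), p.value = unname(sm[, 4]),
                 partial.r2 = unname(partial_r2(sm[, 3], df)))
}

#' @rdname tidy.shape_glm
#' @return `glance()`: one-row tibble with `r.squared`, `adj.r.squared`,
#'   `aic`, `df.residual`, `nobs`.
#' @export
glance.shape_glm <- function(x, ...) {
  sm <- summary(x$fit)
  r2 <- sm$r.squared
  tibble::tibble(r.squared = ifelse(is.nan(r2), NA_real_, r2),
                 adj.r.squared = ifelse(is.nan(sm$adj.r.squared), NA_real_, sm$adj.r.squared),
                 aic = stats::AIC(x$fit),
                 df.residual = x$fit$df.residual,
                 nobs = stats::nobs(x$fit))
}

#' Backward stepwise model reduction
#'
#' Iteratively removes the model term whose removal most improves the
#' criterion — the largest AIC decrease (`criterion = "aic"`), or the largest
#' p-value above `alpha` (`criterion = "alpha"`, a partial-F drop test) —
#' and stops when no removal improves. Marginality is respected throughout:
#' an interaction is dropped before its main effects, and main effects are
#' retained while their interaction remains in the model.
#'
#' @param fit a [fit_shape_glm()] result.
#' @param criterion `"aic"` (default) or `"alpha"`.
#' @param alpha significance threshold for the alpha criterion (default 0.05).
#' @return the reduced `shape_glm`; the drop sequence with the AIC path is in
#'   `$step_path`.
#' @export
backward_stepwise <- function(fit, criterion = c("aic", "alpha"), alpha = 0.05) {
  stopifnot(inherits(fit, "shape_glm"))
  criterion <- match.arg(criterion)
  cur <- fit$fit
  path <- tibble::tibble(dropped = "<start>", aic = stats::AIC(cur))
  repeat {
    # drop1 lists only marginality-respecting single-term deletions
    d1 <- if (criterion == "aic") stats::drop1(cur, k = 2) else stats::drop1(cur, test = "F")
    cand <- rownames(d1)[-1]
    if (length(cand) == 0L) break
    if (criterion == "aic") {
      aics <- d1$AIC[-1]
      best <- which.min(aics)
      if (aics[best] >= d1$AIC[1]) break
      drop_term <- cand[best]
    } else {
      pv <- d1[["Pr(>F)"]][-1]
      worst <- which.max(pv)
      if (pv[worst] <= alpha) break
      drop_term <- cand[worst]
    }
    cur <- stats::update(cur, stats::as.formula(paste(". ~ . -", drop_term)),
                         data = fit$data)
    path <- dplyr::bind_rows(path, tibble::tibble(dropped = drop_term,
                                                  aic = stats::AIC(cur)))
  }
  .as_shape_glm(cur, axis = fit$axis, data = fit$data, step_path = path)
}

#' Partial r-squared from a t-statistic
#'
#' The share of residual variance uniquely explained by one model term:
#' `t^2 / (t^2 + df)`, where `df` is the model's residual degrees of
#' freedom. Equals the ratio of the drop in residual sum of squares to the
#' reduced model's residual sum of squares.
#'
#' @param t_stat t-statistic(s) of the term.
#' @param residual_df residual degrees of freedom (>= 1).
#' @return value(s) in `[0, 1]`.
#' @export
partial_r2 <- function(t_stat, residual_df) {
  if (any(residual_df < 1)) stop("`residual_df` must be >= 1", call. = FALSE)
  t_stat^2 / (t_stat^2 + residual_df)
}

#' Two-group comparison with automatic test choice
#'
#' Shapiro-Wilk normality at alpha = 0.05 on each sample decides the test:
#' both consistent with normality, Welch's t-test; otherwise the
#' Mann-Whitney (Wilcoxon rank-sum) test. Samples with zero variance in both
#' groups skip the test and are flagged.
#'
#' @param x,y numeric samples (each of size >= 3).
#' @return one-row tibble: `statistic`, `p.value`, `test_used`
#'   (`"t"`, `"mann_whitney"` or `"none"`), `mean_diff`, `skipped`.
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) stop("both samples need size >= 3", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(tibble::tibble(statistic = NA_real_, p.value = NA_real_,
                          test_used = "none", mean_diff = mean(x) - mean(y),
                          skipped = TRUE))
  }
  normal <- function(v) {
    if (stats::var(v) == 0 || length(v) > 5000L) return(FALSE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (normal(x) && normal(y)) {
    tt <- stats::t.test(x, y)
    tibble::tibble(statistic = unname(tt$statistic), p.value = tt$p.value,
                   test_used = "t", mean_diff = mean(x) - mean(y), skipped = FALSE)
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    tibble::tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                   test_used = "mann_whitney", mean_diff = mean(x) - mean(y),
                   skipped = FALSE)
  }
}

#' Partial-effect plot data for one model term
#'
#' Exports what a residual effect plot draws: partial residuals (ordinary
#' residuals plus the term's contribution), the partial regression line (the
#' term's coefficient through the mean of the partial residuals), and a 95%
#' confidence band from the coefficient's standard error (half-width
#' `t_crit * SE * |x - mean(x)|`).
#'
#' @param fit a [fit_shape_glm()] result.
#' @param term a single-column model term (e.g. `"volume"`, `"height"`,
#'   `"age_group"`).
#' @return tibble with columns `specimen_id`, `x`, `partial_residual`,
#'   `line`, `ci_lower`, `ci_upper`; the coefficient, its standard error and
#'   the critical t are in attributes `coef`, `se`, `t_crit`.
#' @export
effect_plot_data <- function(fit, term) {
  stopifnot(inherits(fit, "shape_glm"))
  lmfit <- fit$fit
  mm <- stats::model.matrix(lmfit)
  asgn <- attr(mm, "assign")
  labs <- attr(stats::terms(lmfit), "term.labels")
  ti <- match(term, labs)
  if (is.na(ti)) stop(sprintf("term '%s' is not in the model", term), call. = FALSE)
  cols <- which(asgn == ti)
  if (length(cols) != 1L) {
    stop(sprintf("term '%s' spans %d design columns; effect plots need a single-column term",
                 term, length(cols)), call. = FALSE)
  }
  x <- mm[, cols]
  beta <- stats::coef(lmfit)[cols]
  se <- summary(lmfit)$coefficients[cols, 2]
  df <- lmfit$df.residual
  t_crit <- stats::qt(0.975, df)
  pr <- stats::residuals(lmfit) + beta * x
  xbar <- mean(x)
  line <- beta * (x - xbar) + mean(pr)
  half <- t_crit * se * abs(x - xbar)
  out <- tibble::tibble(specimen_id = fit$data$specimen_id,
                        x = unname(x), partial_residual = unname(pr),
                        line = unname(line),
                        ci_lower = unname(line - half),
                        ci_upper = unname(line + half))
  attr(out, "coef") <- unname(beta)
  attr(out, "se") <- unname(se)
  attr(out, "t_crit") <- t_crit
  out
}

#' Plot a partial-effect panel
#'
#' @param fit a [fit_shape_glm()] result.
#' @param term single-column model term to display.
#' @return a ggplot of partial residuals with the partial regression line
#'   and its 95% confidence band.
#' @export
plot_partial_effect <- function(fit, term) {
  df <- effect_plot_data(fit, term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                         fill = "red", alpha = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$partial_residual)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$line), colour = "red") +
    ggplot2::labs(x = term, y = sprintf("%s (partial residual)", fit$axis)) +
    ggplot2::theme_minimal()
}
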