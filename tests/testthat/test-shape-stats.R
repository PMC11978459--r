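test_that("fit_shape_glm recovers a known slope and satisfies OLS identities", {
  set.seed(71)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = cov$specimen_id,
                       PC1 = 3 * cov$volume + rnorm(30, 0, 1e-4))
  fit <- fit_shape_glm(sc, cov, axis = "PC1", terms = "volume")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "volume"], 3, tolerance = 1e-3)
  # fitted + residuals reconstruct the response exactly
  y <- sc$PC1[match(fit$data$specimen_id, sc$specimen_id)]
  expect_equal(unname(fitted(fit$fit) + residuals(fit$fit)), y, tolerance = 1e-10)
  # residual df bookkeeping
  expect_equal(glance(fit)$df.residual, 30 - 2)
})

test_that("an identically zero response is handled without error", {
  set.seed(72)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = cov$specimen_id, PC1 = 0)
  fit <- fit_shape_glm(sc, cov, axis = "PC1", terms = c("volume", "height"))
  td <- tidy(fit)
  expect_true(all(abs(td$estimate) < 1e-12))
  expect_true(is.na(glance(fit)$r.squared) || glance(fit)$r.squared == 0)
})

test_that("mass enters as its natural log and factors use reference coding", {
  set.seed(73)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = cov$specimen_id, PC1 = rnorm(30))
  fit <- fit_shape_glm(sc, cov, axis = "PC1",
                       terms = c("log_mass", "age_group", "sex"))
  td <- tidy(fit)
  expect_true("log_mass" %in% td$term)
  expect_true("age_groupolder" %in% td$term)   # reference level: young
  expect_true("sexmale" %in% td$term)          # reference level: female
  expect_equal(unname(coef(fit$fit)["log_mass"]),
               unname(coef(lm(sc$PC1 ~ log(cov$mass) + cov$age_group + cov$sex))[2]),
               tolerance = 1e-9)
})

test_that("specimens without covariates are dropped by the inner join", {
  set.seed(74)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = c(cov$specimen_id, "S99"),
                       PC1 = rnorm(31))
  expect_message(fit <- fit_shape_glm(sc, cov, axis = "PC1", terms = "volume"),
                 "S99")
  expect_equal(glance(fit)$nobs, 30)
})

test_that("backward stepwise matches exhaustive AIC enumeration", {
  terms4 <- c("log_mass", "volume", "metmin", "height")
  set.seed(75)
  for (rep in 1:20) {
    cov <- simulate_covariates()
    beta_v <- sample(c(0, 2), 1)
    beta_h <- sample(c(0, 0.5), 1)
    sc <- tibble::tibble(
      specimen_id = cov$specimen_id,
      PC1 = beta_v * scale(cov$volume)[, 1] + beta_h * scale(cov$height)[, 1] +
        rnorm(30)
    )
    fit <- fit_shape_glm(sc, cov, axis = "PC1", terms = terms4)
    red <- backward_stepwise(fit, criterion = "aic")
    got <- sort(attr(terms(red$fit), "term.labels"))
    oracle <- exhaustive_aic_best(fit$data, terms4)
    expect_equal(got, oracle$terms,
                 info = sprintf("replicate %d", rep))
  }
})

test_that("stepwise respects marginality for the age-sex interaction", {
  set.seed(76)
  cov <- simulate_covariates()
  g <- as.numeric(cov$age_group == "older")
  s <- as.numeric(cov$sex == "male")
  # strong interaction, weak mains
  sc <- tibble::tibble(specimen_id = cov$specimen_id,
                       PC1 = 3 * g * s + rnorm(30, 0, 0.5))
  fit <- fit_shape_glm(sc, cov, axis = "PC1",
                       terms = c("age_group", "sex", "age_group:sex"))
  red <- backward_stepwise(fit, criterion = "aic")
  kept <- attr(terms(red$fit), "term.labels")
  expect_true("age_group:sex" %in% kept)
  expect_true(all(c("age_group", "sex") %in% kept))
})

test_that("stepwise reduces a pure-noise response to the intercept", {
  set.seed(77)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = cov$specimen_id, PC1 = rnorm(30))
  fit <- fit_shape_glm(sc, cov, axis = "PC1",
                       terms = c("volume", "height", "metmin"))
  red_aic <- backward_stepwise(fit, criterion = "aic")
  oracle <- exhaustive_aic_best(fit$data, c("volume", "height", "metmin"))
  expect_equal(sort(attr(terms(red_aic$fit), "term.labels")), oracle$terms)
  red_alpha <- backward_stepwise(fit, criterion = "alpha")
  td <- tidy(red_alpha)
  # alpha mode keeps only significant terms
  kept_p <- td$p.value[td$term != "(Intercept)"]
  expect_true(length(kept_p) == 0 || all(kept_p <= 0.05 + 1e-12))
})

test_that("partial_r2 follows its definition and the RSS-ratio identity", {
  expect_equal(partial_r2(0, 10), 0)
  expect_equal(partial_r2(2, 16), 0.2)
  expect_gt(partial_r2(1e6, 10), 0.999)
  expect_error(partial_r2(1, 0), "residual_df")
  # identity on a fitted model: t^2/(t^2+df) == (RSS_reduced - RSS_full)/RSS_reduced
  set.seed(78)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = cov$specimen_id,
                       PC1 = 0.8 * scale(cov$volume)[, 1] + rnorm(30))
  fit <- fit_shape_glm(sc, cov, axis = "PC1", terms = c("volume", "height"))
  td <- tidy(fit)
  full <- fit$fit
  red <- lm(.response ~ height, data = fit$data)
  rss_ratio <- (sum(residuals(red)^2) - sum(residuals(full)^2)) /
    sum(residuals(red)^2)
  expect_equal(td$partial.r2[td$term == "volume"], rss_ratio, tolerance = 1e-9)
})

test_that("compare_groups picks Welch t for normal and Mann-Whitney for skewed data", {
  res_t <- compare_groups(1:5, 11:15)
  expect_identical(res_t$test_used, "t")
  expect_lt(res_t$p.value, 0.001)
  # cross-check the p-value against the t distribution
  tt <- t.test(1:5, 11:15)
  expect_equal(res_t$p.value, tt$p.value)
  set.seed(79)
  x <- exp(rnorm(40, 0, 2))       # heavily skewed
  y <- exp(rnorm(40, 0.5, 2))
  res_mw <- compare_groups(x, y)
  expect_identical(res_mw$test_used, "mann_whitney")
  set.seed(80)
  a <- rnorm(20)
  b <- rnorm(20)
  res0 <- compare_groups(a, b)
  expect_true(res0$p.value > 0 && is.finite(res0$p.value))
})

test_that("compare_groups flags zero-variance samples and short input", {
  res <- compare_groups(rep(1, 5), rep(3, 5))
  expect_true(res$skipped)
  expect_identical(res$test_used, "none")
  expect_equal(res$mean_diff, -2)
  expect_error(compare_groups(1:2, 1:5), "size >= 3")
})

test_that("effect plot data reconstructs partial residuals and the fitted slope", {
  set.seed(81)
  cov <- simulate_covariates()
  sc <- tibble::tibble(specimen_id = cov$specimen_id,
                       PC1 = 1.5 * cov$volume + rnorm(30, 0, 5))
  fit <- fit_shape_glm(sc, cov, axis = "PC1", terms = "volume")
  ep <- effect_plot_data(fit, "volume")
  # single covariate: partial residuals reconstruct y - intercept
  y <- fit$data$.response
  expect_equal(ep$partial_residual, y - coef(fit$fit)[1], tolerance = 1e-9,
               ignore_attr = TRUE)
  # least squares through the exported points returns the model coefficient
  slope <- coef(lm(partial_residual ~ x, data = ep))[2]
  expect_equal(unname(slope), unname(coef(fit$fit)["volume"]), tolerance = 1e-9)
  # CI half-width at unit offset tends to 1.96 SE for large df
  hw <- attr(ep, "t_crit") * attr(ep, "se")
  expect_equal(attr(ep, "t_crit"), qt(0.975, fit$fit$df.residual))
  expect_lt(abs(attr(ep, "t_crit") - 1.96) / 1.96, 0.05)
  expect_error(effect_plot_data(fit, "height"), "not in the model")
  p <- plot_partial_effect(fit, "volume")
  expect_s3_class(p, "ggplot")
})

test_that("an injected group shift is retained with the right sign (power)", {
  set.seed(82)
  retained <- 0L
  sign_ok <- 0L
  n_rep <- 30L
  for (rep in seq_len(n_rep)) {
    cov <- simulate_covariates()
    g <- as.numeric(cov$age_group == "older")
    sc <- tibble::tibble(specimen_id = cov$specimen_id,
                         PC1 = 1.5 * g + rnorm(30))   # Delta = 1.5 pooled SD
    fit <- fit_shape_glm(sc, cov, axis = "PC1",
                         terms = c("age_group", "sex", "volume", "height"))
    red <- backward_stepwise(fit, criterion = "aic")
    kept <- attr(terms(red$fit), "term.labels")
    if ("age_group" %in% kept) {
      retained <- retained + 1L
      if (coef(red$fit)["age_groupolder"] > 0) sign_ok <- sign_ok + 1L
    }
  }
  expect_gte(retained / n_rep, 0.9)
  expect_equal(sign_ok, retained)
})

test_that("alpha-criterion retention under the null stays near its nominal level", {
  set.seed(83)
  retained <- 0L
  n_rep <- 100L
  for (rep in seq_len(n_rep)) {
    cov <- simulate_covariates()
    sc <- tibble::tibble(specimen_id = cov$specimen_id, PC1 = rnorm(30))
    fit <- fit_shape_glm(sc, cov, axis = "PC1",
                         terms = c("age_group", "volume", "height"))
    red <- backward_stepwise(fit, criterion = "alpha")
    if ("age_group" %in% attr(terms(red$fit), "term.labels")) retained <- retained + 1L
  }
  expect_lte(retained / n_rep, 0.1)
})

test_that("covariate validation catches structural problems", {
  cov <- simulate_covariates()
  expect_error(validate_covariates(cov[, -4]), "missing columns")
  bad <- cov
  bad$mass[1] <- -1
  expect_error(validate_covariates(bad), "positive")
  dup <- cov
  dup$specimen_id[2] <- dup$specimen_id[1]
  expect_error(validate_covariates(dup), "unique")
  lvl <- cov
  lvl$age_group[1] <- "ancient"
  expect_error(validate_covariates(lvl), "young/older")
})
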