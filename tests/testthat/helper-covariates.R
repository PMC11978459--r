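# covariate tables without the mesh pipeline, for score-level model tests
simulate_covariates <- function(n_young = 15, n_older = 15) {
  n <- n_young + n_older
  tibble::tibble(
    specimen_id = sprintf("S%02d", seq_len(n)),
    age_group = c(rep("young", n_young), rep("older", n_older)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    height = stats::rnorm(n, 171, 9),
    mass = stats::rlnorm(n, log(72), 0.2),
    volume = stats::rlnorm(n, log(250), 0.25),
    metmin = stats::rlnorm(n, log(3000), 0.5)
  )
}

# exhaustive search over all marginality-respecting submodels, by AIC
exhaustive_aic_best <- function(data, terms) {
  all_subsets <- function(v) {
    if (length(v) == 0) return(list(character()))
    rest <- all_subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  ok <- function(s) {
    # marginality: an interaction requires both its main effects
    for (tm in s[grepl(":", s)]) {
      if (!all(strsplit(tm, ":")[[1]] %in% s)) return(FALSE)
    }
    TRUE
  }
  subs <- Filter(ok, all_subsets(terms))
  fits <- lapply(subs, function(s) {
    fml <- if (length(s) == 0) .response ~ 1 else stats::reformulate(s, ".response")
    stats::lm(fml, data = data)
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  list(terms = sort(subs[[which.min(aics)]]), aic = min(aics))
}
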