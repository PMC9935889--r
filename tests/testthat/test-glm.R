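make_fits_row <- function(module_id, phylum, intercept, slope) {
  out <- tibble::tibble(
    module_id = module_id, phylum = phylum,
    intercept = intercept, intercept_se = 0.1,
    slope = slope, slope_se = 0.1, n_obs = 10L, converged = TRUE
  )
  class(out) <- c("mag_glm_fits", class(out))
  out
}

test_that("flat fullness yields a numerically zero slope", {
  df <- tibble::tibble(
    genome_id = sprintf("G%03d", 1:60),
    phylum = "Firmicutes",
    completeness = seq(0.7, 1, length.out = 60),
    module_id = "M1", n_steps = 10L, k = 5L,
    fullness = 0.5
  )
  fit <- fit_module_glms(df)
  expect_true(fit$converged)
  expect_lt(abs(fit$slope), 1e-6)
})

test_that("point estimates are invariant to duplicating every observation", {
  cat1 <- simulate_catalog(1, step_lambda = 6, seed = 1)
  model <- default_parametric_model(cat1, seed = 2)
  sim <- simulate_parametric_fullness(model, n_genomes = 80, seed = 3)
  f1 <- fit_module_glms(sim, tol = 1e-12)
  dup <- dplyr::bind_rows(sim, dplyr::mutate(sim, genome_id = paste0(genome_id, "b")))
  f2 <- fit_module_glms(dup, tol = 1e-12)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-6)
})

test_that("known generative slope is recovered on parametric data", {
  model <- tibble::tibble(
    module_id = "M1", phylum = "Firmicutes", n_steps = 10L,
    alpha = -2, beta = 4
  )
  sim <- simulate_parametric_fullness(model, n_genomes = 2000, seed = 11)
  fit <- fit_module_glms(sim)
  expect_true(fit$converged)
  expect_lt(abs(fit$slope - 4), 0.3)
  expect_lt(abs(fit$intercept - (-2)), 0.3)
})

test_that("derived per-phylum slopes are invariant to the reference level", {
  cat2 <- simulate_catalog(2, seed = 5)
  model <- default_parametric_model(cat2, seed = 6)
  sim <- simulate_parametric_fullness(model, n_genomes = 200, seed = 7)
  fa <- fit_module_glms(sim, reference_phylum = "Actinobacteriota", tol = 1e-12)
  fp <- fit_module_glms(sim, reference_phylum = "Proteobacteria", tol = 1e-12)
  fa <- dplyr::arrange(tidy(fa), module_id, phylum)
  fp <- dplyr::arrange(tidy(fp), module_id, phylum)
  expect_equal(fa$slope, fp$slope, tolerance = 1e-6)
  expect_equal(fa$slope_se, fp$slope_se, tolerance = 1e-4)
  expect_equal(fa$intercept, fp$intercept, tolerance = 1e-6)
})

test_that("linear rescaling of completeness rescales slopes exactly", {
  model <- tibble::tibble(
    module_id = "M1", phylum = "Firmicutes", n_steps = 8L,
    alpha = -1, beta = 3
  )
  sim <- simulate_parametric_fullness(model, n_genomes = 300, seed = 13)
  f1 <- fit_module_glms(sim, tol = 1e-12)
  half <- dplyr::mutate(sim, completeness = completeness / 2)
  f2 <- fit_module_glms(half, tol = 1e-12)
  expect_equal(f2$slope, 2 * f1$slope, tolerance = 1e-6)
})

test_that("counts are recovered from proportions, and incompatible step counts are rejected", {
  df <- tibble::tibble(
    genome_id = c("G1", "G2"), phylum = "Firmicutes",
    completeness = c(0.8, 0.9), module_id = "M1", n_steps = 4L,
    fullness = c(0.25, 0.75)
  )
  fit <- fit_module_glms(df)
  expect_s3_class(fit, "mag_glm_fits")
  df_bad <- dplyr::mutate(df, fullness = c(0.3, 0.75))
  expect_error(fit_module_glms(df_bad), "not an integer")
})

test_that("separated fits are flagged non-converged and excluded from the slope table", {
  cat2 <- simulate_catalog(2, step_lambda = 4, seed = 15)
  mods <- catalog_modules(cat2)
  df <- tidyr::expand_grid(
    genome_id = sprintf("G%02d", 1:20),
    mods[, c("module_id", "n_steps")]
  ) |>
    dplyr::mutate(
      phylum = "Firmicutes",
      completeness = rep(seq(0.7, 1, length.out = 20), each = 2),
      # first module: all steps absent (complete separation at the boundary)
      k = dplyr::if_else(module_id == mods$module_id[1], 0L,
        pmax(1L, n_steps - 1L)
      ),
      fullness = k / n_steps
    )
  fit <- fit_module_glms(df)
  expect_false(fit$converged[fit$module_id == mods$module_id[1]])
  expect_message(
    slopes <- extract_slopes(fit, cat2),
    "non-converged"
  )
  expect_false(mods$module_id[1] %in% slopes$module_id)
})

test_that("prediction and fullness change follow their closed forms", {
  fits <- make_fits_row("M1", "Firmicutes", intercept = -2, slope = 4)
  expect_equal(
    predict_fullness(fits, "Firmicutes", 1)$predicted, plogis(2)
  )
  expect_equal(round(predict_fullness(fits, "Firmicutes", 1)$predicted, 4), 0.8808)
  expect_error(predict_fullness(fits, "Bacteroidota", 1), "not present")

  flat <- make_fits_row("M1", "Firmicutes", 0, 0)
  expect_equal(predict_fullness(flat, "Firmicutes", 0.33)$predicted, 0.5)
  p8 <- make_fits_row("M1", "Firmicutes", qlogis(0.8), 0)
  expect_equal(predict_fullness(p8, "Firmicutes", 0.1)$predicted, 0.8)

  expect_equal(fullness_change(flat)$change_pp, 0)
  f04 <- make_fits_row("M1", "Firmicutes", 0, 4)
  expect_equal(
    fullness_change(f04)$change_pp,
    100 * (plogis(4) - plogis(2.8))
  )
  expect_equal(round(fullness_change(f04)$change_pp, 2), 3.93)
  fm24 <- make_fits_row("M1", "Firmicutes", -2, 4)
  expect_equal(round(fullness_change(fm24)$change_pp, 1), 19.1)
})

test_that("slope table arithmetic: modules x phyla rows, mostly positive under a positive generative model", {
  cat10 <- simulate_catalog(10, seed = 17)
  model <- default_parametric_model(cat10, seed = 18)
  sim <- simulate_parametric_fullness(model, n_genomes = 500, seed = 19)
  fit <- fit_module_glms(sim)
  slopes <- extract_slopes(fit, cat10)
  expect_equal(nrow(slopes), sum(fit$converged))
  if (all(fit$converged)) expect_equal(nrow(slopes), 10 * 4)
  expect_gte(mean(slopes$slope > 0), 0.9)
})
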