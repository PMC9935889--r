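#' Default generative model for the fullness-completeness relationship
#'
#' Builds a parametric model of module fullness on the logit scale:
#' for module m and phylum p, satisfied steps are
#' `k ~ Binomial(S_m, plogis(alpha_m + beta_mp * completeness))` with
#' completeness a proportion. The defaults encode the qualitative structure
#' reported for real MAG cohorts: almost all slopes positive, a phylum
#' ordering with Proteobacteria steepest and Bacteroidota shallowest, a
#' negative association between slope and module step count, and module-level
#' slope heterogeneity (a random intercept at the module level).
#'
#' Specifically, `alpha_m ~ N(alpha_mean, alpha_sd^2)` and
#' `beta_mp = slope_mean + phylum_effects[p] + steps_effect * (S_m - mean(S)) +
#' b_m + e_mp` with `b_m ~ N(0, module_sd^2)` and `e_mp ~ N(0, resid_sd^2)`.
#'
#' @param catalog Module catalog tibble; supplies module ids and step counts.
#' @param phyla Phylum universe.
#' @param alpha_mean,alpha_sd Mean and s.d. of the module intercepts.
#' @param slope_mean Grand mean of the completeness slopes.
#' @param phylum_effects Named numeric vector of phylum offsets to the slope;
#'   must cover `phyla`.
#' @param steps_effect Change in slope per extra module step (centred).
#' @param module_sd S.d. of the module-level random slope component shared
#'   across phyla.
#' @param resid_sd S.d. of the residual module-by-phylum slope component.
#' @param seed Integer seed.
#'
#' @return Tibble of class `mag_parametric_model` with one row per
#'   (module, phylum): `module_id`, `phylum`, `n_steps`, `alpha`, `beta`.
#' @export
default_parametric_model <- function(catalog, phyla = default_phyla(),
                                     alpha_mean = -1.5, alpha_sd = 1,
                                     slope_mean = 3.2,
                                     phylum_effects = c(
                                       Actinobacteriota = -0.15,
                                       Bacteroidota = -0.5,
                                       Firmicutes = 0.15,
                                       Proteobacteria = 0.5
                                     ),
                                     steps_effect = -0.05,
                                     module_sd = 0.5, resid_sd = 0.2,
                                     seed = 1337) {
  if (!all(phyla %in% names(phylum_effects))) {
    stop("`phylum_effects` must name every phylum in `phyla`", call. = FALSE)
  }
  mods <- catalog_modules(catalog)
  withr::with_seed(as.integer(seed), {
    mods$alpha <- rnorm(nrow(mods), alpha_mean, alpha_sd)
    mods$b_m <- rnorm(nrow(mods), 0, module_sd)
    grid <- tidyr::expand_grid(mods, phylum = phyla)
    grid$beta <- slope_mean + phylum_effects[grid$phylum] +
      steps_effect * (grid$n_steps - mean(mods$n_steps)) +
      grid$b_m + rnorm(nrow(grid), 0, resid_sd)
  })
  out <- tibble::as_tibble(
    grid[, c("module_id", "phylum", "n_steps", "alpha", "beta")]
  )
  class(out) <- c("mag_parametric_model", class(out))
  out
}

#' Simulate fullness data from a parametric logit-linear model
#'
#' Draws a cohort of genomes with completeness uniform on
#' `completeness_range` and phyla sampled with probabilities `phylum_mix`,
#' then draws satisfied step counts
#' `k_mg ~ Binomial(S_m, plogis(alpha_m + beta_mp * c_g))` for every
#' (module, genome) pair and returns the long fullness table. This is the
#' generative mirror of the per-module binomial GLM, so that slope recovery
#' can be tested against known truth.
#'
#' @param model Parametric model tibble (`module_id`, `phylum`, `n_steps`,
#'   `alpha`, `beta`), e.g. from [default_parametric_model()].
#' @param n_genomes Number of genomes to draw.
#' @param completeness_range Interval within (0, 1] for the uniform
#'   completeness draw; default `c(0.7, 1)`, the conventional MAG quality
#'   window. A zero-width range is allowed but makes slopes unidentifiable
#'   (a warning is emitted when `n_genomes > 1`).
#' @param phylum_mix Named probabilities over the model's phyla (must sum
#'   to 1); default equal.
#' @param seed Integer seed.
#'
#' @return Long fullness tibble: `genome_id`, `phylum`, `completeness`,
#'   `module_id`, `n_steps`, `k`, `fullness`, with `fullness = k / n_steps`.
#' @export
simulate_parametric_fullness <- function(model, n_genomes,
                                         completeness_range = c(0.7, 1),
                                         phylum_mix = NULL, seed = 1337) {
  assert_columns(
    model, c("module_id", "phylum", "n_steps", "alpha", "beta"),
    "model"
  )
  assert_proportion(completeness_range, "completeness_range",
    lo = 0, lo_open = TRUE
  )
  if (diff(range(completeness_range)) == 0 && n_genomes > 1) {
    warning(
      "degenerate completeness range: slopes are unidentifiable",
      call. = FALSE
    )
  }
  phyla <- sort(unique(model$phylum))
  if (is.null(phylum_mix)) {
    phylum_mix <- setNames(rep(1 / length(phyla), length(phyla)), phyla)
  }
  if (abs(sum(phylum_mix) - 1) > 1e-8) {
    stop("`phylum_mix` must sum to 1", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    genomes <- tibble::tibble(
      genome_id = sprintf("G%05d", seq_len(n_genomes)),
      phylum = sample(names(phylum_mix), n_genomes,
        replace = TRUE, prob = phylum_mix
      ),
      completeness = runif(
        n_genomes, min(completeness_range), max(completeness_range)
      )
    )
    long <- dplyr::inner_join(genomes, model,
      by = "phylum", relationship = "many-to-many"
    )
    long$p <- plogis(long$alpha + long$beta * long$completeness)
    long$k <- rbinom(nrow(long), long$n_steps, long$p)
  })
  long$fullness <- long$k / long$n_steps
  tibble::as_tibble(long[, c(
    "genome_id", "phylum", "completeness", "module_id",
    "n_steps", "k", "fullness"
  )])
}
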