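# synthetic slope table generated from a known mixed model
make_slope_table <- function(n_modules = 40, seed = 1,
                             phylum_eff = c(
                               Actinobacteriota = 0, Bacteroidota = -0.4,
                               Firmicutes = 0.2, Proteobacteria = 0.6
                             ),
                             steps_coef = -0.05, module_sd = 0.5,
                             resid_sd = 0.2, intercept = 3) {
  withr::with_seed(seed, {
    mods <- tibble::tibble(
      module_id = sprintf("M%03d", seq_len(n_modules)),
      domain = rep_len(default_domains()[1:5], n_modules),
      n_steps = 1L + rpois(n_modules, 6),
      b_m = rnorm(n_modules, 0, module_sd)
    )
    tidyr::expand_grid(mods, phylum = names(phylum_eff)) |>
      dplyr::mutate(
        slope = intercept + phylum_eff[phylum] + steps_coef * n_steps +
          b_m + rnorm(dplyr::n(), 0, resid_sd),
        slope_se = 0.1
      ) |>
      dplyr::select(module_id, phylum, slope, slope_se, domain, n_steps)
  })
}

test_that("degenerate inputs: equal slopes give zero contrasts and variances", {
  tbl <- make_slope_table(10, seed = 2)
  tbl$slope <- 1.5
  fit <- suppressWarnings(fit_slope_lmm(tbl))
  expect_true(fit$singular)
  g <- glance(fit)
  expect_lt(g$sigma2_module, 1e-10)
  expect_lt(g$sigma2_residual, 1e-10)
  co <- tidy(fit)
  expect_lt(max(abs(co$estimate[co$term != "(Intercept)"])), 1e-8)
  expect_equal(co$estimate[co$term == "(Intercept)"], 1.5, tolerance = 1e-6)
})

test_that("adding a constant to every slope shifts only the intercept", {
  tbl <- make_slope_table(25, seed = 3)
  f1 <- fit_slope_lmm(tbl)
  tbl2 <- dplyr::mutate(tbl, slope = slope + 2)
  f2 <- fit_slope_lmm(tbl2)
  c1 <- tidy(f1)
  c2 <- tidy(f2)
  expect_equal(
    c2$estimate[c2$term == "(Intercept)"],
    c1$estimate[c1$term == "(Intercept)"] + 2,
    tolerance = 1e-6
  )
  other <- c1$term != "(Intercept)"
  expect_equal(c2$estimate[other], c1$estimate[other], tolerance = 1e-6)
})

test_that("REML optimum matches a grid search over the variance ratio", {
  tbl <- make_slope_table(20, seed = 4)
  fit <- fit_slope_lmm(tbl)
  X <- stats::model.matrix(~ phylum + domain + n_steps, fit$data)
  y <- fit$data$slope
  grp <- fit$data$module_id
  theta <- lme4::getME(fit$model, "theta") # sd ratio sigma_mod / sigma_e
  crit_hat <- oracle_reml_criterion(y, X, grp, lambda = theta^2)
  grid <- c(0, exp(seq(log(1e-4), log(100), length.out = 400)))
  crit_grid <- vapply(grid, function(l) {
    oracle_reml_criterion(y, X, grp, l)
  }, numeric(1))
  expect_lte(crit_hat, min(crit_grid) + 1e-4)
})

test_that("balanced one-way case agrees with closed-form ANOVA estimators", {
  withr::with_seed(5, {
    k <- 30
    n_i <- 4
    grp <- rep(sprintf("M%03d", 1:k), each = n_i)
    y <- rnorm(k, 0, 0.7)[rep(1:k, each = n_i)] + rnorm(k * n_i, 0, 0.3) + 2
  })
  tbl <- tibble::tibble(
    module_id = grp, phylum = "Firmicutes", slope = y, slope_se = 0.1,
    domain = "Energy metabolism", n_steps = 5L
  )
  # phylum/domain collapse to intercept-only; model is slope ~ 1 + (1|module)
  fit <- fit_slope_lmm(tbl)
  vc <- glance(fit)
  want <- oracle_anova_vc(y, grp)
  expect_equal(vc$sigma2_module, unname(want["sigma2_between"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_residual, unname(want["sigma2_within"]), tolerance = 1e-4)
})

test_that("generative fixed effects are recovered and ordered correctly", {
  tbl <- make_slope_table(120, seed = 6)
  fit <- fit_slope_lmm(tbl)
  co <- tidy(fit)
  steps <- co[co$term == "n_steps", ]
  expect_lt(abs(steps$estimate - (-0.05)), 3 * steps$std_error + 0.02)
  # marginal predictions put the constructed strongest phylum first
  mp <- marginal_predictions(fit, "phylum")
  expect_equal(mp$level[1], "Proteobacteria")
  expect_equal(mp$level[4], "Bacteroidota")
  # invariant to row order
  fit2 <- fit_slope_lmm(dplyr::arrange(tbl, dplyr::desc(slope)))
  expect_equal(
    marginal_predictions(fit2, "phylum")$predicted,
    mp$predicted,
    tolerance = 1e-6
  )
  # with all contrasts absent, predictions coincide across levels
  flat <- dplyr::mutate(tbl, slope = 3 + rnorm(dplyr::n(), 0, 1e-3))
  mp_flat <- marginal_predictions(suppressWarnings(fit_slope_lmm(flat)), "phylum")
  expect_lt(diff(range(mp_flat$predicted)), 0.01)
})

test_that("parametric bootstrap is reproducible and covers the generating steps coefficient", {
  tbl <- make_slope_table(40, seed = 7)
  fit <- fit_slope_lmm(tbl)
  ci1 <- bootstrap_slope_cis(fit, n_sim = 60, seed = 99)
  ci2 <- bootstrap_slope_cis(fit, n_sim = 60, seed = 99)
  expect_identical(ci1, ci2)
  expect_equal(nrow(ci1), 4 + 5 + 1) # phylum levels + domain levels + steps
  steps <- ci1[ci1$quantity == "steps", ]
  expect_lt(steps$lower, steps$estimate)
  expect_gt(steps$upper, steps$estimate)
})

test_that("overlap verdicts follow the interval arithmetic", {
  ci <- tibble::tibble(
    quantity = c("phylum", "phylum", "phylum", "steps"),
    level_ = c("A", "B", "C", "n_steps"),
    estimate = c(1.5, 3.5, 2.5, -0.045),
    lower = c(1, 3, 2, -0.08),
    upper = c(2, 4, 3, -0.01)
  )
  fnd <- evaluate_hypotheses(ci)
  ab <- fnd[fnd$level_a == "A" & fnd$level_b == "B", ]
  expect_false(ab$overlap)
  expect_equal(ab$verdict, "difference")
  ac <- fnd[fnd$level_a == "A" & fnd$level_b == "C", ]
  expect_true(ac$overlap) # shared boundary counts as overlap
  st <- fnd[fnd$quantity == "steps", ]
  expect_equal(st$verdict, "negative association")
})
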