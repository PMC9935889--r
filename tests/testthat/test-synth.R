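test_that("catalog generation respects size, uniqueness and determinism", {
  one <- simulate_catalog(n_modules = 1, step_lambda = 0, seed = 3)
  expect_equal(catalog_modules(one)$n_steps, 1L)

  cat195 <- simulate_catalog(195, step_lambda = 6, seed = 1)
  mods <- catalog_modules(cat195)
  expect_equal(nrow(mods), 195)
  expect_false(anyDuplicated(mods$module_id) > 0)
  expect_true(all(mods$n_steps >= 1))
  expect_true(all(mods$n_steps <= 40))
  expect_false(anyDuplicated(cat195$gene_id) > 0)

  again <- simulate_catalog(195, step_lambda = 6, seed = 1)
  expect_identical(cat195, again)
  expect_false(identical(cat195, simulate_catalog(195, step_lambda = 6, seed = 2)))
})

test_that("complete genomes carry all or no modules at probability extremes", {
  cat6 <- simulate_catalog(6, seed = 4)
  g_all <- simulate_genome("G1", "Firmicutes", cat6,
    module_presence_prob = 1, seed = 5
  )
  f <- compute_fullness(g_all, cat6)
  expect_true(all(f$fullness == 1))

  g_none <- simulate_genome("G2", "Firmicutes", cat6,
    module_presence_prob = 0, n_sccg = 10, seed = 5
  )
  expect_setequal(g_none$gene_id, sccg_ids(10))

  # gene conservation across contigs
  expect_equal(nrow(g_all), sum(table(g_all$contig_id)))
})

test_that("contig subsampling keeps round-half-up counts and is a pure function of the seed", {
  cat6 <- simulate_catalog(6, seed = 4)
  g <- simulate_genome("G1", "Firmicutes", cat6, n_contigs = 42, seed = 6)
  expect_equal(dplyr::n_distinct(g$contig_id), 42)

  s1 <- subsample_contigs(g, retention = 0.8, seed = 9)
  expect_equal(dplyr::n_distinct(s1$contig_id), 34) # round(0.8 * 42)
  s2 <- subsample_contigs(g, retention = 0.8, seed = 9)
  expect_identical(s1, s2)

  # conservation: never adds genes
  expect_true(all(s1$gene_id %in% g$gene_id))

  g10 <- simulate_genome("G2", "Firmicutes", cat6, n_contigs = 10, seed = 7)
  expect_equal(
    dplyr::n_distinct(subsample_contigs(g10, 0.7, seed = 1)$contig_id), 7
  )

  ident <- subsample_contigs(g, retention = 1, seed = 1)
  expect_setequal(ident$gene_id, g$gene_id)

  expect_error(subsample_contigs(g, 0), "retention")
  expect_error(subsample_contigs(g, 1.2), "retention")
})

test_that("completeness estimation is the recovered marker fraction", {
  ann <- tiny_annotations(c(sccg_ids(100)[1:85], "K1"))
  expect_equal(estimate_completeness(ann)$est_completeness, 0.85)
  full <- tiny_annotations(sccg_ids(100))
  expect_equal(estimate_completeness(full)$est_completeness, 1)
  expect_error(estimate_completeness(full, character(0)), "non-empty")
})

test_that("mean estimated completeness tracks retention under contig dropout", {
  cat10 <- simulate_catalog(10, seed = 2)
  g <- simulate_genome("G1", "Firmicutes", cat10,
    n_contigs = 100, n_sccg = 100, seed = 3
  )
  ests <- vapply(1:200, function(i) {
    s <- subsample_contigs(g, retention = 0.8, seed = i)
    estimate_completeness(s)$est_completeness
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.8), 3 * se + 1e-12)
})

test_that("parametric fullness generator matches its closed-form mean", {
  cat1 <- simulate_catalog(1, step_lambda = 9, seed = 1)
  model <- tibble::tibble(
    module_id = cat1$module_id[1], phylum = "Firmicutes",
    n_steps = catalog_modules(cat1)$n_steps, alpha = 0, beta = 4
  )
  sim <- simulate_parametric_fullness(model,
    n_genomes = 2000,
    completeness_range = c(1, 1), seed = 5
  ) |> suppressWarnings()
  p <- plogis(4)
  se <- sqrt(p * (1 - p) / (model$n_steps * 2000))
  expect_lt(abs(mean(sim$fullness) - p), 3 * se)

  # flat model: mean fullness 0.5 regardless of completeness
  model0 <- model
  model0$alpha <- 0
  model0$beta <- 0
  sim0 <- simulate_parametric_fullness(model0, n_genomes = 1000, seed = 6)
  expect_lt(abs(mean(sim0$fullness) - 0.5), 0.02)

  # single-step modules only produce 0/1 fullness
  m1 <- tibble::tibble(
    module_id = "M1", phylum = "Firmicutes", n_steps = 1L,
    alpha = 0.3, beta = 1
  )
  s1 <- simulate_parametric_fullness(m1, n_genomes = 200, seed = 7)
  expect_true(all(s1$fullness %in% c(0, 1)))
})

test_that("fullness under dropout is stochastically monotone in retention and hits the mechanistic limit", {
  cat20 <- simulate_catalog(20,
    step_lambda = 5, alt_genes_per_step = 1,
    seed = 8
  )
  g <- simulate_genome("G1", "Proteobacteria", cat20,
    module_presence_prob = 1, n_contigs = 100, seed = 9
  )
  mean_fullness <- function(retention, n_rep) {
    vapply(seq_len(n_rep), function(i) {
      s <- subsample_contigs(g, retention, seed = 1000 + i)
      mean(compute_fullness(s, cat20)$fullness)
    }, numeric(1))
  }
  f7 <- mean_fullness(0.7, 60)
  f9 <- mean_fullness(0.9, 60)
  se_pair <- sqrt(stats::var(f7) / 60 + stats::var(f9) / 60)
  expect_lt(mean(f7), mean(f9) + 2 * se_pair)
  # one gene per step on uniformly assigned contigs: E[fullness] = retention
  se7 <- stats::sd(f7) / sqrt(60)
  expect_lt(abs(mean(f7) - 0.7), 3 * se7 + 1e-12)
})

test_that("injected contamination is reported as marker redundancy", {
  cat5 <- simulate_catalog(5, seed = 2)
  g <- simulate_genome("G1", "Bacteroidota", cat5, seed = 3)
  dirty <- add_contamination(g, fraction = 0.12, seed = 4)
  meta <- summarise_genomes(dirty)
  expect_equal(meta$contamination, 0.12)
  expect_equal(summarise_genomes(g)$contamination, 0)
})
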