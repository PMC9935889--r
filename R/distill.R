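#' Distill gene annotations into module fullness
#'
#' Computes, for every genome and every module of the catalog, the number of
#' module steps satisfied (a step counts as satisfied when at least one of its
#' alternative genes is present in the genome) and the module fullness
#' `k / n_steps` — the proportion of a module's enzymatic steps enabled by the
#' genes present. Genome-module pairs where no step is satisfied get
#' fullness 0, so the result has no missing cells.
#'
#' @param annotations Annotation tibble with columns `genome_id`, `phylum`,
#'   `contig_id` (optional), `gene_id`; genome ids must be unique per genome.
#' @param catalog Module catalog tibble.
#' @return Long fullness tibble: `genome_id`, `phylum`, `module_id`,
#'   `n_steps`, `k`, `fullness`, covering the full genome-by-module grid.
#' @export
#' @examples
#' cat1 <- simulate_catalog(n_modules = 3, seed = 1)
#' g <- simulate_genome("G1", "Firmicutes", cat1, module_presence_prob = 1, seed = 2)
#' compute_fullness(g, cat1)
compute_fullness <- function(annotations, catalog) {
  assert_columns(annotations, c("genome_id", "phylum", "gene_id"), "annotations")
  validate_catalog(catalog)
  genomes <- dplyr::distinct(annotations, .data$genome_id, .data$phylum)
  if (anyDuplicated(genomes$genome_id)) {
    stop("a genome_id maps to more than one phylum", call. = FALSE)
  }
  mods <- catalog_modules(catalog)
  # a step is satisfied iff any of its alternative genes is annotated
  hits <- annotations |>
    dplyr::distinct(.data$genome_id, .data$gene_id) |>
    dplyr::inner_join(
      catalog[, c("module_id", "step_index", "gene_id")],
      by = "gene_id", relationship = "many-to-many"
    ) |>
    dplyr::distinct(.data$genome_id, .data$module_id, .data$step_index) |>
    dplyr::count(.data$genome_id, .data$module_id, name = "k")
  grid <- tidyr::expand_grid(
    genomes,
    mods[, c("module_id", "n_steps")]
  )
  out <- grid |>
    dplyr::left_join(hits, by = c("genome_id", "module_id")) |>
    dplyr::mutate(
      k = dplyr::coalesce(.data$k, 0L),
      fullness = .data$k / .data$n_steps
    )
  tibble::as_tibble(out)
}

#' Module-prevalence threshold count
#'
#' The minimum number of genomes a module must be observed in (fullness > 0)
#' to pass the prevalence filter: `floor(min_prevalence * n_genomes)`. For a
#' cohort of 11,842 genomes at 5% this is 592 genomes.
#'
#' @param n_genomes Cohort size.
#' @param min_prevalence Minimum prevalence as a proportion (default 0.05).
#' @return Integer threshold count.
#' @export
prevalence_threshold <- function(n_genomes, min_prevalence = 0.05) {
  assert_proportion(min_prevalence, "min_prevalence")
  as.integer(floor(min_prevalence * n_genomes))
}

#' Filter modules by prevalence across genomes
#'
#' Keeps only widespread modules: those present (fullness > 0) in at least
#' `floor(min_prevalence * n_genomes)` genomes. Rare modules carry too few
#' informative data points for stable per-module regression.
#'
#' @param fullness Long fullness tibble from [compute_fullness()] or
#'   [simulate_parametric_fullness()].
#' @param min_prevalence Minimum prevalence as a proportion (default 0.05).
#' @return The filtered fullness tibble, with attributes
#'   `prevalence_threshold` (the genome count used) and `modules_kept`. The
#'   operation is idempotent. If no module survives, an empty tibble is
#'   returned with a warning.
#' @export
filter_modules <- function(fullness, min_prevalence = 0.05) {
  assert_columns(fullness, c("genome_id", "module_id", "fullness"), "fullness")
  n_genomes <- dplyr::n_distinct(fullness$genome_id)
  thr <- prevalence_threshold(n_genomes, min_prevalence)
  kept <- fullness |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(n_present = sum(.data$fullness > 0), .groups = "drop") |>
    dplyr::filter(.data$n_present >= thr) |>
    dplyr::pull("module_id")
  if (length(kept) == 0) {
    warning("prevalence filter removed every module", call. = FALSE)
  }
  out <- dplyr::filter(fullness, .data$module_id %in% kept)
  attr(out, "prevalence_threshold") <- thr
  attr(out, "modules_kept") <- kept
  out
}
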