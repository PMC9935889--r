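#' Simulate a synthetic metabolic module catalog
#'
#' Builds a KEGG-like catalog of metabolic modules. A module is an ordered
#' series of enzymatic steps; each step is satisfiable by any one of a small
#' set of alternative gene identifiers (OR-semantics, as in KEGG orthologue
#' alternatives). Step counts are drawn as `1 + Poisson(step_lambda)`,
#' truncated at 40 steps, and each module carries one of `n_domains`
#' functional-domain labels assigned round-robin.
#'
#' Gene identifiers are unique to one (module, step): the synthetic catalog
#' does not share orthologues across modules. Within-step enzyme complexes
#' (AND-semantics) are not modelled.
#'
#' @param n_modules Number of modules to generate (>= 1).
#' @param step_lambda Poisson rate for the step-count distribution; the number
#'   of steps per module is `1 + rpois(step_lambda)` capped at 40.
#' @param n_domains Number of functional domains to use, up to the ten in
#'   [default_domains()].
#' @param alt_genes_per_step Number of alternative gene identifiers per step.
#' @param seed Integer seed; the catalog is a pure function of its arguments.
#'
#' @return A tibble of class `mag_catalog` with one row per alternative gene:
#'   columns `module_id`, `domain`, `step_index`, `gene_id`.
#' @seealso [catalog_modules()] for the per-module summary, [compute_fullness()]
#'   for distillation against genome annotations.
#' @export
#' @examples
#' cat6 <- simulate_catalog(n_modules = 6, seed = 1)
#' catalog_modules(cat6)
simulate_catalog <- function(n_modules, step_lambda = 6, n_domains = 10,
                             alt_genes_per_step = 2, seed = 1337) {
  if (!is.numeric(n_modules) || n_modules < 1) {
    stop("`n_modules` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(step_lambda) || step_lambda < 0) {
    stop("`step_lambda` must be a non-negative Poisson rate", call. = FALSE)
  }
  if (n_domains < 1 || n_domains > length(default_domains())) {
    stop("`n_domains` must be between 1 and ", length(default_domains()),
      call. = FALSE
    )
  }
  if (alt_genes_per_step < 1) {
    stop("`alt_genes_per_step` must be >= 1", call. = FALSE)
  }
  n_modules <- as.integer(n_modules)
  withr::with_seed(as.integer(seed), {
    n_steps <- pmin(1L + rpois(n_modules, step_lambda), 40L)
    modules <- tibble::tibble(
      module_id = sprintf("M%05d", seq_len(n_modules)),
      domain = rep_len(default_domains()[seq_len(n_domains)], n_modules),
      n_steps = n_steps
    )
    long <- tidyr::uncount(modules, weights = .data$n_steps, .id = "step_index")
    long <- tidyr::uncount(long, weights = alt_genes_per_step)
    long$gene_id <- sprintf("K%06d", seq_len(nrow(long)))
  })
  out <- tibble::as_tibble(long[, c("module_id", "domain", "step_index", "gene_id")])
  class(out) <- c("mag_catalog", class(out))
  out
}

#' Summarise a catalog to one row per module
#'
#' @param catalog A catalog tibble (`module_id`, `domain`, `step_index`,
#'   `gene_id`), e.g. from [simulate_catalog()] or [read_catalog()].
#' @return Tibble with columns `module_id`, `domain`, `n_steps`.
#' @export
catalog_modules <- function(catalog) {
  assert_columns(catalog, c("module_id", "domain", "step_index"), "catalog")
  catalog |>
    dplyr::group_by(.data$module_id, .data$domain) |>
    dplyr::summarise(n_steps = max(.data$step_index), .groups = "drop") |>
    dplyr::arrange(.data$module_id)
}

validate_catalog <- function(catalog) {
  assert_columns(
    catalog, c("module_id", "domain", "step_index", "gene_id"),
    "catalog"
  )
  bad <- catalog |>
    dplyr::group_by(.data$module_id) |>
    dplyr::summarise(
      gap = !setequal(unique(.data$step_index), seq_len(max(.data$step_index))),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$gap)
  if (nrow(bad) > 0) {
    stop(
      "catalog has modules with empty steps: ",
      paste(bad$module_id, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(catalog)
}
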