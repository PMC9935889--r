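#' Single-copy core gene identifiers
#'
#' The shared universe of single-copy core marker genes (SCCGs) used to
#' estimate genome completeness, emulating CheckM-style marker sets.
#'
#' @param n Number of marker genes (default 100).
#' @return Character vector of marker gene identifiers.
#' @export
sccg_ids <- function(n = 100) sprintf("SCG%04d", seq_len(n))

#' Simulate one complete genome as an annotation table
#'
#' Generates the gene content of a complete genome against a module catalog.
#' Each module is included with probability `module_presence_prob`; for an
#' included module, one gene (chosen among the step's alternatives) is added
#' per step. `n_sccg` single-copy marker genes are always added. All genes are
#' assigned to `n_contigs` contigs uniformly at random, the key assumption
#' that makes contig dropout remove a binomially-thinned fraction of genes.
#'
#' @param genome_id Genome identifier.
#' @param phylum Phylum label.
#' @param catalog Module catalog tibble (see [simulate_catalog()]).
#' @param module_presence_prob Probability that a module is encoded.
#' @param n_contigs Number of contigs (default 42, a typical lower bound for a
#'   well-assembled MAG).
#' @param n_sccg Number of single-copy marker genes.
#' @param seed Integer seed.
#'
#' @return Annotation tibble with columns `genome_id`, `phylum`, `contig_id`,
#'   `gene_id` (one row per gene copy), the same layout consumed by
#'   [compute_fullness()].
#' @export
simulate_genome <- function(genome_id, phylum, catalog,
                            module_presence_prob = 0.7,
                            n_contigs = 42, n_sccg = 100, seed = 1337) {
  if (n_contigs < 1) stop("`n_contigs` must be >= 1", call. = FALSE)
  if (n_sccg < 1) stop("`n_sccg` must be >= 1", call. = FALSE)
  assert_proportion(module_presence_prob, "module_presence_prob")
  withr::with_seed(as.integer(seed), {
    mods <- catalog_modules(catalog)
    keep <- mods$module_id[
      rbinom(nrow(mods), 1L, module_presence_prob) == 1L
    ]
    genes <- catalog |>
      dplyr::filter(.data$module_id %in% keep) |>
      dplyr::group_by(.data$module_id, .data$step_index) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup() |>
      dplyr::pull("gene_id")
    genes <- c(genes, sccg_ids(n_sccg))
    # uniform assignment, but every contig carries >= 1 gene when possible so
    # the realised contig count equals n_contigs (marginally still uniform)
    n_genes <- length(genes)
    idx <- if (n_genes >= n_contigs) {
      sample(c(
        sample.int(n_contigs),
        sample.int(n_contigs, n_genes - n_contigs, replace = TRUE)
      ))
    } else {
      sample.int(n_contigs, n_genes)
    }
    tibble::tibble(
      genome_id = genome_id,
      phylum = phylum,
      contig_id = sprintf("%s_c%04d", genome_id, idx),
      gene_id = genes
    )
  })
}

#' Simulate a cohort of complete genomes
#'
#' @param n_genomes Number of genomes.
#' @param catalog Module catalog tibble.
#' @param phyla Phylum labels to cycle through (default the four-phylum
#'   universe of [default_phyla()], giving an equal mix).
#' @param seed Integer seed; per-genome seeds are derived from it.
#' @inheritParams simulate_genome
#' @return Annotation tibble covering all genomes.
#' @export
simulate_genomes <- function(n_genomes, catalog, phyla = default_phyla(),
                             module_presence_prob = 0.7, n_contigs = 42,
                             n_sccg = 100, seed = 1337) {
  seeds <- derive_seeds(seed, n_genomes)
  purrr::map2(
    seq_len(n_genomes), seeds,
    function(i, s) {
      simulate_genome(
        genome_id = sprintf("G%05d", i),
        phylum = phyla[(i - 1L) %% length(phyla) + 1L],
        catalog = catalog,
        module_presence_prob = module_presence_prob,
        n_contigs = n_contigs, n_sccg = n_sccg, seed = s
      )
    }
  ) |>
    purrr::list_rbind()
}

#' Subsample contigs to simulate genome incompleteness
#'
#' Mechanistic incompleteness: for each genome, keeps
#' `max(1, round(retention * n_contigs))` contigs (round-half-up), chosen
#' uniformly without replacement, and drops all genes on removed contigs.
#' Mirrors the benchmark design in which complete genomes had contigs randomly
#' subsampled at 70, 80 and 90% retention.
#'
#' @param annotations Annotation tibble (`genome_id`, `phylum`, `contig_id`,
#'   `gene_id`), possibly covering several genomes.
#' @param retention Fraction of contigs to keep, in (0, 1].
#' @param seed Integer seed.
#' @return Annotation tibble restricted to the retained contigs. The gene set
#'   of the result is always a subset of the input's.
#' @export
subsample_contigs <- function(annotations, retention, seed = 1337) {
  assert_columns(annotations, c("genome_id", "contig_id", "gene_id"), "annotations")
  assert_proportion(retention, "retention", lo = 0, lo_open = TRUE)
  contigs <- annotations |>
    dplyr::distinct(.data$genome_id, .data$contig_id)
  genomes <- unique(contigs$genome_id)
  seeds <- derive_seeds(seed, length(genomes))
  kept <- purrr::map2(genomes, seeds, function(g, s) {
    ids <- contigs$contig_id[contigs$genome_id == g]
    n_keep <- max(1L, round_half_up(retention * length(ids)))
    withr::with_seed(s, sample(ids, n_keep))
  })
  keep_tbl <- tibble::tibble(
    genome_id = rep(genomes, lengths(kept)),
    contig_id = unlist(kept)
  )
  dplyr::semi_join(annotations, keep_tbl, by = c("genome_id", "contig_id"))
}

#' Estimate genome completeness from single-copy core genes
#'
#' CheckM-style completeness: the fraction of the marker-gene universe found
#' in each genome. Because the markers sit on ordinary contigs, the estimate
#' is itself noisy under contig dropout, emulating CheckM estimation error.
#'
#' @param annotations Annotation tibble.
#' @param sccg Character vector of marker gene identifiers (non-empty).
#' @return Tibble with columns `genome_id`, `est_completeness`.
#' @export
estimate_completeness <- function(annotations, sccg = sccg_ids()) {
  if (length(sccg) == 0) stop("`sccg` must be non-empty", call. = FALSE)
  assert_columns(annotations, c("genome_id", "gene_id"), "annotations")
  annotations |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      est_completeness = length(intersect(unique(.data$gene_id), sccg)) /
        length(sccg),
      .groups = "drop"
    )
}

#' Per-genome metadata from annotation tables
#'
#' Summarises annotations into the genome-level metadata used downstream:
#' contig and gene counts, true completeness (retained-gene fraction relative
#' to a parent annotation table, if supplied), SCCG-estimated completeness,
#' and contamination (fraction of duplicated marker genes, CheckM-style
#' redundancy).
#'
#' @param annotations Annotation tibble.
#' @param parent Optional annotation tibble of the complete parents (matched
#'   by `genome_id`); when given, `true_completeness` is the fraction of the
#'   parent's genes retained.
#' @param sccg Marker-gene universe for [estimate_completeness()].
#' @return Tibble with one row per genome: `genome_id`, `phylum`, `n_contigs`,
#'   `n_genes`, `true_completeness`, `est_completeness`, `contamination`.
#' @export
summarise_genomes <- function(annotations, parent = NULL, sccg = sccg_ids()) {
  assert_columns(
    annotations, c("genome_id", "phylum", "contig_id", "gene_id"),
    "annotations"
  )
  meta <- annotations |>
    dplyr::group_by(.data$genome_id, .data$phylum) |>
    dplyr::summarise(
      n_contigs = dplyr::n_distinct(.data$contig_id),
      n_genes = dplyr::n(),
      contamination = sum(duplicated(.data$gene_id[.data$gene_id %in% sccg])) /
        length(sccg),
      .groups = "drop"
    )
  est <- estimate_completeness(annotations, sccg)
  meta <- dplyr::left_join(meta, est, by = "genome_id")
  if (is.null(parent)) {
    meta$true_completeness <- 1
  } else {
    par_n <- parent |>
      dplyr::count(.data$genome_id, name = "parent_genes")
    meta <- dplyr::left_join(meta, par_n, by = "genome_id")
    meta$true_completeness <- meta$n_genes / meta$parent_genes
    meta$parent_genes <- NULL
  }
  meta[, c(
    "genome_id", "phylum", "n_contigs", "n_genes",
    "true_completeness", "est_completeness", "contamination"
  )]
}

#' Add duplicated marker genes to emulate contamination
#'
#' Adds `round(fraction * n_sccg)` duplicated single-copy marker genes on a
#' dedicated extra contig, so that [summarise_genomes()] reports a CheckM-style
#' redundancy of about `fraction`. Exists only to exercise the contamination
#' filter of [filter_cohort()].
#'
#' @param annotations Annotation tibble.
#' @param fraction Contamination fraction to inject (>= 0).
#' @param sccg Marker-gene universe.
#' @param seed Integer seed.
#' @return Annotation tibble with the duplicate rows appended.
#' @export
add_contamination <- function(annotations, fraction, sccg = sccg_ids(),
                              seed = 1337) {
  if (fraction < 0) stop("`fraction` must be >= 0", call. = FALSE)
  n_dup <- round_half_up(fraction * length(sccg))
  if (n_dup == 0) {
    return(annotations)
  }
  genomes <- dplyr::distinct(annotations, .data$genome_id, .data$phylum)
  seeds <- derive_seeds(seed, nrow(genomes))
  extra <- purrr::map2(seq_len(nrow(genomes)), seeds, function(i, s) {
    tibble::tibble(
      genome_id = genomes$genome_id[i],
      phylum = genomes$phylum[i],
      contig_id = paste0(genomes$genome_id[i], "_dup"),
      gene_id = withr::with_seed(s, sample(sccg, n_dup))
    )
  }) |>
    purrr::list_rbind()
  dplyr::bind_rows(annotations, extra)
}
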