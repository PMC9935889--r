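#' Read and write module catalogs
#'
#' Catalogs travel either as flat TSV (`module_id`, `domain`, `step_index`,
#' `gene_id`; one row per alternative gene) or as JSON (one object per module
#' with `module_id`, `domain` and `steps` as a list of gene-id lists). The
#' format is chosen by file extension (`.tsv` / `.json`).
#'
#' @param catalog Catalog tibble.
#' @param path File path ending in `.tsv` or `.json`.
#' @return `read_catalog()` returns the catalog tibble; `write_catalog()`
#'   returns `path` invisibly. Write-then-read is the identity.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  if (grepl("\\.json$", path)) {
    mods <- catalog |>
      dplyr::group_by(.data$module_id, .data$domain) |>
      dplyr::group_map(function(df, key) {
        list(
          module_id = key$module_id,
          domain = key$domain,
          steps = unname(lapply(
            split(df$gene_id, df$step_index), as.character
          ))
        )
      })
    jsonlite::write_json(mods, path, auto_unbox = TRUE)
  } else {
    readr::write_tsv(catalog[, c("module_id", "domain", "step_index", "gene_id")], path)
  }
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  if (grepl("\\.json$", path)) {
    mods <- jsonlite::read_json(path)
    out <- purrr::map(mods, function(m) {
      steps <- m$steps
      tibble::tibble(
        module_id = m$module_id,
        domain = m$domain,
        step_index = rep(seq_along(steps), lengths(steps)),
        gene_id = unlist(steps)
      )
    }) |>
      purrr::list_rbind()
  } else {
    out <- readr::read_tsv(
      path,
      col_types = readr::cols(
        module_id = "c", domain = "c", step_index = "i", gene_id = "c"
      )
    )
  }
  validate_catalog(out)
  out <- tibble::as_tibble(out)
  class(out) <- c("mag_catalog", class(out))
  out
}

#' Read and write genome annotation tables
#'
#' The DRAM-like annotation layout: TSV with columns `genome_id`, `phylum`,
#' `contig_id`, `gene_id`, one row per gene copy.
#'
#' @param annotations Annotation tibble.
#' @param path TSV file path.
#' @param allowed_phyla Phylum labels accepted on read; defaults to
#'   [default_phyla()]. Pass `NULL` to accept any label.
#' @return `read_annotations()` returns the annotation tibble;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  assert_columns(
    annotations, c("genome_id", "phylum", "contig_id", "gene_id"),
    "annotations"
  )
  readr::write_tsv(
    annotations[, c("genome_id", "phylum", "contig_id", "gene_id")], path
  )
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path, allowed_phyla = default_phyla()) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      genome_id = "c", phylum = "c", contig_id = "c", gene_id = "c"
    )
  )
  assert_columns(out, c("genome_id", "phylum", "contig_id", "gene_id"), path)
  if (!is.null(allowed_phyla)) {
    bad <- setdiff(unique(out$phylum), allowed_phyla)
    if (length(bad) > 0) {
      stop(sprintf(
        "%s: unknown phylum label(s) %s; allowed: %s",
        path, paste(bad, collapse = ", "),
        paste(allowed_phyla, collapse = ", ")
      ), call. = FALSE)
    }
  }
  tibble::as_tibble(out)
}

#' Read and write genome metadata
#'
#' Genome-level metadata TSV: `genome_id`, `phylum`, `completeness`,
#' `contamination` (plus any extra columns, preserved). Completeness and
#' contamination are stored internally as proportions in \[0, 1\]; files in
#' percent units (e.g. CheckM output) are converted with `percent = TRUE`.
#'
#' @param metadata Metadata tibble (proportions).
#' @param path TSV file path.
#' @param percent Logical; when TRUE the file is in percent (0-100) units.
#' @return `read_metadata()` returns the metadata tibble in proportion units;
#'   `write_metadata()` returns `path` invisibly.
#' @export
write_metadata <- function(metadata, path, percent = FALSE) {
  assert_columns(
    metadata, c("genome_id", "phylum", "completeness", "contamination"),
    "metadata"
  )
  out <- metadata
  if (percent) {
    out$completeness <- 100 * out$completeness
    out$contamination <- 100 * out$contamination
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path, percent = FALSE) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(
    out, c("genome_id", "phylum", "completeness", "contamination"), path
  )
  if (percent) {
    out$completeness <- out$completeness / 100
    out$contamination <- out$contamination / 100
  }
  if (any(out$completeness < 0 | out$completeness > 1) ||
    any(out$contamination < 0)) {
    stop(sprintf(
      "%s: completeness must lie in [0,1] and contamination be >= 0 after unit conversion",
      path
    ), call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Read and write fullness matrices
#'
#' A fullness matrix is stored as three TSVs sharing a path prefix:
#' `<prefix>_fullness.tsv` (genomes x modules fullness values in \[0, 1\]),
#' `<prefix>_counts.tsv` (satisfied-step counts) and `<prefix>_modules.tsv`
#' (`module_id`, `n_steps`). Write-then-read reproduces the long table.
#'
#' @param fullness Long fullness tibble (`genome_id`, `module_id`, `n_steps`,
#'   `k`, `fullness`).
#' @param prefix Path prefix for the three files.
#' @return `read_fullness()` returns the long fullness tibble;
#'   `write_fullness()` returns `prefix` invisibly.
#' @export
write_fullness <- function(fullness, prefix) {
  assert_columns(
    fullness, c("genome_id", "module_id", "n_steps", "k", "fullness"),
    "fullness"
  )
  spread <- function(value) {
    fullness |>
      dplyr::select("genome_id", "module_id", dplyr::all_of(value)) |>
      tidyr::pivot_wider(
        names_from = "module_id", values_from = dplyr::all_of(value)
      )
  }
  readr::write_tsv(spread("fullness"), paste0(prefix, "_fullness.tsv"))
  readr::write_tsv(spread("k"), paste0(prefix, "_counts.tsv"))
  readr::write_tsv(
    dplyr::distinct(fullness, .data$module_id, .data$n_steps),
    paste0(prefix, "_modules.tsv")
  )
  invisible(prefix)
}

#' @rdname write_fullness
#' @export
read_fullness <- function(prefix) {
  fpath <- paste0(prefix, "_fullness.tsv")
  vals <- readr::read_tsv(fpath, show_col_types = FALSE)
  counts <- readr::read_tsv(paste0(prefix, "_counts.tsv"), show_col_types = FALSE)
  mods <- readr::read_tsv(
    paste0(prefix, "_modules.tsv"),
    col_types = readr::cols(module_id = "c", n_steps = "i")
  )
  long_v <- tidyr::pivot_longer(
    vals, -"genome_id",
    names_to = "module_id", values_to = "fullness"
  )
  if (any(long_v$fullness < 0 | long_v$fullness > 1)) {
    bad <- long_v[long_v$fullness < 0 | long_v$fullness > 1, ][1, ]
    stop(sprintf(
      "%s: fullness out of [0,1] at genome %s, module %s (value %g)",
      fpath, bad$genome_id, bad$module_id, bad$fullness
    ), call. = FALSE)
  }
  long_k <- tidyr::pivot_longer(
    counts, -"genome_id",
    names_to = "module_id", values_to = "k"
  )
  out <- long_v |>
    dplyr::inner_join(long_k, by = c("genome_id", "module_id")) |>
    dplyr::inner_join(mods, by = "module_id") |>
    dplyr::mutate(k = as.integer(.data$k)) |>
    dplyr::select("genome_id", "module_id", "n_steps", "k", "fullness")
  if (any(abs(out$fullness - out$k / out$n_steps) > 1e-9)) {
    stop(sprintf("%s: fullness != k / n_steps", prefix), call. = FALSE)
  }
  out
}

#' Serialise fitted per-module models
#'
#' The trained fit bundle travels as JSON so profiles can be corrected
#' without refitting (e.g. models trained on a large reference cohort applied
#' to new incomplete genomes).
#'
#' @param fits `mag_glm_fits` tibble.
#' @param path JSON file path.
#' @return `read_glm_fits()` returns the `mag_glm_fits` tibble;
#'   `write_glm_fits()` returns `path` invisibly.
#' @export
write_glm_fits <- function(fits, path) {
  jsonlite::write_json(
    unclass(tibble::as_tibble(fits)), path,
    auto_unbox = FALSE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_glm_fits
#' @export
read_glm_fits <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(raw)
  assert_columns(
    out,
    c(
      "module_id", "phylum", "intercept", "intercept_se", "slope",
      "slope_se", "n_obs", "converged"
    ),
    path
  )
  class(out) <- c("mag_glm_fits", class(out))
  out
}

#' Filter a genome cohort on quality thresholds
#'
#' Drops genomes below the completeness floor (inclusive: a genome at exactly
#' the floor is kept) or at/above the contamination ceiling (strict: a genome
#' at exactly the ceiling is dropped). Optionally balances the cohort by
#' subsampling to at most `window_target` genomes per phylum within each 1%
#' completeness window (windows are half-open `[lower, upper)` in percent
#' units, with 100% folded into the top window).
#'
#' @param metadata Metadata tibble (`genome_id`, `phylum`, `completeness`,
#'   `contamination`, proportions).
#' @param completeness_min Completeness floor (default 0.70).
#' @param contamination_max Contamination ceiling (default 0.10).
#' @param window_target Optional per-(phylum, window) cap.
#' @param seed Seed for the balanced subsample.
#' @return Filtered metadata tibble. Warns when nothing survives.
#' @export
filter_cohort <- function(metadata, completeness_min = 0.70,
                          contamination_max = 0.10, window_target = NULL,
                          seed = 1337) {
  assert_columns(
    metadata, c("genome_id", "phylum", "completeness", "contamination"),
    "metadata"
  )
  out <- metadata |>
    dplyr::filter(
      .data$completeness >= completeness_min,
      .data$contamination < contamination_max
    )
  if (!is.null(window_target)) {
    withr::with_seed(as.integer(seed), {
      out <- out |>
        dplyr::mutate(
          window = pmin(floor(.data$completeness * 100), 99)
        ) |>
        dplyr::group_by(.data$phylum, .data$window) |>
        dplyr::slice_sample(n = window_target) |>
        dplyr::ungroup() |>
        dplyr::select(-"window")
    })
  }
  message(sprintf(
    "cohort filter: %d of %d genomes kept", nrow(out), nrow(metadata)
  ))
  if (nrow(out) == 0) warning("cohort filter removed every genome", call. = FALSE)
  out
}
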