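#' Contig-subsampling validation of the completeness correction
#'
#' End-to-end benchmark mirroring the mock-community experiment: each
#' complete genome has its contigs randomly subsampled `replicates` times at
#' each retention tier, the subsamples are distilled to module fullness,
#' their completeness is re-estimated from single-copy marker genes, their
#' profiles are corrected with the trained per-module models, and a joint
#' PCoA of complete, raw-subsampled and corrected profiles is computed
#' together with per-subsample distances to the parent complete genome.
#'
#' With the default design of 8 genomes, tiers 0.7/0.8/0.9 and 10 replicates,
#' the report covers 240 subsampled genomes.
#'
#' @param complete Annotation tibble of complete genomes (>= 2 genomes).
#' @param catalog Module catalog tibble.
#' @param fits `mag_glm_fits` trained on an independent reference cohort.
#' @param sccg Marker-gene universe for completeness estimation.
#' @param tiers Contig retention tiers (default `c(0.7, 0.8, 0.9)`).
#' @param replicates Subsampling replicates per genome and tier (default 10).
#' @param seed Master seed; the whole report is deterministic given it.
#' @param metric Distance metric for profiles and PCoA.
#' @param use_true_completeness Drive the correction with the true
#'   retained-gene fraction instead of the SCCG estimate (default FALSE,
#'   matching a CheckM-style workflow).
#'
#' @return Object of class `mag_validation`: list with
#'   `samples` (sample table: `sample_id`, `parent_id`, `type`, `tier`,
#'   `replicate`, `est_completeness`, `true_completeness`),
#'   `pcoa` (joint [run_pcoa()] result),
#'   `distances` (per subsample: `d_raw`, `d_cor`, `gain`, and the signed
#'   projection of the corrected offset onto the raw offset — negative values
#'   indicate overcorrection past the complete genome),
#'   `tier_summary` (mean distances by tier),
#'   `ellipses` (95% normal-approximation ellipse parameters per parent,
#'   tier and profile type on the first two axes), and `n_subsamples`.
#' @export
run_validation <- function(complete, catalog, fits, sccg = sccg_ids(),
                           tiers = c(0.7, 0.8, 0.9), replicates = 10,
                           seed = 1337, metric = c("euclidean", "bray"),
                           use_true_completeness = FALSE) {
  metric <- match.arg(metric)
  assert_proportion(tiers, "tiers", lo = 0, lo_open = TRUE)
  parents <- unique(complete$genome_id)
  if (length(parents) < 2) stop("need >= 2 complete genomes", call. = FALSE)
  fit_modules <- unique(fits$module_id)

  design <- tidyr::expand_grid(tier = tiers, replicate = seq_len(replicates))
  seeds <- derive_seeds(seed, nrow(design))

  pieces <- purrr::pmap(
    list(design$tier, design$replicate, seeds),
    function(tier, rep, s) {
      sub <- subsample_contigs(complete, retention = tier, seed = s)
      meta <- summarise_genomes(sub, parent = complete, sccg = sccg)
      tag <- sprintf("_t%02.0f_r%02d", 100 * tier, rep)
      sub$genome_id <- paste0(sub$genome_id, tag)
      meta$parent_id <- meta$genome_id
      meta$genome_id <- paste0(meta$genome_id, tag)
      meta$tier <- tier
      meta$replicate <- rep
      list(annotations = sub, meta = meta)
    }
  )
  sub_annot <- purrr::list_rbind(purrr::map(pieces, "annotations"))
  sub_meta <- purrr::list_rbind(purrr::map(pieces, "meta"))
  stopifnot(nrow(sub_meta) == length(parents) * length(tiers) * replicates)

  full_complete <- compute_fullness(complete, catalog) |>
    dplyr::filter(.data$module_id %in% fit_modules)
  full_sub <- compute_fullness(sub_annot, catalog) |>
    dplyr::filter(.data$module_id %in% fit_modules)

  driver <- if (use_true_completeness) "true_completeness" else "est_completeness"
  corr_in <- full_sub |>
    dplyr::inner_join(
      sub_meta[, c("genome_id", "parent_id", "tier", "replicate", driver)],
      by = "genome_id"
    ) |>
    dplyr::rename(completeness = dplyr::all_of(driver))
  corrected <- correct_profile(
    corr_in[, c(
      "genome_id", "phylum", "completeness", "module_id", "fullness"
    )],
    fits
  )

  # per-subsample distances to the parent complete profile
  profiles <- corrected |>
    dplyr::left_join(
      sub_meta[, c("genome_id", "parent_id", "tier", "replicate")],
      by = "genome_id"
    ) |>
    dplyr::left_join(
      full_complete |>
        dplyr::select(
          parent_id = "genome_id", "module_id",
          f_true = "fullness"
        ),
      by = c("parent_id", "module_id")
    )
  distances <- profiles |>
    dplyr::group_by(
      .data$genome_id, .data$parent_id, .data$tier, .data$replicate
    ) |>
    dplyr::summarise(
      d_raw = sqrt(sum((.data$f_obs - .data$f_true)^2)),
      d_cor = sqrt(sum((.data$f_cor - .data$f_true)^2)),
      projection = dplyr::if_else(
        .data$d_raw > 0,
        sum((.data$f_cor - .data$f_true) * (.data$f_obs - .data$f_true)) /
          .data$d_raw,
        0
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(gain = .data$d_raw - .data$d_cor)
  tier_summary <- distances |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(
      mean_d_raw = mean(.data$d_raw),
      mean_d_cor = mean(.data$d_cor),
      mean_gain = mean(.data$gain),
      .groups = "drop"
    )

  # joint ordination of complete, raw and corrected profiles
  joint <- dplyr::bind_rows(
    full_complete |>
      dplyr::transmute(
        sample_id = .data$genome_id, .data$module_id, value = .data$fullness
      ),
    corrected |>
      dplyr::transmute(
        sample_id = .data$genome_id, .data$module_id, value = .data$f_obs
      ),
    corrected |>
      dplyr::transmute(
        sample_id = paste0(.data$genome_id, "_cor"), .data$module_id,
        value = .data$f_cor
      )
  )
  pcoa <- run_pcoa(profile_distance(
    joint, metric = metric, value = "value", id = "sample_id"
  ))

  samples <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = parents, parent_id = parents, type = "complete",
      tier = 1, replicate = NA_integer_,
      est_completeness = 1, true_completeness = 1
    ),
    sub_meta |>
      dplyr::transmute(
        sample_id = .data$genome_id, .data$parent_id, type = "raw",
        .data$tier, .data$replicate,
        .data$est_completeness, .data$true_completeness
      ),
    sub_meta |>
      dplyr::transmute(
        sample_id = paste0(.data$genome_id, "_cor"), .data$parent_id,
        type = "corrected", .data$tier, .data$replicate,
        .data$est_completeness, .data$true_completeness
      )
  )

  scores <- pcoa$coordinates |>
    dplyr::inner_join(samples, by = "sample_id")
  ellipses <- scores |>
    dplyr::filter(.data$type %in% c("raw", "corrected")) |>
    dplyr::group_by(.data$parent_id, .data$tier, .data$type) |>
    dplyr::group_map(function(df, key) {
      dplyr::bind_cols(key, ellipse_params(df$axis1, df$axis2))
    }) |>
    purrr::list_rbind()

  out <- list(
    samples = samples,
    pcoa = pcoa,
    distances = distances,
    tier_summary = tier_summary,
    ellipses = ellipses,
    n_subsamples = nrow(sub_meta)
  )
  class(out) <- "mag_validation"
  out
}

# 95% normal-approximation ellipse of 2-D points (chi-squared, 2 df)
ellipse_params <- function(x, y, level = 0.95) {
  if (length(x) < 3) {
    return(tibble::tibble(
      center_x = mean(x), center_y = mean(y),
      semi_major = NA_real_, semi_minor = NA_real_, angle = NA_real_
    ))
  }
  S <- stats::cov(cbind(x, y))
  e <- eigen(S, symmetric = TRUE)
  r <- sqrt(pmax(e$values, 0) * stats::qchisq(level, df = 2))
  tibble::tibble(
    center_x = mean(x), center_y = mean(y),
    semi_major = r[1], semi_minor = r[2],
    angle = atan2(e$vectors[2, 1], e$vectors[1, 1])
  )
}

#' @method print mag_validation
#' @export
print.mag_validation <- function(x, ...) {
  cat(
    "Contig-subsampling validation:", x$n_subsamples, "subsamples of",
    dplyr::n_distinct(x$samples$parent_id), "genomes\n"
  )
  print(x$tier_summary)
  invisible(x)
}

#' @method tidy mag_validation
#' @export
tidy.mag_validation <- function(x, ...) {
  x$distances
}

#' @method glance mag_validation
#' @export
glance.mag_validation <- function(x, ...) {
  tibble::tibble(
    n_subsamples = x$n_subsamples,
    mean_gain = mean(x$distances$gain),
    prop_improved = mean(x$distances$gain > 0)
  )
}

#' Joint PCoA plot of complete, raw and corrected profiles
#'
#' First two principal coordinates with genomes as colours, profile type as
#' shape, and per-tier 95% normal ellipses over the subsampling replicates.
#'
#' @param object `mag_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mag_validation
#' @export
autoplot.mag_validation <- function(object, ...) {
  df <- object$pcoa$coordinates |>
    dplyr::inner_join(object$samples, by = "sample_id")
  pv <- object$pcoa$prop_variance
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$axis1, y = .data$axis2, colour = .data$parent_id)
  ) +
    ggplot2::stat_ellipse(
      data = dplyr::filter(df, .data$type != "complete"),
      ggplot2::aes(group = interaction(
        .data$parent_id, .data$tier, .data$type
      )),
      type = "norm", level = 0.95, linewidth = 0.3
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$type), size = 2) +
    ggplot2::scale_shape_manual(
      values = c(complete = 15, raw = 1, corrected = 17)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$type)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * pv[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * pv[2]),
      colour = "genome", shape = "profile"
    ) +
    ggplot2::theme_minimal()
}
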