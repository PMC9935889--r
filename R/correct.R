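#' Model-based correction of incomplete functional profiles
#'
#' Applies the trained per-module binomial models to correct the observed
#' module fullness of incomplete genomes. For each genome and module, two
#' predictions are made from the genome's phylum-specific model: fullness at
#' the genome's observed completeness, and fullness at 100% completeness.
#' Their difference is added to the observed fullness; corrected values above
#' 1 are rounded down to 1 and values below 0 up to 0 (the lower clamp can be
#' hit for negative-slope modules).
#'
#' Modules without a converged fit for the genome's phylum pass through
#' unchanged, flagged `skipped`, with a warning naming how many were skipped.
#' At completeness 1 the correction is the identity.
#'
#' @param fullness Long fullness tibble with columns `genome_id`, `phylum`,
#'   `completeness` (the estimated completeness driving the correction, in
#'   (0, 1\]), `module_id`, `fullness`.
#' @param fits `mag_glm_fits` tibble from [fit_module_glms()] (typically
#'   trained on an independent reference cohort, see [read_glm_fits()]).
#' @return Tibble `genome_id`, `phylum`, `completeness`, `module_id`,
#'   `f_obs`, `p_obs`, `p_100`, `delta`, `f_cor`, `clamped`, `skipped`.
#' @export
correct_profile <- function(fullness, fits) {
  assert_columns(
    fullness,
    c("genome_id", "phylum", "completeness", "module_id", "fullness"),
    "fullness"
  )
  assert_proportion(fullness$completeness, "completeness", lo_open = TRUE)
  assert_proportion(fullness$fullness, "fullness")
  usable <- fits |>
    dplyr::filter(.data$converged) |>
    dplyr::select("module_id", "phylum", "intercept", "slope")
  out <- fullness |>
    dplyr::rename(f_obs = "fullness") |>
    dplyr::left_join(usable, by = c("module_id", "phylum")) |>
    dplyr::mutate(
      skipped = is.na(.data$intercept),
      p_obs = plogis(.data$intercept + .data$slope * .data$completeness),
      p_100 = plogis(.data$intercept + .data$slope),
      delta = dplyr::if_else(.data$skipped, 0, .data$p_100 - .data$p_obs),
      raw_cor = .data$f_obs + .data$delta,
      f_cor = pmin(1, pmax(0, .data$raw_cor)),
      clamped = .data$raw_cor != .data$f_cor
    ) |>
    dplyr::select(
      "genome_id", "phylum", "completeness", "module_id",
      "f_obs", "p_obs", "p_100", "delta", "f_cor", "clamped", "skipped"
    )
  n_skip <- sum(out$skipped)
  if (n_skip > 0) {
    warning(sprintf(
      "%d genome-module pair(s) had no converged fit for their phylum; left uncorrected",
      n_skip
    ), call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Distance reduction achieved by the correction
#'
#' For each genome, compares the distance of the observed and the corrected
#' functional profile to the true (complete) profile. The gain is
#' `d(observed, true) - d(corrected, true)`; positive gain means the
#' correction moved the profile towards reality.
#'
#' @param profiles Tibble with columns `genome_id`, `module_id`, `f_obs`,
#'   `f_cor`, `f_true`, aligned on the same module set per genome.
#' @param metric `"euclidean"` (default) or `"bray"` (Bray-Curtis).
#' @return Tibble `genome_id`, `d_raw`, `d_cor`, `gain`.
#' @export
correction_gain <- function(profiles, metric = c("euclidean", "bray")) {
  metric <- match.arg(metric)
  assert_columns(
    profiles, c("genome_id", "module_id", "f_obs", "f_cor", "f_true"),
    "profiles"
  )
  pair_dist <- function(x, y) {
    if (metric == "euclidean") {
      sqrt(sum((x - y)^2))
    } else {
      s <- sum(x + y)
      if (s == 0) 0 else sum(abs(x - y)) / s
    }
  }
  profiles |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      d_raw = pair_dist(.data$f_obs, .data$f_true),
      d_cor = pair_dist(.data$f_cor, .data$f_true),
      gain = .data$d_raw - .data$d_cor,
      .groups = "drop"
    )
}
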