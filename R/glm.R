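#' Fit per-module weighted binomial GLMs of fullness on completeness
#'
#' For every module, fits a binomial generalised linear model with logit link
#' to the satisfied-step counts: the response is the proportion of steps
#' present, weighted by the module's total step count (equivalently, a
#' `cbind(k, S - k)` binomial response), and the linear predictor is
#' `completeness * phylum` (treatment coding), so that a phylum-specific
#' completeness slope is estimated for each module.
#'
#' Completeness enters as a proportion in \[0, 1\]. When the input carries
#' only fullness proportions, integer counts are recovered as
#' `k = round(fullness * n_steps)`; an error is raised if the product is not
#' within 1e-6 of an integer (incompatible step count).
#'
#' A fit is flagged `converged = FALSE` when the iteratively reweighted
#' least squares loop did not converge, the design is rank-deficient, or any
#' coefficient standard error is non-finite or exceeds 100 on the logit scale
#' (the signature of complete separation). Phyla with no observations for a
#' module are dropped from that module's design.
#'
#' @param fullness Long fullness tibble with columns `genome_id`, `phylum`,
#'   `completeness`, `module_id`, `n_steps`, and `k` and/or `fullness`.
#' @param reference_phylum Reference level for treatment coding; default the
#'   alphabetically first phylum. Derived per-phylum slopes are invariant to
#'   this choice.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Relative deviance-change convergence tolerance (default 1e-8).
#'
#' @return A tibble of class `mag_glm_fits`, one row per (module, phylum):
#'   `module_id`, `phylum`, `intercept`, `intercept_se`, `slope`, `slope_se`
#'   (the derived per-phylum intercept and completeness slope on the logit
#'   scale, with standard errors), `converged`, `n_obs`.
#' @export
fit_module_glms <- function(fullness, reference_phylum = NULL,
                            max_iter = 100, tol = 1e-8) {
  fullness <- normalise_counts(fullness)
  assert_columns(
    fullness,
    c("genome_id", "phylum", "completeness", "module_id", "n_steps", "k"),
    "fullness"
  )
  assert_proportion(fullness$completeness, "completeness")
  fits <- fullness |>
    dplyr::group_by(.data$module_id) |>
    dplyr::group_map(function(df, key) {
      fit <- fit_one_module(df, reference_phylum, max_iter, tol)
      fit$module_id <- key$module_id
      fit
    }) |>
    purrr::list_rbind() |>
    dplyr::relocate("module_id")
  class(fits) <- c("mag_glm_fits", class(fits))
  fits
}

normalise_counts <- function(fullness) {
  if (!"k" %in% names(fullness)) {
    assert_columns(fullness, c("fullness", "n_steps"), "fullness")
    k_real <- fullness$fullness * fullness$n_steps
    if (any(abs(k_real - round(k_real)) > 1e-6)) {
      stop(
        "fullness * n_steps is not an integer: incompatible step counts",
        call. = FALSE
      )
    }
    fullness$k <- as.integer(round(k_real))
  }
  fullness
}

fit_one_module <- function(df, reference_phylum, max_iter, tol) {
  phyla <- sort(unique(df$phylum))
  if (!is.null(reference_phylum)) {
    if (!reference_phylum %in% phyla) {
      stop("`reference_phylum` not present in data", call. = FALSE)
    }
    phyla <- c(reference_phylum, setdiff(phyla, reference_phylum))
  }
  df$phylum_f <- factor(df$phylum, levels = phyla)
  multi <- length(phyla) > 1
  form <- if (multi) {
    cbind(k, n_steps - k) ~ completeness * phylum_f
  } else {
    cbind(k, n_steps - k) ~ completeness
  }
  fit <- suppressWarnings(stats::glm(
    form,
    family = stats::binomial(), data = df,
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  full_rank <- fit$rank == length(beta) && !anyNA(beta)
  # per-phylum derived intercept/slope via contrast vectors
  rows <- purrr::map(phyla, function(p) {
    ci <- si <- setNames(numeric(length(beta)), names(beta))
    ci["(Intercept)"] <- 1
    si["completeness"] <- 1
    if (multi && p != phyla[1]) {
      ci[paste0("phylum_f", p)] <- 1
      si[paste0("completeness:phylum_f", p)] <- 1
    }
    if (!full_rank) {
      ci <- ci[!is.na(beta)]
      si <- si[!is.na(beta)]
    }
    b <- beta[!is.na(beta)]
    tibble::tibble(
      phylum = p,
      intercept = sum(ci * b),
      intercept_se = sqrt(drop(ci %*% V %*% ci)),
      slope = sum(si * b),
      slope_se = sqrt(drop(si %*% V %*% si)),
      n_obs = sum(df$phylum == p)
    )
  }) |>
    purrr::list_rbind()
  se_ok <- all(is.finite(c(rows$intercept_se, rows$slope_se))) &&
    max(c(rows$intercept_se, rows$slope_se)) < 100
  rows$converged <- fit$converged && full_rank && se_ok
  rows
}

#' Predict module fullness at a given completeness
#'
#' Inverse-logit prediction `plogis(intercept_p + slope_p * completeness)`
#' from fitted per-module models, for one phylum.
#'
#' @param fits `mag_glm_fits` tibble from [fit_module_glms()].
#' @param phylum Phylum to predict for; must be present in the fits (no
#'   cross-phylum extrapolation).
#' @param completeness Completeness as a proportion in \[0, 1\] (scalar).
#' @return Tibble `module_id`, `phylum`, `completeness`, `predicted`,
#'   `converged`.
#' @export
predict_fullness <- function(fits, phylum, completeness) {
  assert_proportion(completeness, "completeness")
  sub <- dplyr::filter(fits, .data$phylum == .env$phylum)
  if (nrow(sub) == 0) {
    stop(sprintf("phylum '%s' not present in fits", phylum), call. = FALSE)
  }
  tibble::tibble(
    module_id = sub$module_id,
    phylum = phylum,
    completeness = completeness,
    predicted = plogis(sub$intercept + sub$slope * completeness),
    converged = sub$converged
  )
}

#' Extract the slope table for meta-analysis
#'
#' Long table of per-(module, phylum) completeness slopes from the binomial
#' fits, annotated with the module's functional domain and step count.
#' Non-converged module fits are excluded (and counted in a message).
#'
#' @param fits `mag_glm_fits` tibble.
#' @param catalog Module catalog tibble (for `domain` and `n_steps`).
#' @return Tibble `module_id`, `phylum`, `slope`, `slope_se`, `domain`,
#'   `n_steps`.
#' @export
extract_slopes <- function(fits, catalog) {
  mods <- catalog_modules(catalog)
  bad <- unique(fits$module_id[!fits$converged])
  if (length(bad) > 0) {
    message(length(bad), " non-converged module fit(s) excluded")
  }
  fits |>
    dplyr::filter(.data$converged) |>
    dplyr::inner_join(mods, by = "module_id") |>
    dplyr::select(
      "module_id", "phylum", "slope", "slope_se", "domain", "n_steps"
    )
}

#' Predicted fullness change across a completeness span
#'
#' The model-implied change in module fullness, in percentage points, when
#' completeness rises from `c_lo` to `c_hi`:
#' `100 * (plogis(a + b * c_hi) - plogis(a + b * c_lo))` per
#' (module, phylum). Only converged fits are evaluated.
#'
#' @param fits `mag_glm_fits` tibble.
#' @param c_lo,c_hi Completeness bounds as proportions (defaults 0.70 and
#'   1.00, the conventional MAG quality window).
#' @return Tibble `module_id`, `phylum`, `change_pp`.
#' @export
fullness_change <- function(fits, c_lo = 0.70, c_hi = 1.00) {
  assert_proportion(c(c_lo, c_hi), "completeness bounds")
  fits |>
    dplyr::filter(.data$converged) |>
    dplyr::mutate(
      change_pp = 100 * (plogis(.data$intercept + .data$slope * c_hi) -
        plogis(.data$intercept + .data$slope * c_lo))
    ) |>
    dplyr::select("module_id", "phylum", "change_pp")
}

#' @method tidy mag_glm_fits
#' @export
tidy.mag_glm_fits <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance mag_glm_fits
#' @export
glance.mag_glm_fits <- function(x, ...) {
  tibble::tibble(
    n_modules = dplyr::n_distinct(x$module_id),
    n_phyla = dplyr::n_distinct(x$phylum),
    n_converged = dplyr::n_distinct(x$module_id[x$converged]),
    prop_positive_slope = mean(x$slope[x$converged] > 0)
  )
}

#' Histogram of fitted completeness slopes by phylum
#'
#' @param object `mag_glm_fits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mag_glm_fits
#' @export
autoplot.mag_glm_fits <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$converged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope, fill = .data$phylum)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$phylum)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "completeness slope (logit scale)", y = "modules",
      title = "Fullness-completeness slopes by phylum"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
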