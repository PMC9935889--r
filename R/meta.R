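#' Mixed-effects meta-analysis of fullness-completeness slopes
#'
#' Models the per-(module, phylum) completeness slopes from the binomial fits
#' as a function of phylum, functional domain and module step count, with a
#' module-level random intercept (four slopes per module share a module
#' effect): `slope ~ phylum + domain + n_steps + (1 | module_id)`, fitted by
#' REML. Slopes enter unweighted (their standard errors are ignored).
#'
#' Categorical terms with fewer than two levels in the data are dropped from
#' the fixed-effects formula. Reference levels are the alphabetically first
#' level unless overridden.
#'
#' @param slopes Slope table from [extract_slopes()]: columns `module_id`,
#'   `phylum`, `slope`, `domain`, `n_steps`.
#' @param reference_phylum,reference_domain Optional reference levels for the
#'   treatment coding.
#' @return An object of class `mag_meta_fit`: a list with elements `model`
#'   (the `lmerMod` fit), `data`, `singular` (TRUE when the module variance
#'   is estimated at zero), and `terms` (the categorical terms retained).
#' @export
fit_slope_lmm <- function(slopes, reference_phylum = NULL,
                          reference_domain = NULL) {
  assert_columns(
    slopes, c("module_id", "phylum", "slope", "domain", "n_steps"),
    "slopes"
  )
  if (dplyr::n_distinct(slopes$module_id) < 2) {
    stop("need at least 2 modules to fit the mixed model", call. = FALSE)
  }
  relevel_first <- function(x, ref) {
    lev <- sort(unique(x))
    if (!is.null(ref)) lev <- c(ref, setdiff(lev, ref))
    factor(x, levels = lev)
  }
  df <- slopes
  df$phylum <- relevel_first(df$phylum, reference_phylum)
  df$domain <- relevel_first(df$domain, reference_domain)
  terms <- c(
    if (nlevels(df$phylum) > 1) "phylum",
    if (nlevels(df$domain) > 1) "domain",
    "n_steps"
  )
  form <- stats::as.formula(paste(
    "slope ~", paste(terms, collapse = " + "), "+ (1 | module_id)"
  ))
  model <- suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE)
  )
  out <- list(
    model = model,
    data = df,
    terms = terms,
    # boundary fits: zero module variance or a degenerate zero-residual fit
    singular = lme4::isSingular(model, tol = 1e-6) ||
      stats::sigma(model) < 1e-8
  )
  class(out) <- "mag_meta_fit"
  out
}

#' @method print mag_meta_fit
#' @export
print.mag_meta_fit <- function(x, ...) {
  cat("Slope meta-analysis (linear mixed model, REML)\n")
  cat(
    "  ", nrow(x$data), "slopes,",
    dplyr::n_distinct(x$data$module_id), "modules\n"
  )
  vc <- as.data.frame(lme4::VarCorr(x$model))
  cat(sprintf(
    "  module variance %.4g, residual variance %.4g%s\n",
    vc$vcov[vc$grp == "module_id"], vc$vcov[vc$grp == "Residual"],
    if (x$singular) " (singular fit)" else ""
  ))
  invisible(x)
}

#' @method tidy mag_meta_fit
#' @export
tidy.mag_meta_fit <- function(x, ...) {
  fe <- lme4::fixef(x$model)
  se <- tryCatch(
    suppressWarnings(summary(x$model)$coefficients[, "Std. Error"]),
    # degenerate zero-variance fits have no usable vcov
    error = function(e) rep(NA_real_, length(fe))
  )
  tibble::tibble(
    term = names(fe),
    estimate = unname(fe),
    std_error = unname(se)
  )
}

#' @method glance mag_meta_fit
#' @export
glance.mag_meta_fit <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble::tibble(
    sigma2_module = vc$vcov[vc$grp == "module_id"],
    sigma2_residual = vc$vcov[vc$grp == "Residual"],
    reml_criterion = lme4::REMLcrit(x$model),
    singular = x$singular,
    n_obs = nrow(x$data)
  )
}

#' Marginal predicted slopes per level of a categorical predictor
#'
#' Population-level predictions for each level of the focal factor, holding
#' the non-focal categorical predictor at its reference level and the module
#' step count at its mean (random effects set to zero).
#'
#' @param fit `mag_meta_fit` object.
#' @param focal `"phylum"` or `"domain"`.
#' @return Tibble `level`, `predicted`, ordered by decreasing prediction.
#' @export
marginal_predictions <- function(fit, focal = c("phylum", "domain")) {
  focal <- match.arg(focal)
  if (!focal %in% fit$terms) {
    stop(sprintf("'%s' was not a term of the fitted model", focal),
      call. = FALSE
    )
  }
  newdata <- marginal_newdata(fit, focal)
  tibble::tibble(
    level = as.character(newdata[[focal]]),
    predicted = stats::predict(fit$model, newdata = newdata, re.form = NA)
  ) |>
    dplyr::arrange(dplyr::desc(.data$predicted))
}

marginal_newdata <- function(fit, focal) {
  lev <- levels(fit$data[[focal]])
  other <- setdiff(c("phylum", "domain"), focal)
  newdata <- data.frame(lev)
  names(newdata) <- focal
  newdata[[focal]] <- factor(lev, levels = levels(fit$data[[focal]]))
  newdata[[other]] <- factor(
    levels(fit$data[[other]])[1],
    levels = levels(fit$data[[other]])
  )
  newdata$n_steps <- mean(fit$data$n_steps)
  newdata
}

#' Parametric-bootstrap confidence intervals for the slope meta-model
#'
#' Simulates new responses from the fitted mixed model (new random intercepts
#' and residuals), refits, and collects the marginal predictions per level of
#' each categorical predictor plus the step-count coefficient; percentile
#' 2.5/97.5% bounds over `n_sim` simulations. One bootstrap mechanism serves
#' every reported quantity. Failed refits are dropped and counted; more than
#' 5% failures aborts with a diagnostic.
#'
#' @param fit `mag_meta_fit` object.
#' @param n_sim Number of parametric-bootstrap simulations (default 999).
#' @param seed Integer seed (bootstrap is reproducible given `seed`, `n_sim`).
#' @param level Confidence level (default 0.95).
#' @return Tibble `quantity` (`"phylum"`, `"domain"` or `"steps"`), `level_`
#'   (factor level, or `"n_steps"`), `estimate`, `lower`, `upper`, with
#'   attributes `n_sim` and `n_failed`.
#' @export
bootstrap_slope_cis <- function(fit, n_sim = 999, seed = 1337, level = 0.95) {
  stat_fun <- function(model) {
    shadow <- list(
      model = model, data = fit$data, terms = fit$terms,
      singular = FALSE
    )
    class(shadow) <- "mag_meta_fit"
    out <- numeric(0)
    for (foc in intersect(c("phylum", "domain"), fit$terms)) {
      nd <- marginal_newdata(shadow, foc)
      pr <- stats::predict(model, newdata = nd, re.form = NA)
      names(pr) <- paste0(foc, ":", as.character(nd[[foc]]))
      out <- c(out, pr)
    }
    c(out, `steps:n_steps` = unname(lme4::fixef(model)["n_steps"]))
  }
  boo <- suppressWarnings(lme4::bootMer(
    fit$model, stat_fun,
    nsim = n_sim, seed = as.integer(seed),
    type = "parametric", use.u = FALSE
  ))
  t_mat <- boo$t
  failed <- apply(t_mat, 1, function(r) any(!is.finite(r)))
  if (mean(failed) > 0.05) {
    stop(sprintf(
      "%d of %d bootstrap refits failed (> 5%%)", sum(failed), n_sim
    ), call. = FALSE)
  }
  t_ok <- t_mat[!failed, , drop = FALSE]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- t(apply(t_ok, 2, stats::quantile, probs = probs, names = FALSE))
  nm <- names(boo$t0)
  out <- tibble::tibble(
    quantity = sub(":.*$", "", nm),
    level_ = sub("^[^:]*:", "", nm),
    estimate = unname(boo$t0),
    lower = qs[, 1],
    upper = qs[, 2]
  )
  attr(out, "n_sim") <- n_sim
  attr(out, "n_failed") <- sum(failed)
  out
}

#' Confidence-interval overlap verdicts
#'
#' Turns a bootstrap CI table into findings: for each categorical quantity,
#' every pair of levels is compared and non-overlapping intervals are flagged
#' as evidence of a difference; for the step-count coefficient, an interval
#' not covering zero is flagged as evidence of an association (with its
#' sign).
#'
#' @param ci_table Output of [bootstrap_slope_cis()].
#' @return Tibble `quantity`, `level_a`, `level_b`, `lower_a`, `upper_a`,
#'   `lower_b`, `upper_b`, `overlap`, `verdict`. The steps row has `level_b`
#'   `"zero"` and compares the interval with 0.
#' @export
evaluate_hypotheses <- function(ci_table) {
  assert_columns(
    ci_table, c("quantity", "level_", "estimate", "lower", "upper"),
    "ci_table"
  )
  rows <- list()
  for (q in intersect(c("phylum", "domain"), unique(ci_table$quantity))) {
    sub <- dplyr::filter(ci_table, .data$quantity == q)
    if (nrow(sub) < 2) next
    pairs <- utils::combn(seq_len(nrow(sub)), 2)
    rows[[q]] <- purrr::map(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]
      b <- pairs[2, j]
      ov <- sub$lower[a] <= sub$upper[b] && sub$lower[b] <= sub$upper[a]
      tibble::tibble(
        quantity = q,
        level_a = sub$level_[a], level_b = sub$level_[b],
        lower_a = sub$lower[a], upper_a = sub$upper[a],
        lower_b = sub$lower[b], upper_b = sub$upper[b],
        overlap = ov,
        verdict = if (ov) "no evidence of difference" else "difference"
      )
    }) |>
      purrr::list_rbind()
  }
  steps <- dplyr::filter(ci_table, .data$quantity == "steps")
  if (nrow(steps) == 1) {
    excl <- steps$lower > 0 || steps$upper < 0
    rows[["steps"]] <- tibble::tibble(
      quantity = "steps",
      level_a = "n_steps", level_b = "zero",
      lower_a = steps$lower, upper_a = steps$upper,
      lower_b = 0, upper_b = 0,
      overlap = !excl,
      verdict = if (!excl) {
        "no evidence of association"
      } else if (steps$upper < 0) {
        "negative association"
      } else {
        "positive association"
      }
    )
  }
  purrr::list_rbind(rows)
}
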