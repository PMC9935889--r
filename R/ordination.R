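#' Pairwise distances between functional profiles
#'
#' Spreads a long fullness table to a genomes-by-modules matrix and computes
#' pairwise distances. Fullness vectors are bounded and dense, so Euclidean
#' distance is the default; Bray-Curtis is offered for compositional reading.
#'
#' @param fullness Long fullness tibble (`genome_id`, `module_id`, and a
#'   value column).
#' @param metric `"euclidean"` (default) or `"bray"`.
#' @param value Name of the value column (default `"fullness"`).
#' @param id Name of the sample identifier column (default `"genome_id"`).
#' @return A `stats::dist` object over genomes.
#' @export
profile_distance <- function(fullness, metric = c("euclidean", "bray"),
                             value = "fullness", id = "genome_id") {
  metric <- match.arg(metric)
  assert_columns(fullness, c(id, "module_id", value), "fullness")
  wide <- fullness |>
    dplyr::select(dplyr::all_of(c(id, "module_id", value))) |>
    tidyr::pivot_wider(
      names_from = "module_id", values_from = dplyr::all_of(value)
    )
  if (nrow(wide) < 2) stop("need at least 2 genomes", call. = FALSE)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide[[id]]
  if (anyNA(mat)) stop("profiles are not aligned on the same module set", call. = FALSE)
  if (metric == "euclidean") {
    stats::dist(mat)
  } else {
    vegan::vegdist(mat, method = "bray")
  }
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-D^2 / 2`,
#' eigendecomposition, and coordinates scaled by the square root of the
#' eigenvalues. Axes with non-positive eigenvalues are dropped; the absolute
#' mass of negative eigenvalues (which arise for non-Euclidean distances) is
#' reported.
#'
#' @param d A `stats::dist` object or symmetric distance matrix.
#' @return An object of class `mag_pcoa`: list with `coordinates` (tibble,
#'   `sample_id` + `axis1..axisK`), `eigenvalues` (descending, retained
#'   positive ones), `prop_variance`, and `negative_mass`.
#' @export
run_pcoa <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m))) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  n_axes <- min(sum(eig > tol), ncol(fit$points))
  eig_pos <- eig[seq_len(n_axes)]
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  coord_tbl <- tibble::tibble(sample_id = labels)
  if (n_axes > 0) {
    colnames(coords) <- paste0("axis", seq_len(n_axes))
    coord_tbl <- dplyr::bind_cols(coord_tbl, tibble::as_tibble(coords))
  }
  out <- list(
    coordinates = coord_tbl,
    eigenvalues = eig_pos,
    prop_variance = if (length(eig_pos) > 0) eig_pos / sum(eig_pos) else numeric(0),
    negative_mass = sum(abs(eig[eig < 0]))
  )
  class(out) <- "mag_pcoa"
  out
}

#' @method print mag_pcoa
#' @export
print.mag_pcoa <- function(x, ...) {
  cat(
    "PCoA:", nrow(x$coordinates), "samples,",
    length(x$eigenvalues), "retained axes\n"
  )
  if (length(x$prop_variance) >= 2) {
    cat(sprintf(
      "  axis1 %.1f%%, axis2 %.1f%% of retained variance\n",
      100 * x$prop_variance[1], 100 * x$prop_variance[2]
    ))
  }
  if (x$negative_mass > 0) {
    cat(sprintf("  negative eigenvalue mass discarded: %.4g\n", x$negative_mass))
  }
  invisible(x)
}

#' @method tidy mag_pcoa
#' @export
tidy.mag_pcoa <- function(x, ...) {
  x$coordinates
}

#' @method glance mag_pcoa
#' @export
glance.mag_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = length(x$eigenvalues),
    prop_axis1 = x$prop_variance[1],
    prop_axis2 = if (length(x$prop_variance) >= 2) x$prop_variance[2] else NA_real_,
    negative_mass = x$negative_mass
  )
}

#' Scatter plot of the first two principal coordinates
#'
#' @param object `mag_pcoa` object.
#' @param colour Optional vector (recycled over samples) mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mag_pcoa
#' @export
autoplot.mag_pcoa <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) stop("fewer than two PCoA axes available", call. = FALSE)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(
    df,
    if (is.null(colour)) {
      ggplot2::aes(x = .data$axis1, y = .data$axis2)
    } else {
      ggplot2::aes(x = .data$axis1, y = .data$axis2, colour = .data$colour)
    }
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_variance[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$prop_variance[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}
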