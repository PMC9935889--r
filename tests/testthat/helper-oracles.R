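# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the code paths they verify.

# brute-force fullness: explicit loops and set intersections
oracle_fullness <- function(annotations, catalog) {
  genomes <- unique(annotations[, c("genome_id", "phylum")])
  module_ids <- unique(catalog$module_id)
  rows <- list()
  for (i in seq_len(nrow(genomes))) {
    g <- genomes$genome_id[i]
    genes <- unique(annotations$gene_id[annotations$genome_id == g])
    for (m in module_ids) {
      sub <- catalog[catalog$module_id == m, ]
      steps <- sort(unique(sub$step_index))
      k <- 0L
      for (s in steps) {
        alts <- sub$gene_id[sub$step_index == s]
        if (length(intersect(alts, genes)) > 0) k <- k + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = g, phylum = genomes$phylum[i], module_id = m,
        n_steps = length(steps), k = k, fullness = k / length(steps)
      )
    }
  }
  do.call(rbind, rows)
}

# maximise the binomial log-likelihood directly with optim (BFGS + gradient),
# starting from zero; returns named coefficient vector on the design used by
# treatment coding with alphabetical reference
oracle_glm_coefs <- function(df) {
  df$phylum_f <- factor(df$phylum, levels = sort(unique(df$phylum)))
  X <- if (nlevels(df$phylum_f) > 1) {
    stats::model.matrix(~ completeness * phylum_f, df)
  } else {
    stats::model.matrix(~completeness, df)
  }
  k <- df$k
  S <- df$n_steps
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(k * eta - S * log1p(exp(eta)))
  }
  grad <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(t(X) %*% (k - S * p))
  }
  opt <- stats::optim(
    rep(0, ncol(X)), negll, grad,
    method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-15)
  )
  # Newton polish on the same hand-written likelihood (quadratic convergence)
  b <- opt$par
  for (it in 1:50) {
    p <- stats::plogis(drop(X %*% b))
    g <- drop(t(X) %*% (k - S * p))
    H <- t(X) %*% (X * (S * p * (1 - p)))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  stats::setNames(b, colnames(X))
}

# profiled REML criterion (up to an additive constant) for the one-random-
# intercept model y = X b + Z u + e, as a function of the variance ratio
# lambda = sigma2_u / sigma2_e
oracle_reml_criterion <- function(y, X, group, lambda) {
  Z <- stats::model.matrix(~ 0 + factor(group))
  n <- length(y)
  p <- qr(X)$rank
  V0 <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V0)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  q <- drop(t(r) %*% Vi %*% r)
  determinant(V0)$modulus + determinant(XtVX)$modulus + (n - p) * log(q)
}

# classical MDS by explicit Gower double-centering + eigendecomposition
oracle_pcoa_coords <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-9
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
}

# balanced one-way random-effects ANOVA variance components (REML-equivalent
# closed form for the balanced case)
oracle_anova_vc <- function(y, group) {
  k <- length(unique(group))
  n_i <- length(y) / k
  gm <- tapply(y, group, mean)
  msb <- n_i * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[as.character(group)])^2) / (length(y) - k)
  c(sigma2_between = max(0, (msb - msw) / n_i), sigma2_within = msw)
}

# small deterministic fixture: 2-module catalog with alternatives
tiny_catalog <- function() {
  tibble::tibble(
    module_id = c("MA", "MA", "MA", "MA", "MA", "MB", "MB"),
    domain = c(rep("Energy metabolism", 5), rep("Glycan metabolism", 2)),
    step_index = c(1L, 1L, 2L, 3L, 4L, 1L, 2L),
    gene_id = c("K1", "K2", "K3", "K4", "K5", "K6", "K7")
  )
}

tiny_annotations <- function(genes, genome_id = "G1", phylum = "Firmicutes") {
  tibble::tibble(
    genome_id = genome_id, phylum = phylum,
    contig_id = paste0(genome_id, "_c1"), gene_id = genes
  )
}
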