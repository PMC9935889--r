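#' Default bacterial phylum universe
#'
#' The four most genome-rich bacterial phyla used throughout the package as the
#' default phylum universe for simulation and modelling.
#'
#' @return Character vector of four phylum names, alphabetically ordered.
#' @export
default_phyla <- function() {
  c("Actinobacteriota", "Bacteroidota", "Firmicutes", "Proteobacteria")
}

#' Ten KEGG-style functional domains
#'
#' Default functional-domain labels attached to synthetic metabolic modules,
#' mirroring the top-level classes of KEGG metabolism modules.
#'
#' @return Character vector of ten domain names.
#' @export
default_domains <- function() {
  c(
    "Amino acid metabolism",
    "Biosynthesis of other secondary metabolites",
    "Biosynthesis of terpenoids and polyketides",
    "Carbohydrate metabolism",
    "Energy metabolism",
    "Glycan metabolism",
    "Lipid metabolism",
    "Metabolism of cofactors and vitamins",
    "Nucleotide metabolism",
    "Xenobiotics biodegradation"
  )
}

# round-half-up; base round() rounds half to even which would make the
# contig-retention rule depend on parity
round_half_up <- function(x) floor(x + 0.5)

# derive n child seeds (< 2^31) from one master seed, deterministically
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

assert_proportion <- function(x, name, lo = 0, hi = 1,
                              lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (lo_open) x > lo else x >= lo) &&
    all(if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf(
      "`%s` must lie in %s%g, %g%s, got: %s",
      name, if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      paste(utils::head(format(x), 3), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
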