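#' Simpson's equitability across samples
#'
#' For an entity's abundance vector across S samples, with proportions
#' `p_i = a_i / sum(a)`, Simpson's index is `D = sum(p_i^2)` and the
#' equitability is `ED = (1/D) / S`. ED is 1 when the entity is uniformly
#' shared across samples and 1/S when all mass sits in one sample. By
#' default S counts every sample, including those where the entity is absent
#' (zeros dilute evenness); set `samples = "present"` to count only
#' occupied samples.
#'
#' @param abundances Non-negative vector with at least one positive value.
#' @param entity Optional entity ID recorded in the result.
#' @param samples Either "all" (default) or "present".
#' @return Object of class `evenness_result`: entity, ed, s, d.
#' @export
simpson_equitability <- function(abundances, entity = NA_character_,
                                 samples = c("all", "present")) {
  samples <- match.arg(samples)
  if (any(abundances < 0)) stop("negative abundances are not allowed")
  if (all(abundances == 0)) stop("evenness undefined for an all-zero vector")
  p <- abundances / sum(abundances)
  d <- sum(p^2)
  s <- if (samples == "all") length(abundances) else sum(abundances > 0)
  structure(list(entity = entity, ed = (1 / d) / s, s = s, d = d),
            class = "evenness_result")
}

#' @export
print.evenness_result <- function(x, ...) {
  cat(sprintf("Simpson's equitability [%s]: ED = %.3f (D = %.3f, S = %d)\n",
              x$entity, x$ed, x$d, x$s))
  invisible(x)
}

#' Gene-versus-taxon evenness contrast
#'
#' Paired Simpson's equitability for a gene family (e.g. a set of
#' beta-glucuronidases) and its host taxon across the same samples, with
#' `delta = ed_gene - ed_taxon`. A positive delta means the gene is more
#' evenly shared across the cohort than the taxon carrying it.
#'
#' @param gene_abundances,taxon_abundances Abundance vectors over the same
#'   samples in the same order (names, if present, must match).
#' @param ... Passed to [simpson_equitability()].
#' @return List with `gene`, `taxon` (evenness results) and `delta`.
#' @export
evenness_contrast <- function(gene_abundances, taxon_abundances, ...) {
  if (length(gene_abundances) != length(taxon_abundances))
    stop("mismatched sample sets")
  if (!is.null(names(gene_abundances)) && !is.null(names(taxon_abundances)) &&
      !identical(names(gene_abundances), names(taxon_abundances)))
    stop("mismatched sample sets: names differ")
  g <- simpson_equitability(gene_abundances, entity = "gene", ...)
  t <- simpson_equitability(taxon_abundances, entity = "taxon", ...)
  list(gene = g, taxon = t, delta = g$ed - t$ed)
}

#' Mean relative abundance per taxon
#'
#' Per-sample relative abundances averaged across samples, in percent,
#' sorted descending.
#'
#' @param table Non-negative taxa x samples matrix.
#' @return Named numeric vector of mean relative abundances (percent,
#'   summing to 100).
#' @export
taxon_summary <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) == 0 || ncol(table) == 0) stop("empty table")
  rel <- to_relative(table)
  sort(100 * rowMeans(rel), decreasing = TRUE)
}
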