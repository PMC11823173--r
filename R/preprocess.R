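# Low-expression filters, probe collapsing, size-factor normalization and
# log transform. Each filter returns the filtered matrix plus a FilterReport
# enumerating removed genes, so no gene disappears silently.

filter_report <- function(rule, removed, kept) {
  structure(list(rule = rule, genes_removed = removed, genes_kept_count = kept),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport [%s]: removed %d, kept %d\n",
              x$rule, length(x$genes_removed), x$genes_kept_count))
  invisible(x)
}

apply_gene_filter <- function(X, remove, rule) {
  V <- expr_values(X)
  removed <- rownames(V)[remove]
  kept <- V[!remove, , drop = FALSE]
  out <- if (inherits(X, "ExpressionMatrix"))
    expression_matrix(kept, unit = X$unit, cohort_label = X$cohort_label) else kept
  list(matrix = out, report = filter_report(rule, removed, nrow(kept)))
}

#' Low-expression filter for normalized RNA-Seq (RSEM) matrices
#'
#' A gene is removed only when BOTH conditions hold: its value is below 1 in
#' at least half the samples AND its overall mean is below 50. The rule is
#' conjunctive; a high-mean gene stays even if mostly silent.
#'
#' @param X ExpressionMatrix with unit "rsem".
#' @return list(matrix, report).
#' @export
filter_low_expression_rsem <- function(X) {
  V <- expr_values(X)
  if (!nrow(V) || !ncol(V)) stop("empty expression matrix")
  u <- expr_unit(X)
  if (!is.na(u) && u != "rsem") stop("filter_low_expression_rsem expects unit 'rsem'")
  frac_low <- rowMeans(V < 1)
  remove <- frac_low >= 0.5 & rowMeans(V) < 50
  apply_gene_filter(X, remove, "rsem: <1 in >=50% of samples AND mean <50")
}

#' Low-expression filter for raw count matrices
#'
#' Removes genes with fewer than \code{min_count} counts in at least
#' \code{frac} of samples (inclusive boundary).
#'
#' @param X ExpressionMatrix with unit "counts".
#' @param min_count count threshold (default 5).
#' @param frac sample-fraction threshold (default 0.90).
#' @return list(matrix, report).
#' @export
filter_low_expression_counts <- function(X, min_count = 5, frac = 0.90) {
  V <- expr_values(X)
  if (!nrow(V) || !ncol(V)) stop("empty expression matrix")
  u <- expr_unit(X)
  if (!is.na(u) && u != "counts") stop("filter_low_expression_counts expects unit 'counts'")
  remove <- rowMeans(V < min_count) >= frac
  apply_gene_filter(X, remove,
                    sprintf("counts: <%g in >=%g%% of samples", min_count, 100 * frac))
}

#' Low-intensity filter for log-scale microarray matrices
#'
#' Removes genes whose intensity is below \code{threshold} in strictly more
#' than \code{frac} of samples. The threshold is dataset-specific and has no
#' default: it must be chosen by the analyst.
#'
#' @param X ExpressionMatrix with unit "log_intensity".
#' @param threshold intensity cutoff (required).
#' @param frac strict sample-fraction threshold (default 0.80).
#' @return list(matrix, report).
#' @export
filter_low_intensity <- function(X, threshold, frac = 0.80) {
  if (missing(threshold)) stop("`threshold` is required (dataset-specific, no default)")
  V <- expr_values(X)
  if (!nrow(V) || !ncol(V)) stop("empty expression matrix")
  remove <- rowMeans(V < threshold) > frac
  apply_gene_filter(X, remove,
                    sprintf("log_intensity: <%g in >%g%% of samples", threshold, 100 * frac))
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to no gene or to more than one gene are dropped. Among the
#' probes of one gene, the probe with the highest mean intensity represents
#' the gene (max-mean rule).
#'
#' @param P ExpressionMatrix or matrix with probe ids as rownames.
#' @param probe_to_gene data.frame with columns \code{probe}, \code{gene}
#'   (one row per mapping; a probe listed with two genes is multi-mapping).
#' @return list with \code{matrix} (gene-level), \code{dropped_unmapped},
#'   \code{dropped_multimapping}.
#' @export
collapse_probes <- function(P, probe_to_gene) {
  V <- expr_values(P)
  if (!nrow(probe_to_gene)) stop("empty probe-to-gene mapping")
  stopifnot(all(c("probe", "gene") %in% names(probe_to_gene)))
  map <- unique(probe_to_gene[, c("probe", "gene")])
  n_genes_per_probe <- table(map$probe)
  multi <- names(n_genes_per_probe)[n_genes_per_probe > 1]
  map <- map[!map$probe %in% multi, , drop = FALSE]
  probes <- rownames(V)
  unmapped <- setdiff(probes, probe_to_gene$probe)
  keep <- map[map$probe %in% probes, , drop = FALSE]
  if (!nrow(keep)) stop("no probe maps to a unique gene")
  means <- rowMeans(V)[keep$probe]
  ord <- order(keep$gene, -means)
  keep <- keep[ord, , drop = FALSE]
  best <- keep[!duplicated(keep$gene), , drop = FALSE]
  G <- V[best$probe, , drop = FALSE]
  rownames(G) <- best$gene
  out <- if (inherits(P, "ExpressionMatrix"))
    expression_matrix(G, unit = P$unit, cohort_label = P$cohort_label) else G
  list(matrix = out,
       dropped_unmapped = unmapped,
       dropped_multimapping = intersect(multi, probes))
}

#' Median-of-ratios size factors and normalization
#'
#' Computes per-sample size factors as the median, over reference genes
#' (genes with strictly positive counts in every sample), of the ratio of
#' the gene's count to its across-sample geometric mean; normalized counts
#' are raw counts divided by the sample's size factor.
#'
#' @param X ExpressionMatrix with unit "counts" (or a count matrix).
#' @return list with \code{matrix} (normalized, unit "rsem"-like continuous;
#'   stored as unit "log2"-free numeric under class ExpressionMatrix with
#'   unit "rsem") and \code{size_factors}.
#' @export
median_of_ratios_normalize <- function(X) {
  V <- expr_values(X)
  if (ncol(V) < 2) stop("need >= 2 samples")
  ref <- rowSums(V <= 0) == 0
  if (!any(ref))
    stop("no gene has all-positive counts; build a pseudo-reference (e.g. add a pseudocount) first")
  loggeo <- rowMeans(log(V[ref, , drop = FALSE]))
  ratios <- V[ref, , drop = FALSE] / exp(loggeo)
  sf <- apply(ratios, 2, stats::median)
  norm <- sweep(V, 2, sf, "/")
  out <- if (inherits(X, "ExpressionMatrix"))
    expression_matrix(norm, unit = "rsem", cohort_label = X$cohort_label) else norm
  list(matrix = out, size_factors = sf)
}

#' Log2 transform with pseudocount
#'
#' @param X ExpressionMatrix or matrix with non-negative values.
#' @param pseudocount added before the log (default 1).
#' @return ExpressionMatrix with unit "log2" (or matrix, matching input).
#' @export
log_transform <- function(X, pseudocount = 1) {
  V <- expr_values(X)
  if (any(V < 0)) stop("log_transform requires non-negative values")
  L <- log2(V + pseudocount)
  if (inherits(X, "ExpressionMatrix"))
    expression_matrix(L, unit = "log2", cohort_label = X$cohort_label) else L
}
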