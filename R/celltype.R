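# Cell-type marker derivation (four-fold rule), signature matrix
# construction, NNLS fraction imputation and fraction-score correlations.

#' Define cell-type-specific markers by the four-fold rule
#'
#' For every ordered type pair (t, t'), the log2 fold change is
#' \code{log2((mean_t + 1) / (mean_t' + 1))} on normalized counts, and the
#' p-value comes from a moderated t test (limma) on
#' \code{log2(normalized + 1)} replicate values: per-gene variances are
#' shrunk toward the common trend, which is essential for power at 2-3
#' replicates per type. P-values are BH-adjusted across all genes x type
#' pairs. A gene is a marker of type t iff its fold change is >= 2 on the
#' log2 scale (four-fold) AND the adjusted p-value is < 0.05 against EVERY
#' other type.
#'
#' @param norm_counts normalized count ExpressionMatrix or matrix.
#' @param labels cell-type label per column (>= 2 replicates per type).
#' @param log2fc_min log2 fold-change gate (default 2).
#' @param alpha adjusted-p gate (default 0.05).
#' @return a \code{MarkerTable}: list with \code{markers} (data.frame gene,
#'   cell_type, min_log2fc, max_p_adj, is_marker, markers only) and
#'   \code{contrasts} (long per-pair data.frame for all genes).
#' @export
define_celltype_markers <- function(norm_counts, labels, log2fc_min = 2, alpha = 0.05) {
  V <- expr_values(norm_counts)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(V))
  types <- unique(labels)
  if (length(types) < 2) stop("need >= 2 cell types")
  reps <- table(labels)
  if (any(reps < 2))
    stop("type(s) with < 2 replicates: ", paste(names(reps)[reps < 2], collapse = ", "))
  L <- log2(V + 1)
  type_means <- vapply(types, function(t) rowMeans(V[, labels == t, drop = FALSE]),
                       numeric(nrow(V)))
  f <- factor(labels, levels = types)
  design <- stats::model.matrix(~ 0 + f)
  colnames(design) <- types
  lfit <- limma::lmFit(L, design)
  pairs <- utils::combn(types, 2, simplify = FALSE)
  cm <- limma::makeContrasts(
    contrasts = vapply(pairs, function(p) paste0(p[1], " - ", p[2]), character(1)),
    levels = design)
  lfit2 <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  rows <- list()
  for (i in seq_along(pairs)) {
    t1 <- pairs[[i]][1]; t2 <- pairs[[i]][2]
    lfc <- log2((type_means[, t1] + 1) / (type_means[, t2] + 1))
    rows[[paste(t1, t2)]] <- data.frame(gene = rownames(V), type_a = t1, type_b = t2,
                                        log2fc = lfc, p = lfit2$p.value[, i],
                                        stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  contrasts$p_adj <- bh_adjust(contrasts$p)
  # marker summary: for gene g and type t, gather contrasts vs every other type
  marker_rows <- list()
  for (t in types) {
    others <- setdiff(types, t)
    # log2fc oriented as t vs other
    lfc_mat <- vapply(others, function(o) {
      sub <- contrasts[(contrasts$type_a == t & contrasts$type_b == o) |
                         (contrasts$type_a == o & contrasts$type_b == t), ]
      sgn <- ifelse(sub$type_a == t, 1, -1)
      stats::setNames(sgn * sub$log2fc, sub$gene)[rownames(V)]
    }, numeric(nrow(V)))
    padj_mat <- vapply(others, function(o) {
      sub <- contrasts[(contrasts$type_a == t & contrasts$type_b == o) |
                         (contrasts$type_a == o & contrasts$type_b == t), ]
      stats::setNames(sub$p_adj, sub$gene)[rownames(V)]
    }, numeric(nrow(V)))
    min_lfc <- apply(lfc_mat, 1, min)
    max_padj <- apply(padj_mat, 1, max)
    is_marker <- min_lfc >= log2fc_min & max_padj < alpha
    marker_rows[[t]] <- data.frame(gene = rownames(V), cell_type = t,
                                   min_log2fc = min_lfc, max_p_adj = max_padj,
                                   is_marker = is_marker, stringsAsFactors = FALSE)
  }
  summary_tab <- do.call(rbind, marker_rows)
  rownames(summary_tab) <- NULL
  structure(list(markers = summary_tab[summary_tab$is_marker, , drop = FALSE],
                 all_genes = summary_tab, contrasts = contrasts),
            class = "MarkerTable")
}

#' @export
print.MarkerTable <- function(x, ...) {
  tab <- table(x$markers$cell_type)
  cat("MarkerTable:", nrow(x$markers), "markers (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Build a cell-type signature matrix from markers
#'
#' Rows are marker genes (capped at \code{max_genes / k} per type, kept in
#' descending order of the marker's minimum pairwise log2 fold change);
#' values are mean normalized expression per type.
#'
#' @param norm_counts normalized count matrix used for the means.
#' @param labels cell-type label per column.
#' @param markers a \code{MarkerTable}.
#' @param max_genes total row cap across types (default Inf).
#' @return matrix, marker genes x cell types; attribute
#'   \code{marker_of} naming each row's type.
#' @export
build_signature_matrix <- function(norm_counts, labels, markers, max_genes = Inf) {
  V <- expr_values(norm_counts)
  labels <- as.character(labels)
  mk <- markers$markers
  types <- unique(labels)
  missing_types <- setdiff(types, unique(mk$cell_type))
  if (length(missing_types))
    stop("type(s) with zero markers: ", paste(missing_types, collapse = ", "))
  if (anyDuplicated(mk$gene))
    stop("a gene is claimed as marker of two types; marker rule violated")
  cap <- if (is.finite(max_genes)) max(1L, floor(max_genes / length(types))) else Inf
  sel <- do.call(rbind, lapply(types, function(t) {
    sub <- mk[mk$cell_type == t, , drop = FALSE]
    sub <- sub[order(-sub$min_log2fc), , drop = FALSE]
    utils::head(sub, cap)
  }))
  S <- vapply(types, function(t) rowMeans(V[sel$gene, labels == t, drop = FALSE]),
              numeric(nrow(sel)))
  rownames(S) <- sel$gene
  attr(S, "marker_of") <- stats::setNames(sel$cell_type, sel$gene)
  S
}

#' Impute cell-type fractions by non-negative least squares
#'
#' Projects each bulk sample's marker-gene vector onto the signature
#' columns by NNLS. Absolute scores are the coefficients; relative
#' fractions divide by the per-sample coefficient sum (NA when the sum
#' is 0).
#'
#' @param signature marker genes x cell types matrix.
#' @param X_bulk bulk ExpressionMatrix or matrix.
#' @return list with \code{absolute} and \code{relative} (samples x types).
#' @export
impute_fractions <- function(signature, X_bulk) {
  V <- expr_values(X_bulk)
  shared <- intersect(rownames(signature), rownames(V))
  if (!length(shared)) stop("no signature genes shared with the bulk matrix")
  if (length(shared) < ncol(signature))
    stop("fewer shared signature genes than cell types")
  S <- signature[shared, , drop = FALSE]
  B <- V[shared, , drop = FALSE]
  abs_mat <- t(apply(B, 2, function(y) pracma::lsqnonneg(S, y)$x))
  colnames(abs_mat) <- colnames(signature)
  rs <- rowSums(abs_mat)
  rel <- abs_mat / ifelse(rs > 0, rs, NA)
  list(absolute = abs_mat, relative = rel)
}

#' Correlate cell-type fractions with %G.A.M.E.
#'
#' Spearman correlation of each cell type's fraction against the per-sample
#' score, Bonferroni-corrected across cell types.
#'
#' @param fractions samples x types matrix (absolute or relative).
#' @param game_values named per-sample scores (matched by name when both
#'   are named, else by position).
#' @return data.frame: cell_type, rho, p, p_bonf.
#' @export
correlate_fractions_with_game <- function(fractions, game_values) {
  fractions <- as.matrix(fractions)
  if (!is.null(rownames(fractions)) && !is.null(names(game_values))) {
    shared <- intersect(rownames(fractions), names(game_values))
    fractions <- fractions[shared, , drop = FALSE]
    game_values <- game_values[shared]
  }
  if (nrow(fractions) < 3) stop("need >= 3 matched samples")
  k <- ncol(fractions)
  rows <- lapply(seq_len(k), function(j) {
    ok <- is.finite(fractions[, j]) & is.finite(game_values)
    ct <- suppressWarnings(stats::cor.test(fractions[ok, j], game_values[ok],
                                           method = "spearman", exact = FALSE))
    data.frame(cell_type = colnames(fractions)[j],
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_bonf <- pmin(1, k * tab$p)
  tab
}
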