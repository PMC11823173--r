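# Gene-set overlap enrichment (Fisher / BH with odds-ratio gate) and
# differential gene-set activity between sample strata with a variance
# inflation factor correcting for inter-gene correlation.

#' Fisher overlap test of a gene set with a module
#'
#' One-sided (enrichment) hypergeometric tail probability of the observed
#' overlap in the 2x2 in-set x in-module table over the universe. Odds
#' ratio is the sample odds ratio a*d / (b*c) (+Inf when b*c = 0 and the
#' overlap is non-empty).
#'
#' @param set_genes gene ids (intersected with the universe before testing).
#' @param module_genes module gene ids (must lie within the universe).
#' @param universe background gene ids (non-empty).
#' @return list with \code{odds_ratio}, \code{p}, \code{overlap} (count) and
#'   \code{overlap_genes}.
#' @export
fisher_overlap <- function(set_genes, module_genes, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  out_mod <- setdiff(module_genes, universe)
  if (length(out_mod))
    stop("module gene(s) outside universe: ", paste(utils::head(out_mod, 5), collapse = ", "))
  s <- intersect(unique(set_genes), universe)
  m <- unique(module_genes)
  ov <- intersect(s, m)
  a <- length(ov)
  b <- length(s) - a
  c_ <- length(m) - a
  d <- length(universe) - a - b - c_
  p <- stats::phyper(a - 1, length(s), length(universe) - length(s), length(m),
                     lower.tail = FALSE)
  or <- if (b * c_ == 0) {
    if (a > 0) Inf else 0
  } else a * d / (b * c_)
  list(odds_ratio = or, p = p, overlap = a, overlap_genes = sort(ov))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Overlap enrichment screen across a gene-set collection
#'
#' Fisher test per set, BH across the collection. A set is significant when
#' its adjusted p-value is below the mode's alpha (0.05 standard; 0.10 for
#' transcription-factor-target candidate discovery) AND its odds ratio
#' exceeds 1.
#'
#' @param collection a \code{GeneSetCollection}.
#' @param module_genes module gene ids.
#' @param universe background gene ids.
#' @param mode "standard" (alpha 0.05) or "tft_discovery" (alpha 0.10).
#' @return data.frame: set, overlap, overlap_genes, odds_ratio, p, p_adj,
#'   significant.
#' @export
enrichment_screen <- function(collection, module_genes, universe,
                              mode = c("standard", "tft_discovery")) {
  mode <- match.arg(mode)
  if (!length(collection$sets)) stop("empty gene-set collection")
  alpha <- if (mode == "standard") 0.05 else 0.10
  rows <- lapply(names(collection$sets), function(nm) {
    f <- fisher_overlap(collection$sets[[nm]], module_genes, universe)
    data.frame(set = nm, overlap = f$overlap,
               overlap_genes = paste(f$overlap_genes, collapse = ";"),
               odds_ratio = f$odds_ratio, p = f$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  tab$significant <- tab$p_adj < alpha & tab$odds_ratio > 1
  tab
}

welch_parts <- function(x_high, x_low) {
  nh <- length(x_high); nl <- length(x_low)
  vh <- stats::var(x_high) / nh
  vl <- stats::var(x_low) / nl
  v <- vh + vl
  df <- v^2 / (vh^2 / (nh - 1) + vl^2 / (nl - 1))
  list(d = mean(x_high) - mean(x_low), v = v, df = df)
}

#' Differential activity of one gene set between high and low strata
#'
#' Per-gene differences \code{d_g = mean_high - mean_low} on the log2 scale;
#' enrichment is the set's mean difference minus the background's mean
#' difference. The variance of the set mean is inflated by
#' \code{VIF = 1 + (m - 1) * rho_bar}, where \code{rho_bar} is the mean
#' pairwise correlation of the set genes across all samples (floored at 0),
#' to account for inter-gene correlation; a two-sided p-value comes from a
#' t statistic with Satterthwaite-combined Welch degrees of freedom. For a
#' singleton set the statistic reduces to the gene's Welch t (shifted by
#' the background offset) with VIF = 1.
#'
#' @param X_log2 log2-scale ExpressionMatrix or matrix.
#' @param groups character/factor per sample with values "high"/"low"
#'   (other values ignored); each group needs >= 3 samples.
#' @param set_genes gene ids of the set (must lie within the background).
#' @param background_genes background gene ids (all genes retained after
#'   preprocessing).
#' @return list: enrichment, vif, t, df, p, mean_set_diff, mean_bg_diff.
#' @export
set_activity <- function(X_log2, groups, set_genes, background_genes) {
  V <- expr_values(X_log2)
  groups <- as.character(groups)
  hi <- which(groups == "high"); lo <- which(groups == "low")
  if (length(hi) < 3 || length(lo) < 3)
    stop("each group needs >= 3 samples")
  background_genes <- intersect(unique(background_genes), rownames(V))
  set_genes <- unique(set_genes)
  if (!all(set_genes %in% background_genes))
    stop("set genes must be a subset of the background")
  m <- length(set_genes)
  B <- V[background_genes, c(hi, lo), drop = FALSE]
  n_h <- length(hi)
  d_all <- rowMeans(B[, seq_len(n_h), drop = FALSE]) -
    rowMeans(B[, -seq_len(n_h), drop = FALSE])
  mean_bg <- mean(d_all)
  parts <- lapply(set_genes, function(g)
    welch_parts(V[g, hi], V[g, lo]))
  d_set <- vapply(parts, `[[`, numeric(1), "d")
  v_set <- vapply(parts, `[[`, numeric(1), "v")
  df_set <- vapply(parts, `[[`, numeric(1), "df")
  enrichment <- mean(d_set) - mean_bg
  rho_bar <- if (m > 1) {
    C <- stats::cor(t(V[set_genes, , drop = FALSE]))
    max(0, mean(C[upper.tri(C)]))
  } else 0
  vif <- 1 + (m - 1) * rho_bar
  var_mean <- vif * sum(v_set) / m^2
  tstat <- enrichment / sqrt(var_mean)
  df <- sum(v_set)^2 / sum(v_set^2 / df_set)
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  list(enrichment = enrichment, vif = vif, t = tstat, df = df, p = p,
       mean_set_diff = mean(d_set), mean_bg_diff = mean_bg)
}

#' Activity screen across a collection with the relative-magnitude rule
#'
#' Computes the anchor module's own activity first (the reference), then
#' each collection set's activity; BH across the collection. A set is
#' significant when its adjusted p-value is below 0.05 AND the absolute
#' enrichment is at least 25 percent of the absolute reference activity.
#' When the reference activity is exactly 0 the magnitude gate degenerates
#' and only the p-value gate applies (with a warning). Positive enrichment
#' is reported as activation, negative as inhibition.
#'
#' @param collection a \code{GeneSetCollection}.
#' @param X log2-scale expression.
#' @param groups per-sample "high"/"low" labels.
#' @param anchor_module_genes the anchor module's genes (the reference set).
#' @param background background gene ids.
#' @param min_ratio magnitude gate as a fraction of the reference (0.25).
#' @return data.frame: set, enrichment, vif, p, p_adj, direction,
#'   significant; attribute \code{reference_activity}.
#' @export
activity_screen <- function(collection, X, groups, anchor_module_genes,
                            background, min_ratio = 0.25) {
  if (!length(collection$sets)) stop("empty gene-set collection")
  ref <- set_activity(X, groups, intersect(anchor_module_genes, background), background)
  rows <- lapply(names(collection$sets), function(nm) {
    a <- set_activity(X, groups, intersect(collection$sets[[nm]], background), background)
    data.frame(set = nm, enrichment = a$enrichment, vif = a$vif, p = a$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  tab$direction <- ifelse(tab$enrichment >= 0, "activation", "inhibition")
  if (ref$enrichment == 0) {
    warning("reference activity is 0; magnitude gate disabled, p_adj gate alone applies")
    tab$significant <- tab$p_adj < 0.05
  } else {
    tab$significant <- tab$p_adj < 0.05 &
      abs(tab$enrichment) >= min_ratio * abs(ref$enrichment)
  }
  attr(tab, "reference_activity") <- ref$enrichment
  tab
}
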