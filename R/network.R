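#' Network construction configuration
#'
#' @param candidate_powers soft-thresholding powers to scan.
#' @param fit_r2_target scale-free model fit R-squared target in (0,1).
#' @param min_module_size smallest cluster kept as a module (default 30).
#' @param deep_split_level integer 0-4 controlling cut depth; mapped to the
#'   \{0.7, 0.6, 0.5, 0.4, 0.3\} quantile of dendrogram merge heights
#'   (level 2 -> the median merge height). Higher levels cut deeper,
#'   yielding more, smaller clusters before size filtering and kME
#'   pruning.
#' @param correlation "pearson" (default) or "spearman".
#' @param max_genes guard against accidental transcriptome-scale single-block
#'   runs (default 20000).
#' @return a \code{NetworkConfig} list.
#' @export
network_config <- function(candidate_powers = 1:20, fit_r2_target = 0.85,
                           min_module_size = 30, deep_split_level = 2,
                           correlation = c("pearson", "spearman"),
                           max_genes = 20000) {
  correlation <- match.arg(correlation)
  if (any(candidate_powers <= 0)) stop("candidate powers must be positive")
  if (fit_r2_target <= 0 || fit_r2_target >= 1) stop("fit_r2_target must be in (0,1)")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (!deep_split_level %in% 0:4) stop("deep_split_level must be in 0..4")
  structure(list(candidate_powers = candidate_powers, fit_r2_target = fit_r2_target,
                 min_module_size = min_module_size, deep_split_level = deep_split_level,
                 correlation = correlation, max_genes = max_genes),
            class = "NetworkConfig")
}

gene_correlation <- function(X, method) {
  V <- expr_values(X)
  sds <- apply(V, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s): ", paste(utils::head(rownames(V)[sds == 0], 5), collapse = ", "))
  stats::cor(t(V), method = method)
}

#' Signed weighted adjacency
#'
#' \code{a_ij = ((1 + cor(x_i, x_j)) / 2)^beta}; diagonal 1. Anticorrelated
#' genes get near-zero adjacency (the "signed" convention), so modules
#' contain positively co-expressed genes only.
#'
#' @param X ExpressionMatrix or gene x sample matrix.
#' @param beta soft-thresholding power (> 0).
#' @param correlation "pearson" or "spearman".
#' @return symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @export
signed_adjacency <- function(X, beta, correlation = "pearson") {
  if (beta <= 0) stop("beta must be > 0")
  C <- gene_correlation(X, correlation)
  adjacency_from_cor(C, beta)
}

# drop clusters below min size, relabel survivors 1..K by descending size
# (ties broken by first appearance)
relabel_by_size <- function(raw, min_size) {
  sizes <- table(raw[raw > 0])
  keep <- names(sizes)[sizes >= min_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-as.integer(sizes[keep]), as.integer(keep))]
    for (i in seq_along(ord))
      labels[raw == as.integer(ord[i])] <- i
  }
  labels
}

adjacency_from_cor <- function(C, beta) {
  A <- ((1 + C) / 2)^beta
  diag(A) <- 1
  A
}

#' Scale-free topology fit for one adjacency
#'
#' Bins the connectivity distribution and regresses log10 frequency on
#' log10 mean connectivity; returns R-squared (signed negative when the
#' slope is positive, i.e. not scale-free) and mean connectivity.
#' @keywords internal
scale_free_fit <- function(A, n_breaks = 10) {
  k <- rowSums(A) - 1
  cut_k <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cut_k, mean)
  pk <- tapply(k, cut_k, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  dk <- dk[keep]; pk <- pk[keep]
  if (length(dk) < 3) return(list(r2 = NA_real_, slope = NA_real_, mean_k = mean(k)))
  fit <- stats::lm(log10(pk) ~ log10(dk))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = r2, slope = unname(slope), mean_k = mean(k))
}

#' Select the soft-thresholding power
#'
#' For each candidate power, builds the signed adjacency and measures the
#' scale-free topology model fit. Returns the smallest power whose fit
#' R-squared (with negative slope) reaches \code{fit_r2_target}; if none
#' does, falls back to the power maximizing R-squared and flags this in the
#' result.
#'
#' @param X ExpressionMatrix or gene x sample matrix (>= 20 genes).
#' @param config a [network_config()].
#' @return list with \code{beta}, \code{fit_table} (power, r_squared, slope,
#'   mean_k), \code{reached_target}.
#' @export
select_soft_power <- function(X, config = network_config()) {
  V <- expr_values(X)
  if (nrow(V) < 20) stop("need >= 20 genes for a scale-free fit")
  C <- gene_correlation(V, config$correlation)
  powers <- config$candidate_powers
  rows <- lapply(powers, function(b) {
    f <- scale_free_fit(adjacency_from_cor(C, b))
    data.frame(power = b, r_squared = f$r2, slope = f$slope, mean_k = f$mean_k)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$r_squared) & tab$r_squared >= config$fit_r2_target &
    !is.na(tab$slope) & tab$slope < 0
  if (any(ok)) {
    beta <- tab$power[which(ok)[1]]
    reached <- TRUE
  } else {
    beta <- tab$power[which.max(tab$r_squared)]
    reached <- FALSE
    message("no candidate power reached the scale-free R2 target ",
            config$fit_r2_target, "; using max-R2 power ", beta)
  }
  list(beta = beta, fit_table = tab, reached_target = reached)
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' where the sum excludes u = i, j and \code{k_i = sum_{u != i} a_iu};
#' diagonal 1. Dissimilarity for clustering is \code{1 - TOM}.
#'
#' @param A symmetric adjacency in [0, 1] with unit diagonal.
#' @return TOM matrix, same dimnames as \code{A}.
#' @export
topological_overlap <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  k <- rowSums(A) - 1
  num <- A %*% A - A        # (A^2)_ij - 2 a_ij + a_ij, using a_ii = 1
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Detect modules by clustering topological-overlap dissimilarity
#'
#' Average-linkage hierarchical clustering of \code{1 - TOM}, cut statically
#' at the merge-height quantile mapped from \code{deep_split_level}.
#' Clusters smaller than \code{min_module_size} are unassigned (label 0);
#' surviving clusters are relabeled 1..K in descending size. When an
#' expression matrix is supplied, cluster membership is refined by module
#' membership: genes whose correlation with their module's eigengene (kME)
#' falls below \code{min_kme} are unassigned, the clusters are re-checked
#' against \code{min_module_size}, and eigengenes are recomputed. This
#' pruning step keeps weakly co-expressed genes out of modules that a
#' coarse static cut would otherwise absorb.
#'
#' @param TOM topological overlap matrix.
#' @param config a [network_config()].
#' @param X optional ExpressionMatrix for eigengene computation and kME
#'   pruning.
#' @param anchor_gene optional anchor gene id to record the anchor module.
#' @param min_kme module-membership threshold for pruning (default 0.3;
#'   only used when \code{X} is supplied).
#' @return a \code{ModulePartition}: list with \code{labels} (named integer
#'   vector), \code{eigengenes} (samples x modules matrix or NULL),
#'   \code{explained_variance}, \code{anchor_module}, \code{cut_height}.
#' @export
detect_modules <- function(TOM, config = network_config(), X = NULL,
                           anchor_gene = NULL, min_kme = 0.3) {
  d <- stats::as.dist(1 - TOM)
  hc <- stats::hclust(d, method = "average")
  q <- c(0.7, 0.6, 0.5, 0.4, 0.3)[config$deep_split_level + 1]
  cut_h <- stats::quantile(hc$height, probs = q, names = FALSE)
  raw <- stats::cutree(hc, h = cut_h)
  labels <- relabel_by_size(raw, config$min_module_size)
  names(labels) <- rownames(TOM)
  if (!any(labels > 0))
    warning("no cluster reached min_module_size; all genes unassigned")
  if (!is.null(X) && any(labels > 0)) {
    V <- expr_values(X)
    for (pass in 1:2) {               # prune, re-check sizes, prune once more
      mods <- sort(unique(labels[labels > 0]))
      for (m in mods) {
        members <- names(labels)[labels == m]
        me <- module_eigengene(V, members)$me
        kme <- stats::cor(t(V[members, , drop = FALSE]), me)[, 1]
        labels[members[kme < min_kme]] <- 0L
      }
      labels <- relabel_by_size(labels, config$min_module_size)
      names(labels) <- rownames(TOM)
    }
  }
  part <- list(labels = labels, eigengenes = NULL, explained_variance = NULL,
               anchor_module = NULL, cut_height = cut_h)
  class(part) <- "ModulePartition"
  if (!is.null(X)) {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods)) {
      me_list <- lapply(mods, function(m)
        module_eigengene(X, names(labels)[labels == m]))
      part$eigengenes <- do.call(cbind, lapply(me_list, `[[`, "me"))
      colnames(part$eigengenes) <- paste0("ME", mods)
      part$explained_variance <- stats::setNames(
        vapply(me_list, `[[`, numeric(1), "explained_variance"), paste0("ME", mods))
    }
  }
  if (!is.null(anchor_gene)) {
    if (!anchor_gene %in% names(labels))
      stop("anchor gene '", anchor_gene, "' not in the network")
    part$anchor_module <- unname(labels[anchor_gene])
  }
  part
}

#' @export
print.ModulePartition <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("ModulePartition: %d genes, %d modules (label 0: %d unassigned)\n",
              length(x$labels), sum(names(tab) != "0"),
              if ("0" %in% names(tab)) tab[["0"]] else 0L))
  if (!is.null(x$anchor_module))
    cat("anchor module:", x$anchor_module, "\n")
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the row-standardized member submatrix,
#' scaled to unit variance and sign-oriented so it correlates positively
#' with the mean standardized member profile (falling back to the first
#' member when the mean profile is constant).
#'
#' @param X ExpressionMatrix or gene x sample matrix.
#' @param member_genes character vector of member gene ids (>= 2).
#' @return list with \code{me} (per-sample vector) and
#'   \code{explained_variance}.
#' @export
module_eigengene <- function(X, member_genes) {
  V <- expr_values(X)
  missing <- setdiff(member_genes, rownames(V))
  if (length(missing))
    stop("member gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (length(member_genes) < 2) stop("need >= 2 member genes")
  M <- V[member_genes, , drop = FALSE]
  Ms <- t(scale(t(M)))          # standardize each gene across samples
  if (any(!is.finite(Ms))) stop("constant member gene; cannot standardize")
  sv <- svd(Ms, nu = 0, nv = 1)
  me <- sv$v[, 1]
  ev <- sv$d[1]^2 / sum(sv$d^2)
  ref <- colMeans(Ms)
  orient <- if (stats::sd(ref) > 0) stats::cor(me, ref) else stats::cor(me, Ms[1, ])
  if (!is.na(orient) && orient < 0) me <- -me
  me <- as.numeric(scale(me))
  names(me) <- colnames(V)
  list(me = me, explained_variance = ev)
}

#' Extract the module containing the anchor gene
#'
#' @param partition a \code{ModulePartition}.
#' @param anchor_gene gene id; must be among the partition's genes.
#' @return list with \code{module_id} (integer, NA when unassigned),
#'   \code{genes} (full member list, anchor included; empty when
#'   unassigned) and \code{status} ("assigned"/"unassigned").
#' @export
extract_anchor_module <- function(partition, anchor_gene) {
  labels <- partition$labels
  if (!anchor_gene %in% names(labels))
    stop("anchor gene '", anchor_gene, "' not present in the partition")
  m <- unname(labels[anchor_gene])
  if (m == 0)
    return(list(module_id = NA_integer_, genes = character(0), status = "unassigned"))
  list(module_id = m, genes = names(labels)[labels == m], status = "assigned")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' used to compare recovered module labels with planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1] (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  s_tab <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_tab - expected) / (max_index - expected)
}
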