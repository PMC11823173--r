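# Module preservation between a reference and a test cohort: observed
# density and connectivity statistics, permutation null over random gene
# sets, per-statistic Z scores summarized as Z_summary.

#' Observed preservation statistics for one module
#'
#' Density statistics (computed on the test cohort): mean off-diagonal
#' intramodular correlation and mean off-diagonal signed adjacency.
#' Connectivity statistics (reference vs test): correlation of intramodular
#' connectivity vectors (\code{cor_kIM}) and correlation of the vectorized
#' intramodular correlation matrices (\code{cor_cor}).
#'
#' @param module_genes character vector; intersected with both cohorts'
#'   genes (>= 3 shared genes required).
#' @param X_ref,X_test reference / test cohorts.
#' @param beta soft power used for the signed adjacency.
#' @return named numeric vector: mean_intramodular_cor, mean_adjacency,
#'   cor_kIM, cor_cor; attribute \code{shared_fraction}.
#' @export
preservation_observed <- function(module_genes, X_ref, X_test, beta = 6) {
  Vr <- expr_values(X_ref); Vt <- expr_values(X_test)
  shared <- intersect(module_genes, intersect(rownames(Vr), rownames(Vt)))
  if (length(shared) < 3) stop("fewer than 3 module genes shared between cohorts")
  stats_vec <- preservation_stats_(Vr[shared, , drop = FALSE],
                                   Vt[shared, , drop = FALSE], beta)
  attr(stats_vec, "shared_fraction") <- length(shared) / length(module_genes)
  stats_vec
}

# core statistic computation on pre-subset matrices
preservation_stats_ <- function(Mr, Mt, beta) {
  if (any(apply(Mt, 1, stats::sd) == 0) || any(apply(Mr, 1, stats::sd) == 0))
    stop("constant gene inside module; correlations undefined")
  Cr <- stats::cor(t(Mr)); Ct <- stats::cor(t(Mt))
  Ar <- adjacency_from_cor(Cr, beta); At <- adjacency_from_cor(Ct, beta)
  off <- upper.tri(Ct)
  k_ref <- rowSums(Ar) - 1
  k_test <- rowSums(At) - 1
  c(mean_intramodular_cor = mean(Ct[off]),
    mean_adjacency = mean(At[off]),
    cor_kIM = stats::cor(k_ref, k_test),
    cor_cor = stats::cor(Cr[off], Ct[off]))
}

#' Permutation Z-summary preservation statistic
#'
#' Builds a null by drawing \code{n_perm} random gene sets of the module's
#' size from the genes shared by both cohorts (excluding the module itself),
#' recomputing all four statistics per draw. Each statistic's Z is
#' (observed - null mean) / null sd; Z_density is the median of the two
#' density Zs, Z_connectivity the median of the two connectivity Zs, and
#' Z_summary their mean. Values above 10 indicate strong preservation.
#'
#' @inheritParams preservation_observed
#' @param n_perm number of permutations (>= 50; default 200).
#' @param seed integer seed for the permutation draws.
#' @return a \code{PreservationResult} list: observed, z (per stat),
#'   z_density, z_connectivity, z_summary, n_permutations, seed.
#' @export
z_summary <- function(module_genes, X_ref, X_test, beta = 6, n_perm = 200, seed = 1L) {
  if (n_perm < 50) stop("n_perm must be >= 50")
  Vr <- expr_values(X_ref); Vt <- expr_values(X_test)
  obs <- preservation_observed(module_genes, X_ref, X_test, beta)
  shared_universe <- intersect(rownames(Vr), rownames(Vt))
  pool <- setdiff(shared_universe, module_genes)
  msize <- length(intersect(module_genes, shared_universe))
  if (length(pool) < msize)
    stop("gene universe too small for permutation draws")
  set.seed(as.integer(seed))
  null_mat <- matrix(NA_real_, n_perm, 4,
                     dimnames = list(NULL, names(obs)))
  for (p in seq_len(n_perm)) {
    g <- sample(pool, msize)
    null_mat[p, ] <- preservation_stats_(Vr[g, , drop = FALSE],
                                         Vt[g, , drop = FALSE], beta)
  }
  mu <- colMeans(null_mat)
  sdv <- apply(null_mat, 2, stats::sd)
  z <- (obs - mu) / sdv
  if (any(sdv == 0)) {
    warning("zero permutation sd for: ",
            paste(names(obs)[sdv == 0], collapse = ", "), "; Z set to +/-Inf")
    z[sdv == 0] <- sign(obs[sdv == 0] - mu[sdv == 0]) * Inf
  }
  z_density <- stats::median(z[c("mean_intramodular_cor", "mean_adjacency")])
  z_connectivity <- stats::median(z[c("cor_kIM", "cor_cor")])
  structure(list(observed = obs, z = z,
                 z_density = z_density, z_connectivity = z_connectivity,
                 z_summary = mean(c(z_density, z_connectivity)),
                 n_permutations = n_perm, seed = as.integer(seed)),
            class = "PreservationResult")
}

#' @export
print.PreservationResult <- function(x, ...) {
  cat(sprintf("PreservationResult: Z_summary = %.2f (density %.2f, connectivity %.2f; %d permutations)\n",
              x$z_summary, x$z_density, x$z_connectivity, x$n_permutations))
  invisible(x)
}
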