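# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately avoid the code paths they check.

# hypergeometric upper-tail p by direct enumeration with choose()
enumerate_hyper_p <- function(overlap, set_size, module_size, universe_size) {
  ks <- overlap:min(set_size, module_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, module_size - ks)) /
    choose(universe_size, module_size)
}

# exhaustive optimal contiguous k-partition of sorted values (total within-class SS)
exhaustive_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  wss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
  best <- Inf; best_classes <- NULL
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    tot <- 0
    classes <- integer(n)
    for (j in seq_len(k)) {
      idx <- (bounds[j] + 1):bounds[j + 1]
      tot <- tot + wss(x[idx])
      classes[idx] <- j
    }
    if (tot < best - 1e-12) { best <- tot; best_classes <- classes }
  }
  list(total_ss = best, classes_sorted = best_classes, x = x)
}

# TOM by direct per-entry summation of the formula
brute_force_tom <- function(A) {
  n <- nrow(A)
  TOM <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- setdiff(seq_len(n), c(i, j))
    num <- sum(A[i, u] * A[u, j]) + A[i, j]
    TOM[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

# BH step-up computed from the definition
hand_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# small expression fixture: named gene x sample matrix
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 2 else length(genes), byrow = TRUE)
  rownames(m) <- if (is.null(genes)) paste0("g", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  m
}

ari_oracle <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else adjusted_rand_index(a, b)
}
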