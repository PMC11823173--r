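# %G.A.M.E. sample scoring and Jenks natural-breaks stratification.

#' Percentage of module genes above median expression (%G.A.M.E.)
#'
#' For each sample, the fraction of module genes whose expression is
#' strictly above that gene's median across all samples. Ties at the median
#' do not count, so a constant gene contributes 0 to every sample. The
#' score is invariant to any strictly increasing per-gene transformation.
#'
#' @param X ExpressionMatrix or gene x sample matrix.
#' @param module_genes non-empty character vector of module gene ids.
#' @return named numeric vector of per-sample scores in [0, 1].
#' @export
game_score <- function(X, module_genes) {
  V <- expr_values(X)
  if (!length(module_genes)) stop("empty module")
  missing <- setdiff(module_genes, rownames(V))
  if (length(missing))
    stop("module gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  M <- V[module_genes, , drop = FALSE]
  med <- apply(M, 1, stats::median)
  colMeans(M > med)
}

#' Fisher-Jenks natural breaks
#'
#' Exact optimal 1-D classification: partitions the sorted values into
#' \code{k} contiguous classes minimizing the total within-class sum of
#' squared deviations from class means (dynamic programming, so provably
#' optimal, not a heuristic). Returns the maxima of the lower k-1 classes
#' as break values.
#'
#' @param values numeric vector with at least \code{k} distinct values.
#' @param k number of classes (default 3: low/medium/high).
#' @return numeric vector of k-1 breakpoints (upper boundaries of the lower
#'   classes), with attribute \code{classes} giving the optimal class of
#'   each input value.
#' @export
jenks_breaks <- function(values, k = 3) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) < k)
    stop("need at least k = ", k, " distinct values")
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # within-class SS for x[i..j]
  ss <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # dp[c, j]: minimal total SS splitting x[1..j] into c classes
  dp <- matrix(Inf, k, n)
  back <- matrix(NA_integer_, k, n)
  for (j in 1:n) dp[1, j] <- ss(1, j)
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:n) {
        best <- Inf; arg <- NA_integer_
        for (i in c:j) {               # class c is x[i..j]
          v <- dp[c - 1, i - 1] + ss(i, j)
          if (v < best - 1e-12) { best <- v; arg <- i }
        }
        dp[c, j] <- best
        back[c, j] <- arg
      }
    }
  }
  # recover class boundaries
  classes_sorted <- integer(n)
  j <- n
  for (c in k:1) {
    i <- if (c == 1) 1L else back[c, j]
    classes_sorted[i:j] <- c
    j <- i - 1L
  }
  breaks <- vapply(seq_len(k - 1), function(c) max(x[classes_sorted == c]), numeric(1))
  classes <- integer(n)
  classes[ord] <- classes_sorted
  structure(breaks, classes = classes, total_ss = dp[k, n])
}

#' Assign low/medium/high groups from Jenks breaks
#'
#' Values at or below the first break are "low"; above the first and at or
#' below the second are "medium"; above the second are "high" (class maxima
#' are the breaks, so boundary values fall in the lower class).
#'
#' @param game_values numeric scores.
#' @param breaks length-2 breakpoints from [jenks_breaks()] with k = 3.
#' @return factor with levels low/medium/high.
#' @export
assign_game_groups <- function(game_values, breaks) {
  if (length(breaks) != 2) stop("need 2 breakpoints for low/medium/high")
  g <- ifelse(game_values <= breaks[1], "low",
              ifelse(game_values <= breaks[2], "medium", "high"))
  factor(g, levels = c("low", "medium", "high"))
}

#' Binarize strata for Kaplan-Meier comparison
#'
#' "low" stays "low"; "medium" and "high" merge into "high" (low versus all
#' other samples).
#'
#' @param groups factor/character of low/medium/high labels.
#' @return factor with levels low/high.
#' @export
binarize_for_km <- function(groups) {
  g <- as.character(groups)
  factor(ifelse(g == "low", "low", "high"), levels = c("low", "high"))
}

#' Score and stratify samples in one call
#'
#' @param X ExpressionMatrix.
#' @param module_genes module member genes.
#' @return a \code{SampleStrata} list: game, breaks, group, km_label.
#' @export
stratify_samples <- function(X, module_genes) {
  game <- game_score(X, module_genes)
  br <- jenks_breaks(game, k = 3)
  grp <- assign_game_groups(game, br)
  km <- binarize_for_km(grp)
  names(grp) <- names(km) <- names(game)
  structure(list(game = game, breaks = as.numeric(br), group = grp,
                 km_label = km),
            class = "SampleStrata")
}

#' @export
print.SampleStrata <- function(x, ...) {
  cat(sprintf("SampleStrata: %d samples; breaks (%.3f, %.3f); %s\n",
              length(x$game), x$breaks[1], x$breaks[2],
              paste(names(table(x$group)), as.integer(table(x$group)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
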