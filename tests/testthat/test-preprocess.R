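test_that("RSEM low-expression rule is conjunctive with inclusive boundary", {
  m <- toy_matrix(c(0.5, 0.5, 2.0,
                    100, 100, 100,
                    0.5, 0.5, 200), genes = c("both", "high", "spiky"))
  X <- expression_matrix(m, unit = "rsem")
  res <- filter_low_expression_rsem(X)
  expect_identical(res$report$genes_removed, "both")       # mean 1, 2/3 below 1
  expect_true(all(c("high", "spiky") %in% rownames(res$matrix$values)))
  # fraction exactly 0.5 triggers removal when the mean is also low
  m2 <- toy_matrix(c(0.5, 0.5, 2, 2), genes = "half")
  res2 <- filter_low_expression_rsem(expression_matrix(m2, unit = "rsem"))
  expect_identical(res2$report$genes_removed, "half")
  expect_error(filter_low_expression_rsem(expression_matrix(m, unit = "rsem")$values[0, , drop = FALSE]),
               "empty")
})

test_that("count filter boundary is inclusive at 90 percent", {
  mk <- function(n_low) {
    v <- c(rep(0, n_low), rep(10, 10 - n_low))
    toy_matrix(v, genes = "g")
  }
  X <- expression_matrix(mk(10), unit = "counts")
  expect_identical(filter_low_expression_counts(X)$report$genes_removed, "g")
  X9 <- expression_matrix(mk(9), unit = "counts")   # exactly 90% below -> removed
  expect_identical(filter_low_expression_counts(X9)$report$genes_removed, "g")
  X8 <- expression_matrix(mk(8), unit = "counts")   # 80% below -> kept
  expect_length(filter_low_expression_counts(X8)$report$genes_removed, 0)
})

test_that("intensity filter boundary is strict at 80 percent and threshold is required", {
  mk <- function(n_low) toy_matrix(c(rep(0, n_low), rep(10, 100 - n_low)), genes = "g")
  X81 <- expression_matrix(mk(81), unit = "log_intensity")
  expect_identical(filter_low_intensity(X81, threshold = 5)$report$genes_removed, "g")
  X80 <- expression_matrix(mk(80), unit = "log_intensity")
  expect_length(filter_low_intensity(X80, threshold = 5)$report$genes_removed, 0)
  expect_length(filter_low_intensity(X81, threshold = -Inf)$report$genes_removed, 0)
  expect_error(filter_low_intensity(X81), "required")
})

test_that("filters are idempotent and partition the gene universe", {
  set.seed(1)
  m <- matrix(rexp(200, 1 / 20), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  X <- expression_matrix(m, unit = "rsem")
  once <- filter_low_expression_rsem(X)
  twice <- filter_low_expression_rsem(once$matrix)
  expect_identical(once$matrix$values, twice$matrix$values)
  expect_length(twice$report$genes_removed, 0)
  expect_setequal(c(once$report$genes_removed, rownames(once$matrix$values)),
                  rownames(m))
})

test_that("probe collapsing applies the max-mean rule and drops bad probes", {
  P <- toy_matrix(c(5, 5, 5,
                    10, 10, 10,
                    1, 2, 3,
                    7, 7, 7,
                    9, 9, 9), genes = paste0("p", 1:5), samples = paste0("s", 1:3))
  map <- data.frame(probe = c("p1", "p2", "p3", "p4", "p4"),
                    gene = c("GA", "GA", "GB", "GC", "GD"))
  res <- collapse_probes(P, map)
  expect_equal(unname(res$matrix["GA", ]), unname(P["p2", ]))  # max-mean probe wins
  expect_equal(unname(res$matrix["GB", ]), unname(P["p3", ]))  # single probe passthrough
  expect_identical(res$dropped_multimapping, "p4")
  expect_identical(res$dropped_unmapped, "p5")
  expect_error(collapse_probes(P, map[0, ]), "empty")
})

test_that("median-of-ratios size factors match the hand-derived example", {
  m <- toy_matrix(c(10, 20, 30, 60, 100, 200), genes = paste0("g", 1:3),
                  samples = c("a", "b"))
  X <- expression_matrix(m, unit = "counts")
  res <- median_of_ratios_normalize(X)
  # sample b = 2 * sample a elementwise -> factors (1/sqrt(2), sqrt(2))
  expect_equal(unname(res$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> unit factors
  m2 <- toy_matrix(c(10, 10, 30, 30), genes = c("g1", "g2"))
  expect_equal(unname(median_of_ratios_normalize(expression_matrix(m2, unit = "counts"))$size_factors),
               c(1, 1))
  # zero-count gene excluded from the reference set
  m3 <- toy_matrix(c(10, 20, 0, 50, 30, 60), genes = paste0("g", 1:3))
  r3 <- median_of_ratios_normalize(m3)
  expect_equal(unname(r3$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # no zero-free gene -> actionable error
  m4 <- toy_matrix(c(0, 5, 5, 0), genes = c("g1", "g2"))
  expect_error(median_of_ratios_normalize(m4), "pseudo-reference")
})

test_that("rescaling one sample rescales only its size factor (up to shared geomean)", {
  set.seed(3)
  m <- matrix(rpois(60, 50) + 1, nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  base <- median_of_ratios_normalize(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  scaled <- median_of_ratios_normalize(m2)
  # geometric means shift by 5^(1/6); correct for the shared rescaling
  shift <- 5^(1 / 6)
  expect_equal(unname(scaled$size_factors[3]), unname(base$size_factors[3]) * 5 / shift,
               tolerance = 1e-9)
  expect_equal(unname(scaled$size_factors[-3] * shift), unname(base$size_factors[-3]),
               tolerance = 1e-9)
  expect_equal(scaled$matrix[, -3], base$matrix[, -3] * shift, tolerance = 1e-9)
})

test_that("log transform is exact on anchors and rejects negatives", {
  m <- toy_matrix(c(0, 1, 3, 7), genes = "g", samples = paste0("s", 1:4))
  L <- log_transform(m)
  expect_equal(unname(L["g", ]), c(0, 1, 2, 3))
  expect_error(log_transform(toy_matrix(c(-1, 1), genes = "g")), "non-negative")
  X <- expression_matrix(toy_matrix(c(0, 1, 3, 7), genes = "g"), unit = "counts")
  expect_identical(log_transform(X)$unit, "log2")
})
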