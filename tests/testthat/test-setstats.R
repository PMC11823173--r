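test_that("Fisher overlap p equals hypergeometric enumeration", {
  universe <- paste0("u", 1:20)
  mod <- universe[1:4]
  set_genes <- c(universe[c(1, 2, 3, 10, 11)])
  res <- fisher_overlap(set_genes, mod, universe)
  expect_identical(res$overlap, 3L)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p, enumerate_hyper_p(3, 5, 4, 20), tolerance = 1e-12)

  # oracle equivalence over random tables with universe <= 60
  set.seed(31)
  for (trial in 1:25) {
    N <- sample(10:60, 1)
    uni <- paste0("g", seq_len(N))
    s <- sample(uni, sample(2:(N - 2), 1))
    m <- sample(uni, sample(2:(N - 2), 1))
    r <- fisher_overlap(s, m, uni)
    expect_equal(r$p, enumerate_hyper_p(r$overlap, length(s), length(m), N),
                 tolerance = 1e-10)
  }
})

test_that("Fisher overlap handles degenerate tables", {
  universe <- paste0("u", 1:10)
  r0 <- fisher_overlap(c("x", "y"), universe[1:3], universe)
  expect_identical(r0$overlap, 0L)
  expect_equal(r0$p, 1)
  rall <- fisher_overlap(universe[1:4], universe, universe)
  expect_identical(rall$overlap, 4L)
  expect_equal(rall$p, 1)
  # b*c = 0 with positive overlap -> infinite odds ratio
  rinf <- fisher_overlap(universe[1:3], universe[1:3], universe)
  expect_identical(rinf$odds_ratio, Inf)
  expect_error(fisher_overlap("a", "b", character(0)), "empty universe")
  expect_error(fisher_overlap("a", "not_in_universe", universe), "outside universe")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(14)
  p <- runif(25)
  expect_equal(bh_adjust(p), hand_bh(p), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment screen applies the dual p_adj / odds-ratio gate by mode", {
  universe <- paste0("g", 1:200)
  mod <- universe[1:20]
  coll <- gene_set_collection(list(
    hit = universe[1:15],                 # strongly overlapping
    anti = universe[181:200],             # disjoint from the module
    flat = universe[sample.int(200, 40)]  # arbitrary
  ))
  res <- enrichment_screen(coll, mod, universe)
  expect_true(res$significant[res$set == "hit"])
  expect_false(res$significant[res$set == "anti"])
  expect_true(all(res$p_adj >= res$p - 1e-12))
  # OR gate blocks depletion even at small p
  expect_false(any(res$significant & res$odds_ratio <= 1))
  # discovery mode relaxes alpha only
  res2 <- enrichment_screen(coll, mod, universe, mode = "tft_discovery")
  expect_true(all(res$significant <= res2$significant[match(res$set, res2$set)]))
  expect_error(enrichment_screen(gene_set_collection(list()), mod, universe), "empty")
})

test_that("set activity is exact in forced cases and antisymmetric", {
  set.seed(40)
  n <- 20
  m <- matrix(rnorm(30 * 2 * n), 30, 2 * n,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:(2 * n))))
  groups <- rep(c("high", "low"), each = n)
  # set == background -> enrichment exactly 0
  r <- set_activity(m, groups, rownames(m), rownames(m))
  expect_equal(r$enrichment, 0)
  # antisymmetry under label swap
  sub <- paste0("g", 1:5)
  r1 <- set_activity(m, groups, sub, rownames(m))
  r2 <- set_activity(m, rev(groups), sub, rownames(m))
  expect_equal(r1$enrichment, -r2$enrichment, tolerance = 1e-12)
  # singleton reduces to the gene's Welch test when the background shift is zero
  g <- "g3"
  m0 <- m
  m0[setdiff(rownames(m0), g), ] <- 0      # background offset exactly 0
  rs <- set_activity(m0, groups, g, rownames(m0))
  expect_equal(rs$vif, 1)
  wt <- t.test(m0[g, groups == "high"], m0[g, groups == "low"])
  shift <- mean(m0[g, groups == "high"]) - mean(m0[g, groups == "low"])
  expect_equal(rs$p,
               unname(2 * pt(abs((shift - rs$mean_bg_diff) / (shift / wt$statistic)),
                             df = wt$parameter, lower.tail = FALSE)),
               tolerance = 1e-9)
  expect_error(set_activity(m, rep(c("high", "low"), c(2, 38)), sub, rownames(m)),
               ">= 3 samples")
  expect_error(set_activity(m, groups, "absent", rownames(m)), "subset")
})

test_that("planted shifts are estimated accurately", {
  set.seed(41)
  n <- 100
  m <- matrix(rnorm(60 * 2 * n), 60, 2 * n,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:(2 * n))))
  groups <- rep(c("high", "low"), each = n)
  sub <- paste0("g", 1:10)
  m[sub, groups == "high"] <- m[sub, groups == "high"] + 1
  r <- set_activity(m, groups, sub, rownames(m))
  # background includes the shifted set: expected enrichment 1 - 10/60
  expect_equal(r$enrichment, 1 - length(sub) / 60, tolerance = 0.1)
  expect_lt(r$p, 0.01)
})

test_that("VIF correction calibrates type-I error under correlated nulls", {
  set.seed(42)
  n_iter <- 400
  m_set <- 10; n <- 40
  rejections <- matrix(NA, n_iter, 2, dimnames = list(NULL, c("vif", "naive")))
  for (i in seq_len(n_iter)) {
    # equicorrelated set genes (rho 0.3) + independent background, no group effect
    z <- rnorm(2 * n)
    S <- sqrt(0.3) * matrix(z, m_set, 2 * n, byrow = TRUE) +
      sqrt(0.7) * matrix(rnorm(m_set * 2 * n), m_set, 2 * n)
    B <- matrix(rnorm(200 * 2 * n), 200, 2 * n)
    X <- rbind(S, B)
    rownames(X) <- paste0("g", seq_len(nrow(X)))
    colnames(X) <- paste0("s", seq_len(2 * n))
    groups <- rep(c("high", "low"), each = n)
    r <- set_activity(X, groups, paste0("g", 1:m_set), rownames(X))
    rejections[i, "vif"] <- r$p < 0.05
    p_naive <- 2 * pt(abs(r$t * sqrt(r$vif)), df = r$df, lower.tail = FALSE)
    rejections[i, "naive"] <- p_naive < 0.05
  }
  rate <- colMeans(rejections)
  expect_gte(rate["vif"], 0.02)
  expect_lte(rate["vif"], 0.08)
  expect_gt(rate["naive"], 0.15)
})

test_that("activity screen applies the 25 percent relative-magnitude rule", {
  set.seed(43)
  n <- 30
  X <- matrix(rnorm(300 * 2 * n), 300, 2 * n,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:(2 * n))))
  groups <- rep(c("high", "low"), each = n)
  anchor <- paste0("g", 1:20)
  X[anchor, groups == "high"] <- X[anchor, groups == "high"] + 1
  strong <- paste0("g", 21:30)
  X[strong, groups == "high"] <- X[strong, groups == "high"] + 0.5
  weak <- paste0("g", 31:40)
  X[weak, groups == "high"] <- X[weak, groups == "high"] + 0.05
  coll <- gene_set_collection(list(strong = strong, weak = weak,
                                   anchor_itself = anchor))
  res <- activity_screen(coll, X, groups, anchor, rownames(X))
  ref <- attr(res, "reference_activity")
  expect_gt(ref, 0)
  expect_true(res$significant[res$set == "strong"])
  expect_false(res$significant[res$set == "weak"])   # magnitude gate
  # the anchor tested against itself always passes the magnitude gate
  expect_gte(abs(res$enrichment[res$set == "anchor_itself"]), 0.25 * abs(ref))
  expect_identical(res$direction[res$set == "strong"], "activation")
})
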