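test_that("size factors are median-of-ratios", {
  cnt <- named_matrix(rep(c(10, 20, 40), 4), 3, 4)
  expect_equal(unname(size_factors(cnt)), rep(1, 4))   # identical columns
  cnt2 <- cnt; cnt2[, 3] <- cnt2[, 3] * 2
  sf <- size_factors(cnt2)
  expect_equal(unname(sf[3] / sf[1]), 2)
  # explicit loop oracle on a 6x4 matrix
  set.seed(80)
  cnt3 <- named_matrix(rpois(24, 40) + 1, 6, 4)
  geo <- exp(rowMeans(log(cnt3)))
  oracle <- vapply(1:4, function(s) median(cnt3[, s] / geo), numeric(1))
  expect_equal(unname(size_factors(cnt3)), oracle)
  # no all-positive gene
  cnt4 <- named_matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors(cnt4), "positive")
})

test_that("nb_wald_de degenerate and symmetry behavior", {
  set.seed(81)
  cnt <- named_matrix(rnbinom(100 * 8, mu = 50, size = 5), 100, 8)
  cnt["g01", ] <- 30                                  # identical everywhere
  g <- factor(rep(c("a", "b"), each = 4), levels = c("a", "b"))
  expect_error(nb_wald_de(cnt[, 1:5], factor(c("a","a","a","b","b"))), "fewer than 3")
  de <- nb_wald_de(cnt, g)
  expect_equal(de$log2FC[de$gene == "g01"], 0)
  expect_equal(de$p[de$gene == "g01"], 1)
  expect_true(all(de$padj >= de$p - 1e-12))
  # swapping group labels flips the fold change and keeps the flags
  de2 <- nb_wald_de(cnt, factor(g, levels = c("b", "a")))
  expect_equal(de2$log2FC, -de$log2FC)
  expect_equal(de2$significant, de$significant)
})

test_that("significance requires both the fold and the adjusted-p cutoff", {
  set.seed(82)
  cnt <- named_matrix(rnbinom(500 * 12, mu = 80, size = 8), 500, 12)
  g <- factor(rep(c("a", "b"), each = 6))
  cnt[1:20, g == "b"] <- matrix(
    rnbinom(20 * 6, mu = 80 * 1.5, size = 8), 20, 6)  # 1.5-fold < 2-fold
  de <- nb_wald_de(cnt, g, fold_cutoff = 2, alpha = 0.05)
  expect_true(all(abs(de$log2FC[de$significant]) >= 1))
  expect_true(all(de$padj[de$significant] <= 0.05))
})

test_that("ssGSEA score matches a 4-gene hand enumeration at alpha 0", {
  x <- c(a = 9, b = 5, c = 3, d = 1)
  # set = top gene: P_in = (1,1,1,1), P_out = (0, 1/3, 2/3, 1)
  expect_equal(ssgsea_score(x, "a", alpha = 0), 1 + 2/3 + 1/3 + 0)
  # set = bottom gene: P_in = (0,0,0,1), P_out = (1/3, 2/3, 1, 1)
  expect_equal(ssgsea_score(x, "d", alpha = 0), -(1/3 + 2/3 + 1))
  expect_error(ssgsea_score(x, c("a", "b", "c", "d")), "some but not all")
  expect_error(ssgsea_score(x, "zzz"), "some but not all")
})

test_that("ssGSEA at alpha 0 is rank-only and anti-symmetric in the set", {
  set.seed(83)
  x <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  gs <- sample(names(x), 12)
  s <- ssgsea_score(x, gs, alpha = 0)
  expect_equal(ssgsea_score(exp(x) + 2, gs, alpha = 0), s)  # monotone transform
  expect_equal(ssgsea_score(x, setdiff(names(x), gs), alpha = 0), -s)
})

test_that("a planted up-regulated gene set scores higher in carrier samples", {
  set.seed(84)
  X <- named_matrix(rnorm(500 * 60, 5, 1), 500, 60)
  gs <- rownames(X)[1:40]
  X[gs, 1:30] <- X[gs, 1:30] + 1.5                     # carriers
  sc <- ssgsea(X, list(set = gs), alpha = 0.75)
  w <- wilcoxon_rank_sum(sc[1, 1:30], sc[1, 31:60])
  expect_lt(w$p.value, 0.01)
  expect_gt(median(sc[1, 1:30]), median(sc[1, 31:60]))
})

test_that("correlation screen flags exact copies and respects the filter", {
  set.seed(85)
  X <- named_matrix(rnorm(60 * 50, 5, 1), 60, 50)
  X["g02", ] <- X["g01", ]                            # exact copy of target
  X["g03", ] <- -X["g01", ] + 10                      # exact negative
  hits <- correlation_screen(X, "g01", r_cutoff = 0.3, alpha = 0.05,
                             min_fpkm = 0, min_frac = 0)
  expect_equal(hits$direction[hits$gene == "g02"], "positive")
  expect_equal(hits$pearson_r[hits$gene == "g02"], 1)
  expect_equal(hits$direction[hits$gene == "g03"], "negative")
  # target failing the expression filter skips the screen
  low <- X; low["g01", ] <- 0.01
  expect_message(out <- correlation_screen(low, "g01", fpkm = low),
                 "fails the expression filter")
  expect_equal(nrow(out), 0L)
  expect_error(correlation_screen(X, "g01", samples = colnames(X)[1:4]),
               "fewer than 5")
})

test_that("correlation screen on independent noise has near-zero hit rate", {
  set.seed(86)
  X <- named_matrix(rnorm(2000 * 50, 5, 1), 2000, 50)
  hits <- correlation_screen(X, rownames(X)[1], min_fpkm = 0, min_frac = 0)
  rate <- mean(hits$direction != "none")
  expect_lt(rate, 0.01)
})

test_that("crosstab counts, percentages and margins are coherent", {
  a <- rep(c("x", "y"), c(3, 2))
  b <- c("p", "p", "q", "q", "q")
  ct <- subgroup_crosstab(a, b)
  expect_equal(ct$n, 5)
  expect_equal(sum(ct$counts), 5)
  expect_true(all(abs(colSums(ct$col_pct) - 100) <= 1))  # rounding slack
  one <- subgroup_crosstab("x", "p")
  expect_equal(unname(one$col_pct[1, 1]), 100)
})
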