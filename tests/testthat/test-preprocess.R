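test_that("expression filter keeps genes at or above the FPKM threshold", {
  f <- named_matrix(c(0.9, 0.5, 1.0, 0.2, 5, 8), 3, 2)
  kept <- filter_expressed_genes(f)
  expect_false("g01" %in% kept)   # max 0.9 < 1
  expect_true("g02" %in% kept)    # exactly 1.0 in one sample: >= is inclusive
  expect_true("g03" %in% kept)
  expect_warning(filter_expressed_genes(f, min_fpkm = 100),
                 "no gene passed")
})

test_that("expression filter matches a brute-force scan", {
  set.seed(10)
  f <- named_matrix(runif(50, 0, 3), 10, 5)
  for (ms in 1:3) {
    kept <- filter_expressed_genes(f, min_fpkm = 1.5, min_samples = ms)
    oracle <- character(0)
    for (g in rownames(f)) {
      hits <- 0
      for (s in seq_len(ncol(f))) if (f[g, s] >= 1.5) hits <- hits + 1
      if (hits >= ms) oracle <- c(oracle, g)
    }
    expect_equal(kept, oracle)
  }
})

test_that("top_variable_genes ranks by variance with lexicographic ties", {
  set.seed(11)
  X <- named_matrix(rnorm(400), 50, 8)
  X["g07", ] <- 5  # constant gene
  got <- top_variable_genes(X, 10)
  v <- apply(X, 1, var)
  oracle <- rownames(X)[order(-v, rownames(X))][1:10]
  expect_equal(got, oracle)
  expect_equal(top_variable_genes(X, 50)[50], "g07")  # zero variance last
  # fraction form: top 10% of 1000 genes -> 100 genes
  Y <- named_matrix(rnorm(4000), 1000, 4)
  expect_length(top_variable_genes(Y, 0.10), 100)
  expect_error(top_variable_genes(X, 0), "k must be")
})

test_that("row_zscale centers and scales with sample sd", {
  z <- row_zscale(named_matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))  # sample sd (n-1)
  zc <- row_zscale(named_matrix(rep(4, 3), 1, 3))
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
  set.seed(12)
  Z <- row_zscale(named_matrix(rnorm(50, 3, 2), 10, 5))
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
})

test_that("combat_correct with a single batch is the identity", {
  X <- named_matrix(rnorm(40, 5), 10, 4)
  expect_identical(combat_correct(X, rep("b1", 4)), X)
  expect_error(combat_correct(X, c("a", "a", "a", "b")), "single sample")
})

test_that("combat_correct removes a planted additive batch shift", {
  set.seed(13)
  X <- named_matrix(rnorm(100 * 100, 6, 0.5), 100, 100)
  batch <- rep(c("A", "B"), each = 50)
  X[, batch == "B"] <- X[, batch == "B"] + 2
  Y <- combat_correct(X, batch)
  d <- rowMeans(Y[, batch == "B"]) - rowMeans(Y[, batch == "A"])
  expect_lt(mean(abs(d)), 0.1)
  expect_equal(dim(Y), dim(X))
})

test_that("combat_correct is approximately idempotent", {
  set.seed(14)
  X <- named_matrix(rnorm(100 * 60, 6, 1), 100, 60)
  batch <- rep(c("A", "B"), each = 30)
  X[, batch == "B"] <- X[, batch == "B"] + 1.5
  Y1 <- combat_correct(X, batch)
  Y2 <- combat_correct(Y1, batch)
  # second-pass adjustment is a small fraction of the first-pass one
  expect_lt(mean(abs(Y2 - Y1)), 0.1 * mean(abs(Y1 - X)))
})

test_that("a subtype effect orthogonal to batch survives correction", {
  set.seed(15)
  sub <- rep(rep(c(1, 2), each = 15), 2)            # balanced within batch
  batch <- rep(c("A", "B"), each = 30)
  X <- named_matrix(rnorm(200 * 60, 5, 1), 200, 60)
  X[1:50, sub == 2] <- X[1:50, sub == 2] + 2
  X[, batch == "B"] <- X[, batch == "B"] + 1.5
  Y <- combat_correct(X, batch)
  km_after <- kmeans(t(row_zscale(Y)), 2, nstart = 10)$cluster
  ari_after <- adjusted_rand_index(km_after, sub)
  expect_gt(ari_after, 0.95)  # planted subtype recovered after correction
})

test_that("receptor status thresholds are strict at the boundary", {
  f <- named_matrix(c(0.5, 3, 10,
                      1.0, 1.5, 35.0,
                      2.0, 0.3, 35.1), 3, 3)
  rownames(f) <- c("ESR1", "PGR", "ERBB2")
  st <- call_receptor_status(f)
  expect_equal(st$subgroup, c("ER-PR+", "ER-PR+", "ER+PR-"))
  expect_equal(st$ER, c("neg", "neg", "pos"))        # FPKM <= 1 is negative
  expect_equal(st$HER2, c("not_enriched", "not_enriched", "enriched"))
  expect_error(call_receptor_status(f[1:2, ]), "ERBB2")
})

test_that("receptor subgroups partition every cohort", {
  sc <- small_cohort(seed = 16, n_per = 20)
  st <- call_receptor_status(counts_to_fpkm(sc$counts, sc$gene_lengths))
  expect_equal(nrow(st), ncol(sc$counts))
  expect_true(all(st$subgroup %in% c("ER-PR-", "ER-PR+", "ER+PR+", "ER+PR-")))
  expect_equal(sum(table(st$subgroup)), ncol(sc$counts))
})
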