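test_that("identical config and seed give byte-identical cohorts", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  c <- small_cohort(seed = 8)
  expect_false(identical(a$counts, c$counts))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(subtypes = list(sp = c(A = 0, B = 5))), "subtypes")
  expect_error(sim_config(
    subtypes = list(a = c(X = 5, Y = 5), b = c(Z = 5)),
    homologous_pair = c(a = "X", b = "Q")), "homologous_pair")
  expect_error(sim_config(n_genes = 40, n_panel_genes = 10,
                          n_informative = 100), "n_genes")
})

test_that("cohort structure matches the declared design", {
  sc <- small_cohort(seed = 3)
  expect_equal(dim(sc$counts), c(300L, 30L))
  expect_true(all(sc$counts >= 0))
  expect_equal(as.vector(table(sc$meta$subtype)), c(15L, 15L))
  expect_true(all(unlist(sc$truth$informative_genes) %in%
                    rownames(sc$counts)))
  # every sample has exactly one subtype and one batch
  expect_false(any(is.na(sc$meta$subtype)))
  expect_false(any(is.na(sc$meta$batch)))
})

test_that("informative genes carry the planted log2 shift", {
  sc <- small_cohort(seed = 5, n_per = 25, effect_size = 2, bio_sd = 0.3)
  lt <- cohort_log2tpm(sc)
  a <- sc$meta$sample[sc$meta$subtype == "A"]
  b <- sc$meta$sample[sc$meta$subtype == "B"]
  ga <- sc$truth$informative_genes[["sp:A"]]
  delta <- rowMeans(lt[ga, a]) - rowMeans(lt[ga, b])
  expect_gt(median(delta), 1)  # shift survives normalization, attenuated by log1p
})

test_that("null cohorts are calibrated: per-gene t tests reject at ~5%", {
  sc <- simulate_cohort(sim_config(
    n_genes = 2000, n_panel_genes = 20,
    subtypes = list(sp = c(A = 50, B = 50)), n_informative = 0,
    effect_size = 0, seed = 11))
  lt <- cohort_log2tpm(sc)
  grp <- sc$meta$subtype == "A"
  keep <- apply(lt, 1L, sd) > 0
  p <- apply(lt[keep, ], 1L, function(x)
    stats::t.test(x[grp], x[!grp])$p.value)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("counts_to_fpkm implements the direct formula", {
  cnt <- named_matrix(c(10, 999990), 2, 1)
  lens <- setNames(c(1000, 1000), rownames(cnt))
  fpkm <- counts_to_fpkm(cnt, lens)
  expect_equal(fpkm["g01", 1], 10)  # 10 * 1e9 / (1000 * 1e6)
  # all-zero gene stays zero
  cnt2 <- named_matrix(c(0, 5, 0, 7), 2, 2)
  expect_equal(unname(counts_to_fpkm(cnt2, c(g01 = 500, g02 = 800))[1, ]),
               c(0, 0))
})

test_that("FPKM is invariant to doubling all counts in a sample", {
  set.seed(2)
  cnt <- named_matrix(rpois(40, 50), 10, 4)
  lens <- setNames(sample(500:2000, 10), rownames(cnt))
  f1 <- counts_to_fpkm(cnt, lens)
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 2
  f2 <- counts_to_fpkm(cnt2, lens)
  expect_equal(f1[, 2], f2[, 2])
})

test_that("zero-total sample is rejected with its name", {
  cnt <- named_matrix(c(1, 2, 0, 0), 2, 2)
  expect_error(counts_to_fpkm(cnt, c(g01 = 100, g02 = 100)), "s02")
})

test_that("fpkm_to_tpm normalizes each column to 1e6", {
  f <- named_matrix(c(2, 2), 2, 1)
  expect_equal(unname(fpkm_to_tpm(f)[, 1]), c(5e5, 5e5))
  f2 <- named_matrix(c(1, 3), 2, 1)
  expect_equal(unname(fpkm_to_tpm(f2)[, 1]), c(2.5e5, 7.5e5))
  set.seed(3)
  f3 <- named_matrix(runif(30, 0.1, 50), 10, 3)
  expect_equal(unname(colSums(fpkm_to_tpm(f3))), rep(1e6, 3))
  f4 <- named_matrix(c(0, 0, 1, 2), 2, 2)
  expect_error(fpkm_to_tpm(f4), "s01")
})

test_that("counts -> FPKM -> TPM preserves within-sample rank for equal lengths", {
  set.seed(4)
  cnt <- named_matrix(rpois(60, 30), 20, 3)
  lens <- setNames(rep(1000, 20), rownames(cnt))
  tpm <- fpkm_to_tpm(counts_to_fpkm(cnt, lens))
  for (j in 1:3)
    expect_equal(rank(tpm[, j]), rank(cnt[, j]))
})

test_that("receptor marker generation straddles the clinical thresholds", {
  sc <- small_cohort(seed = 9, n_per = 30)
  fpkm <- counts_to_fpkm(sc$counts, sc$gene_lengths)
  calls <- call_receptor_status(fpkm)
  truth <- sc$truth$receptor_truth
  expect_gt(mean(calls$ER == truth$ER), 0.95)
  expect_gt(mean(calls$PR == truth$PR), 0.95)
  expect_gt(mean(calls$HER2 == truth$HER2), 0.9)
})
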