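test_that("reference sampling draws the stated design: 4 x 60 + all normal-like", {
  set.seed(60)
  labels <- setNames(
    rep(c("Basal", "LumA", "LumB", "Her2", "Normal"),
        times = c(100, 120, 80, 70, 27)),
    sprintf("h%03d", 1:397))
  sch <- sampling_scheme(seed = 1)
  ids <- sample_reference(labels, sch, 1)
  expect_length(ids, 267)                       # 4 * 60 + 27
  expect_equal(as.integer(table(labels[ids])[c("Basal", "LumA", "LumB",
                                               "Her2")]),
               rep(60L, 4))
  expect_equal(sum(labels[ids] == "Normal"), 27L)
  expect_false(anyDuplicated(ids) > 0)
  # determinism per (seed, repeat)
  expect_identical(ids, sample_reference(labels, sch, 1))
  expect_false(identical(ids, sample_reference(labels, sch, 2)))
  # exhaustive draw when the subtype has exactly n_per_subtype members
  lab2 <- setNames(rep(c("Basal", "LumA"), c(60, 70)), sprintf("x%03d", 1:130))
  ids2 <- sample_reference(lab2, sampling_scheme(
    subtypes_sampled = c("Basal", "LumA"), include_all_of = character(0)), 3)
  expect_setequal(ids2[1:60], names(lab2)[lab2 == "Basal"])
  expect_error(sample_reference(lab2, sampling_scheme(
    subtypes_sampled = "Her2", include_all_of = character(0)), 1), "Her2")
})

test_that("coverage across repeats reaches every reference tumor", {
  set.seed(61)
  labels <- setNames(rep(c("Basal", "LumA", "LumB", "Her2", "Normal"),
                         times = c(90, 90, 90, 90, 27)),
                     sprintf("h%03d", 1:387))
  sch <- sampling_scheme(n_repeats = 50, seed = 2)
  drawn <- unique(unlist(lapply(1:50, function(r)
    sample_reference(labels, sch, r))))
  expect_setequal(drawn, names(labels))
})

test_that("separation cut on a hand-built 4-leaf tree matches hand computation", {
  # distances force merges: {a1,b1} first, then +a2, then +b2
  d <- matrix(c(0, 1.0, 2.0, 6.0,
                1.0, 0, 2.6, 6.2,
                2.0, 2.6, 0, 6.4,
                6.0, 6.2, 6.4, 0), 4, 4,
              dimnames = list(c("a1", "b1", "a2", "b2"),
                              c("a1", "b1", "a2", "b2")))
  tree <- hclust(stats::as.dist(d), method = "average")
  cut <- dendrogram_separation_cut(tree, c("a1", "a2"), c("b1", "b2"))
  # 2-cut: {a1,b1,a2} vs {b2}: pure-A members 0, pure-B members 1 -> S = 1/4
  expect_equal(unname(cut$S["2"]), 0.25)
  # 3-cut: {a1,b1},{a2},{b2}: a2 pure + b2 pure -> S = 2/4
  expect_equal(unname(cut$S["3"]), 0.5)
  # full cut separates everything
  expect_equal(unname(cut$S["4"]), 1)
  expect_equal(cut$k, 4)
})

test_that("two perfectly separated groups split at k = 2 with S = 1", {
  set.seed(62)
  X <- cbind(matrix(rnorm(20 * 5, 0, .1), 20), matrix(rnorm(20 * 5, 8, .1), 20))
  colnames(X) <- sprintf("s%02d", 1:10)
  tree <- hclust(dist(t(X)), "average")
  cut <- dendrogram_separation_cut(tree, colnames(X)[1:5], colnames(X)[6:10])
  expect_equal(cut$k, 2)
  expect_equal(unname(cut$S["2"]), 1)
})

test_that("S(k) is non-decreasing on random trees and reaches 1 at n", {
  set.seed(63)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 15), 8)
    colnames(X) <- sprintf("s%02d", 1:15)
    tree <- hclust(dist(t(X)), sample(c("average", "complete", "single"), 1))
    A <- sample(colnames(X), 4)
    B <- sample(setdiff(colnames(X), A), 5)
    S <- dendrogram_separation_cut(tree, A, B)$S
    expect_true(all(diff(S) >= -1e-12))
    expect_equal(unname(S[as.character(15)]), 1)
  }
})

test_that("majority matching follows the strict >50% rule", {
  # constructed clusters: cluster 1 holds 55/60 of hBLBC and 60/69 of cBLMT
  can <- setNames(rep("cBLMT", 69), sprintf("c%03d", 1:69))
  hum <- setNames(rep("hBLBC", 60), sprintf("h%03d", 1:60))
  cl <- c(setNames(c(rep(1, 60), rep(2, 9)), names(can)),
          setNames(c(rep(1, 55), rep(2, 5)), names(hum)))
  m <- match_subtypes(cl, can, hum)
  expect_equal(m$pairs, data.frame(canine = "cBLMT", human = "hBLBC"),
               ignore_attr = TRUE)
  # an exact 30/30 split is not a majority
  hum2 <- setNames(rep("hBLBC", 60), sprintf("h%03d", 1:60))
  cl2 <- c(setNames(rep(1, 69), names(can)),
           setNames(rep(c(1, 2), each = 30), names(hum2)))
  m2 <- match_subtypes(cl2, can, hum2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_true(is.na(m2$human_majority_cluster[["hBLBC"]]))
  # a canine subtype alone in its own cluster matches no human subtype
  cl3 <- c(setNames(rep(1, 69), names(can)),
           setNames(rep(2, 60), names(hum)))
  expect_equal(nrow(match_subtypes(cl3, can, hum)$pairs), 0L)
})

test_that("classical MDS reproduces geometry", {
  # three collinear points with gaps (1, 1)
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  co <- mds_embed(D, 1)
  g <- diff(sort(co[, 1]))
  expect_equal(g, c(1, 1), tolerance = 1e-8)
  # round trip of random planar points
  set.seed(64)
  P <- matrix(rnorm(20), 10, 2)
  co2 <- mds_embed(dist(P), 2)
  expect_equal(as.matrix(dist(co2)), as.matrix(dist(P)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # identical points embed at the origin (zero-padded with warning)
  D0 <- matrix(0, 4, 4)
  w <- capture_warnings(co3 <- mds_embed(D0, 2))
  expect_true(any(grepl("padding", w)))
  expect_true(all(abs(co3) < 1e-10))
})

test_that("Mahalanobis center distance matches the closed form", {
  set.seed(65)
  A <- matrix(rnorm(40, 0, 1), 20, 2)
  B <- matrix(rnorm(40, 2, 1.5), 20, 2)
  Sp <- ((nrow(A) - 1) * cov(A) + (nrow(B) - 1) * cov(B)) /
    (nrow(A) + nrow(B) - 2) + diag(1e-8, 2)
  delta <- colMeans(A) - colMeans(B)
  expect_equal(mahalanobis_center_distance(A, B),
               sqrt(drop(t(delta) %*% solve(Sp) %*% delta)))
  # identical means -> 0
  expect_equal(mahalanobis_center_distance(A, A), 0)
  # identity covariance -> Euclidean distance of means
  set.seed(66)
  big <- matrix(rnorm(4000), 2000, 2)
  shifted <- sweep(big, 2, c(3, 4), "+")
  d <- mahalanobis_center_distance(big, shifted)
  expect_equal(d, sqrt(sum((colMeans(big) - colMeans(shifted))^2)),
               tolerance = 0.05)
  expect_error(mahalanobis_center_distance(A[1:2, ], B), "points")
})

test_that("a relabeled duplicate of the reference matches itself subtype by subtype", {
  set.seed(67)
  sts <- rep(c("Basal", "LumA", "Her2"), each = 12)
  X <- named_matrix(rnorm(40 * 36, 5, 0.5), 40, 36)
  for (i in seq_along(unique(sts)))
    X[((i - 1) * 10 + 1):(i * 10), sts == unique(sts)[i]] <-
      X[((i - 1) * 10 + 1):(i * 10), sts == unique(sts)[i]] + 3
  hum <- setNames(sts, colnames(X))
  Xc <- X + matrix(rnorm(length(X), 0, 0.05), nrow(X))
  colnames(Xc) <- sprintf("c%02d", 1:36)
  can <- setNames(paste0("c", sts), colnames(Xc))
  rec <- cocluster_once(Xc, X, can, hum, rownames(X),
                        groupA_label = "Basal", groupB_label = "LumA")
  pairs <- rec$match$pairs
  for (st in unique(sts))
    expect_true(any(pairs$canine == paste0("c", st) & pairs$human == st))
})

test_that("planted homologous and orthogonal profiles behave as expected", {
  set.seed(68)
  sts <- rep(c("Basal", "LumA"), each = 15)
  X <- named_matrix(rnorm(30 * 30, 5, 0.5), 30, 30)
  X[1:10, sts == "Basal"] <- X[1:10, sts == "Basal"] + 3
  X[11:20, sts == "LumA"] <- X[11:20, sts == "LumA"] + 3
  hum <- setNames(sts, colnames(X))
  # canine cohort: noisy copies of the Basal profiles
  Xc <- X[, sts == "Basal"] + matrix(rnorm(30 * 15, 0, 0.3), 30)
  colnames(Xc) <- sprintf("c%02d", 1:15)
  can <- setNames(rep("cB", 15), colnames(Xc))
  rec <- cocluster_once(Xc, X, can, hum, rownames(X))
  expect_true(any(rec$match$pairs$canine == "cB" &
                    rec$match$pairs$human == "Basal"))
  # canine cohort with an orthogonal private profile matches nothing
  Xo <- named_matrix(rnorm(30 * 15, 5, 0.5), 30, 15)
  Xo[21:30, ] <- Xo[21:30, ] + 4
  colnames(Xo) <- sprintf("o%02d", 1:15)
  cano <- setNames(rep("cPriv", 15), colnames(Xo))
  reco <- cocluster_once(Xo, X, cano, hum, rownames(X))
  expect_false("cPriv" %in% reco$match$pairs$canine)
  expect_error(cocluster_once(Xo[1:2, ], X, cano, hum, rownames(X)[1:2]),
               "shared panel")
})

test_that("a single-repeat experiment equals its one co-clustering run", {
  set.seed(69)
  sts <- rep(c("Basal", "LumA", "LumB", "Her2", "Normal"), each = 12)
  X <- named_matrix(rnorm(40 * 60, 5, 0.5), 40, 60)
  for (i in 1:5)
    X[((i - 1) * 8 + 1):(i * 8), sts == unique(sts)[i]] <-
      X[((i - 1) * 8 + 1):(i * 8), sts == unique(sts)[i]] + 3
  hum <- setNames(sts, colnames(X))
  Xc <- X[, sts %in% c("Basal", "LumA")] + rnorm(40 * 24, 0, 0.2)
  colnames(Xc) <- sprintf("c%02d", 1:24)
  can <- setNames(ifelse(hum[sts %in% c("Basal", "LumA")] == "Basal",
                         "cB", "cL"), colnames(Xc))
  sch <- sampling_scheme(n_per_subtype = 10, n_repeats = 1, seed = 5)
  hr <- homology_experiment(Xc, can, X, hum, rownames(X), sch,
                            target_pair = c(canine = "cB", human = "Basal"))
  expect_s3_class(hr, "homology_result")
  expect_equal(sum(hr$fisher_table[1, ]), 1L)       # margins = n_repeats
  expect_equal(sum(hr$fisher_table[2, ]), 1L)
  expect_equal(hr$pair_counts[["cB|Basal"]], 1L)
  rep1 <- hr$repeats[[1]]
  expect_equal(unname(hr$fisher_table[1, 1]),
               sum(rep1$pairs$canine == "cB" & rep1$pairs$human == "Basal"))
})

test_that("matching is symmetric under species role swap", {
  can <- setNames(rep(c("X", "Y"), each = 10), sprintf("c%02d", 1:20))
  hum <- setNames(rep(c("P", "Q"), each = 10), sprintf("h%02d", 1:20))
  cl <- setNames(c(rep(1, 10), rep(2, 10), rep(1, 10), rep(2, 10)),
                 c(names(can), names(hum)))
  m1 <- match_subtypes(cl, can, hum)$pairs
  m2 <- match_subtypes(cl, hum, can)$pairs
  expect_setequal(paste(m1$canine, m1$human), paste(m2$human, m2$canine))
})
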