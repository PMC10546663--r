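# All-relevant feature-gene selection: pairwise DE pools feeding an
# iterated Boruta (shadow-feature random forest) selector, with
# frequency-stable gene sets over outer repeats.

#' Boruta configuration
#'
#' @param n_trees random forest trees per round (default 500).
#' @param max_rounds maximum shadow-feature rounds (default 100; stops
#'   early once no features remain tentative).
#' @param alpha significance level of the per-feature binomial hit tests
#'   (Bonferroni-adjusted; default 0.01).
#' @param n_outer_repeats outer Boruta repeats in
#'   [stable_feature_genes()] (default 50).
#' @param freq_cutoff minimum number of repeats a gene must be confirmed in
#'   to be retained (default 50, i.e. all repeats).
#' @param train_fraction stratified training fraction (default 0.80).
#' @param seed RNG seed.
#' @return List of class `boruta_config`.
#' @export
boruta_config <- function(n_trees = 500, max_rounds = 100, alpha = 0.01,
                          n_outer_repeats = 50, freq_cutoff = 50,
                          train_fraction = 0.80, seed = 1L) {
  .check(freq_cutoff <= n_outer_repeats,
         "boruta_config: freq_cutoff must be <= n_outer_repeats")
  .check(train_fraction > 0 && train_fraction < 1,
         "boruta_config: train_fraction must be in (0, 1)")
  .check(alpha > 0 && alpha < 1, "boruta_config: alpha must be in (0, 1)")
  structure(list(n_trees = as.integer(n_trees),
                 max_rounds = as.integer(max_rounds), alpha = alpha,
                 n_outer_repeats = as.integer(n_outer_repeats),
                 freq_cutoff = as.integer(freq_cutoff),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "boruta_config")
}

#' Pairwise differential-expression gene pools
#'
#' For a target subtype, runs [nb_wald_de()] between the target and every
#' other subtype and returns, per comparison, the genes with BH-adjusted
#' p <= `alpha` (no fold-change cutoff at this stage).
#'
#' @param counts gene-by-sample count matrix.
#' @param labels per-sample subtype labels.
#' @param target_subtype the subtype of interest.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return Named list (one entry per other subtype) of gene vectors.
#' @export
pairwise_de_pools <- function(counts, labels, target_subtype, alpha = 0.05) {
  .check_matrix(counts, "counts")
  labels <- as.character(labels)
  .check(length(labels) == ncol(counts),
         "pairwise_de_pools: one label per sample required")
  .check(target_subtype %in% labels,
         "pairwise_de_pools: target subtype absent from labels")
  others <- setdiff(unique(labels), target_subtype)
  .check(length(others) >= 1L, "pairwise_de_pools: need >= 2 groups")
  pools <- lapply(setNames(others, others), function(st) {
    sel <- labels %in% c(target_subtype, st)
    de <- nb_wald_de(counts[, sel, drop = FALSE],
                     factor(labels[sel], levels = c(target_subtype, st)),
                     fold_cutoff = 1, alpha = alpha)
    de$gene[de$padj <= alpha]
  })
  pools
}

#' Boruta all-relevant feature selection
#'
#' Each round appends a shuffled "shadow" copy of every remaining feature,
#' fits a random forest, and records which real features beat the best
#' shadow importance. Features are then classified by two-sided binomial
#' tests on their hit counts (Bonferroni-corrected over the undecided
#' features): significantly more hits than chance confirms a feature,
#' significantly fewer rejects it (rejected features are dropped from later
#' rounds). Selection is *all-relevant*: duplicated informative features
#' are both confirmed. Deterministic given the seed.
#'
#' @param X samples-by-features numeric matrix.
#' @param y per-sample class labels (>= 2 classes).
#' @param config a [boruta_config()].
#' @return List: `confirmed`, `tentative`, `rejected` (feature names),
#'   `hits` (named hit counts), `rounds` (rounds run).
#' @export
boruta_select <- function(X, y, config = boruta_config()) {
  .check(is.matrix(X) && is.numeric(X), "X must be a numeric matrix")
  .check(!is.null(colnames(X)), "X must have feature colnames")
  y <- as.factor(y)
  if (nlevels(y) < 2L)
    stop("boruta_select: y must have at least 2 classes", call. = FALSE)
  .check(length(y) == nrow(X), "boruta_select: one label per row required")
  set.seed(config$seed)
  feats <- colnames(X)
  active <- feats
  hits <- setNames(integer(length(feats)), feats)
  status <- setNames(rep("tentative", length(feats)), feats)
  rounds <- 0L
  min_rounds <- 5L
  while (rounds < config$max_rounds && any(status == "tentative")) {
    rounds <- rounds + 1L
    active <- feats[status != "rejected"]
    Xa <- X[, active, drop = FALSE]
    shadow <- apply(Xa, 2L, sample)
    colnames(shadow) <- paste0(".shadow.", active)
    dat <- cbind(Xa, shadow)
    fit <- ranger::ranger(
      x = dat, y = y, num.trees = config$n_trees,
      mtry = max(1L, floor(sqrt(ncol(dat)))), importance = "impurity",
      num.threads = 1L, seed = .sub_seed(config$seed, rounds))
    imp <- fit$variable.importance
    shadow_max <- max(imp[colnames(shadow)])
    beat <- imp[active] > shadow_max
    hits[active[beat]] <- hits[active[beat]] + 1L
    if (rounds >= min_rounds) {
      tent <- names(status)[status == "tentative"]
      n_adj <- length(tent)
      for (f in tent) {
        p_up <- pbinom(hits[[f]] - 1L, rounds, 0.5, lower.tail = FALSE)
        p_dn <- pbinom(hits[[f]], rounds, 0.5)
        if (p_up * n_adj < config$alpha) status[f] <- "confirmed"
        else if (p_dn * n_adj < config$alpha) status[f] <- "rejected"
      }
    }
  }
  list(confirmed = feats[status == "confirmed"],
       tentative = feats[status == "tentative"],
       rejected = feats[status == "rejected"],
       hits = hits, rounds = rounds)
}

#' Frequency-stable feature genes
#'
#' Splits the samples into a stratified training set (`train_fraction`) and
#' a held-out test set. On the training set, builds pairwise DE pools for
#' the target subtype and runs [boruta_select()] on each pool
#' `n_outer_repeats` times with distinct sub-seeds (each repeat classifies
#' target-vs-that-subtype samples). Genes confirmed in at least
#' `freq_cutoff` repeats are kept; the final set is the union over
#' comparisons. A nearest-centroid model on the selected genes is evaluated
#' on the held-out samples.
#'
#' @param counts gene-by-sample count matrix.
#' @param labels per-sample subtype labels.
#' @param target_subtype subtype whose feature genes are sought.
#' @param config a [boruta_config()].
#' @param pools optional precomputed DE pools (skips [pairwise_de_pools()]).
#' @return Object of class `feature_set`: `genes`, `frequency` (per gene,
#'   max over comparisons), `per_comparison` (list of per-gene confirmation
#'   counts), `test_accuracy`, `test_n`.
#' @export
stable_feature_genes <- function(counts, labels, target_subtype,
                                 config = boruta_config(), pools = NULL) {
  .check_matrix(counts, "counts")
  labels <- as.character(labels)
  names(labels) <- colnames(counts)
  set.seed(config$seed)
  # Stratified train/test split.
  train <- unlist(lapply(unique(labels), function(st) {
    ids <- names(labels)[labels == st]
    sample(ids, max(2L, round(config$train_fraction * length(ids))))
  }))
  test <- setdiff(names(labels), train)
  if (is.null(pools))
    pools <- pairwise_de_pools(counts[, train, drop = FALSE], labels[train],
                               target_subtype)
  pools <- pools[vapply(pools, length, integer(1L)) > 0L]
  log_norm <- function(cnt) {
    sf <- size_factors(cnt)
    log2(sweep(cnt, 2L, sf, "/") + 1)
  }
  per_comp <- list()
  for (other in names(pools)) {
    sel <- train[labels[train] %in% c(target_subtype, other)]
    Xf <- t(log_norm(counts[, sel, drop = FALSE])[pools[[other]], ,
                                                  drop = FALSE])
    yv <- factor(labels[sel] == target_subtype)
    freq <- setNames(integer(length(pools[[other]])), pools[[other]])
    for (r in seq_len(config$n_outer_repeats)) {
      cfg_r <- config
      cfg_r$seed <- .sub_seed(config$seed, r)
      res <- boruta_select(Xf, yv, cfg_r)
      freq[res$confirmed] <- freq[res$confirmed] + 1L
    }
    per_comp[[other]] <- freq
  }
  kept <- lapply(per_comp, function(f) names(f)[f >= config$freq_cutoff])
  genes <- unique(unlist(kept))
  if (length(genes) == 0L)
    warning("stable_feature_genes: no gene reached the frequency cutoff")
  frequency <- setNames(rep(0L, length(genes)), genes)
  for (f in per_comp) {
    common <- intersect(names(f), genes)
    frequency[common] <- pmax(frequency[common], f[common])
  }
  test_accuracy <- NA_real_
  if (length(genes) >= 3L && length(test) >= 2L) {
    ln_all <- log_norm(counts)
    model <- build_centroids(ln_all[, train, drop = FALSE], labels[train],
                             genes)
    calls <- predict(model, ln_all[, test, drop = FALSE])
    test_accuracy <- mean(calls$label == labels[test])
  }
  structure(list(genes = genes, frequency = frequency,
                 per_comparison = per_comp, test_accuracy = test_accuracy,
                 test_n = length(test), target = target_subtype),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set for '%s': %d genes (%d comparisons)\n",
              x$target, length(x$genes), length(x$per_comparison)))
  if (!is.na(x$test_accuracy))
    cat(sprintf("  held-out nearest-centroid accuracy: %.3f (n = %d)\n",
                x$test_accuracy, x$test_n))
  invisible(x)
}
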