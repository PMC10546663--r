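# Consensus subtype discovery across gene-subset NMF runs, plus
# cross-method clustering validation.

#' Default gene subsets for consensus subtyping
#'
#' All expressed genes plus the top 5000, 2000, 1000 and 500 most variable;
#' subset sizes exceeding the gene universe fall back to all genes and
#' duplicates are dropped.
#'
#' @param expr gene-by-sample matrix (log2 TPM).
#' @param sizes variable-gene subset sizes.
#' @return Named list of gene vectors.
#' @export
default_gene_subsets <- function(expr, sizes = c(5000, 2000, 1000, 500)) {
  .check_matrix(expr, "expr")
  subs <- list(all = rownames(expr))
  for (s in sizes) {
    s_eff <- min(s, nrow(expr))
    subs[[paste0("top", s)]] <- top_variable_genes(expr, s_eff)
  }
  subs[!duplicated(lapply(subs, sort))]
}

#' Consensus subtypes across gene-subset NMF runs
#'
#' Runs NMF once per gene subset, aligns the per-subset sample assignments
#' to the first subset's labels by the label permutation maximizing
#' agreement (for two classes: identity vs swap), and flags a sample as
#' *consistent* when its aligned label is identical in every subset run.
#' Consistent samples receive a consensus label; inconsistent samples get
#' `NA`. Metagenes are extracted from the all-genes basis matrix.
#'
#' @param expr gene-by-sample matrix of log2(TPM + 1) values (non-negative).
#' @param gene_subsets named list of gene vectors; default
#'   [default_gene_subsets()].
#' @param rank number of subtypes (default 2).
#' @param n_runs NMF restarts per subset.
#' @param seed RNG seed.
#' @param ... passed to [nmf_factorize()].
#' @return Object of class `subtype_result`: `per_subset` (samples x
#'   subsets aligned label matrix), `consistent` (logical per sample),
#'   `consensus_label` (label or NA), `metagenes`, `cophenetic` (per
#'   subset), `fits` (the per-subset `nmf_result`s).
#' @export
consensus_subtypes <- function(expr, gene_subsets = NULL, rank = 2,
                               n_runs = 30, seed = NULL, ...) {
  .check_matrix(expr, "expr")
  if (is.null(gene_subsets)) gene_subsets <- default_gene_subsets(expr)
  .check(is.list(gene_subsets) && length(gene_subsets) >= 1L,
         "consensus_subtypes: gene_subsets must be a nonempty list")
  for (nm in names(gene_subsets))
    .check(length(gene_subsets[[nm]]) > 0 &&
             all(gene_subsets[[nm]] %in% rownames(expr)),
           "consensus_subtypes: subset '", nm, "' empty or not in matrix")
  fits <- vector("list", length(gene_subsets))
  names(fits) <- names(gene_subsets)
  labs <- matrix(NA_integer_, ncol(expr), length(gene_subsets),
                 dimnames = list(colnames(expr), names(gene_subsets)))
  for (i in seq_along(gene_subsets)) {
    s <- if (is.null(seed)) NULL else .sub_seed(seed, i)
    fits[[i]] <- nmf_factorize(expr[gene_subsets[[i]], , drop = FALSE],
                               rank, n_runs = n_runs, seed = s, ...)
    labs[, i] <- fits[[i]]$labels
  }
  for (i in seq_along(gene_subsets)[-1L])
    labs[, i] <- .align_labels(labs[, 1L], labs[, i], k = rank)
  consistent <- apply(labs, 1L, function(v) length(unique(v)) == 1L)
  consensus_label <- ifelse(consistent, labs[, 1L], NA_integer_)
  names(consensus_label) <- rownames(labs)
  metagenes <- extract_metagenes(fits[[1L]]$W)
  structure(list(per_subset = labs, consistent = consistent,
                 consensus_label = consensus_label, metagenes = metagenes,
                 cophenetic = vapply(fits, `[[`, numeric(1L), "cophenetic"),
                 rank = rank, fits = fits),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  n <- length(x$consistent)
  cat(sprintf("Consensus subtyping over %d gene subsets (rank %d)\n",
              ncol(x$per_subset), x$rank))
  cat(sprintf("  %d / %d samples consistently assigned (%.0f%%)\n",
              sum(x$consistent), n, 100 * mean(x$consistent)))
  tab <- table(x$consensus_label, useNA = "no")
  cat("  subtype sizes:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", "), "\n")
  cat(sprintf("  %d metagenes\n", length(x$metagenes)))
  invisible(x)
}

#' @export
summary.subtype_result <- function(object, ...) {
  print(object)
  cat("  cophenetic by subset:\n")
  print(round(object$cophenetic, 4))
  invisible(object)
}

# Resampled consensus clustering: subsample columns, cluster, accumulate
# co-assignment frequencies among co-sampled pairs, then cut the tree of
# the consensus dissimilarity.
.consensus_cluster <- function(X, k, n_resample = 1000, frac = 0.8,
                               linkage = "average") {
  m <- ncol(X)
  co <- matrix(0, m, m)
  cnt <- matrix(0, m, m)
  n_sub <- max(2L, floor(frac * m))
  for (b in seq_len(n_resample)) {
    idx <- sample.int(m, n_sub)
    lab <- cutree(hclust(dist(t(X[, idx, drop = FALSE])), linkage), k = k)
    cnt[idx, idx] <- cnt[idx, idx] + 1
    co[idx, idx] <- co[idx, idx] + outer(lab, lab, "==")
  }
  consensus <- ifelse(cnt > 0, co / cnt, 0)
  diag(consensus) <- 1
  lab <- cutree(hclust(stats::as.dist(1 - consensus), linkage), k = k)
  names(lab) <- colnames(X)
  list(labels = lab, consensus = consensus)
}

# Hierarchical clustering with plain bootstrap co-clustering support:
# resample genes with replacement, recluster, and report how often sample
# pairs assigned together on the full data stay together.
.hclust_boot <- function(X, k, n_boot = 100, linkage = "average") {
  lab <- cutree(hclust(dist(t(X)), linkage), k = k)
  m <- ncol(X)
  co <- matrix(0, m, m)
  for (b in seq_len(n_boot)) {
    gi <- sample.int(nrow(X), nrow(X), replace = TRUE)
    lb <- cutree(hclust(dist(t(X[gi, , drop = FALSE])), linkage), k = k)
    co <- co + outer(lb, lb, "==")
  }
  support <- co / n_boot
  same <- outer(lab, lab, "==")
  names(lab) <- colnames(X)
  list(labels = lab,
       mean_support = mean(support[same & upper.tri(same)]))
}

#' Cross-method clustering validation
#'
#' Clusters the samples with (a) k-means, (b) resampled consensus
#' clustering (hierarchical inner clustering on random sample subsets, then
#' a consensus cut), and (c) hierarchical clustering with bootstrap
#' co-clustering support, and reports all pairwise adjusted Rand indices,
#' plus agreement with a reference labeling when given.
#'
#' @param expr gene-by-sample matrix (log2 TPM).
#' @param genes genes to cluster on; default the top 10% most variable.
#' @param k number of clusters (>= 2).
#' @param reference optional per-sample reference labels.
#' @param n_resample consensus-clustering resamples (default 1000).
#' @param subsample_frac fraction of samples per resample (default 0.8).
#' @param n_boot gene bootstraps for hierarchical support.
#' @param linkage hierarchical linkage.
#' @param seed RNG seed.
#' @return List with per-method labels, the pairwise ARI matrix
#'   (`ari`), `ari_vs_reference`, and the bootstrap co-clustering support.
#' @export
validate_clustering <- function(expr, genes = NULL, k = 2, reference = NULL,
                                n_resample = 1000, subsample_frac = 0.8,
                                n_boot = 100, linkage = "average",
                                seed = NULL) {
  .check_matrix(expr, "expr")
  .check(k >= 2, "validate_clustering: k must be >= 2")
  .check(ncol(expr) >= k, "validate_clustering: fewer samples than clusters")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- top_variable_genes(expr, 0.10)
  X <- expr[genes, , drop = FALSE]
  km <- kmeans(t(X), centers = k, nstart = 25)$cluster
  cc <- .consensus_cluster(X, k, n_resample, subsample_frac, linkage)
  hb <- .hclust_boot(X, k, n_boot, linkage)
  labs <- list(kmeans = km, consensus = cc$labels, hierarchical = hb$labels)
  ari <- matrix(NA_real_, 3L, 3L, dimnames = list(names(labs), names(labs)))
  for (i in 1:3) for (j in 1:3)
    ari[i, j] <- adjusted_rand_index(labs[[i]], labs[[j]])
  ari_ref <- if (is.null(reference)) NULL else
    vapply(labs, adjusted_rand_index, numeric(1L), b = reference)
  list(labels = labs, ari = ari, ari_vs_reference = ari_ref,
       hierarchical_boot_support = hb$mean_support)
}
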