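# Resampled cross-species co-clustering homology test: repeated reference
# sampling, joint hierarchical clustering, a dendrogram cut that maximally
# separates two anchor groups, majority-based subtype matching, MDS
# embedding with Mahalanobis center distances, and Fisher/Wilcoxon
# statistics over the repeats.

#' Reference sampling scheme
#'
#' @param n_per_subtype tumors drawn (without replacement) per sampled
#'   subtype (default 60).
#' @param subtypes_sampled subtypes sampled at `n_per_subtype` each
#'   (default LumA, LumB, Basal, Her2).
#' @param include_all_of subtypes included in full (default Normal).
#' @param n_repeats number of random samplings (default 100).
#' @param seed RNG seed; each repeat draws from a stream derived from
#'   (seed, repeat index), so repeats are individually reproducible.
#' @return List of class `sampling_scheme`.
#' @export
sampling_scheme <- function(n_per_subtype = 60,
                            subtypes_sampled = c("LumA", "LumB", "Basal",
                                                 "Her2"),
                            include_all_of = "Normal",
                            n_repeats = 100, seed = 1L) {
  .check(n_per_subtype > 0, "sampling_scheme: n_per_subtype must be positive")
  .check(n_repeats >= 1, "sampling_scheme: n_repeats must be >= 1")
  structure(list(n_per_subtype = as.integer(n_per_subtype),
                 subtypes_sampled = subtypes_sampled,
                 include_all_of = include_all_of,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)), class = "sampling_scheme")
}

#' Draw one reference sample of the human cohort
#'
#' Draws `n_per_subtype` tumors without replacement from each sampled
#' subtype, plus every tumor of the subtypes listed in `include_all_of`.
#' Deterministic given (scheme seed, repeat index).
#'
#' @param labels named per-sample subtype labels of the reference cohort.
#' @param scheme a [sampling_scheme()].
#' @param repeat_index which repeat (1-based).
#' @return Character vector of sample ids.
#' @export
sample_reference <- function(labels, scheme, repeat_index = 1L) {
  .check(inherits(scheme, "sampling_scheme"), "scheme must be a sampling_scheme")
  .check(!is.null(names(labels)), "labels must be named by sample id")
  set.seed(.sub_seed(scheme$seed, repeat_index))
  out <- character(0)
  for (st in scheme$subtypes_sampled) {
    ids <- names(labels)[labels == st]
    if (length(ids) < scheme$n_per_subtype)
      stop("sample_reference: subtype '", st, "' has ", length(ids),
           " samples, fewer than n_per_subtype = ", scheme$n_per_subtype,
           call. = FALSE)
    out <- c(out, if (length(ids) == scheme$n_per_subtype) ids
             else sample(ids, scheme$n_per_subtype))
  }
  c(out, names(labels)[labels %in% scheme$include_all_of])
}

#' Cut a dendrogram at the minimum k that maximally separates two groups
#'
#' For each k in 2..k_max, the k-cluster cut is scored by the separation
#' purity S(k) = (#A in clusters with no B + #B in clusters with no A) /
#' (|A| + |B|). S is non-decreasing in k (splitting a cluster can only free
#' more members). The smallest k attaining the maximum S is returned.
#'
#' @param tree an [stats::hclust] tree.
#' @param groupA,groupB disjoint, nonempty sets of leaf labels.
#' @param k_max largest cut considered (default: number of leaves).
#' @return List: `k`, `clusters` (named cluster membership of the k-cut),
#'   `S` (named vector of S(k) over the scanned range).
#' @export
dendrogram_separation_cut <- function(tree, groupA, groupB, k_max = NULL) {
  .check(inherits(tree, "hclust"), "tree must be an hclust object")
  leaves <- tree$labels
  .check(length(groupA) > 0 && length(groupB) > 0,
         "dendrogram_separation_cut: groups must be nonempty")
  .check(length(intersect(groupA, groupB)) == 0,
         "dendrogram_separation_cut: groups must be disjoint")
  .check(all(c(groupA, groupB) %in% leaves),
         "dendrogram_separation_cut: groups must be leaves of the tree")
  n <- length(leaves)
  k_max <- as.integer(k_max %||% n)
  .check(k_max >= 2, "dendrogram_separation_cut: k_max must be >= 2")
  k_max <- min(k_max, n)
  cuts <- cutree(tree, k = 2:k_max)
  S <- vapply(seq_len(ncol(cuts)), function(j) {
    cl <- cuts[, j]
    a_by <- table(cl[groupA]); b_by <- table(cl[groupB])
    pureA <- setdiff(names(a_by), names(b_by))
    pureB <- setdiff(names(b_by), names(a_by))
    (sum(a_by[pureA]) + sum(b_by[pureB])) / (length(groupA) + length(groupB))
  }, numeric(1L))
  names(S) <- as.character(2:k_max)
  k <- (2:k_max)[which.max(S)]  # which.max returns the first (smallest k)
  list(k = k, clusters = cuts[, as.character(k)], S = S)
}

#' Match canine and human subtypes by cluster majorities
#'
#' A pair (canine subtype c, human subtype h) is *matched* iff some cluster
#' contains a strict majority (> 50%) of all samples of c and a strict
#' majority of all samples of h.
#'
#' @param clusters named cluster assignments covering both cohorts.
#' @param canine_labels,human_labels named per-sample subtype labels of
#'   each cohort (names must appear in `clusters`).
#' @return List: `pairs` (data frame of matched canine/human pairs, possibly
#'   empty), `canine_majority_cluster` / `human_majority_cluster` (named:
#'   the cluster holding each subtype's majority, NA when split).
#' @export
match_subtypes <- function(clusters, canine_labels, human_labels) {
  .check(!is.null(names(clusters)), "clusters must be named by sample id")
  .check(all(names(canine_labels) %in% names(clusters)) &&
           all(names(human_labels) %in% names(clusters)),
         "match_subtypes: every labeled sample must appear in clusters")
  majority_cluster <- function(labels) {
    sts <- unique(labels)
    setNames(vapply(sts, function(st) {
      ids <- names(labels)[labels == st]
      tab <- table(clusters[ids])
      w <- names(tab)[tab > length(ids) / 2]
      if (length(w)) w else NA_character_
    }, character(1L)), sts)
  }
  cm <- majority_cluster(canine_labels)
  hm <- majority_cluster(human_labels)
  pairs <- expand.grid(canine = names(cm), human = names(hm),
                       stringsAsFactors = FALSE)
  matched <- !is.na(cm[pairs$canine]) & !is.na(hm[pairs$human]) &
    cm[pairs$canine] == hm[pairs$human]
  list(pairs = pairs[matched, , drop = FALSE],
       canine_majority_cluster = cm, human_majority_cluster = hm)
}

#' Classical multidimensional scaling
#'
#' Torgerson MDS of a symmetric distance matrix; coordinate columns are
#' ordered by eigenvalue. When fewer than `d` positive eigenvalues exist
#' the remaining columns are zero-padded with a warning.
#'
#' @param distance_matrix symmetric matrix (or [stats::dist]) with zero
#'   diagonal.
#' @param d number of output dimensions (default 2).
#' @return Numeric matrix (points x d).
#' @export
mds_embed <- function(distance_matrix, d = 2) {
  if (!inherits(distance_matrix, "dist")) {
    .check(is.matrix(distance_matrix) &&
             isTRUE(all.equal(distance_matrix, t(distance_matrix))) &&
             all(abs(diag(distance_matrix)) < 1e-12),
           "mds_embed: distance matrix must be symmetric with zero diagonal")
    distance_matrix <- stats::as.dist(distance_matrix)
  }
  n <- attr(distance_matrix, "Size")
  .check(d >= 1, "mds_embed: d must be >= 1")
  co <- cmdscale(distance_matrix, k = min(d, n - 1L))
  if (!is.matrix(co)) co <- matrix(co, ncol = 1L)
  if (ncol(co) < d) {
    warning("mds_embed: requested ", d, " dimensions but only ", ncol(co),
            " supported; padding with zeros")
    co <- cbind(co, matrix(0, nrow(co), d - ncol(co)))
  }
  co
}

#' Mahalanobis distance between two group centers
#'
#' D = sqrt((muA - muB)' S^-1 (muA - muB)), with S the pooled within-group
#' covariance plus a small ridge on the diagonal.
#'
#' @param coordsA,coordsB numeric matrices (points x dims) of the two
#'   groups; each group needs at least dims + 1 points.
#' @param ridge diagonal regularization (default 1e-8).
#' @return Nonnegative scalar distance.
#' @export
mahalanobis_center_distance <- function(coordsA, coordsB, ridge = 1e-8) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  d <- ncol(coordsA)
  .check(ncol(coordsB) == d, "groups must share the embedding dimension")
  .check(nrow(coordsA) >= d + 1 && nrow(coordsB) >= d + 1,
         "mahalanobis_center_distance: each group needs >= d + 1 points")
  nA <- nrow(coordsA); nB <- nrow(coordsB)
  Sp <- ((nA - 1) * stats::cov(coordsA) + (nB - 1) * stats::cov(coordsB)) /
    (nA + nB - 2) + diag(ridge, d)
  delta <- colMeans(coordsA) - colMeans(coordsB)
  sol <- tryCatch(solve(Sp, delta), error = function(e)
    stop("mahalanobis_center_distance: singular pooled covariance",
         call. = FALSE))
  sqrt(drop(crossprod(delta, sol)))
}

#' One cross-species co-clustering run
#'
#' Merges the two cohorts on their shared panel genes, (optionally) takes
#' log2(TPM + 1), row z-scales the merged matrix jointly, clusters all
#' samples hierarchically (Euclidean distance), cuts the dendrogram at the
#' minimum k maximally separating the two human anchor groups, and matches
#' subtypes by cluster majorities. Also returns a 2-D MDS embedding and the
#' Mahalanobis center distances between all species-subtype groups.
#'
#' @param canine_expr,human_expr gene-by-sample matrices of the two cohorts.
#' @param canine_labels,human_labels named per-sample subtype labels.
#' @param panel panel genes to merge on (>= 3 must be shared).
#' @param groupA_label,groupB_label the two human subtypes whose separation
#'   drives the dendrogram cut (defaults Basal vs LumA).
#' @param unit `"log2tpm"` (values used as-is) or `"tpm"` (log2(x+1) taken).
#' @param linkage hierarchical linkage (default average).
#' @param k_max largest dendrogram cut scanned (default 30). Because S(k)
#'   always reaches 1 once every stray tumor is carved into its own
#'   cluster, an uncapped scan would shatter overlapping cohorts; the cap
#'   keeps the cut at the cluster granularity at which subtype majorities
#'   are meaningful.
#' @param mds_dims dimensions of the MDS embedding used for the
#'   Mahalanobis statistic (default 2).
#' @return List: `cut` (k, clusters, S), `match` (from [match_subtypes()]),
#'   `mds` (coordinates), `center_distances` (named pairwise Mahalanobis
#'   distances between species:subtype groups), `groups` (per-sample
#'   species:subtype).
#' @export
cocluster_once <- function(canine_expr, human_expr, canine_labels,
                           human_labels, panel,
                           groupA_label = "Basal", groupB_label = "LumA",
                           unit = c("log2tpm", "tpm"), linkage = "average",
                           k_max = 30, mds_dims = 2) {
  unit <- match.arg(unit)
  .check_matrix(canine_expr, "canine_expr")
  .check_matrix(human_expr, "human_expr")
  shared <- intersect(intersect(panel, rownames(canine_expr)),
                      rownames(human_expr))
  if (length(shared) < 3L)
    stop("cocluster_once: fewer than 3 shared panel genes", call. = FALSE)
  M <- cbind(canine_expr[shared, names(canine_labels), drop = FALSE],
             human_expr[shared, names(human_labels), drop = FALSE])
  if (unit == "tpm") M <- log2(M + 1)
  Z <- row_zscale(M)
  D <- dist(t(Z))
  tree <- hclust(D, method = linkage)
  A <- names(human_labels)[human_labels == groupA_label]
  B <- names(human_labels)[human_labels == groupB_label]
  cut <- dendrogram_separation_cut(tree, A, B, k_max = k_max)
  match <- match_subtypes(cut$clusters, canine_labels, human_labels)
  co <- mds_embed(D, mds_dims)
  rownames(co) <- colnames(Z)
  groups <- c(paste0("canine:", canine_labels),
              paste0("human:", human_labels))
  names(groups) <- c(names(canine_labels), names(human_labels))
  grp_names <- unique(groups)
  cd <- c()
  for (i in seq_along(grp_names)) for (j in seq_along(grp_names)) {
    if (j <= i) next
    gi <- names(groups)[groups == grp_names[i]]
    gj <- names(groups)[groups == grp_names[j]]
    if (length(gi) <= mds_dims || length(gj) <= mds_dims) next
    cd[paste(grp_names[i], grp_names[j], sep = "|")] <-
      mahalanobis_center_distance(co[gi, , drop = FALSE],
                                  co[gj, , drop = FALSE])
  }
  list(cut = cut, match = match, mds = co, center_distances = cd,
       groups = groups)
}

#' Resampled cross-species homology experiment
#'
#' Repeats [cocluster_once()] over random reference samplings of the human
#' cohort ([sample_reference()]), tallies how often each (canine, human)
#' subtype pair matches, and summarizes:
#' * a 2x2 Fisher exact test comparing how often the target canine subtype
#'   matches the target human subtype vs how often the other canine subtype
#'   matches *any* human subtype (rows sum to the number of repeats);
#' * Wilcoxon rank-sum tests comparing the per-repeat Mahalanobis distance
#'   of the target (homologous) pair with every other cross/within-species
#'   pair involving the same subtypes;
#' * a post-hoc coverage check that every reference sample was drawn at
#'   least once.
#'
#' @param canine_expr,canine_labels canine cohort (log2 TPM + labels).
#' @param human_expr,human_labels human cohort (log2 TPM + labels).
#' @param panel panel genes.
#' @param scheme a [sampling_scheme()].
#' @param target_pair named character vector `c(canine = ..., human = ...)`
#'   giving the putatively homologous pair (defaults: first canine subtype,
#'   `groupA_label`).
#' @param other_canine the comparison canine subtype (default: the other).
#' @param ... passed to [cocluster_once()].
#' @inheritParams cocluster_once
#' @return Object of class `homology_result`.
#' @export
homology_experiment <- function(canine_expr, canine_labels, human_expr,
                                human_labels, panel, scheme,
                                target_pair = NULL, other_canine = NULL,
                                groupA_label = "Basal",
                                groupB_label = "LumA", ...) {
  .check(inherits(scheme, "sampling_scheme"), "scheme must be a sampling_scheme")
  .check(!is.null(names(canine_labels)) && !is.null(names(human_labels)),
         "labels must be named by sample id")
  canine_sts <- unique(canine_labels)
  if (is.null(target_pair))
    target_pair <- c(canine = canine_sts[1L], human = groupA_label)
  if (is.null(other_canine))
    other_canine <- setdiff(canine_sts, target_pair[["canine"]])[1L]
  n_rep <- scheme$n_repeats
  pair_counts <- new.env(parent = emptyenv())
  other_matched_any <- 0L
  dist_records <- vector("list", n_rep)
  repeats <- vector("list", n_rep)
  sampled <- character(0)
  for (r in seq_len(n_rep)) {
    ids <- sample_reference(human_labels, scheme, r)
    sampled <- union(sampled, ids)
    rec <- cocluster_once(canine_expr, human_expr, canine_labels,
                          human_labels[ids], panel,
                          groupA_label = groupA_label,
                          groupB_label = groupB_label, ...)
    if (nrow(rec$match$pairs)) for (i in seq_len(nrow(rec$match$pairs))) {
      key <- paste(rec$match$pairs$canine[i], rec$match$pairs$human[i],
                   sep = "|")
      pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
    }
    if (other_canine %in% rec$match$pairs$canine)
      other_matched_any <- other_matched_any + 1L
    dist_records[[r]] <- rec$center_distances
    repeats[[r]] <- list(k = rec$cut$k, S = max(rec$cut$S),
                         pairs = rec$match$pairs,
                         center_distances = rec$center_distances)
  }
  counts <- unlist(as.list(pair_counts))
  if (is.null(counts)) counts <- integer(0)
  target_key <- paste(target_pair[["canine"]], target_pair[["human"]],
                      sep = "|")
  n_target <- if (target_key %in% names(counts)) counts[[target_key]] else 0L
  fisher_table <- matrix(c(n_target, n_rep - n_target,
                           other_matched_any, n_rep - other_matched_any),
                         2L, 2L, byrow = TRUE,
                         dimnames = list(
                           c(paste0(target_pair[["canine"]], "~",
                                    target_pair[["human"]]),
                             paste0(other_canine, "~any")),
                           c("matched", "unmatched")))
  fisher <- fisher_exact_2x2(fisher_table)
  # Distance distributions over repeats for pairs involving the subtypes of
  # interest; the homologous pair should be stochastically smallest.
  all_keys <- unique(unlist(lapply(dist_records, names)))
  dist_by_pair <- lapply(setNames(all_keys, all_keys), function(k)
    vapply(dist_records, function(d) d[k] %||% NA_real_, numeric(1L)))
  homol_key <- .find_pair_key(all_keys, paste0("canine:", target_pair[["canine"]]),
                              paste0("human:", target_pair[["human"]]))
  wilcoxon <- NULL
  if (!is.na(homol_key)) {
    x <- dist_by_pair[[homol_key]]
    others <- setdiff(all_keys, homol_key)
    wilcoxon <- vapply(setNames(others, others), function(k) {
      y <- dist_by_pair[[k]]
      wilcoxon_rank_sum(x[!is.na(x)], y[!is.na(y)])$p.value
    }, numeric(1L))
  }
  structure(list(
    pair_counts = counts, n_repeats = n_rep, target_pair = target_pair,
    other_canine = other_canine, other_matched_any = other_matched_any,
    fisher_table = fisher_table, fisher = fisher,
    distance_by_pair = dist_by_pair, homologous_key = homol_key,
    wilcoxon_p = wilcoxon, repeats = repeats,
    coverage = length(sampled) /
      sum(human_labels %in% c(scheme$subtypes_sampled,
                              scheme$include_all_of))),
    class = "homology_result")
}

.find_pair_key <- function(keys, a, b) {
  hit <- keys %in% c(paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  if (any(hit)) keys[hit][1L] else NA_character_
}

#' @export
print.homology_result <- function(x, ...) {
  cat(sprintf("Cross-species homology experiment (%d repeats)\n",
              x$n_repeats))
  cat(sprintf("  target pair %s ~ %s matched in %d / %d repeats\n",
              x$target_pair[["canine"]], x$target_pair[["human"]],
              x$fisher_table[1L, 1L], x$n_repeats))
  cat(sprintf("  %s matched any human subtype in %d / %d repeats\n",
              x$other_canine, x$other_matched_any, x$n_repeats))
  cat(sprintf("  Fisher exact p = %.3g (odds ratio %.3g)\n",
              x$fisher$p.value, x$fisher$odds_ratio))
  cat(sprintf("  reference coverage: %.0f%% of tumors drawn at least once\n",
              100 * x$coverage))
  invisible(x)
}

#' @export
summary.homology_result <- function(object, ...) {
  print(object)
  cat("  per-pair match counts:\n")
  print(object$pair_counts)
  if (!is.null(object$wilcoxon_p)) {
    cat("  Wilcoxon p, homologous-pair distance vs other pairs:\n")
    print(signif(object$wilcoxon_p, 3))
  }
  invisible(object)
}
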