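# Panel-based nearest-centroid subtype classification (PAM50-style),
# tolerant of partial panels.

# Canonical intrinsic-subtype order used for deterministic tie-breaking.
.subtype_order <- c("Basal", "Her2", "LumA", "LumB", "Normal")

#' Intersect a gene panel with an annotation's gene universe
#'
#' @param panel character vector of panel gene symbols (unique).
#' @param annotation_genes gene symbols available in the annotation.
#' @return The panel genes present in the annotation, original order
#'   preserved, with the missing genes attached as attribute `missing`.
#'   Warns when fewer than half of the panel survives.
#' @export
intersect_panel <- function(panel, annotation_genes) {
  .check(!anyDuplicated(panel), "intersect_panel: panel symbols must be unique")
  keep <- panel[panel %in% annotation_genes]
  attr(keep, "missing") <- setdiff(panel, keep)
  if (length(keep) < length(panel) / 2)
    warning(sprintf(
      "intersect_panel: only %d of %d panel genes found in the annotation",
      length(keep), length(panel)))
  keep
}

#' Train a nearest-centroid model from a labeled reference
#'
#' Fits per-gene standardization (mean/sd) on the reference expression over
#' the panel genes, then takes the per-subtype, per-gene *median* of the
#' standardized profiles as the subtype centroid.
#'
#' @param ref_expr gene-by-sample matrix of log2(TPM + 1) reference values.
#' @param labels per-sample subtype labels (length = ncol(ref_expr)).
#' @param panel gene panel; genes absent from the matrix are dropped (with
#'   the usual [intersect_panel()] warning below 50% coverage).
#' @return Object of class `centroid_model`: `centroids` (genes x
#'   subtypes), `center`/`scale` (training standardization), `panel`,
#'   `subtypes`.
#' @export
build_centroids <- function(ref_expr, labels, panel) {
  .check_matrix(ref_expr, "ref_expr")
  .check(length(labels) == ncol(ref_expr),
         "build_centroids: one label per reference sample required")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("build_centroids: subtype(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  genes <- intersect_panel(panel, rownames(ref_expr))
  .check(length(genes) >= 3L, "build_centroids: fewer than 3 panel genes present")
  X <- ref_expr[genes, , drop = FALSE]
  ctr <- rowMeans(X)
  scl <- apply(X, 1L, sd)
  keep <- scl > 0
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
    genes <- genes[keep]
  }
  .check(length(genes) >= 3L,
         "build_centroids: fewer than 3 panel genes with nonzero variance")
  Z <- (X - ctr) / scl
  subtypes <- sort(unique(labels))
  centroids <- vapply(subtypes, function(st)
    apply(Z[, labels == st, drop = FALSE], 1L, median), numeric(nrow(Z)))
  dimnames(centroids) <- list(genes, subtypes)
  structure(list(centroids = centroids, center = ctr, scale = scl,
                 panel = genes, subtypes = subtypes),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("Nearest-centroid model: %d panel genes, %d subtypes (%s)\n",
              length(x$panel), length(x$subtypes),
              paste(x$subtypes, collapse = ", ")))
  invisible(x)
}

#' Classify samples against trained centroids
#'
#' Each sample is correlated (Spearman) with every subtype centroid over
#' the panel genes shared between the model and the expression matrix; the
#' call is the centroid with the highest correlation and the confidence is
#' that winning correlation (the margin to the runner-up is also reported).
#' Because the correlation is rank-based, calls are invariant to any
#' strictly monotone per-sample transform of expression. Samples constant
#' over the panel are labeled `"unclassified"`. Exact ties are broken by
#' the fixed intrinsic order Basal, Her2, LumA, LumB, Normal (unknown
#' subtype names follow, alphabetically).
#'
#' @param object a `centroid_model`.
#' @param expr gene-by-sample matrix to classify (log2 TPM or any
#'   per-sample monotone transform thereof).
#' @param ... unused.
#' @return Data frame: sample, label, confidence, margin.
#' @export
predict.centroid_model <- function(object, expr, ...) {
  .check_matrix(expr, "expr")
  genes <- intersect(object$panel, rownames(expr))
  .check(length(genes) >= 3L,
         "classify: fewer than 3 panel genes present in the matrix")
  cent <- object$centroids[genes, , drop = FALSE]
  ord <- c(intersect(.subtype_order, colnames(cent)),
           sort(setdiff(colnames(cent), .subtype_order)))
  cent <- cent[, ord, drop = FALSE]
  cent_rank <- apply(cent, 2L, rank)
  X <- expr[genes, , drop = FALSE]
  out <- data.frame(sample = colnames(X), label = NA_character_,
                    confidence = NA_real_, margin = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (sd(x) == 0) { out$label[j] <- "unclassified"; next }
    r <- cor(rank(x), cent_rank)[1L, ]
    best <- which.max(r)  # first max = fixed-order tie-break
    out$label[j] <- colnames(cent)[best]
    out$confidence[j] <- r[best]
    out$margin[j] <- if (ncol(cent) > 1L)
      r[best] - max(r[-best]) else NA_real_
  }
  out
}

#' @rdname predict.centroid_model
#' @param model a `centroid_model` from [build_centroids()].
#' @export
classify_samples <- function(expr, model) {
  .check(inherits(model, "centroid_model"),
         "classify_samples: model must be a centroid_model")
  predict(model, expr)
}
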