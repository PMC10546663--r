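# Expression filtering, scaling, batch correction, receptor-status calls.

#' Filter to expressed genes
#'
#' Keeps the named genes whose FPKM reaches `min_fpkm` in at least
#' `min_samples` samples (the "expressed in at least one sample" rule at the
#' defaults).
#'
#' @param fpkm gene-by-sample FPKM matrix.
#' @param named_genes candidate genes (must be rows of `fpkm`); defaults to
#'   all rows.
#' @param min_fpkm expression threshold (inclusive), default 1.
#' @param min_samples minimum number of samples at or above the threshold,
#'   default 1.
#' @return Character vector of genes passing the filter (warns if empty).
#' @export
filter_expressed_genes <- function(fpkm, named_genes = rownames(fpkm),
                                   min_fpkm = 1, min_samples = 1) {
  .check_matrix(fpkm, "fpkm")
  .check(all(named_genes %in% rownames(fpkm)),
         "filter_expressed_genes: named_genes must be rows of the matrix")
  n_hit <- rowSums(fpkm[named_genes, , drop = FALSE] >= min_fpkm)
  keep <- named_genes[n_hit >= min_samples]
  if (length(keep) == 0L)
    warning("filter_expressed_genes: no gene passed the expression filter")
  keep
}

#' Top variable genes
#'
#' Ranks genes by variance (descending) and returns the top `k`. Ties are
#' broken by gene-id lexicographic order so the result is deterministic.
#'
#' @param expr gene-by-sample matrix (log2 TPM recommended).
#' @param k either an integer count or a fraction in (0, 1\] of the genes
#'   (`k = 0.10` gives the top 10% most variable genes).
#' @return Character vector of gene names.
#' @export
top_variable_genes <- function(expr, k) {
  .check_matrix(expr, "expr")
  .check(is.numeric(k) && length(k) == 1L && k > 0,
         "top_variable_genes: k must be a positive count or fraction")
  n <- nrow(expr)
  if (k < 1) k <- floor(k * n)
  k <- as.integer(k)
  .check(k >= 1L && k <= n, "top_variable_genes: k exceeds the gene count")
  v <- apply(expr, 1L, var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord[seq_len(k)]]
}

#' Row-wise z-scaling
#'
#' Centers each row to mean 0 and scales to unit standard deviation (sample
#' sd, n-1 denominator, the heatmap-scaling convention). Constant rows map
#' to all zeros rather than NaN.
#'
#' @param expr numeric matrix.
#' @return Matrix of the same dimensions.
#' @export
row_zscale <- function(expr) {
  .check(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  m <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  out <- (expr - m) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Parametric location-scale batch adjustment on log-scale expression:
#' standardize per gene, estimate per-batch location and scale, shrink
#' toward batch-level priors, adjust and back-transform. A single batch is
#' an identity transform. Genes that are constant across all samples are
#' passed through unchanged.
#'
#' @param expr gene-by-sample matrix of log2(TPM + 1) values.
#' @param batch per-sample batch labels (length = ncol(expr)).
#' @return Corrected matrix of the same dimensions.
#' @export
combat_correct <- function(expr, batch) {
  .check_matrix(expr, "expr")
  .check(length(batch) == ncol(expr),
         "combat_correct: one batch label per sample required")
  batch <- as.character(batch)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("combat_correct: batch(es) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  if (length(tab) == 1L) return(expr)
  keep <- apply(expr, 1L, var) > 0
  out <- expr
  if (any(keep)) {
    adj <- suppressMessages(
      sva::ComBat(dat = expr[keep, , drop = FALSE], batch = batch))
    out[keep, ] <- adj
  }
  out
}

#' Receptor thresholds
#'
#' @param er_pr_fpkm FPKM threshold for ER/PR positivity (call is positive
#'   strictly above, negative at or below), default 1.
#' @param her2_fpkm FPKM threshold for HER2 enrichment, default 35.
#' @return List of class `receptor_thresholds`.
#' @export
receptor_thresholds <- function(er_pr_fpkm = 1, her2_fpkm = 35) {
  .check(er_pr_fpkm > 0 && her2_fpkm > 0,
         "receptor_thresholds: thresholds must be positive")
  structure(list(er_pr_fpkm = er_pr_fpkm, her2_fpkm = her2_fpkm),
            class = "receptor_thresholds")
}

#' Call ER/PR/HER2 status from marker-gene FPKM
#'
#' ER (ESR1) and PR (PGR) are positive iff FPKM strictly exceeds the ER/PR
#' threshold; HER2 (ERBB2) is enriched iff FPKM strictly exceeds the HER2
#' threshold. The ER/PR calls compose the four-way subgroup label.
#'
#' @param fpkm gene-by-sample FPKM matrix.
#' @param marker_genes named character vector with entries `ER`, `PR`,
#'   `HER2` naming the marker genes.
#' @param thresholds a [receptor_thresholds()].
#' @return Data frame with columns sample, ER, PR, HER2, subgroup.
#' @export
call_receptor_status <- function(fpkm,
                                 marker_genes = c(ER = "ESR1", PR = "PGR",
                                                  HER2 = "ERBB2"),
                                 thresholds = receptor_thresholds()) {
  .check_matrix(fpkm, "fpkm")
  .check(all(c("ER", "PR", "HER2") %in% names(marker_genes)),
         "call_receptor_status: marker_genes must name ER, PR and HER2")
  missing <- setdiff(unname(marker_genes[c("ER", "PR", "HER2")]),
                     rownames(fpkm))
  if (length(missing))
    stop("call_receptor_status: marker gene(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  er <- ifelse(fpkm[marker_genes[["ER"]], ] > thresholds$er_pr_fpkm,
               "pos", "neg")
  pr <- ifelse(fpkm[marker_genes[["PR"]], ] > thresholds$er_pr_fpkm,
               "pos", "neg")
  her2 <- ifelse(fpkm[marker_genes[["HER2"]], ] > thresholds$her2_fpkm,
                 "enriched", "not_enriched")
  subgroup <- paste0("ER", ifelse(er == "pos", "+", "-"),
                     "PR", ifelse(pr == "pos", "+", "-"))
  data.frame(sample = colnames(fpkm), ER = unname(er), PR = unname(pr),
             HER2 = unname(her2), subgroup = subgroup,
             stringsAsFactors = FALSE)
}
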