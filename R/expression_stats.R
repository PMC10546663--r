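# Downstream expression statistics: size factors, NB Wald differential
# expression, ssGSEA scoring, dual-coefficient correlation screens, and
# subgroup crosstabs.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over genes with positive
#' counts in every sample, of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts gene-by-sample count matrix.
#' @return Named per-sample factors.
#' @export
size_factors <- function(counts) {
  .check_matrix(counts, "counts")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("size_factors: no gene has positive counts in all samples",
         call. = FALSE)
  sub <- counts[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2L, median)
  setNames(sf, colnames(counts))
}

#' Negative-binomial Wald differential expression
#'
#' Two-group DE test: counts are normalized by median-of-ratios size
#' factors; a per-gene NB dispersion is estimated by method of moments from
#' the pooled within-group variance and shrunk 50/50 toward a fitted
#' mean-dispersion trend (a0 + a1/mu); the log2 fold change is tested by a
#' Wald statistic whose standard error comes from the NB information,
#' Var(log mean) ~ (1/mu + alpha)/n per group. P-values are BH adjusted and
#' genes are flagged significant when |log2FC| >= log2(fold_cutoff) and the
#' adjusted p is at or below `alpha`.
#'
#' @param counts gene-by-sample count matrix.
#' @param groups per-sample factor with exactly two levels, each with >= 3
#'   samples. The fold change is level2 over level1.
#' @param fold_cutoff fold-change cutoff (default 2).
#' @param alpha adjusted-p cutoff (default 0.05; 0.01 for stricter screens).
#' @return Data frame of class `de_result`: gene, baseMean, log2FC,
#'   dispersion, p, padj, significant.
#' @export
nb_wald_de <- function(counts, groups, fold_cutoff = 2, alpha = 0.05) {
  .check_matrix(counts, "counts")
  groups <- as.factor(groups)
  .check(nlevels(groups) == 2L, "nb_wald_de: exactly two groups required")
  .check(length(groups) == ncol(counts),
         "nb_wald_de: one group label per sample required")
  tab <- table(groups)
  if (any(tab < 3L))
    stop("nb_wald_de: group(s) with fewer than 3 samples: ",
         paste(names(tab)[tab < 3L], collapse = ", "), call. = FALSE)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  g1 <- groups == levels(groups)[1L]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1L, var)
  v2 <- apply(norm[, g2, drop = FALSE], 1L, var)
  v_pool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m_pool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  # Method-of-moments dispersion, floored, then shrunk toward a trend.
  disp_mom <- pmax((v_pool - m_pool) / m_pool^2, 1e-8)
  disp_mom[!is.finite(disp_mom)] <- 1e-8
  use <- m_pool > 1 & is.finite(disp_mom)
  if (sum(use) >= 10L) {
    fit <- stats::lm(disp_mom[use] ~ I(1 / m_pool[use]))
    trend <- pmax(stats::coef(fit)[1L] + stats::coef(fit)[2L] / m_pool, 1e-8)
  } else trend <- rep(median(disp_mom), length(disp_mom))
  disp <- 0.5 * disp_mom + 0.5 * trend
  pc <- 0.5
  lfc <- log2((m2 + pc) / (m1 + pc))
  se <- sqrt((1 / (m1 + pc) + disp) / n1 + (1 / (m2 + pc) + disp) / n2) /
    log(2)
  z <- lfc / se
  p <- 2 * pt(-abs(z), df = n1 + n2 - 2)
  p[m1 == 0 & m2 == 0] <- 1
  # a gene with identical raw counts in every sample carries no evidence
  constant <- rowSums(counts != counts[, 1L]) == 0L
  lfc[constant] <- 0
  p[constant] <- 1
  padj <- bh_adjust(p)
  out <- data.frame(gene = rownames(counts),
                    baseMean = rowMeans(norm),
                    log2FC = lfc, dispersion = disp, p = p, padj = padj,
                    significant = abs(lfc) >= log2(fold_cutoff) &
                      padj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Single-sample gene set enrichment score
#'
#' Ranks the sample's genes by expression (descending; ties broken by gene
#' id so the score is deterministic), and walks the ranked list
#' accumulating the difference between the weighted empirical distribution
#' of set members (member at rank position i weighted by |N - i + 1|^alpha,
#' i.e. its rank from the bottom) and the uniform empirical distribution of
#' non-members. The score is the sum of the running difference. At
#' alpha = 0 the score depends on ranks only, so any strictly monotone
#' transform of the expression leaves it unchanged.
#'
#' @param expr_sample named per-gene expression values of one sample.
#' @param gene_set character vector of member genes; the intersection with
#'   the sample's genes must be nonempty and proper.
#' @param alpha rank-weight exponent (default 0.75).
#' @return Scalar enrichment score.
#' @export
ssgsea_score <- function(expr_sample, gene_set, alpha = 0.75) {
  .check(!is.null(names(expr_sample)), "expr_sample must be named by gene")
  .check(alpha >= 0, "ssgsea_score: alpha must be >= 0")
  genes <- names(expr_sample)
  inset <- genes %in% gene_set
  n_in <- sum(inset)
  if (n_in == 0L || n_in == length(genes))
    stop("ssgsea_score: gene set must cover some but not all genes",
         call. = FALSE)
  ord <- order(-expr_sample, genes)
  inset <- inset[ord]
  N <- length(genes)
  w <- (N - seq_len(N) + 1)^alpha
  w_in <- w * inset
  P_in <- cumsum(w_in) / sum(w_in)
  P_out <- cumsum(!inset) / (N - n_in)
  sum(P_in - P_out)
}

#' ssGSEA scores for a matrix of samples and a list of gene sets
#'
#' @param expr gene-by-sample matrix.
#' @param gene_sets named list of gene sets (e.g. from [read_gmt()]).
#' @inheritParams ssgsea_score
#' @param normalize divide all scores by the global score range.
#' @return Matrix of scores, sets x samples.
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.75, normalize = FALSE) {
  .check_matrix(expr, "expr")
  .check(is.list(gene_sets) && !is.null(names(gene_sets)),
         "gene_sets must be a named list")
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- setNames(expr[, j], rownames(expr))
    vapply(gene_sets, function(gs) ssgsea_score(x, gs, alpha), numeric(1L))
  }, numeric(length(gene_sets)))
  scores <- matrix(scores, nrow = length(gene_sets),
                   dimnames = list(names(gene_sets), colnames(expr)))
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Dual Pearson/Spearman correlation screen against a target gene
#'
#' Restricts to the given subtype samples, keeps genes expressed above
#' `min_fpkm` in at least `min_frac` of those samples, and correlates each
#' passing gene with the target using both Pearson and Spearman
#' coefficients. Each coefficient's p-value family is BH adjusted
#' separately. A gene is a positive hit when both coefficients exceed
#' `r_cutoff` and both adjusted p-values are below `alpha`; negative hits
#' symmetrically with both coefficients below `-r_cutoff`. If the target
#' gene itself fails the expression filter the screen is skipped (empty
#' result with a message).
#'
#' @param expr gene-by-sample expression used for the correlations (log2
#'   TPM recommended).
#' @param target_gene gene the screen correlates against.
#' @param samples sample ids of the subtype screened (>= 5).
#' @param r_cutoff coefficient magnitude cutoff (default 0.3).
#' @param alpha BH-adjusted p cutoff (default 0.05).
#' @param fpkm FPKM matrix used for the expression filter; defaults to
#'   `expr`.
#' @param min_fpkm,min_frac expression filter: FPKM > `min_fpkm` in at
#'   least `min_frac` of the subtype samples (defaults 1 and 0.10).
#' @return Data frame: gene, pearson_r, pearson_p, pearson_padj,
#'   spearman_r, spearman_p, spearman_padj, direction ("positive",
#'   "negative" or "none").
#' @export
correlation_screen <- function(expr, target_gene, samples = colnames(expr),
                               r_cutoff = 0.3, alpha = 0.05, fpkm = expr,
                               min_fpkm = 1, min_frac = 0.10) {
  .check_matrix(expr, "expr")
  .check(target_gene %in% rownames(expr),
         "correlation_screen: target gene not in matrix")
  .check(all(samples %in% colnames(expr)),
         "correlation_screen: unknown sample id(s)")
  if (length(samples) < 5L)
    stop("correlation_screen: fewer than 5 samples", call. = FALSE)
  f <- fpkm[, samples, drop = FALSE]
  pass <- rownames(f)[rowMeans(f > min_fpkm) >= min_frac]
  empty <- data.frame(gene = character(0), pearson_r = numeric(0),
                      pearson_p = numeric(0), pearson_padj = numeric(0),
                      spearman_r = numeric(0), spearman_p = numeric(0),
                      spearman_padj = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (!target_gene %in% pass) {
    message("correlation_screen: target '", target_gene,
            "' fails the expression filter in this subtype; skipped")
    return(empty)
  }
  genes <- setdiff(pass, target_gene)
  if (!length(genes)) return(empty)
  x <- expr[target_gene, samples]
  pe <- t(vapply(genes, function(g) {
    ct <- suppressWarnings(cor.test(x, expr[g, samples], method = "pearson"))
    c(ct$estimate, ct$p.value)
  }, numeric(2L)))
  sp <- t(vapply(genes, function(g) {
    ct <- suppressWarnings(cor.test(x, expr[g, samples], method = "spearman",
                                    exact = FALSE))
    c(ct$estimate, ct$p.value)
  }, numeric(2L)))
  out <- data.frame(gene = genes,
                    pearson_r = pe[, 1L], pearson_p = pe[, 2L],
                    pearson_padj = bh_adjust(pe[, 2L]),
                    spearman_r = sp[, 1L], spearman_p = sp[, 2L],
                    spearman_padj = bh_adjust(sp[, 2L]),
                    stringsAsFactors = FALSE, row.names = NULL)
  sig <- out$pearson_padj < alpha & out$spearman_padj < alpha
  out$direction <- ifelse(
    sig & out$pearson_r > r_cutoff & out$spearman_r > r_cutoff, "positive",
    ifelse(sig & out$pearson_r < -r_cutoff & out$spearman_r < -r_cutoff,
           "negative", "none"))
  out
}

#' Two-way crosstab with column percentages
#'
#' Contingency counts of two per-sample categorical labelings over the same
#' sample universe, with column and row percentages rounded to integers and
#' marginals.
#'
#' @param labels_a,labels_b equal-length category vectors (e.g. PAM50 call
#'   and ER/PR subgroup), or a preformed counts matrix passed as `counts`.
#' @param counts optional: a counts matrix to summarize directly (then
#'   `labels_a`/`labels_b` are ignored).
#' @return List of class `crosstab`: `counts`, `col_pct`, `row_pct`,
#'   `row_totals`, `col_totals`, `n`.
#' @export
subgroup_crosstab <- function(labels_a = NULL, labels_b = NULL,
                              counts = NULL) {
  if (is.null(counts)) {
    .check(length(labels_a) == length(labels_b),
           "subgroup_crosstab: label vectors must have equal length")
    counts <- unclass(table(labels_a, labels_b))
    names(dimnames(counts)) <- NULL
  } else {
    .check(is.matrix(counts) && all(counts >= 0),
           "subgroup_crosstab: counts must be a nonnegative matrix")
  }
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  col_pct <- round(sweep(counts, 2L, pmax(col_tot, 1), "/") * 100)
  row_pct <- round(sweep(counts, 1L, pmax(row_tot, 1), "/") * 100)
  structure(list(counts = counts, col_pct = col_pct, row_pct = row_pct,
                 row_totals = row_tot, col_totals = col_tot,
                 n = sum(counts)), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Crosstab (n =", x$n, ")\ncounts:\n")
  print(x$counts)
  cat("column %:\n")
  print(x$col_pct)
  invisible(x)
}
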