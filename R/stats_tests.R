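# Exact statistical primitives used across the pipeline.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed
#' table. The odds ratio reported is the sample odds ratio ad/bc.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return List with `odds_ratio` and `p.value`.
#' @export
fisher_exact_2x2 <- function(table) {
  .check(is.matrix(table) && all(dim(table) == 2L),
         "fisher_exact_2x2: a 2x2 matrix is required")
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_exact_2x2: counts must be nonnegative integers",
         call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  list(odds_ratio = or, p.value = p)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided. When n + m <= 12 and there are no ties, the p-value is exact,
#' by enumerating all choose(n + m, n) group assignments of the ranks.
#' Otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y nonempty numeric vectors.
#' @return List with `U` (Mann-Whitney statistic of `x`), `p.value`, and
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(x, y) {
  .check(length(x) > 0 && length(y) > 0,
         "wilcoxon_rank_sum: both samples must be nonempty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (n + m <= 12L && !ties) {
    center <- n * m / 2
    dev_obs <- abs(U - center)
    sets <- combn(n + m, n)
    allr <- seq_len(n + m)
    devs <- apply(sets, 2L, function(idx)
      abs(sum(allr[idx]) - n * (n + 1) / 2 - center))
    p <- mean(devs >= dev_obs - 1e-9)
    return(list(U = U, p.value = p, method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0) return(list(U = U, p.value = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(U = U, p.value = p, method = "normal")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p ascending, q_i =
#' p_i * m / i, enforce monotonicity from the largest down, cap at 1, and
#' restore the original order. Backed by [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}
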