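# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

.check_matrix <- function(x, what = "x") {
  .check(is.matrix(x) && is.numeric(x), what, " must be a numeric matrix")
  .check(!is.null(rownames(x)), what, " must have rownames (gene identifiers)")
  .check(!is.null(colnames(x)), what, " must have colnames (sample identifiers)")
  invisible(TRUE)
}

# All permutations of 1..n as rows (n small; used for label alignment).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

# Align integer labels `x` (values 1..k) to a reference labeling by the
# permutation of label codes that maximizes agreement. Invariant to
# permutation of the input codes by construction.
.align_labels <- function(ref, x, k = max(ref, x)) {
  .check(length(ref) == length(x), "label vectors must have equal length")
  if (k > 7L) stop("label alignment supports at most 7 classes", call. = FALSE)
  perms <- .permutations(k)
  agree <- apply(perms, 1L, function(p) sum(p[x] == ref))
  p <- perms[which.max(agree), ]
  p[x]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length.
#' @return A scalar in \[-1, 1\]; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  .check(length(a) == length(b), "label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}

# Derive a per-repeat seed from a base seed; kept below 2^31.
.sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587)
}
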