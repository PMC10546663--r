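# Plain-text readers/writers for the formats the pipeline consumes:
# gene-by-sample expression TSV, sample metadata TSV, GMT gene sets,
# one-symbol-per-line gene panels.

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column is the gene identifier, remaining columns are samples.
#'
#' @param path path to a tab-separated file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expr_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check(ncol(df) >= 2L, "expression TSV needs a gene column plus >=1 sample")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a gene-by-sample expression matrix to TSV
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param gene_col name of the gene-identifier column.
#' @export
write_expr_tsv <- function(expr, path, gene_col = "gene") {
  .check_matrix(expr, "expr")
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path path to a .gmt file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    .check(length(parts) >= 3L, "malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

#' Read a gene panel (one symbol per line)
#'
#' @param path path to a plain-text gene list.
#' @return Character vector of unique symbols, input order preserved.
#' @export
read_gene_panel <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  unique(g[nzchar(g)])
}

#' Write a simulated cohort to disk
#'
#' Writes counts (TSV), sample metadata (TSV), and the ground truth (JSON)
#' so external tools can consume a simulated cohort.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  .check(inherits(cohort, "sim_cohort"), "cohort must be a sim_cohort")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    meta = file.path(dir, "meta.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expr_tsv(cohort$counts, paths[["counts"]])
  write.table(cohort$meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(
    data.frame(gene = rownames(cohort$counts), length = cohort$gene_lengths),
    paths[["lengths"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
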