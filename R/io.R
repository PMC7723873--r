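#' Read a tumors-by-genes mutation matrix from TSV
#'
#' The expected dialect is a tab-separated file whose header row names the
#' genes and whose first column holds tumor identifiers.  Raw somatic
#' profiles are binary (a gene is either altered in a tumor or not);
#' propagated profiles hold smoothed values in \[0, 1\].
#'
#' @param path Path to the TSV file.
#' @param binary If `TRUE`, any strictly positive value is coerced to 1 and
#'   the result is validated as a 0/1 matrix.
#' @param transpose If `TRUE`, the file stores genes as rows and tumors as
#'   columns and is transposed after reading.
#' @return A numeric matrix with tumor IDs as row names and gene IDs as
#'   column names.
#' @export
read_mutation_matrix <- function(path, binary = FALSE, transpose = FALSE) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]][-1L]
  dup <- header[duplicated(header)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s ID in header: '%s'",
                 if (transpose) "tumor" else "gene", dup[1L]))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("mutation matrix file must have an ID column plus at least one gene column")
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad[1L]], bad[1L], colnames(m)[j]))
    }
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (binary) m[m > 0] <- 1
  validate_mutation_matrix(m, binary = binary)
  m
}

#' Write a mutation matrix to TSV
#'
#' Inverse of [read_mutation_matrix()]: header row of gene IDs, first column
#' of tumor IDs.
#'
#' @param m Numeric matrix with tumor row names and gene column names.
#' @param path Output path.
#' @export
write_mutation_matrix <- function(m, path) {
  validate_mutation_matrix(m)
  df <- data.frame(tumor_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a mutation matrix
#'
#' Enforces the container invariants: unique tumor and gene identifiers, at
#' least two of each, finite numeric values, and (for `binary = TRUE`)
#' membership in \{0, 1\}.  Propagated matrices must lie in \[0, 1\].
#'
#' @param m Matrix to validate.
#' @param binary Require strictly 0/1 entries.
#' @return The matrix, invisibly.
#' @export
validate_mutation_matrix <- function(m, binary = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("mutation matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("mutation matrix needs tumor row names and gene column names")
  dup_t <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_t) > 0L) stop(sprintf("duplicate tumor ID: '%s'", dup_t[1L]))
  dup_g <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_g) > 0L) stop(sprintf("duplicate gene ID: '%s'", dup_g[1L]))
  if (nrow(m) < 2L || ncol(m) < 2L) stop("mutation matrix must have at least 2 tumors and 2 genes")
  if (anyNA(m) || any(!is.finite(m))) stop("mutation matrix contains missing or non-finite values")
  if (binary && !all(m %in% c(0, 1))) stop("binary mutation matrix may only contain 0 and 1")
  if (any(m < 0) || any(m > 1)) stop("mutation matrix values must lie in [0, 1]")
  invisible(m)
}

#' Read a gene-interaction edge list
#'
#' Reads a STRING-style whitespace- or tab-delimited edge list with at least
#' three columns (gene_a, gene_b, confidence score).  Rows scoring below
#' `score_threshold` are dropped, self-loops removed, and duplicate
#' undirected pairs collapsed keeping the maximum score.
#'
#' @param path Path to the edge-list file.
#' @param score_threshold Minimum confidence score to keep an edge.  The
#'   default 400 is the STRING "medium confidence" convention.
#' @param aliases Optional 2-column data frame (or path to a whitespace
#'   delimited file) mapping node identifiers (e.g. STRING protein IDs) to
#'   gene symbols; unmapped identifiers are kept verbatim.
#' @param header Whether the file has a header row.
#' @return A data frame with columns `gene_a`, `gene_b`, `score`.
#' @export
read_edge_list <- function(path, score_threshold = 400, aliases = NULL,
                           header = FALSE) {
  raw <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("edge list must have at least 3 columns: gene_a, gene_b, score")
  edges <- data.frame(gene_a = as.character(raw[[1L]]),
                      gene_b = as.character(raw[[2L]]),
                      score  = as.numeric(raw[[3L]]),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$score)) stop("non-numeric score in edge list")
  if (any(edges$score < 0)) stop("edge scores must be non-negative")
  if (!is.null(aliases)) {
    if (is.character(aliases) && length(aliases) == 1L) {
      aliases <- utils::read.table(aliases, header = FALSE, stringsAsFactors = FALSE)
    }
    map <- stats::setNames(as.character(aliases[[2L]]), as.character(aliases[[1L]]))
    hit_a <- edges$gene_a %in% names(map)
    hit_b <- edges$gene_b %in% names(map)
    edges$gene_a[hit_a] <- unname(map[edges$gene_a[hit_a]])
    edges$gene_b[hit_b] <- unname(map[edges$gene_b[hit_b]])
  }
  edges <- edges[edges$score >= score_threshold, , drop = FALSE]
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  if (nrow(edges) == 0L) stop(sprintf("no edges remain after applying score threshold %s", score_threshold))
  # canonical undirected orientation, then collapse duplicates keeping max score
  lo <- pmin(edges$gene_a, edges$gene_b)
  hi <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(lo, hi, sep = "\r")
  best <- tapply(edges$score, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                    gene_b = vapply(parts, `[[`, "", 2L),
                    score  = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a partition from labels
#'
#' A partition assigns each tumor to exactly one cluster.  Internally it is
#' a named character vector: names are tumor IDs, values are cluster labels.
#'
#' @param x A named vector of labels, a factor with names, or a 2-column
#'   data frame (tumor_id, label).
#' @return A named character vector of class `partition`.
#' @export
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("partition data frame needs columns (tumor_id, label)")
    p <- stats::setNames(as.character(x[[2L]]), as.character(x[[1L]]))
  } else {
    if (is.null(names(x))) stop("partition vector must be named by tumor ID")
    p <- stats::setNames(as.character(x), names(x))
  }
  dup <- names(p)[duplicated(names(p))]
  if (length(dup) > 0L) stop(sprintf("tumor '%s' appears more than once in partition", dup[1L]))
  class(p) <- c("partition", class(p))
  p
}

#' Split a partition into its clusters
#'
#' @param p A partition (see [as_partition()]).
#' @return A named list of character vectors of tumor IDs, one per cluster,
#'   ordered by cluster label.
#' @export
partition_clusters <- function(p) {
  p <- as_partition(p)
  split(names(p), unclass(p))
}

#' Write a partition as a 2-column CSV
#'
#' @param partition A partition.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  if (length(partition) == 0L) {
    df <- data.frame(tumor_id = character(0), label = character(0))
  } else {
    partition <- as_partition(partition)
    ord <- order(names(partition))
    df <- data.frame(tumor_id = names(partition)[ord],
                     label = unname(unclass(partition))[ord],
                     stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a partition from a 2-column CSV
#'
#' @param path Path to a CSV with columns (tumor_id, label).
#' @return A partition.
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) {
    p <- character(0)
    class(p) <- c("partition", class(p))
    return(p)
  }
  as_partition(df)
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file holding pipeline settings (alpha,
#'   tolerance, encoder layer sizes, dropout, seeds, k-range, theta grid...).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
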