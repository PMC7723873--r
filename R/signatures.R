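#' Fisher's exact test for one gene in one subtype
#'
#' Builds the 2x2 table crossing mutation status (mutated / not) with
#' subtype membership (in / out) over the whole cohort and tests for
#' enrichment of mutations inside the subtype.  The default one-sided
#' alternative asks whether the gene is mutated more often inside the
#' subtype than expected under the hypergeometric null; `two.sided` is
#' available for a direction-agnostic test.
#'
#' @param mutations Raw binary mutation matrix (tumors by genes).
#' @param partition Subtype partition covering the matrix rows.
#' @param gene Gene (column) to test.
#' @param subtype Subtype label defining the "in" group.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A list of class `gene_test` with the `table`, `p_value`,
#'   `odds_direction` (`"enriched"` or `"depleted"`), `gene`, `subtype`.
#' @export
fisher_gene_test <- function(mutations, partition, gene, subtype,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  partition <- as_partition(partition)
  ids <- intersect(rownames(mutations), names(partition))
  if (length(ids) == 0L) stop("mutation matrix and partition share no tumors")
  if (!gene %in% colnames(mutations)) stop(sprintf("gene '%s' not in mutation matrix", gene))
  inside <- unclass(partition)[ids] == subtype
  if (!any(inside)) stop(sprintf("subtype '%s' is empty", subtype))
  mut <- mutations[ids, gene] > 0
  tab <- matrix(c(sum(mut & inside), sum(mut & !inside),
                  sum(!mut & inside), sum(!mut & !inside)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("mutated", "not_mutated"),
                                c("in_subtype", "out_subtype")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  rate_in <- tab[1, 1] / sum(tab[, 1])
  rate_out <- tab[1, 2] / sum(tab[, 2])
  structure(list(gene = gene, subtype = subtype, table = tab,
                 p_value = unname(ft$p.value),
                 odds_direction = if (rate_in >= rate_out) "enriched" else "depleted"),
            class = "gene_test")
}

#' Mutation signature of one subtype
#'
#' Tests every gene for mutation enrichment in the subtype, keeps those
#' with p below `p_threshold`, sorts by ascending p (ties broken
#' lexicographically by gene ID) and truncates to the `top_n` best.  For
#' speed the enrichment p-values are computed in bulk from the
#' hypergeometric tail, which is identical to the one-sided Fisher test.
#'
#' @inheritParams fisher_gene_test
#' @param top_n Maximum signature length (default 50).
#' @param p_threshold Raw p-value cutoff (default 0.05).
#' @param correction `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment before thresholding.
#' @return A data frame of class `signature` with columns `gene`,
#'   `p_value` (and `p_adjusted` when corrected), ascending in p.
#'   Metadata attributes record the sidedness and correction used.
#' @export
gene_signature <- function(mutations, partition, subtype, top_n = 50,
                           p_threshold = 0.05,
                           alternative = c("greater", "two.sided"),
                           correction = c("none", "BH")) {
  alternative <- match.arg(alternative)
  correction <- match.arg(correction)
  partition <- as_partition(partition)
  ids <- intersect(rownames(mutations), names(partition))
  if (length(ids) == 0L) stop("mutation matrix and partition share no tumors")
  inside <- unclass(partition)[ids] == subtype
  if (!any(inside)) stop(sprintf("subtype '%s' is empty", subtype))
  M <- mutations[ids, , drop = FALSE] > 0
  n_tot <- length(ids)
  n_in <- sum(inside)
  mut_tot <- colSums(M)
  mut_in <- colSums(M[inside, , drop = FALSE])
  if (alternative == "greater") {
    # P[X >= mut_in], X ~ Hypergeom(white = mut_tot, black = rest, drawn = n_in)
    p <- stats::phyper(mut_in - 1, mut_tot, n_tot - mut_tot, n_in,
                       lower.tail = FALSE)
  } else {
    p <- vapply(colnames(M), function(gn)
      fisher_gene_test(mutations[ids, , drop = FALSE],
                       partition[ids], gn, subtype,
                       alternative = "two.sided")$p_value,
      0)
  }
  df <- data.frame(gene = colnames(M), p_value = unname(p),
                   stringsAsFactors = FALSE)
  if (correction == "BH") {
    df$p_adjusted <- stats::p.adjust(df$p_value, method = "BH")
    keep <- df$p_adjusted < p_threshold
  } else {
    keep <- df$p_value < p_threshold
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$p_value, df$gene), , drop = FALSE]
  df <- utils::head(df, top_n)
  rownames(df) <- NULL
  attr(df, "subtype") <- subtype
  attr(df, "alternative") <- alternative
  attr(df, "correction") <- correction
  class(df) <- c("signature", class(df))
  df
}

#' Signatures for every subtype of a partition
#'
#' @inheritParams gene_signature
#' @return A named list of signatures, one per subtype label.
#' @export
all_signatures <- function(mutations, partition, top_n = 50,
                           p_threshold = 0.05,
                           alternative = c("greater", "two.sided"),
                           correction = c("none", "BH")) {
  partition <- as_partition(partition)
  subs <- sort(unique(unclass(partition)))
  out <- lapply(subs, function(s)
    gene_signature(mutations, partition, s, top_n = top_n,
                   p_threshold = p_threshold, alternative = alternative,
                   correction = correction))
  stats::setNames(out, subs)
}

#' Write one CSV per subtype signature
#'
#' @param signatures Output of [all_signatures()].
#' @param dir Output directory (created if needed).
#' @export
write_signatures <- function(signatures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(signatures)) {
    utils::write.csv(signatures[[s]],
                     file.path(dir, paste0("signature_", s, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
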