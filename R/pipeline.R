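#' Run the full subtyping pipeline
#'
#' Executes the stages in order on a cohort: network propagation of the
#' raw profiles, cluster-number selection (or a fixed k) with deep
#' embedded clustering, agreement metrics against a reference partition
#' when one is available, per-subtype Fisher signatures, and repeated
#' cross-validated subtype prediction.  Artifacts and a manifest of all
#' parameters are written to `outdir` when given.
#'
#' @param mutations Raw binary mutation matrix, or a `synthetic_cohort`
#'   (in which case `network` and `reference` default to its contents).
#' @param network Gene network (igraph or edge-list data frame).
#' @param reference Optional reference partition for evaluation and
#'   k-selection.
#' @param k Fixed number of clusters; when `NULL`, selected over `k_range`
#'   by AUMF against `reference`.
#' @param k_range Candidate k values used when `k` is `NULL`.
#' @param alpha,tolerance Propagation parameters.
#' @param sae An [sae_config()] for the clustering stage.
#' @param cv A [cv_config()] for the prediction stage.
#' @param theta_grid Threshold grid for the matching metrics.
#' @param top_n,p_threshold Signature parameters.
#' @param outdir Optional directory for artifacts (labels, signatures,
#'   reports, manifest).
#' @param seed Global seed; module seeds are derived from it
#'   deterministically.
#' @return A list with the propagated matrix, fitted partition, selection
#'   table (if run), metric report vs the reference (if given),
#'   signatures, cross-validation report and importance table.
#' @export
run_pipeline <- function(mutations, network = NULL, reference = NULL,
                         k = NULL, k_range = 2:6, alpha = 0.4,
                         tolerance = 1e-6, sae = NULL, cv = NULL,
                         theta_grid = seq(0, 1, by = 0.05), top_n = 50,
                         p_threshold = 0.05, outdir = NULL, seed = 1) {
  if (inherits(mutations, "synthetic_cohort")) {
    cohort <- mutations
    mutations <- cohort$mutations
    if (is.null(network)) network <- cohort$network
    if (is.null(reference)) reference <- cohort$truth_labels
  }
  if (is.null(network)) stop("a gene network is required")
  if (is.null(sae)) sae <- sae_config(seed = seed)
  if (is.null(cv)) cv <- cv_config(repeats = 10, seed = seed + 1L)

  prop <- propagate(mutations, network, alpha = alpha, tolerance = tolerance)
  X <- prop$matrix

  selection <- NULL
  if (is.null(k)) {
    if (is.null(reference)) stop("either a fixed k or a reference partition is required")
    runner <- function(X, k) fit_dec(X, k, config = sae)$partition
    selection <- select_k(X, reference, k_range, runner = runner,
                          theta_grid = theta_grid)
    k <- selection$best_k
    partition <- selection$partitions[[as.character(k)]]
    fit <- NULL
  } else {
    fit <- fit_dec(X, k, config = sae)
    partition <- fit$partition
  }

  report <- if (!is.null(reference)) {
    metric_report(reference, partition, X = X, theta_grid = theta_grid)
  }
  sigs <- all_signatures(mutations, partition, top_n = top_n,
                         p_threshold = p_threshold)
  smallest <- min(table(unclass(partition)))
  if (smallest < cv$folds) {
    warning(sprintf("smallest discovered cluster has %d tumors; reducing CV folds from %d to %d",
                    smallest, cv$folds, max(2L, smallest)))
    cv <- cv_config(folds = max(2L, smallest), repeats = cv$repeats,
                    seed = cv$seed, classifier = cv$classifier)
  }
  cv_report <- cross_validate(X, partition, config = cv)
  importance <- feature_importance(X, partition, seed = cv$seed)

  result <- list(propagation = prop, partition = partition, k = k,
                 selection = selection, report = report, signatures = sigs,
                 cv_report = cv_report, importance = importance)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_mutation_matrix(X, file.path(outdir, "propagated.tsv"))
    write_partition(partition, file.path(outdir, "labels.csv"))
    write_signatures(sigs, file.path(outdir, "signatures"))
    utils::write.csv(importance, file.path(outdir, "importance.csv"),
                     row.names = FALSE)
    if (!is.null(report)) {
      jsonlite::write_json(report[c("PPV", "SN", "ACC", "AUMF", "silhouette",
                                    "MMR_at_theta", "Fplus_at_theta")],
                           file.path(outdir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(alpha = alpha, tolerance = tolerance, k = k,
                     k_range = if (is.null(selection)) NULL else k_range,
                     theta_grid = theta_grid, top_n = top_n,
                     p_threshold = p_threshold, seed = seed,
                     sae = unclass(sae), cv = unclass(cv),
                     package_version = as.character(utils::packageVersion("mutclust")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' Principal-component scatter of tumors colored by partition
#'
#' A convenience visual: projects the tumors onto their first two
#' principal components and colors them by cluster label.  Purely
#' qualitative; no quantity is derived from it.
#'
#' @param X Tumors-by-features matrix.
#' @param partition Partition covering the rows of X.
#' @param main Plot title.
#' @export
plot_partition_pca <- function(X, partition, main = "Tumors in PC space") {
  partition <- as_partition(partition)
  ids <- intersect(rownames(X), names(partition))
  pc <- stats::prcomp(X[ids, , drop = FALSE], rank. = 2)
  lab <- factor(unclass(partition)[ids])
  cols <- grDevices::hcl.colors(nlevels(lab), "Dark 3")
  graphics::plot(pc$x[, 1L], pc$x[, 2L], col = cols[as.integer(lab)],
                 pch = 19, cex = 0.7, xlab = "PC1", ylab = "PC2",
                 main = main)
  graphics::legend("topright", legend = levels(lab), col = cols, pch = 19,
                   bty = "n")
  invisible(pc)
}
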