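#' Shared-tumor contingency between two partitions
#'
#' Forms the weighted bipartite graph between a reference partition P and a
#' discovered partition C: entry `v[i, j]` counts the tumors shared between
#' reference cluster i and discovered cluster j.  Tumors present in only
#' one partition are dropped (with a warning) before counting.
#'
#' @param P Reference partition.
#' @param C Discovered partition.
#' @return A list of class `contingency` with the count matrix `v`,
#'   `row_sizes` (reference cluster sizes l_i) and `col_sizes` (discovered
#'   cluster sizes k_j).
#' @export
contingency <- function(P, C) {
  P <- as_partition(P); C <- as_partition(C)
  common <- intersect(names(P), names(C))
  if (length(common) == 0L) stop("partitions share no tumors")
  if (length(common) < length(P) || length(common) < length(C)) {
    warning(sprintf("partitions compared on their %d shared tumors", length(common)))
  }
  v <- unclass(table(factor(unclass(P)[common]), factor(unclass(C)[common])))
  structure(list(v = v, row_sizes = rowSums(v), col_sizes = colSums(v)),
            class = "contingency")
}

#' Cluster-wise positive predictive value, sensitivity and accuracy
#'
#' From the contingency counts v:
#' PPV = sum_j max_i v_ij / sum_ij v_ij,
#' SN  = sum_i max_j v_ij / sum_i l_i,
#' ACC = sqrt(SN * PPV) (their geometric mean).
#'
#' @param g A `contingency` (or a pair of partitions via [contingency()]).
#' @param geometric If `FALSE`, return the raw product SN * PPV as ACC
#'   instead of the geometric mean.
#' @return A named list with `PPV`, `SN`, `ACC`.
#' @export
ppv_sn_acc <- function(g, geometric = TRUE) {
  if (!inherits(g, "contingency")) stop("expected a contingency object")
  if (sum(g$v) == 0) stop("empty contingency graph")
  ppv <- sum(apply(g$v, 2L, max)) / sum(g$v)
  sn <- sum(apply(g$v, 1L, max)) / sum(g$row_sizes)
  acc <- if (geometric) sqrt(sn * ppv) else sn * ppv
  list(PPV = ppv, SN = sn, ACC = acc)
}

#' Neighborhood affinity between two clusters
#'
#' `NA(p, c) = |p intersect c|^2 / (|p| * |c|)`, an overlap score in
#' \[0, 1\] reaching 1 only for identical sets.
#'
#' @param p,c Non-empty character vectors of tumor IDs.
#' @return A number in \[0, 1\].
#' @export
na_affinity <- function(p, c) {
  if (length(p) == 0L || length(c) == 0L) stop("clusters must be non-empty")
  length(intersect(p, c))^2 / (length(p) * length(c))
}

# Affinity matrix (|P| x |C|) from the contingency counts.
.na_matrix <- function(g) {
  g$v^2 / outer(g$row_sizes, g$col_sizes)
}

# Bipartite matching on the theta-thresholded affinity graph.
# weighted = TRUE: maximum total affinity; FALSE: maximum cardinality.
# Zero-affinity pairs never form edges (a zero-weight edge is no edge).
.match_affinity <- function(na_mat, theta, weighted) {
  keep <- which(na_mat >= theta & na_mat > 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(list(weight = 0, size = 0L))
  nr <- nrow(na_mat); nc <- ncol(na_mat)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(rbind(keep[, 1L], nr + keep[, 2L])))
  w <- na_mat[keep]
  m <- if (weighted) {
    igraph::max_bipartite_match(g, weights = w)
  } else {
    igraph::max_bipartite_match(g)
  }
  size <- m$matching_size
  weight <- if (weighted) m$matching_weight else NA_real_
  list(weight = weight, size = as.integer(size))
}

#' Maximum matching ratio between two partitions
#'
#' Edges between reference and discovered clusters are weighted by their
#' neighborhood affinity when it reaches the threshold theta (otherwise
#' absent); MMR is the weight of the maximum weighted bipartite matching
#' divided by the number of reference clusters.
#'
#' @param P Reference partition.
#' @param C Discovered partition.
#' @param theta Affinity threshold in \[0, 1\].
#' @return A number in \[0, 1\].
#' @export
mmr <- function(P, C, theta) {
  stopifnot(theta >= 0, theta <= 1)
  g <- contingency(P, C)
  na_mat <- .na_matrix(g)
  .match_affinity(na_mat, theta, weighted = TRUE)$weight / nrow(na_mat)
}

#' Matched-cluster precision, recall and F-measure at a threshold
#'
#' A maximum-cardinality (unweighted) matching is computed on the
#' theta-thresholded affinity graph.  `Np_plus` / `Nc_plus` count matched
#' reference / discovered clusters, `Precision_plus = Np_plus / |P|`,
#' `Recall_plus = Nc_plus / |C|`, and `F_plus` is their harmonic mean
#' (0 when both are 0).
#'
#' @inheritParams mmr
#' @return A named list with `Np_plus`, `Nc_plus`, `Precision_plus`,
#'   `Recall_plus`, `F_plus`.
#' @export
plus_metrics <- function(P, C, theta) {
  stopifnot(theta >= 0, theta <= 1)
  g <- contingency(P, C)
  na_mat <- .na_matrix(g)
  m <- .match_affinity(na_mat, theta, weighted = FALSE)
  np <- m$size
  nc <- m$size
  prec <- np / nrow(na_mat)
  rec <- nc / ncol(na_mat)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(Np_plus = np, Nc_plus = nc, Precision_plus = prec,
       Recall_plus = rec, F_plus = f)
}

#' Area under the MMR + F-measure+ threshold curve
#'
#' Integrates theta -> MMR(theta) + F+(theta) over \[0, 1\] by the
#' trapezoidal rule on `theta_grid`.  Both summands live in \[0, 1\], so
#' the area lies in \[0, 2\]; identical partitions give exactly 2.
#'
#' @param P Reference partition.
#' @param C Discovered partition.
#' @param theta_grid Increasing grid covering \[0, 1\] (default step 0.05).
#' @return A number in \[0, 2\].  The per-theta curves are attached as
#'   attribute `"curve"`.
#' @export
aumf <- function(P, C, theta_grid = seq(0, 1, by = 0.05)) {
  stopifnot(length(theta_grid) >= 2L, !is.unsorted(theta_grid),
            abs(theta_grid[1L]) < 1e-12,
            abs(theta_grid[length(theta_grid)] - 1) < 1e-12)
  g <- contingency(P, C)
  na_mat <- .na_matrix(g)
  mmr_t <- vapply(theta_grid, function(th)
    .match_affinity(na_mat, th, weighted = TRUE)$weight, 0) / nrow(na_mat)
  f_t <- vapply(theta_grid, function(th) {
    m <- .match_affinity(na_mat, th, weighted = FALSE)
    prec <- m$size / nrow(na_mat); rec <- m$size / ncol(na_mat)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 0)
  y <- mmr_t + f_t
  area <- sum(diff(theta_grid) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  attr(area, "curve") <- data.frame(theta = theta_grid, MMR = mmr_t, F_plus = f_t)
  area
}

#' Mean silhouette width of a partition
#'
#' For tumor i in cluster k with cohesion a(i) (mean Euclidean distance to
#' the other members of its own cluster) and separation b(i) (minimum over
#' other clusters of the mean distance to that cluster),
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`; singletons score 0.  The
#' criterion is the mean of s(i) over all tumors, in \[-1, 1\].
#'
#' @param X Tumors-by-features numeric matrix (rows named by tumor ID).
#' @param C A partition covering the rows of X.
#' @return The mean silhouette width.
#' @export
silhouette_score <- function(X, C) {
  C <- as_partition(C)
  ids <- intersect(rownames(X), names(C))
  if (length(ids) < 2L) stop("need at least 2 tumors shared by X and the partition")
  X <- X[ids, , drop = FALSE]
  lab <- unclass(C)[ids]
  if (length(unique(lab)) < 2L) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  clusters <- split(seq_along(ids), lab)
  # sums of distances from every tumor to each cluster
  sums <- vapply(clusters, function(idx) rowSums(D[, idx, drop = FALSE]),
                 numeric(length(ids)))
  sizes <- lengths(clusters)
  s <- numeric(length(ids))
  for (i in seq_along(ids)) {
    k <- lab[i]
    nk <- sizes[[k]]
    if (nk == 1L) { s[i] <- 0; next }
    a <- sums[i, k] / (nk - 1)
    others <- setdiff(names(clusters), k)
    b <- min(sums[i, others] / sizes[others])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Full agreement report between two partitions
#'
#' Bundles PPV/SN/ACC, the per-theta MMR and F+ curves, Precision+/Recall+
#' at each theta, AUMF, and (when X is given) the silhouette of C.
#'
#' @param P Reference partition.
#' @param C Discovered partition.
#' @param X Optional feature matrix for the silhouette.
#' @param theta_grid Threshold grid for the matching metrics.
#' @return A list of class `metric_report`.
#' @export
metric_report <- function(P, C, X = NULL, theta_grid = seq(0, 1, by = 0.05)) {
  g <- contingency(P, C)
  base <- ppv_sn_acc(g)
  a <- aumf(P, C, theta_grid)
  curve <- attr(a, "curve")
  plus <- lapply(theta_grid, function(th) plus_metrics(P, C, th))
  sil <- if (is.null(X)) NA_real_ else silhouette_score(X, C)
  structure(list(
    PPV = base$PPV, SN = base$SN, ACC = base$ACC,
    MMR_at_theta = stats::setNames(curve$MMR, curve$theta),
    Fplus_at_theta = stats::setNames(curve$F_plus, curve$theta),
    Precision_plus = vapply(plus, `[[`, 0, "Precision_plus"),
    Recall_plus = vapply(plus, `[[`, 0, "Recall_plus"),
    AUMF = as.numeric(a),
    silhouette = sil,
    theta_grid = theta_grid), class = "metric_report")
}

#' Select the number of clusters by AUMF against a reference
#'
#' Runs a clustering procedure for each candidate k, scores every
#' discovered partition against the reference with the matching-metric
#' suite, and returns the k maximizing AUMF together with the full per-k
#' report table.  Ties on AUMF are reported explicitly (all tied k values
#' in `tied_k`; `best_k` is the smallest).
#'
#' @param X Feature matrix handed to the runner (also used for the
#'   silhouette column).
#' @param reference Reference partition (e.g. planted truth or PAM50
#'   calls).
#' @param k_range Candidate numbers of clusters.
#' @param runner `function(X, k)` returning a partition; defaults to
#'   seeded k-means on X.  A failing k is skipped with a warning.
#' @param theta_grid Threshold grid for the matching metrics.
#' @return A list with `best_k`, `tied_k`, `table` (one row per k),
#'   `reports` and `partitions`.
#' @export
select_k <- function(X, reference, k_range, runner = NULL,
                     theta_grid = seq(0, 1, by = 0.05)) {
  stopifnot(length(k_range) >= 1L)
  reference <- as_partition(reference)
  if (is.null(runner)) {
    runner <- function(X, k) {
      km <- stats::kmeans(X, centers = k, nstart = 20, iter.max = 100)
      as_partition(stats::setNames(as.character(km$cluster), rownames(X)))
    }
  }
  reports <- list()
  partitions <- list()
  for (k in k_range) {
    part <- tryCatch(runner(X, k), error = function(e) {
      warning(sprintf("clustering failed for k = %d: %s", k, conditionMessage(e)))
      NULL
    })
    if (is.null(part)) next
    reports[[as.character(k)]] <- metric_report(reference, part, X = X,
                                                theta_grid = theta_grid)
    partitions[[as.character(k)]] <- part
  }
  if (length(reports) == 0L) stop("clustering failed for every k in k_range")
  tab <- data.frame(
    k = as.integer(names(reports)),
    AUMF = vapply(reports, `[[`, 0, "AUMF"),
    ACC = vapply(reports, `[[`, 0, "ACC"),
    PPV = vapply(reports, `[[`, 0, "PPV"),
    SN = vapply(reports, `[[`, 0, "SN"),
    silhouette = vapply(reports, `[[`, 0, "silhouette"),
    row.names = NULL)
  best <- max(tab$AUMF)
  tied <- tab$k[abs(tab$AUMF - best) < 1e-12]
  list(best_k = min(tied), tied_k = tied, table = tab,
       reports = reports, partitions = partitions)
}
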