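# Independent brute-force oracles used to validate the optimized
# implementations.  These deliberately share no code with the package
# internals.

# Exhaustive bipartite matching: tries every injective assignment of rows
# to columns over the allowed edges, maximizing total weight and
# cardinality independently.
enumerate_matchings <- function(w, allowed) {
  nr <- nrow(w); ncl <- ncol(w)
  best_weight <- 0
  best_size <- 0L
  rec <- function(i, used, cw, cc) {
    if (i > nr) {
      best_weight <<- max(best_weight, cw)
      best_size <<- max(best_size, cc)
      return(invisible())
    }
    rec(i + 1L, used, cw, cc)          # row i unmatched
    for (j in seq_len(ncl)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        rec(i + 1L, used, cw + w[i, j], cc + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, ncl), 0, 0L)
  list(weight = best_weight, size = best_size)
}

# Brute-force MMR and F+ for a pair of partitions at threshold theta,
# recomputing affinities from raw tumor sets.
brute_mmr_fplus <- function(P, C, theta) {
  pc <- split(names(P), unclass(P))
  cc <- split(names(C), unclass(C))
  na_mat <- outer(seq_along(pc), seq_along(cc), Vectorize(function(i, j) {
    length(intersect(pc[[i]], cc[[j]]))^2 / (length(pc[[i]]) * length(cc[[j]]))
  }))
  allowed <- na_mat >= theta & na_mat > 0
  m <- enumerate_matchings(na_mat, allowed)
  prec <- m$size / length(pc)
  rec <- m$size / length(cc)
  list(mmr = m$weight / length(pc),
       f_plus = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# Plain pairwise-loop silhouette.
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == cl)
      b <- min(b, mean(vapply(idx, function(j) d(i, j), 0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# One-sided enrichment p-value by exhaustive enumeration of all 2x2
# tables with the observed margins, weighting each by its arrangement
# count (no distribution function involved).
brute_fisher_greater <- function(a, mut_total, in_total, n_total) {
  lo <- max(0L, mut_total + in_total - n_total)
  hi <- min(mut_total, in_total)
  counts <- vapply(lo:hi, function(x)
    choose(in_total, x) * choose(n_total - in_total, mut_total - x), 0)
  sum(counts[(lo:hi) >= a]) / sum(counts)
}

# Pairwise rank-count AUC (Mann-Whitney), ties counted half.
brute_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Random partition over n tumors with at most k clusters (each cluster
# guaranteed non-empty).
random_partition <- function(n, k, ids = sprintf("t%03d", seq_len(n))) {
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  as_partition(stats::setNames(as.character(sample(labels)), ids))
}

# Tiny deterministic fixtures shared across files.
tiny_edges <- function() {
  data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"), score = c(900, 900),
             stringsAsFactors = FALSE)
}

worked_partitions <- function() {
  list(P = as_partition(stats::setNames(c("1", "1", "2", "2"),
                                        c("a", "b", "c", "d"))),
       C = as_partition(stats::setNames(c("x", "x", "x", "y"),
                                        c("a", "b", "c", "d"))))
}
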