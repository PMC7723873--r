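#' Build a gene network from an edge list
#'
#' Constructs an undirected, simple igraph over gene symbols.  Isolated
#' nodes cannot arise from an edge list; duplicate edges are collapsed
#' keeping the maximum confidence score (stored as the `weight` attribute).
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `score` (see
#'   [read_edge_list()]), or an igraph object passed through unchanged.
#' @return An undirected igraph with a `weight` edge attribute.
#' @export
gene_network <- function(edges) {
  if (inherits(edges, "igraph")) return(edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$gene_a, to = edges$gene_b, weight = edges$score),
    directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Degree-normalized transition matrix of a gene network
#'
#' For adjacency H and diagonal degree-inverse D, the walk matrix is
#' A = H D, i.e. `A[i, j] = h_ij / degree(j)`: every column sums to one, so
#' a random walker at gene j moves to a uniformly chosen neighbor.
#' Isolated nodes have no well-defined column and are dropped with a
#' warning before normalization.
#'
#' @param network An igraph (or edge-list data frame) over gene symbols.
#' @param weighted If `TRUE`, use edge confidence scores instead of 0/1
#'   adjacency; columns are then normalized by weighted degree.
#' @return A list of class `transition_matrix` with elements `A` (sparse
#'   column-stochastic matrix with dimnames) and `nodes`.
#' @export
transition_matrix <- function(network, weighted = FALSE) {
  g <- gene_network(network)
  deg <- igraph::degree(g)
  if (any(deg == 0)) {
    warning(sprintf("dropping %d isolated node(s) from the network before normalization",
                    sum(deg == 0)))
    g <- igraph::delete_vertices(g, which(deg == 0))
  }
  if (igraph::vcount(g) < 2L) stop("network must retain at least 2 connected nodes")
  nodes <- sort(igraph::V(g)$name)
  H <- igraph::as_adjacency_matrix(g, sparse = TRUE,
                                   attr = if (weighted) "weight" else NULL)
  H <- H[nodes, nodes]
  colsums <- Matrix::colSums(H)
  if (any(colsums == 0)) stop("zero-degree node encountered; remove isolated nodes first")
  A <- H %*% Matrix::Diagonal(x = 1 / colsums)
  dimnames(A) <- list(nodes, nodes)
  structure(list(A = A, nodes = nodes), class = "transition_matrix")
}

# Split profile columns into those covered by the network and the rest.
# Genes absent from the network are passed through untouched (their
# propagated value is their raw value); the caller is warned once.
.align_profiles <- function(profiles, tm, quiet = FALSE) {
  in_net <- colnames(profiles) %in% tm$nodes
  if (!any(in_net)) stop("no mutation-matrix gene overlaps the network")
  if (!quiet && !all(in_net)) {
    warning(sprintf("%d gene(s) in the mutation matrix are absent from the network and pass through unpropagated",
                    sum(!in_net)))
  }
  missing_profile <- setdiff(tm$nodes, colnames(profiles))
  # network nodes never mutated still receive flow; pad with zero columns
  D0 <- matrix(0, nrow(profiles), length(tm$nodes),
               dimnames = list(rownames(profiles), tm$nodes))
  common <- colnames(profiles)[in_net]
  D0[, common] <- profiles[, common]
  list(D0 = D0, passthrough = profiles[, !in_net, drop = FALSE],
       common = common, padded = missing_profile)
}

.as_transition <- function(x, weighted = FALSE) {
  if (inherits(x, "transition_matrix")) x else transition_matrix(x, weighted = weighted)
}

#' Smooth mutation profiles by random walk with restart
#'
#' Iterates the propagation map
#' \deqn{D_{i+1} = \alpha D_i A + (1 - \alpha) D_0}
#' from \eqn{D_0} (the raw tumors-by-genes profile) until the Frobenius norm
#' of the update falls below `tolerance`.  The restart weight
#' \eqn{1 - \alpha} pins each tumor's original mutations while \eqn{\alpha}
#' controls how far a mutation's signal diffuses along the network.
#'
#' Genes present in the profile but absent from the network keep their raw
#' values; network genes never mutated in a tumor still accumulate flow
#' from mutated neighbors.
#'
#' @param profiles Tumors-by-genes mutation matrix.
#' @param network A `transition_matrix`, igraph, or edge-list data frame.
#' @param alpha Diffusion weight in (0, 1); default 0.4.
#' @param tolerance Convergence threshold on the Frobenius norm of
#'   \eqn{D_{i+1} - D_i}; default 1e-6.
#' @param max_iter Iteration cap; hitting it flags the result as
#'   unconverged (with a warning) rather than erroring.
#' @param weighted Use confidence-weighted adjacency when `network` is not
#'   already a transition matrix.
#' @return A list of class `propagation_result` with `matrix` (the smoothed
#'   profile over the union of profile and network genes), `iterations`,
#'   `final_delta` and `converged`.
#' @export
propagate <- function(profiles, network, alpha = 0.4, tolerance = 1e-6,
                      max_iter = 1000, weighted = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 1)
  validate_mutation_matrix(profiles)
  tm <- .as_transition(network, weighted = weighted)
  al <- .align_profiles(profiles, tm)
  D0 <- al$D0
  Di <- D0
  delta <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Dnext <- alpha * as.matrix(Di %*% tm$A) + (1 - alpha) * D0
    delta <- sqrt(sum((Dnext - Di)^2))
    Di <- Dnext
    if (delta < tolerance) break
  }
  converged <- delta < tolerance
  if (!converged) {
    warning(sprintf("propagation did not converge in %d iterations (final delta %.3g)",
                    max_iter, delta))
  }
  out <- cbind(Di, al$passthrough)
  out <- pmin(pmax(out, 0), 1)
  structure(list(matrix = out, iterations = iter, final_delta = delta,
                 converged = converged),
            class = "propagation_result")
}

#' Closed-form fixed point of the propagation map
#'
#' The iteration \eqn{D_{i+1} = \alpha D_i A + (1-\alpha) D_0} converges,
#' for \eqn{\alpha < 1} and column-stochastic A, to the unique fixed point
#' \deqn{D_\infty = (1-\alpha)\, D_0 (I - \alpha A)^{-1},}
#' computed here by a direct sparse linear solve.  This is the exact
#' reference against which the iterative solver is checked.
#'
#' @inheritParams propagate
#' @return The smoothed mutation matrix (same layout as
#'   `propagate(...)$matrix`).
#' @export
propagate_closed_form <- function(profiles, network, alpha = 0.4,
                                  weighted = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 1)
  validate_mutation_matrix(profiles)
  tm <- .as_transition(network, weighted = weighted)
  al <- .align_profiles(profiles, tm, quiet = TRUE)
  n <- length(tm$nodes)
  M <- Matrix::Diagonal(n) - alpha * tm$A
  # D (I - aA) = (1-a) D0  =>  (I - aA)' D' = (1-a) D0'
  Dt <- Matrix::solve(Matrix::t(M), (1 - alpha) * t(al$D0))
  D <- t(as.matrix(Dt))
  dimnames(D) <- dimnames(al$D0)
  out <- cbind(D, al$passthrough)
  pmin(pmax(out, 0), 1)
}
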