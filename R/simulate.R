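#' Configuration for synthetic cohorts
#'
#' Defines the study conditions the simulator emulates: a sparse binary
#' tumors-by-genes matrix in which each tumor belongs to one of
#' `k_subtypes` planted subtypes, mutating that subtype's driver genes at
#' `driver_rate` and every other gene at `background_rate`, plus a random
#' gene-interaction network in which each subtype's drivers are adjacent
#' (same stochastic block, or chained) so that network smoothing can pool
#' their signal.
#'
#' The defaults (500 genes, 240 tumors, 4 subtypes, 12 drivers each,
#' background rate 0.01, driver rate 0.5) give a cohort whose overall
#' mutation density (~2-3%) matches the sparsity regime of real somatic
#' profiles while remaining small enough to run the full pipeline in
#' seconds.
#'
#' @param n_genes,n_tumors Cohort dimensions.
#' @param k_subtypes Number of planted subtypes.
#' @param drivers_per_subtype Drivers planted per subtype (disjoint across
#'   subtypes).
#' @param background_rate,driver_rate Per-gene Bernoulli mutation rates;
#'   `driver_rate` must exceed `background_rate`.
#' @param network_model `"stochastic_block"` (default), `"erdos_renyi"` or
#'   `"barabasi_albert"`.
#' @param p_within,p_between Stochastic-block edge probabilities (within /
#'   between blocks); `p_within` doubles as the Erdos-Renyi density.
#' @param attach_m Attachment parameter for the Barabasi-Albert model.
#' @param proportions Optional subtype mixing proportions (default equal).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, n_tumors = 240, k_subtypes = 4,
                       drivers_per_subtype = 12, background_rate = 0.01,
                       driver_rate = 0.5,
                       network_model = c("stochastic_block", "erdos_renyi",
                                         "barabasi_albert"),
                       p_within = 0.05, p_between = 0.005, attach_m = 2,
                       proportions = NULL, seed = 1) {
  network_model <- match.arg(network_model)
  stopifnot(n_genes >= 4, n_tumors >= 4, k_subtypes >= 1,
            drivers_per_subtype >= 1,
            drivers_per_subtype * k_subtypes <= n_genes,
            background_rate > 0, background_rate < 1,
            driver_rate > 0, driver_rate < 1,
            driver_rate > background_rate)
  if (is.null(proportions)) proportions <- rep(1 / k_subtypes, k_subtypes)
  stopifnot(length(proportions) == k_subtypes, all(proportions > 0))
  structure(list(n_genes = as.integer(n_genes), n_tumors = as.integer(n_tumors),
                 k_subtypes = as.integer(k_subtypes),
                 drivers_per_subtype = as.integer(drivers_per_subtype),
                 background_rate = background_rate, driver_rate = driver_rate,
                 network_model = network_model, p_within = p_within,
                 p_between = p_between, attach_m = attach_m,
                 proportions = proportions / sum(proportions),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# gene / tumor identifier helpers
.gene_ids <- function(n) sprintf("g%04d", seq_len(n))
.tumor_ids <- function(n) sprintf("t%04d", seq_len(n))

# Block assignment: genes dealt contiguously into k near-equal blocks;
# the first `drivers_per_subtype` genes of block s are subtype s's drivers.
.block_layout <- function(config) {
  sizes <- rep(config$n_genes %/% config$k_subtypes, config$k_subtypes)
  extra <- config$n_genes %% config$k_subtypes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(config$k_subtypes), sizes)
  genes <- .gene_ids(config$n_genes)
  starts <- cumsum(c(1L, utils::head(sizes, -1L)))
  drivers <- lapply(seq_len(config$k_subtypes), function(s)
    genes[starts[s] + seq_len(config$drivers_per_subtype) - 1L])
  names(drivers) <- as.character(seq_len(config$k_subtypes))
  list(block = block, genes = genes, drivers = drivers, sizes = sizes)
}

#' Simulate a gene-interaction network with planted driver modules
#'
#' Generates a random graph over `n_genes` named genes, chains each
#' subtype's drivers with a path (guaranteeing every driver set induces a
#' connected subgraph), and bridges any remaining components so the final
#' network is connected with no node dropped.
#'
#' @param config A [sim_config()].
#' @return An igraph with vertex attributes `block` and `driver_of`
#'   (subtype label or NA).
#' @export
simulate_network <- function(config = sim_config()) {
  set.seed(config$seed)
  lay <- .block_layout(config)
  g <- switch(config$network_model,
    erdos_renyi = igraph::sample_gnp(config$n_genes, config$p_within),
    barabasi_albert = igraph::sample_pa(config$n_genes, m = config$attach_m,
                                        directed = FALSE),
    stochastic_block = {
      pm <- matrix(config$p_between, config$k_subtypes, config$k_subtypes)
      diag(pm) <- config$p_within
      igraph::sample_sbm(config$n_genes, pref.matrix = pm,
                         block.sizes = lay$sizes)
    })
  igraph::V(g)$name <- lay$genes
  igraph::V(g)$block <- lay$block
  driver_of <- rep(NA_character_, config$n_genes)
  for (s in names(lay$drivers)) {
    driver_of[match(lay$drivers[[s]], lay$genes)] <- s
  }
  igraph::V(g)$driver_of <- driver_of
  # chain each subtype's drivers so the planted module is connected
  for (s in names(lay$drivers)) {
    d <- lay$drivers[[s]]
    if (length(d) > 1L) {
      path <- as.vector(rbind(d[-length(d)], d[-1L]))
      g <- igraph::add_edges(g, match(path, igraph::V(g)$name))
    }
  }
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    anchor <- which(comp$membership == main)[1L]
    for (cc in setdiff(seq_len(comp$no), main)) {
      v <- which(comp$membership == cc)[1L]
      g <- igraph::add_edges(g, c(v, anchor))
    }
  }
  g
}

#' Simulate a mutation cohort with planted subtypes
#'
#' Draws near-equal subtype sizes from a multinomial, then mutates each
#' tumor's subtype drivers at `driver_rate` and all other genes at
#' `background_rate`, independently.  Redraws sizes (deterministically
#' continuing the seeded stream) in the rare event a subtype comes up
#' empty.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with `mutations` (binary
#'   matrix), `network` (igraph), `truth_labels` (partition) and
#'   `truth_drivers` (list subtype -> gene set).
#' @export
simulate_cohort <- function(config = sim_config()) {
  network <- simulate_network(config)   # seeds the stream
  lay <- .block_layout(config)
  k <- config$k_subtypes
  repeat {
    sizes <- as.vector(stats::rmultinom(1L, config$n_tumors, config$proportions))
    if (all(sizes > 0L)) break
  }
  labels <- sample(rep(seq_len(k), sizes))
  tumors <- .tumor_ids(config$n_tumors)
  rate <- matrix(config$background_rate, config$n_tumors, config$n_genes,
                 dimnames = list(tumors, lay$genes))
  for (s in seq_len(k)) {
    rate[labels == s, lay$drivers[[as.character(s)]]] <- config$driver_rate
  }
  mutations <- matrix(stats::rbinom(length(rate), 1L, as.vector(rate)),
                      nrow = config$n_tumors,
                      dimnames = dimnames(rate))
  storage.mode(mutations) <- "double"
  truth <- as_partition(stats::setNames(as.character(labels), tumors))
  structure(list(mutations = mutations, network = network,
                 truth_labels = truth, truth_drivers = lay$drivers,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to the pipeline's standard files
#'
#' Writes `mutations.tsv` (tumors-by-genes TSV), `edges.txt` (3-column
#' edge list with a constant confidence score) and `truth.csv` (the
#' planted partition) to a directory.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param edge_score Constant confidence score written for simulated edges.
#' @export
write_cohort <- function(cohort, dir, edge_score = 999) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mutation_matrix(cohort$mutations, file.path(dir, "mutations.tsv"))
  el <- igraph::as_edgelist(cohort$network)
  utils::write.table(data.frame(el[, 1L], el[, 2L], edge_score),
                     file.path(dir, "edges.txt"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_partition(cohort$truth_labels, file.path(dir, "truth.csv"))
  invisible(dir)
}
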