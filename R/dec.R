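#' Configuration for the stacked auto-encoder
#'
#' The encoder is trained greedily: one auto-encoder per entry of
#' `layer_sizes`, each minimizing the squared reconstruction error
#' \eqn{\|y - x\|^2} of its own input, with inverted dropout applied to the
#' layer inputs during pretraining only.  The code of each auto-encoder
#' feeds the next; the last width is the latent dimension.  Hidden encoder
#' layers use ReLU, the final code layer is linear, decoders are linear.
#'
#' The `"deep"` preset keeps the reference stack geometry 514-500-200-500-514
#' (encoder widths 500 and 200); the default `c(64, 32)` is sized for
#' cohorts of a few hundred tumors and genes, where a 200-unit code would be
#' needlessly slow to train.
#'
#' @param layer_sizes Integer vector of encoder widths; the last entry is
#'   the latent dimension.
#' @param dropout_rate Dropout probability in \[0, 1) used during
#'   pretraining.
#' @param epochs Pretraining epochs per auto-encoder.
#' @param learning_rate,momentum SGD hyperparameters (shared with the
#'   self-training stage).
#' @param batch_size Minibatch size.
#' @param seed Single integer seeding every stochastic component (init,
#'   dropout, shuffling, k-means).
#' @param preset Either `"default"` or `"deep"`; ignored when `layer_sizes`
#'   is given explicitly.
#' @return A list of class `sae_config`.
#' @export
sae_config <- function(layer_sizes = NULL, dropout_rate = 0.2, epochs = 50,
                       learning_rate = 0.01, momentum = 0.9,
                       batch_size = 32, seed = 1, preset = "default") {
  if (is.null(layer_sizes)) {
    layer_sizes <- switch(preset,
                          default = c(64L, 32L),
                          deep = c(500L, 200L),
                          stop("unknown preset: ", preset))
  }
  stopifnot(length(layer_sizes) >= 1L, all(layer_sizes >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "sae_config")
}

#' Greedy layerwise pretraining of the stacked auto-encoder
#'
#' Trains one auto-encoder per configured width on the output of the
#' previous one and composes the encoders into a single map
#' \eqn{f_\theta : X \to Z}.  Mirrored decoders are retained so the
#' clustering stage can optionally keep a reconstruction term.
#'
#' @param X Numeric matrix (tumors by features), e.g. a propagated
#'   mutation matrix.
#' @param config An [sae_config()].
#' @return A list of class `sae_encoder` with `encoder` and `decoder` layer
#'   stacks and the pretraining `losses` per auto-encoder.
#' @export
pretrain_sae <- function(X, config = sae_config()) {
  stopifnot(is.matrix(X), is.numeric(X))
  set.seed(config$seed)
  latent <- config$layer_sizes[length(config$layer_sizes)]
  if (latent >= ncol(X)) {
    warning(sprintf("latent dimension %d is not smaller than the input dimension %d",
                    latent, ncol(X)))
  }
  cur <- X
  enc <- list()
  dec <- list()
  losses <- list()
  for (i in seq_along(config$layer_sizes)) {
    w <- config$layer_sizes[i]
    last <- i == length(config$layer_sizes)
    ae <- list(.new_layer(ncol(cur), w, act = if (last) "linear" else "relu"),
               .new_layer(w, ncol(cur), act = "linear"))
    fit <- .train_net(ae, cur, cur, epochs = config$epochs,
                      lr = config$learning_rate, momentum = config$momentum,
                      batch_size = config$batch_size,
                      dropout_rate = config$dropout_rate)
    enc[[i]] <- fit$layers[[1L]]
    dec[[i]] <- fit$layers[[2L]]
    losses[[i]] <- fit$losses
    cur <- .act_fun(sweep(cur %*% enc[[i]]$W, 2L, enc[[i]]$b, "+"),
                    enc[[i]]$act)
  }
  structure(list(encoder = enc, decoder = rev(dec), losses = losses,
                 config = config),
            class = "sae_encoder")
}

#' Map samples to the latent space
#'
#' @param encoder An `sae_encoder` or `dec_model`.
#' @param X Numeric matrix with the same feature columns used for training.
#' @return The latent matrix Z (samples by latent dimension).
#' @export
encode <- function(encoder, X) {
  layers <- if (inherits(encoder, "dec_model")) encoder$encoder else encoder$encoder
  cache <- .net_forward(layers, X)
  cache$acts[[length(layers) + 1L]]
}

.pairwise_sq_dist <- function(Z, centers) {
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") - 2 * Z %*% t(centers)
  pmax(d2, 0)
}

#' Student-t soft cluster assignment
#'
#' \deqn{q_{ij} = \frac{(1 + \|z_i - \mu_j\|^2)^{-1}}
#'                     {\sum_{j'} (1 + \|z_i - \mu_{j'}\|^2)^{-1}}}
#' Rows sum to one and every entry is strictly positive.
#'
#' @param Z Latent matrix (samples by d).
#' @param centers Centroid matrix (k by d), pairwise distinct.
#' @return The soft-assignment matrix Q (samples by k).
#' @export
soft_assign <- function(Z, centers) {
  Z <- as.matrix(Z); centers <- as.matrix(centers)
  stopifnot(ncol(Z) == ncol(centers))
  s <- 1 / (1 + .pairwise_sq_dist(Z, centers))
  s / rowSums(s)
}

#' Auxiliary target distribution for self-training
#'
#' Sharpens a soft assignment by squaring and renormalizing by the soft
#' cluster frequencies \eqn{f_j = \sum_i q_{ij}}:
#' \deqn{p_{ij} = \frac{q_{ij}^2 / f_j}{\sum_{j'} q_{ij'}^2 / f_{j'}}}
#'
#' @param Q Row-stochastic soft-assignment matrix.
#' @return The target matrix P with the same shape, rows summing to one.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  if (any(f == 0)) stop("dead cluster: soft frequency f_j = 0 for some cluster")
  W <- sweep(Q^2, 2L, f, "/")
  W / rowSums(W)
}

#' Kullback-Leibler divergence between row-stochastic matrices
#'
#' \eqn{\mathrm{KLD}(P\|Q) = \sum_i \sum_j p_{ij} \log(p_{ij}/q_{ij})},
#' with the convention \eqn{0 \log(0/q) = 0}.  If some \eqn{q_{ij} = 0}
#' where \eqn{p_{ij} > 0} the divergence is infinite (returned as `Inf`
#' with a warning).
#'
#' @param P,Q Matrices of matching shape with rows summing to one.
#' @return A non-negative number (zero iff P equals Q).
#' @export
kld <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(all(dim(P) == dim(Q)))
  pos <- P > 0
  if (any(Q[pos] == 0)) {
    warning("q_ij = 0 where p_ij > 0: divergence is infinite")
    return(Inf)
  }
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Deep embedded clustering
#'
#' Pretrains the stacked auto-encoder (unless a pretrained `encoder` is
#' supplied), initializes k centroids by k-means on the latent codes
#' (20 restarts, best inertia), then alternates (a) recomputing the soft
#' assignment Q and target distribution P over the full cohort and (b) one
#' epoch of minibatch SGD on the encoder parameters and centroids,
#' minimizing KLD(P || Q).  Self-training stops when the fraction of
#' samples whose hard label (argmax of Q) changed between consecutive
#' target refreshes falls below `label_change_tol`.
#'
#' Dropout is used only during pretraining.  By default the self-training
#' loss is the KL divergence alone; `recon_weight > 0` adds a squared
#' reconstruction term through the pretrained decoder.
#'
#' @param X Numeric matrix, typically a propagated mutation matrix.
#' @param k Number of clusters (k = 1 returns the trivial partition).
#' @param config An [sae_config()]; its seed drives all randomness.
#' @param label_change_tol Stopping threshold on the changed-label
#'   fraction; default 0.001.
#' @param max_updates Cap on target-distribution refreshes.
#' @param recon_weight Weight of the optional reconstruction loss
#'   (default 0 = pure KLD).
#' @param encoder Optional pretrained `sae_encoder` to reuse.
#' @return A list of class `dec_fit` with `model` (a `dec_model`:
#'   encoder layers, centroids `centers`, `k`), `partition` (hard labels),
#'   `Q`, number of `iterations`, `converged`, final `kld`, and
#'   `empty_clusters`.
#' @export
fit_dec <- function(X, k, config = sae_config(), label_change_tol = 0.001,
                    max_updates = 50, recon_weight = 0, encoder = NULL) {
  stopifnot(is.matrix(X), is.numeric(X), k >= 1, k <= nrow(X))
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  if (k == 1L) {
    part <- as_partition(stats::setNames(rep("1", nrow(X)), ids))
    model <- structure(list(encoder = NULL, centers = NULL, k = 1L),
                       class = "dec_model")
    return(structure(list(model = model, partition = part,
                          Q = matrix(1, nrow(X), 1L), iterations = 0L,
                          converged = TRUE, kld = 0,
                          empty_clusters = character(0)),
                     class = "dec_fit"))
  }
  set.seed(config$seed)
  if (is.null(encoder)) encoder <- pretrain_sae(X, config)
  layers <- encoder$encoder
  Z <- encode(encoder, X)
  km <- stats::kmeans(Z, centers = k, nstart = 20, iter.max = 100)
  mu <- km$centers
  lr <- config$learning_rate
  mom <- config$momentum
  vel <- .zero_velocity(layers)
  dec_vel <- .zero_velocity(encoder$decoder)
  vmu <- mu * 0
  n <- nrow(X)
  prev_labels <- NULL
  converged <- FALSE
  iter <- 0L
  final_kld <- NA_real_
  for (update in seq_len(max_updates)) {
    iter <- update
    Zfull <- .net_forward(layers, X)$acts[[length(layers) + 1L]]
    Q <- soft_assign(Zfull, mu)
    P <- target_distribution(Q)
    labels <- max.col(Q, ties.method = "first")
    final_kld <- kld(P, Q)
    if (!is.null(prev_labels) &&
        mean(labels != prev_labels) < label_change_tol) {
      converged <- TRUE
      break
    }
    prev_labels <- labels
    idx <- sample.int(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      b <- idx[start:min(start + config$batch_size - 1L, n)]
      cache <- .net_forward(layers, X[b, , drop = FALSE])
      z <- cache$acts[[length(layers) + 1L]]
      s <- 1 / (1 + .pairwise_sq_dist(z, mu))
      q <- s / rowSums(s)
      coef <- s * (P[b, , drop = FALSE] - q)          # n_b x k
      # dL/dz_i =  2 sum_j coef_ij (z_i - mu_j); dL/dmu_j = -(same, summed over i)
      dz <- 2 * (z * rowSums(coef) - coef %*% mu) / length(b)
      dmu <- -2 * (crossprod(coef, z) - colSums(coef) * mu) / length(b)
      if (recon_weight > 0) {
        dcache <- .net_forward(encoder$decoder, z)
        xhat <- dcache$acts[[length(encoder$decoder) + 1L]]
        derr <- 2 * recon_weight * (xhat - X[b, , drop = FALSE]) / length(b)
        dgrads <- .net_backward(encoder$decoder, dcache, derr)
        dstep <- .sgd_step(encoder$decoder, dgrads, dec_vel, lr, mom)
        encoder$decoder <- dstep$layers
        dec_vel <- dstep$vel
        dz <- dz + dgrads$d_input
      }
      grads <- .clip_grads(.net_backward(layers, cache, dz))
      step <- .sgd_step(layers, grads, vel, lr, mom)
      layers <- step$layers
      vel <- step$vel
      vmu <- mom * vmu - lr * dmu
      mu <- mu + vmu
    }
  }
  Zfull <- .net_forward(layers, X)$acts[[length(layers) + 1L]]
  Q <- soft_assign(Zfull, mu)
  labels <- max.col(Q, ties.method = "first")
  empty <- setdiff(as.character(seq_len(k)), as.character(unique(labels)))
  if (length(empty) > 0L) {
    warning(sprintf("%d cluster(s) empty at convergence: %s",
                    length(empty), paste(empty, collapse = ", ")))
  }
  encoder$encoder <- layers
  part <- as_partition(stats::setNames(as.character(labels), ids))
  model <- structure(list(encoder = layers, decoder = encoder$decoder,
                          centers = mu, k = as.integer(k)),
                     class = "dec_model")
  structure(list(model = model, partition = part, Q = Q,
                 iterations = iter, converged = converged, kld = final_kld,
                 empty_clusters = empty),
            class = "dec_fit")
}

#' Assign new samples with a fitted clustering model
#'
#' @param object A `dec_model` from [fit_dec()].
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return A list with the soft assignment `Q` and the hard `partition`.
#' @export
predict.dec_model <- function(object, newdata, ...) {
  if (object$k == 1L) {
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(newdata)))
    return(list(Q = matrix(1, nrow(newdata), 1L),
                partition = as_partition(stats::setNames(rep("1", nrow(newdata)), ids))))
  }
  Z <- .net_forward(object$encoder, newdata)$acts[[length(object$encoder) + 1L]]
  Q <- soft_assign(Z, object$centers)
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(newdata)))
  labels <- max.col(Q, ties.method = "first")
  list(Q = Q, partition = as_partition(stats::setNames(as.character(labels), ids)))
}
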