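# Minimal dense feed-forward machinery used by the stacked auto-encoder and
# the self-training clustering stage.  Layers are plain lists so models are
# serializable with saveRDS and fully reproducible from a seed.

.act_fun <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         linear = x,
         sigmoid = 1 / (1 + exp(-x)),
         stop("unknown activation: ", act))
}

.act_grad <- function(pre, act) {
  switch(act,
         relu = (pre > 0) * 1,
         linear = matrix(1, nrow(pre), ncol(pre)),
         sigmoid = { s <- 1 / (1 + exp(-pre)); s * (1 - s) },
         stop("unknown activation: ", act))
}

# Glorot-scaled random init; consumes the current RNG stream.
.new_layer <- function(d_in, d_out, act = "relu") {
  sd <- sqrt(2 / (d_in + d_out))
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = rep(0, d_out),
       act = act)
}

# Forward pass.  dropout_rate > 0 applies inverted dropout to the *input*
# of every layer (training mode only); masks are cached for backprop.
.net_forward <- function(layers, X, dropout_rate = 0, training = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  pres <- vector("list", L)
  masks <- vector("list", L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    xin <- acts[[l]]
    if (training && dropout_rate > 0) {
      m <- matrix(stats::runif(length(xin)) >= dropout_rate,
                  nrow(xin), ncol(xin)) / (1 - dropout_rate)
      xin <- xin * m
      masks[[l]] <- m
    }
    pre <- xin %*% layers[[l]]$W
    pre <- sweep(pre, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- .act_fun(pre, layers[[l]]$act)
    pres[[l]] <- pre
    acts[[l]] <- xin   # store the (possibly dropped) input actually used
  }
  list(acts = acts, pres = pres, masks = masks)
}

# Backward pass from the gradient of the loss w.r.t. the network output.
# Returns per-layer weight/bias gradients and the gradient w.r.t. the input.
.net_backward <- function(layers, cache, d_out) {
  L <- length(layers)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    d_pre <- d * .act_grad(cache$pres[[l]], layers[[l]]$act)
    gW[[l]] <- crossprod(cache$acts[[l]], d_pre)
    gb[[l]] <- colSums(d_pre)
    d <- d_pre %*% t(layers[[l]]$W)
    if (!is.null(cache$masks[[l]])) d <- d * cache$masks[[l]]
  }
  list(gW = gW, gb = gb, d_input = d)
}

# Global gradient-norm clipping: rescales all gradients when their joint
# L2 norm exceeds max_norm, keeping plain SGD stable across input scales.
.clip_grads <- function(grads, max_norm = 5) {
  total <- sqrt(sum(vapply(grads$gW, function(g) sum(g^2), 0)) +
                sum(vapply(grads$gb, function(g) sum(g^2), 0)))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    grads$gW <- lapply(grads$gW, `*`, sc)
    grads$gb <- lapply(grads$gb, `*`, sc)
  }
  grads
}

.zero_velocity <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

.sgd_step <- function(layers, grads, vel, lr, momentum) {
  for (l in seq_along(layers)) {
    vel[[l]]$W <- momentum * vel[[l]]$W - lr * grads$gW[[l]]
    vel[[l]]$b <- momentum * vel[[l]]$b - lr * grads$gb[[l]]
    layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
    layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
  }
  list(layers = layers, vel = vel)
}

# Train an arbitrary feed-forward net to map X -> Y under squared error
# ||y - x||^2 averaged over the minibatch, by minibatch SGD with momentum
# and gradient-norm clipping.  Returns the trained layers and the
# per-epoch mean loss trajectory.
.train_net <- function(layers, X, Y, epochs, lr, momentum, batch_size,
                       dropout_rate = 0) {
  n <- nrow(X)
  losses <- numeric(epochs)
  vel <- .zero_velocity(layers)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    total <- 0
    for (start in seq(1L, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1L, n)]
      cache <- .net_forward(layers, X[b, , drop = FALSE],
                            dropout_rate = dropout_rate, training = TRUE)
      out <- cache$acts[[length(layers) + 1L]]
      err <- out - Y[b, , drop = FALSE]
      total <- total + sum(err^2)
      grads <- .clip_grads(.net_backward(layers, cache, 2 * err / length(b)))
      step <- .sgd_step(layers, grads, vel, lr, momentum)
      layers <- step$layers
      vel <- step$vel
    }
    losses[e] <- total / n
  }
  list(layers = layers, losses = losses)
}
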