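# Dense feed-forward network for the neural classifier family:
# 17 -> 32 (ReLU) -> 16 (ReLU) -> 1 (sigmoid), binary cross-entropy,
# full-batch Adam. Inputs are standardised by the caller.

mlp_init <- function(n_in, units, seed) {
  sizes <- c(n_in, units)
  with_seed(seed, {
    lapply(seq_along(units), function(i) {
      # He initialisation for the ReLU layers
      sd <- sqrt(2 / sizes[i])
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0, sd),
                      sizes[i], sizes[i + 1L]),
           b = rep(0, sizes[i + 1L]))
    })
  })
}

mlp_forward <- function(layers, x, activations) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    acts[[i + 1L]] <- switch(activations[i],
      relu = pmax(z, 0),
      sigmoid = 1 / (1 + exp(-z)),
      stop("unknown activation: ", activations[i], call. = FALSE))
  }
  acts
}

mlp_train <- function(x, y, units = c(32L, 16L, 1L),
                      activations = c("relu", "relu", "sigmoid"),
                      epochs = 200L, learning_rate = 0.01, seed = 1L) {
  layers <- mlp_init(ncol(x), units, seed)
  n <- nrow(x)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  for (epoch in seq_len(epochs)) {
    acts <- mlp_forward(layers, x, activations)
    out <- acts[[length(acts)]]
    # d(BCE)/dz of the sigmoid output layer
    delta <- (out - y) / n
    for (i in rev(seq_along(layers))) {
      gW <- crossprod(acts[[i]], delta)
      gb <- colSums(delta)
      if (i > 1L) {
        delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
      }
      m[[i]]$W <- beta1 * m[[i]]$W + (1 - beta1) * gW
      m[[i]]$b <- beta1 * m[[i]]$b + (1 - beta1) * gb
      v[[i]]$W <- beta2 * v[[i]]$W + (1 - beta2) * gW^2
      v[[i]]$b <- beta2 * v[[i]]$b + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^epoch
      corr2 <- 1 - beta2^epoch
      layers[[i]]$W <- layers[[i]]$W -
        learning_rate * (m[[i]]$W / corr1) / (sqrt(v[[i]]$W / corr2) + adam_eps)
      layers[[i]]$b <- layers[[i]]$b -
        learning_rate * (m[[i]]$b / corr1) / (sqrt(v[[i]]$b / corr2) + adam_eps)
    }
  }
  list(layers = layers, activations = activations)
}

mlp_predict_prob <- function(net, x) {
  acts <- mlp_forward(net$layers, x, net$activations)
  as.numeric(acts[[length(acts)]])
}
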