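# Minimal fully-connected network machinery with explicit reverse-mode
# gradients: linear layers, batch normalization, ReLU, row-wise L2
# normalization, and Adam. Written directly in (BLAS-backed) matrix ops;
# gradient correctness is pinned by finite-difference tests.
#
# A network is list(layers = list(...)); each layer is a list with a
# `type` and its tensors. Batches are row-major (B x features).

.nn_linear <- function(d_in, d_out) {
  list(type = "linear",
       W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

.nn_bn <- function(d, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, d), beta = numeric(d),
       rmean = numeric(d), rvar = rep(1, d), momentum = momentum, eps = eps)
}

.nn_relu <- function() list(type = "relu")

# Four fully connected layers (3 hidden + output), each hidden layer
# followed by batch norm and ReLU; the output layer is affine.
nn_encoder <- function(input_dim, hidden_dims, embed_dim) {
  dims <- c(input_dim, hidden_dims)
  layers <- list()
  for (i in seq_along(hidden_dims)) {
    layers <- c(layers, list(.nn_linear(dims[i], dims[i + 1L]),
                             .nn_bn(dims[i + 1L]), .nn_relu()))
  }
  layers <- c(layers, list(.nn_linear(dims[length(dims)], embed_dim)))
  list(layers = layers)
}

# Two-layer MLP with an expanded hidden layer and ReLU non-linearity.
nn_decoder <- function(embed_in, embed_out, hidden = 4L * embed_out) {
  list(layers = list(.nn_linear(embed_in, hidden), .nn_relu(),
                     .nn_linear(hidden, embed_out)))
}

# Forward pass. Returns list(out, cache, net): `net` carries updated
# running statistics when training = TRUE.
nn_forward <- function(net, x, training = TRUE) {
  cache <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "linear") {
      cache[[i]] <- list(x = x)
      x <- sweep(x %*% l$W, 2L, l$b, "+")
    } else if (l$type == "relu") {
      mask <- x > 0
      cache[[i]] <- list(mask = mask)
      x <- x * mask
    } else if (l$type == "bn") {
      if (training && nrow(x) > 1L) {
        mu <- colMeans(x)
        va <- colMeans(x^2) - mu^2
        net$layers[[i]]$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu
        net$layers[[i]]$rvar <- (1 - l$momentum) * l$rvar + l$momentum * va
      } else {
        mu <- l$rmean
        va <- l$rvar
      }
      inv_sd <- 1 / sqrt(va + l$eps)
      xc <- sweep(x, 2L, mu)
      xhat <- sweep(xc, 2L, inv_sd, "*")
      cache[[i]] <- list(xc = xc, xhat = xhat, inv_sd = inv_sd,
                         batch_stats = training && nrow(x) > 1L)
      x <- sweep(sweep(xhat, 2L, l$gamma, "*"), 2L, l$beta, "+")
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, cache = cache, net = net)
}

# Backward pass. Returns list(grads, dx); grads[[i]] holds the gradient
# tensors for layer i (NULL for parameter-free layers).
nn_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    c_i <- cache[[i]]
    if (l$type == "linear") {
      grads[[i]] <- list(W = crossprod(c_i$x, dout), b = colSums(dout))
      dout <- dout %*% t(l$W)
    } else if (l$type == "relu") {
      dout <- dout * c_i$mask
    } else if (l$type == "bn") {
      dgamma <- colSums(dout * c_i$xhat)
      dbeta <- colSums(dout)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dxhat <- sweep(dout, 2L, l$gamma, "*")
      if (c_i$batch_stats) {
        B <- nrow(dout)
        # d/dx of (x - mu)/sqrt(var + eps) with batch mu, var
        t1 <- dxhat
        t2 <- matrix(colMeans(dxhat), B, ncol(dout), byrow = TRUE)
        t3 <- sweep(c_i$xhat, 2L, colMeans(dxhat * c_i$xhat), "*")
        dout <- sweep(t1 - t2 - t3, 2L, c_i$inv_sd, "*")
      } else {
        dout <- sweep(dxhat, 2L, c_i$inv_sd, "*")
      }
    }
  }
  list(grads = grads, dx = dout)
}

# --- parameter plumbing -----------------------------------------------

.nn_trainable <- c(linear = list(c("W", "b")), bn = list(c("gamma", "beta")))

# Flat named list of a network's trainable tensors.
nn_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (nm in .nn_trainable[[l$type]] %||% character(0))
      out[[paste0("L", i, ".", nm)]] <- l[[nm]]
  }
  out
}

nn_set_params <- function(net, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    i <- as.integer(sub("^L", "", parts[1L]))
    net$layers[[i]][[parts[2L]]] <- params[[key]]
  }
  net
}

# Gradients from nn_backward in the same flat layout as nn_params.
nn_flat_grads <- function(net, grads) {
  out <- list()
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) out[[paste0("L", i, ".", nm)]] <- g[[nm]]
  }
  out
}

# --- row-wise L2 normalization ----------------------------------------

l2_normalize <- function(x) {
  n <- sqrt(rowSums(x^2))
  n <- pmax(n, 1e-12)
  list(out = x / n, norm = n)
}

l2_normalize_backward <- function(dy, out, norm) {
  (dy - out * rowSums(dy * out)) / norm
}

# --- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(params)) {
    g <- grads[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / bc1
    vhat <- state$v[[key]] / bc2
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
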