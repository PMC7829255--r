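# Minimal neural-network layer engine: each layer is a list with a type,
# parameter matrices and (for batch norm) running buffers. Forward passes
# return the output plus a cache consumed by the matching backward pass;
# gradients are exact (validated against central differences in the tests).
#
# Data layout: sequence activations are arrays dim (batch, time, channels);
# dense activations are matrices (batch, features). Column-major flattening
# of (batch, time) into batch*time rows makes 1-D convolution an im2col
# matrix product handled by BLAS.

layer_dense <- function(n_in, n_out, activation = c("relu", "linear", "sigmoid")) {
  activation <- match.arg(activation)
  list(type = "dense", activation = activation,
       W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

layer_conv1d <- function(n_in_channels, filters, kernel = 3L) {
  fan_in <- kernel * n_in_channels
  list(type = "conv1d", kernel = kernel, filters = filters,
       W = matrix(stats::rnorm(fan_in * filters, sd = sqrt(2 / fan_in)),
                  fan_in, filters),
       b = numeric(filters))
}

layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", momentum = momentum, eps = eps,
       gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

layer_maxpool <- function(width = 2L) list(type = "maxpool", width = width)

layer_relu <- function() list(type = "relu")

layer_dropout <- function(rate) list(type = "dropout", rate = rate)

layer_flatten <- function() list(type = "flatten")

layer_reshape_seq <- function() list(type = "reshape_seq")

layer_lstm <- function(n_in, units, return_sequences = FALSE) {
  s <- 1 / sqrt(units)
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1   # forget-gate bias
  list(type = "lstm", units = units, return_sequences = return_sequences,
       Wx = matrix(stats::runif(n_in * 4 * units, -s, s), n_in, 4 * units),
       Wh = matrix(stats::runif(units * 4 * units, -s, s), units, 4 * units),
       b = b)
}

as_seq_matrix <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_seq_array <- function(m, batch, time) {
  dim(m) <- c(batch, time, ncol(m) %||% dim(m)[2])
  m
}

im2col <- function(x, kernel) {
  d <- dim(x)                       # (batch, time, ch)
  half <- (kernel - 1L) %/% 2L
  pad <- array(0, dim = c(d[1], d[2] + 2L * half, d[3]))
  pad[, (half + 1L):(half + d[2]), ] <- x
  cols <- vector("list", kernel)
  for (k in seq_len(kernel)) {
    sl <- pad[, k:(k + d[2] - 1L), , drop = FALSE]
    dim(sl) <- c(d[1] * d[2], d[3])
    cols[[k]] <- sl
  }
  do.call(cbind, cols)
}

col2im <- function(dM, dims, kernel) {
  d <- dims
  half <- (kernel - 1L) %/% 2L
  dpad <- array(0, dim = c(d[1], d[2] + 2L * half, d[3]))
  for (k in seq_len(kernel)) {
    blk <- dM[, ((k - 1L) * d[3] + 1L):(k * d[3]), drop = FALSE]
    dim(blk) <- c(d[1], d[2], d[3])
    dpad[, k:(k + d[2] - 1L), ] <- dpad[, k:(k + d[2] - 1L), , drop = FALSE] + blk
  }
  dpad[, (half + 1L):(half + d[2]), , drop = FALSE]
}

apply_activation <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

activation_grad <- function(out, activation) {
  switch(activation,
         relu = (out > 0) * 1,
         sigmoid = out * (1 - out),
         linear = 1)
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      z <- sweep(x %*% layer$W, 2, layer$b, `+`)
      out <- apply_activation(z, layer$activation)
      list(layer = layer, out = out, cache = list(x = x, out = out))
    },
    conv1d = {
      d <- dim(x)
      M <- im2col(x, layer$kernel)
      z <- sweep(M %*% layer$W, 2, layer$b, `+`)
      out <- as_seq_array(z, d[1], d[2])
      list(layer = layer, out = out, cache = list(M = M, dims = d))
    },
    batchnorm = {
      d <- dim(x)
      xm <- as_seq_matrix(x)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu, `-`)^2)
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu, `-`), 2, invstd, `*`)
      out <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
      list(layer = layer, out = as_seq_array(out, d[1], d[2]),
           cache = list(xhat = xhat, invstd = invstd, dims = d,
                        training = training))
    },
    maxpool = {
      d <- dim(x)
      nt <- d[2] %/% layer$width
      out <- x[, seq(1L, by = layer$width, length.out = nt), , drop = FALSE]
      mask <- array(1L, dim(out))
      for (w in seq_len(layer$width)[-1]) {
        bset <- x[, seq(w, by = layer$width, length.out = nt), , drop = FALSE]
        upd <- bset > out          # ties keep the earlier position
        out[upd] <- bset[upd]
        mask[upd] <- w
      }
      list(layer = layer, out = out, cache = list(mask = mask, dims = d, nt = nt))
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- array(stats::runif(length(x)) >= layer$rate, dim(x) %||% length(x))
        out <- x * keep / (1 - layer$rate)
        list(layer = layer, out = out, cache = list(keep = keep))
      } else {
        list(layer = layer, out = x, cache = list(keep = NULL))
      }
    },
    flatten = {
      d <- dim(x)
      # (batch, time, ch) -> (batch, time*ch); column-major keeps batch rows
      out <- matrix(x, nrow = d[1])
      list(layer = layer, out = out, cache = list(dims = d))
    },
    reshape_seq = {
      out <- array(x, dim = c(nrow(x), ncol(x), 1L))
      list(layer = layer, out = out, cache = list(dims = dim(x)))
    },
    relu = {
      out <- pmax(x, 0)
      list(layer = layer, out = out, cache = list(out = out))
    },
    lstm = lstm_forward(layer, x),
    stop_invalid("unknown layer type ", layer$type)
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      dz <- dout * activation_grad(cache$out, layer$activation)
      list(dx = dz %*% t(layer$W),
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    },
    conv1d = {
      d <- cache$dims
      dz <- as_seq_matrix(dout)
      dW <- crossprod(cache$M, dz)
      db <- colSums(dz)
      dM <- dz %*% t(layer$W)
      list(dx = col2im(dM, d, layer$kernel), grads = list(W = dW, b = db))
    },
    batchnorm = {
      d <- cache$dims
      dy <- as_seq_matrix(dout)
      xhat <- cache$xhat
      n <- nrow(dy)
      dgamma <- colSums(dy * xhat)
      dbeta <- colSums(dy)
      if (cache$training) {
        dxhat <- sweep(dy, 2, layer$gamma, `*`)
        dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                      sweep(xhat, 2, colMeans(dxhat * xhat), `*`),
                    2, cache$invstd, `*`)
      } else {
        dx <- sweep(sweep(dy, 2, layer$gamma, `*`), 2, cache$invstd, `*`)
      }
      list(dx = as_seq_array(dx, d[1], d[2]),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    maxpool = {
      d <- cache$dims
      dx <- array(0, d)
      nt <- cache$nt
      for (w in seq_len(layer$width)) {
        sel <- cache$mask == w
        slice <- array(0, dim(dout))
        slice[sel] <- dout[sel]
        dx[, seq(w, by = layer$width, length.out = nt), ] <- slice
      }
      list(dx = dx, grads = list())
    },
    dropout = {
      if (!is.null(cache$keep)) {
        list(dx = dout * cache$keep / (1 - layer$rate), grads = list())
      } else list(dx = dout, grads = list())
    },
    flatten = {
      list(dx = array(dout, cache$dims), grads = list())
    },
    reshape_seq = {
      list(dx = matrix(dout, cache$dims[1], cache$dims[2]), grads = list())
    },
    relu = {
      list(dx = dout * (cache$out > 0), grads = list())
    },
    lstm = lstm_backward(layer, cache, dout),
    stop_invalid("unknown layer type ", layer$type)
  )
}

lstm_forward <- function(layer, x) {
  d <- dim(x)                       # (batch, time, in)
  batch <- d[1]; time <- d[2]
  u <- layer$units
  h <- matrix(0, batch, u)
  cs <- matrix(0, batch, u)
  steps <- vector("list", time)
  outs <- if (layer$return_sequences) array(0, c(batch, time, u)) else NULL
  for (t in seq_len(time)) {
    xt <- matrix(x[, t, ], batch, d[3])
    z <- xt %*% layer$Wx + h %*% layer$Wh
    z <- sweep(z, 2, layer$b, `+`)
    i <- 1 / (1 + exp(-z[, 1:u, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, (u + 1):(2 * u), drop = FALSE]))
    o <- 1 / (1 + exp(-z[, (2 * u + 1):(3 * u), drop = FALSE]))
    g <- tanh(z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cs
    h_prev <- h
    cs <- f * cs + i * g
    tc <- tanh(cs)
    h <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, o = o, g = g,
                       c_prev = c_prev, h_prev = h_prev, cs = cs, tc = tc)
    if (layer$return_sequences) outs[, t, ] <- h
  }
  out <- if (layer$return_sequences) outs else h
  list(layer = layer, out = out, cache = list(steps = steps, dims = d))
}

lstm_backward <- function(layer, cache, dout) {
  d <- cache$dims
  batch <- d[1]; time <- d[2]; n_in <- d[3]
  u <- layer$units
  dWx <- matrix(0, n_in, 4 * u)
  dWh <- matrix(0, u, 4 * u)
  db <- numeric(4 * u)
  dx <- array(0, d)
  dh_next <- matrix(0, batch, u)
  dc_next <- matrix(0, batch, u)
  for (t in rev(seq_len(time))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (layer$return_sequences) dh <- dh + matrix(dout[, t, ], batch, u)
    else if (t == time) dh <- dh + dout
    do_ <- dh * st$tc * st$o * (1 - st$o)
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g * st$i * (1 - st$i)
    df <- dc * st$c_prev * st$f * (1 - st$f)
    dg <- dc * st$i * (1 - st$g^2)
    dz <- cbind(di, df, do_, dg)
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(layer$Wx)
    dh_next <- dz %*% t(layer$Wh)
    dc_next <- dc * st$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

layer_param_names <- function(layer) {
  switch(layer$type,
         dense = c("W", "b"),
         conv1d = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         lstm = c("Wx", "Wh", "b"),
         character())
}

layer_update_sgd <- function(layer, grads, lr, momentum, scale = 1) {
  for (p in layer_param_names(layer)) {
    g <- grads[[p]] * scale
    vname <- paste0(".v_", p)
    v <- layer[[vname]] %||% (g * 0)
    v <- momentum * v - lr * g
    layer[[p]] <- layer[[p]] + v
    layer[[vname]] <- v
  }
  layer
}
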