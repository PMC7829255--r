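# Instantiation and execution of intermediate-fusion networks. A network is
# a list of runtime layers per MNet plus the head; forward passes cache the
# intermediates needed by backpropagation, and batch-norm running statistics
# live on the layers themselves (hence layers are threaded through calls).

instantiate_layers <- function(descriptors, shape, dropout_rate) {
  layers <- list()
  for (l in descriptors) {
    switch(l$kind,
      conv_block = {
        layers <- c(layers, list(layer_conv1d(shape$channels, l$width),
                                 layer_batchnorm(l$width),
                                 layer_relu(),
                                 layer_maxpool(2L)))
        shape <- list(kind = "seq", time = shape$time %/% 2L, channels = l$width)
      },
      lstm = {
        layers <- c(layers, list(layer_lstm(shape$channels, l$width,
                                            return_sequences = l$sequences)))
        shape <- if (l$sequences) list(kind = "seq", time = shape$time,
                                       channels = l$width)
                 else list(kind = "dense", d = l$width)
      },
      flatten = {
        if (shape$kind == "seq") {
          layers <- c(layers, list(layer_flatten()))
          shape <- list(kind = "dense", d = shape$time * shape$channels)
        }
      },
      reshape_seq = {
        layers <- c(layers, list(layer_reshape_seq()))
        shape <- list(kind = "seq", time = shape$d, channels = 1L)
      },
      dense_hidden = {
        layers <- c(layers, list(layer_dense(shape$d, l$width, "relu")))
        if (dropout_rate > 0) layers <- c(layers, list(layer_dropout(dropout_rate)))
        shape <- list(kind = "dense", d = l$width)
      },
      dense_proj = {
        layers <- c(layers, list(layer_dense(shape$d, l$width, "linear")))
        shape <- list(kind = "dense", d = l$width)
      },
      output = {
        layers <- c(layers, list(layer_dense(shape$d, 1L, "sigmoid")))
        shape <- list(kind = "dense", d = 1L)
      })
  }
  list(layers = layers, shape = shape)
}

#' Build an intermediate-fusion network with freshly initialized weights
#'
#' Instantiates one MNet per enabled modality and the shared head described
#' by `spec`. Weight initialization draws from R's RNG; seed it (or use the
#' `seed` argument) for reproducible builds.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed for weight initialization.
#' @return An `mwl_network` object; its predictions always lie in \[0, 1\]
#'   (single sigmoid output unit).
#' @export
build_model <- function(spec, seed = NULL) {
  if (!inherits(spec, "model_spec")) stop_invalid("spec must be a model_spec")
  if (!is.null(seed)) set.seed(seed)
  mnets <- list()
  proj_widths <- integer()
  for (m in spec$modalities) {
    shp <- spec$input_shapes[[m]]
    res <- instantiate_layers(
      build_mnet(m, spec$variant, spec$dropout_rate, spec$width_scale),
      list(kind = "seq", time = as.integer(shp[[1]]),
           channels = as.integer(shp[[2]])),
      dropout_rate = spec$dropout_rate)
    mnets[[m]] <- res$layers
    proj_widths[[m]] <- res$shape$d
  }
  head <- instantiate_layers(head_layers(spec),
                             list(kind = "dense", d = sum(proj_widths)),
                             dropout_rate = spec$dropout_rate)$layers
  structure(list(spec = spec, mnets = mnets, head = head,
                 proj_widths = proj_widths),
            class = "mwl_network")
}

#' @export
print.mwl_network <- function(x, ...) {
  cat(sprintf("<mwl_network %s (%s): fused width %d>\n", x$spec$variant,
              paste(x$spec$modalities, collapse = "+"), sum(x$proj_widths)))
  invisible(x)
}

run_layers <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (j in seq_along(layers)) {
    r <- layer_forward(layers[[j]], x, training = training)
    layers[[j]] <- r$layer
    caches[[j]] <- r$cache
    x <- r$out
  }
  list(layers = layers, out = x, caches = caches)
}

backprop_layers <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (j in rev(seq_along(layers))) {
    r <- layer_backward(layers[[j]], caches[[j]], dout)
    grads[[j]] <- r$grads
    dout <- r$dx
  }
  list(grads = grads, dx = dout)
}

forward_network <- function(net, batch, training = FALSE) {
  outs <- list()
  mnet_caches <- list()
  for (m in net$spec$modalities) {
    if (is.null(batch[[m]])) {
      stop(errorCondition(paste0("batch is missing modality '", m, "'"),
                          class = c("mwlfuse_shape_error", "error")))
    }
    shp <- net$spec$input_shapes[[m]]
    d <- dim(batch[[m]])
    if (length(d) != 3L || d[2] != shp[[1]] || d[3] != shp[[2]]) {
      stop(errorCondition(
        sprintf("modality '%s' window shape (%s) does not match spec (%d x %d)",
                m, paste(d[-1], collapse = " x "), shp[[1]], shp[[2]]),
        class = c("mwlfuse_shape_error", "error")))
    }
    r <- run_layers(net$mnets[[m]], batch[[m]], training)
    net$mnets[[m]] <- r$layers
    outs[[m]] <- r$out
    mnet_caches[[m]] <- r$caches
  }
  fused <- do.call(cbind, outs[net$spec$modalities])
  r <- run_layers(net$head, fused, training)
  net$head <- r$layers
  list(net = net, pred = as.numeric(r$out),
       caches = list(mnets = mnet_caches, head = r$caches))
}

backward_network <- function(net, caches, dpred) {
  hb <- backprop_layers(net$head, caches$head, matrix(dpred, ncol = 1))
  grads <- list(head = hb$grads, mnets = list())
  dfused <- hb$dx
  offset <- 0L
  for (m in net$spec$modalities) {
    w <- net$proj_widths[[m]]
    dm <- dfused[, (offset + 1L):(offset + w), drop = FALSE]
    offset <- offset + w
    mb <- backprop_layers(net$mnets[[m]], caches$mnets[[m]], dm)
    grads$mnets[[m]] <- mb$grads
  }
  grads
}

update_network <- function(net, grads, lr, momentum) {
  for (j in seq_along(net$head)) {
    if (length(grads$head[[j]])) {
      net$head[[j]] <- layer_update_sgd(net$head[[j]], grads$head[[j]],
                                        lr, momentum)
    }
  }
  for (m in names(net$mnets)) {
    for (j in seq_along(net$mnets[[m]])) {
      if (length(grads$mnets[[m]][[j]])) {
        net$mnets[[m]][[j]] <- layer_update_sgd(net$mnets[[m]][[j]],
                                                grads$mnets[[m]][[j]],
                                                lr, momentum)
      }
    }
  }
  net
}

# Stack sample windows into per-modality arrays (batch, time, channels),
# optionally standardizing with per-channel statistics.
batch_arrays <- function(samples, modalities, norm = NULL) {
  out <- list()
  for (m in modalities) {
    w1 <- samples[[1]]$windows[[m]]
    arr <- array(0, dim = c(length(samples), nrow(w1), ncol(w1)))
    for (b in seq_along(samples)) arr[b, , ] <- samples[[b]]$windows[[m]]
    if (!is.null(norm)) {
      mu <- norm[[m]]$mean; sdv <- norm[[m]]$sd
      for (ch in seq_len(dim(arr)[3])) {
        arr[, , ch] <- (arr[, , ch] - mu[ch]) / sdv[ch]
      }
    }
    out[[m]] <- arr
  }
  out
}

# Per-modality, per-channel mean and SD over a list of samples.
normalization_stats <- function(samples, modalities) {
  stats_of <- function(m) {
    mats <- lapply(samples, function(s) s$windows[[m]])
    all <- do.call(rbind, mats)
    mu <- colMeans(all)
    sdv <- apply(all, 2, stats::sd)
    sdv[sdv < 1e-8] <- 1
    list(mean = mu, sd = sdv)
  }
  out <- lapply(modalities, stats_of)
  names(out) <- modalities
  out
}
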