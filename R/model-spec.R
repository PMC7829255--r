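# Architecture tables for the four intermediate-fusion variants. Widths are
# the full-sized unit/filter counts; the S_ variants use exactly half of
# every width, and `width_scale` can shrink all widths further for reduced-
# scale experiments. Every MNet ends in a flatten plus one linear dense
# projection; the projections are concatenated in the fixed order
# (PPG, GSR, ET, fNIRS) and fed to the shared head, which ends in a single
# sigmoid unit.

VARIANTS <- c("MLP", "S_MLP", "LIT", "S_LIT")

PROJECTION_WIDTHS <- c(PPG = 256, GSR = 256, ET = 1024, fNIRS = 2048)

variant_family <- function(variant) sub("^S_", "", variant)

variant_half <- function(variant) grepl("^S_", variant)

mnet_architecture <- function(modality, family) {
  if (family == "MLP") {
    widths <- switch(modality,
      PPG = c(256), GSR = c(256),
      ET = c(1024, 1024), fNIRS = c(2048, 2048),
      stop_invalid("unknown modality '", modality, "'"))
    c(list(list(kind = "flatten")),
      lapply(widths, function(w) list(kind = "dense_hidden", width = w)),
      list(list(kind = "dense_proj", width = PROJECTION_WIDTHS[[modality]])))
  } else if (family == "LIT") {
    switch(modality,
      PPG = list(list(kind = "conv_block", width = 128),
                 list(kind = "conv_block", width = 128),
                 list(kind = "flatten"),
                 list(kind = "dense_proj", width = 256)),
      GSR = list(list(kind = "conv_block", width = 128),
                 list(kind = "conv_block", width = 128),
                 list(kind = "lstm", width = 256, sequences = TRUE),
                 list(kind = "lstm", width = 256, sequences = FALSE),
                 list(kind = "dense_proj", width = 256)),
      ET = list(list(kind = "conv_block", width = 256),
                list(kind = "conv_block", width = 256),
                list(kind = "conv_block", width = 256),
                list(kind = "conv_block", width = 256),
                list(kind = "flatten"),
                list(kind = "dense_proj", width = 1024)),
      fNIRS = list(list(kind = "conv_block", width = 512),
                   list(kind = "conv_block", width = 512),
                   list(kind = "flatten"),
                   list(kind = "dense_hidden", width = 2048),
                   list(kind = "dense_hidden", width = 2048),
                   list(kind = "dense_proj", width = 2048)),
      stop_invalid("unknown modality '", modality, "'"))
  } else {
    stop_invalid("unknown variant family '", family, "'")
  }
}

head_architecture <- function(family) {
  if (family == "MLP") {
    list(list(kind = "dense_hidden", width = 3584),
         list(kind = "dense_hidden", width = 2048),
         list(kind = "dense_hidden", width = 1024),
         list(kind = "dense_hidden", width = 512),
         list(kind = "output"))
  } else {
    list(list(kind = "dense_hidden", width = 3584),
         list(kind = "dense_hidden", width = 4096),
         list(kind = "reshape_seq"),
         list(kind = "conv_block", width = 512),
         list(kind = "conv_block", width = 512),
         list(kind = "conv_block", width = 256),
         list(kind = "flatten"),
         list(kind = "dense_hidden", width = 512),
         list(kind = "dense_hidden", width = 256),
         list(kind = "output"))
  }
}

scale_width <- function(width, variant, width_scale) {
  f <- width_scale * if (variant_half(variant)) 0.5 else 1
  max(1L, as.integer(floor(width * f)))
}

default_input_shapes <- function(window_length = 8,
                                 rates = DEFAULT_RATES,
                                 channels = DEFAULT_CHANNELS) {
  shapes <- lapply(MODALITIES, function(m) {
    c(time = as.integer(round(window_length * rates[[m]])),
      channels = channels[[m]])
  })
  names(shapes) <- MODALITIES
  shapes
}

#' Describe an intermediate-fusion model architecture
#'
#' @param variant One of `"MLP"`, `"S_MLP"`, `"LIT"`, `"S_LIT"`. The `S_`
#'   variants use exactly half of every layer width of the full variant.
#' @param modalities Enabled modalities, non-empty subset of
#'   `c("PPG", "GSR", "ET", "fNIRS")`. Concatenation order is fixed to this
#'   canonical order regardless of how the subset is written.
#' @param dropout_rate Dropout applied after each hidden dense layer (not to
#'   projections or the output).
#' @param input_shapes Named list of `c(time, channels)` per modality;
#'   defaults to 8-s windows at the native rates (2048x1 GSR and PPG,
#'   960x4 ET, 80x54 fNIRS).
#' @param width_scale Extra multiplier on every width (default 1); used for
#'   reduced-scale experiments.
#' @return A `model_spec` object.
#' @export
model_spec <- function(variant = c("MLP", "S_MLP", "LIT", "S_LIT"),
                       modalities = MODALITIES,
                       dropout_rate = 0.1,
                       input_shapes = default_input_shapes(),
                       width_scale = 1) {
  variant <- match.arg(variant)
  modalities <- unique(modalities)
  if (length(modalities) == 0L || !all(modalities %in% MODALITIES)) {
    stop_invalid("modalities must be a non-empty subset of ",
                 paste(MODALITIES, collapse = ", "))
  }
  modalities <- MODALITIES[MODALITIES %in% modalities]
  assert_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  missing_shapes <- setdiff(modalities, names(input_shapes))
  if (length(missing_shapes)) {
    stop_invalid("input_shapes missing for: ",
                 paste(missing_shapes, collapse = ", "))
  }
  structure(list(variant = variant, modalities = modalities,
                 dropout_rate = dropout_rate,
                 input_shapes = input_shapes[modalities],
                 width_scale = width_scale),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %s; dropout %.2f; fused width %d; %s parameters>\n",
              x$variant, paste(x$modalities, collapse = "+"), x$dropout_rate,
              fused_width(x), format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Layer stack of one per-modality sub-network (MNet)
#'
#' Returns the architecture description of the MNet for one modality:
#' convolutional blocks (1-D convolution, kernel 3, stride 1, same padding;
#' batch normalization; rectifier; max-pool width 2) and/or dense layers per
#' the variant's width table, terminated by a flatten and a single linear
#' dense projection whose width is the modality's fusion contribution.
#'
#' @param modality One of `"PPG"`, `"GSR"`, `"ET"`, `"fNIRS"`.
#' @param variant Model variant.
#' @param dropout_rate Dropout rate for hidden dense layers.
#' @param width_scale Extra width multiplier.
#' @return List of layer descriptors (`kind`, scaled `width`).
#' @export
build_mnet <- function(modality, variant = c("MLP", "S_MLP", "LIT", "S_LIT"),
                       dropout_rate = 0.1, width_scale = 1) {
  variant <- match.arg(variant)
  if (!modality %in% MODALITIES) stop_invalid("unknown modality '", modality, "'")
  arch <- mnet_architecture(modality, variant_family(variant))
  lapply(arch, function(l) {
    if (!is.null(l$width)) l$width <- scale_width(l$width, variant, width_scale)
    l$dropout <- dropout_rate
    l
  })
}

head_layers <- function(spec) {
  arch <- head_architecture(variant_family(spec$variant))
  lapply(arch, function(l) {
    if (!is.null(l$width)) {
      l$width <- scale_width(l$width, spec$variant, spec$width_scale)
    }
    l$dropout <- spec$dropout_rate
    l
  })
}

#' Width of the fused representation
#'
#' The head consumes the concatenation of the enabled MNet projections, so
#' the fused width is the sum of the (scaled) per-modality projection widths:
#' 256 (PPG) + 256 (GSR) + 1024 (ET) + 2048 (fNIRS) = 3584 for the
#' full-sized four-modality model.
#'
#' @param spec A [model_spec()].
#' @return Integer width.
#' @export
fused_width <- function(spec) {
  as.integer(sum(vapply(spec$modalities, function(m) {
    scale_width(PROJECTION_WIDTHS[[m]], spec$variant, spec$width_scale)
  }, numeric(1))))
}

# Walk an architecture, tracking the activation shape and parameter count.
# shape: list(kind = "seq", time, channels) or list(kind = "dense", d).
walk_layers <- function(layers, shape, count_only = TRUE) {
  params <- 0
  for (l in layers) {
    switch(l$kind,
      conv_block = {
        if (shape$kind != "seq") stop_invalid("conv block needs sequence input")
        params <- params + (3 * shape$channels + 1) * l$width + 2 * l$width
        shape <- list(kind = "seq", time = shape$time %/% 2L, channels = l$width)
      },
      lstm = {
        n_in <- if (shape$kind == "seq") shape$channels else
          stop_invalid("lstm needs sequence input")
        params <- params + 4 * l$width * (n_in + l$width + 1)
        shape <- if (l$sequences) list(kind = "seq", time = shape$time,
                                       channels = l$width)
                 else list(kind = "dense", d = l$width)
      },
      flatten = {
        if (shape$kind == "seq") {
          shape <- list(kind = "dense", d = shape$time * shape$channels)
        }
      },
      reshape_seq = {
        shape <- list(kind = "seq", time = shape$d, channels = 1L)
      },
      dense_hidden = ,
      dense_proj = {
        if (shape$kind != "dense") stop_invalid(l$kind, " needs flat input")
        params <- params + (shape$d + 1) * l$width
        shape <- list(kind = "dense", d = l$width)
      },
      output = {
        params <- params + shape$d + 1
        shape <- list(kind = "dense", d = 1L)
      },
      stop_invalid("unknown layer kind ", l$kind))
  }
  list(params = params, shape = shape)
}

#' Trainable parameter count of a model spec
#'
#' Computed analytically from the architecture tables and input shapes
#' (convolution and batch-norm parameters, LSTM gate matrices, dense
#' weights and biases), without instantiating any weights.
#'
#' @param spec A [model_spec()].
#' @return Number of trainable parameters.
#' @export
count_parameters <- function(spec) {
  total <- 0
  for (m in spec$modalities) {
    shp <- spec$input_shapes[[m]]
    res <- walk_layers(build_mnet(m, spec$variant, spec$dropout_rate,
                                  spec$width_scale),
                       list(kind = "seq", time = shp[[1]], channels = shp[[2]]))
    total <- total + res$params
  }
  res <- walk_layers(head_layers(spec),
                     list(kind = "dense", d = fused_width(spec)))
  total + res$params
}
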