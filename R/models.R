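#' Specification of the 4-channel 1D residual CNN
#'
#' The default layer table: a stem convolution (kernel 32, 64 filters,
#' stride 2), four residual stages of (4, 3, 3, 4) double-convolution
#' blocks with kernel 7 and filter counts growing 64-128-256-512 (stride 2
#' on the first convolution of each stage), then average pooling (kernel
#' 3), global average pooling, dropout (p = 0.3), and a dense 512 -> 4
#' softmax head. Total convolution layers: 1 + 2 * (4+3+3+4) = 29. The
#' `reduced` preset keeps the same topology at desk scale (one block per
#' stage, narrower filters, shorter channels) for fast CPU training.
#'
#' @param channel_length Length of each of the 4 input channels
#'   (default 2^15; never dictated by the architecture itself).
#' @param stem_filters,stem_kernel,stem_stride Stem convolution geometry.
#' @param blocks Residual blocks per stage.
#' @param filters Filter count per stage.
#' @param kernel Convolution kernel inside residual blocks.
#' @param avgpool_kernel Average-pooling kernel at the head.
#' @param dropout_p Dropout probability before the dense head.
#' @param n_classes Number of phenotype classes.
#' @param reduced If `TRUE`, return the reduced desk-scale preset.
#' @return A list of class `model_1d_spec`.
#' @export
model_1d_spec <- function(channel_length = 2L^15L, stem_filters = 64L,
                          stem_kernel = 32L, stem_stride = 2L,
                          blocks = c(4L, 3L, 3L, 4L),
                          filters = c(64L, 128L, 256L, 512L),
                          kernel = 7L, avgpool_kernel = 3L,
                          dropout_p = 0.3, n_classes = 4L,
                          reduced = FALSE) {
  if (reduced) {
    channel_length <- 512L; stem_filters <- 8L; stem_kernel <- 16L
    blocks <- c(1L, 1L, 1L, 1L); filters <- c(8L, 16L, 16L, 32L)
  }
  stopifnot(length(blocks) == length(filters))
  structure(list(channel_length = as.integer(channel_length),
                 in_channels = 4L,
                 stem_filters = as.integer(stem_filters),
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride),
                 blocks = as.integer(blocks),
                 filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 avgpool_kernel = as.integer(avgpool_kernel),
                 dropout_p = dropout_p,
                 n_classes = as.integer(n_classes)),
            class = "model_1d_spec")
}

#' Specification of the 3D CNN
#'
#' Eight 3D convolution layers (valid padding), batch normalization after
#' each convolution, PReLU activations, three max-pooling layers whose
#' strides equal their kernels, adaptive average pooling to (2, 2, 2), and
#' a dense 4096 -> 64 -> 4 head. On the default 256 x 256 x 98 input the
#' convolution cascade lands exactly on 512 channels x (2, 2, 2) = 4096
#' features, so the adaptive pool is the identity there.
#'
#' @param input_dim Input volume (height, width, depth), default
#'   `c(256, 256, 98)`.
#' @param n_classes Number of phenotype classes.
#' @return A list of class `model_3d_spec` with a `layers` table.
#' @export
model_3d_spec <- function(input_dim = c(256L, 256L, 98L), n_classes = 4L) {
  layers <- list(
    list(op = "conv", kernel = c(7L, 9L, 9L), filters = 16L),
    list(op = "maxpool", kernel = c(3L, 3L, 3L)),
    list(op = "conv", kernel = c(5L, 7L, 7L), filters = 16L),
    list(op = "maxpool", kernel = c(2L, 2L, 2L)),
    list(op = "conv", kernel = c(5L, 7L, 7L), filters = 32L),
    list(op = "maxpool", kernel = c(2L, 2L, 2L)),
    list(op = "conv", kernel = c(2L, 5L, 5L), filters = 32L),
    list(op = "conv", kernel = c(2L, 5L, 5L), filters = 64L),
    list(op = "conv", kernel = c(1L, 3L, 3L), filters = 128L),
    list(op = "conv", kernel = c(1L, 3L, 3L), filters = 256L),
    list(op = "conv", kernel = c(1L, 3L, 3L), filters = 512L))
  structure(list(input_dim = as.integer(input_dim),
                 layers = layers,
                 adaptive_out = c(2L, 2L, 2L),
                 dense_widths = c(4096L, 64L, n_classes),
                 n_classes = as.integer(n_classes)),
            class = "model_3d_spec")
}

#' Build the 4-channel 1D residual CNN
#'
#' @param spec A [model_1d_spec()].
#' @param seed Integer seed for the variance-scaling weight initialization.
#' @return An object of class `ms_model` mapping a 4 x channel_length input
#'   to 4 class probabilities.
#' @export
build_1d_model <- function(spec = model_1d_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_1d_spec"))
  # every stage halves the length once, as does the stem; the head needs at
  # least `avgpool_kernel` positions left
  n_halvings <- 1L + length(spec$blocks)
  min_len <- spec$avgpool_kernel * 2L^n_halvings
  if (spec$channel_length < min_len)
    stop(sprintf("channel_length %d too short for the stride cascade; minimum is %d",
                 spec$channel_length, min_len))
  set.seed(as.integer(seed))
  layers <- list(layer_conv1d(spec$in_channels, spec$stem_filters,
                              spec$stem_kernel, spec$stem_stride),
                 layer_bn(spec$stem_filters),
                 layer_gelu())
  in_ch <- spec$stem_filters
  for (s in seq_along(spec$blocks)) {
    for (b in seq_len(spec$blocks[s])) {
      stride <- if (b == 1L) 2L else 1L
      layers <- c(layers, list(layer_residual1d(in_ch, spec$filters[s],
                                                spec$kernel, stride)))
      in_ch <- spec$filters[s]
    }
  }
  layers <- c(layers,
              list(layer_avgpool1d(spec$avgpool_kernel),
                   layer_globalavg1d(),
                   layer_dropout(spec$dropout_p),
                   # near-zero head: an untrained model answers uniformly
                   layer_dense(in_ch, spec$n_classes, init_scale = 0.01)))
  structure(list(type = "1d", spec = spec, layers = layers,
                 embed_dim = in_ch, seed = as.integer(seed)),
            class = "ms_model")
}

#' Build the 3D CNN
#'
#' @param spec A [model_3d_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ms_model` mapping one volume (either omics
#'   layer) to 4 class probabilities.
#' @export
build_3d_model <- function(spec = model_3d_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_3d_spec"))
  set.seed(as.integer(seed))
  layers <- list()
  in_ch <- 1L
  for (ls in spec$layers) {
    if (ls$op == "conv") {
      layers <- c(layers, list(layer_conv3d(in_ch, ls$filters, ls$kernel),
                               layer_bn(ls$filters),
                               layer_prelu(ls$filters)))
      in_ch <- ls$filters
    } else {
      layers <- c(layers, list(layer_maxpool3d(ls$kernel)))
    }
  }
  layers <- c(layers,
              list(layer_adaptiveavg3d(spec$adaptive_out),
                   layer_flatten(),
                   layer_dense(spec$dense_widths[1], spec$dense_widths[2]),
                   layer_prelu(spec$dense_widths[2]),
                   layer_dense(spec$dense_widths[2], spec$dense_widths[3],
                               init_scale = 0.01)))
  structure(list(type = "3d", spec = spec, layers = layers,
                 embed_dim = spec$dense_widths[2], seed = as.integer(seed)),
            class = "ms_model")
}

#' @export
print.ms_model <- function(x, ...) {
  audit <- audit_architecture(x)
  cat(sprintf("<ms_model %s> %d convolution layers, embedding dim %d, %d classes\n",
              x$type, sum(audit$type %in% c("conv1d", "conv3d")),
              x$embed_dim, x$spec$n_classes))
  invisible(x)
}

walk_layers <- function(layers) {
  rows <- list()
  for (l in layers) {
    if (l$type == "residual1d") {
      rows <- c(rows, walk_layers(l$main), walk_layers(l$skip))
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        type = l$type,
        kernel = if (!is.null(l$kernel)) paste(l$kernel, collapse = "x") else NA,
        filters = if (!is.null(l$out_ch)) l$out_ch else
          if (!is.null(l$n_out)) l$n_out else NA,
        stride = if (!is.null(l$stride)) l$stride else NA,
        stringsAsFactors = FALSE)
    }
  }
  rows
}

#' Programmatic audit of a built model's architecture
#'
#' Walks every layer (descending into residual blocks, main path before
#' skip projection) and tabulates type, kernel, filter count and stride,
#' so the layer tables of both classifiers can be checked mechanically.
#'
#' @param model An `ms_model`.
#' @return A data frame with one row per primitive layer.
#' @export
audit_architecture <- function(model) {
  do.call(rbind, walk_layers(model$layers))
}

#' Count the convolution layers of a model
#' @param model An `ms_model`.
#' @param include_projections Count the 1-kernel skip projections of
#'   residual blocks too? Default `FALSE`: the canonical layer count (29
#'   for the default 1D model, 8 for the 3D model) refers to the stem and
#'   block convolutions.
#' @return Integer count.
#' @export
count_conv_layers <- function(model, include_projections = FALSE) {
  audit <- audit_architecture(model)
  n <- sum(audit$type %in% c("conv1d", "conv3d"))
  if (!include_projections) {
    n_proj <- sum(audit$type == "conv1d" & audit$kernel == "1")
    n <- n - n_proj
  }
  n
}

# input check + list-of-samples coercion shared by forward paths
coerce_batch <- function(model, x) {
  if (is.list(x)) return(x)
  if (model$type == "1d") {
    if (is.matrix(x)) return(list(x))
    if (length(dim(x)) == 3) # (n, 4, L)
      return(lapply(seq_len(dim(x)[1]), function(i) x[i, , ]))
  } else {
    d <- dim(x)
    if (length(d) == 3) { # one volume (H, W, frames) -> (1, depth, H, W)
      v <- aperm(x, c(3, 1, 2))
      dim(v) <- c(1, d[3], d[1], d[2])
      return(list(v))
    }
    if (length(d) == 4 && d[1] == 1) return(list(x))
  }
  stop("cannot interpret input shape for model type ", model$type)
}

#' Forward pass: class probabilities
#'
#' @param model An `ms_model`.
#' @param x Input batch: for the 1D model a 4 x L matrix, an n x 4 x L
#'   array, or a list of matrices; for the 3D model a volume (as from
#'   [file_to_volume()]) or a list of (1, depth, H, W) arrays.
#' @param training Run in training mode (batch statistics, active dropout)?
#' @return A matrix (n x n_classes) of softmax probabilities.
#' @export
model_predict_proba <- function(model, x, training = FALSE) {
  xs <- coerce_batch(model, x)
  res <- forward_layers(model$layers, xs, training)
  do.call(rbind, lapply(res$out, softmax))
}

#' Penultimate embedding of inputs
#'
#' Returns the flattened features entering the final dense layer, in
#' evaluation mode: a 512-vector for the default 1D model (the filter
#' count of its last stage), a 64-vector for the 3D model.
#'
#' @param model An `ms_model`.
#' @param x Input batch (see [model_predict_proba()]).
#' @return A matrix (n x embed_dim).
#' @export
model_embed <- function(model, x) {
  xs <- coerce_batch(model, x)
  n_layers <- length(model$layers)
  res <- forward_layers(model$layers[-n_layers], xs, training = FALSE)
  do.call(rbind, lapply(res$out, as.numeric))
}
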