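#' Convolutional network architecture specifications
#'
#' A `cnn_spec` is an ordered list of layer descriptors plus an input shape
#' `c(height, width, channels)`. Convolution layers carry batch
#' normalisation and ReLU activation; spatial arithmetic for convolutions
#' and max-pools follows `out = floor((in + 2*pad - kernel)/stride) + 1`.
#' Every classifier ends `fully_connected(2) -> softmax -> classification`.
#'
#' @param input_shape Integer vector `c(h, w, c)`.
#' @param layers List of layer descriptors created by [conv_layer()],
#'   [pool_layer()], [fc_layer()] etc.
#' @param name Spec name.
#' @return An object of class `cnn_spec`. Construction validates dimension
#'   propagation and fails naming the first layer whose output would have a
#'   non-positive size.
#' @export
cnn_spec <- function(input_shape, layers, name = "cnn") {
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  spec <- structure(list(input_shape = as.integer(input_shape),
                         layers = layers, name = name),
                    class = "cnn_spec")
  propagate_dims(spec)   # validates
  spec
}

#' @rdname cnn_spec
#' @param filters Number of convolution filters.
#' @param kernel,stride,pad Kernel size, stride and zero padding; scalars
#'   are used for both spatial axes.
#' @export
conv_layer <- function(filters, kernel = 3, stride = 1, pad = 1) {
  list(kind = "conv", filters = as.integer(filters),
       kernel = rep_len(as.integer(kernel), 2L),
       stride = rep_len(as.integer(stride), 2L),
       pad = rep_len(as.integer(pad), 2L),
       batch_norm = TRUE, relu = TRUE)
}

#' @rdname cnn_spec
#' @export
pool_layer <- function(kernel, stride = 2, pad = 0) {
  list(kind = "max_pool",
       kernel = rep_len(as.integer(kernel), 2L),
       stride = rep_len(as.integer(stride), 2L),
       pad = rep_len(as.integer(pad), 2L))
}

#' @rdname cnn_spec
#' @param units Number of output units of a fully connected layer.
#' @param relu Apply ReLU after the layer (default for hidden layers).
#' @export
fc_layer <- function(units, relu = TRUE) {
  list(kind = "fully_connected", units = as.integer(units),
       relu = isTRUE(relu))
}

flatten_layer <- function() list(kind = "flatten")
softmax_layer <- function() list(kind = "softmax")
classification_layer <- function() list(kind = "classification")

#' Propagate layer output shapes through a spec
#'
#' Applies the floor rule `out = floor((in + 2*pad - kernel)/stride) + 1`
#' through every convolution and pooling layer and tracks the flatten width
#' and fully-connected sizes.
#'
#' @param spec A [cnn_spec()].
#' @return List with one entry per layer: the output shape `c(h, w, c)` for
#'   spatial layers or the unit count for flatten/dense layers.
#' @export
propagate_dims <- function(spec) {
  shape <- spec$input_shape
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    out[[i]] <- switch(
      ly$kind,
      conv = ,
      max_pool = {
        hw <- floor((shape[1:2] + 2L * ly$pad - ly$kernel) / ly$stride) + 1L
        if (any(hw < 1L))
          stop("layer ", i, " (", ly$kind, "): output size ",
               paste(hw, collapse = "x"),
               " is non-positive for input ",
               paste(shape[1:2], collapse = "x"))
        shape <- c(hw, if (ly$kind == "conv") ly$filters else shape[3])
        shape
      },
      flatten = {
        shape <- prod(shape)
        shape
      },
      fully_connected = {
        if (length(shape) != 1L)
          stop("layer ", i, ": fully connected layer needs flattened input")
        shape <- ly$units
        shape
      },
      softmax = shape,
      classification = shape,
      stop("unknown layer kind: ", ly$kind))
  }
  out
}

#' Flatten width of a spec
#'
#' Number of features entering the first fully connected layer.
#'
#' @param spec A [cnn_spec()].
#' @return Integer.
#' @export
flatten_width <- function(spec) {
  dims <- propagate_dims(spec)
  i <- which(vapply(spec$layers, `[[`, "", "kind") == "flatten")
  if (!length(i)) stop("spec has no flatten point")
  dims[[i[1]]]
}

#' @export
print.cnn_spec <- function(x, ...) {
  dims <- propagate_dims(x)
  cat(sprintf("<cnn_spec> %s  input %s\n", x$name,
              paste(x$input_shape, collapse = "x")))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    d <- dims[[i]]
    cat(sprintf("  %2d %-16s -> %s\n", i, ly$kind,
                paste(d, collapse = "x")))
  }
  invisible(x)
}

#' The 17-layer wavelet-scalogram classifier architecture
#'
#' Seven convolution blocks (batch norm + ReLU; kernel 3, stride 1, pad 1;
#' 32, 48, 64, 96, 128, 192, 256 filters), each followed by a stride-2
#' max-pool with kernels `[3 2], 2, 3, [3 2], [2 3], [4 5], 2`, then fully
#' connected layers 1536 (the flatten width) -> 24 -> 2 and a softmax +
#' classification head. With the default 333 x 500 x 3 input, the per-layer
#' spatial sizes are 166x250, 83x125, 41x62, 20x31, 10x15, 4x6, 2x3 and the
#' flatten width is 2*3*256 = 1536. Smaller inputs (desk profile) can be
#' built by passing reduced `filters`/`pools`.
#'
#' @param input_shape `c(height, width, channels)` of the scalogram image.
#' @param filters Convolution filter counts.
#' @param pools List of max-pool kernels (scalar or `c(kh, kw)`), one per
#'   convolution block.
#' @param fc_units Hidden fully-connected sizes before the 2-unit head.
#' @return A [cnn_spec()].
#' @export
build_ws_cnn <- function(input_shape = c(333L, 500L, 3L),
                         filters = c(32L, 48L, 64L, 96L, 128L, 192L, 256L),
                         pools = list(c(3L, 2L), 2L, 3L, c(3L, 2L),
                                      c(2L, 3L), c(4L, 5L), 2L),
                         fc_units = 24L) {
  stopifnot(length(filters) == length(pools))
  layers <- list()
  for (i in seq_along(filters)) {
    layers <- c(layers, list(conv_layer(filters[i]),
                             pool_layer(pools[[i]], stride = 2)))
  }
  layers <- c(layers, list(flatten_layer()),
              lapply(fc_units, fc_layer),
              list(fc_layer(2L, relu = FALSE), softmax_layer(),
                   classification_layer()))
  cnn_spec(input_shape, layers, name = "ws_cnn")
}

#' The 14-layer dominant-feature-matrix (wavelet/Fourier) classifier
#'
#' A 2D network for `L x 3 x 1` inputs (CWT-at-scale-80, band-limited
#' reconstruction, raw). Six convolution blocks (kernel 3, stride 1,
#' pad 1), the first five each followed by a max-pool that acts only along
#' the time axis (kernel and stride `[4 1]`), so the 3-column feature axis
#' is preserved until the flatten point and no pool reduces the time axis
#' by more than a factor 4. Counting the flatten row and the two dense
#' layers as the fully-connected block, the schedule is 14 layers deep and
#' builds for both the full-scale L = 51,302 and reduced desk-scale
#' lengths (L >= 1024).
#'
#' @param input_length Segment length L.
#' @param n_cols Number of feature columns (3).
#' @param filters Six convolution filter counts.
#' @param fc_units Hidden fully-connected sizes.
#' @return A [cnn_spec()].
#' @export
build_wf_cnn <- function(input_length = 51302L, n_cols = 3L,
                         filters = c(16L, 24L, 32L, 48L, 64L, 96L),
                         fc_units = 24L) {
  stopifnot(length(filters) == 6L)
  layers <- list()
  for (i in seq_along(filters)) {
    layers <- c(layers, list(conv_layer(filters[i])))
    if (i < length(filters))
      layers <- c(layers, list(pool_layer(c(4L, 1L), stride = c(4L, 1L))))
  }
  layers <- c(layers, list(flatten_layer()),
              lapply(fc_units, fc_layer),
              list(fc_layer(2L, relu = FALSE), softmax_layer(),
                   classification_layer()))
  cnn_spec(c(input_length, n_cols, 1L), layers, name = "wf_cnn")
}

#' The 14-layer raw-signal 1D classifier
#'
#' Mirrors [build_wf_cnn()] for `L x 1` raw EEG segments: six convolution
#' blocks with 1D kernels (9 samples along time), five time-axis
#' max-pools of factor 4, then the fully-connected block and binary
#' softmax head.
#'
#' @param input_length Segment length L.
#' @param filters Six convolution filter counts.
#' @param kernel Time extent of the 1D convolution kernels.
#' @param fc_units Hidden fully-connected sizes.
#' @return A [cnn_spec()].
#' @export
build_1d_cnn <- function(input_length = 51302L,
                         filters = c(16L, 24L, 32L, 48L, 64L, 96L),
                         kernel = 9L, fc_units = 24L) {
  stopifnot(length(filters) == 6L)
  pad <- (kernel - 1L) %/% 2L
  layers <- list()
  for (i in seq_along(filters)) {
    layers <- c(layers, list(conv_layer(filters[i], kernel = c(kernel, 1L),
                                        stride = 1, pad = c(pad, 0L))))
    if (i < length(filters))
      layers <- c(layers, list(pool_layer(c(4L, 1L), stride = c(4L, 1L))))
  }
  layers <- c(layers, list(flatten_layer()),
              lapply(fc_units, fc_layer),
              list(fc_layer(2L, relu = FALSE), softmax_layer(),
                   classification_layer()))
  cnn_spec(c(input_length, 1L, 1L), layers, name = "cnn_1d")
}

#' Desk-scale profile
#'
#' Reduced problem sizes for laptop/CI runs: shorter segments (1024
#' samples, 4 s at 256 Hz), smaller rendered scalograms (50 x 33), fewer
#' filters and fewer epochs. Full-scale settings (51,302-sample segments,
#' 500 x 333 images, the printed filter schedule, 60 epochs) remain the
#' package defaults.
#'
#' @return Named list of profile settings.
#' @export
desk_profile <- function() {
  list(segment_length = 1024L,
       image_width = 50L, image_height = 33L,
       ws_filters = c(8L, 12L, 16L),
       ws_pools = list(2L, 2L, 2L),
       wf_filters = c(8L, 8L, 12L, 12L, 16L, 16L),
       epochs = 8L, batch_size = 32L)
}
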