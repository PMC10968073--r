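# Training engine for the cnn_spec architectures: vectorised im2col
# convolutions, batch normalisation, max-pooling, dense layers and a
# softmax cross-entropy head, optimised with RMSProp. All randomness
# (initialisation, validation split, epoch shuffling) is driven by the
# config seed, so training is reproducible bit for bit.

im2col_index <- function(Hp, Wp, C, kernel, stride, oh, ow) {
  ivec <- rep((0:(oh - 1)) * stride[1], times = ow)
  jvec <- rep((0:(ow - 1)) * stride[2], each = oh)
  K <- kernel[1] * kernel[2] * C
  IDX <- matrix(0L, oh * ow, K)
  q <- 0L
  for (c0 in 0:(C - 1)) for (kj in seq_len(kernel[2]))
    for (ki in seq_len(kernel[1])) {
      q <- q + 1L
      IDX[, q] <- (ivec + ki) + (jvec + kj - 1L) * Hp + c0 * Hp * Wp
    }
  IDX
}

conv_block_forward <- function(x, pm, ly, training = TRUE, eps = 1e-5,
                               momentum = 0.9) {
  d <- dim(x)
  H <- d[1]; W0 <- d[2]; C <- d[3]; N <- d[4]
  ph <- ly$pad[1]; pw <- ly$pad[2]
  Hp <- H + 2L * ph; Wp <- W0 + 2L * pw
  if (ph > 0 || pw > 0) {
    xp <- array(0, c(Hp, Wp, C, N))
    xp[ph + seq_len(H), pw + seq_len(W0), , ] <- x
  } else xp <- x
  oh <- (Hp - ly$kernel[1]) %/% ly$stride[1] + 1L
  ow <- (Wp - ly$kernel[2]) %/% ly$stride[2] + 1L
  IDX <- im2col_index(Hp, Wp, C, ly$kernel, ly$stride, oh, ow)
  K <- ncol(IDX)
  tmp <- matrix(xp, Hp * Wp * C, N)[as.vector(IDX), , drop = FALSE]
  M <- matrix(aperm(array(tmp, c(oh * ow, K, N)), c(1, 3, 2)),
              oh * ow * N, K)
  Z <- sweep(M %*% pm$W, 2, pm$b, "+")          # (oh*ow*N) x F
  f <- length(pm$b)
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(Z * Z) - mu^2
    pm$run_mean <- momentum * pm$run_mean + (1 - momentum) * mu
    pm$run_var <- momentum * pm$run_var + (1 - momentum) * va
  } else {
    mu <- pm$run_mean
    va <- pm$run_var
  }
  sdv <- sqrt(va + eps)
  xhat <- sweep(sweep(Z, 2, mu, "-"), 2, sdv, "/")
  A <- sweep(sweep(xhat, 2, pm$gamma, "*"), 2, pm$beta, "+")
  A[A < 0] <- 0                                  # ReLU
  out <- aperm(array(A, c(oh, ow, N, f)), c(1, 2, 4, 3))
  cache <- if (training)
    list(M = M, IDX = IDX, xhat = xhat, sdv = sdv, act = A,
         in_dim = d, pad_dim = c(Hp, Wp), out_hw = c(oh, ow)) else NULL
  list(out = out, cache = cache, pm = pm)
}

conv_block_backward <- function(dout, cache, pm, ly) {
  oh <- cache$out_hw[1]; ow <- cache$out_hw[2]
  d <- cache$in_dim
  N <- d[4]
  f <- length(pm$b)
  dA <- matrix(aperm(dout, c(1, 2, 4, 3)), oh * ow * N, f)
  dA[cache$act <= 0] <- 0                        # ReLU gate
  # batch-norm backward (per filter over all positions and images)
  m <- nrow(dA)
  dgamma <- colSums(dA * cache$xhat)
  dbeta <- colSums(dA)
  dxhat <- sweep(dA, 2, pm$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dZ <- sweep(
    dxhat - matrix(s1 / m, m, f, byrow = TRUE) -
      cache$xhat * matrix(s2 / m, m, f, byrow = TRUE),
    2, cache$sdv, "/")
  db <- colSums(dZ)
  dW <- crossprod(cache$M, dZ)
  dM <- dZ %*% t(pm$W)
  K <- nrow(pm$W)
  dM2 <- matrix(aperm(array(dM, c(oh * ow, N, K)), c(1, 3, 2)),
                oh * ow * K, N)
  rs <- rowsum(dM2, group = rep(as.vector(cache$IDX), 1L))
  Hp <- cache$pad_dim[1]; Wp <- cache$pad_dim[2]
  dxp <- matrix(0, Hp * Wp * d[3], N)
  dxp[as.integer(rownames(rs)), ] <- rs
  dxp <- array(dxp, c(Hp, Wp, d[3], N))
  ph <- ly$pad[1]; pw <- ly$pad[2]
  dx <- dxp[ph + seq_len(d[1]), pw + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db, gamma = dgamma, beta = dbeta))
}

pool_forward <- function(x, ly) {
  d <- dim(x)
  oh <- (d[1] - ly$kernel[1]) %/% ly$stride[1] + 1L
  ow <- (d[2] - ly$kernel[2]) %/% ly$stride[2] + 1L
  out <- array(-Inf, c(oh, ow, d[3], d[4]))
  arg <- array(0L, c(oh, ow, d[3], d[4]))
  for (kj in seq_len(ly$kernel[2])) for (ki in seq_len(ly$kernel[1])) {
    sl <- x[(0:(oh - 1)) * ly$stride[1] + ki,
            (0:(ow - 1)) * ly$stride[2] + kj, , , drop = FALSE]
    m <- sl > out
    out[m] <- sl[m]
    arg[m] <- (kj - 1L) * ly$kernel[1] + ki
  }
  list(out = out, cache = list(arg = arg, in_dim = d, out_hw = c(oh, ow)))
}

pool_backward <- function(dout, cache, ly) {
  oh <- cache$out_hw[1]; ow <- cache$out_hw[2]
  dx <- array(0, cache$in_dim)
  for (kj in seq_len(ly$kernel[2])) for (ki in seq_len(ly$kernel[1])) {
    k <- (kj - 1L) * ly$kernel[1] + ki
    m <- cache$arg == k
    if (!any(m)) next
    ri <- (0:(oh - 1)) * ly$stride[1] + ki
    ci <- (0:(ow - 1)) * ly$stride[2] + kj
    dx[ri, ci, , ] <- dx[ri, ci, , , drop = FALSE] + dout * m
  }
  dx
}

init_cnn_params <- function(spec, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  shape <- spec$input_shape
  params <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      K <- prod(ly$kernel) * shape[3]
      params[[i]] <- list(
        W = matrix(stats::rnorm(K * ly$filters, sd = sqrt(2 / K)),
                   K, ly$filters),
        b = numeric(ly$filters),
        gamma = rep(1, ly$filters), beta = numeric(ly$filters),
        run_mean = numeric(ly$filters), run_var = rep(1, ly$filters))
      shape <- c(floor((shape[1:2] + 2 * ly$pad - ly$kernel) / ly$stride) + 1,
                 ly$filters)
    } else if (ly$kind == "max_pool") {
      shape <- c(floor((shape[1:2] + 2 * ly$pad - ly$kernel) / ly$stride) + 1,
                 shape[3])
    } else if (ly$kind == "flatten") {
      shape <- prod(shape)
    } else if (ly$kind == "fully_connected") {
      params[[i]] <- list(
        W = matrix(stats::rnorm(shape * ly$units, sd = sqrt(2 / shape)),
                   shape, ly$units),
        b = numeric(ly$units))
      shape <- ly$units
    }
  }
  params
}

# Forward pass; returns class probabilities and (in training mode) caches.
cnn_forward <- function(spec, params, x, training = FALSE) {
  caches <- vector("list", length(spec$layers))
  cur <- x
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      r <- conv_block_forward(cur, params[[i]], ly, training = training)
      cur <- r$out
      caches[[i]] <- r$cache
      params[[i]] <- r$pm                     # running stats updated
    } else if (ly$kind == "max_pool") {
      r <- pool_forward(cur, ly)
      cur <- r$out
      caches[[i]] <- r$cache
    } else if (ly$kind == "flatten") {
      d <- dim(cur)
      caches[[i]] <- d
      cur <- t(matrix(cur, prod(d[1:3]), d[4]))  # N x features
    } else if (ly$kind == "fully_connected") {
      Z <- sweep(cur %*% params[[i]]$W, 2, params[[i]]$b, "+")
      A <- if (ly$relu) pmax(Z, 0) else Z
      caches[[i]] <- list(x = cur, act = A)
      cur <- A
    } else if (ly$kind == "softmax") {
      z <- cur - apply(cur, 1, max)
      e <- exp(z)
      cur <- e / rowSums(e)
    }
    # classification layer: decision only, handled in predict
  }
  list(probs = cur, caches = caches, params = params)
}

# Backward pass from softmax cross-entropy; y_idx in {1, 2}.
cnn_backward <- function(spec, params, caches, probs, y_idx) {
  n <- nrow(probs)
  grads <- vector("list", length(spec$layers))
  delta <- probs
  delta[cbind(seq_len(n), y_idx)] <- delta[cbind(seq_len(n), y_idx)] - 1
  delta <- delta / n
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$kind %in% c("softmax", "classification")) next
    if (ly$kind == "fully_connected") {
      if (ly$relu) delta <- delta * (caches[[i]]$act > 0)
      grads[[i]] <- list(W = crossprod(caches[[i]]$x, delta),
                         b = colSums(delta))
      delta <- delta %*% t(params[[i]]$W)
    } else if (ly$kind == "flatten") {
      d <- caches[[i]]
      delta <- array(t(delta), d)
    } else if (ly$kind == "max_pool") {
      delta <- pool_backward(delta, caches[[i]], ly)
    } else if (ly$kind == "conv") {
      r <- conv_block_backward(delta, caches[[i]], params[[i]], ly)
      grads[[i]] <- r$grads
      delta <- r$dx
    }
  }
  grads
}

#' Training configuration
#'
#' RMSProp hyperparameters: learning rate 1e-3 and squared-gradient decay
#' 0.9 (the optimiser defaults), 60 epochs, with a stratified 90/10
#' train/validation split of the training partition.
#'
#' @param learning_rate RMSProp learning rate.
#' @param squared_gradient_decay RMSProp decay of the squared-gradient
#'   accumulator.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction of the data held out (stratified by
#'   class) for per-epoch validation.
#' @param seed Integer seed controlling initialisation, the validation
#'   split and epoch shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, squared_gradient_decay = 0.9,
                         epochs = 60L, batch_size = 32L,
                         validation_fraction = 0.1, seed = 1L,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, squared_gradient_decay > 0,
            squared_gradient_decay < 1, epochs >= 1, batch_size >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 squared_gradient_decay = squared_gradient_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train a CNN seizure classifier
#'
#' Optimises the given architecture with RMSProp on labelled inputs. No
#' denoising and no data augmentation are applied: inputs are consumed
#' exactly as provided. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param spec A [cnn_spec()].
#' @param x 4-D input array `(h, w, c, n)` matching the spec's input shape.
#' @param y Labels, `"HAS"`/`"non-HAS"`, length `n`; both classes must be
#'   present.
#' @param config A [train_config()].
#' @return An object of class `trained_classifier`: the spec, learned
#'   parameters, per-epoch history (loss/accuracy, validation loss/
#'   accuracy), the config and a fingerprint of the training data.
#' @export
train_classifier <- function(spec, x, y, config = train_config()) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(config, "train_config"))
  if (length(dim(x)) != 4L)
    stop("`x` must be a 4-D array (h, w, c, n)")
  if (!all(dim(x)[1:3] == spec$input_shape))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match the spec's ",
         paste(spec$input_shape, collapse = "x"))
  n <- dim(x)[4]
  if (n == 0L || length(y) == 0L) stop("empty training dataset")
  if (length(y) != n) stop("length(y) must match dim(x)[4]")
  y <- as.character(y)
  if (!all(y %in% c("HAS", "non-HAS")))
    stop("labels must be 'HAS' or 'non-HAS'")
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; both HAS and non-HAS ",
         "examples are required")
  y_idx <- ifelse(y == "HAS", 2L, 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  # stratified validation split
  val <- integer(0)
  if (config$validation_fraction > 0) {
    for (cls in c(1L, 2L)) {
      idx <- which(y_idx == cls)
      nv <- floor(length(idx) * config$validation_fraction)
      if (nv > 0) val <- c(val, sample(idx, nv))
    }
  }
  tr <- setdiff(seq_len(n), val)
  if (length(unique(y_idx[tr])) < 2L) {
    val <- integer(0)
    tr <- seq_len(n)
  }
  params <- init_cnn_params(spec, seed = config$seed + 1L)
  rms <- rapply(params, function(p) p * 0, how = "replace")
  lr <- config$learning_rate
  rho <- config$squared_gradient_decay
  eps <- 1e-8
  hist <- vector("list", config$epochs)
  trainable <- c("W", "b", "gamma", "beta")
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    losses <- numeric(0)
    correct <- 0L
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- x[, , , bi, drop = FALSE]
      fw <- cnn_forward(spec, params, xb, training = TRUE)
      params <- fw$params
      p <- fw$probs
      li <- -mean(log(pmax(p[cbind(seq_along(bi), y_idx[bi])], 1e-12)))
      if (!is.finite(li))
        stop("training aborted: non-finite loss at epoch ", ep,
             " (learning rate too high or degenerate inputs)")
      losses <- c(losses, li)
      correct <- correct + sum((p[, 2] > p[, 1]) == (y_idx[bi] == 2L))
      grads <- cnn_backward(spec, params, fw$caches, p, y_idx[bi])
      for (i in seq_along(params)) {
        if (is.null(grads[[i]])) next
        for (nm in intersect(names(grads[[i]]), trainable)) {
          g <- grads[[i]][[nm]]
          rms[[i]][[nm]] <- rho * rms[[i]][[nm]] + (1 - rho) * g * g
          params[[i]][[nm]] <- params[[i]][[nm]] -
            lr * g / (sqrt(rms[[i]][[nm]]) + eps)
        }
      }
    }
    row <- data.frame(epoch = ep, loss = mean(losses),
                      accuracy = correct / length(ord),
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (length(val)) {
      pv <- predict_probs(spec, params, x[, , , val, drop = FALSE])
      row$val_loss <- -mean(log(pmax(pv[cbind(seq_along(val), y_idx[val])],
                                     1e-12)))
      row$val_accuracy <- mean((pv[, 2] > pv[, 1]) == (y_idx[val] == 2L))
    }
    hist[[ep]] <- row
    if (config$verbose)
      message(sprintf("epoch %d/%d loss %.4f acc %.3f", ep, config$epochs,
                      row$loss, row$accuracy))
  }
  structure(
    list(spec = spec, params = params, config = config,
         history = do.call(rbind, hist),
         data_fingerprint = object_fingerprint(list(dim(x), y))),
    class = "trained_classifier")
}

# inference forward in memory-bounded chunks
predict_probs <- function(spec, params, x, chunk = 128L) {
  n <- dim(x)[4]
  out <- matrix(0, n, 2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- cnn_forward(spec, params, x[, , , idx, drop = FALSE],
                              training = FALSE)$probs
  }
  colnames(out) <- c("non-HAS", "HAS")
  out
}

#' Predict seizure probabilities and labels
#'
#' @param object A [train_classifier()] result.
#' @param x 4-D input array matching the spec's input shape.
#' @param type `"prob"` (n x 2 softmax matrix), `"score"` (HAS-class
#'   probability) or `"label"` (argmax; an exact tie is called
#'   `"non-HAS"`, the conservative choice).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.trained_classifier <- function(object, x,
                                       type = c("prob", "score", "label"),
                                       ...) {
  type <- match.arg(type)
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (!all(dim(x)[1:3] == object$spec$input_shape))
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match the classifier's ",
         paste(object$spec$input_shape, collapse = "x"))
  p <- predict_probs(object$spec, object$params, x)
  switch(type,
         prob = p,
         score = p[, "HAS"],
         label = ifelse(p[, "HAS"] > p[, "non-HAS"], "HAS", "non-HAS"))
}

#' @export
print.trained_classifier <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<trained_classifier> %s  %d epochs  final loss %.4f acc %.3f\n",
    x$spec$name, nrow(x$history), h$loss, h$accuracy))
  invisible(x)
}

#' Convert labelled segments to classifier inputs
#'
#' Builds the 4-D input arrays the three detectors consume: `"ws"` renders
#' each segment's Morlet scalogram as an RGB image (`height x width x 3`),
#' `"wf"` stacks the three dominant-feature columns (`L x 3 x 1`), `"1d"`
#' passes the raw segment (`L x 1 x 1`). Raw-amplitude front-ends are
#' scaled by a fixed factor 1/100 (microvolts to order-one units); the
#' image front-end is already in the unit range.
#'
#' @param segments List of [eeg_segment()].
#' @param frontend `"ws"`, `"wf"` or `"1d"`.
#' @param width,height Rendered image size for `"ws"`.
#' @param scales CWT scale grid for `"ws"`.
#' @param input_scale Amplitude scaling for the `"wf"`/`"1d"` front-ends.
#' @return 4-D array with `length(segments)` slabs plus a `labels`
#'   attribute.
#' @export
segments_to_input <- function(segments, frontend = c("ws", "wf", "1d"),
                              width = 500L, height = 333L,
                              scales = seq(1, 500, by = 5),
                              input_scale = 1 / 100) {
  frontend <- match.arg(frontend)
  stopifnot(length(segments) >= 1L)
  L <- length(segments[[1]]$samples)
  n <- length(segments)
  x <- switch(frontend,
    "1d" = {
      a <- array(0, c(L, 1L, 1L, n))
      for (i in seq_len(n)) a[, 1, 1, i] <- segments[[i]]$samples * input_scale
      a
    },
    wf = {
      a <- array(0, c(L, 3L, 1L, n))
      for (i in seq_len(n))
        a[, , 1, i] <- unclass(compute_wf_matrix(segments[[i]])) * input_scale
      a
    },
    ws = {
      a <- array(0, c(height, width, 3L, n))
      plan <- cwt_plan(L, scales)
      for (i in seq_len(n)) {
        co <- cwt_apply(segments[[i]]$samples -
                          mean(segments[[i]]$samples), plan)
        sg <- structure(list(coefficients = abs(co), scales = scales,
                             fs = segments[[i]]$fs, wavelet = "morlet"),
                        class = "scalogram")
        a[, , , i] <- render_scalogram_image(sg, width = width,
                                             height = height)
      }
      a
    })
  attr(x, "labels") <- vapply(segments, `[[`, "", "label")
  x
}

# Precomputed-kernel CWT for repeated transforms of equal-length signals.
cwt_plan <- function(L, scales) {
  hmax <- ceiling(4 * max(scales))
  m <- stats::nextn(L + 2L * hmax, 2)
  kf <- vector("list", length(scales))
  hs <- integer(length(scales))
  for (i in seq_along(scales)) {
    a <- scales[i]
    h <- ceiling(4 * a)
    ker <- morl_psi(((-h):h) / a) / sqrt(a)
    kf[[i]] <- stats::fft(c(ker, numeric(m - length(ker))))
    hs[i] <- h
  }
  list(L = L, m = m, kf = kf, hs = hs, n_scales = length(scales))
}

cwt_apply <- function(x, plan) {
  X <- stats::fft(c(x, numeric(plan$m - plan$L)))
  out <- matrix(0, plan$n_scales, plan$L)
  for (i in seq_len(plan$n_scales)) {
    Y <- stats::fft(X * plan$kf[[i]], inverse = TRUE) / plan$m
    out[i, ] <- Re(Y[(plan$hs[i] + 1):(plan$hs[i] + plan$L)])
  }
  out
}
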