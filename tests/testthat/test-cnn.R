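# Independent dimension-propagation oracle: the floor rule applied by hand.
propagate_oracle <- function(hw, schedule) {
  out <- list()
  for (step in schedule) {
    hw <- floor((hw + 2 * step$pad - step$kernel) / step$stride) + 1
    out[[length(out) + 1L]] <- hw
  }
  out
}

test_that("the 17-layer scalogram net reproduces every tabulated size", {
  spec <- build_ws_cnn()
  dims <- propagate_dims(spec)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  pool_dims <- lapply(dims[kinds == "max_pool"], function(s) s[1:2])
  # hand propagation through the reference conv/pool schedule
  pools <- list(c(3, 2), c(2, 2), c(3, 3), c(3, 2), c(2, 3), c(4, 5),
                c(2, 2))
  schedule <- list()
  for (p in pools) {
    schedule <- c(schedule,
                  list(list(kernel = c(3, 3), stride = c(1, 1),
                            pad = c(1, 1)),
                       list(kernel = p, stride = c(2, 2), pad = c(0, 0))))
  }
  oracle <- propagate_oracle(c(333, 500), schedule)
  expect_equal(pool_dims, oracle[seq(2, 14, by = 2)])
  expect_equal(pool_dims,
               list(c(166, 250), c(83, 125), c(41, 62), c(20, 31),
                    c(10, 15), c(4, 6), c(2, 3)))
  expect_equal(flatten_width(spec), 1536L)
  # convolutions preserve spatial size (kernel 3, stride 1, pad 1)
  conv_dims <- lapply(dims[kinds == "conv"], function(s) s[1:2])
  expect_equal(conv_dims[[1]], c(333L, 500L))
  # reference filter schedule
  expect_equal(vapply(spec$layers[kinds == "conv"], `[[`, 0L, "filters"),
               c(32L, 48L, 64L, 96L, 128L, 192L, 256L))
})

test_that("incompatible input shapes fail naming the offending layer", {
  expect_error(build_ws_cnn(input_shape = c(100, 100, 3)),
               "layer \\d+ \\(max_pool\\)")
})

test_that("the 14-layer nets build at full and desk scale", {
  for (L in c(51302L, 1024L)) {
    wf <- build_wf_cnn(L)
    d1 <- build_1d_cnn(L)
    for (spec in list(wf, d1)) {
      kinds <- vapply(spec$layers, `[[`, "", "kind")
      # 14 layers under the table counting convention: conv/pool stack plus
      # the fully-connected block (flatten, hidden, binary head)
      expect_equal(sum(kinds %in% c("conv", "max_pool")) +
                     sum(kinds == "flatten") +
                     sum(kinds == "fully_connected"), 14L)
      # binary head: last dense layer has 2 units, then softmax/classification
      fc <- which(kinds == "fully_connected")
      expect_equal(spec$layers[[fc[length(fc)]]]$units, 2L)
      expect_equal(kinds[(length(kinds) - 1):length(kinds)],
                   c("softmax", "classification"))
    }
    # the 3-column axis of the feature matrix survives to the flatten point
    dims <- propagate_dims(wf)
    kindsw <- vapply(wf$layers, `[[`, "", "kind")
    pre_flat <- dims[[which(kindsw == "flatten") - 1L]]
    expect_equal(pre_flat[2], 3L)
  }
})

test_that("no pool reduces the time axis by more than a factor four", {
  for (spec in list(build_wf_cnn(51302L), build_1d_cnn(51302L),
                    build_wf_cnn(1024L))) {
    dims <- propagate_dims(spec)
    kinds <- vapply(spec$layers, `[[`, "", "kind")
    for (i in which(kinds == "max_pool")) {
      before <- if (i == 1) spec$input_shape[1] else dims[[i - 1]][1]
      expect_lte(before / dims[[i]][1], 4.1)
    }
  }
})

test_that("analytic gradients match finite differences on a small net", {
  ns <- asNamespace("hasdetect")
  spec <- cnn_spec(c(6L, 5L, 2L), list(
    conv_layer(3), pool_layer(2, stride = 2), ns$flatten_layer(),
    fc_layer(4), fc_layer(2, relu = FALSE), ns$softmax_layer(),
    ns$classification_layer()))
  set.seed(1)
  x <- array(rnorm(6 * 5 * 2 * 7), c(6, 5, 2, 7))
  y_idx <- sample(1:2, 7, replace = TRUE)
  params <- ns$init_cnn_params(spec, seed = 2)
  loss_fn <- function(p) {
    fw <- ns$cnn_forward(spec, p, x, training = TRUE)
    -mean(log(pmax(fw$probs[cbind(1:7, y_idx)], 1e-12)))
  }
  fw <- ns$cnn_forward(spec, params, x, training = TRUE)
  grads <- ns$cnn_backward(spec, fw$params, fw$caches, fw$probs, y_idx)
  eps <- 1e-6
  set.seed(3)
  for (li in seq_along(params)) {
    if (is.null(grads[[li]])) next
    for (nm in intersect(names(grads[[li]]), c("W", "gamma", "beta"))) {
      g <- grads[[li]][[nm]]
      for (j in sample(length(g), min(6, length(g)))) {
        p2 <- params; p2[[li]][[nm]][j] <- p2[[li]][[nm]][j] + eps
        p3 <- params; p3[[li]][[nm]][j] <- p3[[li]][[nm]][j] - eps
        num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
        expect_lt(abs(num - g[j]) / max(1e-6, abs(num) + abs(g[j])),
                  1e-4)
      }
    }
  }
})

test_that("softmax scores normalise, preserve order and repeat exactly", {
  spec <- tiny_spec()
  set.seed(4)
  x <- array(rnorm(8 * 6 * 1 * 12), c(8, 6, 1, 12))
  y <- rep(c("HAS", "non-HAS"), 6)
  clf <- train_classifier(spec, x, y,
                          train_config(epochs = 2, batch_size = 4,
                                       validation_fraction = 0, seed = 9))
  p <- predict(clf, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 12), tolerance = 1e-12)
  expect_identical(p, predict(clf, x, type = "prob"))
  # batch predictions are order-preserving
  p_rev <- predict(clf, x[, , , 12:1, drop = FALSE], type = "prob")
  expect_equal(p_rev, p[12:1, ], tolerance = 1e-12)
  lab <- predict(clf, x, type = "label")
  expect_true(all(lab %in% c("HAS", "non-HAS")))
})

test_that("training is reproducible bit for bit under a fixed seed", {
  spec <- tiny_spec()
  set.seed(5)
  x <- array(rnorm(8 * 6 * 1 * 20), c(8, 6, 1, 20))
  y <- rep(c("HAS", "non-HAS"), 10)
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 42)
  a <- train_classifier(spec, x, y, cfg)
  b <- train_classifier(spec, x, y, cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_identical(a$data_fingerprint, b$data_fingerprint)
})

test_that("degenerate training inputs are rejected", {
  spec <- tiny_spec()
  x <- array(rnorm(8 * 6 * 1 * 4), c(8, 6, 1, 4))
  expect_error(train_classifier(spec, x[, , , 0, drop = FALSE],
                                character(0)), "empty")
  expect_error(train_classifier(spec, x, rep("HAS", 4)), "single class")
  expect_error(train_classifier(spec, x, c("HAS", "bad", "non-HAS", "HAS")),
               "labels")
  bad <- array(rnorm(7 * 6 * 1 * 4), c(7, 6, 1, 4))
  expect_error(train_classifier(spec, bad, rep(c("HAS", "non-HAS"), 2)),
               "shape")
})

test_that("training history records the configured optimisation", {
  spec <- tiny_spec()
  set.seed(6)
  x <- array(rnorm(8 * 6 * 1 * 30), c(8, 6, 1, 30))
  # separable toy problem: positive class has a shifted mean
  y <- rep(c("HAS", "non-HAS"), 15)
  x[, , , y == "HAS"] <- x[, , , y == "HAS"] + 3
  cfg <- train_config(epochs = 10, batch_size = 10, seed = 1)
  clf <- train_classifier(spec, x, y, cfg)
  expect_equal(nrow(clf$history), 10L)
  expect_lt(clf$history$loss[10], clf$history$loss[1])
  expect_gte(clf$history$accuracy[10], 0.9)
  expect_identical(clf$config$learning_rate, 1e-3)
  expect_identical(clf$config$squared_gradient_decay, 0.9)
})
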