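test_that("preprocess pads to square, resizes, normalizes and replicates", {
  x <- matrix(runif(434 * 636, 0, 255), 434, 636)
  out <- preprocess(x, preprocess_spec(128))
  expect_equal(dim(out), c(128, 128, 3))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(out[, , 1], out[, , 3])
  # constant white image maps to all ones
  ones <- preprocess(matrix(255, 128, 128), preprocess_spec(128))
  expect_equal(ones, array(1, c(128, 128, 3)))
  # square target-size input: geometry untouched, intensities scaled
  sq <- matrix(seq(0, 255, length.out = 64 * 64), 64, 64)
  expect_equal(preprocess(sq, preprocess_spec(64))[, , 1], sq / 255)
  expect_error(preprocess(array(1, c(4, 4, 2))), "2-D")
})

test_that("zero padding is symmetric with the odd pixel at bottom/right", {
  m <- matrix(1, 3, 4)
  p <- fedus:::pad_to_square(m)
  expect_equal(dim(p), c(4, 4))
  expect_equal(p[4, ], rep(0, 4))     # extra row at the bottom
  expect_true(all(p[1:3, ] == 1))
  m2 <- matrix(1, 4, 1)
  p2 <- fedus:::pad_to_square(m2)
  expect_equal(unname(colSums(p2)), c(0, 4, 0, 0))  # pad 1 left, 2 right
  # center crop keeps the middle fraction
  big <- matrix(0, 40, 40)
  big[11:30, 11:30] <- 255
  cropped <- preprocess(big, preprocess_spec(20, crop_frac = 0.5))
  expect_equal(cropped[, , 1], matrix(1, 20, 20))
})

test_that("augmentation is a seeded involution-friendly transform", {
  x <- preprocess(matrix(runif(64 * 64, 0, 255), 64, 64), preprocess_spec(64))
  # flip twice restores; rotation by 0 is identity
  expect_equal(fedus:::augment_plane(fedus:::augment_plane(x[, , 1],
                                                           TRUE, 0),
                                     TRUE, 0), x[, , 1])
  expect_equal(fedus:::augment_plane(x[, , 1], FALSE, 0), x[, , 1])
  # same seed, same output; shape preserved
  a1 <- augment(x, rot_deg = 15, seed = 5)
  a2 <- augment(x, rot_deg = 15, seed = 5)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(x))
  expect_false(identical(a1, augment(x, rot_deg = 15, seed = 6)))
})

test_that("focal loss matches hand values and reduces to scaled BCE", {
  # gamma = 0, alpha = 0.5: half the binary cross-entropy
  p <- c(0.2, 0.7, 0.9, 0.4)
  y <- c(0, 1, 1, 0)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, gamma = 0, alpha_weight = 0.5), 0.5 * bce,
               tolerance = 1e-12)
  # hand-evaluated single case
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha_weight = 0.25),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(round(focal_loss(0.9, 1, gamma = 2, alpha_weight = 0.25), 7),
               2.634e-4)
  # loss -> 0 monotonically as p -> 1 for a positive
  ps <- seq(0.5, 0.999, length.out = 20)
  ls <- vapply(ps, function(q) focal_loss(q, 1), numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[20], 1e-5)
  expect_true(all(focal_loss(runif(50, 0.01, 0.99),
                             rbinom(50, 1, 0.5), reduce = FALSE) >= 0))
  expect_warning(focal_loss(c(0, 0.5), c(1, 1)), "clipped")
})

test_that("model construction is seed-deterministic with sigmoid outputs", {
  n1 <- build_model("tiny", init_seed = 7)
  n2 <- build_model("tiny", init_seed = 7)
  expect_identical(n1$weights, n2$weights)
  expect_false(identical(build_model("tiny", init_seed = 8)$weights,
                         n1$weights))
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  p <- fedus:::net_predict(n1, n1$weights, x)
  expect_true(all(p > 0 & p < 1))
  # zero image gives a finite probability
  z <- fedus:::net_predict(n1, n1$weights, array(0, c(64, 64, 3, 1)))
  expect_true(is.finite(z))
  expect_error(build_model("resnet"), "arg")
})

test_that("the full-scale architecture forward pass is a valid probability", {
  vgg <- build_model("vgg16_like", init_seed = 1)
  expect_equal(vgg$input_dim, c(128L, 128L, 3L))
  x <- array(runif(128 * 128 * 3), c(128, 128, 3, 1))
  p <- fedus:::net_predict(vgg, vgg$weights, x)
  expect_true(is.finite(p) && p > 0 && p < 1)
})

test_that("backprop matches finite differences on small models", {
  flat_loss <- function(net, wvec, x, y, mu, anchor) {
    fw <- fedus:::net_forward(net, wvec, x)
    p <- pmin(pmax(as.numeric(fw$out), 1e-7), 1 - 1e-7)
    focal_loss(p, y) +
      mu / 2 * sum(vapply(names(wvec), function(nm)
        sum((wvec[[nm]] - anchor[[nm]])^2), numeric(1)))
  }
  grad_backprop <- function(net, wvec, x, y, mu, anchor) {
    fw <- fedus:::net_forward(net, wvec, x, keep_cache = TRUE)
    p <- pmin(pmax(as.numeric(fw$out), 1e-7), 1 - 1e-7)
    dz <- matrix(fedus:::focal_loss_grad(p, y) * p * (1 - p) / length(y),
                 ncol = 1)
    g <- fedus:::net_backward(net, wvec, fw$cache, dz)
    for (nm in names(g)) g[[nm]] <- g[[nm]] + mu * (wvec[[nm]] - anchor[[nm]])
    g
  }
  check_net <- function(layers, input_dim, n = 3, mu = 0.7) {
    net <- fedus:::new_net(layers, input_dim, init_seed = 3)
    set.seed(9)
    x <- array(runif(prod(input_dim) * n), c(input_dim, n))
    y <- rbinom(n, 1, 0.5)
    anchor <- lapply(net$weights, function(w) w + 0.05)
    ana <- grad_backprop(net, net$weights, x, y, mu, anchor)
    h <- 1e-5
    for (nm in names(net$weights)) {
      w <- net$weights[[nm]]
      for (i in seq_len(min(length(w), 6))) {
        wp <- net$weights; wp[[nm]][i] <- w[i] + h
        wm <- net$weights; wm[[nm]][i] <- w[i] - h
        fd <- (flat_loss(net, wp, x, y, mu, anchor) -
                 flat_loss(net, wm, x, y, mu, anchor)) / (2 * h)
        denom <- max(abs(fd), abs(ana[[nm]][i]), 1e-8)
        expect_lt(abs(fd - ana[[nm]][i]) / denom, 1e-4)
      }
    }
  }
  # dense-only toy (a dozen parameters)
  check_net(list(list(type = "flatten"),
                 list(type = "dense", units = 2L, act = "relu"),
                 list(type = "dense", units = 1L, act = "sigmoid")),
            c(2L, 2L, 1L))
  # conv + pool + dense
  check_net(list(list(type = "conv", filters = 2L),
                 list(type = "pool"),
                 list(type = "flatten"),
                 list(type = "dense", units = 1L, act = "sigmoid")),
            c(4L, 4L, 1L))
})

test_that("local training honors the optimizer and proximal contracts", {
  net <- build_model("tiny", init_seed = 2, input_size = 16)
  set.seed(5)
  data <- list(x = array(runif(16 * 16 * 12), c(16, 16, 12)),
               y = rep(c(0, 1), 6), patient_id = as.character(1:12))
  # zero learning rate: weights unchanged
  frozen <- local_train(net$weights, net, data,
                        train_config(learning_rate = 0, batch_size = 4,
                                     input_size = 16), seed = 1)
  expect_identical(frozen, net$weights)
  # prox_mu = 0 ignores the anchor entirely
  far <- lapply(net$weights, function(w) w + 100)
  cfg <- train_config(batch_size = 4, input_size = 16)
  expect_identical(
    local_train(net$weights, net, data, cfg, global_anchor = far, seed = 1),
    local_train(net$weights, net, data, cfg, seed = 1))
  # growing mu pins the update ever closer to the anchor
  dist_at <- function(mu) {
    w <- local_train(net$weights, net, data,
                     train_config(batch_size = 4, prox_mu = mu,
                                  learning_rate = 1e-3, input_size = 16),
                     global_anchor = net$weights, seed = 1)
    fedus:::wv_dist(w, net$weights)
  }
  d <- vapply(c(0, 1, 1e2, 1e6), dist_at, numeric(1))
  expect_lt(d[2], d[1])        # any mu pulls toward the anchor
  expect_lt(d[3], d[2] / 2)    # stronger mu pulls much harder
  # at huge mu the update stays in a small ball around the anchor
  # (Adam's normalized steps put a floor under the distance)
  expect_lt(d[4], d[2] / 2)
  expect_error(local_train(net$weights, net,
                           list(x = array(0, c(16, 16, 0)), y = numeric(0),
                                patient_id = character(0)),
                           cfg), "no training images")
})

test_that("the optimizer separates a linearly separable toy problem", {
  # two-feature toy task embedded in tiny 4x4 frames; dense head only
  net <- fedus:::new_net(list(list(type = "flatten"),
                              list(type = "dense", units = 4L, act = "relu"),
                              list(type = "dense", units = 1L,
                                   act = "sigmoid")),
                         c(4L, 4L, 1L), init_seed = 1)
  set.seed(11)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  f1 <- ifelse(y == 1, 0.7, 0.3) + rnorm(n, 0, 0.05)
  f2 <- ifelse(y == 1, 0.2, 0.6) + rnorm(n, 0, 0.05)
  x <- array(0, c(4, 4, n))
  x[1:2, , ] <- rep(f1, each = 8)
  x[3:4, , ] <- rep(f2, each = 8)
  data <- list(x = x, y = y, patient_id = as.character(1:n))
  w <- local_train(net$weights, net, data,
                   train_config(batch_size = 16, learning_rate = 1e-2,
                                local_epochs = 50, augment = FALSE),
                   seed = 2)
  p <- fedus:::net_predict(net, w,
                           fedus:::stack_channels(x, 1))
  expect_gt(roc_auc(score_set(p, y)), 0.95)
})
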