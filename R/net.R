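## Sequential conv-net: definition, Glorot-uniform initialization, forward
## and backward passes. Convolutions are 3x3 same-padding (compiled), pools
## are 2x2 max, the head is dense with a sigmoid scalar output.

net_layers_tiny <- function() {
  list(list(type = "conv", filters = 8L),
       list(type = "pool"),
       list(type = "conv", filters = 16L),
       list(type = "pool"),
       list(type = "conv", filters = 32L),
       list(type = "pool"),
       list(type = "flatten"),
       list(type = "dense", units = 32L, act = "relu"),
       list(type = "dense", units = 1L, act = "sigmoid"))
}

net_layers_vgg16 <- function() {
  blocks <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                 c(512L, 512L, 512L), c(512L, 512L, 512L))
  layers <- list()
  for (b in blocks) {
    for (f in b) layers <- c(layers, list(list(type = "conv", filters = f)))
    layers <- c(layers, list(list(type = "pool")))
  }
  c(layers, list(list(type = "flatten"),
                 list(type = "dense", units = 256L, act = "relu"),
                 list(type = "dense", units = 1L, act = "sigmoid")))
}

#' Build a classifier network with seeded Glorot-uniform weights
#'
#' Two architectures: `"vgg16_like"` (the thirteen-convolution VGG16 stack
#' with a small dense head, 128 x 128 x 3 input, sigmoid scalar output) and
#' `"tiny"` (three conv/pool blocks plus a dense head, configurable input
#' size, default 64 x 64 x 3) for desk-scale experiments. Weights are drawn
#' layer-wise from a uniform distribution with Glorot (fan-based) bounds;
#' two calls with the same architecture and seed yield identical weights, so
#' every federated site can start from the same initial model.
#'
#' @param arch `"tiny"` or `"vgg16_like"`.
#' @param init_seed integer seed for the weight draw.
#' @param input_size spatial input size (square); defaults 64 for tiny,
#'   128 for vgg16_like.
#' @param channels input channels (default 3).
#' @return object of class `"fl_net"`: layer plan plus the weight vector.
#' @export
build_model <- function(arch = c("tiny", "vgg16_like"), init_seed = 1L,
                        input_size = NULL, channels = 3L) {
  arch <- match.arg(arch)
  layers <- switch(arch, tiny = net_layers_tiny(),
                   vgg16_like = net_layers_vgg16())
  if (is.null(input_size)) input_size <- if (arch == "tiny") 64L else 128L
  new_net(layers, input_dim = c(input_size, input_size, channels),
          init_seed = init_seed, arch = arch)
}

# generic constructor; also used for toy dense-only nets in checks
new_net <- function(layers, input_dim, init_seed = 1L, arch = "custom") {
  h <- input_dim[1]; w <- input_dim[2]; c_in <- input_dim[3]
  weights <- list()
  with_seed(derive_seed(init_seed, 21L), {
    li <- 0L
    for (k in seq_along(layers)) {
      ly <- layers[[k]]
      if (ly$type == "conv") {
        li <- li + 1L
        fan_in <- 9L * c_in
        fan_out <- 9L * ly$filters
        lim <- sqrt(6 / (fan_in + fan_out))
        weights[[paste0("conv", li, "_w")]] <-
          matrix(runif(fan_in * ly$filters, -lim, lim), fan_in, ly$filters)
        weights[[paste0("conv", li, "_b")]] <- numeric(ly$filters)
        layers[[k]]$name <- paste0("conv", li)
        c_in <- ly$filters
      } else if (ly$type == "pool") {
        if (h %% 2L || w %% 2L) stop("input size not divisible through pools")
        h <- h %/% 2L; w <- w %/% 2L
      } else if (ly$type == "flatten") {
        c_in <- h * w * c_in
      } else if (ly$type == "dense") {
        li <- li + 1L
        lim <- sqrt(6 / (c_in + ly$units))
        weights[[paste0("dense", li, "_w")]] <-
          matrix(runif(c_in * ly$units, -lim, lim), c_in, ly$units)
        weights[[paste0("dense", li, "_b")]] <- numeric(ly$units)
        layers[[k]]$name <- paste0("dense", li)
        c_in <- ly$units
      } else stop("unknown layer type '", ly$type, "'")
    }
  })
  structure(list(arch = arch, layers = layers, input_dim = input_dim,
                 weights = weights),
            class = "fl_net")
}

#' @export
print.fl_net <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat("fl_net '", x$arch, "': input ",
      paste(x$input_dim, collapse = "x"), ", ",
      length(x$layers), " layers, ", format(np, big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; x is h x w x c x n. Returns probs and (optionally) caches
# for backprop.
net_forward <- function(net, weights, x, keep_cache = FALSE) {
  a <- x
  cache <- if (keep_cache) list() else NULL
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    if (ly$type == "conv") {
      z <- conv2d_fwd(a, weights[[paste0(ly$name, "_w")]],
                      weights[[paste0(ly$name, "_b")]])
      if (keep_cache) cache[[k]] <- list(input = a, pre = z)
      a <- z * (z > 0)
    } else if (ly$type == "pool") {
      pf <- maxpool2_fwd(a)
      if (keep_cache) cache[[k]] <- list(idx = pf$idx, in_dim = dim(a))
      a <- pf$y
    } else if (ly$type == "flatten") {
      if (keep_cache) cache[[k]] <- list(in_dim = dim(a))
      d <- dim(a)
      a <- t(matrix(a, nrow = prod(d[1:3]), ncol = d[4]))
    } else if (ly$type == "dense") {
      z <- sweep(a %*% weights[[paste0(ly$name, "_w")]], 2L,
                 weights[[paste0(ly$name, "_b")]], `+`)
      if (keep_cache) cache[[k]] <- list(input = a, pre = z)
      a <- if (identical(ly$act, "sigmoid")) sigmoid(z) else z * (z > 0)
    }
  }
  list(out = a, cache = cache)
}

# backward pass from d(loss)/d(logit) of the final dense layer (n x units).
# Returns gradient weight vector conformable with `weights`.
net_backward <- function(net, weights, cache, dz_out) {
  grads <- wv_zero(weights)
  da <- NULL
  for (k in rev(seq_along(net$layers))) {
    ly <- net$layers[[k]]
    if (ly$type == "dense") {
      cc <- cache[[k]]
      dz <- if (k == length(net$layers)) dz_out
            else da * (cc$pre > 0)          # relu through pre-activation
      grads[[paste0(ly$name, "_w")]] <- crossprod(cc$input, dz)
      grads[[paste0(ly$name, "_b")]] <- colSums(dz)
      da <- dz %*% t(weights[[paste0(ly$name, "_w")]])
    } else if (ly$type == "flatten") {
      da <- array(t(da), dim = cache[[k]]$in_dim)
    } else if (ly$type == "pool") {
      cc <- cache[[k]]
      da <- maxpool2_bwd(da, cc$idx, cc$in_dim[1], cc$in_dim[2])
    } else if (ly$type == "conv") {
      cc <- cache[[k]]
      dz <- da * (cc$pre > 0)
      bw <- conv2d_bwd(cc$input, weights[[paste0(ly$name, "_w")]], dz)
      grads[[paste0(ly$name, "_w")]] <- bw$dw
      grads[[paste0(ly$name, "_b")]] <- bw$db
      da <- bw$dx
    }
  }
  grads
}

# prediction in batches; x is h x w x c x n, returns probability vector
net_predict <- function(net, weights, x, batch_size = 128L) {
  n <- dim(x)[4]
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- x[, , , i:j, drop = FALSE]
    out[i:j] <- as.numeric(net_forward(net, weights, xb)$out)
    i <- j + 1L
  }
  out
}
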