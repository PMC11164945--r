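#' Local training configuration
#'
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-4).
#' @param adam_beta1,adam_beta2 Adam moment decays (0.9, 0.999).
#' @param focal_gamma,focal_alpha focal-loss parameters (2, 0.25).
#' @param local_epochs passes over the site's data per round (1 or 5 in the
#'   standard schedules).
#' @param prox_mu proximal weight `mu >= 0`; 0 disables the FedProx term.
#' @param augment apply flip/rotation augmentation during training.
#' @param rot_deg rotation half-range in degrees.
#' @param init_seed seed for the shared initial weights.
#' @param arch `"tiny"` or `"vgg16_like"`.
#' @param input_size network input size (square); `NULL` for the
#'   architecture default.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-4,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         focal_gamma = 2, focal_alpha = 0.25,
                         local_epochs = 1L, prox_mu = 0,
                         augment = TRUE, rot_deg = 15,
                         init_seed = 1L, arch = "tiny", input_size = NULL) {
  stopifnot(batch_size >= 1, focal_gamma >= 0, prox_mu >= 0,
            local_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 local_epochs = as.integer(local_epochs), prox_mu = prox_mu,
                 augment = augment, rot_deg = rot_deg,
                 init_seed = as.integer(init_seed), arch = arch,
                 input_size = input_size),
            class = "train_config")
}

## ---- Adam ------------------------------------------------------------------
adam_init <- function(weights) {
  list(m = wv_zero(weights), v = wv_zero(weights), t = 0L)
}

adam_step <- function(opt, weights, grads, lr, beta1, beta2, eps = 1e-7) {
  opt$t <- opt$t + 1L
  opt$m <- wv_add(wv_scale(opt$m, beta1), wv_scale(grads, 1 - beta1))
  opt$v <- wv_map(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(weights)) {
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, weights = weights)
}

## ---- data plumbing ---------------------------------------------------------

# Preprocess a patient set into a training stack: single-channel planes
# h x w x n (channels are replicated at batch time), labels, patient ids.
make_tensor <- function(patients, images, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  planes <- list()
  y <- numeric(0)
  pid <- character(0)
  for (i in seq_len(nrow(patients))) {
    id <- patients$patient_id[i]
    imgs <- images[[id]]
    if (is.null(imgs)) stop("no images for patient '", id, "'")
    for (im in imgs) {
      planes[[length(planes) + 1L]] <- preprocess(im, spec)[, , 1L]
      y <- c(y, as.numeric(patients$binary_class[i] == "S1plus"))
      pid <- c(pid, id)
    }
  }
  tg <- spec$target_size[1]
  x <- array(unlist(planes, use.names = FALSE), dim = c(tg, tg, length(planes)))
  list(x = x, y = y, patient_id = pid, channels = spec$channels)
}

# replicate single-channel planes (h x w x n) into an h x w x c x n input
stack_channels <- function(planes, channels) {
  d <- dim(planes)
  x <- array(0, dim = c(d[1], d[2], channels, d[3]))
  for (ch in seq_len(channels)) x[, , ch, ] <- planes
  x
}

## ---- local training --------------------------------------------------------

#' One site's local update: mini-batch Adam on focal loss (+ proximal term)
#'
#' Runs `local_epochs` passes of shuffled mini-batch Adam over the site's
#' preprocessed images, minimizing the focal loss plus, when `prox_mu > 0`,
#' the proximal penalty `(mu / 2) * ||w - anchor||^2` whose gradient
#' `mu * (w - anchor)` keeps the local model near the global one (the
#' FedProx local objective). With `prox_mu = 0` this is plain local
#' training, as used by FedAvg, FedAvgM and FedYogi.
#'
#' @param start_weights weight vector broadcast by the server.
#' @param net an `"fl_net"` (layer plan; weights are passed separately).
#' @param data training stack from `make_tensor()`.
#' @param config a [train_config()].
#' @param global_anchor anchor weights of the proximal term (the current
#'   global model); defaults to `start_weights`.
#' @param seed RNG seed for shuffling and augmentation.
#' @return updated weight vector.
#' @export
local_train <- function(start_weights, net, data, config,
                        global_anchor = start_weights, seed = 1L) {
  n <- length(data$y)
  if (n == 0) stop("site has no training images")
  weights <- start_weights
  opt <- adam_init(weights)
  channels <- net$input_dim[3]
  for (ep in seq_len(config$local_epochs)) {
    ep_seed <- derive_seed(seed, 31L, ep)
    ord <- with_seed(ep_seed, sample.int(n))
    nb <- ceiling(n / config$batch_size)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      planes <- data$x[, , idx, drop = FALSE]
      if (isTRUE(config$augment))
        planes <- augment_stack(planes, config$rot_deg,
                                derive_seed(ep_seed, 32L, b))
      xb <- stack_channels(planes, channels)
      yb <- data$y[idx]
      fw <- net_forward(net, weights, xb, keep_cache = TRUE)
      p <- as.numeric(fw$out)
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      # d(mean loss)/d(logit) through the output sigmoid
      dz <- matrix(focal_loss_grad(pc, yb, config$focal_gamma,
                                   config$focal_alpha) *
                     pc * (1 - pc) / length(yb), ncol = 1L)
      grads <- net_backward(net, weights, fw$cache, dz)
      if (config$prox_mu > 0)
        grads <- wv_add(grads,
                        wv_scale(wv_sub(weights, global_anchor),
                                 config$prox_mu))
      st <- adam_step(opt, weights, grads, config$learning_rate,
                      config$adam_beta1, config$adam_beta2)
      opt <- st$opt
      weights <- st$weights
    }
  }
  weights
}
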