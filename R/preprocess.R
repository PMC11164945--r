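#' Preprocessing specification
#'
#' @param target_size length-2 integer, output height/width (square).
#' @param crop_frac optional center-crop fraction in (0, 1\]; `NULL` keeps
#'   the full frame.
#' @param channels channels of the network input; grayscale is replicated.
#' @export
preprocess_spec <- function(target_size = c(128L, 128L), crop_frac = NULL,
                            channels = 3L) {
  if (length(target_size) == 1L) target_size <- rep(target_size, 2L)
  if (target_size[1] != target_size[2]) stop("target_size must be square")
  if (!is.null(crop_frac) && (crop_frac <= 0 || crop_frac > 1))
    stop("crop_frac must be in (0, 1]")
  structure(list(target_size = as.integer(target_size),
                 crop_frac = crop_frac, channels = as.integer(channels)),
            class = "preprocess_spec")
}

#' Preprocess a grayscale image into a network input tensor
#'
#' Optional center crop, symmetric zero padding of the shorter dimension to
#' a square (extra pixel on the bottom/right when odd), bilinear resize to
#' the target size, division by 255 and channel replication. A 434 x 636
#' frame is padded to 636 x 636 before resizing, preserving aspect ratio.
#'
#' @param pixels 2-D numeric matrix with values in \[0, 255\].
#' @param spec a [preprocess_spec()].
#' @return array `target x target x channels` with values in \[0, 1\].
#' @export
preprocess <- function(pixels, spec = preprocess_spec()) {
  if (length(dim(pixels)) != 2L) stop("pixels must be a 2-D array")
  x <- pixels
  if (!is.null(spec$crop_frac)) {
    h <- nrow(x); w <- ncol(x)
    ch <- max(1L, round(h * spec$crop_frac))
    cw <- max(1L, round(w * spec$crop_frac))
    r0 <- (h - ch) %/% 2L
    c0 <- (w - cw) %/% 2L
    x <- x[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), drop = FALSE]
  }
  x <- pad_to_square(x)
  tg <- spec$target_size[1]
  if (nrow(x) != tg)
    x <- EBImage::resize(x, w = tg, h = tg, filter = "bilinear")
  x <- x / 255
  array(x, dim = c(tg, tg, spec$channels))
}

pad_to_square <- function(x) {
  h <- nrow(x); w <- ncol(x)
  if (h == w) return(x)
  s <- max(h, w)
  out <- matrix(0, s, s)
  r0 <- (s - h) %/% 2L        # extra row goes to the bottom when odd
  c0 <- (s - w) %/% 2L        # extra column goes to the right when odd
  out[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w)] <- x
  out
}

#' Training-time augmentation
#'
#' Horizontal mirror with probability 0.5 followed by a rotation at an angle
#' uniform in +/- `rot_deg` degrees (bilinear, zero fill, output size
#' preserved). Deterministic for a fixed seed. Applied only during training.
#'
#' @param tensor array `h x w x channels` (a [preprocess()] output).
#' @param rot_deg rotation half-range in degrees.
#' @param seed integer RNG seed.
#' @return augmented tensor of identical shape.
#' @export
augment <- function(tensor, rot_deg = 15, seed = 1L) {
  d <- dim(tensor)
  if (length(d) != 3L) stop("tensor must be h x w x channels")
  with_seed(seed, {
    flip <- runif(1) < 0.5
    angle <- runif(1, -rot_deg, rot_deg)
    out <- tensor
    for (ch in seq_len(d[3]))
      out[, , ch] <- augment_plane(tensor[, , ch], flip, angle)
    out
  })
}

augment_plane <- function(m, flip, angle) {
  if (flip) m <- m[, ncol(m):1, drop = FALSE]
  if (angle != 0)
    m <- EBImage::rotate(m, angle, filter = "bilinear",
                         output.dim = dim(m), bg.col = 0)
  m
}

# Augment a stack of single-channel planes (h x w x n) in place; one RNG
# draw pair per plane. Used by the training loop.
augment_stack <- function(x, rot_deg, seed) {
  n <- dim(x)[3]
  with_seed(seed, {
    flips <- runif(n) < 0.5
    angles <- runif(n, -rot_deg, rot_deg)
    for (i in seq_len(n))
      x[, , i] <- augment_plane(x[, , i], flips[i], angles[i])
    x
  })
}
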