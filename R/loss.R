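#' Focal loss for binary classification
#'
#' Cross-entropy modulated by `(1 - p_t)^gamma` to down-weight easy
#' examples, with class-balance weight `alpha_weight` on the positive
#' class:
#' `y = 1: -alpha_weight * (1 - p)^gamma * log(p)`;
#' `y = 0: -(1 - alpha_weight) * p^gamma * log(1 - p)`.
#' With `gamma = 0` and `alpha_weight = 0.5` this is half the binary
#' cross-entropy. Probabilities outside `(0, 1)` are clipped to
#' `[1e-7, 1 - 1e-7]` with a warning.
#'
#' @param p predicted probabilities.
#' @param y binary labels in \{0, 1\}.
#' @param gamma focusing parameter, >= 0 (default 2).
#' @param alpha_weight positive-class balance weight in \[0, 1\]
#'   (default 0.25).
#' @param reduce if `TRUE` (default) return the batch mean, else the
#'   per-sample losses.
#' @return scalar mean loss (or per-sample vector).
#' @examples
#' focal_loss(0.9, 1)   # easy positive: near zero
#' @export
focal_loss <- function(p, y, gamma = 2, alpha_weight = 0.25, reduce = TRUE) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)), gamma >= 0)
  p <- clip_prob(p)
  l <- ifelse(y == 1,
              -alpha_weight * (1 - p)^gamma * log(p),
              -(1 - alpha_weight) * p^gamma * log(1 - p))
  if (reduce) mean(l) else l
}

clip_prob <- function(p, eps = 1e-7) {
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities clipped to [", eps, ", 1 - ", eps, "]")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

# d(loss_i)/d(p_i), per element (no reduction)
focal_loss_grad <- function(p, y, gamma = 2, alpha_weight = 0.25) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ifelse(y == 1,
         alpha_weight * (gamma * (1 - p)^(gamma - 1) * log(p) -
                           (1 - p)^gamma / p),
         (1 - alpha_weight) * (p^gamma / (1 - p) -
                                 gamma * p^(gamma - 1) * log(1 - p)))
}
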