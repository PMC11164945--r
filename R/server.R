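#' Server-side optimizer state
#'
#' Holds the global weights, the round counter and the algorithm-specific
#' buffers: the momentum accumulator for FedAvgM, and the first/second
#' moments for FedYogi (the second moment is initialized at `tau^2`
#' elementwise so the adaptive denominator `sqrt(v) + tau` is
#' well-conditioned from the first round). FedAvg and FedProx keep no
#' server buffers — their server step is the weighted average itself.
#'
#' @param algorithm one of `"fedavg"`, `"fedavgm"`, `"fedyogi"`,
#'   `"fedprox"`.
#' @param global_weights initial global weight vector.
#' @param hparams list from [server_hparams()].
#' @export
server_state <- function(algorithm = c("fedavg", "fedavgm", "fedyogi",
                                       "fedprox"),
                         global_weights, hparams = server_hparams(algorithm)) {
  algorithm <- match.arg(algorithm)
  st <- list(algorithm = algorithm, t = 0L, global_weights = global_weights,
             hparams = hparams)
  if (algorithm == "fedavgm") st$momentum <- wv_zero(global_weights)
  if (algorithm == "fedyogi") {
    st$m <- wv_zero(global_weights)
    st$v <- wv_map(function(x) x * 0 + hparams$tau^2, global_weights)
  }
  structure(st, class = "server_state")
}

#' Default server hyperparameters
#'
#' FedAvgM: momentum `beta = 0.9`, server learning rate `eta = 1`. FedYogi:
#' `beta1 = 0.9`, `beta2 = 0.99`, adaptivity `tau = 1e-3`, `eta = 1e-2`.
#' FedProx: proximal weight `mu = 0.01` (applied in the local objective;
#' the server step is identical to FedAvg).
#'
#' @param algorithm algorithm name.
#' @export
server_hparams <- function(algorithm = "fedavg") {
  switch(algorithm,
         fedavg = list(),
         fedavgm = list(beta = 0.9, eta = 1.0),
         fedyogi = list(beta1 = 0.9, beta2 = 0.99, tau = 1e-3, eta = 1e-2),
         fedprox = list(mu = 0.01),
         stop("unknown algorithm '", algorithm, "'"))
}

#' Sample-size-weighted federated average
#'
#' `w = sum_i (n_i / n) w_i`: the FedAvg aggregate of the site updates,
#' weighted by local sample counts.
#'
#' @param site_weights list of conformable weight vectors.
#' @param site_sizes positive sample counts, one per site.
#' @export
fedavg_aggregate <- function(site_weights, site_sizes) {
  if (!length(site_weights)) stop("no site weights to aggregate")
  if (length(site_weights) != length(site_sizes))
    stop("site_weights and site_sizes lengths differ")
  if (any(site_sizes <= 0)) stop("site sizes must be positive")
  for (i in seq_along(site_weights)[-1])
    wv_check_conformable(site_weights[[1]], site_weights[[i]])
  wv_weighted_sum(site_weights, site_sizes / sum(site_sizes))
}

#' FedAvgM server update
#'
#' Server momentum over the pseudo-gradient
#' `Delta_t = w^(t-1) - w_FedAvg`:
#' `v^t = beta * v^(t-1) + Delta_t`, `w^t = w^(t-1) - eta * v^t`.
#' With `beta = 0`, `eta = 1` this reduces exactly to FedAvg.
#'
#' @param state a `"server_state"` with `algorithm = "fedavgm"`.
#' @param fedavg_result the [fedavg_aggregate()] of the round.
#' @return updated state (weights and momentum buffer advanced one round).
#' @export
fedavgm_update <- function(state, fedavg_result) {
  stopifnot(inherits(state, "server_state"), state$algorithm == "fedavgm")
  wv_check_conformable(state$global_weights, fedavg_result)
  hp <- state$hparams
  delta <- wv_sub(state$global_weights, fedavg_result)
  state$momentum <- wv_add(wv_scale(state$momentum, hp$beta), delta)
  if (hp$beta == 0 && hp$eta == 1) {
    # algebraic reduction to plain averaging, kept exact in floating point
    state$global_weights <- fedavg_result
  } else {
    state$global_weights <- wv_sub(state$global_weights,
                                   wv_scale(state$momentum, hp$eta))
  }
  state$t <- state$t + 1L
  state
}

#' FedYogi server update
#'
#' Adaptive server step over the pseudo-gradient
#' `Delta_t = w_FedAvg - w^(t-1)` (note the sign is opposite to FedAvgM):
#' `m^t = beta1 m^(t-1) + (1 - beta1) Delta_t`;
#' `v^t = v^(t-1) - (1 - beta2) Delta_t^2 sign(v^(t-1) - Delta_t^2)`;
#' `w^t = w^(t-1) + eta * m^t / (sqrt(v^t) + tau)`, all elementwise, with
#' `sign(0) = 0`.
#'
#' @param state a `"server_state"` with `algorithm = "fedyogi"`.
#' @param fedavg_result the [fedavg_aggregate()] of the round.
#' @export
fedyogi_update <- function(state, fedavg_result) {
  stopifnot(inherits(state, "server_state"), state$algorithm == "fedyogi")
  wv_check_conformable(state$global_weights, fedavg_result)
  hp <- state$hparams
  delta <- wv_sub(fedavg_result, state$global_weights)
  state$m <- wv_add(wv_scale(state$m, hp$beta1),
                    wv_scale(delta, 1 - hp$beta1))
  state$v <- wv_map(function(v, d) v - (1 - hp$beta2) * d^2 * sign(v - d^2),
                    state$v, delta)
  if (any(vapply(state$v, function(v) any(v <= 0), logical(1))))
    stop("FedYogi second moment became non-positive; check tau/initialization")
  for (nm in names(state$global_weights))
    state$global_weights[[nm]] <- state$global_weights[[nm]] +
      hp$eta * state$m[[nm]] / (sqrt(state$v[[nm]]) + hp$tau)
  state$t <- state$t + 1L
  state
}

# one server step, dispatching on algorithm; fedavg/fedprox take the
# aggregate as the new global model
server_update <- function(state, fedavg_result) {
  switch(state$algorithm,
         fedavg = ,
         fedprox = {
           state$global_weights <- fedavg_result
           state$t <- state$t + 1L
           state
         },
         fedavgm = fedavgm_update(state, fedavg_result),
         fedyogi = fedyogi_update(state, fedavg_result))
}
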