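#' @useDynLib fedus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma rbinom qnorm pnorm sd var
#' @importFrom utils write.csv read.csv head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based seed derivation: reproducible, collision-free at the scales
# used here, and always below 2^31 so it is a valid R integer seed.
derive_seed <- function(base, ...) {
  parts <- c(...)
  s <- as.double(base) %% 2147483647
  for (p in parts) s <- (s * 1000003 + as.double(p) * 7919 + 17) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- weight-vector algebra -------------------------------------------------
## A weight vector is an ordered named list of numeric arrays (the unit of
## exchange between sites and server). All elementwise ops preserve names,
## order and dims.

wv_check_conformable <- function(a, b) {
  if (!identical(names(a), names(b)))
    stop("weight vectors are not conformable: tensor names differ")
  for (nm in names(a)) {
    da <- dim(a[[nm]]) %||% length(a[[nm]])
    db <- dim(b[[nm]]) %||% length(b[[nm]])
    if (!identical(da, db))
      stop("weight vectors are not conformable: shape of '", nm, "' differs")
  }
  invisible(TRUE)
}

wv_map <- function(f, a, b = NULL) {
  if (is.null(b)) {
    out <- lapply(a, f)
  } else {
    wv_check_conformable(a, b)
    out <- mapply(f, a, b, SIMPLIFY = FALSE)
  }
  names(out) <- names(a)
  out
}

wv_add <- function(a, b) wv_map(`+`, a, b)
wv_sub <- function(a, b) wv_map(`-`, a, b)
wv_scale <- function(a, k) wv_map(function(x) x * k, a)
wv_zero <- function(a) wv_map(function(x) x * 0, a)

# squared L2 norm of the full parameter vector
wv_sq_norm <- function(a) sum(vapply(a, function(x) sum(x^2), numeric(1)))

wv_dist <- function(a, b) sqrt(wv_sq_norm(wv_sub(a, b)))

# weighted sum: sum_i coef[i] * ws[[i]]
wv_weighted_sum <- function(ws, coef) {
  stopifnot(length(ws) == length(coef))
  out <- wv_scale(ws[[1L]], coef[1L])
  if (length(ws) > 1L)
    for (i in 2L:length(ws)) out <- wv_add(out, wv_scale(ws[[i]], coef[i]))
  out
}
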