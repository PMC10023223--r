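# Add a length-ncol bias vector to every row of a matrix.
add_bias <- function(x, b) x + rep(b, each = nrow(x))

# Numerically stable row-wise softmax.
softmax_rows <- function(x) {
  x <- as.matrix(x)
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

# Backward of row-wise softmax: given p = softmax(z) and dL/dp, return dL/dz.
softmax_rows_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

#' Gaussian-error linear unit
#'
#' Exact GELU, `x * pnorm(x)`; used as the activation of the feed-forward
#' blocks.
#' @param x numeric vector or matrix.
#' @return object of the same shape as `x`.
#' @keywords internal
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

relu <- function(x) pmax(x, 0)

.ln_eps <- 1e-5

# Row-wise layer normalization with gain g and bias b (both length d').
# Returns the normalized output; when cache = TRUE also the quantities the
# backward pass needs.
layernorm_rows <- function(x, g, b, cache = FALSE) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  s <- sqrt(v + .ln_eps)
  xhat <- xc / s
  y <- add_bias(xhat * rep(g, each = nrow(x)), b)
  if (!cache) return(y)
  list(y = y, xhat = xhat, s = s)
}

# Backward of layernorm_rows. Takes the forward cache and dL/dy; returns
# dL/dx and parameter gradients.
layernorm_rows_backward <- function(cache, g, dy) {
  xhat <- cache$xhat
  s <- cache$s
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / s
  list(dx = dx, dg = dg, db = db)
}

# L2-normalize a vector; error on (near-)zero norm.
l2_normalize <- function(x, what = "vector") {
  nrm <- sqrt(sum(x^2))
  if (nrm < 1e-12) {
    stop("degenerate ", what, ": zero L2 norm, cannot normalize", call. = FALSE)
  }
  x / nrm
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# Draw from an isolated RNG stream so library calls do not perturb the
# caller's random state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
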