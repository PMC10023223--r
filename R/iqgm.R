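#' Deep projection layer forward pass
#'
#' Recalibrates raw instance features: fully connected layer, layer
#' normalization, ReLU, then a second linear layer. Row-wise (each instance
#' is mapped independently) and deterministic.
#'
#' @param features numeric `n x d` matrix of raw instance features.
#' @param params model parameter list (fields `dpl_*`).
#' @param cache logical; return intermediate activations for backprop.
#' @return `n x d_prime` matrix, or a list with `out` and caches.
#' @export
project_features <- function(features, params, cache = FALSE) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(params$dpl_W1)) {
    stop("validation error: feature dimension ", ncol(features),
         " does not match model d = ", nrow(params$dpl_W1), call. = FALSE)
  }
  h <- add_bias(features %*% params$dpl_W1, params$dpl_b1)
  ln <- layernorm_rows(h, params$dpl_ln_g, params$dpl_ln_b, cache = TRUE)
  r <- relu(ln$y)
  out <- add_bias(r %*% params$dpl_W2, params$dpl_b2)
  if (!cache) return(out)
  list(out = out, h = h, ln = ln, r = r, features = features)
}

#' Instance probability matrix
#'
#' Applies the instance classification head to the raw `d`-dimensional
#' features (not the projected ones) and a per-instance softmax over the `N`
#' subtypes.
#'
#' @param features `n x d` matrix.
#' @param params model parameter list (fields `cls1_W`, `cls1_b`).
#' @return list with `P` (`n x N`, rows sum to 1) and `logits`.
#' @export
instance_probabilities <- function(features, params) {
  logits <- add_bias(as.matrix(features) %*% params$cls1_W, params$cls1_b)
  list(P = softmax_rows(logits), logits = logits)
}

#' Top-K count from a bag length and a ratio
#'
#' `K = max(1, floor(r * n))`, clamped so that even tiny bags contribute at
#' least one instance.
#'
#' @param n integer bag length.
#' @param r ratio in `(0, 1]`.
#' @return integer `K` with `1 <= K <= n`.
#' @export
top_k_count <- function(n, r) {
  stopifnot(n >= 1L, r > 0, r <= 1)
  max(1L, as.integer(floor(r * n)))
}

# Indices of the K largest values, ties broken by ascending index.
.top_k_idx <- function(x, k) {
  order(-x, seq_along(x))[seq_len(k)]
}

#' Confidence factor of one subtype
#'
#' Mean minus population standard deviation (divisor `K1`) of the subtype's
#' top-`K1` instance probabilities. A subtype whose best instances are both
#' high-probability and consistent gets a high factor.
#'
#' @param class_probs numeric vector: one column of the instance probability
#'   matrix.
#' @param k1 integer number of top instances to use.
#' @return scalar confidence factor.
#' @export
confidence_factor <- function(class_probs, k1) {
  stopifnot(k1 >= 1L, k1 <= length(class_probs))
  top <- class_probs[.top_k_idx(class_probs, k1)]
  m <- mean(top)
  sigma <- sqrt(sum((top - m)^2) / k1)
  m - sigma
}

#' Generate per-subtype internal queries
#'
#' For each subtype, instances are ranked by that subtype's column of the
#' instance probability matrix. The subtype with the largest confidence
#' factor is declared reliable when its factor beats every other subtype's
#' by more than the margin `beta`; a reliable subtype aggregates (averages)
#' the projected features of its top-`K1` instances, all other subtypes
#' their top-`K2`. When no subtype passes the gate, every subtype uses
#' top-`K2`. Ties in ranking are broken by ascending instance index, and a
#' tied maximal confidence factor yields no reliable subtype.
#'
#' With `config$beta_class` set, the margin is instead subtracted from that
#' class's own confidence factor before an ordinary (margin-free) strict
#' comparison — the asymmetric gate for detection-style data where one
#' subtype's instances are systematically under-scored.
#'
#' @param f_proj `n x d_prime` projected feature matrix (DPL output).
#' @param P `n x N` instance probability matrix.
#' @param config a [mdmil_config()].
#' @return an `iqgm_output` list: `queries` (`N x d_prime`), `conf`
#'   (length-`N`), `reliable_class` (0-based index or `NULL`), `P1` (= `P`),
#'   `selected` (list of integer index vectors actually averaged per class),
#'   `K1`, `K2`.
#' @export
generate_internal_queries <- function(f_proj, P, config) {
  f_proj <- as.matrix(f_proj); P <- as.matrix(P)
  n <- nrow(f_proj); N <- ncol(P)
  if (n < 1L) stop("validation error: empty bag", call. = FALSE)
  stopifnot(nrow(P) == n, N == config$n_classes)
  k1 <- top_k_count(n, config$r1)
  k2 <- top_k_count(n, config$r2)
  conf <- vapply(seq_len(N), function(j) confidence_factor(P[, j], k1), numeric(1))

  gate_conf <- conf
  if (!is.null(config$beta_class)) {
    gate_conf[config$beta_class + 1L] <- gate_conf[config$beta_class + 1L] - config$beta
    margin <- 0
  } else {
    margin <- config$beta
  }
  jmax <- which.max(gate_conf)
  others <- gate_conf[-jmax]
  reliable <- length(others) > 0 &&
    all(gate_conf[jmax] - margin > others) &&
    sum(gate_conf == gate_conf[jmax]) == 1L

  selected <- vector("list", N)
  queries <- matrix(0, N, ncol(f_proj))
  for (j in seq_len(N)) {
    k <- if (reliable && j == jmax) k1 else k2
    idx <- .top_k_idx(P[, j], k)
    selected[[j]] <- idx
    queries[j, ] <- colMeans(f_proj[idx, , drop = FALSE])
  }
  structure(
    list(queries = queries, conf = conf,
         reliable_class = if (reliable) jmax - 1L else NULL,
         P1 = P, selected = selected, K1 = k1, K2 = k2),
    class = "iqgm_output"
  )
}
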