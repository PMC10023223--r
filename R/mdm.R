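#' Scaled dot-product attention matrix for one head
#'
#' Softmax over keys of the query-key dot products scaled by
#' `1 / sqrt(d_k)`. Every row is a probability distribution over the `n`
#' instances.
#'
#' @param Q `N x d_k` query block.
#' @param K `n x d_k` key block.
#' @return `N x n` attention matrix with rows summing to 1.
#' @export
attention_matrix <- function(Q, K) {
  Q <- as.matrix(Q); K <- as.matrix(K)
  if (nrow(K) == 0L) stop("validation error: attention over zero keys", call. = FALSE)
  stopifnot(ncol(Q) == ncol(K))
  softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
}

# Column indices of head h when d' is split into `heads` contiguous blocks.
.head_cols <- function(h, dk) ((h - 1L) * dk + 1L):(h * dk)

#' Dual-query multi-head cross-attention
#'
#' Pre-normalizes the internal queries, the variational queries and the
#' projected bag; projects them to queries Q1 (internal), Q2 (variational),
#' keys and values; computes two per-head attention matrices and mixes them
#' convexly with weight `alpha` on the internal-query matrix; aggregates
#' values, concatenates heads, applies the output projection and adds the
#' internal queries as a residual.
#'
#' @param IQ `N x d_prime` internal queries.
#' @param VQ `N x d_prime` variational queries.
#' @param f_proj `n x d_prime` projected instance features.
#' @param params model parameter list (fields `mdca_*`).
#' @param heads number of heads `m` (divides `d_prime`).
#' @param alpha convex mixing weight in `[0, 1]`.
#' @param cache logical; keep intermediates for backprop.
#' @return list with `out` (`N x d_prime`), `attn` (`N x n`, head-averaged
#'   mixed attention), and caches when requested.
#' @export
mdca <- function(IQ, VQ, f_proj, params, heads, alpha, cache = FALSE) {
  if (alpha < 0 || alpha > 1) {
    stop("validation error: alpha must lie in [0, 1]", call. = FALSE)
  }
  N <- nrow(IQ); n <- nrow(f_proj); dp <- ncol(IQ)
  stopifnot(dp %% heads == 0L, ncol(VQ) == dp, ncol(f_proj) == dp)
  dk <- dp %/% heads
  ln_iq <- layernorm_rows(IQ, params$mdca_ln_iq_g, params$mdca_ln_iq_b, cache = TRUE)
  ln_vq <- layernorm_rows(VQ, params$mdca_ln_vq_g, params$mdca_ln_vq_b, cache = TRUE)
  ln_f  <- layernorm_rows(f_proj, params$mdca_ln_f_g, params$mdca_ln_f_b, cache = TRUE)
  Q1 <- ln_iq$y %*% params$mdca_W1
  Q2 <- ln_vq$y %*% params$mdca_W2
  Kf <- ln_f$y %*% params$mdca_W3
  V  <- ln_f$y %*% params$mdca_W4
  O <- matrix(0, N, dp)
  mt1 <- vector("list", heads); mt2 <- vector("list", heads)
  mixed <- vector("list", heads)
  attn_sum <- matrix(0, N, n)
  for (h in seq_len(heads)) {
    cols <- .head_cols(h, dk)
    m1 <- attention_matrix(Q1[, cols, drop = FALSE], Kf[, cols, drop = FALSE])
    m2 <- attention_matrix(Q2[, cols, drop = FALSE], Kf[, cols, drop = FALSE])
    mp <- alpha * m1 + (1 - alpha) * m2
    O[, cols] <- mp %*% V[, cols, drop = FALSE]
    attn_sum <- attn_sum + mp
    if (cache) { mt1[[h]] <- m1; mt2[[h]] <- m2; mixed[[h]] <- mp }
  }
  proj <- add_bias(O %*% params$mdca_Wo, params$mdca_bo)
  out <- proj + IQ
  res <- list(out = out, attn = attn_sum / heads)
  if (cache) {
    res <- c(res, list(ln_iq = ln_iq, ln_vq = ln_vq, ln_f = ln_f,
                       Q1 = Q1, Q2 = Q2, Kf = Kf, V = V, O = O,
                       mt1 = mt1, mt2 = mt2, mixed = mixed,
                       alpha = alpha, heads = heads, dk = dk,
                       IQ = IQ, VQ = VQ, f_proj = f_proj))
  }
  res
}

#' Multi-head self-attention over the subtype tokens
#'
#' Standard multi-head self-attention where queries, keys and values all
#' arise from the same `N x d_prime` input, followed by a residual
#' connection and post-layer normalization.
#'
#' @param x `N x d_prime` subtype representations.
#' @param params model parameter list (fields `mhsa_*`).
#' @param heads number of heads.
#' @param cache logical; keep intermediates for backprop.
#' @return list with `out` (`N x d_prime`) and caches when requested.
#' @export
mhsa <- function(x, params, heads, cache = FALSE) {
  N <- nrow(x); dp <- ncol(x)
  dk <- dp %/% heads
  Q <- x %*% params$mhsa_Wq
  K <- x %*% params$mhsa_Wk
  V <- x %*% params$mhsa_Wv
  O <- matrix(0, N, dp)
  att <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- .head_cols(h, dk)
    a <- attention_matrix(Q[, cols, drop = FALSE], K[, cols, drop = FALSE])
    O[, cols] <- a %*% V[, cols, drop = FALSE]
    if (cache) att[[h]] <- a
  }
  proj <- add_bias(O %*% params$mhsa_Wo, params$mhsa_bo)
  z <- x + proj
  ln <- layernorm_rows(z, params$mhsa_ln_g, params$mhsa_ln_b, cache = TRUE)
  res <- list(out = ln$y)
  if (cache) {
    res <- c(res, list(Q = Q, K = K, V = V, O = O, att = att, ln = ln,
                       x = x, heads = heads, dk = dk))
  }
  res
}

#' Post-layer-normalization feed-forward block
#'
#' Row-wise two-layer perceptron (expansion, GELU, contraction) with a
#' residual connection, normalized after the residual sum.
#'
#' @param x `N x d_prime` input.
#' @param params model parameter list.
#' @param prefix `"ffn1"` or `"ffn2"` selecting the block's weights.
#' @param cache logical; keep intermediates for backprop.
#' @return list with `out` and caches when requested.
#' @export
ffn <- function(x, params, prefix = "ffn1", cache = FALSE) {
  W1 <- params[[paste0(prefix, "_W1")]]; b1 <- params[[paste0(prefix, "_b1")]]
  W2 <- params[[paste0(prefix, "_W2")]]; b2 <- params[[paste0(prefix, "_b2")]]
  g <- params[[paste0(prefix, "_ln_g")]]; b <- params[[paste0(prefix, "_ln_b")]]
  h1 <- add_bias(x %*% W1, b1)
  a <- gelu(h1)
  f <- add_bias(a %*% W2, b2)
  z <- x + f
  ln <- layernorm_rows(z, g, b, cache = TRUE)
  res <- list(out = ln$y)
  if (cache) res <- c(res, list(h1 = h1, a = a, ln = ln, x = x))
  res
}

#' Average the subtype representations into one bag vector
#'
#' @param features `N x d_prime` matrix of per-subtype representations.
#' @return numeric vector of length `d_prime`.
#' @export
bag_representation <- function(features) {
  stopifnot(nrow(features) >= 1L)
  colMeans(as.matrix(features))
}

#' Full forward pass over one bag
#'
#' Composes the instance classification head, the deep projection layer, the
#' internal query generation, the dual-query cross-attention, two
#' feed-forward blocks and the self-attention block, averages the subtype
#' representations and classifies the bag.
#'
#' @param model a [mdmil_model()].
#' @param features `n x d` raw instance feature matrix (or an
#'   [instance_bag()]).
#' @param cache logical; keep every intermediate for backprop.
#' @return a list: `P1` (`n x N` instance probabilities), `P2` (length-`N`
#'   bag probabilities), `f_subtypes` (`N x d_prime`), `rep`
#'   (`d_prime`-vector), `attn` (`N x n` head-averaged mixed cross-attention),
#'   `iqgm` (the [generate_internal_queries()] output), `alpha` (mixing
#'   weight used), plus caches when requested.
#' @export
forward_bag <- function(model, features, cache = FALSE) {
  if (inherits(features, "instance_bag")) features <- features$features
  cfg <- model$config; p <- model$params
  ip <- instance_probabilities(features, p)
  dpl <- project_features(features, p, cache = TRUE)
  iq <- generate_internal_queries(dpl$out, ip$P, cfg)
  alpha <- if (cfg$alpha_gated) {
    if (is.null(iq$reliable_class)) cfg$alpha_lo else cfg$alpha_hi
  } else cfg$alpha_attn
  md <- mdca(iq$queries, p$VQ, dpl$out, p, cfg$heads, alpha, cache = cache)
  f1 <- ffn(md$out, p, "ffn1", cache = cache)
  sa <- mhsa(f1$out, p, cfg$heads, cache = cache)
  f2 <- ffn(sa$out, p, "ffn2", cache = cache)
  f_subtypes <- f2$out
  rep_vec <- bag_representation(f_subtypes)
  logits2 <- as.numeric(rep_vec %*% p$cls2_W) + p$cls2_b
  P2 <- as.numeric(softmax_rows(matrix(logits2, 1L)))
  out <- list(P1 = ip$P, P2 = P2, f_subtypes = f_subtypes, rep = rep_vec,
              attn = md$attn, iqgm = iq, alpha = alpha)
  if (cache) {
    out$caches <- list(ip = ip, dpl = dpl, md = md, f1 = f1, sa = sa, f2 = f2,
                       logits2 = logits2, features = as.matrix(features))
  }
  out
}
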