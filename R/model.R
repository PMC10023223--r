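#' Model configuration
#'
#' Collects every architecture and loss hyperparameter in one list.
#'
#' @param d input feature dimension per instance.
#' @param n_classes number of subtypes `N >= 2`.
#' @param d_prime hidden width after the deep projection layer; must be a
#'   multiple of `heads`.
#' @param heads number of attention heads `m`.
#' @param r1,r2 top-K ratios of the internal query module; `r1 >= r2`.
#' @param beta confidence-gate margin in `[-1, 1]`.
#' @param beta_class optional 0-based class index; when set, `beta` is
#'   subtracted from that class's confidence factor before the gate instead
#'   of from the maximal one (asymmetric gating for instance-imbalanced
#'   detection data).
#' @param alpha_attn convex weight of the internal-query attention matrix in
#'   `[0, 1]`; `alpha_gated = TRUE` switches between `alpha_hi` (reliable
#'   query found) and `alpha_lo` (none) instead.
#' @param alpha_gated,alpha_hi,alpha_lo gated-alpha policy (see above).
#' @param ffn_expansion feed-forward hidden expansion factor.
#' @param alpha_loss weight of the contrastive term in the composite loss.
#' @param tau contrastive temperature.
#' @param momentum memory-bank momentum coefficient.
#' @param instance_pooling `"per_class_max"` (default) pools the instance
#'   probability matrix by a per-class maximum over instances;
#'   `"global_max"` takes the single row holding the overall maximum.
#' @return a `mdmil_config` list.
#' @export
mdmil_config <- function(d = 64L, n_classes = 2L, d_prime = 64L, heads = 8L,
                         r1 = 0.05, r2 = 0.01, beta = 0, beta_class = NULL,
                         alpha_attn = 0.5, alpha_gated = FALSE,
                         alpha_hi = 0.7, alpha_lo = 0.3,
                         ffn_expansion = 4L, alpha_loss = 0.5,
                         tau = 0.07, momentum = 0.999,
                         instance_pooling = c("per_class_max", "global_max")) {
  instance_pooling <- match.arg(instance_pooling)
  stopifnot(n_classes >= 2L, d >= 1L, d_prime >= 1L,
            d_prime %% heads == 0L,
            r1 > 0, r1 <= 1, r2 > 0, r2 <= 1,
            beta >= -1, beta <= 1,
            alpha_attn >= 0, alpha_attn <= 1,
            ffn_expansion >= 1L, alpha_loss >= 0, tau > 0,
            momentum >= 0, momentum <= 1)
  if (r1 < r2) stop("r1 must be >= r2", call. = FALSE)
  structure(
    list(d = as.integer(d), n_classes = as.integer(n_classes),
         d_prime = as.integer(d_prime), heads = as.integer(heads),
         r1 = r1, r2 = r2, beta = beta, beta_class = beta_class,
         alpha_attn = alpha_attn, alpha_gated = alpha_gated,
         alpha_hi = alpha_hi, alpha_lo = alpha_lo,
         ffn_expansion = as.integer(ffn_expansion),
         alpha_loss = alpha_loss, tau = tau, momentum = momentum,
         instance_pooling = instance_pooling),
    class = "mdmil_config"
  )
}

# Truncated-normal-free initializer: plain Gaussian, std scaled by fan-in.
.init_mat <- function(nin, nout, std = NULL) {
  if (is.null(std)) std <- sqrt(2 / (nin + nout))
  matrix(rnorm(nin * nout, sd = std), nin, nout)
}

.ffn_params <- function(dp, e) {
  list(W1 = .init_mat(dp, e * dp), b1 = numeric(e * dp),
       W2 = .init_mat(e * dp, dp), b2 = numeric(dp),
       ln_g = rep(1, dp), ln_b = numeric(dp))
}

#' Initialize a model
#'
#' Creates all trainable tensors: the deep projection layer (DPL), the
#' instance classification head `cls1`, the variational query `VQ`, the
#' dual-query cross-attention projections, two feed-forward blocks, the
#' self-attention block and the final bag classifier. The two classification
#' heads start at zero so the initial composite loss has the closed form
#' `2 log N` plus the weighted contrastive term.
#'
#' @param config a [mdmil_config()].
#' @param seed integer seed for the Gaussian initialization.
#' @return a `mdmil_model` list with `config`, `params` (named list of
#'   matrices/vectors) and `memory` (`NULL` until [init_memory()]).
#' @export
mdmil_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mdmil_config"))
  d <- config$d; dp <- config$d_prime; N <- config$n_classes
  e <- config$ffn_expansion
  params <- with_seed(seed, {
    p <- list(
      # deep projection layer: FC -> LN -> ReLU -> FC
      dpl_W1 = .init_mat(d, dp), dpl_b1 = numeric(dp),
      dpl_ln_g = rep(1, dp), dpl_ln_b = numeric(dp),
      dpl_W2 = .init_mat(dp, dp), dpl_b2 = numeric(dp),
      # instance classification head on raw features
      cls1_W = matrix(0, d, N), cls1_b = numeric(N),
      # variational query
      VQ = matrix(rnorm(N * dp, sd = 0.02), N, dp),
      # dual-query cross-attention
      mdca_ln_iq_g = rep(1, dp), mdca_ln_iq_b = numeric(dp),
      mdca_ln_vq_g = rep(1, dp), mdca_ln_vq_b = numeric(dp),
      mdca_ln_f_g = rep(1, dp), mdca_ln_f_b = numeric(dp),
      mdca_W1 = .init_mat(dp, dp), mdca_W2 = .init_mat(dp, dp),
      mdca_W3 = .init_mat(dp, dp), mdca_W4 = .init_mat(dp, dp),
      mdca_Wo = .init_mat(dp, dp), mdca_bo = numeric(dp),
      # self-attention over the N subtype tokens
      mhsa_Wq = .init_mat(dp, dp), mhsa_Wk = .init_mat(dp, dp),
      mhsa_Wv = .init_mat(dp, dp), mhsa_Wo = .init_mat(dp, dp),
      mhsa_bo = numeric(dp),
      mhsa_ln_g = rep(1, dp), mhsa_ln_b = numeric(dp),
      # final bag classifier
      cls2_W = matrix(0, dp, N), cls2_b = numeric(N)
    )
    ffn1 <- .ffn_params(dp, e)
    names(ffn1) <- paste0("ffn1_", names(ffn1))
    ffn2 <- .ffn_params(dp, e)
    names(ffn2) <- paste0("ffn2_", names(ffn2))
    c(p, ffn1, ffn2)
  })
  structure(list(config = config, params = params, memory = NULL),
            class = "mdmil_model")
}

#' @export
print.mdmil_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<mdmil_model: d=%d, d'=%d, N=%d, heads=%d, %d parameters%s>\n",
              x$config$d, x$config$d_prime, x$config$n_classes,
              x$config$heads, np,
              if (is.null(x$memory)) "" else ", memory initialized"))
  invisible(x)
}
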