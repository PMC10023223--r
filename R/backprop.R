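# Exact reverse-mode gradients of the composite loss for one bag.
#
# The discrete decisions of the forward pass (top-K membership, the reliable
# gate, the arg-max instances of the pooled instance loss) are locally
# constant almost everywhere, so they are treated as constants and the
# gradient flows through the continuous operations only.

zero_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
}

#' Composite loss of one bag (no gradients)
#'
#' @param model a [mdmil_model()].
#' @param bag an [instance_bag()] or raw feature matrix with `label`.
#' @param bank a `memory_bank`.
#' @param label 0-based label (taken from the bag when omitted).
#' @return scalar loss.
#' @export
bag_loss <- function(model, bag, bank, label = NULL) {
  if (is.null(label)) label <- bag$label
  fwd <- forward_bag(model, bag)
  total_loss(fwd$P1, fwd$P2, fwd$f_subtypes[label + 1L, ], bank, label,
             model$config)
}

# Backward through one post-LN feed-forward block. Returns dx and writes
# parameter gradients into `grads` (environment-style in-place via list
# return).
.ffn_backward <- function(cache, params, prefix, dy, grads) {
  g <- params[[paste0(prefix, "_ln_g")]]
  W1 <- params[[paste0(prefix, "_W1")]]; W2 <- params[[paste0(prefix, "_W2")]]
  lb <- layernorm_rows_backward(cache$ln, g, dy)
  grads[[paste0(prefix, "_ln_g")]] <- grads[[paste0(prefix, "_ln_g")]] + lb$dg
  grads[[paste0(prefix, "_ln_b")]] <- grads[[paste0(prefix, "_ln_b")]] + lb$db
  dz <- lb$dx
  dx <- dz                                   # residual branch
  grads[[paste0(prefix, "_W2")]] <- grads[[paste0(prefix, "_W2")]] + t(cache$a) %*% dz
  grads[[paste0(prefix, "_b2")]] <- grads[[paste0(prefix, "_b2")]] + colSums(dz)
  da <- dz %*% t(W2)
  dh1 <- da * gelu_grad(cache$h1)
  grads[[paste0(prefix, "_W1")]] <- grads[[paste0(prefix, "_W1")]] + t(cache$x) %*% dh1
  grads[[paste0(prefix, "_b1")]] <- grads[[paste0(prefix, "_b1")]] + colSums(dh1)
  dx <- dx + dh1 %*% t(W1)
  list(dx = dx, grads = grads)
}

.mhsa_backward <- function(cache, params, dy, grads) {
  heads <- cache$heads; dk <- cache$dk
  lb <- layernorm_rows_backward(cache$ln, params$mhsa_ln_g, dy)
  grads$mhsa_ln_g <- grads$mhsa_ln_g + lb$dg
  grads$mhsa_ln_b <- grads$mhsa_ln_b + lb$db
  dz <- lb$dx
  dx <- dz
  grads$mhsa_Wo <- grads$mhsa_Wo + t(cache$O) %*% dz
  grads$mhsa_bo <- grads$mhsa_bo + colSums(dz)
  dO <- dz %*% t(params$mhsa_Wo)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    cols <- .head_cols(h, dk)
    a <- cache$att[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    da <- dOh %*% t(Vh)
    dV[, cols] <- t(a) %*% dOh
    dS <- softmax_rows_backward(a, da) / sqrt(dk)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE]
  }
  grads$mhsa_Wq <- grads$mhsa_Wq + t(cache$x) %*% dQ
  grads$mhsa_Wk <- grads$mhsa_Wk + t(cache$x) %*% dK
  grads$mhsa_Wv <- grads$mhsa_Wv + t(cache$x) %*% dV
  dx <- dx + dQ %*% t(params$mhsa_Wq) + dK %*% t(params$mhsa_Wk) +
    dV %*% t(params$mhsa_Wv)
  list(dx = dx, grads = grads)
}

# Backward through the dual-query cross-attention. Returns gradients w.r.t.
# the internal queries (dIQ) and the projected bag features (dFp); writes
# parameter gradients (including VQ) into `grads`.
.mdca_backward <- function(cache, params, dy, grads) {
  heads <- cache$heads; dk <- cache$dk; alpha <- cache$alpha
  dproj <- dy
  dIQ <- dy                                   # residual branch
  grads$mdca_Wo <- grads$mdca_Wo + t(cache$O) %*% dproj
  grads$mdca_bo <- grads$mdca_bo + colSums(dproj)
  dO <- dproj %*% t(params$mdca_Wo)
  dQ1 <- matrix(0, nrow(cache$Q1), ncol(cache$Q1))
  dQ2 <- dQ1
  dKf <- matrix(0, nrow(cache$Kf), ncol(cache$Kf))
  dV <- dKf
  for (h in seq_len(heads)) {
    cols <- .head_cols(h, dk)
    mp <- cache$mixed[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dmp <- dOh %*% t(Vh)
    dV[, cols] <- t(mp) %*% dOh
    dS1 <- softmax_rows_backward(cache$mt1[[h]], alpha * dmp) / sqrt(dk)
    dS2 <- softmax_rows_backward(cache$mt2[[h]], (1 - alpha) * dmp) / sqrt(dk)
    Kh <- cache$Kf[, cols, drop = FALSE]
    dQ1[, cols] <- dS1 %*% Kh
    dQ2[, cols] <- dS2 %*% Kh
    dKf[, cols] <- t(dS1) %*% cache$Q1[, cols, drop = FALSE] +
      t(dS2) %*% cache$Q2[, cols, drop = FALSE]
  }
  grads$mdca_W1 <- grads$mdca_W1 + t(cache$ln_iq$y) %*% dQ1
  grads$mdca_W2 <- grads$mdca_W2 + t(cache$ln_vq$y) %*% dQ2
  grads$mdca_W3 <- grads$mdca_W3 + t(cache$ln_f$y) %*% dKf
  grads$mdca_W4 <- grads$mdca_W4 + t(cache$ln_f$y) %*% dV
  lb_iq <- layernorm_rows_backward(cache$ln_iq, params$mdca_ln_iq_g,
                                   dQ1 %*% t(params$mdca_W1))
  grads$mdca_ln_iq_g <- grads$mdca_ln_iq_g + lb_iq$dg
  grads$mdca_ln_iq_b <- grads$mdca_ln_iq_b + lb_iq$db
  dIQ <- dIQ + lb_iq$dx
  lb_vq <- layernorm_rows_backward(cache$ln_vq, params$mdca_ln_vq_g,
                                   dQ2 %*% t(params$mdca_W2))
  grads$mdca_ln_vq_g <- grads$mdca_ln_vq_g + lb_vq$dg
  grads$mdca_ln_vq_b <- grads$mdca_ln_vq_b + lb_vq$db
  grads$VQ <- grads$VQ + lb_vq$dx
  lb_f <- layernorm_rows_backward(cache$ln_f, params$mdca_ln_f_g,
                                  dKf %*% t(params$mdca_W3) +
                                  dV %*% t(params$mdca_W4))
  grads$mdca_ln_f_g <- grads$mdca_ln_f_g + lb_f$dg
  grads$mdca_ln_f_b <- grads$mdca_ln_f_b + lb_f$db
  list(dIQ = dIQ, dFp = lb_f$dx, grads = grads)
}

#' Loss and analytic parameter gradients for one bag
#'
#' Runs the cached forward pass, evaluates the composite objective, and
#' backpropagates through every module, returning gradients for all
#' trainable tensors.
#'
#' @param model a [mdmil_model()].
#' @param bag an [instance_bag()].
#' @param bank a `memory_bank`.
#' @return list: `loss`, `grads` (named like `model$params`), `fwd` (the
#'   cached forward output).
#' @export
bag_loss_grad <- function(model, bag, bank) {
  cfg <- model$config; p <- model$params
  label <- bag$label
  y <- label + 1L
  N <- cfg$n_classes
  fwd <- forward_bag(model, bag, cache = TRUE)
  ca <- fwd$caches
  Fraw <- ca$features
  n <- nrow(Fraw)
  grads <- zero_like(p)

  f_lab <- fwd$f_subtypes[y, ]
  loss <- total_loss(fwd$P1, fwd$P2, f_lab, bank, label, cfg)

  ## ---- instance cross-entropy -> cls1 -------------------------------
  P1 <- fwd$P1
  dP1 <- matrix(0, n, N)
  if (cfg$instance_pooling == "per_class_max") {
    s <- apply(P1, 2L, max)
    imax <- apply(P1, 2L, which.max)
    ds <- 1 / sum(s) - (seq_len(N) == y) / s[y]
    for (j in seq_len(N)) dP1[imax[j], j] <- dP1[imax[j], j] + ds[j]
  } else {
    i <- which(P1 == max(P1), arr.ind = TRUE)[1L, 1L]
    dP1[i, y] <- -1 / P1[i, y]
  }
  dlogits1 <- softmax_rows_backward(P1, dP1)
  grads$cls1_W <- grads$cls1_W + t(Fraw) %*% dlogits1
  grads$cls1_b <- grads$cls1_b + colSums(dlogits1)

  ## ---- bag cross-entropy -> cls2, rep -------------------------------
  dlogits2 <- fwd$P2
  dlogits2[y] <- dlogits2[y] - 1
  grads$cls2_W <- grads$cls2_W + outer(fwd$rep, dlogits2)
  grads$cls2_b <- grads$cls2_b + dlogits2
  drep <- as.numeric(p$cls2_W %*% dlogits2)

  ## ---- contrastive loss -> labeled subtype row ----------------------
  nrm <- sqrt(sum(f_lab^2))
  fn <- f_lab / nrm
  logits_c <- as.numeric(bank$centers %*% fn) / bank$tau
  pc <- as.numeric(softmax_rows(matrix(logits_c, 1L)))
  dlogits_c <- cfg$alpha_loss * (pc - (seq_len(N) == y))
  dfn <- as.numeric(t(bank$centers) %*% dlogits_c) / bank$tau
  df_lab <- (dfn - fn * sum(dfn * fn)) / nrm

  ## ---- back through the MDM stack -----------------------------------
  dFS <- matrix(drep / N, N, cfg$d_prime, byrow = TRUE)
  dFS[y, ] <- dFS[y, ] + df_lab
  b2 <- .ffn_backward(ca$f2, p, "ffn2", dFS, grads); grads <- b2$grads
  bs <- .mhsa_backward(ca$sa, p, b2$dx, grads); grads <- bs$grads
  b1 <- .ffn_backward(ca$f1, p, "ffn1", bs$dx, grads); grads <- b1$grads
  bm <- .mdca_backward(ca$md, p, b1$dx, grads); grads <- bm$grads

  ## ---- internal queries -> projected features -----------------------
  dFp <- bm$dFp
  for (j in seq_len(N)) {
    idx <- fwd$iqgm$selected[[j]]
    dFp[idx, ] <- dFp[idx, ] +
      matrix(bm$dIQ[j, ] / length(idx), length(idx), cfg$d_prime, byrow = TRUE)
  }

  ## ---- deep projection layer ----------------------------------------
  dpl <- ca$dpl
  grads$dpl_W2 <- grads$dpl_W2 + t(dpl$r) %*% dFp
  grads$dpl_b2 <- grads$dpl_b2 + colSums(dFp)
  dr <- dFp %*% t(p$dpl_W2)
  dlny <- dr * (dpl$ln$y > 0)
  lb <- layernorm_rows_backward(dpl$ln, p$dpl_ln_g, dlny)
  grads$dpl_ln_g <- grads$dpl_ln_g + lb$dg
  grads$dpl_ln_b <- grads$dpl_ln_b + lb$db
  grads$dpl_W1 <- grads$dpl_W1 + t(Fraw) %*% lb$dx
  grads$dpl_b1 <- grads$dpl_b1 + colSums(lb$dx)

  list(loss = loss, grads = grads, fwd = fwd)
}
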