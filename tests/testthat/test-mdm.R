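test_that("attention rows are distributions with closed-form values", {
  # single key: weight 1
  expect_equal(attention_matrix(matrix(1:2, 1, 2), matrix(3:4, 1, 2)),
               matrix(1, 1, 1), ignore_attr = TRUE)
  # equal dot products: 0.5 / 0.5
  K <- rbind(c(1, 0), c(0, 1))
  expect_equal(as.numeric(attention_matrix(matrix(c(1, 1), 1, 2), K)),
               c(0.5, 0.5))
  # scaled logits (1, 0): closed-form softmax (d_k = 1)
  expect_equal(as.numeric(attention_matrix(matrix(1, 1, 1), matrix(c(1, 0), 2, 1))),
               c(0.73106, 0.26894), tolerance = 1e-5)
  expect_error(attention_matrix(matrix(1, 1, 1), matrix(0, 0, 1)), "zero keys")
})

make_mdca_inputs <- function(N = 2L, n = 7L, dp = 8L, seed = 5L) {
  mdmil:::with_seed(seed, list(
    IQ = matrix(rnorm(N * dp), N, dp),
    VQ = matrix(rnorm(N * dp), N, dp),
    Fp = matrix(rnorm(n * dp), n, dp)
  ))
}

test_that("dual-query attention mixes convexly and respects its boundaries", {
  m <- toy_model(d = 8L, d_prime = 8L, heads = 2L)
  x <- make_mdca_inputs()
  for (alpha in c(0, 0.25, 0.5, 1)) {
    out <- mdca(x$IQ, x$VQ, x$Fp, m$params, heads = 2L, alpha = alpha,
                cache = TRUE)
    for (h in 1:2) {
      expect_equal(rowSums(out$mixed[[h]]), rep(1, 2), tolerance = 1e-6)
      expect_true(all(out$mixed[[h]] >= 0))
    }
    expect_equal(rowSums(out$attn), rep(1, 2), tolerance = 1e-6)
  }
  expect_error(mdca(x$IQ, x$VQ, x$Fp, m$params, 2L, alpha = 1.5), "alpha")

  # alpha = 1: identical to ignoring VQ entirely
  a1 <- mdca(x$IQ, x$VQ, x$Fp, m$params, 2L, alpha = 1)
  a1b <- mdca(x$IQ, x$VQ * 100, x$Fp, m$params, 2L, alpha = 1)
  expect_equal(a1$out, a1b$out, tolerance = 1e-12)

  # alpha = 0: attention ignores IQ but the residual still adds it
  a0 <- mdca(x$IQ, x$VQ, x$Fp, m$params, 2L, alpha = 0)
  IQ2 <- x$IQ + 1
  a0b <- mdca(IQ2, x$VQ, x$Fp, m$params, 2L, alpha = 0)
  expect_equal(a0b$out - a0$out, IQ2 - x$IQ, tolerance = 1e-9)
})

test_that("a single-instance bag broadcasts its value row", {
  m <- toy_model(d = 8L, d_prime = 8L, heads = 2L)
  x <- make_mdca_inputs(n = 1L)
  out <- mdca(x$IQ, x$VQ, x$Fp, m$params, 2L, alpha = 0.5, cache = TRUE)
  # attention weights are all 1; pre-residual rows equal the projected value
  pre <- out$out - x$IQ
  v <- mdmil:::layernorm_rows(x$Fp, m$params$mdca_ln_f_g, m$params$mdca_ln_f_b) %*%
    m$params$mdca_W4
  manual <- as.numeric(v %*% m$params$mdca_Wo) + m$params$mdca_bo
  expect_equal(pre[1, ], manual, tolerance = 1e-9)
  expect_equal(pre[2, ], manual, tolerance = 1e-9)
})

test_that("cross-attention output is invariant to instance permutation", {
  m <- toy_model(d = 8L, d_prime = 8L, heads = 2L)
  x <- make_mdca_inputs(n = 9L)
  out <- mdca(x$IQ, x$VQ, x$Fp, m$params, 2L, alpha = 0.5)
  perm <- mdmil:::with_seed(8L, sample(9L))
  out_p <- mdca(x$IQ, x$VQ, x$Fp[perm, ], m$params, 2L, alpha = 0.5)
  expect_equal(out$out, out_p$out, tolerance = 1e-6)
  expect_equal(out$attn[, perm], out_p$attn, tolerance = 1e-9)
})

test_that("self-attention matches a loop-based oracle", {
  m <- toy_model(d = 8L, d_prime = 8L, heads = 2L)
  x <- mdmil:::with_seed(9L, matrix(rnorm(3 * 8), 3, 8))
  got <- mhsa(x, m$params, heads = 2L)$out

  p <- m$params
  Q <- x %*% p$mhsa_Wq; K <- x %*% p$mhsa_Wk; V <- x %*% p$mhsa_Wv
  O <- matrix(0, 3, 8)
  for (h in 1:2) {
    cols <- ((h - 1) * 4 + 1):(h * 4)
    S <- Q[, cols] %*% t(K[, cols]) / 2   # sqrt(d_k) = 2
    for (i in 1:3) {
      w <- exp(S[i, ] - max(S[i, ])); w <- w / sum(w)
      O[i, cols] <- colSums(w * V[, cols])
    }
  }
  z <- x + (O %*% p$mhsa_Wo + matrix(p$mhsa_bo, 3, 8, byrow = TRUE))
  want <- t(apply(z, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * p$mhsa_ln_g + p$mhsa_ln_b
  }))
  expect_equal(got, want, tolerance = 1e-9)

  # N = 1: attention weight is 1
  x1 <- x[1, , drop = FALSE]
  got1 <- mhsa(x1, m$params, heads = 2L)$out
  z1 <- x1 + (x1 %*% p$mhsa_Wv %*% p$mhsa_Wo +
                matrix(p$mhsa_bo, 1, 8, byrow = TRUE))
  want1 <- mdmil:::layernorm_rows(z1, p$mhsa_ln_g, p$mhsa_ln_b)
  expect_equal(got1, want1, tolerance = 1e-9)

  # identical input rows give identical output rows
  xx <- rbind(x[1, ], x[1, ])
  got2 <- mhsa(xx, m$params, heads = 2L)$out
  expect_equal(got2[1, ], got2[2, ], tolerance = 1e-12)
})

test_that("feed-forward block is a row-wise residual map", {
  m <- toy_model(d = 8L, d_prime = 8L)
  x <- mdmil:::with_seed(10L, matrix(rnorm(4 * 8), 4, 8))
  out <- ffn(x, m$params, "ffn1")$out
  perm <- c(4L, 2L, 1L, 3L)
  expect_identical(ffn(x[perm, ], m$params, "ffn1")$out, out[perm, ])

  # zero expansion path: pure layer norm of the residual passthrough
  p0 <- m$params
  p0$ffn1_W1[] <- 0; p0$ffn1_b1[] <- 0; p0$ffn1_W2[] <- 0; p0$ffn1_b2[] <- 0
  expect_equal(ffn(x, p0, "ffn1")$out,
               mdmil:::layernorm_rows(x, p0$ffn1_ln_g, p0$ffn1_ln_b),
               tolerance = 1e-12)

  # stage-by-stage oracle on one row
  p <- m$params
  h1 <- as.numeric(x[3, ] %*% p$ffn1_W1) + p$ffn1_b1
  a <- h1 * pnorm(h1)
  z <- x[3, ] + as.numeric(a %*% p$ffn1_W2) + p$ffn1_b2
  want <- (z - mean(z)) / sqrt(mean((z - mean(z))^2) + 1e-5) *
    p$ffn1_ln_g + p$ffn1_ln_b
  expect_equal(out[3, ], want, tolerance = 1e-9)
})

test_that("bag representation is the arithmetic mean of subtype rows", {
  x <- matrix(rnorm(16), 2, 8)
  expect_equal(bag_representation(x), (x[1, ] + x[2, ]) / 2)
  expect_equal(bag_representation(x[1, , drop = FALSE]), x[1, ])
  y <- mdmil:::with_seed(3L, matrix(rnorm(40), 5, 8))
  expect_equal(bag_representation(y), colSums(y) / 5, tolerance = 1e-12)
})

test_that("the full forward pass composes the stages faithfully", {
  m <- toy_model(d = 6L, n_classes = 2L, d_prime = 8L, heads = 2L,
                 r1 = 0.5, r2 = 0.25, randomize_heads = TRUE)
  bag <- toy_bag(4L, 6L, label = 1L, seed = 44L)
  fwd <- forward_bag(m, bag)

  # hand-unrolled composition
  p <- m$params; cfg <- m$config
  P1 <- instance_probabilities(bag$features, p)$P
  Fp <- project_features(bag$features, p)
  iq <- generate_internal_queries(Fp, P1, cfg)
  z <- mdca(iq$queries, p$VQ, Fp, p, cfg$heads, cfg$alpha_attn)$out
  z <- ffn(z, p, "ffn1")$out
  z <- mhsa(z, p, cfg$heads)$out
  z <- ffn(z, p, "ffn2")$out
  rep_vec <- bag_representation(z)
  logits <- as.numeric(rep_vec %*% p$cls2_W) + p$cls2_b
  P2 <- exp(logits - max(logits)); P2 <- P2 / sum(P2)

  expect_equal(fwd$P1, P1, tolerance = 1e-12)
  expect_equal(fwd$f_subtypes, z, tolerance = 1e-12)
  expect_equal(fwd$P2, P2, tolerance = 1e-12)
  expect_equal(sum(fwd$P2), 1, tolerance = 1e-9)

  # permutation invariance of the whole pass
  perm <- c(3L, 1L, 4L, 2L)
  bag_p <- instance_bag(bag$features[perm, ], bag$label, "perm")
  fwd_p <- forward_bag(m, bag_p)
  expect_equal(fwd_p$P2, fwd$P2, tolerance = 1e-5)
  expect_equal(fwd_p$f_subtypes, fwd$f_subtypes, tolerance = 1e-5)

  # zero-weight final classifier: uniform bag posterior
  m0 <- toy_model(d = 6L, n_classes = 2L, d_prime = 8L, heads = 2L)
  expect_equal(forward_bag(m0, bag)$P2, c(0.5, 0.5))

  # instance dimension is reduced from n to N after cross-attention
  expect_equal(dim(fwd$f_subtypes), c(2L, 8L))
  expect_equal(dim(fwd$attn), c(2L, 4L))
})
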