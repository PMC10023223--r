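test_that("deep projection is a deterministic row-wise map", {
  m <- toy_model(d = 8L, d_prime = 8L)
  F <- toy_bag(5L, 8L, seed = 2L)$features
  out <- project_features(F, m$params)
  # permuting rows permutes outputs identically
  perm <- c(3L, 1L, 5L, 2L, 4L)
  expect_identical(project_features(F[perm, ], m$params), out[perm, ])
  # degenerate single-instance bag
  expect_equal(dim(project_features(F[1, , drop = FALSE], m$params)), c(1L, 8L))
  # stage-by-stage oracle on one row
  p <- m$params
  h <- as.numeric(F[2, ] %*% p$dpl_W1) + p$dpl_b1
  xc <- h - mean(h)
  xhat <- xc / sqrt(mean(xc^2) + 1e-5)
  r <- pmax(xhat * p$dpl_ln_g + p$dpl_ln_b, 0)
  manual <- as.numeric(r %*% p$dpl_W2) + p$dpl_b2
  expect_equal(as.numeric(out[2, ]), manual, tolerance = 1e-12)
  expect_error(project_features(matrix(0, 2, 5), m$params), "dimension")
})

test_that("instance probabilities are a per-instance softmax of raw features", {
  m <- toy_model(d = 4L, d_prime = 8L)
  F <- matrix(rnorm(12), 3, 4)
  # zero-initialized head: uniform rows
  P <- instance_probabilities(F, m$params)$P
  expect_equal(P, matrix(0.5, 3, 2), ignore_attr = TRUE)
  # closed-form softmax of logits (ln 3, 0)
  p2 <- m$params
  p2$cls1_W <- matrix(0, 4, 2); p2$cls1_b <- c(log(3), 0)
  expect_equal(instance_probabilities(F, p2)$P[1, ], c(0.75, 0.25),
               tolerance = 1e-12)
  # rows always normalize
  p3 <- m$params
  p3$cls1_W <- matrix(rnorm(8), 4, 2); p3$cls1_b <- rnorm(2)
  expect_equal(rowSums(instance_probabilities(F, p3)$P), rep(1, 3),
               tolerance = 1e-9)
})

test_that("top-K count floors and clamps", {
  expect_identical(top_k_count(100L, 0.05), 5L)
  expect_identical(top_k_count(10L, 0.01), 1L)   # floor 0, clamped to 1
  expect_identical(top_k_count(7L, 1.0), 7L)
})

test_that("confidence factor is mean minus population std of top-K1", {
  expect_equal(confidence_factor(c(0.9, 0.7, 0.5, 0.1, 0.2), 3L),
               0.536701, tolerance = 1e-6)
  # equal top probabilities: sigma = 0, cf = p
  expect_equal(confidence_factor(rep(0.4, 5), 3L), 0.4)
  # K1 = 1: cf is the single max
  expect_equal(confidence_factor(c(0.2, 0.8, 0.5), 1L), 0.8)
})

test_that("the reliable-query gate follows the confidence margin", {
  # engineered P with cf = (0.9, 0.2) at K1 = 3 (n = 10, r1 = 0.3)
  col0 <- c(0.9, 0.9, 0.9, rep(0.8, 7))
  P <- cbind(col0, 1 - col0)
  Fp <- mdmil:::with_seed(4L, matrix(rnorm(10 * 6), 10, 6))

  cfg0 <- mdmil_config(d = 6, n_classes = 2, d_prime = 6, heads = 2,
                       r1 = 0.3, r2 = 0.1, beta = 0)
  out0 <- generate_internal_queries(Fp, P, cfg0)
  expect_equal(out0$conf, c(0.9, 0.2), tolerance = 1e-12)
  expect_identical(out0$reliable_class, 0L)
  expect_equal(out0$queries[1, ], colMeans(Fp[1:3, ]))   # top-K1 average
  expect_equal(out0$queries[2, ], colMeans(Fp[4, , drop = FALSE]))  # top-K2

  # beta = 0.8: 0.9 - 0.8 = 0.1 < 0.2, gate fails, both classes use K2
  cfg8 <- mdmil_config(d = 6, n_classes = 2, d_prime = 6, heads = 2,
                       r1 = 0.3, r2 = 0.1, beta = 0.8)
  out8 <- generate_internal_queries(Fp, P, cfg8)
  expect_null(out8$reliable_class)
  expect_equal(out8$queries[1, ], Fp[1, ])

  # beta = 1 can never produce a reliable class for cf in [0, 1]
  cfg1 <- mdmil_config(d = 6, n_classes = 2, d_prime = 6, heads = 2,
                       r1 = 0.3, r2 = 0.1, beta = 1)
  expect_null(generate_internal_queries(Fp, P, cfg1)$reliable_class)

  # tied maximal confidence: no reliable class
  Pt <- cbind(c(0.9, 0.9, 0.9, rep(0.1, 7)), c(0.9, 0.9, 0.9, rep(0.1, 7)))
  Pt <- Pt / rowSums(Pt)
  expect_null(generate_internal_queries(Fp, Pt, cfg0)$reliable_class)
})

test_that("asymmetric gating subtracts the margin from the designated class", {
  col0 <- c(0.9, 0.9, 0.9, rep(0.8, 7))   # cf = (0.9, 0.2)
  P <- cbind(col0, 1 - col0)
  Fp <- mdmil:::with_seed(4L, matrix(rnorm(10 * 6), 10, 6))
  # subtracting beta = -0.8 from class 1's cf lifts it to 1.0 > 0.9
  cfg <- mdmil_config(d = 6, n_classes = 2, d_prime = 6, heads = 2,
                      r1 = 0.3, r2 = 0.1, beta = -0.8, beta_class = 1L)
  out <- generate_internal_queries(Fp, P, cfg)
  expect_identical(out$reliable_class, 1L)
  # reported conf stays unmodified
  expect_equal(out$conf, c(0.9, 0.2), tolerance = 1e-12)
})

test_that("query generation matches the brute-force oracle on random bags", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:20, 1); N <- sample(2:3, 1); dp <- sample(3:8, 1)
    r1 <- runif(1, 0.1, 1); r2 <- runif(1, 0.05, r1)
    beta <- runif(1, -0.5, 0.5)
    P <- matrix(rexp(n * N), n, N)
    P <- P / rowSums(P)
    Fp <- matrix(rnorm(n * dp), n, dp)
    cfg <- mdmil_config(d = dp, n_classes = N, d_prime = dp, heads = 1,
                        r1 = r1, r2 = r2, beta = beta)
    got <- generate_internal_queries(Fp, P, cfg)
    want <- iqgm_oracle(Fp, P, r1, r2, beta)
    expect_equal(got$queries, want$queries, tolerance = 1e-6)
    expect_equal(got$conf, want$conf, tolerance = 1e-6)
    expect_identical(got$reliable_class, want$reliable_class)
  }
})

test_that("queries are invariant to instance permutation", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 12L
    P <- matrix(rexp(n * 2), n, 2); P <- P / rowSums(P)
    Fp <- matrix(rnorm(n * 6), n, 6)
    cfg <- mdmil_config(d = 6, n_classes = 2, d_prime = 6, heads = 2,
                        r1 = 0.4, r2 = 0.2)
    perm <- sample(n)
    a <- generate_internal_queries(Fp, P, cfg)
    b <- generate_internal_queries(Fp[perm, ], P[perm, ], cfg)
    expect_equal(a$queries, b$queries, tolerance = 1e-12)
    expect_equal(a$conf, b$conf, tolerance = 1e-12)
  }
})

test_that("raising beta can only remove the reliable class, never create one", {
  set.seed(19)
  Fp <- matrix(rnorm(10 * 4), 10, 4)
  P <- matrix(rexp(20), 10, 2); P <- P / rowSums(P)
  betas <- seq(-1, 1, by = 0.1)
  states <- vapply(betas, function(b) {
    cfg <- mdmil_config(d = 4, n_classes = 2, d_prime = 4, heads = 2,
                        r1 = 0.3, r2 = 0.1, beta = b)
    !is.null(generate_internal_queries(Fp, P, cfg)$reliable_class)
  }, logical(1))
  # monotone: TRUE ... TRUE FALSE ... FALSE as beta grows
  expect_true(all(diff(as.integer(states)) <= 0))
})

test_that("reliable and fallback branches coincide when K1 equals K2", {
  Fp <- mdmil:::with_seed(23L, matrix(rnorm(8 * 5), 8, 5))
  P <- mdmil:::with_seed(24L, {
    x <- matrix(rexp(16), 8, 2); x / rowSums(x)
  })
  # r1 = r2 = 0.25 -> K1 = K2 = 2; gate on (beta = -1 forces reliable)
  on_cfg <- mdmil_config(d = 5, n_classes = 2, d_prime = 5, heads = 1,
                         r1 = 0.25, r2 = 0.25, beta = -1)
  off_cfg <- mdmil_config(d = 5, n_classes = 2, d_prime = 5, heads = 1,
                          r1 = 0.25, r2 = 0.25, beta = 1)
  q_on <- generate_internal_queries(Fp, P, on_cfg)
  q_off <- generate_internal_queries(Fp, P, off_cfg)
  expect_false(is.null(q_on$reliable_class))
  expect_null(q_off$reliable_class)
  expect_equal(q_on$queries, q_off$queries, tolerance = 1e-12)
})
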