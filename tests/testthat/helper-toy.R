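# Small builders shared across tests. Everything is generated in code; no
# stored fixtures.

toy_bag <- function(n = 6L, d = 8L, label = 0L, seed = 1L, id = "toy") {
  feats <- mdmil:::with_seed(seed, matrix(rnorm(n * d), n, d))
  instance_bag(feats, label, id)
}

toy_model <- function(d = 8L, n_classes = 2L, d_prime = 8L, heads = 2L,
                      r1 = 0.5, r2 = 0.25, seed = 1L, randomize_heads = FALSE,
                      ...) {
  cfg <- mdmil_config(d = d, n_classes = n_classes, d_prime = d_prime,
                      heads = heads, r1 = r1, r2 = r2, ...)
  m <- mdmil_model(cfg, seed = seed)
  if (randomize_heads) {
    m$params$cls1_W <- mdmil:::with_seed(seed + 1L,
      matrix(rnorm(d * n_classes, sd = 0.5), d, n_classes))
    m$params$cls1_b <- mdmil:::with_seed(seed + 2L, rnorm(n_classes, sd = 0.1))
    m$params$cls2_W <- mdmil:::with_seed(seed + 3L,
      matrix(rnorm(d_prime * n_classes, sd = 0.5), d_prime, n_classes))
  }
  m
}

orthonormal_bank <- function(n_classes, d_prime, tau = 0.07, momentum = 0.999) {
  memory_bank(diag(d_prime)[seq_len(n_classes), , drop = FALSE],
              momentum = momentum, tau = tau)
}

random_unit_bank <- function(n_classes, d_prime, seed = 1L, tau = 0.5,
                             momentum = 0.9) {
  centers <- mdmil:::with_seed(seed, {
    t(apply(matrix(rnorm(n_classes * d_prime), n_classes, d_prime), 1L,
            function(x) x / sqrt(sum(x^2))))
  })
  memory_bank(centers, momentum = momentum, tau = tau)
}

# Independent brute-force re-implementation of the internal query module:
# literal full sorts, explicit loops, its own mean/std arithmetic. Kept
# deliberately separate from the package's vectorized path.
iqgm_oracle <- function(f_proj, P, r1, r2, beta) {
  n <- nrow(P); N <- ncol(P)
  K1 <- max(1, floor(r1 * n)); K2 <- max(1, floor(r2 * n))
  cf <- numeric(N)
  ranked <- vector("list", N)
  for (j in 1:N) {
    ord <- order(-P[, j], seq_len(n))   # descending prob, ties by index
    ranked[[j]] <- ord
    top <- P[ord[1:K1], j]
    mbar <- sum(top) / K1
    sigma <- sqrt(sum((top - mbar)^2) / K1)
    cf[j] <- mbar - sigma
  }
  jmax <- which(cf == max(cf))
  reliable <- FALSE
  if (length(jmax) == 1L) {
    ok <- TRUE
    for (j in setdiff(1:N, jmax)) if (!(cf[jmax] - beta > cf[j])) ok <- FALSE
    reliable <- ok
  }
  queries <- matrix(0, N, ncol(f_proj))
  for (j in 1:N) {
    k <- if (reliable && j == jmax[1]) K1 else K2
    rows <- ranked[[j]][1:k]
    for (c in seq_len(ncol(f_proj))) queries[j, c] <- sum(f_proj[rows, c]) / k
  }
  list(queries = queries, conf = cf,
       reliable_class = if (reliable) jmax[1] - 1L else NULL)
}

# Tiny RGB raster with selected saturated (colored) tiles; everything else
# neutral gray. Values in [0, 1].
toy_slide <- function(n_tile_rows = 2L, n_tile_cols = 2L, tile = 8L,
                      colored = list()) {
  h <- n_tile_rows * tile; w <- n_tile_cols * tile
  img <- array(0.5, c(h, w, 3))
  for (rc in colored) {
    ri <- (rc[1] * tile + 1):((rc[1] + 1) * tile)
    ci <- (rc[2] * tile + 1):((rc[2] + 1) * tile)
    img[ri, ci, 1] <- 0.9; img[ri, ci, 2] <- 0.2; img[ri, ci, 3] <- 0.3
  }
  img
}
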