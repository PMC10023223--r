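#' Specification of the synthetic heterogeneous-bag generator
#'
#' Bags are Gaussian mixtures in feature space: every instance is a cluster
#' mean plus isotropic noise. Each class owns `phenotypes_per_class`
#' phenotype clusters (tumor heterogeneity: several distinct positive
#' patterns under one label) and all classes share `background_clusters`
#' background clusters. A bag of class `k` plants
#' `ceil(prevalence[k] * n)` critical instances drawn uniformly from class
#' `k`'s phenotypes; the rest are background. Cluster means are random
#' directions scaled by `cluster_separation * noise_std`, so separation is
#' expressed in noise units.
#'
#' @param n_classes number of subtypes `N >= 2`.
#' @param d instance feature dimension (default 64 for fast CPU work; the
#'   1024-d regime is a parameter change).
#' @param phenotypes_per_class phenotype clusters per class (`>= 1`).
#' @param background_clusters shared background clusters (`>= 1`).
#' @param prevalence length-`N` fraction of critical instances per bag of
#'   each class, in `[0, 1]`; `0` marks a background-only (negative) class.
#' @param bag_length integer `(min, max)` of the uniform bag-length law.
#' @param class_proportions length-`N` vector summing to 1.
#' @param cluster_separation distance of cluster means from the origin in
#'   units of `noise_std`.
#' @param noise_std isotropic instance noise standard deviation.
#' @param seed integer seed fixing the cluster geometry.
#' @return a `synthetic_spec` list (cluster means are drawn immediately and
#'   stored, so the geometry is part of the spec).
#' @export
synthetic_spec <- function(n_classes = 2L, d = 64L,
                           phenotypes_per_class = 2L,
                           background_clusters = 2L,
                           prevalence = c(0, 0.05),
                           bag_length = c(80L, 120L),
                           class_proportions = rep(1 / n_classes, n_classes),
                           cluster_separation = 6,
                           noise_std = 1,
                           seed = 1L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L, d >= 2L, phenotypes_per_class >= 1L,
            background_clusters >= 1L,
            length(prevalence) == n_classes,
            all(prevalence >= 0), all(prevalence <= 1),
            length(bag_length) == 2L, bag_length[1] >= 1L,
            bag_length[2] >= bag_length[1],
            length(class_proportions) == n_classes,
            abs(sum(class_proportions) - 1) < 1e-9,
            cluster_separation >= 0, noise_std > 0)
  radius <- cluster_separation * noise_std
  means <- with_seed(seed + 1000L, {
    unit <- function() {
      v <- rnorm(d)
      v / sqrt(sum(v^2))
    }
    list(
      background = lapply(seq_len(background_clusters),
                          function(i) radius * unit()),
      phenotype = lapply(seq_len(n_classes), function(k) {
        lapply(seq_len(phenotypes_per_class), function(j) radius * unit())
      })
    )
  })
  structure(
    list(n_classes = n_classes, d = as.integer(d),
         phenotypes_per_class = as.integer(phenotypes_per_class),
         background_clusters = as.integer(background_clusters),
         prevalence = prevalence, bag_length = as.integer(bag_length),
         class_proportions = class_proportions,
         cluster_separation = cluster_separation, noise_std = noise_std,
         seed = as.integer(seed), means = means),
    class = "synthetic_spec"
  )
}

#' Draw one synthetic bag
#'
#' Uses the current RNG state (call `set.seed()` or let
#' [generate_dataset()] manage it). Critical instances are listed first in
#' the feature matrix; `instance_labels` records `0` for background and the
#' global phenotype id `(k * phenotypes_per_class + j + 1)` otherwise.
#'
#' @param spec a [synthetic_spec()].
#' @param class_k 0-based class of the bag.
#' @param bag_id bag identifier.
#' @return an [instance_bag()] with `instance_labels` ground truth.
#' @export
generate_bag <- function(spec, class_k, bag_id = "bag") {
  stopifnot(inherits(spec, "synthetic_spec"),
            class_k >= 0L, class_k < spec$n_classes)
  n <- spec$bag_length[1] +
    sample.int(spec$bag_length[2] - spec$bag_length[1] + 1L, 1L) - 1L
  prev <- spec$prevalence[class_k + 1L]
  n_crit <- if (prev > 0) as.integer(ceiling(prev * n)) else 0L
  feats <- matrix(0, n, spec$d)
  ilab <- integer(n)
  if (n_crit > 0L) {
    ph <- sample.int(spec$phenotypes_per_class, n_crit, replace = TRUE)
    for (i in seq_len(n_crit)) {
      mu <- spec$means$phenotype[[class_k + 1L]][[ph[i]]]
      feats[i, ] <- mu + rnorm(spec$d, sd = spec$noise_std)
      ilab[i] <- class_k * spec$phenotypes_per_class + ph[i]
    }
  }
  if (n_crit < n) {
    bg <- sample.int(spec$background_clusters, n - n_crit, replace = TRUE)
    for (i in seq_len(n - n_crit)) {
      mu <- spec$means$background[[bg[i]]]
      feats[n_crit + i, ] <- mu + rnorm(spec$d, sd = spec$noise_std)
    }
  }
  instance_bag(feats, class_k, bag_id, instance_labels = ilab)
}

#' Generate a full synthetic dataset
#'
#' Class counts follow `class_proportions` (largest-remainder rounding),
#' bags are drawn deterministically from `seed`, and the dataset is
#' stratified-split 60/15/25 (or as requested).
#'
#' @param spec a [synthetic_spec()].
#' @param n_bags total number of bags.
#' @param seed integer seed for bag sampling and splitting (defaults to
#'   `spec$seed`).
#' @param ratios split proportions passed to [split_dataset()].
#' @return a [bag_dataset()] with splits assigned and ground-truth
#'   `instance_labels` on every bag.
#' @export
generate_dataset <- function(spec, n_bags = 100L, seed = NULL,
                             ratios = c(0.6, 0.15, 0.25)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- as.integer(seed %||% spec$seed)
  exact <- spec$class_proportions * n_bags
  counts <- floor(exact)
  rem <- n_bags - sum(counts)
  if (rem > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  labels <- rep(seq_len(spec$n_classes) - 1L, times = counts)
  bags <- with_seed(seed, {
    lapply(seq_along(labels), function(i) {
      generate_bag(spec, labels[i], sprintf("bag_%04d", i))
    })
  })
  ds <- bag_dataset(bags, n_classes = spec$n_classes)
  split_dataset(ds, ratios = ratios, seed = seed)
}

#' Low-prevalence detection-style preset
#'
#' Two classes: negatives are background-only, positives plant ~5% critical
#' instances (metastasis-detection regime, where tumor occupies a small
#' fraction of the tissue). Class imbalance echoes a 159:111
#' normal-to-tumor ratio.
#'
#' @param seed integer seed.
#' @param n_bags total bags (default 330).
#' @param ratios split proportions.
#' @return a [bag_dataset()].
#' @export
camelyon_like <- function(seed = 1L, n_bags = 330L,
                          ratios = c(200, 50, 80) / 330) {
  spec <- synthetic_spec(
    n_classes = 2L, d = 64L, phenotypes_per_class = 2L,
    background_clusters = 2L, prevalence = c(0, 0.05),
    bag_length = c(80L, 120L),
    class_proportions = c(159, 111) / 270,
    cluster_separation = 6, noise_std = 1, seed = seed
  )
  generate_dataset(spec, n_bags = n_bags, seed = seed, ratios = ratios)
}

#' High-prevalence subtyping-style preset
#'
#' Three imbalanced classes (111:489:284-style), each planting ~80%
#' critical instances from three phenotype clusters (subtyping regime,
#' where tumor covers most of the slide and heterogeneity dominates).
#'
#' @param seed integer seed.
#' @param n_bags total bags (default 330).
#' @param ratios split proportions.
#' @return a [bag_dataset()].
#' @export
tcga_like <- function(seed = 1L, n_bags = 330L,
                      ratios = c(200, 50, 80) / 330) {
  spec <- synthetic_spec(
    n_classes = 3L, d = 64L, phenotypes_per_class = 3L,
    background_clusters = 2L, prevalence = c(0.8, 0.8, 0.8),
    bag_length = c(80L, 120L),
    class_proportions = c(111, 489, 284) / 884,
    cluster_separation = 6, noise_std = 1, seed = seed
  )
  generate_dataset(spec, n_bags = n_bags, seed = seed, ratios = ratios)
}
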