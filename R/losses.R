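#' Create a memory bank
#'
#' @param centers `N x d_prime` matrix of class centers (unit L2 rows).
#' @param momentum momentum coefficient `m` in `[0, 1]`.
#' @param tau contrastive temperature, `> 0`.
#' @return a `memory_bank` list.
#' @export
memory_bank <- function(centers, momentum = 0.999, tau = 0.07) {
  if (tau <= 0) stop("validation error: tau must be > 0", call. = FALSE)
  stopifnot(momentum >= 0, momentum <= 1)
  centers <- as.matrix(centers)
  structure(list(centers = centers, momentum = momentum, tau = tau),
            class = "memory_bank")
}

# The per-subtype feature the contrastive machinery anchors on: the row of
# the MDM output indexed by the bag's true label, L2-normalized.
labeled_subtype_representation <- function(fwd, label) {
  l2_normalize(fwd$f_subtypes[label + 1L, ], "labeled subtype representation")
}

#' Initialize memory centers from the training set
#'
#' Runs the forward pass over every training bag, collects each bag's
#' labeled subtype representation, averages them per class and L2-normalizes
#' the per-class means. Deterministic given the model state.
#'
#' @param model a [mdmil_model()].
#' @param train_bags list of [instance_bag()] (the training split).
#' @param momentum,tau memory hyperparameters (default from the model
#'   config).
#' @return a `memory_bank` with one unit-norm center per class.
#' @export
init_memory <- function(model, train_bags, momentum = NULL, tau = NULL) {
  cfg <- model$config
  momentum <- momentum %||% cfg$momentum
  tau <- tau %||% cfg$tau
  N <- cfg$n_classes
  sums <- matrix(0, N, cfg$d_prime)
  counts <- integer(N)
  for (b in train_bags) {
    fwd <- forward_bag(model, b)
    k <- b$label + 1L
    sums[k, ] <- sums[k, ] + fwd$f_subtypes[k, ]
    counts[k] <- counts[k] + 1L
  }
  if (any(counts == 0L)) {
    stop("validation error: class(es) ",
         paste(which(counts == 0L) - 1L, collapse = ", "),
         " have no training bags", call. = FALSE)
  }
  centers <- sums / counts
  centers <- t(apply(centers, 1L, l2_normalize, what = "memory center"))
  memory_bank(centers, momentum = momentum, tau = tau)
}

#' Momentum update of one memory center
#'
#' `c_k <- m * c_k + (1 - m) * f`, followed by re-normalization to unit L2
#' so the inner-product scale of the contrastive logits stays fixed across
#' training. Other centers are untouched.
#'
#' @param bank a `memory_bank`.
#' @param k 0-based class index.
#' @param f `d_prime`-vector (will be L2-normalized before blending).
#' @return the updated bank.
#' @export
update_memory <- function(bank, k, f) {
  stopifnot(inherits(bank, "memory_bank"))
  assert_finite(f, "representation f")
  if (k < 0L || k >= nrow(bank$centers)) {
    stop("validation error: class index out of range", call. = FALSE)
  }
  fn <- l2_normalize(f, "representation f")
  m <- bank$momentum
  mixed <- m * bank$centers[k + 1L, ] + (1 - m) * fn
  bank$centers[k + 1L, ] <- l2_normalize(mixed, "updated memory center")
  bank
}

#' Memory-based contrastive loss
#'
#' Cross-entropy of the softmax over temperature-scaled inner products
#' between the (L2-normalized) labeled subtype representation and every
#' class center, with the true class as target: the representation is pulled
#' toward its own class center and pushed from the others.
#'
#' @param f `d_prime`-vector (normalized internally).
#' @param bank a `memory_bank`.
#' @param label 0-based true class.
#' @return non-negative scalar loss.
#' @export
contrastive_loss <- function(f, bank, label) {
  stopifnot(inherits(bank, "memory_bank"))
  if (bank$tau <= 0) stop("validation error: tau must be > 0", call. = FALSE)
  fn <- l2_normalize(f, "representation f")
  logits <- as.numeric(bank$centers %*% fn) / bank$tau
  logz <- max(logits) + log(sum(exp(logits - max(logits))))
  -(logits[label + 1L] - logz)
}

#' Instance-level cross-entropy via max-pooling
#'
#' Pools the instance probability matrix over instances — by default a
#' per-class maximum, renormalized to a distribution — and takes the
#' negative log of the true class's pooled mass. The `"global_max"` mode
#' instead scores the single instance holding the overall maximum
#' probability.
#'
#' @param P1 `n x N` instance probability matrix (rows sum to 1).
#' @param label 0-based true class.
#' @param pooling `"per_class_max"` or `"global_max"`.
#' @return scalar loss.
#' @export
instance_ce <- function(P1, label, pooling = c("per_class_max", "global_max")) {
  pooling <- match.arg(pooling)
  P1 <- as.matrix(P1)
  if (pooling == "per_class_max") {
    s <- apply(P1, 2L, max)
    q <- s / sum(s)
  } else {
    i <- which(P1 == max(P1), arr.ind = TRUE)[1L, 1L]
    q <- P1[i, ]
  }
  -log(q[label + 1L])
}

#' Bag-level cross-entropy
#'
#' @param P2 length-`N` bag probability vector (sums to 1).
#' @param label 0-based true class.
#' @return `-log P2[label]`.
#' @export
bag_ce <- function(P2, label) {
  -log(P2[label + 1L])
}

#' Composite training objective
#'
#' Instance cross-entropy + bag cross-entropy + `alpha_loss` times the
#' memory-based contrastive loss.
#'
#' @param P1 `n x N` instance probabilities.
#' @param P2 length-`N` bag probabilities.
#' @param f labeled subtype representation (`d_prime`-vector).
#' @param bank a `memory_bank`.
#' @param label 0-based true class.
#' @param config a [mdmil_config()] (uses `alpha_loss`, `instance_pooling`).
#' @return scalar loss.
#' @export
total_loss <- function(P1, P2, f, bank, label, config) {
  instance_ce(P1, label, config$instance_pooling) +
    bag_ce(P2, label) +
    config$alpha_loss * contrastive_loss(f, bank, label)
}
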