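#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param lr Adam learning rate (cosine-decayed over epochs).
#' @param weight_decay decoupled weight decay.
#' @param seed integer seed controlling shuffling.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 30L, lr = 2e-4, weight_decay = 1e-5,
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1L, lr > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

.adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(params = params, state = state)
}

#' Train a model on a split dataset
#'
#' One bag per optimization step (bags have variable length). The memory
#' bank is initialized from the training split before the first epoch and
#' momentum-updated after every optimizer step with the current bag's
#' labeled subtype representation. After each epoch the model is scored on
#' the validation split; the checkpoint with the best validation AUC (ties:
#' higher accuracy, then earlier epoch) is returned. Fully reproducible
#' given the seeds.
#'
#' @param model a freshly initialized [mdmil_model()].
#' @param dataset a [bag_dataset()] with train and val splits assigned.
#' @param config a [train_config()].
#' @return list: `model` (best checkpoint, including its memory bank),
#'   `history` (per-epoch data.frame), `best_epoch`.
#' @export
train_mdmil <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "mdmil_model"), inherits(dataset, "bag_dataset"))
  train_bags <- dataset_split(dataset, "train")
  val_bags <- dataset_split(dataset, "val")
  if (length(train_bags) == 0L) stop("empty training split", call. = FALSE)
  bank <- init_memory(model, train_bags)
  opt <- .adam_init(model$params)
  n_epochs <- config$epochs
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0), val_accuracy = numeric(0))
  best <- list(auc = -Inf, acc = -Inf, epoch = NA_integer_,
               params = model$params, memory = bank)
  for (epoch in seq_len(n_epochs)) {
    lr_t <- config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / n_epochs))
    ord <- with_seed((config$seed %% 100000L) * 10000L + epoch,
                     sample(length(train_bags)))
    epoch_loss <- 0
    for (i in ord) {
      bg <- train_bags[[i]]
      gl <- bag_loss_grad(model, bg, bank)
      if (!is.finite(gl$loss)) {
        stop("divergence: non-finite loss at epoch ", epoch,
             ", bag '", bg$bag_id, "'", call. = FALSE)
      }
      upd <- .adam_step(model$params, gl$grads, opt, lr_t, config$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      bank <- update_memory(bank, bg$label,
                            gl$fwd$f_subtypes[bg$label + 1L, ])
      epoch_loss <- epoch_loss + gl$loss
    }
    ev <- evaluate_mdmil(model, val_bags, dataset$n_classes)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / length(train_bags),
      val_auc = ev$auc, val_accuracy = ev$accuracy))
    if (config$verbose) {
      message(sprintf("epoch %2d  loss %.4f  val auc %.4f  val acc %.4f",
                      epoch, epoch_loss / length(train_bags), ev$auc,
                      ev$accuracy))
    }
    if (ev$auc > best$auc ||
        (ev$auc == best$auc && ev$accuracy > best$acc)) {
      best <- list(auc = ev$auc, acc = ev$accuracy, epoch = epoch,
                   params = model$params, memory = bank)
    }
  }
  model$params <- best$params
  model$memory <- best$memory
  list(model = model, history = history, best_epoch = best$epoch)
}

# Binary or macro one-vs-rest AUROC from a score matrix.
.auroc <- function(scores, labels, n_classes) {
  if (length(unique(labels)) < 2L) {
    stop("AUC undefined: evaluation set contains a single class", call. = FALSE)
  }
  roc_auc <- function(resp, pred) {
    r <- pROC::roc(response = resp, predictor = pred,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  }
  if (n_classes == 2L) {
    roc_auc(labels == 1L, scores[, 2L])
  } else {
    present <- sort(unique(labels))
    mean(vapply(present, function(k) roc_auc(labels == k, scores[, k + 1L]),
                numeric(1)))
  }
}

#' Evaluate a model on a set of bags
#'
#' @param model a trained [mdmil_model()].
#' @param bags list of labeled [instance_bag()].
#' @param n_classes number of classes.
#' @return an `eval_report` list: `accuracy`, `auc` (binary AUROC for two
#'   classes, macro one-vs-rest otherwise), `per_class` (precision, recall,
#'   support), `confusion` (`N x N` counts, rows = truth), `scores`
#'   (bag-probability matrix), `labels`.
#' @export
evaluate_mdmil <- function(model, bags, n_classes = model$config$n_classes) {
  stopifnot(length(bags) >= 1L)
  scores <- matrix(0, length(bags), n_classes)
  labels <- integer(length(bags))
  for (i in seq_along(bags)) {
    fwd <- forward_bag(model, bags[[i]])
    scores[i, ] <- fwd$P2
    labels[i] <- bags[[i]]$label
  }
  pred <- max.col(scores, ties.method = "first") - 1L
  confusion <- table(factor(labels, levels = 0:(n_classes - 1L)),
                     factor(pred, levels = 0:(n_classes - 1L)))
  confusion <- unclass(confusion)
  per_class <- data.frame(
    class = 0:(n_classes - 1L),
    precision = vapply(1:n_classes, function(k) {
      denom <- sum(confusion[, k])
      if (denom == 0) NA_real_ else confusion[k, k] / denom
    }, numeric(1)),
    recall = vapply(1:n_classes, function(k) {
      denom <- sum(confusion[k, ])
      if (denom == 0) NA_real_ else confusion[k, k] / denom
    }, numeric(1)),
    support = as.integer(rowSums(confusion))
  )
  structure(
    list(accuracy = mean(pred == labels),
         auc = .auroc(scores, labels, n_classes),
         per_class = per_class, confusion = confusion,
         scores = scores, labels = labels),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.4f, AUC %.4f, %d bags>\n",
              x$accuracy, x$auc, length(x$labels)))
  invisible(x)
}

#' Export per-instance attention weights
#'
#' Writes (or returns) the head-averaged mixed cross-attention of one bag:
#' one row per (instance, subtype) with columns `bag_id`, `instance_index`,
#' `row`, `col`, `subtype`, `attention_weight`. Weights of each subtype sum
#' to 1 over the instances. Grid coordinates come from the bag's `coords`
#' when present, else the instance index stands in for `row`.
#'
#' @param model a trained [mdmil_model()].
#' @param bag an [instance_bag()].
#' @param path optional TSV output path.
#' @return the attention table (a data.frame), invisibly when `path` is
#'   given.
#' @export
export_attention <- function(model, bag, path = NULL) {
  fwd <- forward_bag(model, bag)
  n <- nrow(bag$features); N <- model$config$n_classes
  if (!is.null(bag$coords)) {
    rows <- bag$coords[, 1]; cols <- bag$coords[, 2]
  } else {
    rows <- seq_len(n) - 1L; cols <- rep(0L, n)
  }
  out <- data.frame(
    bag_id = bag$bag_id,
    instance_index = rep(seq_len(n) - 1L, times = N),
    row = rep(rows, times = N),
    col = rep(cols, times = N),
    subtype = rep(0:(N - 1L), each = n),
    attention_weight = as.numeric(t(fwd$attn))
  )
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t")
    return(invisible(out))
  }
  out
}

#' Attention mass on planted critical instances, relative to uniform
#'
#' For a synthetic bag with ground-truth `instance_labels`, computes the
#' mean attention the true subtype's query assigns to the planted critical
#' instances divided by the uniform baseline `1/n`. Values well above 1 mean
#' the model localizes the instances that trigger the label.
#'
#' @param model a trained [mdmil_model()].
#' @param bag an [instance_bag()] with `instance_labels`.
#' @return scalar ratio.
#' @export
attention_on_critical <- function(model, bag) {
  if (is.null(bag$instance_labels)) {
    stop("bag has no ground-truth instance labels", call. = FALSE)
  }
  crit <- which(bag$instance_labels > 0L)
  if (length(crit) == 0L) {
    stop("bag has no critical instances", call. = FALSE)
  }
  fwd <- forward_bag(model, bag)
  n <- nrow(bag$features)
  mean(fwd$attn[bag$label + 1L, crit]) * n
}
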