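#' Instance-feature bag for one slide
#'
#' A bag holds the per-patch feature matrix of one whole slide image together
#' with its slide-level label. Optional per-instance metadata (patch grid
#' coordinates, synthetic ground-truth instance labels) travels with the bag.
#'
#' @param features numeric matrix, one row per instance (patch), one column
#'   per feature dimension. All entries must be finite.
#' @param label integer subtype label in `[0, n_classes)`.
#' @param bag_id character scalar identifying the slide.
#' @param coords optional integer matrix `n x 2` of patch grid coordinates
#'   (row, col).
#' @param instance_labels optional integer vector of length `n`;
#'   `0` = background, `k > 0` = planted phenotype id (synthetic ground truth
#'   only).
#' @return an object of class `instance_bag`.
#' @export
instance_bag <- function(features, label, bag_id,
                         coords = NULL, instance_labels = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  dimnames(features) <- NULL
  n <- nrow(features)
  if (n < 1L) stop("bag '", bag_id, "': needs at least one instance", call. = FALSE)
  if (!all(is.finite(features))) {
    stop("bag '", bag_id, "': non-finite feature values", call. = FALSE)
  }
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 0L) {
    stop("bag '", bag_id, "': label must be a single non-negative integer",
         call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "integer"
    dimnames(coords) <- NULL
    if (nrow(coords) != n || ncol(coords) != 2L) {
      stop("bag '", bag_id, "': coords must be n x 2", call. = FALSE)
    }
  }
  if (!is.null(instance_labels)) {
    instance_labels <- as.integer(instance_labels)
    if (length(instance_labels) != n) {
      stop("bag '", bag_id, "': instance_labels must have length n", call. = FALSE)
    }
  }
  structure(
    list(features = features, label = label, bag_id = as.character(bag_id),
         coords = coords, instance_labels = instance_labels),
    class = "instance_bag"
  )
}

#' @export
print.instance_bag <- function(x, ...) {
  cat(sprintf("<instance_bag '%s': %d instances x %d features, label %d>\n",
              x$bag_id, nrow(x$features), ncol(x$features), x$label))
  invisible(x)
}

#' Collection of bags with labels and split assignments
#'
#' @param bags list of [instance_bag()] objects with a common feature
#'   dimension.
#' @param n_classes integer number of subtypes `N >= 2`; defaults to
#'   `max(label) + 1`.
#' @param split_assignments optional named character vector mapping `bag_id`
#'   to `"train"`, `"val"` or `"test"`.
#' @return an object of class `bag_dataset`.
#' @export
bag_dataset <- function(bags, n_classes = NULL, split_assignments = NULL) {
  if (length(bags) < 1L) stop("dataset needs at least one bag", call. = FALSE)
  ids <- vapply(bags, function(b) b$bag_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate bag_id in dataset", call. = FALSE)
  d <- vapply(bags, function(b) ncol(b$features), integer(1))
  if (length(unique(d)) != 1L) {
    stop("feature dimension differs across bags: ",
         paste(unique(d), collapse = ", "), call. = FALSE)
  }
  labels <- vapply(bags, function(b) b$label, integer(1))
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  bad <- labels >= n_classes
  if (any(bad)) {
    stop("label >= n_classes for bag(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(split_assignments)) {
    split_assignments <- split_assignments[ids]
    ok <- split_assignments %in% c("train", "val", "test")
    if (any(!ok | is.na(split_assignments))) {
      stop("split_assignments must cover every bag with train/val/test",
           call. = FALSE)
    }
    names(split_assignments) <- ids
  }
  names(bags) <- ids
  structure(
    list(bags = bags, n_classes = n_classes,
         split_assignments = split_assignments),
    class = "bag_dataset"
  )
}

#' @export
print.bag_dataset <- function(x, ...) {
  d <- ncol(x$bags[[1]]$features)
  cat(sprintf("<bag_dataset: %d bags, d = %d, %d classes>\n",
              length(x$bags), d, x$n_classes))
  if (!is.null(x$split_assignments)) {
    print(table(split = x$split_assignments))
  }
  invisible(x)
}

#' @export
length.bag_dataset <- function(x) length(x$bags)

#' Subset a dataset to one split
#'
#' @param dataset a [bag_dataset()].
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return a list of `instance_bag` objects.
#' @export
dataset_split <- function(dataset, split = c("train", "val", "test")) {
  split <- match.arg(split)
  if (is.null(dataset$split_assignments)) {
    stop("dataset has no split assignments; call split_dataset() first",
         call. = FALSE)
  }
  dataset$bags[names(dataset$split_assignments)[dataset$split_assignments == split]]
}

# %.17g round-trips IEEE doubles exactly through text.
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a dataset to a delimited-text container
#'
#' Lays out one CSV feature matrix per bag plus a `labels.csv` manifest
#' (`bag_id,label,split`) and a `dataset.yaml` with the class count. Optional
#' coords / instance labels are written as side files only when present.
#' Features are serialized with 17 significant digits so that reading the
#' container back reproduces them bit-exactly.
#'
#' @param dataset a [bag_dataset()].
#' @param path directory to create (or overwrite files in).
#' @return `path`, invisibly.
#' @seealso [read_bag_container()]
#' @export
write_bag_container <- function(dataset, path) {
  stopifnot(inherits(dataset, "bag_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create container directory: ", path, call. = FALSE)
  for (b in dataset$bags) {
    fm <- apply(b$features, c(1L, 2L), .fmt_num)
    if (nrow(b$features) == 1L) fm <- matrix(fm, nrow = 1L)
    dt <- data.table::as.data.table(fm)
    data.table::setnames(dt, paste0("f", seq_len(ncol(b$features))))
    data.table::fwrite(dt, file.path(path, paste0(b$bag_id, ".csv")), quote = FALSE)
    if (!is.null(b$coords)) {
      data.table::fwrite(
        data.table::data.table(row = b$coords[, 1], col = b$coords[, 2]),
        file.path(path, paste0(b$bag_id, ".coords.csv"))
      )
    }
    if (!is.null(b$instance_labels)) {
      data.table::fwrite(
        data.table::data.table(instance_label = b$instance_labels),
        file.path(path, paste0(b$bag_id, ".instance_labels.csv"))
      )
    }
  }
  ids <- names(dataset$bags)
  splits <- if (is.null(dataset$split_assignments)) rep(NA_character_, length(ids))
            else unname(dataset$split_assignments[ids])
  manifest <- data.table::data.table(
    bag_id = ids,
    label = vapply(dataset$bags, function(b) b$label, integer(1)),
    split = splits
  )
  data.table::fwrite(manifest, file.path(path, "labels.csv"))
  yaml::write_yaml(list(n_classes = dataset$n_classes,
                        d = ncol(dataset$bags[[1]]$features)),
                   file.path(path, "dataset.yaml"))
  invisible(path)
}

#' Read a delimited-text bag container
#'
#' Inverse of [write_bag_container()]: `read_bag_container(write_bag_container(x))`
#' reproduces `x` with bit-exact features. Validates that the feature
#' dimension is shared across bags, that all features are finite, and that
#' every label is below the class count.
#'
#' @param path container directory.
#' @return a [bag_dataset()].
#' @export
read_bag_container <- function(path) {
  manifest_file <- file.path(path, "labels.csv")
  if (!file.exists(manifest_file)) {
    stop("not a bag container (missing labels.csv): ", path, call. = FALSE)
  }
  manifest <- data.table::fread(manifest_file, colClasses = list(character = "bag_id"))
  meta <- yaml::read_yaml(file.path(path, "dataset.yaml"))
  n_classes <- as.integer(meta$n_classes)
  bags <- vector("list", nrow(manifest))
  d_seen <- NA_integer_
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$bag_id[i]
    feat <- as.matrix(data.table::fread(file.path(path, paste0(id, ".csv"))))
    if (!all(is.finite(feat))) {
      stop("validation error: non-finite features in bag '", id, "'", call. = FALSE)
    }
    if (is.na(d_seen)) d_seen <- ncol(feat)
    if (ncol(feat) != d_seen) {
      stop("format error: bag '", id, "' has d = ", ncol(feat),
           " but container d = ", d_seen, call. = FALSE)
    }
    if (manifest$label[i] >= n_classes) {
      stop("validation error: bag '", id, "' label ", manifest$label[i],
           " >= n_classes ", n_classes, call. = FALSE)
    }
    coords_file <- file.path(path, paste0(id, ".coords.csv"))
    coords <- if (file.exists(coords_file)) {
      as.matrix(data.table::fread(coords_file))
    } else NULL
    il_file <- file.path(path, paste0(id, ".instance_labels.csv"))
    il <- if (file.exists(il_file)) {
      data.table::fread(il_file)$instance_label
    } else NULL
    bags[[i]] <- instance_bag(feat, manifest$label[i], id,
                              coords = coords, instance_labels = il)
  }
  splits <- NULL
  if (!all(is.na(manifest$split)) && !all(manifest$split == "")) {
    splits <- stats::setNames(as.character(manifest$split), manifest$bag_id)
  }
  bag_dataset(bags, n_classes = n_classes, split_assignments = splits)
}

#' Stratified random train/val/test split at the slide level
#'
#' Assigns bags to splits class by class so that every class's split counts
#' track the requested proportions to within one bag (largest-remainder
#' rounding). Deterministic for a given `(dataset, ratios, seed)`.
#'
#' @param dataset a [bag_dataset()].
#' @param ratios length-3 numeric `(train, val, test)`, non-negative, summing
#'   to 1.
#' @param seed integer seed controlling the permutation.
#' @return the dataset with `split_assignments` filled in.
#' @export
split_dataset <- function(dataset, ratios = c(0.6, 0.15, 0.25), seed = 1L) {
  stopifnot(inherits(dataset, "bag_dataset"))
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three non-negative numbers summing to 1", call. = FALSE)
  }
  labels <- vapply(dataset$bags, function(b) b$label, integer(1))
  ids <- names(dataset$bags)
  assignment <- character(0)
  alloc <- c(0, 0, 0)
  with_seed(seed, {
    for (k in sort(unique(labels))) {
      k_ids <- ids[labels == k]
      nk <- length(k_ids)
      # largest-remainder apportionment of nk bags over the three splits;
      # remainder ties go to the split furthest below its global share so
      # that the overall totals also track the ratios
      exact <- ratios * nk
      base <- floor(exact)
      rem <- nk - sum(base)
      if (rem > 0) {
        deficit <- ratios * (sum(alloc) + nk) - (alloc + base)
        order_rem <- order(-(exact - base), -deficit, seq_along(ratios))
        base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
      }
      alloc <- alloc + base
      n_nonzero <- sum(ratios > 0)
      if (sum(base[ratios > 0] > 0) < n_nonzero) {
        stop("validation error: class ", k, " has too few bags (", nk,
             ") for the requested splits", call. = FALSE)
      }
      perm <- sample(k_ids)
      assignment[perm] <- rep(c("train", "val", "test"), times = base)
    }
  })
  dataset$split_assignments <- assignment[ids]
  names(dataset$split_assignments) <- ids
  dataset
}
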