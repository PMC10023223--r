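#' Non-overlapping tile grid over a slide raster
#'
#' Covers the image with `tile_size x tile_size` non-overlapping tiles
#' anchored at the top-left corner; right/bottom remainders smaller than one
#' tile are discarded. Coordinates are 0-based pixel offsets of each tile's
#' top-left corner, enumerated in row-major order.
#'
#' @param image numeric array `H x W x 3` (RGB, values in `[0, 1]` or
#'   `[0, 255]`) or `H x W` matrix (grayscale).
#' @param tile_size integer tile side in pixels.
#' @return a `tile_grid` list: `tile_size`, integer `coords` matrix
#'   (`n_tiles x 2`, columns `row`/`col` pixel offsets), logical `kept_mask`
#'   (all `TRUE` until filtered).
#' @export
tile_image <- function(image, tile_size = 256L) {
  dims <- dim(image)
  if (is.null(dims) || length(dims) < 2L) stop("image must be a 2-D or 3-D array", call. = FALSE)
  h <- dims[1]; w <- dims[2]
  tile_size <- as.integer(tile_size)
  if (h < tile_size || w < tile_size) {
    stop("validation error: image (", h, "x", w,
         ") smaller than one tile of size ", tile_size, call. = FALSE)
  }
  nr <- h %/% tile_size
  nc <- w %/% tile_size
  grid <- expand.grid(col = (seq_len(nc) - 1L) * tile_size,
                      row = (seq_len(nr) - 1L) * tile_size)
  coords <- cbind(row = as.integer(grid$row), col = as.integer(grid$col))
  structure(
    list(tile_size = tile_size, coords = coords,
         kept_mask = rep(TRUE, nrow(coords))),
    class = "tile_grid"
  )
}

# Extract one tile (as an H x W x 3 array) given its top-left offset.
.crop_tile <- function(image, row0, col0, tile_size) {
  ri <- (row0 + 1L):(row0 + tile_size)
  ci <- (col0 + 1L):(col0 + tile_size)
  if (length(dim(image)) == 3L) image[ri, ci, , drop = FALSE]
  else image[ri, ci, drop = FALSE]
}

#' Mean HSV saturation of an RGB tile on the 0-255 scale
#'
#' @param tile numeric array `H x W x 3`; values in `[0, 1]` or `[0, 255]`
#'   (detected from the range).
#' @return mean saturation in `[0, 255]`.
#' @export
tile_saturation <- function(tile) {
  if (length(dim(tile)) != 3L || dim(tile)[3] < 3L) {
    stop("tile must be an RGB array", call. = FALSE)
  }
  r <- tile[, , 1]; g <- tile[, , 2]; b <- tile[, , 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  mean(s) * 255
}

#' Background filter: keep tiles with mean saturation at or above a threshold
#'
#' Background (glass) regions of a slide are nearly gray, so their HSV
#' saturation is low; tissue is stained and saturated. A tile is discarded
#' when its mean saturation is strictly below `threshold` on the 0-255 scale.
#'
#' @param tile RGB array as in [tile_saturation()].
#' @param threshold numeric saturation threshold (default 15).
#' @return logical: `TRUE` to keep the tile.
#' @export
saturation_filter <- function(tile, threshold = 15) {
  tile_saturation(tile) >= threshold
}

#' Deterministic random-projection feature extractor
#'
#' A lightweight stand-in encoder for tests and synthetic pipelines: the tile
#' is average-pooled to `pool x pool` per channel, flattened, and multiplied
#' by a fixed-seed Gaussian projection to `output_dim` dimensions. The same
#' tile always maps to the same vector. Real deployments plug a pretrained
#' CNN behind the same interface.
#'
#' @param output_dim integer feature dimension `d`.
#' @param pool integer pooled side length per channel.
#' @param seed integer seed fixing the projection matrix.
#' @return a `feature_extractor` list with fields `name`, `output_dim`,
#'   `transform(tile) -> numeric(d)`.
#' @export
random_projection_extractor <- function(output_dim = 64L, pool = 8L, seed = 42L) {
  in_dim <- 3L * pool * pool
  proj <- with_seed(seed, matrix(rnorm(in_dim * output_dim), in_dim, output_dim))
  proj <- proj / sqrt(in_dim)
  pool_tile <- function(tile) {
    ts <- dim(tile)[1]
    fac <- ts %/% pool
    out <- numeric(in_dim)
    idx <- 1L
    for (ch in 1:3) {
      m <- tile[seq_len(fac * pool), seq_len(fac * pool), ch]
      pooled <- matrix(0, pool, pool)
      for (i in seq_len(pool)) for (j in seq_len(pool)) {
        pooled[i, j] <- mean(m[((i - 1L) * fac + 1L):(i * fac),
                               ((j - 1L) * fac + 1L):(j * fac)])
      }
      out[idx:(idx + pool * pool - 1L)] <- as.vector(pooled)
      idx <- idx + pool * pool
    }
    out
  }
  structure(
    list(name = "random_projection",
         output_dim = as.integer(output_dim),
         transform = function(tile) as.numeric(pool_tile(tile) %*% proj)),
    class = "feature_extractor"
  )
}

#' Convert a slide raster into an instance bag
#'
#' Tiles the image, drops background tiles by the saturation rule, and
#' encodes each surviving tile with the extractor. Feature rows follow the
#' row-major tile order; `coords` records each kept tile's grid position
#' (0-based row, col).
#'
#' @param image RGB raster array.
#' @param label slide-level label for the produced bag.
#' @param bag_id bag identifier.
#' @param tile_size integer tile side (default 256).
#' @param threshold saturation threshold (default 15).
#' @param extractor a `feature_extractor`; defaults to
#'   [random_projection_extractor()] at the tile's dimension.
#' @return an [instance_bag()] with one row per kept tile.
#' @export
extract_bag <- function(image, label = 0L, bag_id = "slide",
                        tile_size = 256L, threshold = 15,
                        extractor = random_projection_extractor()) {
  grid <- tile_image(image, tile_size)
  keep <- logical(nrow(grid$coords))
  for (i in seq_len(nrow(grid$coords))) {
    tile <- .crop_tile(image, grid$coords[i, 1], grid$coords[i, 2], grid$tile_size)
    keep[i] <- saturation_filter(tile, threshold)
  }
  if (!any(keep)) {
    stop("empty-bag error: no tile passed the saturation filter", call. = FALSE)
  }
  kept_idx <- which(keep)
  feats <- matrix(0, length(kept_idx), extractor$output_dim)
  for (j in seq_along(kept_idx)) {
    i <- kept_idx[j]
    tile <- .crop_tile(image, grid$coords[i, 1], grid$coords[i, 2], grid$tile_size)
    feats[j, ] <- extractor$transform(tile)
  }
  assert_finite(feats, "extracted features")
  coords <- cbind(grid$coords[kept_idx, 1] %/% grid$tile_size,
                  grid$coords[kept_idx, 2] %/% grid$tile_size)
  instance_bag(feats, label, bag_id, coords = coords)
}

#' Read a slide raster from a TIFF file
#'
#' @param path TIFF file path.
#' @return numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}
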