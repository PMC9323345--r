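# Desk-scale pixel classifier: a pluggable stand-in for the out-of-scope
# deep segmentation network. Any object answering predict_labels() with an
# 8-class raster satisfies the contract; the baseline is LDA on local
# window descriptors.

# Per-pixel descriptor maps: window means of R, G, B and gray, windowed
# gray SD, and window means of |horizontal| / |vertical| gray increments
# (the latter capture grain anisotropy). Returns an (H*W) x 7 matrix.
pixel_feature_maps <- function(pixels, window = 9L) {
  stopifnot(length(dim(pixels)) == 3L, window %% 2 == 1, window >= 3)
  half <- (window - 1L) %/% 2L
  gray <- rgb_to_gray_int(pixels)
  g <- gray * 1.0
  W <- ncol(g); H <- nrow(g)
  dx <- abs(g[, c(2:W, W), drop = FALSE] - g)
  dy <- abs(g[c(2:H, H), , drop = FALSE] - g)
  mR <- box_mean(pixels[, , 1] * 1.0, half)
  mG <- box_mean(pixels[, , 2] * 1.0, half)
  mB <- box_mean(pixels[, , 3] * 1.0, half)
  mg <- box_mean(g, half)
  vg <- pmax(box_mean(g^2, half) - mg^2, 0)
  feats <- cbind(meanR = as.vector(mR), meanG = as.vector(mG),
                 meanB = as.vector(mB), meanGray = as.vector(mg),
                 sdGray = as.vector(sqrt(vg)),
                 meanAbsDx = as.vector(box_mean(dx, half)),
                 meanAbsDy = as.vector(box_mean(dy, half)))
  feats
}

#' Fit the baseline LDA pixel classifier
#'
#' Samples up to `samples_per_class` foreground pixels per 8-class label
#' from each training image's local-descriptor maps and fits a linear
#' discriminant. Deterministic for a fixed seed. Errors if any of the
#' eight classes is absent from the pooled training pixels.
#'
#' @param train list of `labeled_image`s.
#' @param window odd descriptor window size in pixels (default 9).
#' @param samples_per_class per-image, per-class pixel sample cap.
#' @param seed integer seed for the pixel sampling.
#' @return a `pixel_classifier`.
#' @export
fit_baseline_classifier <- function(train, window = 9L,
                                    samples_per_class = 400L, seed = 1L) {
  if (!length(train)) stop("no training images")
  xs <- list(); ys <- list()
  with_seed(seed, {
    for (im in train) {
      stopifnot(inherits(im, "labeled_image"))
      lab <- class8_code(im$mask, im$subtype)
      feats <- pixel_feature_maps(im$pixels, window)
      for (k in 1:8) {
        idx <- which(as.vector(lab) == k)
        if (!length(idx)) next
        if (length(idx) > samples_per_class)
          idx <- sample(idx, samples_per_class)
        xs[[length(xs) + 1L]] <- feats[idx, , drop = FALSE]
        ys[[length(ys) + 1L]] <- rep.int(k, length(idx))
      }
    }
  })
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  absent <- setdiff(1:8, unique(y))
  if (length(absent))
    stop("class absent from training data: ",
         paste(bcc_classes()[absent], collapse = ", "))
  fit <- MASS::lda(x, grouping = factor(y, levels = 1:8))
  structure(list(model = fit, window = as.integer(window),
                 samples_per_class = as.integer(samples_per_class),
                 seed = as.integer(seed),
                 train_ids = vapply(train, `[[`, "", "image_id"),
                 classes = bcc_classes()),
            class = "pixel_classifier")
}

#' Predict an 8-class label raster for an image
#'
#' Deterministic given the fitted state; the output raster has the input's
#' shape with codes 1-8.
#'
#' @param clf a `pixel_classifier`.
#' @param image a `labeled_image` or an HxWx3 integer array.
#' @return integer label matrix.
#' @export
predict_labels <- function(clf, image) {
  stopifnot(inherits(clf, "pixel_classifier"))
  pixels <- if (inherits(image, "labeled_image")) image$pixels else image
  if (length(dim(pixels)) != 3L)
    stop("expected an RGB raster")
  feats <- pixel_feature_maps(pixels, clf$window)
  pred <- stats::predict(clf$model, feats)$class
  matrix(as.integer(as.character(pred)), nrow(pixels[, , 1]),
         ncol(pixels[, , 1]))
}

#' Tile-wise inference for large rasters
#'
#' Applies the classifier tile by tile (edge tiles are shifted inward so
#' every pixel is covered); where tiles overlap, each pixel keeps the
#' prediction from the tile whose center is nearest. A tile larger than
#' the image degrades to a single full-image call.
#'
#' @param clf a `pixel_classifier`.
#' @param image a `labeled_image` or HxWx3 array.
#' @param tile tile side in pixels; must exceed `overlap`.
#' @param overlap overlap between neighboring tiles in pixels (>= 0).
#' @return integer label matrix of the input shape.
#' @export
tiled_inference <- function(clf, image, tile = 256L, overlap = 32L) {
  pixels <- if (inherits(image, "labeled_image")) image$pixels else image
  if (overlap < 0 || tile <= overlap) stop("need tile > overlap >= 0")
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (tile >= H && tile >= W) return(predict_labels(clf, pixels))
  starts <- function(n) {
    if (tile >= n) return(1L)
    s <- seq(1L, n - tile + 1L, by = tile - overlap)
    unique(c(s, n - tile + 1L))
  }
  out <- matrix(0L, H, W)
  best <- matrix(Inf, H, W)
  for (r0 in starts(H)) for (c0 in starts(W)) {
    rows <- r0:min(r0 + tile - 1L, H)
    cols <- c0:min(c0 + tile - 1L, W)
    pred <- predict_labels(clf, pixels[rows, cols, , drop = FALSE])
    cr <- mean(range(rows)); cc <- mean(range(cols))
    d <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    take <- d < best[rows, cols]
    sub <- out[rows, cols]
    sub[take] <- pred[take]
    out[rows, cols] <- sub
    bsub <- best[rows, cols]
    bsub[take] <- d[take]
    best[rows, cols] <- bsub
  }
  out
}

#' Mine uniformly correct patches
#'
#' Scans non-overlapping `size x size` tiles (stride = `size`) and keeps a
#' tile iff all its predicted pixels share one class and that class equals
#' the target everywhere in the tile -- the patch-mining rule used to
#' inspect what a segmenter finds homogeneous. Images smaller than `size`
#' give an empty list.
#'
#' @param pixels HxWx3 array (or `labeled_image`).
#' @param target,predicted integer label rasters aligned with `pixels`.
#' @param size patch side in pixels (100 by convention).
#' @return list of patches: `row`, `col` (top-left), `class` code and the
#'   cropped `pixels`.
#' @export
extract_uniform_patches <- function(pixels, target, predicted, size = 100L) {
  if (inherits(pixels, "labeled_image")) pixels <- pixels$pixels
  if (!identical(dim(target), dim(predicted)))
    stop("target and predicted rasters must be aligned")
  H <- dim(target)[1]; W <- dim(target)[2]
  out <- list()
  if (size > H || size > W) return(out)
  for (r0 in seq(1L, H - size + 1L, by = size))
    for (c0 in seq(1L, W - size + 1L, by = size)) {
      rows <- r0:(r0 + size - 1L); cols <- c0:(c0 + size - 1L)
      pr <- predicted[rows, cols]
      cl <- pr[1]
      if (cl == 0L || any(pr != cl)) next
      if (any(target[rows, cols] != cl)) next
      out[[length(out) + 1L]] <- list(row = r0, col = c0, class = cl,
                                      pixels = pixels[rows, cols, ,
                                                      drop = FALSE])
    }
  out
}

#' Import an externally produced label raster
#'
#' Reads a single-channel PNG holding 8-class codes (0 = unannotated).
#' Unknown codes are an error that names the offending values; an optional
#' expected shape is enforced so predictions can be paired with masks.
#'
#' @param path PNG file path.
#' @param expected_dim optional `c(height, width)`.
#' @return integer label matrix.
#' @export
import_predictions <- function(path, expected_dim = NULL) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) stop("expected a single-channel PNG: ", path)
  lab <- round(raw * 255); storage.mode(lab) <- "integer"
  bad <- setdiff(unique(as.vector(lab)), 0:8)
  if (length(bad))
    stop("label raster contains invalid codes: ",
         paste(sort(bad), collapse = ", "))
  if (!is.null(expected_dim) && !identical(dim(lab), as.integer(expected_dim)))
    stop("label raster shape ", paste(dim(lab), collapse = "x"),
         " does not match expected ",
         paste(expected_dim, collapse = "x"))
  lab
}

#' Export a label raster as a single-channel PNG
#'
#' @param raster integer matrix with codes 0..8.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(raster, path) {
  bad <- setdiff(unique(as.vector(raster)), 0:8)
  if (length(bad)) stop("invalid label codes: ", paste(bad, collapse = ", "))
  png::writePNG(raster / 255, path)
  invisible(path)
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> LDA, window %d, %d training images\n",
              x$window, length(x$train_ids)))
  invisible(x)
}
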