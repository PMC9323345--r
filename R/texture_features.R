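# Trimmed-GLCM Haralick features and central histogram moments.
#
# The co-occurrence matrix uses a horizontal offset of (0, 1), no
# symmetrization, and 9 quantization levels over the fixed range [0, 255].
# Because background is exactly black in component images, every pair that
# touches quantization bin 1 is purged by dropping the first row and column,
# leaving an 8x8 matrix. This also discards genuinely dark tissue pixels
# (gray 1-28) -- a documented conflation inherited from the procedure.

#' Quantize an 8-bit grayscale image into co-occurrence levels
#'
#' `level(g) = floor(g * levels / 256) + 1` over the fixed range
#' `[0, 255]`, so background (gray 0) always lands in level 1.
#'
#' @param gray a `gray_image` or an integer matrix of 8-bit values.
#' @param levels number of levels (>= 2); 9 by convention.
#' @return integer matrix of levels in `1..levels`, with a `levels`
#'   attribute.
#' @export
quantize_levels <- function(gray, levels = 9L) {
  if (inherits(gray, "gray_image")) gray <- gray$pixels
  if (!is.numeric(levels) || levels < 2) stop("levels must be >= 2")
  levels <- as.integer(levels)
  if (any(gray < 0 | gray > 255)) stop("gray values must be in [0, 255]")
  lv <- (as.integer(gray) * levels) %/% 256L + 1L
  lv <- matrix(lv, nrow(gray), ncol(gray))
  attr(lv, "levels") <- levels
  lv
}

#' Horizontal gray-level co-occurrence matrix
#'
#' Counts how many times level `i` occurs immediately to the left of level
#' `j` (offset `(0, 1)`, no symmetry). The total count is always
#' `H * (W - 1)`.
#'
#' @param levels an integer level matrix from [quantize_levels()].
#' @return a `glcm` object: list with `counts` (levels x levels integer
#'   matrix), `levels`, `offset`.
#' @export
glcm <- function(levels) {
  L <- attr(levels, "levels") %||% max(levels)
  if (ncol(levels) < 2) stop("image must have at least 2 columns")
  i <- levels[, -ncol(levels)]
  j <- levels[, -1]
  counts <- matrix(tabulate((i - 1L) * L + j, nbins = L * L),
                   L, L, byrow = TRUE)
  structure(list(counts = counts, levels = L, offset = c(0L, 1L)),
            class = "glcm")
}

#' Trim the background row/column and normalize to probabilities
#'
#' Drops the first row and column of the co-occurrence counts (all pairs
#' involving the background bin) and normalizes the remainder to a
#' probability matrix, along with its marginals and sum/difference
#' distributions. A matrix whose every pair touched the background comes
#' back empty-flagged, never silently zero.
#'
#' @param g a `glcm` object.
#' @return a `trimmed_glcm`: list with `p` ((L-1)x(L-1) probabilities),
#'   `n_pairs`, marginals `px`, `py`, sum distribution `p_sum` (named by
#'   k = 2..2(L-1)), difference distribution `p_diff` (k = 0..L-2) and an
#'   `empty` flag.
#' @export
trim_and_normalize <- function(g) {
  stopifnot(inherits(g, "glcm"))
  cts <- g$counts[-1, -1, drop = FALSE]
  n_pairs <- sum(cts)
  L <- nrow(cts)
  if (n_pairs == 0) {
    return(structure(list(p = matrix(0, L, L), n_pairs = 0L, px = NULL,
                          py = NULL, p_sum = NULL, p_diff = NULL,
                          empty = TRUE), class = "trimmed_glcm"))
  }
  p <- cts / n_pairs
  px <- rowSums(p); py <- colSums(p)
  i <- row(p); j <- col(p)
  p_sum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), 0)
  names(p_sum) <- 2:(2 * L)
  p_diff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), 0)
  names(p_diff) <- 0:(L - 1)
  structure(list(p = p, n_pairs = n_pairs, px = px, py = py,
                 p_sum = p_sum, p_diff = p_diff, empty = FALSE),
            class = "trimmed_glcm")
}

haralick_feature_names <- function() {
  c("energy", "contrast", "correlation", "variance", "homogeneity",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2",
    "max_corr_coef")
}

moment_feature_names <- function() c("m2_variance", "m3_skewness",
                                     "m4_kurtosis")

#' The 14 Haralick texture features of a trimmed co-occurrence matrix
#'
#' Evaluates the classical 1973 definitions on the retained levels
#' (re-indexed 1..8 after trimming), with natural logarithms and the
#' `0 log 0 = 0` convention. Sum variance is centered on the sum average;
#' variance uses the mean of the x-marginal. The information measures use
#' `log(p + 1e-12)` inside the joint/marginal product entropies.
#' The maximal correlation coefficient is the square root of the
#' second-largest eigenvalue of `Q(i,j) = sum_k p(i,k) p(j,k) /
#' (px(i) py(k))` with zero-marginal rows/columns excluded; degenerate
#' single-level matrices return 0 there, as do correlation and IMC-II when
#' their denominators vanish.
#'
#' @param x a `trimmed_glcm`.
#' @return named numeric vector of the 14 features; all `NA` when the
#'   matrix is empty-flagged.
#' @export
haralick_features <- function(x) {
  stopifnot(inherits(x, "trimmed_glcm"))
  nm <- haralick_feature_names()
  if (x$empty) return(stats::setNames(rep(NA_real_, 14), nm))
  p <- x$p; px <- x$px; py <- x$py
  L <- nrow(p)
  i <- row(p); j <- col(p)
  lev <- seq_len(L)
  psum <- x$p_sum; ks <- as.numeric(names(psum))
  pdif <- x$p_diff; kd <- as.numeric(names(pdif))
  eps <- 1e-12

  f1 <- sum(p^2)
  f2 <- sum(kd^2 * pdif)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px)); sigy <- sqrt(sum((lev - muy)^2 * py))
  f3 <- if (sigx * sigy < eps) 0 else
    (sum(i * j * p) - mux * muy) / (sigx * sigy)
  f4 <- sum((i - mux)^2 * p)
  f5 <- sum(p / (1 + (i - j)^2))
  f6 <- sum(ks * psum)
  f7 <- sum((ks - f6)^2 * psum)
  f8 <- -sum(xlogx(psum))
  f9 <- -sum(xlogx(p))
  mud <- sum(kd * pdif)
  f10 <- sum((kd - mud)^2 * pdif)
  f11 <- -sum(xlogx(pdif))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log(pxy + eps))
  hxy2 <- -sum(pxy * log(pxy + eps))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  f12 <- if (max(hx, hy) < eps) 0 else (f9 - hxy1) / max(hx, hy)
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  nzr <- px > 0; nzc <- py > 0
  f14 <- if (sum(nzr) < 2 || sum(nzc) < 2) 0 else {
    A <- p[nzr, nzc, drop = FALSE] / px[nzr]
    B <- sweep(p[nzr, nzc, drop = FALSE], 2, py[nzc], `/`)
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  stats::setNames(c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12,
                    f13, f14), nm)
}

#' Central histogram moments of a component's foreground pixels
#'
#' Literal unstandardized central moments with denominator `n`:
#' `m_k = (1/n) sum (x_i - m)^k` for k = 2, 3, 4, where `x_i` are the
#' grayscale foreground pixel values and `m` their mean. By this
#' convention m2 is the variance and m3/m4 play the role of skewness and
#' kurtosis without standardization.
#'
#' @param img a `component_image` (converted to grayscale internally) or a
#'   `gray_image`.
#' @return list with `mean`, `m2`, `m3`, `m4`, `n`; all moments `NA` when
#'   the component is empty.
#' @export
histogram_moments <- function(img) {
  if (inherits(img, "component_image")) img <- to_grayscale(img)
  stopifnot(inherits(img, "gray_image"))
  x <- as.numeric(img$pixels[img$fg])
  n <- length(x)
  if (n == 0)
    return(list(mean = NA_real_, m2 = NA_real_, m3 = NA_real_,
                m4 = NA_real_, n = 0L))
  m <- mean(x)
  d <- x - m
  list(mean = m, m2 = mean(d^2), m3 = mean(d^3), m4 = mean(d^4), n = n)
}

#' Build the per-(image, component) feature table
#'
#' Four rows per image -- one per component -- with the 14 Haralick
#' features and the three Eq.-style central moments (17 feature columns).
#' Empty components yield `NA` markers, never silent zeros.
#'
#' @param dataset list of `labeled_image`s.
#' @param levels GLCM quantization levels (default 9).
#' @return data frame keyed by `image_id`, `subtype`, `component`.
#' @export
build_feature_table <- function(dataset, levels = 9L) {
  if (!length(dataset)) stop("dataset is empty")
  rows <- lapply(dataset, function(im) {
    stopifnot(inherits(im, "labeled_image"))
    # Fast path equivalent to extract_component() + to_grayscale() per
    # component: zeroing non-component RGB pixels and then taking the luma
    # is the same as taking the luma once and zeroing outside the
    # component, and gray 0 always quantizes to the trimmed level 1.
    gray_full <- rgb_to_gray_int(im$pixels)
    lev_full <- quantize_levels(gray_full, levels)
    per_comp <- lapply(component_names(), function(comp) {
      code <- bcc_components()[[comp]]
      fg <- im$mask == code
      if (!any(fg)) {
        hv <- stats::setNames(rep(NA_real_, 14), haralick_feature_names())
        mo <- list(m2 = NA_real_, m3 = NA_real_, m4 = NA_real_)
      } else {
        lev <- lev_full
        lev[!fg] <- 1L
        attr(lev, "levels") <- levels
        hv <- haralick_features(trim_and_normalize(glcm(lev)))
        x <- as.numeric(gray_full[fg])
        d <- x - mean(x)
        mo <- list(m2 = mean(d^2), m3 = mean(d^3), m4 = mean(d^4))
      }
      cbind(data.frame(image_id = im$image_id, subtype = im$subtype,
                       component = comp, stringsAsFactors = FALSE),
            as.data.frame(as.list(hv)),
            data.frame(m2_variance = mo$m2, m3_skewness = mo$m3,
                       m4_kurtosis = mo$m4))
    })
    do.call(rbind, per_comp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.trimmed_glcm <- function(x, ...) {
  cat(sprintf("<trimmed_glcm> %dx%d, %d pairs%s\n", nrow(x$p), ncol(x$p),
              x$n_pairs, if (x$empty) " (empty)" else ""))
  invisible(x)
}
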