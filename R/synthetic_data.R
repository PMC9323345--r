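# Synthetic two-subtype "histology" generator with exact component masks.
#
# The generator is a stated world, not a photorealistic simulator: it encodes
# the statistical structure the downstream analysis assumes -- nodular (N)
# images carry 1-3 large islands, micronodular (MN) images >= 10 small ones
# (diameter bounded by 0.15 mm); the tumor-core texture differs moderately
# between subtypes (oriented elongated grain for N vs. finer isotropic grain
# for MN), the palisade rim (TT) texture is drawn from identical
# distributions, the peritumoral cleft (PC) texture diverges strongly and the
# stroma (S) texture only weakly. Stroma additionally carries an equal-luma
# chroma shift between subtypes, invisible to the grayscale morphometry but
# available to an RGB pixel classifier.

.bcc_cache <- new.env(parent = emptyenv())

#' Describe a synthetic two-subtype dataset
#'
#' Builds the parameter object consumed by [generate_dataset()]. Defaults
#' reproduce the clinical acquisition scale: 1920 x 1017 px at 0.038 square
#' microns per pixel, 216 nodular and 201 micronodular images. The `desk`
#' preset (512 x 384 px at 4x coarser sampling) is the recommended scale for
#' interactive work and tests; `tiny` (192 x 144) exists for fast unit tests.
#'
#' @param preset one of `"full"`, `"desk"`, `"tiny"`; presets override the
#'   image geometry (size, microns per pixel, rim and cleft widths) only.
#' @param n_nodular,n_micronodular image counts per subtype.
#' @param image_height_px,image_width_px raster size in pixels.
#' @param microns_per_pixel linear pixel size in micrometres per pixel
#'   (`0.195` corresponds to the nominal 0.038 square-micron pixel area).
#' @param micronodule_max_diameter_um defining upper bound on micronodule
#'   diameter, micrometres (0.15 mm by convention).
#' @param rim_width_px,cleft_width_px nominal width of the palisade rim
#'   (TT; scaled 0.6-1.5x per nodule) and width of the peritumoral cleft
#'   annulus (PC), in pixels.
#' @param texture_divergence named vector in `[0, 1]` over `T`, `TT`, `PC`,
#'   `S`: how strongly the subtype texture parameters diverge per component.
#' @param cleft_presence_prob probability that a nodule carries a cleft.
#' @param stroma_chroma_shift equal-luma hue shift of stroma between
#'   subtypes (0 disables it).
#' @param seed integer master seed; the dataset is a pure function of the
#'   spec including this seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("full", "desk", "tiny"),
                           n_nodular = 216L, n_micronodular = 201L,
                           image_height_px = NULL, image_width_px = NULL,
                           microns_per_pixel = NULL,
                           micronodule_max_diameter_um = 150,
                           rim_width_px = NULL, cleft_width_px = NULL,
                           texture_divergence = c(T = 0.5, TT = 0,
                                                  PC = 0.95, S = 0.18),
                           cleft_presence_prob = 0.95,
                           stroma_chroma_shift = 0.30,
                           seed = 1L) {
  preset <- match.arg(preset)
  geom <- switch(preset,
    full = list(h = 1017L, w = 1920L, mpp = 0.195, rim = 24L, cleft = 18L),
    desk = list(h = 384L, w = 512L, mpp = 0.78, rim = 6L, cleft = 5L),
    tiny = list(h = 144L, w = 192L, mpp = 3.0, rim = 3L, cleft = 3L))
  spec <- structure(list(
    preset = preset,
    n_nodular = as.integer(n_nodular),
    n_micronodular = as.integer(n_micronodular),
    image_height_px = as.integer(image_height_px %||% geom$h),
    image_width_px = as.integer(image_width_px %||% geom$w),
    microns_per_pixel = microns_per_pixel %||% geom$mpp,
    micronodule_max_diameter_um = micronodule_max_diameter_um,
    rim_width_px = as.integer(rim_width_px %||% geom$rim),
    cleft_width_px = as.integer(cleft_width_px %||% geom$cleft),
    texture_divergence = texture_divergence,
    cleft_presence_prob = cleft_presence_prob,
    stroma_chroma_shift = stroma_chroma_shift,
    seed = as.integer(seed)), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with(spec, {
    if (!is_count(n_nodular) || !is_count(n_micronodular))
      stop("image counts must be positive integers")
    if (!is_count(image_height_px) || !is_count(image_width_px))
      stop("image dimensions must be positive integers")
    if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
      stop("microns_per_pixel must be positive")
    if (cleft_presence_prob < 0 || cleft_presence_prob > 1)
      stop("cleft_presence_prob must be in [0, 1]")
    if (!all(component_names() %in% names(texture_divergence)))
      stop("texture_divergence must name all of T, TT, PC, S")
    if (any(texture_divergence < 0 | texture_divergence > 1))
      stop("texture_divergence values must be in [0, 1]")
  })
  geo <- nodule_geometry(spec)
  if (geo$n_hi <= geo$n_lo)
    stop("a nodular island (diameter > ",
         spec$micronodule_max_diameter_um, " um) cannot fit in a ",
         spec$image_height_px, "x", spec$image_width_px, " image at ",
         spec$microns_per_pixel, " um/px")
  if (geo$mn_lo <= spec$rim_width_px + 2)
    stop("a micronodule cannot accommodate the ", spec$rim_width_px,
         "-px palisade rim at ", spec$microns_per_pixel, " um/px")
  invisible(spec)
}

# Radius ranges (px) for the two subtypes. The micronodule bound is a hard
# geometric guarantee: max radius including shape harmonics stays below the
# defining 0.15 mm diameter; nodular islands always exceed it.
nodule_geometry <- function(spec) {
  bound_r <- (spec$micronodule_max_diameter_um / 2) / spec$microns_per_pixel
  half_min <- min(spec$image_height_px, spec$image_width_px) / 2
  list(bound_r = bound_r,
       n_lo = 1.15 * bound_r,
       n_hi = min(1.55 * bound_r, (half_min - 2) / 1.08),
       mn_lo = 0.30 * bound_r,
       mn_hi = 0.80 * bound_r)
}

# -- texture parameter model ---------------------------------------------

# Per-component base texture parameters (gray level 0-255, noise amplitude
# in gray levels, correlation lengths along/across the grain in micrometres)
# and the full-divergence offsets. The subtype draw is base +/- d * delta / 2
# (+ for N, - for MN) plus a per-image jitter, so divergence 0 gives exactly
# identical distributions.
texture_model <- function() {
  list(
    base = list(
      T  = c(gray = 118, amp = 20, lu = 6.5, lv = 5.0),
      TT = c(gray = 117, amp = 19.5, lu = 5.0, lv = 3.5),
      PC = c(gray = 215, amp = 10, lu = 4.0, lv = 4.0),
      S  = c(gray = 156, amp = 18, lu = 9.0, lv = 3.0)),
    # PC's gray offset is chosen so the bright N cleft sits mid-bin of the
    # 9-level quantizer (edge-flicker would otherwise dominate its
    # difference statistics) while the MN cleft spans several bins.
    delta = list(
      T  = c(gray = 4,  amp = 4,   lu = 4, lv = -1.6),
      TT = c(gray = 0,  amp = 0,   lu = 0, lv = 0),
      PC = c(gray = 52, amp = -24, lu = 5, lv = 2),
      S  = c(gray = 0,  amp = 12,  lu = 0, lv = 0)),
    # Per-image jitter differs by tissue: the palisade rim is the most
    # heterogeneous band in practice, and its larger jitter also dominates
    # the small geometry-linked estimator bias (N rims are long and
    # straight, MN rims short and curved), keeping TT at its null.
    jitter = list(
      T  = c(gray = 6, amp = 3,   lu = 1.0, lv = 0.5),
      TT = c(gray = 2, amp = 1,   lu = 0.3, lv = 0.2),
      PC = c(gray = 5, amp = 2.5, lu = 0.8, lv = 0.5),
      S  = c(gray = 4, amp = 2,   lu = 0.8, lv = 0.4)),
    fine_sd = 4)
}

draw_texture_params <- function(subtype, spec) {
  mod <- texture_model()
  s <- if (subtype == "N") 1 else -1
  out <- list()
  for (comp in component_names()) {
    d <- spec$texture_divergence[[comp]]
    mu <- mod$base[[comp]] + s * d * mod$delta[[comp]] / 2
    p <- mu + stats::rnorm(4, 0, mod$jitter[[comp]])
    p["amp"] <- max(p["amp"], 1)
    p["lu"] <- max(p["lu"], 0.8)
    p["lv"] <- max(p["lv"], 0.8)
    p[["theta"]] <- stats::runif(1, 0, pi)
    out[[comp]] <- p
  }
  out
}

# Equal-luma H&E-like tints per component; stroma hue rotates between
# subtypes by `stroma_chroma_shift` (toward violet for MN) at constant
# luma, and the tumor core hue tilts with its texture divergence (the N
# core's richer eosinophilic intercellular matrix reads pinker, the MN
# core bluer). Grayscale morphometry is blind to both by construction.
component_tint <- function(comp, subtype, spec) {
  t <- switch(comp,
    T  = c(0.95, 0.80, 1.45),
    TT = c(0.95, 0.80, 1.45),
    PC = c(1.02, 1.00, 0.95),
    S  = c(1.25, 0.85, 1.00))
  if (comp == "S" && subtype == "MN") {
    sh <- spec$stroma_chroma_shift
    t <- t + c(-sh, 0.2 * sh, sh)
  }
  if (comp == "T") {
    sh <- 0.085 * spec$texture_divergence[["T"]] *
      (if (subtype == "N") 1 else -1)
    t <- t + c(sh, 0.2 * sh, -sh)
  }
  w <- c(0.2989, 0.5870, 0.1140)
  t / sum(w * t)
}

# -- oriented filtered-noise field ---------------------------------------

freq_grids <- function(h, w) {
  key <- paste0("f", h, "x", w)
  g <- .bcc_cache[[key]]
  if (is.null(g)) {
    fr <- (seq_len(h) - 1); fr <- ifelse(fr > h / 2, fr - h, fr) / h
    fc <- (seq_len(w) - 1); fc <- ifelse(fc > w / 2, fc - w, fc) / w
    g <- list(FY = matrix(fr, h, w), FX = matrix(fc, h, w, byrow = TRUE))
    .bcc_cache[[key]] <- g
  }
  g
}

# Stationary Gaussian random field with anisotropic correlation lengths
# lu (along orientation theta) and lv (across), unit variance. `spectrum`
# lets one white-noise FFT be reused across several filters of the same
# image (one forward transform instead of four); the resulting fields are
# mutually correlated, which is irrelevant because each is only visible in
# its own component's region.
noise_field <- function(h, w, lu, lv, theta, spectrum = NULL) {
  g <- freq_grids(h, w)
  fu <- g$FX * cos(theta) + g$FY * sin(theta)
  fv <- -g$FX * sin(theta) + g$FY * cos(theta)
  H <- exp(-2 * pi^2 * ((lu * fu)^2 + (lv * fv)^2))
  if (is.null(spectrum))
    spectrum <- stats::fft(matrix(stats::rnorm(h * w), h, w))
  f <- Re(stats::fft(spectrum * H, inverse = TRUE)) / (h * w)
  s <- stats::sd(f)
  if (s < 1e-12) matrix(0, h, w) else f / s
}

# -- mask construction ----------------------------------------------------

# Nodules are harmonic-deformed disks; TT is a fixed-width inner rim, PC a
# fixed-width outer annulus carved out of stroma only (so islands never eat
# into each other's interiors).
make_mask <- function(subtype, spec) {
  H <- spec$image_height_px; W <- spec$image_width_px
  geo <- nodule_geometry(spec)
  mask <- matrix(4L, H, W)
  k <- if (subtype == "N") sample(1:3, 1, prob = c(0.45, 0.35, 0.20))
       else sample(10:16, 1)
  r0 <- if (subtype == "N") stats::runif(k, geo$n_lo, geo$n_hi)
        else stats::runif(k, geo$mn_lo, geo$mn_hi)
  a <- matrix(stats::runif(2 * k, 0, 0.04), k, 2)
  psi <- matrix(stats::runif(2 * k, 0, 2 * pi), k, 2)
  cleft <- stats::runif(k) < spec$cleft_presence_prob
  # palisade rims vary nodule to nodule; diversifies the T/TT boundary
  rims <- spec$rim_width_px * stats::runif(k, 0.6, 1.5)
  rmax <- r0 * (1 + a[, 1] + a[, 2])
  cx <- cy <- numeric(k)
  for (i in seq_len(k)) {
    m <- ceiling(rmax[i]) + 1
    if (W - m <= m + 1 || H - m <= m + 1)
      stop("nodule of radius ", round(rmax[i]), " px cannot fit in the image")
    for (try in 1:8) {
      x <- stats::runif(1, m + 1, W - m); y <- stats::runif(1, m + 1, H - m)
      ok <- if (i == 1) TRUE else
        all(sqrt((x - cx[1:(i - 1)])^2 + (y - cy[1:(i - 1)])^2) >=
              0.7 * (r0[i] + r0[1:(i - 1)]))
      if (ok) break
    }
    cx[i] <- x; cy[i] <- y
  }
  radius_at <- function(phi, i)
    r0[i] * (1 + a[i, 1] * cos(2 * phi + psi[i, 1]) +
               a[i, 2] * cos(3 * phi + psi[i, 2]))
  boxes <- vector("list", k)
  for (i in seq_len(k)) {
    ext <- ceiling(rmax[i]) + spec$cleft_width_px + 1
    rows <- max(1, floor(cy[i] - ext)):min(H, ceiling(cy[i] + ext))
    cols <- max(1, floor(cx[i] - ext)):min(W, ceiling(cx[i] + ext))
    dy <- rows - cy[i]; dx <- cols - cx[i]
    rr <- sqrt(outer(dy^2, dx^2, `+`))
    phi <- atan2(matrix(dy, length(rows), length(cols)),
                 matrix(dx, length(rows), length(cols), byrow = TRUE))
    Rphi <- radius_at(phi, i)
    boxes[[i]] <- list(rows = rows, cols = cols, rr = rr, Rphi = Rphi)
    sub <- mask[rows, cols]
    sub[rr <= Rphi - rims[i]] <- 1L
    sub[rr > Rphi - rims[i] & rr <= Rphi] <- 2L
    mask[rows, cols] <- sub
  }
  for (i in seq_len(k)) {
    if (!cleft[i]) next
    b <- boxes[[i]]
    sub <- mask[b$rows, b$cols]
    sub[b$rr > b$Rphi & b$rr <= b$Rphi + spec$cleft_width_px & sub == 4L] <- 3L
    mask[b$rows, b$cols] <- sub
  }
  info <- data.frame(nodule = seq_len(k), cx = cx, cy = cy, r0_px = r0,
                     max_radius_px = rmax, cleft = cleft,
                     diameter_um = 2 * rmax * spec$microns_per_pixel)
  list(mask = mask, nodules = info)
}

# -- image rendering ------------------------------------------------------

#' Render one labeled synthetic image
#'
#' Draws the island geometry and per-component textures for a single image
#' of the requested subtype. Texture fields are oriented filtered Gaussian
#' noise; the tumor core of N images has elongated grain with a shared
#' per-image orientation while MN cores are finer and isotropic. All tissue
#' channels are clamped to a minimum of 1 so that true black remains
#' reserved for background.
#'
#' @param subtype `"N"` or `"MN"`.
#' @param spec a [synthetic_spec()].
#' @param seed integer seed for this image's random draws.
#' @param image_id identifier stored in the result.
#' @return a `labeled_image`: list with `pixels` (HxWx3 integer array,
#'   0-255), `mask` (integer matrix, codes 0-4), `subtype`, `image_id`,
#'   `pc_absent` flag and per-nodule bookkeeping in `nodule_info`.
#' @export
render_subtype_image <- function(subtype, spec, seed = 1L,
                                 image_id = paste0(subtype, "_1")) {
  stopifnot(subtype %in% c("N", "MN"))
  validate_spec(spec)
  with_seed(seed, {
    H <- spec$image_height_px; W <- spec$image_width_px
    mk <- make_mask(subtype, spec)
    pars <- draw_texture_params(subtype, spec)
    mpp <- spec$microns_per_pixel
    spectrum <- stats::fft(matrix(stats::rnorm(H * W), H, W))
    gray <- matrix(0, H, W)
    for (comp in c("S", "T", "TT", "PC")) {
      p <- pars[[comp]]
      fld <- noise_field(H, W, p[["lu"]] / mpp, p[["lv"]] / mpp,
                         p[["theta"]], spectrum)
      sel <- mk$mask == bcc_components()[[comp]]
      gray[sel] <- p[["gray"]] + p[["amp"]] * fld[sel]
    }
    gray <- gray + stats::rnorm(H * W, 0, texture_model()$fine_sd)
    gray <- clamp(gray, 1, 255)
    # Per-pixel tint lookup, one multiply per channel. Quantization to
    # 8 bits uses uniform dither rather than round-half-up: deterministic
    # rounding of the tinted channels would imprint a class-specific
    # sawtooth on the reconstructed luma, a spurious grayscale signature
    # of the (luma-neutral) chroma differences. Dither keeps the expected
    # channel value exact.
    tints <- vapply(component_names(),
                    function(comp) component_tint(comp, subtype, spec),
                    numeric(3))
    pix <- array(0L, dim = c(H, W, 3))
    for (ch in 1:3) {
      tch <- tints[ch, ][as.vector(mk$mask)]
      plane <- clamp(floor(gray * tch + stats::runif(H * W)), 1, 255)
      storage.mode(plane) <- "integer"
      pix[, , ch] <- plane
    }
    structure(list(pixels = pix, mask = mk$mask, subtype = subtype,
                   image_id = image_id, pc_absent = !any(mk$mask == 3L),
                   nodule_info = mk$nodules),
              class = "labeled_image")
  })
}

#' Generate a seeded synthetic dataset
#'
#' Produces `n_nodular + n_micronodular` labeled images (N first, then MN).
#' The result is a pure function of the spec: a fixed seed yields
#' bit-identical rasters.
#'
#' @param spec a [synthetic_spec()].
#' @return list of `labeled_image` objects, named by `image_id`.
#' @export
generate_dataset <- function(spec) {
  validate_spec(spec)
  n <- spec$n_nodular + spec$n_micronodular
  seeds <- with_seed(spec$seed, sample.int(2147483646L, n))
  subtypes <- c(rep("N", spec$n_nodular), rep("MN", spec$n_micronodular))
  idx <- c(seq_len(spec$n_nodular), seq_len(spec$n_micronodular))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("%s_%04d", subtypes[i], idx[i])
    images[[i]] <- render_subtype_image(subtypes[i], spec, seeds[i], id)
  }
  names(images) <- vapply(images, `[[`, "", "image_id")
  images
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image %s> %dx%d px, subtype %s, %d nodule(s)%s\n",
              x$image_id, nrow(x$mask), ncol(x$mask), x$subtype,
              if (is.null(x$nodule_info)) NA_integer_ else nrow(x$nodule_info),
              if (isTRUE(x$pc_absent)) ", no cleft (flagged)" else ""))
  invisible(x)
}

# -- on-disk layout -------------------------------------------------------

#' Write a dataset as PNG images, PNG masks and a CSV manifest
#'
#' One 8-bit RGB PNG and one single-channel PNG mask (codes 0-4) per image,
#' plus `manifest.csv` with columns `image_id`, `subtype`, `image_path`,
#' `mask_path` (relative to the directory) and `pc_absent`. The round trip
#' through [read_dataset()] is lossless.
#'
#' @param images list of `labeled_image`s.
#' @param directory output directory, created if needed.
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(images, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  rows <- lapply(images, function(im) {
    ip <- paste0(im$image_id, "_image.png")
    mp <- paste0(im$image_id, "_mask.png")
    png::writePNG(im$pixels / 255, file.path(directory, ip))
    png::writePNG(im$mask / 255, file.path(directory, mp))
    data.frame(image_id = im$image_id, subtype = im$subtype,
               image_path = ip, mask_path = mp,
               pc_absent = isTRUE(im$pc_absent))
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  n_png <- length(list.files(directory, pattern = "_image\\.png$"))
  if (n_png != length(images))
    stop("manifest/file count mismatch: ", n_png, " image files for ",
         length(images), " images")
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Accepts externally produced data in the same layout; mask codes must be
#' in 0-4.
#'
#' @param directory dataset directory containing `manifest.csv`.
#' @return list of `labeled_image` objects.
#' @export
read_dataset <- function(directory) {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", directory)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  need <- c("image_id", "subtype", "image_path", "mask_path")
  if (!all(need %in% names(manifest)))
    stop("manifest lacks columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    px <- png::readPNG(file.path(directory, row$image_path))
    if (length(dim(px)) != 3L || dim(px)[3] < 3)
      stop("image ", row$image_id, " is not RGB")
    pix <- round(px[, , 1:3] * 255); storage.mode(pix) <- "integer"
    mraw <- png::readPNG(file.path(directory, row$mask_path))
    if (length(dim(mraw)) == 3L) mraw <- mraw[, , 1]
    mask <- round(mraw * 255); storage.mode(mask) <- "integer"
    bad <- setdiff(unique(as.vector(mask)), 0:4)
    if (length(bad))
      stop("mask for ", row$image_id, " contains invalid codes: ",
           paste(bad, collapse = ", "))
    structure(list(pixels = pix, mask = mask, subtype = row$subtype,
                   image_id = row$image_id, pc_absent = !any(mask == 3L),
                   nodule_info = NULL),
              class = "labeled_image")
  })
  names(images) <- manifest$image_id
  images
}
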