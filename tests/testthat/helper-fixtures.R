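# Shared fixtures, built in code. The tiny preset keeps unit tests fast;
# fixtures are memoised per test file.

.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function(n_n = 3, n_mn = 3, seed = 7) {
  key <- paste("tiny", n_n, n_mn, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    sp <- synthetic_spec(preset = "tiny", n_nodular = n_n,
                         n_micronodular = n_mn, seed = seed)
    .fixture_cache[[key]] <- generate_dataset(sp)
  }
  .fixture_cache[[key]]
}

# Two hand-built, trivially separable labeled images (one per subtype):
# four quadrants, one component each, near-constant distinctive colors.
quadrant_image <- function(subtype, base, h = 96, w = 128, seed = 11) {
  stopifnot(subtype %in% c("N", "MN"))
  mask <- matrix(0L, h, w)
  mask[1:(h / 2), 1:(w / 2)] <- 1L
  mask[1:(h / 2), (w / 2 + 1):w] <- 2L
  mask[(h / 2 + 1):h, 1:(w / 2)] <- 3L
  mask[(h / 2 + 1):h, (w / 2 + 1):w] <- 4L
  cols <- base + 25 * (0:3) # distinct mean level per component
  pix <- array(0L, dim = c(h, w, 3))
  set.seed(seed)
  for (comp in 1:4) {
    sel <- mask == comp
    for (ch in 1:3) {
      plane <- pix[, , ch]
      v <- cols[comp] + (ch - 1) * 10 + sample(0:2, sum(sel), replace = TRUE)
      plane[sel] <- as.integer(pmin(pmax(v, 1), 255))
      pix[, , ch] <- plane
    }
  }
  structure(list(pixels = pix, mask = mask, subtype = subtype,
                 image_id = paste0("quad_", subtype), pc_absent = FALSE,
                 nodule_info = NULL), class = "labeled_image")
}

quadrant_pair <- function() {
  list(quadrant_image("N", base = 40, seed = 11),
       quadrant_image("MN", base = 150, seed = 12))
}

# Feature table of pure-noise features (both subtypes from one shared
# distribution) for null-calibration checks.
null_feature_table <- function(n_per_side = 40, seed = 1) {
  feats <- c(bccmorph:::haralick_feature_names(),
             bccmorph:::moment_feature_names())
  set.seed(seed)
  n <- n_per_side * 2 * 4
  base <- data.frame(
    image_id = rep(sprintf("im%03d", seq_len(n_per_side * 2)), each = 4),
    subtype = rep(c("N", "MN"), each = n_per_side * 4),
    component = rep(c("T", "TT", "PC", "S"), times = n_per_side * 2),
    stringsAsFactors = FALSE)
  for (f in feats) base[[f]] <- rnorm(n)
  base
}
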