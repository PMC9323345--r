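# Quantization, co-occurrence, trimming, Haralick features, moments.

lev_mat <- function(m, L = 9L) {
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  attr(m, "levels") <- L
  m
}

test_that("quantization bins the fixed [0,255] range", {
  g <- matrix(c(0L, 255L, 128L, 28L, 29L, 200L), 2, 3)
  lv <- quantize_levels(g, 9)
  expect_equal(as.vector(lv)[1:5], c(1L, 9L, 5L, 1L, 2L))
  expect_error(quantize_levels(g, 1), ">= 2")
  expect_error(quantize_levels(matrix(300L, 1, 2)), "\\[0, 255\\]")
})

test_that("glcm counts horizontal pairs exactly", {
  lv <- lev_mat(rbind(c(1, 1, 2), c(2, 3, 3)))
  cts <- glcm(lv)$counts
  expect_equal(sum(cts), 4)
  expect_equal(cts[1, 1], 1); expect_equal(cts[1, 2], 1)
  expect_equal(cts[2, 3], 1); expect_equal(cts[3, 3], 1)
  # constant image: single diagonal entry H*(W-1)
  cts5 <- glcm(lev_mat(matrix(5, 4, 7)))$counts
  expect_equal(cts5[5, 5], 4 * 6)
  expect_equal(sum(cts5 != 0), 1)
  expect_error(glcm(lev_mat(matrix(1, 3, 1))), "2 columns")
})

test_that("glcm conservation and brute-force equivalence", {
  set.seed(42)
  for (rep in 1:20) {
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    lv <- lev_mat(matrix(sample(1:9, h * w, replace = TRUE), h, w))
    cts <- glcm(lv)$counts
    expect_equal(sum(cts), h * (w - 1))
    expect_equal(cts, naive_glcm(lv, 9L))
  }
})

test_that("trimming drops the background row/column and normalizes", {
  set.seed(1)
  lv <- lev_mat(matrix(sample(1:9, 40, replace = TRUE), 5, 8))
  tg <- trim_and_normalize(glcm(lv))
  expect_equal(dim(tg$p), c(8, 8))
  expect_equal(sum(tg$p), 1, tolerance = 1e-12)
  expect_equal(rowSums(tg$p), tg$px, tolerance = 1e-12)
  expect_equal(colSums(tg$p), tg$py, tolerance = 1e-12)
  expect_equal(sum(tg$p_sum), 1, tolerance = 1e-12)
  expect_equal(sum(tg$p_diff), 1, tolerance = 1e-12)

  # counts {(2,2):3, (3,2):1} in raw coordinates -> p {(1,1):.75, (2,1):.25}
  cts <- matrix(0L, 9, 9); cts[2, 2] <- 3L; cts[3, 2] <- 1L
  g <- structure(list(counts = cts, levels = 9L, offset = c(0L, 1L)),
                 class = "glcm")
  tg2 <- trim_and_normalize(g)
  expect_equal(tg2$p[1, 1], 0.75); expect_equal(tg2$p[2, 1], 0.25)

  # all pairs touching background -> empty flag, and features go missing
  all_bg <- lev_mat(matrix(c(1, 2, 1, 3), 2, 2))
  tg3 <- trim_and_normalize(glcm(lev_mat(matrix(1, 3, 4))))
  expect_true(tg3$empty)
  expect_true(all(is.na(haralick_features(tg3))))
  expect_false(trim_and_normalize(glcm(all_bg))$empty ||
                 FALSE) # 1-2 and 1-3 pairs all touch bin 1 -> empty
})

test_that("haralick features on degenerate and closed-form cases", {
  mk <- function(p) structure(
    list(p = p, n_pairs = 100L, px = rowSums(p), py = colSums(p),
         p_sum = {i <- row(p); j <- col(p)
                  setNames(vapply(2:16, function(k) sum(p[i + j == k]), 0),
                           2:16)},
         p_diff = {i <- row(p); j <- col(p)
                   setNames(vapply(0:7, function(k) sum(p[abs(i - j) == k]),
                                   0), 0:7)},
         empty = FALSE), class = "trimmed_glcm")
  # single concentrated cell
  p <- matrix(0, 8, 8); p[3, 3] <- 1
  hv <- haralick_features(mk(p))
  expect_equal(hv[["energy"]], 1)
  expect_equal(hv[["entropy"]], 0)
  expect_equal(hv[["contrast"]], 0)
  expect_equal(hv[["homogeneity"]], 1)
  # uniform distribution over the 64 cells
  pu <- matrix(1 / 64, 8, 8)
  hvu <- haralick_features(mk(pu))
  expect_equal(hvu[["energy"]], 1 / 64)
  expect_equal(hvu[["entropy"]], log(64), tolerance = 1e-12)
  # two-level diagonal: Q is the identity on 2 levels, f14 = 1
  pd <- matrix(0, 8, 8); pd[1, 1] <- 0.5; pd[2, 2] <- 0.5
  expect_equal(haralick_features(mk(pd))[["max_corr_coef"]], 1,
               tolerance = 1e-8)
})

test_that("haralick features equal the brute-force oracle", {
  set.seed(99)
  for (rep in 1:20) {
    tg <- random_trimmed_glcm()
    got <- haralick_features(tg)
    want <- naive_haralick(tg$p)
    expect_equal(unname(got[1:13]), want[1:13], tolerance = 1e-10)
    expect_equal(unname(got[14]), want[14], tolerance = 1e-8)
    expect_gte(got[["max_corr_coef"]], 0)
    expect_lte(got[["max_corr_coef"]], 1 + 1e-8)
  }
})

test_that("histogram moments: golden values and oracle equivalence", {
  mk_img <- function(vals) {
    n <- length(vals)
    pix <- array(0L, dim = c(1, n, 3))
    for (ch in 1:3) pix[1, , ch] <- as.integer(vals)
    extract_component(pix, matrix(1L, 1, n), "T")
  }
  # {0, 2} in equal counts -> m = 1, m2 = 1, m3 = 0, m4 = 1 (gray of equal
  # RGB channels is the channel value)
  mo <- histogram_moments(mk_img(c(0, 2, 0, 2)))
  # value 0 pixels are background by the black-pixel convention; use 2/4
  mo2 <- histogram_moments(mk_img(c(2, 4, 2, 4)))
  expect_equal(mo2$mean, 3); expect_equal(mo2$m2, 1)
  expect_equal(mo2$m3, 0);   expect_equal(mo2$m4, 1)
  # {0,0,3} analog shifted off black: {1,1,4} -> same central moments
  mo3 <- histogram_moments(mk_img(c(1, 1, 4)))
  expect_equal(mo3$m2, 2); expect_equal(mo3$m3, 2); expect_equal(mo3$m4, 6)
  want <- naive_moments(c(1, 1, 4))
  expect_equal(mo3[c("mean", "m2", "m3", "m4")], want)
  # constant foreground
  moc <- histogram_moments(mk_img(rep(7, 5)))
  expect_equal(c(moc$m2, moc$m3, moc$m4), c(0, 0, 0))
})

test_that("moment inequalities hold on random inputs", {
  set.seed(5)
  for (rep in 1:25) {
    x <- sample(1:255, sample(3:40, 1), replace = TRUE)
    pix <- array(0L, dim = c(1, length(x), 3))
    for (ch in 1:3) pix[1, , ch] <- x
    mo <- histogram_moments(extract_component(pix, matrix(1L, 1, length(x)),
                                              "T"))
    expect_gte(mo$m4, mo$m2^2 - 1e-9) # Jensen
  }
  # symmetric histogram -> m3 = 0
  x <- c(10, 20, 30, 40, 50, 10, 20, 30, 40, 50, 30)
  pix <- array(0L, dim = c(1, length(x), 3))
  for (ch in 1:3) pix[1, , ch] <- x
  mo <- histogram_moments(extract_component(pix, matrix(1L, 1, length(x)),
                                            "T"))
  expect_equal(mo$m3, 0, tolerance = 1e-9)
})

test_that("feature table shape, columns and determinism", {
  ds <- tiny_dataset(3, 3, 7)
  ft <- build_feature_table(ds)
  expect_equal(nrow(ft), length(ds) * 4)
  feat_cols <- setdiff(names(ft), c("image_id", "subtype", "component"))
  expect_length(feat_cols, 17) # 14 Haralick + 3 moments
  expect_identical(ft, build_feature_table(ds))
  # fast path == documented per-component path on one image
  im <- ds[[2]]
  for (comp in c("T", "PC")) {
    gi <- to_grayscale(extract_component(im, component = comp))
    hv <- haralick_features(trim_and_normalize(glcm(quantize_levels(gi))))
    row <- ft[ft$image_id == im$image_id & ft$component == comp, ]
    expect_equal(unlist(row[, names(hv)]), hv, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})
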