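# Synthetic generator: bookkeeping, determinism, geometry, round trips.

test_that("generate_dataset honors counts, labels and determinism", {
  sp <- synthetic_spec(preset = "tiny", n_nodular = 3, n_micronodular = 3,
                       seed = 7)
  ds <- tiny_dataset(3, 3, 7)
  expect_length(ds, 6)
  expect_identical(vapply(ds, `[[`, "", "subtype"),
                   setNames(rep(c("N", "MN"), each = 3), names(ds)))
  for (im in ds) {
    expect_setequal(unique(as.vector(im$mask)), 1:4)
    expect_identical(dim(im$pixels)[1:2], dim(im$mask))
    expect_true(all(im$pixels >= 0 & im$pixels <= 255))
  }
  ds2 <- generate_dataset(sp)
  expect_identical(lapply(ds, `[[`, "pixels"), lapply(ds2, `[[`, "pixels"))
  expect_identical(lapply(ds, `[[`, "mask"), lapply(ds2, `[[`, "mask"))
})

test_that("subtype geometry: nodule counts and the 0.15 mm bound", {
  ds <- tiny_dataset(3, 3, 7)
  for (im in ds) {
    k <- nrow(im$nodule_info)
    if (im$subtype == "N") {
      expect_true(k >= 1 && k <= 3)
      expect_true(all(im$nodule_info$diameter_um > 150))
    } else {
      expect_gte(k, 10)
      expect_true(all(im$nodule_info$diameter_um <= 150))
    }
  }
})

test_that("tissue pixels never collide with true black", {
  im <- tiny_dataset(3, 3, 7)[[1]]
  tissue <- im$mask > 0
  for (ch in 1:3) expect_true(all(im$pixels[, , ch][tissue] >= 1))
})

test_that("cleft_presence_prob = 0 yields flagged PC-free images", {
  sp <- synthetic_spec(preset = "tiny", n_nodular = 1, n_micronodular = 1,
                       cleft_presence_prob = 0, seed = 3)
  ds <- generate_dataset(sp)
  for (im in ds) {
    expect_equal(sum(im$mask == 3L), 0)
    expect_true(im$pc_absent)
  }
})

test_that("invalid specs are rejected up front", {
  expect_error(synthetic_spec(preset = "tiny", n_nodular = 0),
               "positive integers")
  expect_error(synthetic_spec(preset = "tiny",
                              texture_divergence = c(T = 2, TT = 0,
                                                     PC = 1, S = 0)),
               "\\[0, 1\\]")
  expect_error(synthetic_spec(preset = "tiny", image_height_px = 60,
                              image_width_px = 60),
               "cannot fit")
  expect_error(synthetic_spec(preset = "tiny", rim_width_px = 20),
               "rim")
})

test_that("write_dataset/read_dataset round-trips losslessly", {
  ds <- tiny_dataset(2, 2, 21)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(manifest), 4)
  expect_equal(sum(manifest$subtype == "N"), 2)
  expect_equal(sum(manifest$subtype == "MN"), 2)
  expect_length(list.files(dir, pattern = "_image\\.png$"), 4)
  expect_length(list.files(dir, pattern = "_mask\\.png$"), 4)
  back <- read_dataset(dir)
  expect_identical(names(back), names(ds))
  for (id in names(ds)) {
    expect_identical(back[[id]]$pixels, ds[[id]]$pixels)
    expect_identical(back[[id]]$mask, ds[[id]]$mask)
    expect_identical(back[[id]]$subtype, ds[[id]]$subtype)
  }
})

test_that("zero divergence gives null-level significance rates", {
  # Scaled-down analog of the 200-images-per-side simulation oracle: with
  # all divergences at 0 (and no stroma chroma shift) the N and MN feature
  # draws share one distribution, so across 3 replicate datasets of 30+30
  # tiny images the 3 * 68 = 204 tests should reject at roughly the alpha
  # rate. Features within a component are correlated, so the bound is
  # generous: a systematic subtype leak would produce far more.
  total <- 0
  for (r in 1:3) {
    sp <- synthetic_spec(preset = "tiny", n_nodular = 30,
                         n_micronodular = 30,
                         texture_divergence = c(T = 0, TT = 0, PC = 0,
                                                S = 0),
                         stroma_chroma_shift = 0, seed = 400 + r)
    ft <- build_feature_table(generate_dataset(sp))
    rep <- significance_report(ft)
    total <- total + sum(rep$tests$significant)
  }
  expect_lte(total, 26)
})
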