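# Splits, confusion matrices, metric calculus, protocol machinery and the
# baseline pixel classifier.

test_that("split sizes follow floor/floor/remainder and are disjoint", {
  ids <- sprintf("im%03d", 1:417)
  sp <- split_dataset(ids, seed = 5)
  expect_length(sp$train, 291)
  expect_length(sp$val, 62)
  expect_length(sp$test, 64)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(sp, split_dataset(ids, seed = 5))
  expect_false(identical(sp$train, split_dataset(ids, seed = 6)$train))
  expect_error(split_dataset(ids[1:2]), "at least 3")
  expect_error(split_dataset(ids, fractions = c(0.5, 0.3, 0.3)), "summing")
})

test_that("confusion matrix counts, normalization and exclusions", {
  t <- matrix(c(1L, 1L, 1L, 2L, 0L, 3L), 2, 3)
  p <- matrix(c(1L, 1L, 2L, 2L, 5L, 3L), 2, 3)
  cm <- confusion_matrix(t, p)
  expect_equal(sum(cm$counts), 5) # the code-0 pixel is excluded
  expect_equal(cm$counts[1, 1], 2)
  expect_equal(cm$counts[1, 2], 1)
  expect_equal(cm$counts[2, 2], 1)
  expect_equal(cm$counts[3, 3], 1)
  nm <- cm_normalized(cm)
  expect_equal(nm[1, 1], 2 / 3)
  rs <- rowSums(nm)
  expect_equal(unname(rs[is.finite(rs)]), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(nm["TT-N", "TT-N"]), 1)
  expect_error(confusion_matrix(t, p[, 1:2]), "shapes")
  expect_error(confusion_matrix(matrix(0L, 2, 2), matrix(1L, 2, 2)),
               "no annotated")
  expect_warning(confusion_matrix(matrix(1L, 2, 2), matrix(0L, 2, 2)),
                 "background")
})

test_that("class metrics match direct substitution and the pixel oracle", {
  # TP=1, FP=1, FN=1, TN=7 for class 1
  t <- c(1L, 1L, 2L, rep(3L, 7))
  p <- c(1L, 2L, 1L, rep(3L, 7))
  cm <- confusion_matrix(matrix(t, 2, 5), matrix(p, 2, 5))
  m <- class_metrics(cm, "T-N")
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$iou, 1 / 3)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  # random rasters vs brute-force one-vs-rest loops
  set.seed(8)
  for (rep in 1:10) {
    t <- matrix(sample(0:8, 100, replace = TRUE, prob = c(1, rep(2, 8))),
                10, 10)
    p <- matrix(sample(1:8, 100, replace = TRUE), 10, 10)
    if (!any(t > 0)) next
    cm <- confusion_matrix(t, p)
    nmv <- cm_normalized(cm)
    for (k in sample(1:8, 3)) {
      got <- class_metrics(cm, k)
      want <- naive_class_metrics(as.vector(t), as.vector(p), k)
      for (f in c("TP", "TN", "FP", "FN"))
        expect_equal(got[[f]], want[[f]])
      for (f in c("accuracy", "iou", "precision", "recall"))
        expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
      # identities: f1 vs IoU, recall vs normalized diagonal
      if (!is.na(got$iou))
        expect_equal(got$f1, 2 * got$iou / (1 + got$iou), tolerance = 1e-10)
      if (!is.na(got$recall) && sum(cm$counts[k, ]) > 0)
        expect_equal(got$recall, nmv[k, k], tolerance = 1e-10)
    }
  }
})

test_that("perfect and absent classes behave at the boundaries", {
  t <- matrix(rep(1:4, each = 4), 4, 4)
  cm <- confusion_matrix(t, t)
  m <- class_metrics(cm, "T-N")
  expect_equal(unlist(m[c("accuracy", "iou", "precision", "recall", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
  absent <- class_metrics(cm, "S-MN")
  expect_true(absent$undefined)
  expect_true(is.na(absent$iou))
})

test_that("aggregate_runs reproduces the reference macro rows", {
  ref <- reference_tables()$metrics
  run <- data.frame(class = ref$class, TP = 0, TN = 0, FP = 0, FN = 0,
                    accuracy = ref$accuracy, iou = ref$iou,
                    precision = NA_real_, recall = NA_real_, f1 = ref$f1)
  rep <- aggregate_runs(list(run))
  expect_equal(unname(rep$macro_display["accuracy"]), 0.83)
  expect_equal(unname(rep$macro_display["iou"]), 0.65)
  expect_equal(unname(rep$macro_display["f1"]), 0.61)
  # single run: mean = run, SD = 0
  expect_equal(rep$mean_matrix[, "iou"], setNames(ref$iou, ref$class))
  expect_true(all(rep$sd_matrix == 0))
})

test_that("select_best_run takes the macro-IoU argmax with first-tie", {
  mk_run <- function(iou) data.frame(class = bcc_classes(), TP = 0, TN = 0,
                                     FP = 0, FN = 0, accuracy = 0.5,
                                     iou = iou, precision = 0.5,
                                     recall = 0.5, f1 = 0.5)
  rep <- aggregate_runs(list(mk_run(0.5), mk_run(0.7), mk_run(0.6)))
  expect_equal(select_best_run(rep), 2)
  rep2 <- aggregate_runs(list(mk_run(0.7), mk_run(0.7)))
  expect_equal(select_best_run(rep2), 1)
  rep3 <- aggregate_runs(list(mk_run(0.4)))
  expect_equal(select_best_run(rep3), 1)
  expect_error(aggregate_runs(list()), "at least one")
})

test_that("baseline classifier: separable sanity, determinism, errors", {
  pair <- quadrant_pair()
  clf <- fit_baseline_classifier(pair, window = 5, seed = 3)
  acc <- numeric(0)
  for (im in pair) {
    pred <- predict_labels(clf, im)
    expect_identical(dim(pred), dim(im$mask))
    truth <- bccmorph:::class8_code(im$mask, im$subtype)
    acc <- c(acc, mean(pred == truth))
  }
  expect_gt(mean(acc), 0.95)
  clf2 <- fit_baseline_classifier(pair, window = 5, seed = 3)
  expect_identical(predict_labels(clf2, pair[[1]]),
                   predict_labels(clf, pair[[1]]))
  # training without the MN classes errors and names one of them
  expect_error(fit_baseline_classifier(pair[1], window = 5), "T-MN")
})

test_that("tiled inference covers the raster and matches untiled output", {
  pair <- quadrant_pair()
  clf <- fit_baseline_classifier(pair, window = 5, seed = 3)
  im <- pair[[1]]
  whole <- predict_labels(clf, im)
  big <- tiled_inference(clf, im, tile = 1000L, overlap = 10L)
  expect_identical(big, whole) # tile larger than image -> single call
  tiled <- tiled_inference(clf, im, tile = 48L, overlap = 8L)
  expect_identical(dim(tiled), dim(im$mask))
  expect_true(all(tiled %in% 1:8))
  # interior agreement is high; only window-truncation at tile borders
  # can differ
  expect_gt(mean(tiled == whole), 0.97)
  expect_error(tiled_inference(clf, im, tile = 8L, overlap = 8L),
               "overlap")
})

test_that("uniform patch mining follows the strict tile rule", {
  t <- matrix(1L, 30, 30)
  p <- matrix(1L, 30, 30)
  pix <- array(7L, dim = c(30, 30, 3))
  patches <- extract_uniform_patches(pix, t, p, size = 10)
  expect_length(patches, 9) # 3x3 tiling
  expect_identical(dim(patches[[1]]$pixels), c(10L, 10L, 3L))
  # a tile straddling a predicted-class boundary is excluded
  p2 <- p; p2[1:30, 5] <- 2L
  expect_length(extract_uniform_patches(pix, t, p2, size = 10), 6)
  # prediction uniform but wrong vs target -> excluded
  t3 <- t; t3[2, 2] <- 4L
  expect_length(extract_uniform_patches(pix, t3, p, size = 10), 8)
  # patch larger than image: empty, no error
  expect_length(extract_uniform_patches(pix, t, p, size = 100), 0)
})

test_that("label raster export/import round-trips and validates", {
  dir <- withr::local_tempdir()
  lab <- matrix(sample(0:8, 60, replace = TRUE), 6, 10)
  path <- file.path(dir, "pred.png")
  write_label_png(lab, path)
  back <- import_predictions(path, expected_dim = c(6, 10))
  expect_identical(back, lab)
  expect_error(import_predictions(path, expected_dim = c(10, 6)), "shape")
  bad <- matrix(17L, 4, 4)
  png::writePNG(bad / 255, path)
  expect_error(import_predictions(path), "17")
})

test_that("run_protocol is deterministic and aggregates consistently", {
  ds <- tiny_dataset(5, 5, 31)
  prot <- run_protocol(ds, runs = 2, seed = 9, window = 5,
                       samples_per_class = 150)
  prot2 <- run_protocol(ds, runs = 2, seed = 9, window = 5,
                        samples_per_class = 150)
  expect_equal(prot$report$mean_matrix, prot2$report$mean_matrix)
  expect_identical(prot$best_run, prot2$best_run)
  expect_identical(prot$best_confusion$counts, prot2$best_confusion$counts)
  expect_equal(prot$report$n_runs, 2)
  # macro average is the unweighted mean of per-class means
  expect_equal(unname(prot$report$macro["iou"]),
               mean(prot$report$mean_matrix[, "iou"]))
})
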