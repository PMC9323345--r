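# Repeated-resampling evaluation protocol: 70/15/15 splits, per-run
# metrics, mean/SD aggregation, macro averages and best-run selection.

#' Random train/validation/test split of image ids
#'
#' Sizes follow the floor/floor/remainder rule: `train = floor(f1 n)`,
#' `val = floor(f2 n)`, `test` the rest. Deterministic for a fixed seed.
#'
#' @param ids character vector of image ids (>= 3).
#' @param fractions length-3 numeric summing to 1 (default 0.70/0.15/0.15).
#' @param seed integer seed.
#' @return a `dataset_split`: list with disjoint `train`, `val`, `test`.
#' @export
split_dataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- length(ids)
  if (n < 3) stop("need at least 3 ids")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split produces an empty partition cell for n = ", n)
  perm <- with_seed(seed, sample(ids, n))
  structure(list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[n_train + n_val + seq_len(n_test)],
                 fractions = fractions, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Aggregate per-run per-class metrics into a run report
#'
#' Computes per-class mean and SD over runs for each metric, macro averages
#' (unweighted mean over the eight classes of the per-class means, with a
#' 2-decimal display version mirroring the conventional table layout) and
#' per-run macro rows used for best-run selection.
#'
#' @param reports list of per-run data frames from [all_class_metrics()].
#' @return a `run_report`.
#' @export
aggregate_runs <- function(reports) {
  if (!length(reports)) stop("need at least one run")
  metrics <- c("accuracy", "iou", "precision", "recall", "f1")
  classes <- reports[[1]]$class
  for (r in reports)
    if (!identical(r$class, classes))
      stop("inconsistent class sets across runs")
  arr <- vapply(reports, function(r) as.matrix(r[, metrics]),
                matrix(0, length(classes), length(metrics)))
  mean_mat <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sd_mat <- if (length(reports) > 1) apply(arr, c(1, 2), stats::sd,
                                           na.rm = TRUE)
            else matrix(0, length(classes), length(metrics))
  dimnames(mean_mat) <- dimnames(sd_mat) <- list(classes, metrics)
  macro <- colMeans(mean_mat, na.rm = TRUE)
  run_macro <- t(apply(arr, c(2, 3), mean, na.rm = TRUE))
  colnames(run_macro) <- metrics
  structure(list(per_run = reports,
                 mean = as.data.frame(cbind(class = classes,
                                            as.data.frame(mean_mat)),
                                      stringsAsFactors = FALSE),
                 sd = as.data.frame(cbind(class = classes,
                                          as.data.frame(sd_mat)),
                                    stringsAsFactors = FALSE),
                 mean_matrix = mean_mat, sd_matrix = sd_mat,
                 macro = macro, macro_display = round(macro, 2),
                 run_macro = as.data.frame(run_macro),
                 n_runs = length(reports)),
            class = "run_report")
}

#' Select the best run of a report
#'
#' Argmax of the per-run macro criterion (macro test IoU by default, the
#' field-standard segmentation criterion; accuracy or F1 selectable).
#' Ties break toward the lower run index.
#'
#' @param report a `run_report`.
#' @param criterion `"iou"`, `"accuracy"` or `"f1"`.
#' @return integer run index.
#' @export
select_best_run <- function(report, criterion = c("iou", "accuracy", "f1")) {
  stopifnot(inherits(report, "run_report"))
  criterion <- match.arg(criterion)
  which.max(report$run_macro[[criterion]])
}

#' Run the full resampling evaluation protocol
#'
#' For each run: split the ids 70/15/15, fit the baseline classifier on the
#' training images, predict every test image and accumulate a test-set
#' confusion matrix and per-class metrics. Aggregates over runs, selects
#' the best run and re-applies its classifier to the whole dataset (the
#' confusion matrix conventionally reported for the best model). The whole
#' protocol is a deterministic function of the master seed. The validation
#' cell is reserved by the split contract; the LDA baseline has no
#' early-stopping use for it.
#'
#' @param images list of `labeled_image`s.
#' @param runs number of resampling runs (100 at full scale; keep ~10 at
#'   desk scale).
#' @param fractions split fractions.
#' @param seed master seed; per-run seeds are derived from it.
#' @param window,samples_per_class baseline classifier settings.
#' @param best_criterion criterion handed to [select_best_run()].
#' @return a `segmentation_protocol`: list with `report` (a `run_report`),
#'   `best_run`, `best_classifier`, `best_confusion` (whole-dataset),
#'   per-run `confusions` and `splits`.
#' @export
run_protocol <- function(images, runs = 10L, fractions = c(0.70, 0.15, 0.15),
                         seed = 1L, window = 9L, samples_per_class = 400L,
                         best_criterion = "iou") {
  if (runs < 1) stop("runs must be >= 1")
  ids <- vapply(images, `[[`, "", "image_id")
  names(images) <- ids
  per_run <- vector("list", runs)
  confusions <- vector("list", runs)
  splits <- vector("list", runs)
  classifiers <- vector("list", runs)
  for (r in seq_len(runs)) {
    sr <- derive_seed(seed, r)
    sp <- split_dataset(ids, fractions, seed = sr)
    clf <- fit_baseline_classifier(images[sp$train], window = window,
                                   samples_per_class = samples_per_class,
                                   seed = derive_seed(sr, 1L))
    counts <- matrix(0L, 8, 8)
    for (id in sp$test) {
      im <- images[[id]]
      pred <- predict_labels(clf, im)
      cm <- confusion_matrix(class8_code(im$mask, im$subtype), pred)
      counts <- counts + cm$counts
    }
    cm_run <- structure(list(counts = counts, classes = bcc_classes()),
                        class = "confusion_matrix")
    per_run[[r]] <- all_class_metrics(cm_run)
    confusions[[r]] <- cm_run
    splits[[r]] <- sp
    classifiers[[r]] <- clf
  }
  report <- aggregate_runs(per_run)
  best <- select_best_run(report, best_criterion)
  best_clf <- classifiers[[best]]
  counts <- matrix(0L, 8, 8)
  for (im in images) {
    pred <- predict_labels(best_clf, im)
    cm <- confusion_matrix(class8_code(im$mask, im$subtype), pred)
    counts <- counts + cm$counts
  }
  best_cm <- structure(list(counts = counts, classes = bcc_classes()),
                       class = "confusion_matrix")
  structure(list(report = report, best_run = best,
                 best_classifier = best_clf, best_confusion = best_cm,
                 confusions = confusions, splits = splits,
                 seed = as.integer(seed), runs = as.integer(runs)),
            class = "segmentation_protocol")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d run(s); macro means:\n", x$n_runs))
  print(x$macro_display)
  invisible(x)
}

#' Reference per-class segmentation benchmark tables
#'
#' The published per-class metric table (accuracy/IoU/F1 for the eight
#' component-by-subtype classes) and the row-normalized confusion matrix of
#' the best network from the original clinical N/MN evaluation, shipped as
#' plain CSVs. Used for in-table arithmetic (macro averaging, diagonal and
#' column queries); the per-class values themselves depend on the
#' undeposited clinical images and are not reproduction targets.
#'
#' @return list with `metrics` (data frame, 8 rows) and `confusion`
#'   (8x8 numeric matrix, rows = target classes).
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", package = "bccmorph")
  metrics <- utils::read.csv(file.path(dir,
                                       "reference_segmentation_metrics.csv"),
                             stringsAsFactors = FALSE, check.names = FALSE)
  conf <- utils::read.csv(file.path(dir, "reference_confusion_normalized.csv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  cm <- as.matrix(conf[, -1])
  rownames(cm) <- conf[[1]]
  list(metrics = metrics, confusion = cm)
}
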