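# Pixel-level segmentation evaluation calculus: 8-class confusion matrices
# and the accuracy / IoU / precision / recall / F1 metric family.

#' Pixel-level confusion matrix over the eight classes
#'
#' `counts[t, p]` is the number of pixels with target class `t` and
#' predicted class `p` (classes in [bcc_classes()] order). Unannotated
#' pixels (target code 0) are excluded; predicted code 0 on an annotated
#' pixel is dropped with a warning.
#'
#' @param target,predicted integer label rasters of identical shape with
#'   codes in 0..8.
#' @return a `confusion_matrix`: list with `counts` (8x8) and `classes`.
#' @export
confusion_matrix <- function(target, predicted) {
  if (!identical(dim(target), dim(predicted)))
    stop("target and predicted rasters have different shapes")
  t <- as.integer(target); p <- as.integer(predicted)
  if (any(t < 0 | t > 8) || any(p < 0 | p > 8))
    stop("label codes must be in 0..8")
  keep <- t > 0L
  if (!any(keep)) stop("no annotated pixels")
  t <- t[keep]; p <- p[keep]
  if (any(p == 0L)) {
    warning(sum(p == 0L), " annotated pixels predicted as background; dropped")
    t <- t[p > 0L]; p <- p[p > 0L]
  }
  counts <- matrix(tabulate((t - 1L) * 8L + p, nbins = 64L), 8, 8,
                   byrow = TRUE, dimnames = list(target = bcc_classes(),
                                                 predicted = bcc_classes()))
  structure(list(counts = counts, classes = bcc_classes()),
            class = "confusion_matrix")
}

#' Row-normalized view of a confusion matrix
#'
#' Each row is divided by its sum, so the diagonal equals per-class recall.
#' Rows with no pixels come back as `NA`.
#'
#' @param cm a `confusion_matrix` (or a bare 8x8 count matrix).
#' @return 8x8 numeric matrix whose positive rows sum to 1.
#' @export
cm_normalized <- function(cm) {
  counts <- if (inherits(cm, "confusion_matrix")) cm$counts else cm
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' One-vs-rest metrics for a single class
#'
#' Direct substitution of the one-vs-rest pixel counts into the defining
#' formulas: accuracy `(TP+TN)/(TP+TN+FP+FN)`, IoU `TP/(TP+FP+FN)`,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1
#' `2 * precision * recall / (precision + recall)`. A class absent from
#' both target and prediction yields flagged `NA`s.
#'
#' @param cm a `confusion_matrix`.
#' @param class class name (see [bcc_classes()]) or code 1-8.
#' @return list with `TP`, `TN`, `FP`, `FN` and the five metrics.
#' @export
class_metrics <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- if (is.character(class)) match(class, cm$classes) else as.integer(class)
  if (is.na(k) || k < 1 || k > 8) stop("unknown class: ", class)
  cts <- cm$counts
  total <- sum(cts)
  TP <- cts[k, k]
  FP <- sum(cts[, k]) - TP
  FN <- sum(cts[k, ]) - TP
  TN <- total - TP - FP - FN
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- sdiv(TP, TP + FP)
  rec <- sdiv(TP, TP + FN)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    if (TP + FP + FN == 0) NA_real_ else 0
  } else 2 * prec * rec / (prec + rec)
  list(class = cm$classes[k], TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = sdiv(TP + TN, total),
       iou = sdiv(TP, TP + FP + FN),
       precision = prec, recall = rec, f1 = f1,
       undefined = (TP + FP + FN) == 0)
}

#' Metrics for all eight classes of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return data frame with one row per class: counts and the five metrics.
#' @export
all_class_metrics <- function(cm) {
  rows <- lapply(seq_along(bcc_classes()), function(k) {
    m <- class_metrics(cm, k)
    data.frame(class = m$class, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               accuracy = m$accuracy, iou = m$iou, precision = m$precision,
               recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-subtype confusion per component
#'
#' For each component, the mean of the two row-normalized entries linking
#' its N and MN classes (e.g. `T-N` predicted `T-MN` and vice versa) -- the
#' quantity used to judge how often the classifier mixes up the subtypes
#' within a component.
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector over `T`, `TT`, `PC`, `S`.
#' @export
cross_subtype_confusion <- function(cm) {
  nm <- cm_normalized(cm)
  out <- vapply(1:4, function(i) mean(c(nm[i, i + 4], nm[i + 4, i])), 0)
  stats::setNames(out, component_names())
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> row-normalized:\n")
  print(round(cm_normalized(x), 2))
  invisible(x)
}
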