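# Per-component, per-feature two-sample t-test screening between subtypes.

#' Classical two-sample Student's t-test
#'
#' Two-sided, pooled-variance by default (`var_equal = FALSE` switches to
#' the Welch form -- a config hook, not the default convention). Degenerate
#' zero-variance cases are resolved explicitly: equal means give `p = 1`,
#' unequal means `p = 0` with a degeneracy flag.
#'
#' @param a,b numeric samples; `NA`s are dropped. Each needs >= 2 values.
#' @param alpha significance level used for the `significant` flag.
#' @param var_equal pooled variance (classical Student) when `TRUE`.
#' @return a `t_test_result`: list with `t`, `df`, `p`, `n_a`, `n_b`,
#'   `significant`, `degenerate`, `missing`.
#' @export
student_t_test <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  res <- list(t = NA_real_, df = NA_real_, p = NA_real_,
              n_a = n1, n_b = n2, significant = NA,
              degenerate = FALSE, missing = FALSE)
  class(res) <- "t_test_result"
  if (n1 < 2 || n2 < 2) {
    res$missing <- TRUE
    return(res)
  }
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0)
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else NA_real_
  }
  if (!is.finite(se) || se == 0) {
    res$degenerate <- TRUE
    res$df <- df
    if (isTRUE(all.equal(m1, m2))) {
      res$t <- 0; res$p <- 1
    } else {
      res$t <- sign(m1 - m2) * Inf; res$p <- 0
    }
  } else {
    res$t <- (m1 - m2) / se
    res$df <- df
    res$p <- 2 * stats::pt(-abs(res$t), df)
  }
  res$significant <- is.finite(res$p) && res$p < alpha
  res
}

#' Per-component significance screening of the feature table
#'
#' For each morphological component, runs one two-sample t-test per feature
#' (14 Haralick + 3 moments) between the N and MN groups, counts the
#' significantly different Haralick features (0-14) and flags the
#' significant moments. No multiple-testing correction is applied -- the
#' per-feature counting design is the object of study. Components present
#' in only one subtype are omitted with a warning; missing feature values
#' are dropped pairwise.
#'
#' @param table a feature table from [build_feature_table()].
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @return a `significance_report`: list with `tests` (long data frame:
#'   component, feature, t, p, n_N, n_MN, significant), `haralick_counts`
#'   (named integer vector), `moment_flags` (data frame) and `alpha`.
#' @export
significance_report <- function(table, alpha = 0.05, var_equal = TRUE) {
  stopifnot(is.data.frame(table),
            all(c("subtype", "component") %in% names(table)))
  feats <- c(haralick_feature_names(), moment_feature_names())
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols))
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  comps <- intersect(component_names(), unique(table$component))
  tests <- list()
  counts <- integer(0)
  for (comp in comps) {
    sub <- table[table$component == comp, ]
    if (!all(c("N", "MN") %in% sub$subtype)) {
      warning("component ", comp, " present in only one subtype; omitted")
      next
    }
    for (f in feats) {
      tt <- student_t_test(sub[[f]][sub$subtype == "N"],
                           sub[[f]][sub$subtype == "MN"],
                           alpha = alpha, var_equal = var_equal)
      tests[[length(tests) + 1L]] <- data.frame(
        component = comp, feature = f, t = tt$t, p = tt$p,
        n_N = tt$n_a, n_MN = tt$n_b,
        significant = isTRUE(tt$significant),
        degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }
    done <- do.call(rbind, tests)
    hsub <- done[done$component == comp &
                   done$feature %in% haralick_feature_names(), ]
    counts[comp] <- sum(hsub$significant)
  }
  tests <- do.call(rbind, tests)
  moment_flags <- if (!is.null(tests))
    tests[tests$feature %in% moment_feature_names(),
          c("component", "feature", "p", "significant")] else NULL
  structure(list(tests = tests, haralick_counts = counts,
                 moment_flags = moment_flags, alpha = alpha,
                 components = names(counts)),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat("Significantly different Haralick features per component (alpha =",
      x$alpha, "):\n")
  for (comp in names(x$haralick_counts))
    cat(sprintf("  %-3s %2d / 14\n", comp, x$haralick_counts[[comp]]))
  invisible(x)
}

#' Write a significance report to CSV files
#'
#' `counts.csv` mirrors the one-row-per-component count layout;
#' `tests_long.csv` holds the full long-format test results.
#'
#' @param report a `significance_report`.
#' @param directory output directory.
#' @return invisibly, the paths written.
#' @export
write_significance_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(directory, "counts.csv")
  utils::write.csv(data.frame(component = names(report$haralick_counts),
                              n_significant_haralick =
                                as.integer(report$haralick_counts)),
                   counts_path, row.names = FALSE)
  tests_path <- file.path(directory, "tests_long.csv")
  utils::write.csv(report$tests, tests_path, row.names = FALSE)
  invisible(c(counts_path, tests_path))
}
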