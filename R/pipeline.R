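# End-to-end experiment orchestration: config, staged execution, report
# bundle. Each stage derives its own child seed from the master seed, so
# stages are independently rerunnable and `all` equals running the
# subcommands in sequence.

#' Build and validate a pipeline configuration
#'
#' @param dataset a [synthetic_spec()] or a list of arguments for it
#'   (e.g. `list(preset = "desk", n_nodular = 40, n_micronodular = 40)`).
#' @param alpha significance level for the feature screening.
#' @param glcm_levels co-occurrence quantization levels.
#' @param runs resampling runs for the segmentation protocol.
#' @param fractions train/val/test fractions.
#' @param window,samples_per_class baseline classifier settings.
#' @param tile,overlap tiled-inference settings (recorded; applied by the
#'   tiling helper).
#' @param patch_size uniform-patch side in pixels.
#' @param max_patches cap on patches written to the gallery.
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir output directory for [run_experiment()].
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(dataset = list(preset = "desk", n_nodular = 40,
                                           n_micronodular = 40),
                            alpha = 0.05, glcm_levels = 9L, runs = 10L,
                            fractions = c(0.70, 0.15, 0.15), window = 9L,
                            samples_per_class = 400L, tile = 256L,
                            overlap = 32L, patch_size = 100L,
                            max_patches = 24L, seed = 1L,
                            out_dir = "bccmorph_out") {
  if (inherits(dataset, "synthetic_spec")) {
    spec_args <- unclass(dataset)
  } else {
    spec_args <- dataset
  }
  cfg <- structure(list(dataset = spec_args, alpha = alpha,
                        glcm_levels = as.integer(glcm_levels),
                        runs = as.integer(runs), fractions = fractions,
                        window = as.integer(window),
                        samples_per_class = as.integer(samples_per_class),
                        tile = as.integer(tile),
                        overlap = as.integer(overlap),
                        patch_size = as.integer(patch_size),
                        max_patches = as.integer(max_patches),
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$runs < 1) stop("config invalid: runs must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config invalid: alpha must be in (0, 1)")
  if (cfg$glcm_levels < 2) stop("config invalid: glcm_levels must be >= 2")
  if (cfg$tile <= cfg$overlap || cfg$overlap < 0)
    stop("config invalid: need tile > overlap >= 0")
  if (cfg$patch_size < 1) stop("config invalid: patch_size must be >= 1")
  config_spec(cfg) # validates the dataset spec too
  invisible(cfg)
}

# The dataset spec with the generation-stage child seed patched in.
config_spec <- function(cfg) {
  args <- cfg$dataset
  args$seed <- derive_seed(cfg$seed, 1L)
  do.call(synthetic_spec, args)
}

#' Read / write pipeline configurations as YAML
#'
#' A round-tripped config reproduces the run bit-identically.
#' @param path YAML file path.
#' @param cfg a `pipeline_config`.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list() # empty file -> all defaults
  if (!is.list(raw)) stop("config file must hold a YAML mapping: ", path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  lst$dataset <- lst$dataset[!vapply(lst$dataset, is.null, TRUE)]
  if (!is.null(lst$dataset$texture_divergence))
    lst$dataset$texture_divergence <-
      as.list(lst$dataset$texture_divergence)
  yaml::write_yaml(lst, path)
  invisible(path)
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  message(msg)
}

# -- stages ---------------------------------------------------------------

stage_generate <- function(cfg, log_path = NULL) {
  spec <- config_spec(cfg)
  images <- generate_dataset(spec)
  write_dataset(images, file.path(cfg$out_dir, "dataset"))
  if (!is.null(log_path))
    log_line(log_path, "generate: ", length(images), " images -> dataset/")
  invisible(images)
}

stage_features <- function(cfg, images = NULL, log_path = NULL) {
  images <- images %||% read_dataset(file.path(cfg$out_dir, "dataset"))
  tab <- build_feature_table(images, levels = cfg$glcm_levels)
  utils::write.csv(tab, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(log_path))
    log_line(log_path, "features: ", nrow(tab), " rows -> features.csv")
  invisible(tab)
}

stage_stats <- function(cfg, table = NULL, log_path = NULL) {
  table <- table %||% utils::read.csv(file.path(cfg$out_dir, "features.csv"),
                                      stringsAsFactors = FALSE)
  rep <- significance_report(table, alpha = cfg$alpha)
  utils::write.csv(
    data.frame(component = names(rep$haralick_counts),
               n_significant_haralick = as.integer(rep$haralick_counts)),
    file.path(cfg$out_dir, "table1_analog.csv"), row.names = FALSE)
  utils::write.csv(rep$tests, file.path(cfg$out_dir, "tests_long.csv"),
                   row.names = FALSE)
  if (!is.null(log_path))
    log_line(log_path, "stats: counts ",
             paste(names(rep$haralick_counts), rep$haralick_counts,
                   sep = "=", collapse = " "))
  invisible(rep)
}

stage_segeval <- function(cfg, images = NULL, log_path = NULL) {
  images <- images %||% read_dataset(file.path(cfg$out_dir, "dataset"))
  prot <- run_protocol(images, runs = cfg$runs, fractions = cfg$fractions,
                       seed = derive_seed(cfg$seed, 4L),
                       window = cfg$window,
                       samples_per_class = cfg$samples_per_class)
  rep <- prot$report
  disp <- data.frame(class = rep$mean$class,
                     accuracy = sprintf("%.2f (%.2f)",
                                        rep$mean_matrix[, "accuracy"],
                                        rep$sd_matrix[, "accuracy"]),
                     iou = sprintf("%.2f (%.2f)", rep$mean_matrix[, "iou"],
                                   rep$sd_matrix[, "iou"]),
                     f1 = sprintf("%.2f (%.2f)", rep$mean_matrix[, "f1"],
                                  rep$sd_matrix[, "f1"]),
                     recall_diag = sprintf("%.2f",
                                           rep$mean_matrix[, "recall"]),
                     stringsAsFactors = FALSE)
  disp <- rbind(disp, data.frame(
    class = "AVERAGE",
    accuracy = sprintf("%.2f", rep$macro_display[["accuracy"]]),
    iou = sprintf("%.2f", rep$macro_display[["iou"]]),
    f1 = sprintf("%.2f", rep$macro_display[["f1"]]),
    recall_diag = sprintf("%.2f", rep$macro_display[["recall"]])))
  utils::write.csv(disp, file.path(cfg$out_dir, "table2_analog.csv"),
                   row.names = FALSE)
  full <- cbind(rep$mean[, "class", drop = FALSE],
                stats::setNames(as.data.frame(rep$mean_matrix),
                                paste0(colnames(rep$mean_matrix), "_mean")),
                stats::setNames(as.data.frame(rep$sd_matrix),
                                paste0(colnames(rep$sd_matrix), "_sd")))
  utils::write.csv(full, file.path(cfg$out_dir, "table2_fullprec.csv"),
                   row.names = FALSE)
  nm <- cm_normalized(prot$best_confusion)
  utils::write.csv(data.frame(class = rownames(nm), round(nm, 2),
                              check.names = FALSE),
                   file.path(cfg$out_dir, "table3_analog.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(class = rownames(nm), nm, check.names = FALSE),
                   file.path(cfg$out_dir, "table3_fullprec.csv"),
                   row.names = FALSE)
  if (!is.null(log_path))
    log_line(log_path, "segeval: ", cfg$runs, " runs, best run ",
             prot$best_run, ", macro IoU ",
             sprintf("%.3f", rep$macro[["iou"]]))
  invisible(prot)
}

stage_report <- function(cfg, images = NULL, prot = NULL, log_path = NULL) {
  images <- images %||% read_dataset(file.path(cfg$out_dir, "dataset"))
  patch_dir <- file.path(cfg$out_dir, "patches")
  dir.create(patch_dir, recursive = TRUE, showWarnings = FALSE)
  n_written <- 0L
  if (!is.null(prot)) {
    for (im in images) {
      if (n_written >= cfg$max_patches) break
      pred <- predict_labels(prot$best_classifier, im)
      patches <- extract_uniform_patches(im$pixels,
                                         class8_code(im$mask, im$subtype),
                                         pred, size = cfg$patch_size)
      for (p in patches) {
        if (n_written >= cfg$max_patches) break
        fn <- sprintf("%s_%s_r%d_c%d.png", im$image_id,
                      gsub("-", "", bcc_classes()[p$class]), p$row, p$col)
        png::writePNG(p$pixels / 255, file.path(patch_dir, fn))
        n_written <- n_written + 1L
      }
    }
  }
  write_config(cfg, file.path(cfg$out_dir, "config_snapshot.yml"))
  if (!is.null(log_path))
    log_line(log_path, "report: ", n_written, " uniform patches -> patches/")
  invisible(n_written)
}

#' Run the full experiment
#'
#' Executes generate -> features -> stats -> segeval -> report in order,
#' deterministically for the master seed, and writes the report bundle:
#' the component-count table analog, the per-class metric table analog
#' (2-decimal display plus full-precision companion), the best-run
#' confusion analog, a uniform-patch gallery, a config snapshot and a run
#' log.
#'
#' @param config a `pipeline_config`.
#' @return a `report_bundle`: named list of artifact paths.
#' @export
run_experiment <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  images <- stage_generate(config, log_path)
  stage_features(config, images, log_path)
  # stats always consumes the serialized table so that running the
  # subcommands in sequence is bit-identical to this composite run
  stage_stats(config, log_path = log_path)
  prot <- stage_segeval(config, images, log_path)
  stage_report(config, images, prot, log_path)
  out <- config$out_dir
  structure(list(
    table1 = file.path(out, "table1_analog.csv"),
    tests_long = file.path(out, "tests_long.csv"),
    table2 = file.path(out, "table2_analog.csv"),
    table2_fullprec = file.path(out, "table2_fullprec.csv"),
    table3 = file.path(out, "table3_analog.csv"),
    table3_fullprec = file.path(out, "table3_fullprec.csv"),
    features = file.path(out, "features.csv"),
    dataset = file.path(out, "dataset"),
    patches = file.path(out, "patches"),
    config_snapshot = file.path(out, "config_snapshot.yml"),
    log = log_path), class = "report_bundle")
}
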