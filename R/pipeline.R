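#' End-to-end run configuration
#'
#' Bundles the per-stage configurations plus the run-level choices (window
#' length, subject split sizes, image size, augmentation) under one global
#' seed.  Per-stage seeds are derived deterministically from the global seed
#' unless a stage config is supplied explicitly, so a run is a pure function
#' of its configuration.
#'
#' @param seed Global integer seed.
#' @param window_s Segment window in seconds (3 or 5).
#' @param n_train_subjects,n_test_subjects Subject split sizes.
#' @param image_size Rendered scalogram side length in pixels.  224 is the
#'   reference size; smaller sizes give proportionally faster desk-scale
#'   runs.
#' @param augment Add one white-Gaussian-noise copy per training image.
#' @param preprocess Apply the preprocessing chain; `FALSE` is the ablation
#'   that feeds scalograms of the raw infrared channel to the classifier.
#' @param generator,prep,morse,cnn,augmentation Optional stage
#'   configurations ([generator_config()], [preprocess_config()],
#'   [morse_params()], [cnn_config()], [augment_config()]); defaults are
#'   derived from `seed`.
#' @param out_dir Output directory for run artifacts, or `NULL` to keep the
#'   run in memory.
#' @param save_scalograms Also write every rendered scalogram as PNG (slow
#'   for full-size runs; the index JSON is always written when `out_dir` is
#'   set).
#' @param verbose Log stage progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       window_s = 5,
                       n_train_subjects = 11,
                       n_test_subjects = 3,
                       image_size = 224,
                       augment = FALSE,
                       preprocess = TRUE,
                       generator = NULL,
                       prep = NULL,
                       morse = NULL,
                       cnn = NULL,
                       augmentation = NULL,
                       out_dir = NULL,
                       save_scalograms = FALSE,
                       verbose = FALSE) {
  if (!window_s %in% c(3, 5)) {
    stop("`window_s` must be 3 or 5", call. = FALSE)
  }
  generator <- generator %||% generator_config(seed = derive_seed(seed, "synth"))
  prep <- prep %||% preprocess_config()
  morse <- morse %||% morse_params()
  cnn <- cnn %||% cnn_config(input_shape = c(image_size, image_size, 3),
                             seed = derive_seed(seed, "cnn"))
  augmentation <- augmentation %||%
    augment_config(seed = derive_seed(seed, "augment"))
  if (!all(cnn$input_shape[1:2] == image_size)) {
    stop("`cnn$input_shape` must match `image_size`", call. = FALSE)
  }
  if (n_train_subjects + n_test_subjects != generator$n_subjects) {
    stop("subject split sizes must sum to `generator$n_subjects`",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), window_s = window_s,
         n_train_subjects = as.integer(n_train_subjects),
         n_test_subjects = as.integer(n_test_subjects),
         image_size = as.integer(image_size), augment = isTRUE(augment),
         preprocess = isTRUE(preprocess),
         generator = generator, prep = prep, morse = morse, cnn = cnn,
         augmentation = augmentation, out_dir = out_dir,
         save_scalograms = isTRUE(save_scalograms),
         verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Render a list of segments as CNN-ready images
#'
#' Applies the Morse CWT to every segment and renders each magnitude matrix
#' at `size x size x 3`.
#'
#' @param segments List of `ppg_segment` objects (equal lengths).
#' @param morse A [morse_params()].
#' @param size Image side length in pixels.
#' @return A list with `images` (`size x size x 3 x N` array) and `labels`
#'   (1 = stressed).
#' @export
segments_to_images <- function(segments, morse = morse_params(), size = 224) {
  if (!length(segments)) stop("no segments supplied", call. = FALSE)
  n_samp <- length(segments[[1]]$samples)
  fs <- segments[[1]]$fs
  bank <- morse_filterbank(morse, n_samp, fs)
  images <- array(0, dim = c(size, size, 3L, length(segments)))
  for (i in seq_along(segments)) {
    scal <- cwt_morse(segments[[i]]$samples, bank)
    images[, , , i] <- render_scalogram(scal, size = size)
  }
  list(images = images, labels = segment_labels(segments))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[earppg] %s", sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes synthesis, preprocessing, subject-disjoint splitting,
#' segmentation, scalogram rendering, (optional) augmentation, CNN training
#' and evaluation in order, and returns the evaluation report together with
#' all intermediate bookkeeping.  With `cfg$out_dir` set, the run
#' configuration, preprocessing report, training history, segment index and
#' evaluation report are written as JSON/CSV artifacts (plus PNG scalograms
#' when `save_scalograms` is enabled); rerunning with an identical
#' configuration rewrites identical CSV/JSON artifacts.
#'
#' @param cfg A [run_config()].
#' @return A list of class `pipeline_result` with `report` (an
#'   [eval_report()]), `model`, `split`, `segment_counts`, `train_size`
#'   (after augmentation), `preprocess_summary` (axis and `|r|` per
#'   recording) and the echoed `config`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()

  log_stage(cfg$verbose, "generating %d subjects x 2 conditions",
            cfg$generator$n_subjects)
  recordings <- generate_dataset(cfg$generator)

  if (cfg$preprocess) {
    log_stage(cfg$verbose, "preprocessing %d recordings", length(recordings))
    clean <- lapply(recordings, preprocess_recording, cfg = cfg$prep)
  } else {
    log_stage(cfg$verbose, "ablation: skipping preprocessing (raw IR channel)")
    clean <- lapply(recordings, function(rec) {
      structure(
        list(subject_id = rec$subject_id, condition = rec$condition,
             fs = rec$fs, signal = rec$ppg_ir,
             reference_axis_used = "none", r_max = NA_real_,
             r_per_axis = c(x = NA_real_, y = NA_real_, z = NA_real_)),
        class = "clean_ppg"
      )
    })
  }
  preprocess_summary <- data.frame(
    subject_id = vapply(clean, `[[`, character(1), "subject_id"),
    condition = vapply(clean, `[[`, character(1), "condition"),
    reference_axis = vapply(clean, `[[`, character(1),
                            "reference_axis_used"),
    r_max = vapply(clean, `[[`, numeric(1), "r_max")
  )

  split <- split_subjects(clean, cfg$n_train_subjects, cfg$n_test_subjects,
                          seed = derive_seed(cfg$seed, "split"))
  seg_set <- build_segment_set(clean, cfg$window_s, split)
  log_stage(cfg$verbose, "segments: %d train / %d test (%g s windows)",
            length(seg_set$train), length(seg_set$test), cfg$window_s)

  log_stage(cfg$verbose, "rendering scalograms at %d px", cfg$image_size)
  train_data <- segments_to_images(seg_set$train, cfg$morse, cfg$image_size)
  test_data <- segments_to_images(seg_set$test, cfg$morse, cfg$image_size)

  if (cfg$augment) {
    aug <- augment_with_noise(train_data$images, train_data$labels,
                              cfg$augmentation)
    train_data <- list(images = aug$images, labels = aug$labels)
    log_stage(cfg$verbose, "augmented training set to %d images",
              length(train_data$labels))
  }

  log_stage(cfg$verbose, "training CNN (%s, lr %g, <= %d epochs)",
            cfg$cnn$optimizer, cfg$cnn$learning_rate, cfg$cnn$max_epochs)
  model <- build_cnn(cfg$cnn)
  model <- train_cnn(model, train_data$images, train_data$labels,
                     verbose = cfg$verbose)

  probs <- predict_cnn(model, test_data$images)
  report <- eval_report(test_data$labels, probs)
  log_stage(cfg$verbose, "test accuracy %.2f%%, AUC %.3f",
            report$accuracy, report$auc)

  result <- structure(
    list(report = report,
         model = model,
         split = split,
         segment_counts = c(train = length(seg_set$train),
                            test = length(seg_set$test)),
         train_size = length(train_data$labels),
         preprocess_summary = preprocess_summary,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
         config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(cfg$out_dir)) {
    write_run_artifacts(result, seg_set, train_data, test_data)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d/%d segments, train size %d, %.1f s\n",
              x$segment_counts["train"], x$segment_counts["test"],
              x$train_size, x$elapsed_s))
  print(x$report)
  invisible(x)
}

config_as_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

write_run_artifacts <- function(result, seg_set, train_data, test_data) {
  cfg <- result$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config_as_list(cfg),
                       file.path(cfg$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(result$preprocess_summary,
                       file.path(cfg$out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(result$model$history,
            file.path(cfg$out_dir, "training_history.csv"),
            row.names = FALSE)
  index <- do.call(rbind, lapply(c(seg_set$train, seg_set$test), function(s) {
    data.frame(subject_id = s$subject_id, condition = s$condition,
               offset = s$offset, window_s = s$window_s)
  }))
  index$role <- rep(c("train", "test"),
                    c(length(seg_set$train), length(seg_set$test)))
  jsonlite::write_json(index, file.path(cfg$out_dir, "segment_index.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(eval_report_as_list(result$report),
                       file.path(cfg$out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(result$report$roc, file.path(cfg$out_dir, "roc_points.csv"),
            row.names = FALSE)
  if (cfg$save_scalograms) {
    img_dir <- file.path(cfg$out_dir, "scalograms")
    dir.create(img_dir, showWarnings = FALSE)
    save_batch <- function(data, prefix) {
      for (i in seq_len(dim(data$images)[4])) {
        write_scalogram_png(
          data$images[, , , i],
          file.path(img_dir, sprintf("%s_%05d_label%d.png", prefix, i,
                                     data$labels[i])))
      }
    }
    save_batch(train_data, "train")
    save_batch(test_data, "test")
  }
  invisible(result)
}
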