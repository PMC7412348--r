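#' Pipeline run configuration
#'
#' Bundles every stage parameter of the simulate -> trim/window -> recurrence
#' plot -> PCA -> features -> classify/evaluate pipeline. The config is
#' serialized verbatim into the run directory, and a rerun under an
#' identical config and seed reproduces identical deterministic artifacts.
#'
#' @param seed master seed for the simulation stage.
#' @param subjects_per_class,duration,fs cohort size and trace geometry
#'   passed to [simulate_cohort()].
#' @param profiles class profiles (default [ndd_profiles()]).
#' @param exclusions subject ids removed after simulation/ingest, mirroring
#'   an explicit corrupt-record exclusion list.
#' @param input_dir optional directory of existing three-column records to
#'   ingest instead of simulating (file stem = subject id; labels read from
#'   `manifest.csv` when present).
#' @param windowing a [windowing_params()].
#' @param resolution recurrence-plot image side length in pixels.
#' @param pca logical: apply full-PC feature enhancement between the
#'   recurrence-plot and feature-extraction stages (flowchart order).
#' @param pca_center center pixels before the scatter decomposition
#'   (default `FALSE`: the scatter matrix is literally `t(X) %*% X`).
#' @param extractor a [feature_extractor()]; its `input_size` should match
#'   `resolution`.
#' @param classifier an [svm_spec()].
#' @param cv_unit `"window"` (comparable to published tables, leaks subject
#'   identity) or `"subject"` (honest generalization).
#' @param channels force channels to evaluate, subset of LF/RF/CF.
#' @param tasks `"all"` for the seven two-class tasks plus the four-class
#'   task, or a character subset of task names (see [ndd_task_grid()]),
#'   optionally including `"multiclass"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, subjects_per_class = 4L,
                            duration = 300, fs = 300,
                            profiles = ndd_profiles(),
                            exclusions = character(),
                            input_dir = NULL,
                            windowing = windowing_params(),
                            resolution = 227L,
                            pca = TRUE, pca_center = FALSE,
                            extractor = NULL,
                            classifier = svm_spec(),
                            cv_unit = c("window", "subject"),
                            channels = c("LF", "RF", "CF"),
                            tasks = "all") {
  cv_unit <- match.arg(cv_unit)
  channels <- match.arg(channels, c("LF", "RF", "CF"), several.ok = TRUE)
  extractor <- extractor %||% feature_extractor("tiny-cnn-test",
                                                input_size = resolution)
  stopifnot(inherits(windowing, "windowing_params"),
            inherits(classifier, "svm_spec"),
            inherits(extractor, "feature_extractor_spec"))
  structure(list(seed = as.integer(seed),
                 subjects_per_class = as.integer(subjects_per_class),
                 duration = duration, fs = fs, profiles = profiles,
                 exclusions = exclusions, input_dir = input_dir,
                 windowing = windowing, resolution = as.integer(resolution),
                 pca = isTRUE(pca), pca_center = isTRUE(pca_center),
                 extractor = extractor, classifier = classifier,
                 cv_unit = cv_unit, channels = channels, tasks = tasks),
            class = "pipeline_config")
}

#' The experiment grid of classification tasks
#'
#' The seven two-class tasks (three disease-vs-control, three
#' disease-vs-disease, and pooled NDD-vs-control) evaluated per force
#' channel. The pooled task relabels every disease window as `NDD`.
#'
#' @return list of task descriptors (`name`, `classes`, `positive`, `pool`).
#' @export
ndd_task_grid <- function() {
  list(
    list(name = "ALS vs. HC", classes = c("ALS", "HC"), positive = "ALS",
         pool = FALSE),
    list(name = "HD vs. HC", classes = c("HD", "HC"), positive = "HD",
         pool = FALSE),
    list(name = "PD vs. HC", classes = c("PD", "HC"), positive = "PD",
         pool = FALSE),
    list(name = "ALS vs. HD", classes = c("ALS", "HD"), positive = "ALS",
         pool = FALSE),
    list(name = "PD vs. ALS", classes = c("PD", "ALS"), positive = "PD",
         pool = FALSE),
    list(name = "HD vs. PD", classes = c("HD", "PD"), positive = "HD",
         pool = FALSE),
    list(name = "NDD vs. HC", classes = c("ALS", "PD", "HD", "HC"),
         positive = "NDD", pool = TRUE)
  )
}

#' Run the full pipeline
#'
#' Executes the requested stages in order, writing every stage's artifacts
#' and a content-hash manifest under `out_dir`. A stage is recomputed only
#' when its parameters or upstream artifacts changed, so
#' `run_pipeline(cfg, dir, stages = "rp")` resumes from cached windows.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "window", "rp", "pca", "features", "evaluate")`, or
#'   `"all"`. Requested stages pull any missing upstream stage in.
#' @return invisibly, the evaluation report (also written as
#'   `report.json` and `summary.csv`).
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "window", "rp", "pca", "features", "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # pull in everything up to the latest requested stage
  stages <- all_stages[seq_len(max(match(stages, all_stages)))]
  dir.create(file.path(out_dir, "stages"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(config_summary(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)

  cohort <- run_stage(out_dir, "simulate",
                      params = config[c("seed", "subjects_per_class",
                                        "duration", "fs", "profiles",
                                        "exclusions", "input_dir")],
                      upstream = NULL, fun = function() {
    co <- if (!is.null(config$input_dir)) ingest_cohort(config$input_dir)
          else simulate_cohort(config$subjects_per_class, config$duration,
                               config$fs, config$seed, config$profiles)
    apply_exclusions(co, config$exclusions)
  })
  if (length(stages) == 1) return(invisible(NULL))

  windows <- run_stage(out_dir, "window",
                       params = config["windowing"],
                       upstream = "simulate", fun = function() {
    lapply(stats::setNames(config$channels, config$channels), function(ch) {
      bind_window_sets(lapply(cohort$records, window_record,
                              channel = ch, params = config$windowing))
    })
  })
  if (length(stages) == 2) return(invisible(NULL))

  images <- run_stage(out_dir, "rp",
                      params = list(resolution = config$resolution),
                      upstream = "window", fun = function() {
    lapply(windows, function(ws) {
      lapply(seq_len(nrow(ws$samples)), function(i)
        rp_to_image(compute_rp(ws$samples[i, ]), config$resolution))
    })
  })
  if (length(stages) == 3) return(invisible(NULL))

  if (config$pca) {
    images <- run_stage(out_dir, "pca",
                        params = config[c("pca", "pca_center", "resolution")],
                        upstream = "rp", fun = function() {
      lapply(images, function(imgs) {
        X <- images_to_matrix(imgs)
        model <- fit_pixel_pca(X, center = config$pca_center)
        scores_to_images(apply_pixel_pca(model, X), config$resolution)
      })
    })
  }
  if (length(stages) == 4) return(invisible(NULL))

  features <- run_stage(out_dir, "features",
                        params = list(extractor = config$extractor,
                                      pca = config$pca),
                        upstream = if (config$pca) "pca" else "rp",
                        fun = function() {
    lapply(stats::setNames(config$channels, config$channels), function(ch) {
      extract_features(images[[ch]], config$extractor,
                       labels = windows[[ch]]$meta$label,
                       groups = windows[[ch]]$meta$subject_id)
    })
  })
  if (length(stages) == 5) return(invisible(NULL))

  report <- run_stage(out_dir, "evaluate",
                      params = config[c("classifier", "cv_unit", "tasks")],
                      upstream = "features", fun = function() {
    evaluate_tasks(features, config)
  })
  write_report(report, out_dir)
  invisible(report)
}

# Execute (or reuse) one cached stage. The cache key hashes the stage
# parameters together with the upstream stage's key, so any upstream change
# invalidates the chain.
run_stage <- function(out_dir, name, params, upstream, fun) {
  sdir <- file.path(out_dir, "stages")
  up_hash <- if (is.null(upstream)) "" else {
    hf <- file.path(sdir, paste0(upstream, ".hash"))
    if (!file.exists(hf))
      stop_invalid("stage '%s' needs stage '%s', which has not run in %s",
                   name, upstream, out_dir)
    readLines(hf, n = 1)
  }
  key <- hash_object(list(params = params, upstream = up_hash))
  hash_file <- file.path(sdir, paste0(name, ".hash"))
  data_file <- file.path(sdir, paste0(name, ".rds"))
  if (file.exists(hash_file) && file.exists(data_file) &&
      identical(readLines(hash_file, n = 1), key)) {
    return(readRDS(data_file))
  }
  value <- fun()
  saveRDS(value, data_file)
  writeLines(key, hash_file)
  value
}

# Read an existing directory of three-column records (plus optional
# manifest.csv carrying subject_id,label) into a gait_cohort.
ingest_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop_invalid("no .txt records found in %s", dir)
  labels <- NULL
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    man <- utils::read.csv(mf, stringsAsFactors = FALSE)
    labels <- stats::setNames(man$label, man$subject_id)
  }
  records <- list()
  for (f in files) {
    id <- sub("\\.txt$", "", basename(f))
    lab <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
           else "unknown"
    records[[id]] <- read_gait_record(f, "three-column", subject_id = id,
                                      label = lab)
  }
  manifest <- data.frame(
    subject_id = names(records),
    label = vapply(records, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  structure(list(records = records, manifest = manifest,
                 duration = length(records[[1]]$time) / records[[1]]$fs,
                 fs = records[[1]]$fs, seed = NA_integer_),
            class = "gait_cohort")
}

evaluate_tasks <- function(features, config) {
  grid <- ndd_task_grid()
  want <- config$tasks
  run_multi <- identical(want, "all") || "multiclass" %in% want
  if (!identical(want, "all"))
    grid <- Filter(function(t) t$name %in% want, grid)
  tasks <- lapply(grid, function(task) {
    per_channel <- lapply(features, function(fm) {
      evaluate_binary_task(fm, task, config$cv_unit, config$classifier)
    })
    list(name = task$name, positive = task$positive,
         channels = per_channel,
         best_channel = select_best_channel(per_channel))
  })
  names(tasks) <- vapply(grid, `[[`, character(1), "name")
  multi <- NULL
  if (run_multi) {
    multi <- lapply(features, function(fm) {
      cv <- loocv(fm, unit = config$cv_unit, spec = config$classifier)
      multiclass_metrics(confusion_matrix(cv$truth, cv$pred,
                                          levels = levels(cv$truth)))
    })
  }
  list(cv_unit = config$cv_unit,
       leakage_warning = if (config$cv_unit == "window")
         paste("window-level LOOCV: overlapping windows of one subject",
               "appear in both train and test folds; use unit = 'subject'",
               "for an honest generalization estimate") else NULL,
       tasks = tasks, multiclass = multi)
}

evaluate_binary_task <- function(fm, task, unit, spec) {
  keep <- as.character(fm$labels) %in% task$classes
  labs <- as.character(fm$labels)[keep]
  if (task$pool) labs[labs != "HC"] <- "NDD"
  negative <- if (task$pool) "HC" else setdiff(task$classes, task$positive)
  sub <- feature_matrix(fm$F[keep, , drop = FALSE],
                        labels = factor(labs, levels = c(task$positive,
                                                         negative)),
                        groups = fm$groups[keep])
  cv <- loocv(sub, unit = unit, spec = spec)
  cm <- confusion_matrix(cv$truth, cv$pred, levels = levels(cv$truth))
  binary_metrics(cm, positive = task$positive,
                 scores = cv$score, truth = cv$truth)
}

config_summary <- function(config) {
  list(seed = config$seed,
       subjects_per_class = config$subjects_per_class,
       duration = config$duration, fs = config$fs,
       exclusions = config$exclusions,
       windowing = unclass(config$windowing),
       resolution = config$resolution,
       pca = config$pca, pca_center = config$pca_center,
       extractor = list(backend = config$extractor$backend,
                        input_size = config$extractor$input_size,
                        seed = config$extractor$seed,
                        output_dim = config$extractor$output_dim),
       classifier = unclass(config$classifier),
       cv_unit = config$cv_unit, channels = config$channels,
       tasks = config$tasks,
       profiles = lapply(config$profiles, unclass))
}

write_report <- function(report, out_dir) {
  summary_rows <- list()
  for (tn in names(report$tasks)) {
    task <- report$tasks[[tn]]
    for (ch in names(task$channels)) {
      m <- task$channels[[ch]]
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        task = tn, channel = ch,
        acc_pct = round_half_up(100 * m$accuracy, 2),
        sens_pct = round_half_up(100 * m$sensitivity, 2),
        spec_pct = round_half_up(100 * m$specificity, 2),
        auc = round_half_up(m$auc_balanced, 4),
        J = round_half_up(m$youden, 4),
        best = ch == task$best_channel,
        stringsAsFactors = FALSE)
      utils::write.csv(
        as.data.frame(m$confusion),
        file.path(out_dir, sprintf("confusion_%s_%s.csv",
                                   gsub("[^A-Za-z]+", "", tn), ch)),
        row.names = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  json <- list(cv_unit = report$cv_unit,
               leakage_warning = report$leakage_warning,
               tasks = lapply(report$tasks, function(task) {
                 list(positive = task$positive,
                      best_channel = task$best_channel,
                      channels = lapply(task$channels, metrics_to_list))
               }),
               multiclass = if (!is.null(report$multiclass))
                 lapply(report$multiclass, function(mm) {
                   list(overall_accuracy = mm$overall_accuracy,
                        confusion = mm$confusion,
                        per_class = lapply(mm$per_class, metrics_to_list))
                 }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       na = "null")
  invisible(summary)
}

metrics_to_list <- function(m) {
  list(n = m$n, accuracy = m$accuracy, sensitivity = m$sensitivity,
       specificity = m$specificity, auc_balanced = m$auc_balanced,
       auc_rank = m$auc_rank, youden = m$youden,
       flags = if (length(m$flags)) m$flags else NULL)
}
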