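#' Pipeline run configuration
#'
#' A fully serialisable description of an end-to-end run: simulate a
#' synthetic cohort, preprocess (centre seizures and cut labelled
#' segments), featurise, train the selected detectors, evaluate the
#' selected study designs and write report tables. The `"desk"` scale
#' profile (see [desk_profile()]) shrinks segment length, image size,
#' filter counts and epochs for laptop-scale runs; `"paper"` keeps the
#' full-scale architecture defaults.
#'
#' @param out_dir Output directory for the run.
#' @param scale `"desk"` or `"paper"`.
#' @param detectors Subset of `c("ws", "wf", "1d")`.
#' @param studies Subset of `c(1, 2, 3)`.
#' @param k Folds for study #3.
#' @param seed Master seed for the run.
#' @param cohort A [synthetic_cohort_config()] (its own seed is overridden
#'   by `seed`).
#' @param center `"truth"` (use generator ground truth centres) or
#'   `"detect"` (run [center_seizure()] on every marked event).
#' @param epochs,batch_size Training overrides (defaults from the scale
#'   profile).
#' @param write_records Also write the cohort as EDF files.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(out_dir, scale = c("desk", "paper"),
                            detectors = c("ws", "wf", "1d"),
                            studies = c(1, 2, 3), k = 5L, seed = 1L,
                            cohort = NULL,
                            center = c("truth", "detect"),
                            epochs = NULL, batch_size = NULL,
                            write_records = FALSE) {
  scale <- match.arg(scale)
  center <- match.arg(center)
  detectors <- match.arg(detectors, several.ok = TRUE)
  stopifnot(all(studies %in% 1:3))
  prof <- desk_profile()
  if (is.null(cohort)) {
    cohort <- if (scale == "desk")
      synthetic_cohort_config(animals_per_group = 2L,
                              record_duration = 900,
                              segment_length = prof$segment_length)
    else synthetic_cohort_config()
  }
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, scale = scale, detectors = detectors,
                 studies = studies, k = as.integer(k),
                 seed = as.integer(seed), cohort = cohort, center = center,
                 epochs = epochs %||% (if (scale == "desk") prof$epochs
                                       else 60L),
                 batch_size = batch_size %||% prof$batch_size,
                 write_records = isTRUE(write_records)),
            class = "run_config")
}

#' Run the full seizure-detection pipeline
#'
#' Executes simulate, preprocess, featurize, train, evaluate and report
#' stages, writing each stage's outputs plus a run manifest into
#' `config$out_dir`. Re-running with the same config reproduces the metric
#' tables exactly. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the metric tables and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass_deep(config),
                   config_fingerprint = object_fingerprint(unclass_deep(config)),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds =
                                       round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  cohort <- stage("simulate", {
    co <- generate_cohort(config$cohort)
    write_annotations(co$truth, file.path(config$out_dir, "truth.tsv"))
    if (config$write_records)
      write_cohort(co, file.path(config$out_dir, "records"))
    co
  })

  dataset <- stage("preprocess", {
    ds <- build_segment_dataset(cohort, L = config$cohort$segment_length,
                                center = config$center,
                                seed = config$seed + 100L)
    write_segment_store(ds$segments, file.path(config$out_dir, "segments"))
    ds
  })

  prof <- desk_profile()
  features <- stage("featurize", {
    out <- list()
    for (det in config$detectors) {
      out[[det]] <- switch(det,
        ws = segments_to_input(dataset$segments, "ws",
                               width = if (config$scale == "desk")
                                 prof$image_width else 500L,
                               height = if (config$scale == "desk")
                                 prof$image_height else 333L),
        wf = segments_to_input(dataset$segments, "wf"),
        `1d` = segments_to_input(dataset$segments, "1d"))
    }
    out
  })

  schemes <- stage("evaluate_design", {
    sc <- list()
    if (1 %in% config$studies)
      sc <- c(sc, build_loocv_schemes(dataset$manifest, include_sham = TRUE))
    if (2 %in% config$studies)
      sc <- c(sc, build_loocv_schemes(dataset$manifest, include_sham = FALSE))
    if (3 %in% config$studies)
      sc <- c(sc, build_kfold(dataset$manifest, k = config$k,
                              seed = config$seed))
    sc
  })

  results <- stage("train", {
    rows <- list()
    L <- config$cohort$segment_length
    for (det in config$detectors) {
      x <- features[[det]]
      y <- attr(x, "labels")
      spec <- detector_spec(det, config, prof, dim(x))
      for (sch in schemes) {
        tc <- train_config(epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = config$seed + 17L * sch$study_id +
                             as.integer(if (is.numeric(sch$scheme))
                               sch$scheme else 0L))
        clf <- train_classifier(spec, x[, , , sch$train_idx, drop = FALSE],
                                y[sch$train_idx], tc)
        p <- predict(clf, x[, , , sch$test_idx, drop = FALSE], type = "prob")
        lab <- ifelse(p[, "HAS"] > p[, "non-HAS"], "HAS", "non-HAS")
        roc <- roc_auc(p[, "HAS"], y[sch$test_idx])
        cm <- confusion(y[sch$test_idx], lab, auc = roc$auc)
        rows[[length(rows) + 1L]] <- list(detector = det, scheme = sch,
                                          metrics = cm, roc = roc,
                                          history = clf$history)
        # per-scheme training manifest (group x label counts on each side)
        tm <- table(dataset$manifest$group[sch$train_idx],
                    dataset$manifest$label[sch$train_idx])
        write.csv(as.data.frame(tm),
                  file.path(config$out_dir,
                            sprintf("train_manifest_%s_study%d_scheme%s.csv",
                                    det, sch$study_id,
                                    as.character(sch$scheme))),
                  row.names = FALSE)
      }
    }
    rows
  })

  tables <- stage("report", {
    out <- list()
    for (det in config$detectors) {
      rr <- Filter(function(r) r$detector == det, results)
      tab <- do.call(rbind, lapply(rr, function(r) {
        cbind(data.frame(study = r$scheme$study_id,
                         scheme = as.character(r$scheme$scheme),
                         test_on = r$scheme$test_group),
              metrics_table(list(r$metrics))[-1])
      }))
      write.csv(tab, file.path(config$out_dir,
                               sprintf("metrics_%s.csv", det)),
                row.names = FALSE)
      out[[det]] <- tab
      for (st in unique(tab$study)) {
        rocs <- lapply(Filter(function(r) r$scheme$study_id == st, rr),
                       `[[`, "roc")
        write.csv(average_roc(rocs),
                  file.path(config$out_dir,
                            sprintf("roc_%s_study%d.csv", det, st)),
                  row.names = FALSE)
      }
    }
    summ <- do.call(rbind, lapply(config$detectors, function(det) {
      do.call(rbind, lapply(unique(vapply(results, function(r)
        r$scheme$study_id, 0L)), function(st) {
          ms <- lapply(Filter(function(r)
            r$detector == det && r$scheme$study_id == st, results),
            `[[`, "metrics")
          cbind(data.frame(detector = det, study = st),
                summarize_study(ms))
        }))
    }))
    write.csv(summ, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    out$summary <- summ
    out
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, tables = tables,
                 manifest = manifest))
}

detector_spec <- function(det, config, prof, xdim) {
  L <- xdim[1]
  if (config$scale == "desk") {
    switch(det,
           ws = build_ws_cnn(input_shape = xdim[1:3],
                             filters = prof$ws_filters,
                             pools = prof$ws_pools),
           wf = build_wf_cnn(input_length = L, filters = prof$wf_filters),
           `1d` = build_1d_cnn(input_length = L,
                               filters = prof$wf_filters))
  } else {
    switch(det,
           ws = build_ws_cnn(),
           wf = build_wf_cnn(input_length = L),
           `1d` = build_1d_cnn(input_length = L))
  }
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
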