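#' Pipeline configuration
#'
#' Assembles and validates the full-run configuration: synthetic-cohort
#' parameters (or an input directory of CSV records plus a JSON label
#' file), detector parameters, the feature stage (reference lead, beat
#' segmentation on/off), criteria thresholds, the classifier and split
#' plan, and the output directory. `pipeline_config()` builds one from
#' arguments; `read_pipeline_config()` loads a YAML file with the same
#' field names.
#'
#' @param out_dir Run directory (created; must not require parents).
#' @param simulate A `[cohort_spec()]` for synthetic input, or `NULL`
#'   when reading records from `input_dir`.
#' @param input_dir Directory of `<subject_id>.csv` wide records, with a
#'   `labels.json` file, used when `simulate` is `NULL`.
#' @param detector A `[detector_params()]`.
#' @param reference_lead Segmentation anchor lead.
#' @param segment Use beat segmentation for model rows (default `TRUE`);
#'   `FALSE` trains on one case-median row per subject.
#' @param model Classifier method for `[lvh_model()]`.
#' @param model_args List of extra `[lvh_model()]` arguments.
#' @param plan A `[split_plan()]`.
#' @param balance Balance classes before splitting (default `TRUE`).
#' @param thresholds Criteria threshold table.
#' @param seed Master seed recorded in every output.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = cohort_spec(),
                            input_dir = NULL,
                            detector = detector_params(),
                            reference_lead = "II", segment = TRUE,
                            model = "tree", model_args = list(),
                            plan = split_plan(), balance = TRUE,
                            thresholds = lvh_criteria_thresholds(),
                            seed = 1L) {
  if (is.null(simulate) && is.null(input_dir)) {
    stop("config needs either `simulate` or `input_dir`")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  stopifnot(inherits(detector, "detector_params"),
            inherits(plan, "split_plan"),
            reference_lead %in% ecg_leads(),
            model %in% c("tree", "kmeans", "bpn"))
  structure(list(out_dir = out_dir, simulate = simulate,
                 input_dir = input_dir, detector = detector,
                 reference_lead = reference_lead, segment = segment,
                 model = model, model_args = model_args, plan = plan,
                 balance = balance, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML config path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config validation: `out_dir` is required")
  sim <- if (!is.null(y$simulate)) do.call(cohort_spec, y$simulate)
  det <- if (!is.null(y$detector)) do.call(detector_params, y$detector)
    else detector_params()
  plan <- if (!is.null(y$plan)) do.call(split_plan, y$plan) else split_plan()
  thr <- modifyList(lvh_criteria_thresholds(),
                    if (is.null(y$thresholds)) list() else y$thresholds)
  args <- list(out_dir = y$out_dir, simulate = sim, detector = det,
               plan = plan, thresholds = thr)
  for (nm in c("input_dir", "reference_lead", "segment", "model",
               "model_args", "balance", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # the hash identifies parameters, not the location
  yaml::write_yaml(lapply(cfg, function(z) if (is.list(z)) unclass(z) else z),
                   tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full LVH detection pipeline
#'
#' Composes every stage: acquire records (simulate or read), detect R/S
#' annotations per lead, build case-median features, score the seven
#' voltage criteria, optionally segment beats, balance classes, split
#' 7:3 (grouped by subject when training on beats), train the
#' classifier, and evaluate on the held-out set. All stage outputs are
#' written under `config$out_dir` together with `manifest.json`
#' (package version, seeds, config hash, per-file MD5 checksums); a
#' rerun with the same config and seed is bit-identical.
#'
#' @param config A `[pipeline_config()]`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the run directory, the manifest, the
#'   criteria table, the fitted model, and the test-set
#'   `[model_report()]`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[ecglvh] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "acquire"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      say("simulating cohort (", config$simulate$n_lvh, " LVH + ",
          config$simulate$n_control, " control)")
      cohort <- synth_cohort(config$simulate)
      ecgs <- lapply(cohort$records, `[[`, "ecg")
      labels <- cohort$labels
    } else {
      files <- list.files(config$input_dir, pattern = "\\.csv$",
                          full.names = TRUE)
      labels <- read_labels(file.path(config$input_dir, "labels.json"))
      ecgs <- lapply(files, function(f) {
        read_ecg(f, subject_id = sub("\\.csv$", "", basename(f)))
      })
    }
    ids <- vapply(ecgs, `[[`, "", "subject_id")
    names(ecgs) <- ids
    sexes <- setNames(as.character(labels$sex[match(ids, labels$subject_id)]),
                      ids)
    lvh <- setNames(labels$lvh[match(ids, labels$subject_id)], ids)
    if (anyNA(lvh)) stop("missing label for subject(s): ",
                         paste(ids[is.na(lvh)], collapse = ", "))

    stage <- "detect"
    say("detecting R peaks / S valleys in ", length(ecgs), " records")
    ann <- lapply(ecgs, detect_ecg, params = config$detector)
    annotations_to_csv_all(ann, file.path(config$out_dir, "annotations.csv"))

    stage <- "features"
    feats <- do.call(rbind, lapply(ids, function(id) {
      data.frame(subject_id = id, sex = sexes[[id]], lvh = lvh[[id]],
                 as.data.frame(as.list(median_amplitudes(ann[[id]]))))
    }))
    write_features(feats, file.path(config$out_dir, "features.csv"))

    stage <- "criteria"
    crit <- evaluate_criteria_cohort(feats, feats$lvh, sex = feats$sex,
                                     thresholds = config$thresholds)
    write.csv(crit, file.path(config$out_dir, "criteria_report.csv"),
              row.names = FALSE)

    stage <- "model"
    if (config$segment) {
      fs <- ecgs[[1]]$fs
      beats <- segment_cohort(ann, labels,
                              reference_lead = config$reference_lead,
                              fs = fs)
      x <- beats[, lvh_features()]; y <- beats$label; grp <- beats$subject_id
    } else {
      x <- feats[, lvh_features()]; y <- feats$lvh; grp <- NULL
    }
    if (config$balance) {
      keep_subj <- if (is.null(grp)) {
        seq_len(nrow(x))[balanced_cohort(y, seed = config$seed)]
      } else {
        # balance at the subject level, then keep those subjects' beats
        ok_ids <- ids[balanced_cohort(unname(lvh), seed = config$seed)]
        which(grp %in% ok_ids)
      }
      x <- x[keep_subj, , drop = FALSE]; y <- y[keep_subj]
      if (!is.null(grp)) grp <- grp[keep_subj]
    }
    say("training ", config$model, " on ", nrow(x), " rows",
        if (!is.null(grp)) " (subject-grouped split)")
    sp <- train_test_split(nrow(x), config$plan, group = grp)
    fit <- do.call(lvh_model, c(list(x = x[sp$train, , drop = FALSE],
                                     y = y[sp$train],
                                     method = config$model,
                                     seed = config$plan$seed),
                                config$model_args))
    report <- evaluate_model(fit, x[sp$test, , drop = FALSE], y[sp$test])
    jsonlite::write_json(
      c(list(model = config$model, n_train = length(sp$train),
             n_test = length(sp$test)), as.data.frame(report)),
      file.path(config$out_dir, "model_report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")

    stage <- "manifest"
    files <- c("annotations.csv", "features.csv", "criteria_report.csv",
               "model_report.json")
    manifest <- list(
      package = "ecglvh",
      version = as.character(utils::packageVersion("ecglvh")),
      seed = config$seed, split_seed = config$plan$seed,
      config_hash = config_hash(config),
      files = as.list(setNames(
        unname(tools::md5sum(file.path(config$out_dir, files))), files))
    )
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("done: ", config$out_dir)
    list(out_dir = config$out_dir, manifest = manifest, criteria = crit,
         model = fit, report = report, features = feats)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# stack per-subject annotation lists into one long CSV
annotations_to_csv_all <- function(ann_list, path) {
  rows <- lapply(names(ann_list), function(id) {
    df <- annotations_to_csv(ann_list[[id]])
    if (nrow(df) == 0) return(NULL)
    cbind(subject_id = id, df)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
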