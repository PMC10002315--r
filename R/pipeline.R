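#' Default end-to-end run configuration
#'
#' A fully serializable description of a pipeline run: master seed,
#' synthesis settings (see [cohort_config()]), clustering and learner
#' options, and the output directory. A run is reproducible from its config
#' alone.
#'
#' @param seed master seed; per-stage seeds are derived deterministically
#' @param out_dir output directory
#' @param n_per_group subjects per latent group
#' @param ... overrides for synthesis config fields
#' @return a `run_config` list
#' @export
default_config <- function(seed = 1, out_dir = tempfile("voicesym_run_"),
                           n_per_group = 20, ...) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthesis = unclass(cohort_config(n_per_group = n_per_group, ...)),
    clustering = list(n_restarts = 20),
    learner = default_learner(),
    n_folds = 5,
    cutoff_on = "train",
    skip_synthesis = FALSE,
    audio_dir = NULL,
    hamd_csv = NULL
  ), class = "run_config")
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) {
    if (nm == "synthesis") {
      for (s in names(cfg$synthesis)) base$synthesis[[s]] <- cfg$synthesis[[s]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' @rdname read_config
#' @param config a `run_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate user-supplied audio and HAM-D inputs
#'
#' Checks that every WAV is readable mono PCM, that every subject in the
#' HAM-D table has recordings, reports the phrase coverage, and verifies the
#' HAM-D row invariants (item ranges, total = item sum).
#'
#' @param audio_dir directory of `subject__Pnn.wav` files
#' @param hamd_csv HAM-D CSV path (header `subject_id,item_1..item_17,total`)
#' @return a data frame with one row per subject: `subject_id`, `pass`,
#'   `n_phrases`, `issues`
#' @export
validate_inputs <- function(audio_dir, hamd_csv) {
  if (!dir.exists(audio_dir)) stop("audio directory not found: ", audio_dir)
  if (!file.exists(hamd_csv)) stop("HAM-D CSV not found: ", hamd_csv)
  df <- read.csv(hamd_csv, stringsAsFactors = FALSE)
  rng <- hamd_item_ranges()
  wavs <- list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE)
  wav_subject <- sub("__P[0-9]+\\.wav$", "", basename(wavs))

  rows <- lapply(seq_len(nrow(df)), function(i) {
    sid <- df$subject_id[i]
    issues <- character(0)
    items <- suppressWarnings(as.integer(df[i, hamd_item_names()]))
    if (anyNA(items) || any(items < rng[, "min"] | items > rng[, "max"])) {
      issues <- c(issues, "item score outside its standard range")
    } else if (!is.null(df$total) && df$total[i] != sum(items)) {
      issues <- c(issues, sprintf("total %d != item sum %d", df$total[i],
                                  sum(items)))
    }
    mine <- wavs[wav_subject == sid]
    if (length(mine) == 0) {
      issues <- c(issues, "no recordings")
    } else {
      for (w in mine) {
        chk <- tryCatch(read_wav(w), error = function(e) e)
        if (inherits(chk, "error")) {
          issues <- c(issues, paste0(basename(w), ": unreadable"))
        } else if (chk$channels != 1) {
          issues <- c(issues, paste0(basename(w), ": not mono"))
        }
      }
    }
    data.frame(subject_id = sid, pass = length(issues) == 0,
               n_phrases = length(mine),
               issues = paste(issues, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

load_user_data <- function(audio_dir, hamd_csv) {
  records <- read_hamd_csv(hamd_csv)
  wavs <- list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE)
  by_subject <- list()
  for (w in wavs) {
    base <- sub("\\.wav$", "", basename(w))
    parts <- strsplit(base, "__P", fixed = TRUE)[[1]]
    wv <- read_wav(w)
    rec <- audio_recording(wv$samples, wv$rate,
                           phrase_id = as.integer(parts[2]),
                           subject_id = parts[1])
    by_subject[[parts[1]]] <- c(by_subject[[parts[1]]], list(rec))
  }
  list(records = records, by_subject = by_subject)
}

#' Run the full analysis pipeline
#'
#' Executes synthesize (unless `skip_synthesis`), extract, cluster, classify
#' and report in order, writing every stage artifact under the config's
#' output directory: `hamd.csv`, `wav/`, `features.csv`, `assignment.csv`,
#' `item_tests.json`, `metrics.json`, `feature_report.csv`, `report.json`.
#' `metrics.json` contains no timestamps, so reruns from one config are
#' byte-identical.
#'
#' @param config a [default_config()] / [read_config()] object
#' @return a `run_report` list (config echo, stage timings, clustering and
#'   CV summaries, file manifest), invisibly
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  manifest <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  if (isTRUE(config$skip_synthesis)) {
    user <- stage("load", load_user_data(config$audio_dir, config$hamd_csv))
    records <- user$records
    by_subject <- user$by_subject
    phrases <- sort(unique(unlist(lapply(by_subject, function(rs) {
      vapply(rs, `[[`, 0L, "phrase_id")
    }))))
  } else {
    dataset <- stage("synthesize", {
      cfg <- do.call(cohort_config, config$synthesis)
      generate_cohort_dataset(cfg, seed = derive_seed(config$seed, 1))
    })
    stage("write_dataset", {
      manifest <- c(manifest, write_cohort_dataset(dataset, out))
    })
    records <- dataset$hamd
    by_subject <- NULL
    phrases <- dataset$config$phrases
  }

  registry <- feature_registry(phrases)
  features <- stage("extract", {
    if (is.null(by_subject)) {
      extract_feature_table(dataset, registry)
    } else {
      extract_feature_table(by_subject, registry)
    }
  })
  f_features <- file.path(out, "features.csv")
  write.csv(features, f_features, row.names = FALSE)
  f_registry <- file.path(out, "registry.json")
  write_registry_json(registry, f_registry)

  clust <- stage("cluster", {
    cluster_cohort(records, seed = derive_seed(config$seed, 2),
                   n_restarts = config$clustering$n_restarts)
  })
  f_assign <- file.path(out, "assignment.csv")
  write.csv(data.frame(subject_id = names(clust$assignment),
                       group = ifelse(is.na(clust$assignment), "excluded",
                                      clust$assignment),
                       stage = clust$stage),
            f_assign, row.names = FALSE)
  tests <- item_wise_tests(records, clust$assignment)
  f_tests <- file.path(out, "item_tests.json")
  jsonlite::write_json(
    list(corrected_levels = as.list(attr(tests, "corrected_levels")),
         tests = tests),
    f_tests, auto_unbox = TRUE, digits = NA)

  cv <- stage("classify", {
    keep <- !is.na(clust$assignment)
    crossvalidate(features[features$subject_id %in%
                             names(clust$assignment)[keep], , drop = FALSE],
                  clust$assignment[keep],
                  n_folds = config$n_folds %||% 5,
                  seed = derive_seed(config$seed, 3),
                  learner = config$learner,
                  cutoff_on = config$cutoff_on %||% "train")
  })
  f_metrics <- file.path(out, "metrics.json")
  jsonlite::write_json(
    list(seed = config$seed,
         fold_cutoffs = cv$fold_cutoffs,
         fold_confusions = lapply(cv$fold_confusions, unclass),
         overall = unclass(cv$overall),
         sensitivity = cv$sensitivity, specificity = cv$specificity,
         accuracy = cv$accuracy),
    f_metrics, auto_unbox = TRUE, digits = NA)
  rep_df <- feature_report(cv)
  f_report_csv <- file.path(out, "feature_report.csv")
  write.csv(rep_df, f_report_csv, row.names = FALSE)

  manifest <- c(manifest, f_features, f_registry, f_assign, f_tests,
                f_metrics, f_report_csv)
  report <- list(
    config = unclass(config),
    timings = as.list(timings),
    clustering = list(
      group_sizes = as.list(table(factor(clust$assignment, levels = c(1, 2)))),
      n_excluded = sum(is.na(clust$assignment)),
      significant_items = tests$test[tests$tier != ""]
    ),
    cv = list(accuracy = cv$accuracy, sensitivity = cv$sensitivity,
              specificity = cv$specificity,
              fold_cutoffs = cv$fold_cutoffs),
    manifest = manifest
  )
  f_report <- file.path(out, "report.json")
  jsonlite::write_json(report, f_report, auto_unbox = TRUE, digits = NA)
  missing <- manifest[!file.exists(manifest)]
  if (length(missing) > 0) {
    stop("pipeline stage 'report' failed: manifest files missing: ",
         paste(missing, collapse = ", "))
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> accuracy %.1f%%; groups %s/%s (+%d excluded); %d artifacts\n",
              100 * x$cv$accuracy, x$clustering$group_sizes[[1]],
              x$clustering$group_sizes[[2]], x$clustering$n_excluded,
              length(x$manifest)))
  invisible(x)
}
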