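#' The acoustic feature registry
#'
#' Single source of truth for which (feature, statistic, phrase) triples the
#' feature vector contains, and in which order. Frame- or cycle-wise
#' features get a mean and a standard deviation per phrase; jitter and
#' shimmer are single-valued per phrase and registered under the `mean`
#' statistic only.
#'
#' @param phrases phrase ids covered (default 1-21)
#' @param n_mfcc number of MFCCs (default 12)
#' @param n_formants number of formants (default 5)
#' @return a data frame with columns `feature`, `statistic`, `phrase_id`,
#'   `name` (the canonical `feature__stat__phraseNN` column label), with the
#'   registry version in attribute `"registry_version"`
#' @export
feature_registry <- function(phrases = 1:21, n_mfcc = 12, n_formants = 5) {
  two_stat <- c("naq", "qoq",
                "band_power_0_500", "band_power_500_1000",
                "band_power_1000_4000", "centroid", "flux",
                paste0("formant_", seq_len(n_formants)),
                paste0("mfcc_", seq_len(n_mfcc)),
                "rms", "f0", "hnr")
  one_stat <- c("jitter", "shimmer")
  per_phrase <- rbind(
    expand.grid(feature = two_stat, statistic = c("mean", "std"),
                stringsAsFactors = FALSE),
    data.frame(feature = one_stat, statistic = "mean",
               stringsAsFactors = FALSE)
  )
  reg <- do.call(rbind, lapply(sort(unique(as.integer(phrases))), function(p) {
    cbind(per_phrase, phrase_id = p)
  }))
  reg$name <- sprintf("%s__%s__phrase%02d", reg$feature, reg$statistic,
                      reg$phrase_id)
  attr(reg, "registry_version") <- sprintf("v1/mfcc%d/formant%d", n_mfcc,
                                           n_formants)
  reg
}

#' Analyze one recording into per-feature summaries
#'
#' Runs the full acoustic analysis (pitch, HNR, cycle perturbation, spectral
#' set, formants, MFCC, IAIF glottal quotients) and reduces each feature to
#' its mean and standard deviation over valid frames or cycles. Features
#' without enough valid data are NA.
#'
#' @param rec an `audio_recording`
#' @param n_mfcc,n_formants registry dimensions
#' @return a named list: `<feature>__mean`, `<feature>__std` values
#' @export
analyze_recording <- function(rec, n_mfcc = 12, n_formants = 5) {
  out <- list()
  put <- function(feature, x) {
    x <- x[is.finite(x)]
    out[[paste0(feature, "__mean")]] <<-
      if (length(x) >= 1) mean(x) else NA_real_
    out[[paste0(feature, "__std")]] <<-
      if (length(x) >= 2) sd(x) else NA_real_
  }

  f0 <- estimate_f0(rec)
  pa <- attr(f0, "analysis")
  put("f0", f0$values)
  put("hnr", ifelse(pa$voiced, hnr_from_r(pa$r), NA_real_))

  cyc <- detect_cycles(rec, f0)
  out[["jitter__mean"]] <- if (length(cyc$periods) >= 2) {
    jitter_local(cyc$periods)
  } else NA_real_
  out[["shimmer__mean"]] <- if (length(cyc$amplitudes) >= 2) {
    shimmer_local(cyc$amplitudes)
  } else NA_real_

  sp <- spectral_features(rec)
  for (nm in names(sp)) put(nm, sp[[nm]]$values)

  fm <- formants(rec, n = n_formants, f0 = f0)
  for (k in seq_len(n_formants)) put(paste0("formant_", k), fm$values[, k])

  mf <- mfcc(rec, n_coeff = n_mfcc)
  for (k in seq_len(n_mfcc)) put(paste0("mfcc_", k), mf$values[, k])

  gq <- tryCatch({
    gf <- suppressWarnings(iaif(rec, f0 = f0))
    if (length(gf$cycle_boundaries) >= 2) glottal_quotients(gf) else NULL
  }, error = function(e) NULL)
  put("naq", if (is.null(gq)) numeric(0) else gq$naq)
  put("qoq", if (is.null(gq)) numeric(0) else gq$qoq)

  out
}

#' Build the fixed-order feature vector for one subject
#'
#' Evaluates every (feature, statistic, phrase) triple of the registry on
#' the subject's recordings. A phrase with no recording yields NA for its
#' whole block; the vector's order and length are fixed by the registry.
#'
#' @param recordings list of `audio_recording`s for one subject (one per
#'   phrase; all `phrase_id`s must be registered)
#' @param registry a [feature_registry()]
#' @return a named numeric vector in registry order
#' @export
extract_feature_vector <- function(recordings, registry = feature_registry()) {
  recordings <- recordings[!vapply(recordings, is.null, TRUE)]
  phrase_ids <- vapply(recordings, `[[`, 0L, "phrase_id")
  known <- unique(registry$phrase_id)
  if (any(!phrase_ids %in% known)) {
    stop("unknown phrase id: ",
         paste(setdiff(phrase_ids, known), collapse = ", "))
  }
  if (anyDuplicated(phrase_ids)) stop("duplicate phrase ids for one subject")

  n_mfcc <- sum(grepl("^mfcc_", unique(registry$feature)))
  n_formants <- sum(grepl("^formant_", unique(registry$feature)))
  vec <- stats::setNames(rep(NA_real_, nrow(registry)), registry$name)
  for (i in seq_along(recordings)) {
    s <- analyze_recording(recordings[[i]], n_mfcc = n_mfcc,
                           n_formants = n_formants)
    sel <- registry$phrase_id == phrase_ids[i]
    key <- paste0(registry$feature[sel], "__", registry$statistic[sel])
    vec[which(sel)] <- vapply(key, function(k) s[[k]] %||% NA_real_, 0)
  }
  vec
}

#' Feature table for a whole cohort
#'
#' One row per subject, columns in registry order plus `subject_id`.
#'
#' @param dataset a `cohort_dataset` (or a named list of per-subject
#'   recording lists)
#' @param registry a [feature_registry()]
#' @param verbose print progress
#' @return a data frame
#' @export
extract_feature_table <- function(dataset, registry = NULL, verbose = FALSE) {
  if (inherits(dataset, "cohort_dataset")) {
    if (is.null(registry)) registry <- feature_registry(dataset$config$phrases)
    subjects <- names(dataset$true_group)
    get_recs <- function(sid) subject_recordings(dataset, sid)
  } else {
    if (is.null(registry)) registry <- feature_registry()
    subjects <- names(dataset)
    get_recs <- function(sid) dataset[[sid]]
  }
  rows <- lapply(subjects, function(sid) {
    if (verbose) message("extracting ", sid)
    extract_feature_vector(get_recs(sid), registry)
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- registry$name
  cbind(data.frame(subject_id = subjects, stringsAsFactors = FALSE), df)
}

#' Dump the registry as JSON for provenance
#'
#' @param registry a [feature_registry()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(
    list(registry_version = attr(registry, "registry_version"),
         entries = registry[, c("feature", "statistic", "phrase_id")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
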