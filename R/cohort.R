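#' Synthesis configuration for a linked cohort dataset
#'
#' Defines the cohort size, the recorded phrase set, the recording format,
#' the HAM-D generator settings and the acoustic group contrast. The group
#' contrast is a single `acoustic_effect` multiplier on a fixed vector of
#' group-2-minus-group-1 parameter offsets (fundamental frequency, open
#' quotient, jitter, shimmer, aspiration SNR and a relative formant shift);
#' 0 gives acoustically indistinguishable groups, 1 the package default,
#' larger values a stronger contrast.
#'
#' @param n_per_group subjects per latent group
#' @param phrases integer vector of phrase ids (subset of 1-21)
#' @param duration_s per-phrase duration in seconds
#' @param rate sample rate in Hz
#' @param acoustic_effect scalar effect-size multiplier (>= 0, finite)
#' @param hamd_separation item-profile separation passed to
#'   [default_symptom_profiles()]
#' @param item_corr_target target item-1/item-7 correlation
#' @param ... must be empty; unknown keys are an error
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(n_per_group = 20, phrases = 1:21, duration_s = 1.0,
                          rate = 11025, acoustic_effect = 1,
                          hamd_separation = 1.3, item_corr_target = 0.7,
                          ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown config keys: ", paste(names(extra), collapse = ", "))
  }
  stopifnot(n_per_group >= 1, length(phrases) >= 1,
            all(phrases %in% 1:21), duration_s > 0, rate >= 8000)
  if (!is.finite(acoustic_effect) || acoustic_effect < 0) {
    stop("acoustic_effect must be finite and non-negative")
  }
  structure(list(n_per_group = n_per_group, phrases = as.integer(phrases),
                 duration_s = duration_s, rate = rate,
                 acoustic_effect = acoustic_effect,
                 hamd_separation = hamd_separation,
                 item_corr_target = item_corr_target),
            class = "cohort_config")
}

# fixed per-phrase vowel-like formant patterns, cycled over the 21 phrases;
# centre frequencies stay below the 11.025 kHz Nyquist
phrase_formants <- function(phrase_id) {
  patterns <- list(
    a = c(730, 1090, 2440, 3500, 4700),
    i = c(390, 1990, 2550, 3600, 4700),
    u = c(440, 1020, 2240, 3400, 4600),
    e = c(530, 1840, 2480, 3500, 4650),
    o = c(570, 840, 2410, 3400, 4600)
  )
  p <- patterns[[(phrase_id - 1L) %% length(patterns) + 1L]]
  formant_spec(p, bandwidths = c(80, 110, 160, 220, 280))
}

# group-2-minus-group-1 acoustic offsets at effect size 1
acoustic_offsets <- function(effect) {
  list(f0 = 12 * effect, oq = 0.08 * effect, jitter = 0.8 * effect,
       shimmer = 1.0 * effect, snr = -5 * effect, formant = 0.05 * effect)
}

#' Generate a linked synthetic cohort of HAM-D scores and recordings
#'
#' Each subject receives a HAM-D record and one recording per configured
#' phrase. The subject's latent group drives both the symptom profile and
#' the acoustic parameters: subject-level glottal parameters are drawn from
#' group-conditional normal distributions (offset between groups by
#' `acoustic_effect` times fixed base offsets), each phrase adds small
#' within-subject variation, and the phrase id selects a vowel-like formant
#' pattern. Everything is a pure function of `(config, seed)`.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return a `cohort_dataset`: list with `hamd` (records), `recordings`
#'   (list keyed `subject__phrase`), `true_group`, `config`, `seed`
#' @export
generate_cohort_dataset <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  hamd <- generate_hamd_cohort(
    config$n_per_group,
    profiles = default_symptom_profiles(config$hamd_separation),
    item_corr_target = config$item_corr_target,
    seed = derive_seed(seed, 1)
  )
  off <- acoustic_offsets(config$acoustic_effect)
  subjects <- names(hamd$true_group)

  recordings <- list()
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    g <- hamd$true_group[[sid]]
    sgn <- if (g == 1) -0.5 else 0.5
    sseed <- derive_seed(seed, 100 + i)
    subj <- with_seed(sseed, list(
      f0 = max(70, rnorm(1, 120 + sgn * off$f0, 8)),
      oq = min(0.9, max(0.35, rnorm(1, 0.60 + sgn * off$oq, 0.04))),
      jitter = max(0.05, rnorm(1, 1.2 + sgn * off$jitter, 0.4)),
      shimmer = max(0.05, rnorm(1, 2.0 + sgn * off$shimmer, 0.5)),
      snr = rnorm(1, 25 + sgn * off$snr, 2),
      fshift = exp(rnorm(1, sgn * off$formant, 0.02))
    ))
    for (j in seq_along(config$phrases)) {
      ph <- config$phrases[j]
      pseed <- derive_seed(seed, 10000 + i * 100 + ph)
      pv <- with_seed(pseed, list(
        f0 = subj$f0 * exp(rnorm(1, 0, 0.015)),
        amp = exp(rnorm(1, 0, 0.1))
      ))
      base_tr <- phrase_formants(ph)
      tract <- formant_spec(
        pmin(base_tr$centers * subj$fshift, config$rate / 2 - 60),
        base_tr$bandwidths
      )
      gl <- glottal_params(f0_mean = pv$f0, f0_sd = 2,
                           open_quotient = subj$oq,
                           jitter_pct = subj$jitter,
                           shimmer_pct = subj$shimmer,
                           noise_snr_db = subj$snr,
                           amplitude = pv$amp)
      rec <- synthesize_voice(gl, tract, duration = config$duration_s,
                              rate = config$rate,
                              seed = derive_seed(seed, 20000 + i * 100 + ph),
                              phrase_id = ph, subject_id = sid)
      recordings[[paste0(sid, "__P", sprintf("%02d", ph))]] <- rec
    }
  }
  structure(list(hamd = hamd$records, recordings = recordings,
                 true_group = hamd$true_group, config = config, seed = seed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x %d phrases (%d recordings), seed %d\n",
              length(x$hamd), length(x$config$phrases), length(x$recordings),
              x$seed))
  invisible(x)
}

#' Recordings of one subject from a cohort dataset
#'
#' @param dataset a `cohort_dataset`
#' @param subject_id subject identifier
#' @return a list of `audio_recording`s, one per phrase
#' @export
subject_recordings <- function(dataset, subject_id) {
  keys <- paste0(subject_id, "__P", sprintf("%02d", dataset$config$phrases))
  dataset$recordings[keys]
}

#' Write a cohort dataset to disk
#'
#' Writes the HAM-D CSV, one 16-bit PCM WAV per recording and a ground-truth
#' group CSV (tests only) to `dir`.
#'
#' @param dataset a `cohort_dataset`
#' @param dir output directory, created if absent
#' @return a character vector of the files written, invisibly
#' @export
write_cohort_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "wav"), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- file.path(dir, "hamd.csv")
  write_hamd_csv(dataset$hamd, p)
  files <- c(files, p)
  for (key in names(dataset$recordings)) {
    rec <- dataset$recordings[[key]]
    p <- file.path(dir, "wav", paste0(key, ".wav"))
    write_wav(rec$samples, rec$rate, p)
    files <- c(files, p)
  }
  p <- file.path(dir, "true_group.csv")
  write.csv(data.frame(subject_id = names(dataset$true_group),
                       group = as.integer(dataset$true_group)),
            p, row.names = FALSE)
  invisible(c(files, p))
}
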