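#' Standard HAM-D-17 item score ranges
#'
#' Items 4, 5, 6, 12, 13, 14, 16 and 17 are scored 0-2; all other items 0-4.
#'
#' @return a 17 x 2 matrix with columns `min` and `max`
#' @export
hamd_item_ranges <- function() {
  hi <- rep(4L, 17)
  hi[c(4, 5, 6, 12, 13, 14, 16, 17)] <- 2L
  cbind(min = rep(0L, 17), max = hi)
}

hamd_item_names <- function() paste0("item_", 1:17)

#' Construct a HAM-D-17 record
#'
#' @param subject_id opaque subject identifier
#' @param items integer vector of 17 item scores, each within its standard
#'   range
#' @return a `hamd_record` with the total equal to the item sum
#' @export
hamd_record <- function(subject_id, items) {
  items <- as.integer(items)
  if (length(items) != 17) stop("a HAM-D-17 record needs 17 item scores")
  rng <- hamd_item_ranges()
  if (any(items < rng[, "min"] | items > rng[, "max"])) {
    stop("item score outside its standard range")
  }
  structure(list(subject_id = as.character(subject_id), items = items,
                 total = sum(items)),
            class = "hamd_record")
}

#' A latent symptom profile for cohort generation
#'
#' @param item_means 17 non-negative item means (clipped to item ranges when
#'   sampling)
#' @param item_sds 17 non-negative item standard deviations
#' @param label group tag
#' @return a `symptom_profile`
#' @export
symptom_profile <- function(item_means, item_sds, label = "") {
  if (length(item_means) != 17 || length(item_sds) != 17) {
    stop("profiles must have 17 item means and sds")
  }
  if (any(item_means < 0) || any(item_sds < 0)) {
    stop("item means and sds must be non-negative")
  }
  structure(list(item_means = as.numeric(item_means),
                 item_sds = as.numeric(item_sds), label = label),
            class = "symptom_profile")
}

#' Default two-group symptom profiles
#'
#' A mildly depressed base profile with group 1 elevated on guilt (item 2),
#' work and activities (item 7) and loss of appetite (item 12) — an
#' inactivity-leaning profile — and group 2 elevated on early insomnia
#' (item 4). `separation` scales the elevations in units of the item
#' standard deviation.
#'
#' @param separation elevation of the distinguishing items, in pooled-SD units
#' @return a list of two `symptom_profile`s
#' @export
default_symptom_profiles <- function(separation = 1.3) {
  base <- c(1.2, 0.4, 0.2, 0.5, 0.5, 0.4, 0.8, 0.5, 0.3, 0.8,
            0.6, 0.3, 0.5, 0.3, 0.2, 0.2, 0.1)
  rng <- hamd_item_ranges()
  sds <- ifelse(rng[, "max"] == 2L, 0.6, 0.9)
  m1 <- base
  m1[c(2, 7, 12)] <- base[c(2, 7, 12)] + separation * sds[c(2, 7, 12)]
  m2 <- base
  m2[4] <- base[4] + separation * sds[4]
  list(symptom_profile(m1, sds, "inactivity"),
       symptom_profile(m2, sds, "insomnia"))
}

#' Generate a two-group synthetic HAM-D cohort
#'
#' Scores are drawn from a one-factor Gaussian latent model: items 1
#' (depressed mood) and 7 (work and activities) load strongly on a shared
#' severity factor so that their scores correlate at approximately
#' `item_corr_target`; the remaining items carry a weak general loading.
#' Latent values are scaled by the profile SDs, shifted by the profile means,
#' rounded and clipped to the standard item ranges. The loading is inflated
#' slightly (factor 1.12) to offset the attenuation caused by rounding and
#' clipping.
#'
#' @param n_per_group subjects per group (>= 1)
#' @param profiles list of two [symptom_profile()]s
#' @param item_corr_target target Pearson correlation between items 1 and 7
#' @param seed integer seed
#' @return a list with `records` (list of `hamd_record`) and `true_group`
#'   (named integer vector of 1/2)
#' @export
generate_hamd_cohort <- function(n_per_group,
                                 profiles = default_symptom_profiles(),
                                 item_corr_target = 0.7, seed = 1) {
  if (n_per_group < 1) stop("n_per_group must be at least 1")
  if (length(profiles) != 2 ||
      !all(vapply(profiles, inherits, TRUE, "symptom_profile"))) {
    stop("profiles must be a list of two symptom_profile objects")
  }
  rng <- hamd_item_ranges()
  lam_strong <- calibrate_factor_loading(profiles, item_corr_target)
  loadings <- rep(0.45, 17)
  loadings[c(1, 7)] <- lam_strong

  with_seed(seed, {
    n <- 2L * n_per_group
    grp <- rep(1:2, each = n_per_group)
    u <- rnorm(n)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      pr <- profiles[[grp[i]]]
      z <- loadings * u[i] + sqrt(1 - loadings^2) * rnorm(17)
      raw <- pr$item_means + pr$item_sds * z
      sc <- pmin(rng[, "max"], pmax(rng[, "min"], round(raw)))
      records[[i]] <- hamd_record(sprintf("S%03d", i), sc)
    }
    true_group <- stats::setNames(grp, vapply(records, `[[`, "", "subject_id"))
    list(records = records, true_group = true_group)
  })
}

#' Strongly separated two-group symptom profiles
#'
#' Profiles for clustering-recovery studies: each group is elevated on its
#' own block of items by `separation` item-SD units (group 1 on
#' guilt/work-activity/retardation/anxiety/appetite items by default, group
#' 2 on the insomnia and somatic items). With the default ten separated
#' items the between-group Mahalanobis distance is large enough that
#' near-perfect recovery is information-theoretically possible, which the
#' minimal three-item configuration is not.
#'
#' @param separation per-item elevation in item-SD units
#' @param items_g1,items_g2 item indices elevated in each group
#' @return a list of two [symptom_profile()]s
#' @export
separated_symptom_profiles <- function(separation = 2,
                                       items_g1 = c(2, 7, 8, 10, 12),
                                       items_g2 = c(4, 5, 6, 11, 13)) {
  base <- c(1.2, 0.4, 0.2, 0.5, 0.5, 0.4, 0.8, 0.5, 0.3, 0.8,
            0.6, 0.3, 0.5, 0.3, 0.2, 0.2, 0.1)
  rng <- hamd_item_ranges()
  sds <- ifelse(rng[, "max"] == 2L, 0.6, 0.9)
  m1 <- base
  m1[items_g1] <- base[items_g1] + separation * sds[items_g1]
  m2 <- base
  m2[items_g2] <- base[items_g2] + separation * sds[items_g2]
  list(symptom_profile(m1, sds, "inactivity"),
       symptom_profile(m2, sds, "insomnia"))
}

# Numerically calibrate the shared-factor loading of items 1 and 7 so that
# the post-discretization (round + clip) Pearson correlation of the two item
# scores, pooled over both group profiles, hits the target. The conditional
# moments of a clipped, rounded Gaussian given the factor are exact (probit
# bin probabilities); the factor is integrated over a fine Gaussian grid,
# and the loading is solved by uniroot.
calibrate_factor_loading <- function(profiles, target, items = c(1, 7)) {
  rng <- hamd_item_ranges()
  u <- seq(-6, 6, length.out = 241)
  wu <- stats::dnorm(u)
  wu <- wu / sum(wu)

  cond_mean <- function(m, s, lam, hi) {
    # E[clip(round(m + s(lam u + sqrt(1-lam^2) e)))| u] for each grid u
    sde <- s * sqrt(max(1 - lam^2, 1e-12))
    mu <- m + s * lam * u
    a <- 0:hi
    cuts <- c(-Inf, a[-length(a)] + 0.5, Inf)
    ev <- numeric(length(u))
    for (k in seq_along(a)) {
      p <- stats::pnorm((cuts[k + 1] - mu) / sde) -
        stats::pnorm((cuts[k] - mu) / sde)
      ev <- ev + a[k] * p
    }
    ev
  }
  cond_m2 <- function(m, s, lam, hi) {
    sde <- s * sqrt(max(1 - lam^2, 1e-12))
    mu <- m + s * lam * u
    a <- 0:hi
    cuts <- c(-Inf, a[-length(a)] + 0.5, Inf)
    ev <- numeric(length(u))
    for (k in seq_along(a)) {
      p <- stats::pnorm((cuts[k + 1] - mu) / sde) -
        stats::pnorm((cuts[k] - mu) / sde)
      ev <- ev + a[k]^2 * p
    }
    ev
  }

  pooled_corr <- function(lam) {
    e1 <- e7 <- e11 <- e77 <- e17 <- 0
    for (pr in profiles) {
      c1 <- cond_mean(pr$item_means[items[1]], pr$item_sds[items[1]], lam,
                      rng[items[1], "max"])
      c7 <- cond_mean(pr$item_means[items[2]], pr$item_sds[items[2]], lam,
                      rng[items[2], "max"])
      e1 <- e1 + 0.5 * sum(wu * c1)
      e7 <- e7 + 0.5 * sum(wu * c7)
      e11 <- e11 + 0.5 * sum(wu * cond_m2(pr$item_means[items[1]],
                                          pr$item_sds[items[1]], lam,
                                          rng[items[1], "max"]))
      e77 <- e77 + 0.5 * sum(wu * cond_m2(pr$item_means[items[2]],
                                          pr$item_sds[items[2]], lam,
                                          rng[items[2], "max"]))
      e17 <- e17 + 0.5 * sum(wu * c1 * c7)
    }
    (e17 - e1 * e7) / sqrt((e11 - e1^2) * (e77 - e7^2))
  }

  hi_corr <- pooled_corr(0.9995)
  if (hi_corr <= target) return(0.9995)
  stats::uniroot(function(l) pooled_corr(l) - target,
                 c(0.05, 0.9995), tol = 1e-4)$root
}

#' HAM-D records as a data frame
#'
#' @param records list of `hamd_record`s
#' @return a data frame with subject_id, item_1..item_17, total
#' @export
hamd_to_df <- function(records) {
  m <- t(vapply(records, `[[`, integer(17), "items"))
  colnames(m) <- hamd_item_names()
  data.frame(subject_id = vapply(records, `[[`, "", "subject_id"), m,
             total = vapply(records, `[[`, 0L, "total"),
             stringsAsFactors = FALSE)
}

#' Read / write HAM-D cohort CSVs
#'
#' The CSV has the header `subject_id,item_1..item_17,total`.
#'
#' @param path file path
#' @return `read_hamd_csv` returns a list of `hamd_record`s;
#'   `write_hamd_csv` returns `path` invisibly
#' @export
read_hamd_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", hamd_item_names())
  if (!all(need %in% names(df))) stop("HAM-D CSV missing required columns")
  lapply(seq_len(nrow(df)), function(i) {
    hamd_record(df$subject_id[i], as.integer(df[i, hamd_item_names()]))
  })
}

#' @rdname read_hamd_csv
#' @param records list of `hamd_record`s
#' @export
write_hamd_csv <- function(records, path) {
  write.csv(hamd_to_df(records), path, row.names = FALSE)
  invisible(path)
}
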