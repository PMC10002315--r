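#' Correlation distance between two item-score profiles
#'
#' One minus the Pearson correlation of the two profiles. If either profile
#' has zero variance the correlation is undefined; the distance is then 1
#' (the profiles are treated as uncorrelated) and attribute
#' `"zero_variance"` is set on the result.
#'
#' @param a,b numeric score vectors of equal length (17 items in standard
#'   use)
#' @return a distance in [0, 2]
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (sd(a) == 0 || sd(b) == 0) {
    return(structure(1, zero_variance = TRUE))
  }
  1 - cor(a, b)
}

# vectorized rows-vs-centroids correlation distance; zero-variance rows or
# centroids get distance 1
corr_dist_matrix <- function(x, centers) {
  xs <- apply(x, 1, sd)
  cs <- apply(centers, 1, sd)
  d <- matrix(1, nrow(x), nrow(centers))
  ok_r <- xs > 0
  ok_c <- cs > 0
  if (any(ok_r) && any(ok_c)) {
    cc <- cor(t(x[ok_r, , drop = FALSE]), t(centers[ok_c, , drop = FALSE]))
    d[ok_r, ok_c] <- 1 - cc
  }
  d
}

#' Cluster a HAM-D cohort into two symptom groups
#'
#' Three-tier procedure: subjects with a total score of 0 are excluded
#' (their symptoms cannot be characterised); subjects with totals of 4 or
#' more are clustered into two groups by K-means under the correlation
#' distance (assignment to the nearest centroid by `1 - r`, centroid update
#' by the arithmetic mean of member profiles), taking the best of
#' `n_restarts` random initialisations by total within-cluster distance;
#' subjects with totals 1-3 are then allocated to the nearer of the two
#' centroids. Group labels are canonicalized so that group 1 has the higher
#' centroid mean on item 7 (work and activities); ties anywhere resolve to
#' group 1.
#'
#' @param records list of `hamd_record`s
#' @param seed integer seed (initial centroids are random subjects)
#' @param n_restarts number of K-means restarts
#' @param max_iter iteration cap per restart
#' @return a `clustering_result`: list with `assignment` (named integer,
#'   NA = excluded), `stage` (named character: `seed_clustered`,
#'   `allocated`, `excluded`), `centroids` (2 x 17), `objective`,
#'   `n_restarts_used`, `seed`
#' @export
cluster_cohort <- function(records, seed = 1, n_restarts = 20,
                           max_iter = 100) {
  ids <- vapply(records, `[[`, "", "subject_id")
  totals <- vapply(records, `[[`, 0L, "total")
  x_all <- t(vapply(records, `[[`, integer(17), "items"))
  rownames(x_all) <- ids

  excluded <- totals == 0
  core <- totals >= 4
  mid <- totals >= 1 & totals <= 3
  if (sum(core) < 2) {
    if (all(excluded)) stop("no clusterable subjects")
    stop("fewer than 2 subjects with total >= 4; cannot seed clusters")
  }
  x <- x_all[core, , drop = FALSE]
  n <- nrow(x)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- x[sample.int(n, 2), , drop = FALSE]
      assign_old <- rep(0L, n)
      for (it in seq_len(max_iter)) {
        d <- corr_dist_matrix(x, centers)
        assign_new <- ifelse(d[, 1] <= d[, 2], 1L, 2L)
        if (length(unique(assign_new)) == 1L) {
          # a cluster emptied: re-seed it with the farthest point
          far <- which.max(d[cbind(seq_len(n), assign_new)])
          assign_new[far] <- 3L - assign_new[far]
        }
        if (identical(assign_new, assign_old)) break
        assign_old <- assign_new
        centers <- rbind(colMeans(x[assign_new == 1L, , drop = FALSE]),
                         colMeans(x[assign_new == 2L, , drop = FALSE]))
      }
      d <- corr_dist_matrix(x, centers)
      obj <- sum(d[cbind(seq_len(n), assign_old)])
      if (is.null(best) || obj < best$objective - 1e-12) {
        best <- list(assign = assign_old, centers = centers, objective = obj)
      }
    }
  })

  # canonical labels: group 1 = higher centroid mean on item 7
  if (best$centers[1, 7] < best$centers[2, 7]) {
    best$assign <- 3L - best$assign
    best$centers <- best$centers[2:1, , drop = FALSE]
  }

  assignment <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  stage <- stats::setNames(rep("excluded", length(ids)), ids)
  assignment[core] <- best$assign
  stage[core] <- "seed_clustered"
  if (any(mid)) {
    d_mid <- corr_dist_matrix(x_all[mid, , drop = FALSE], best$centers)
    assignment[mid] <- ifelse(d_mid[, 1] <= d_mid[, 2], 1L, 2L)
    stage[mid] <- "allocated"
  }

  structure(list(assignment = assignment, stage = stage,
                 centroids = best$centers, objective = best$objective,
                 n_restarts_used = n_restarts, seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = c(1, 2)), useNA = "ifany")
  cat(sprintf("<clustering_result> group 1: %d, group 2: %d, excluded: %d (objective %.4f)\n",
              tab[1], tab[2], sum(is.na(x$assignment)), x$objective))
  invisible(x)
}

#' Item-wise Wilcoxon rank-sum tests between symptom groups
#'
#' Two-sided Wilcoxon rank-sum tests (normal approximation with tie and
#' continuity correction) comparing the two groups on each of the 17 HAM-D
#' items and on the total score — 18 tests. Significance tiers are assigned
#' against Bonferroni-corrected levels `tier_alphas / n_tests`
#' (0.05/18 = 2.8e-3 for `*`, 0.01/18 for `**`, 0.005/18 for `***`).
#'
#' @param records list of `hamd_record`s
#' @param assignment named group vector (1/2; NA = excluded) as produced by
#'   [cluster_cohort()]
#' @param tier_alphas family-wise alpha levels for the `*`, `**`, `***`
#'   tiers
#' @param n_tests number of tests in the family (default 18)
#' @return an `item_test_report` data frame with columns `test`,
#'   `statistic`, `p_value`, `tier`; corrected levels in attribute
#'   `"corrected_levels"`
#' @export
item_wise_tests <- function(records, assignment,
                            tier_alphas = c(0.05, 0.01, 0.005),
                            n_tests = 18) {
  ids <- vapply(records, `[[`, "", "subject_id")
  grp <- assignment[ids]
  keep <- !is.na(grp)
  if (!any(grp[keep] == 1) || !any(grp[keep] == 2)) {
    stop("both groups must be non-empty")
  }
  x <- t(vapply(records, `[[`, integer(17), "items"))[keep, , drop = FALSE]
  tot <- vapply(records, `[[`, 0L, "total")[keep]
  g <- grp[keep]
  levels <- tier_alphas / n_tests

  one_test <- function(v) {
    wt <- suppressWarnings(wilcox.test(v[g == 1], v[g == 2],
                                       exact = FALSE, correct = TRUE))
    p <- wt$p.value
    if (!is.finite(p)) p <- 1   # fully tied data carry no evidence
    c(statistic = unname(wt$statistic), p_value = p)
  }
  res <- t(vapply(c(lapply(1:17, function(i) x[, i]), list(tot)), one_test,
                  c(statistic = 0, p_value = 0)))
  tier <- vapply(res[, "p_value"], function(p) {
    if (p < levels[3]) "***" else if (p < levels[2]) "**"
    else if (p < levels[1]) "*" else ""
  }, "")
  out <- data.frame(test = c(hamd_item_names(), "total"),
                    statistic = res[, "statistic"],
                    p_value = res[, "p_value"], tier = tier,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "corrected_levels") <- stats::setNames(levels, c("*", "**", "***"))
  attr(out, "alpha_family") <- tier_alphas[1]
  attr(out, "n_tests") <- n_tests
  class(out) <- c("item_test_report", "data.frame")
  out
}
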