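test_that("correlation distance matches direct Pearson evaluation", {
  a <- c(1, 2, 3)
  expect_equal(correlation_distance(a, a), 0)
  expect_equal(correlation_distance(a, 10 - 2 * a), 2)
  # r((1,2,3),(1,3,2)) = 0.5 by direct formula, distance 0.5
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  x <- c(4, 0, 2, 1, 3, 0, 4, 2, 1, 0, 3, 2, 0, 1, 2, 4, 0)
  y <- c(2, 1, 0, 3, 2, 1, 4, 0, 0, 2, 3, 1, 2, 0, 1, 3, 2)
  n <- length(x)
  r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(correlation_distance(x, y), 1 - r_hand)
})

test_that("zero-variance profiles get distance 1 with a flag", {
  d <- correlation_distance(rep(2, 17), 1:17)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "zero_variance"))
  expect_error(correlation_distance(1:5, 1:6), "length")
})

test_that("assignment stages follow the total-score tiers exactly", {
  ch <- generate_hamd_cohort(15, profiles = separated_symptom_profiles(2),
                             seed = 2)
  recs <- ch$records
  # force a few subjects into the low tiers
  recs[[1]]$items <- rep(0L, 17); recs[[1]]$total <- 0L
  recs[[2]]$items <- c(1L, rep(0L, 16)); recs[[2]]$total <- 1L
  recs[[3]]$items <- c(2L, 1L, rep(0L, 15)); recs[[3]]$total <- 3L
  cl <- cluster_cohort(recs, seed = 1)
  totals <- vapply(recs, `[[`, 0L, "total")
  expect_true(all(cl$stage[totals == 0] == "excluded"))
  expect_true(all(is.na(cl$assignment[totals == 0])))
  expect_true(all(cl$stage[totals >= 1 & totals <= 3] == "allocated"))
  expect_true(all(cl$stage[totals >= 4] == "seed_clustered"))
  expect_true(all(!is.na(cl$assignment[totals >= 1])))
})

test_that("a cohort with no clusterable subjects is an error", {
  recs <- lapply(1:5, function(i) hamd_record(paste0("S", i), rep(0L, 17)))
  expect_error(cluster_cohort(recs), "no clusterable subjects")
  recs[[1]] <- hamd_record("S1", c(4L, rep(0L, 16)))
  expect_error(cluster_cohort(recs), "fewer than 2")
})

test_that("K-means matches the exhaustive best 2-partition for small n", {
  for (seed in 1:4) {
    ch <- generate_hamd_cohort(4, profiles = separated_symptom_profiles(2),
                               seed = seed)
    x <- t(vapply(ch$records, `[[`, integer(17), "items"))
    keep <- rowSums(x) >= 4
    x <- x[keep, , drop = FALSE]
    cl <- cluster_cohort(ch$records[keep], seed = seed, n_restarts = 30)
    b <- brute_force_partition(x)
    got <- cl$assignment[!is.na(cl$assignment)]
    expect_equal(cl$objective, b$objective, tolerance = 1e-9)
    expect_true(all(got == b$g) || all(got == 3L - b$g))
  }
})

test_that("equidistant low-total subjects take the canonical group 1", {
  # two symmetric seed clusters; the probe profile is invariant under the
  # item permutation that swaps the clusters, so both distances are equal
  mk <- function(id, items) {
    v <- rep(0L, 17); v[items] <- 4L
    hamd_record(id, v)
  }
  recs <- list(mk("A1", c(1, 2)), mk("A2", c(1, 2)),
               mk("B1", c(3, 7)), mk("B2", c(3, 7)))
  probe <- rep(0L, 17); probe[1] <- 1L; probe[3] <- 1L
  recs$P <- hamd_record("P", probe)
  cl <- cluster_cohort(recs, seed = 1)
  d <- voicesym:::corr_dist_matrix(matrix(as.numeric(probe), 1), cl$centroids)
  expect_equal(d[1, 1], d[1, 2], tolerance = 1e-12)
  expect_equal(cl$stage[["P"]], "allocated")
  expect_equal(cl$assignment[["P"]], 1L)
  # canonical labels: group 1 carries the higher item-7 centroid
  expect_gte(cl$centroids[1, 7], cl$centroids[2, 7])
})

test_that("canonical labeling is invariant to the clustering seed", {
  ch <- generate_hamd_cohort(20, profiles = separated_symptom_profiles(2),
                             seed = 9)
  a <- cluster_cohort(ch$records, seed = 1)
  b <- cluster_cohort(ch$records, seed = 99)
  expect_identical(a$assignment, b$assignment)
})

test_that("item tests use the Bonferroni-corrected tiers", {
  ch <- generate_hamd_cohort(25, profiles = separated_symptom_profiles(2),
                             seed = 3)
  cl <- cluster_cohort(ch$records, seed = 3)
  rep_ <- item_wise_tests(ch$records, cl$assignment)
  lv <- attr(rep_, "corrected_levels")
  expect_equal(unname(lv["*"]), 0.05 / 18)
  expect_equal(unname(lv["**"]), 0.01 / 18)
  expect_equal(unname(lv["***"]), 0.005 / 18)
  expect_equal(nrow(rep_), 18)
  expect_true(all(rep_$tier[rep_$p_value >= 0.05 / 18] == ""))
})

test_that("type-I error is controlled under the null", {
  # both groups drawn from one distribution; fraction of significant calls
  # at the corrected level stays below the family alpha
  n_sig <- 0L
  n_tot <- 0L
  pr <- default_symptom_profiles(0)
  for (s in 1:200) {
    ch <- generate_hamd_cohort(30, profiles = list(pr[[1]], pr[[1]]),
                               seed = 5000 + s)
    rep_ <- item_wise_tests(ch$records, ch$true_group)
    n_sig <- n_sig + sum(rep_$tier != "")
    n_tot <- n_tot + nrow(rep_)
  }
  expect_lte(n_sig / n_tot, 0.05)
})

test_that("a shifted item is flagged and the normal approximation is close
           to exact enumeration", {
  pr <- default_symptom_profiles(0)
  pr2 <- pr[[1]]
  pr2$item_means[5] <- pr2$item_means[5] + 2
  ch <- generate_hamd_cohort(25, profiles = list(pr[[1]], pr2), seed = 7)
  rep_ <- item_wise_tests(ch$records, ch$true_group)
  expect_true(rep_$tier[rep_$test == "item_5"] != "")

  # exact permutation oracle at n = 5 / 5
  x <- c(0L, 1L, 1L, 2L, 0L)
  y <- c(2L, 3L, 1L, 4L, 2L)
  mk <- function(id, v5) {
    v <- rep(0L, 17); v[5] <- min(v5, 2L); v[1] <- max(0L, v5 - 2L)
    hamd_record(id, v)
  }
  recs <- c(lapply(1:5, function(i) mk(paste0("a", i), x[i])),
            lapply(1:5, function(i) mk(paste0("b", i), y[i])))
  grp <- stats::setNames(rep(1:2, each = 5),
                         vapply(recs, `[[`, "", "subject_id"))
  rep2 <- item_wise_tests(recs, grp)
  u_obs <- rep2$statistic[rep2$test == "total"]
  tot <- vapply(recs, `[[`, 0L, "total")
  splits <- utils::combn(10, 5)
  u_all <- apply(splits, 2, function(ix) {
    r <- rank(tot)
    sum(r[ix]) - 5 * 6 / 2
  })
  p_exact <- mean(abs(u_all - mean(u_all)) >= abs(u_obs - mean(u_all)) - 1e-9)
  p_ours <- rep2$p_value[rep2$test == "total"]
  expect_lt(abs(p_ours - p_exact), 0.06)
})

test_that("both groups must be non-empty for item tests", {
  ch <- generate_hamd_cohort(5, seed = 1)
  grp <- ch$true_group
  grp[] <- 1L
  expect_error(item_wise_tests(ch$records, grp), "non-empty")
})
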