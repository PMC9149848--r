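toy_covariates <- function(tug1 = 10, tug3 = 10, ugs1 = 120, ugs3 = 120,
                           dtgs1 = 110, dtgs3 = 110, mmse1 = 29, mmse3 = 29,
                           moca1 = 26, moca3 = 26, falls1 = 0, falls3 = 0) {
  data.frame(participant_id = "p1", tug1 = tug1, tug3 = tug3,
             ugs1 = ugs1, ugs3 = ugs3, dtgs1 = dtgs1, dtgs3 = dtgs3,
             mmse1 = mmse1, mmse3 = mmse3, moca1 = moca1, moca3 = moca3,
             falls1 = falls1, falls3 = falls3, stringsAsFactors = FALSE)
}

test_that("decline cut-offs fire exactly at their boundaries", {
  expect_true(decline_flags(toy_covariates(tug1 = 11, tug3 = 12))$tug_decline)
  expect_false(decline_flags(toy_covariates(tug1 = 12, tug3 = 13))$tug_decline)
  expect_true(decline_flags(toy_covariates(ugs1 = 100, ugs3 = 99))$ugs_decline)
  expect_false(decline_flags(toy_covariates(ugs1 = 99, ugs3 = 90))$ugs_decline)
  expect_true(decline_flags(toy_covariates(mmse1 = 29, mmse3 = 27))$mmse_decline)
  expect_false(decline_flags(toy_covariates(mmse1 = 29, mmse3 = 28))$mmse_decline)
  expect_true(decline_flags(toy_covariates(moca1 = 26, moca3 = 24))$moca_decline)
  expect_false(decline_flags(toy_covariates(falls1 = 0, falls3 = 0))$new_faller)
  expect_true(decline_flags(toy_covariates(falls1 = 0, falls3 = 2))$new_faller)
  expect_false(decline_flags(toy_covariates(falls1 = 1, falls3 = 2))$new_faller)
})

test_that("missing inputs yield absent flags, never silent FALSE", {
  flg <- decline_flags(toy_covariates(tug3 = NA, mmse1 = NA))
  expect_true(is.na(flg$tug_decline))
  expect_true(is.na(flg$mmse_decline))
  expect_false(is.na(flg$ugs_decline))
})

test_that("tug decline is monotone in the wave-3 value", {
  flagged <- FALSE
  for (t3 in seq(10, 25, by = 0.5)) {
    f <- decline_flags(toy_covariates(tug1 = 11, tug3 = t3))$tug_decline
    expect_false(flagged && !f)   # once flagged, worsening never unflags
    flagged <- f
  }
})

test_that("relative change follows its definition", {
  expect_equal(relative_change(100, 90), 0.10)
  expect_equal(relative_change(7, 7), 0)
  expect_equal(round(relative_change(17.7, 120.7), 2), -5.82)
  expect_true(is.na(relative_change(0, 5)))
})

test_that("paired wave comparison handles shift, symmetry and degeneracy", {
  x <- rnorm(50, 100, 5)
  expect_lt(compare_waves_within_cluster(x, x + 3)$p_value, 0.001)

  r <- compare_waves_within_cluster(x, x)
  expect_true(is.na(r$p_value))
  expect_equal(r$n_effective, 0L)

  mag <- (1:10) - 0.5
  d <- c(mag, -mag)             # antisymmetric differences
  w1 <- rep(100, 20)
  r2 <- compare_waves_within_cluster(w1 + d, w1)
  expect_equal(unname(r2$statistic), 20 * 21 / 4)   # null centre n(n+1)/4
})

test_that("between-cluster comparison is a Mann-Whitney U test", {
  a <- rep(1, 10); b <- rep(1, 15)
  expect_equal(compare_change_between_clusters(a, b)$statistic, 10 * 15 / 2)
  sep <- compare_change_between_clusters(1:10, 101:110)
  expect_true(sep$statistic %in% c(0, 100))
  expect_error(compare_change_between_clusters(numeric(0), 1:3), "empty")
})

test_that("a known location shift is detected in most replicates", {
  hits <- 0
  for (i in 1:200) {
    set.seed(6000 + i)
    a <- rlnorm(40, 0, 0.5)
    b <- rlnorm(40, 1, 0.5)
    if (compare_change_between_clusters(a, b)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("decline-by-cluster chi-square matches the textbook formula", {
  labels <- rep(c("blue", "green", "red"), each = 50)
  flags <- c(rep(c(TRUE, FALSE), c(5, 45)),
             rep(c(TRUE, FALSE), c(10, 40)),
             rep(c(TRUE, FALSE), c(20, 30)))
  r <- decline_by_cluster_test(flags, labels)
  # manual expected-count oracle on the 2x3 table
  obs <- rbind(c(45, 40, 30), c(5, 10, 20))
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(r$chi2, sum((obs - exp_)^2 / exp_), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(round_half_out(r$critical_value, 2), 5.99)
  expect_equal(unname(r$percentages), c(10, 20, 40))

  same <- decline_by_cluster_test(rep(c(TRUE, FALSE), c(10, 40)) |>
                                    rep(3), labels)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
})

test_that("untestable clusters are dropped with adjusted df", {
  labels <- rep(c("a", "b", "c"), each = 20)
  flags <- c(rep(TRUE, 8), rep(FALSE, 12), rep(c(TRUE, FALSE), 10),
             rep(NA, 20))
  expect_warning(r <- decline_by_cluster_test(flags, labels), "dropped")
  expect_equal(r$df, 1)
})

test_that("spearman trend covers monotone, reversed and constant input", {
  expect_equal(spearman_trend(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_trend(1:10, 10:1)$rho, -1)
  expect_true(is.na(spearman_trend(rep(2, 10), rnorm(10))$rho))
  low <- 0
  for (i in 1:100) {
    set.seed(7000 + i)
    if (abs(spearman_trend(rnorm(500), rnorm(500))$rho) < 0.1) low <- low + 1
  }
  expect_gte(low / 100, 0.95)
})

test_that("decliner-enriched cohorts put the highest decline in the red cluster", {
  # full generator -> features -> FCM -> semantics -> decline percentages
  hits <- c(ugs = 0, mmse = 0, moca = 0)
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    coh <- generate_cohort(n = 1000, rng_seed = 20000 + i)
    ex <- extract_features(coh$trials)
    f1 <- ex$features[ex$features$wave == 1, ]
    f3 <- ex$features[ex$features$wave == 3, ]
    pts <- cbind(f1$bp[match(f3$participant_id, f1$participant_id)], f3$bp)
    fit <- fcm_restarts(pts, c = 3, seed = 20000 + i, restarts = 3)
    sem <- label_semantics(fit$centroids)
    labels <- sem[assign_hard(fit)]
    cv <- coh$covariates[match(f3$participant_id,
                               coh$covariates$participant_id), ]
    flg <- decline_flags(cv)
    for (v in c("ugs", "mmse", "moca")) {
      pcts <- tapply(flg[[paste0(v, "_decline")]], labels, mean,
                     na.rm = TRUE)
      if (!is.na(pcts["red"]) && pcts["red"] == max(pcts, na.rm = TRUE) &&
          sum(pcts == max(pcts, na.rm = TRUE), na.rm = TRUE) == 1) {
        hits[v] <- hits[v] + 1
      }
    }
  }
  expect_gte(hits[["ugs"]] / n_rep, 0.9)
  expect_gte(hits[["mmse"]] / n_rep, 0.9)
  expect_gte(hits[["moca"]] / n_rep, 0.9)
})

test_that("full characterisation report is internally consistent", {
  coh <- generate_cohort(n = 200, rng_seed = 31)
  labels <- coh$labels
  rep_ <- suppressWarnings(characterize_clusters(coh$covariates, labels))
  expect_s3_class(rep_, "cluster_report")
  expect_equal(nrow(rep_$decline_tests), 6)
  pct_cols <- grep("^pct_", names(rep_$decline_tests), value = TRUE)
  pcts <- unlist(rep_$decline_tests[, pct_cols])
  expect_true(all(pcts >= 0 & pcts <= 100, na.rm = TRUE))
  # percentages recompute from raw flags by brute-force counting
  flg <- rep_$decline_flags
  ug <- flg$ugs_decline
  for (cl in unique(labels)) {
    manual <- 100 * sum(ug[labels == cl], na.rm = TRUE) /
      sum(!is.na(ug[labels == cl]))
    got <- rep_$decline_tests[rep_$decline_tests$variable == "ugs",
                              paste0("pct_", cl)]
    expect_equal(got, round_half_out(manual, 1))
  }
})
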