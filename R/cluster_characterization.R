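#' Mobility and cognitive decline flags
#'
#' Applies the clinical decline cut-offs to a participant's two-wave
#' covariates: TUG decline (TUG1 < 12 s and TUG3 >= 12 s), usual and
#' dual-task gait-speed decline (wave-1 speed >= 100 cm/s and wave-3 speed
#' < 100 cm/s), MMSE and MoCA decline (a drop of at least 2 points), and new
#' faller (no falls before wave 1, at least one before wave 3). A flag is NA
#' whenever either wave's input is missing: absence of evidence is never
#' reported as "no decline".
#'
#' @param covariates wide covariate data frame (columns `tug1`, `tug3`,
#'   `ugs1`, `ugs3`, `dtgs1`, `dtgs3`, `mmse1`, `mmse3`, `moca1`, `moca3`,
#'   `falls1`, `falls3`; extra columns pass through unharmed).
#' @param tug_cutoff,gait_cutoff,score_drop configurable cut-offs (12 s,
#'   100 cm/s, 2 points).
#' @return data frame: `participant_id` plus logical columns `tug_decline`,
#'   `ugs_decline`, `dtgs_decline`, `mmse_decline`, `moca_decline`,
#'   `new_faller`.
#' @export
decline_flags <- function(covariates, tug_cutoff = 12, gait_cutoff = 100,
                          score_drop = 2) {
  cv <- covariates
  flag <- function(x1, x3, rule) ifelse(is.na(x1) | is.na(x3), NA, rule)
  data.frame(
    participant_id = cv$participant_id,
    tug_decline = flag(cv$tug1, cv$tug3,
                       cv$tug1 < tug_cutoff & cv$tug3 >= tug_cutoff),
    ugs_decline = flag(cv$ugs1, cv$ugs3,
                       cv$ugs1 >= gait_cutoff & cv$ugs3 < gait_cutoff),
    dtgs_decline = flag(cv$dtgs1, cv$dtgs3,
                        cv$dtgs1 >= gait_cutoff & cv$dtgs3 < gait_cutoff),
    mmse_decline = flag(cv$mmse1, cv$mmse3,
                        cv$mmse1 - cv$mmse3 >= score_drop),
    moca_decline = flag(cv$moca1, cv$moca3,
                        cv$moca1 - cv$moca3 >= score_drop),
    new_faller = flag(cv$falls1, cv$falls3,
                      cv$falls1 == 0 & cv$falls3 > 0),
    stringsAsFactors = FALSE
  )
}

#' Relative inter-wave change
#'
#' `(x1 - x3) / x1`: positive values mean decline for "higher is better"
#' variables (gait speeds, MMSE, MoCA) and improvement for "lower is better"
#' ones (TUG, falls). Undefined when the wave-1 value is zero; such cases
#' are returned as NA and should be excluded (with their count reported)
#' from downstream distributions.
#'
#' @param x1,x3 wave-1 and wave-3 values.
#' @return numeric vector of relative changes (NA where `x1 == 0`).
#' @examples
#' relative_change(100, 90)     # 0.10
#' relative_change(17.7, 120.7) # -5.82...: a 582% increase
#' @export
relative_change <- function(x1, x3) {
  ifelse(is.na(x1) | is.na(x3) | x1 == 0, NA_real_, (x1 - x3) / x1)
}

#' Paired two-wave comparison within a cluster
#'
#' Wilcoxon signed-rank test on the paired wave-1/wave-3 values of one
#' variable within one cluster (exact for small samples without ties, normal
#' approximation with continuity correction otherwise, as in
#' [stats::wilcox.test()]). When every difference is zero the test is
#' degenerate and the p-value is reported as NA.
#'
#' @param values_w1,values_w3 paired numeric vectors.
#' @return list: `statistic` (V), `p_value`, `n_effective` (non-zero-
#'   difference pairs).
#' @export
compare_waves_within_cluster <- function(values_w1, values_w3) {
  ok <- !is.na(values_w1) & !is.na(values_w3)
  d <- values_w1[ok] - values_w3[ok]
  n_eff <- sum(d != 0)
  if (n_eff == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_effective = 0L))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(values_w1[ok], values_w3[ok], paired = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_effective = n_eff)
}

#' Between-cluster comparison of inter-wave changes
#'
#' Mann-Whitney U test comparing the distributions of relative inter-wave
#' changes between two clusters (independent samples).
#'
#' @param changes_a,changes_b numeric vectors of relative changes.
#' @return list: `statistic` (U), `p_value`, sample sizes.
#' @export
compare_change_between_clusters <- function(changes_a, changes_b) {
  a <- changes_a[!is.na(changes_a)]
  b <- changes_b[!is.na(changes_b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(a), n_b = length(b))
}

#' Independence of decline and cluster membership
#'
#' Pearson chi-square (no continuity correction) on the 2 x c table of
#' decline vs cluster. For a 2 x c table the degrees of freedom equal
#' c - 1; with three clusters df = 2 and the alpha = 0.05 critical value is
#' 5.99. Clusters with no testable member are dropped with a warning and the
#' df adjusted. An expected count below 5 triggers a warning, not an exact
#' test.
#'
#' @param flags logical decline flags per participant (NA = untestable).
#' @param labels cluster labels, same length.
#' @param alpha significance level for the reported critical value.
#' @return list: `chi2`, `df`, `p_value`, `critical_value`,
#'   `percentages` (per-cluster decline %), `n_tested` per cluster.
#' @export
decline_by_cluster_test <- function(flags, labels, alpha = 0.05) {
  stopifnot(length(flags) == length(labels))
  ok <- !is.na(flags)
  f <- flags[ok]; l <- as.character(labels[ok])
  counts <- table(l)
  if (length(counts) < 2) stop("need at least 2 clusters with tested members")
  dropped <- setdiff(unique(as.character(labels)), names(counts))
  if (length(dropped)) {
    warning("clusters with no tested members dropped: ",
            paste(dropped, collapse = ", "))
  }
  tab <- table(factor(f, levels = c(FALSE, TRUE)), l)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("chi-square expected count below 5; interpret with caution")
  }
  pct <- vapply(names(counts), function(cl) {
    percent(sum(f[l == cl]), sum(l == cl), 1)
  }, numeric(1))
  list(
    chi2 = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    critical_value = stats::qchisq(1 - alpha, unname(ht$parameter)),
    percentages = pct,
    n_tested = as.integer(counts)
  )
}

#' Spearman trend between the two waves' bad performances
#'
#' Rank correlation (mid-ranks for ties) between BP at wave 1 and wave 3.
#'
#' @param bp1,bp3 paired numeric vectors (n >= 3).
#' @return list: `rho`, `p_value`, `n`; `rho` is NA for constant input.
#' @export
spearman_trend <- function(bp1, bp3) {
  ok <- !is.na(bp1) & !is.na(bp3)
  x <- bp1[ok]; y <- bp3[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

# Which variables improve with larger values; controls the sign reading of
# relative-change summaries.
higher_is_better <- c(tug = FALSE, falls = FALSE, ugs = TRUE, dtgs = TRUE,
                      mmse = TRUE, moca = TRUE)

#' Full three-level cluster characterisation
#'
#' For each of the six main variables (TUG, falls, UGS, DTGS, MMSE, MoCA)
#' runs (i) the paired within-cluster wave comparison, (ii) pairwise
#' between-cluster Mann-Whitney tests of the relative inter-wave change, and
#' (iii) the chi-square independence test of the decline proportion across
#' clusters. A between-cluster comparison whose sample empties out through
#' the zero-baseline exclusion (common for falls) is reported as NA with the
#' excluded count, not an error.
#'
#' @param covariates wide covariate table (as from [generate_cohort()]).
#' @param labels cluster labels per participant (same order as
#'   `covariates`), e.g. semantic colours.
#' @param alpha significance level.
#' @return an object of class `cluster_report` with elements `within_waves`,
#'   `between_changes`, `decline_tests` (data frames) and `decline_flags`.
#' @export
characterize_clusters <- function(covariates, labels, alpha = 0.05) {
  stopifnot(nrow(covariates) == length(labels))
  vars <- c("tug", "falls", "ugs", "dtgs", "mmse", "moca")
  labs <- as.character(labels)
  flg <- decline_flags(covariates)

  within <- list(); between <- list(); decl <- list()
  for (v in vars) {
    x1 <- covariates[[paste0(v, "1")]]
    x3 <- covariates[[paste0(v, "3")]]
    for (cl in unique(labs)) {
      idx <- labs == cl
      r <- compare_waves_within_cluster(x1[idx], x3[idx])
      within[[length(within) + 1]] <- data.frame(
        variable = v, cluster = cl,
        mean_w1 = mean(x1[idx], na.rm = TRUE),
        sd_w1 = stats::sd(x1[idx], na.rm = TRUE),
        mean_w3 = mean(x3[idx], na.rm = TRUE),
        sd_w3 = stats::sd(x3[idx], na.rm = TRUE),
        statistic = r$statistic, p_value = r$p_value,
        n_effective = r$n_effective, stringsAsFactors = FALSE)
    }
    rc <- relative_change(x1, x3)
    cls <- sort(unique(labs))
    if (length(cls) >= 2) {
      prs <- utils::combn(cls, 2)
      for (j in seq_len(ncol(prs))) {
        a <- prs[1, j]; b <- prs[2, j]
        # a cluster can lose every member to the x1 = 0 exclusion
        # (typical for falls); report the pair as unavailable, not an abort
        r <- tryCatch(
          compare_change_between_clusters(rc[labs == a], rc[labs == b]),
          error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                                   n_a = sum(!is.na(rc[labs == a])),
                                   n_b = sum(!is.na(rc[labs == b]))))
        between[[length(between) + 1]] <- data.frame(
          variable = v, cluster_a = a, cluster_b = b,
          statistic = r$statistic, p_value = r$p_value,
          n_a = r$n_a, n_b = r$n_b,
          n_undefined = sum(is.na(rc[labs %in% c(a, b)])),
          stringsAsFactors = FALSE)
      }
    }
    fname <- switch(v, falls = "new_faller", paste0(v, "_decline"))
    dt <- decline_by_cluster_test(flg[[fname]], labs, alpha)
    decl[[length(decl) + 1]] <- cbind(
      data.frame(variable = v, chi2 = dt$chi2, df = dt$df,
                 p_value = dt$p_value, critical_value = dt$critical_value,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(
        dt$percentages, paste0("pct_", names(dt$percentages))))))
  }
  structure(list(
    within_waves = do.call(rbind, within),
    between_changes = do.call(rbind, between),
    decline_tests = do.call(rbind, decl),
    decline_flags = flg,
    alpha = alpha
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster characterisation (alpha =", x$alpha, ")\n\n")
  cat("Decline-proportion independence tests:\n")
  print(x$decline_tests, row.names = FALSE, digits = 3)
  invisible(x)
}
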