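#' Validate a raw trial log
#'
#' Checks the structural invariants of a single participant-wave session:
#' exactly 207 records, digits follow the fixed 1..9 order within each of the
#' 23 cycles (so exactly 23 no-go presentations of the digit 3), unique and
#' exhaustive (cycle, position) pairs, and an RT present iff a response was
#' recorded.
#'
#' @param log a trial-log data frame (one participant, one wave).
#' @return the log, invisibly, if valid; otherwise an error.
#' @export
validate_trial_log <- function(log) {
  need <- c("cycle", "position", "digit", "responded", "rt_ms")
  if (!all(need %in% names(log))) {
    stop("trial log lacks columns: ", paste(setdiff(need, names(log)),
                                            collapse = ", "))
  }
  if (nrow(log) != 207) {
    stop("trial log must contain exactly 207 records (23 cycles x 9 digits), ",
         "found ", nrow(log))
  }
  key <- (log$cycle - 1L) * 9L + log$position
  if (anyDuplicated(key)) stop("duplicate (cycle, position) pairs in trial log")
  if (!identical(sort(as.integer(key)), 1:207)) {
    stop("(cycle, position) pairs are not exhaustive over 23 x 9")
  }
  if (any(log$digit != log$position)) {
    stop("digits must follow the fixed 1..9 presentation order within a cycle")
  }
  if (any(log$responded & is.na(log$rt_ms)) ||
      any(!log$responded & !is.na(log$rt_ms))) {
    stop("rt_ms must be present exactly for responded presentations")
  }
  invisible(log)
}

#' Per-cycle mistake counts for one session
#'
#' A mistake is a commission (response on the no-go digit 3) or an omission
#' (no response on a go digit). Each 9-digit cycle therefore carries 0 to 9
#' mistakes.
#'
#' @param log a validated trial log (one participant-wave).
#' @return a data frame of 23 rows: `cycle`, `n_mistakes`, `mean_rt` (mean RT
#'   over responded presentations in the cycle; NA when none responded).
#' @export
count_cycle_mistakes <- function(log) {
  validate_trial_log(log)
  log <- log[order(log$cycle, log$position), ]
  mistake <- ifelse(log$digit == 3, log$responded, !log$responded)
  by_cycle <- split(seq_len(207), log$cycle)
  data.frame(
    cycle = 1:23,
    n_mistakes = vapply(by_cycle, function(i) sum(mistake[i]), integer(1)),
    mean_rt = vapply(by_cycle, function(i) {
      r <- log$rt_ms[i][log$responded[i]]
      if (length(r)) mean(r) else NA_real_
    }, numeric(1)),
    row.names = NULL
  )
}

#' Session-level SART features
#'
#' Computes the thresholded "bad performance" statistic and the global SART
#' features for one session: `bp` counts the cycles with at least
#' `threshold` (default 4) mistakes out of 9 actions; `total_mistakes` sums
#' mistakes over all 23 cycles; `mistakes_good` sums mistakes over the good
#' cycles only (those below the threshold). Mean and SD of RT are computed
#' over all responded presentations, i.e. go hits and commission presses.
#'
#' @param cycles output of [count_cycle_mistakes()].
#' @param log the matching trial log (for the RT summary).
#' @param threshold minimum mistakes per cycle for a bad performance.
#' @return one-row data frame: `bp`, `total_mistakes`, `mistakes_good`,
#'   `mean_rt`, `sd_rt`.
#' @export
wave_features <- function(cycles, log, threshold = 4) {
  stopifnot(nrow(cycles) == 23, threshold >= 1)
  bad <- cycles$n_mistakes >= threshold
  rts <- log$rt_ms[log$responded]
  data.frame(
    bp = sum(bad),
    total_mistakes = sum(cycles$n_mistakes),
    mistakes_good = sum(cycles$n_mistakes[!bad]),
    mean_rt = if (length(rts)) mean(rts) else NA_real_,
    sd_rt = if (length(rts) > 1) stats::sd(rts) else NA_real_
  )
}

#' Extract per-participant features for a whole cohort
#'
#' Runs [count_cycle_mistakes()] and [wave_features()] over every
#' participant-wave session in a long trial-log table.
#'
#' @param trials trial-log rows for one or more participants and waves.
#' @param threshold bad-performance threshold (mistakes per cycle).
#' @return a list with `features` (one row per participant-wave:
#'   `participant_id`, `wave`, `bp`, `total_mistakes`, `mistakes_good`,
#'   `mean_rt`, `sd_rt`) and `cycles` (one row per participant-wave-cycle).
#' @export
extract_features <- function(trials, threshold = 4) {
  parts <- split(trials, list(trials$participant_id, trials$wave), drop = TRUE)
  feats <- vector("list", length(parts))
  cycs <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    log <- parts[[i]]
    cyc <- count_cycle_mistakes(log)
    f <- wave_features(cyc, log, threshold)
    id <- log$participant_id[1]; wv <- log$wave[1]
    feats[[i]] <- cbind(participant_id = id, wave = wv, f,
                        stringsAsFactors = FALSE)
    cycs[[i]] <- cbind(participant_id = id, wave = wv, cyc,
                       stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  cycles <- do.call(rbind, cycs)
  features <- features[order(features$participant_id, features$wave), ]
  cycles <- cycles[order(cycles$participant_id, cycles$wave, cycles$cycle), ]
  rownames(features) <- rownames(cycles) <- NULL
  list(features = features, cycles = cycles)
}

#' Distribution of per-cycle mistake counts at both waves
#'
#' For each mistake count k = 0..9, tabulates how many participants had at
#' least one cycle with exactly k mistakes and how many cycles in total
#' carried k mistakes, at each wave, together with the percent change
#' between waves (one decimal, half away from zero; undefined when the
#' wave-1 count is zero).
#'
#' @param cycles_w1,cycles_w3 per-cycle tables (from [extract_features()])
#'   for the same cohort at waves 1 and 3.
#' @return a data frame with one row per k = 0..9: participant and cycle
#'   counts per wave, numeric percent changes, and formatted versions.
#' @export
mistake_distribution <- function(cycles_w1, cycles_w3) {
  if (!setequal(unique(cycles_w1$participant_id),
                unique(cycles_w3$participant_id))) {
    stop("wave 1 and wave 3 cycle tables must cover the same cohort")
  }
  tab <- function(cycles) {
    k <- 0:9
    n_cycles <- vapply(k, function(kk) sum(cycles$n_mistakes == kk),
                       numeric(1))
    n_participants <- vapply(k, function(kk) {
      length(unique(cycles$participant_id[cycles$n_mistakes == kk]))
    }, numeric(1))
    list(p = n_participants, c = n_cycles)
  }
  t1 <- tab(cycles_w1); t3 <- tab(cycles_w3)
  data.frame(
    k = 0:9,
    n_participants_w1 = t1$p, n_cycles_w1 = t1$c,
    n_participants_w3 = t3$p, n_cycles_w3 = t3$c,
    pct_change_participants = pct_change(t1$p, t3$p),
    pct_change_cycles = pct_change(t1$c, t3$c),
    fmt_change_participants = format_pct_change(pct_change(t1$p, t3$p)),
    fmt_change_cycles = format_pct_change(pct_change(t1$c, t3$c)),
    stringsAsFactors = FALSE
  )
}

#' Longitudinal bad-performance transition summary
#'
#' Bookkeeping for the two-wave evolution of the bad-performance statistic:
#' how many participants had any bad performance at each wave, how many
#' persisted, improved (bad at wave 1 only) or worsened (bad at wave 3
#' only), plus the density of exact (BP1, BP3) pairs with the mean wave-1
#' age per pair.
#'
#' @param features_w1,features_w3 per-participant feature rows at each wave.
#' @param ages_w1 optional data frame `participant_id`, `age1` for the pair
#'   density colouring.
#' @return a list of class `bp_transition` with counts `n_bp_w1`, `n_bp_w3`,
#'   `n_persist`, `n_improved`, `n_worsened`, percentages
#'   `pct_improved_of_w1` and `pct_new_of_w3` (integer-rounded), and the
#'   `pair_density` data frame.
#' @export
bp_transition <- function(features_w1, features_w3, ages_w1 = NULL) {
  m <- merge(features_w1[, c("participant_id", "bp")],
             features_w3[, c("participant_id", "bp")],
             by = "participant_id", suffixes = c("1", "3"))
  if (nrow(m) != nrow(features_w1) || nrow(m) != nrow(features_w3)) {
    stop("unpaired participant ids between waves")
  }
  n_bp_w1 <- sum(m$bp1 >= 1)
  n_bp_w3 <- sum(m$bp3 >= 1)
  n_persist <- sum(m$bp1 >= 1 & m$bp3 >= 1)
  if (!is.null(ages_w1)) {
    m <- merge(m, ages_w1[, c("participant_id", "age1")],
               by = "participant_id", all.x = TRUE)
  } else {
    m$age1 <- NA_real_
  }
  agg <- aggregate(age1 ~ bp1 + bp3, data = m, FUN = mean,
                   na.action = stats::na.pass)
  cnt <- aggregate(participant_id ~ bp1 + bp3, data = m, FUN = length)
  pair_density <- merge(cnt, agg, by = c("bp1", "bp3"))
  names(pair_density) <- c("bp1", "bp3", "count", "mean_age_w1")
  pair_density <- pair_density[order(pair_density$bp1, pair_density$bp3), ]
  rownames(pair_density) <- NULL
  structure(list(
    n = nrow(m),
    n_bp_w1 = n_bp_w1, n_bp_w3 = n_bp_w3, n_persist = n_persist,
    n_improved = n_bp_w1 - n_persist,
    n_worsened = n_bp_w3 - n_persist,
    pct_improved_of_w1 = if (n_bp_w1 > 0)
      percent(n_bp_w1 - n_persist, n_bp_w1, 0) else NA_real_,
    pct_new_of_w3 = if (n_bp_w3 > 0)
      percent(n_bp_w3 - n_persist, n_bp_w3, 0) else NA_real_,
    pair_density = pair_density
  ), class = "bp_transition")
}

#' @export
print.bp_transition <- function(x, ...) {
  cat("Bad-performance transitions over", x$n, "paired participants\n")
  cat(sprintf("  wave 1 with BP >= 1: %d (%s%%)\n", x$n_bp_w1,
              format(percent(x$n_bp_w1, x$n, 1))))
  cat(sprintf("  wave 3 with BP >= 1: %d\n", x$n_bp_w3))
  cat(sprintf("  persisted: %d | improved: %d (%s%% of wave-1) | ",
              x$n_persist, x$n_improved, format(x$pct_improved_of_w1)))
  cat(sprintf("worsened: %d (%s%% of wave-3 new)\n",
              x$n_worsened, format(x$pct_new_of_w3)))
  invisible(x)
}

#' Dichotomise wave-3 bad performances
#'
#' The binary outcome of the predictive models: 1 for participants with at
#' least one bad performance at wave 3, 0 otherwise.
#'
#' @param features_w3 wave-3 feature rows (column `bp`).
#' @return integer 0/1 vector, named by participant id.
#' @export
dichotomise_bp3 <- function(features_w3) {
  stats::setNames(as.integer(features_w3$bp >= 1),
                  features_w3$participant_id)
}
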