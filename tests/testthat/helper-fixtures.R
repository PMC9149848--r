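# Fixtures built in code: perfect sessions, mistake injection, and
# brute-force oracles independent of the implementation under test.

perfect_log <- function(pid = "p1", wave = 1) {
  digit <- rep(1:9, 23)
  responded <- digit != 3
  data.frame(
    participant_id = pid, wave = as.integer(wave),
    cycle = rep(1:23, each = 9), position = rep(1:9, 23), digit = digit,
    responded = responded,
    rt_ms = ifelse(responded, 300 + digit, NA_real_),
    stringsAsFactors = FALSE
  )
}

# Force exactly k mistakes into one cycle: a commission on the 3 first,
# then omissions on go digits.
inject_mistakes <- function(log, cycle, k) {
  stopifnot(k >= 0, k <= 9)
  if (k == 0) return(log)
  pos <- c(3, setdiff(1:9, 3))[seq_len(k)]
  idx <- log$cycle == cycle & log$position %in% pos
  flip <- log$digit[idx] == 3
  log$responded[idx] <- flip
  log$rt_ms[idx] <- ifelse(flip, 300, NA_real_)
  log
}

# Build a session whose 23 cycles carry the given mistake counts.
log_with_mistakes <- function(mistakes, pid = "p1", wave = 1) {
  stopifnot(length(mistakes) == 23)
  log <- perfect_log(pid, wave)
  for (cy in which(mistakes > 0)) log <- inject_mistakes(log, cy, mistakes[cy])
  log
}

# Brute-force feature oracle: direct iteration over the 207 records.
oracle_features <- function(log, threshold = 4) {
  per_cycle <- integer(23)
  rts <- numeric(0)
  for (r in seq_len(nrow(log))) {
    wrong <- if (log$digit[r] == 3) log$responded[r] else !log$responded[r]
    if (wrong) per_cycle[log$cycle[r]] <- per_cycle[log$cycle[r]] + 1L
    if (log$responded[r]) rts <- c(rts, log$rt_ms[r])
  }
  bad <- per_cycle >= threshold
  list(per_cycle = per_cycle, bp = sum(bad), total = sum(per_cycle),
       good = sum(per_cycle[!bad]),
       mean_rt = if (length(rts)) mean(rts) else NA_real_,
       sd_rt = if (length(rts) > 1) sd(rts) else NA_real_)
}

# Brute-force transition oracle: explicit loop over participants.
oracle_transition <- function(bp1, bp3) {
  n1 <- 0; n3 <- 0; persist <- 0
  for (i in seq_along(bp1)) {
    if (bp1[i] >= 1) n1 <- n1 + 1
    if (bp3[i] >= 1) n3 <- n3 + 1
    if (bp1[i] >= 1 && bp3[i] >= 1) persist <- persist + 1
  }
  list(n_bp_w1 = n1, n_bp_w3 = n3, n_persist = persist,
       n_improved = n1 - persist, n_worsened = n3 - persist)
}

# Brute-force WSS.
oracle_wss <- function(points, labels, centroids) {
  s <- 0
  for (i in seq_len(nrow(points))) {
    s <- s + sum((points[i, ] - centroids[labels[i], ])^2)
  }
  s
}

# A paired feature table with given BP values.
features_from_bp <- function(bp, wave) {
  data.frame(participant_id = sprintf("P%05d", seq_along(bp)),
             wave = wave, bp = bp, total_mistakes = bp * 4L,
             mistakes_good = 0L, mean_rt = 400, sd_rt = 60,
             stringsAsFactors = FALSE)
}

quiet_profile <- function(weight = 1, lapse_w1 = 0, lapse_w3 = 0,
                          p_lapsed = 0.7, p_normal = 0) {
  class_profile(
    label = "test", weight = weight,
    lapse_rate_w1 = lapse_w1, lapse_rate_w3 = lapse_w3,
    p_mistake_lapsed = p_lapsed, p_mistake_normal = p_normal,
    rt_mean_w1 = 380, rt_mean_w3 = 350, rt_sd = 90,
    covariate_base = list(tug = c(8.4, 1.6), ugs = c(138, 19),
                          dtgs = c(114, 25), mmse = c(29, 1.5),
                          moca = c(26, 2.7), age = c(61, 7.6)),
    covariate_shift = list(tug = 0.5, ugs = -2, dtgs = 0, mmse = 0, moca = 0)
  )
}
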