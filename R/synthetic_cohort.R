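#' Latent trajectory class profile
#'
#' A class profile bundles everything the generator needs to simulate one
#' latent trajectory class: the probability of drawing a participant into the
#' class, per-wave attentional lapse rates, per-action mistake probabilities
#' inside lapsed vs normal cycles, reaction-time parameters, and the
#' class-conditional covariate model (wave-1 baselines plus additive wave-3
#' shifts).
#'
#' The mistake model is a per-cycle mixture: each 9-digit cycle is "lapsed"
#' with the wave's lapse rate, and every action within a cycle is
#' independently wrong with `p_mistake_lapsed` (lapsed) or `p_mistake_normal`
#' (normal). A wrong action on the no-go digit 3 is a commission (a press); a
#' wrong action on any other digit is an omission (a missed press). The
#' burst structure makes cycles with >= 4 mistakes ("bad performances")
#' occur at realistic rates, which a per-presentation i.i.d. error model
#' cannot do.
#'
#' @param label class label, one of `"stable"`, `"improver"`, `"decliner"`
#'   (free-form labels are allowed for custom profiles).
#' @param weight probability of drawing a participant into this class.
#' @param lapse_rate_w1,lapse_rate_w3 per-cycle lapse probability at each wave.
#' @param p_mistake_lapsed,p_mistake_normal per-action mistake probability
#'   within lapsed / normal cycles.
#' @param rt_mean_w1,rt_mean_w3 mean reaction time (ms) per wave.
#' @param rt_sd reaction-time SD (ms); RTs are drawn from a normal truncated
#'   below at 150 ms.
#' @param covariate_base named list of `c(mean, sd)` wave-1 baselines for
#'   `tug` (s), `ugs`, `dtgs` (cm/s), `mmse`, `moca` (points), `age` (years).
#' @param covariate_shift named list of additive wave-3 shifts for the same
#'   continuous variables (falls are governed by the two rates instead).
#' @param falls_rate_w1,falls_rate_w3 Poisson rates for falls in the year
#'   before each wave.
#' @param p_female,p_antihypertensives,p_diabetes Bernoulli probabilities for
#'   the wave-1-only binary covariates.
#' @param education_probs,smoker_probs,drinking_probs,ipaq_probs length-3
#'   probability vectors for the categorical covariates.
#' @return an object of class `class_profile`.
#' @seealso [default_profiles()], [generate_session()], [generate_cohort()]
#' @export
class_profile <- function(label, weight,
                          lapse_rate_w1, lapse_rate_w3,
                          p_mistake_lapsed, p_mistake_normal,
                          rt_mean_w1, rt_mean_w3, rt_sd,
                          covariate_base, covariate_shift,
                          falls_rate_w1 = 0.3, falls_rate_w3 = 0.3,
                          p_female = 0.54,
                          education_probs = c(0.17, 0.42, 0.41),
                          p_antihypertensives = 0.30,
                          p_diabetes = 0.05,
                          smoker_probs = c(0.47, 0.40, 0.13),
                          drinking_probs = c(0.79, 0.07, 0.14),
                          ipaq_probs = c(0.26, 0.37, 0.37)) {
  probs <- c(weight, lapse_rate_w1, lapse_rate_w3,
             p_mistake_lapsed, p_mistake_normal)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (rt_mean_w1 <= 0 || rt_mean_w3 <= 0 || rt_sd <= 0) {
    stop("reaction-time parameters must be positive")
  }
  needed <- c("tug", "ugs", "dtgs", "mmse", "moca")
  if (!all(c(needed, "age") %in% names(covariate_base))) {
    stop("covariate_base must name tug, ugs, dtgs, mmse, moca, age")
  }
  if (!all(needed %in% names(covariate_shift))) {
    stop("covariate_shift must name tug, ugs, dtgs, mmse, moca")
  }
  structure(list(
    label = label, weight = weight,
    lapse_rate_w1 = lapse_rate_w1, lapse_rate_w3 = lapse_rate_w3,
    p_mistake_lapsed = p_mistake_lapsed, p_mistake_normal = p_mistake_normal,
    rt_mean_w1 = rt_mean_w1, rt_mean_w3 = rt_mean_w3, rt_sd = rt_sd,
    covariate_base = lapply(covariate_base, as.numeric),
    covariate_shift = lapply(covariate_shift, as.numeric),
    falls_rate_w1 = falls_rate_w1, falls_rate_w3 = falls_rate_w3,
    p_female = p_female,
    education_probs = education_probs,
    p_antihypertensives = p_antihypertensives,
    p_diabetes = p_diabetes,
    smoker_probs = smoker_probs,
    drinking_probs = drinking_probs,
    ipaq_probs = ipaq_probs
  ), class = "class_profile")
}

#' Default three-class trajectory profiles
#'
#' Loads the versioned generator configuration shipped with the package:
#' a stable majority (94%), a small improving class (5%) and a very small
#' declining class (1%) whose wave-3 lapse rate and covariate shifts produce
#' dramatic attentional, mobility and cognitive decline.
#'
#' @param path optional path to an alternative YAML profile file with the
#'   same structure.
#' @return a named list of [class_profile()] objects.
#' @export
default_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_profiles.yaml",
                                package = "sartdysreg", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  profiles <- lapply(names(raw), function(lab) {
    p <- raw[[lab]]
    class_profile(
      label = lab, weight = p$weight,
      lapse_rate_w1 = p$lapse_rate_w1, lapse_rate_w3 = p$lapse_rate_w3,
      p_mistake_lapsed = p$p_mistake_lapsed,
      p_mistake_normal = p$p_mistake_normal,
      rt_mean_w1 = p$rt_mean_w1, rt_mean_w3 = p$rt_mean_w3, rt_sd = p$rt_sd,
      covariate_base = p$covariate_base,
      covariate_shift = p$covariate_shift,
      falls_rate_w1 = p$falls_rate_w1, falls_rate_w3 = p$falls_rate_w3,
      p_female = p$p_female,
      education_probs = unlist(p$education_probs),
      p_antihypertensives = p$p_antihypertensives,
      p_diabetes = p$p_diabetes,
      smoker_probs = unlist(p$smoker_probs),
      drinking_probs = unlist(p$drinking_probs),
      ipaq_probs = unlist(p$ipaq_probs)
    )
  })
  names(profiles) <- names(raw)
  profiles
}

# Inverse-CDF draw from a normal truncated below at `lower`.
rtnorm_lower <- function(n, mean, sd, lower = 150) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Generate one raw SART session
#'
#' Simulates a single participant-wave go/no-go session: 23 cycles of the
#' digits 1 to 9 in fixed order (207 presentations). Each cycle is lapsed
#' with the profile's wave-specific lapse rate; each of its 9 actions is
#' independently wrong with the lapsed or normal mistake probability. A wrong
#' action on digit 3 is a commission (response recorded), on any other digit
#' an omission (no response). Reaction times for responded presentations are
#' drawn from a normal truncated below at 150 ms.
#'
#' @param profile a [class_profile()].
#' @param wave 1 or 3.
#' @param rng_seed integer seed; the session is fully reproducible.
#' @param participant_id id stored in the log.
#' @return a trial-log data frame with 207 rows and columns
#'   `participant_id`, `wave`, `cycle`, `position`, `digit`, `responded`,
#'   `rt_ms` (NA when no response).
#' @export
generate_session <- function(profile, wave, rng_seed, participant_id = "p1") {
  if (!wave %in% c(1, 3)) stop("wave must be 1 or 3")
  stopifnot(inherits(profile, "class_profile"))
  lapse <- if (wave == 1) profile$lapse_rate_w1 else profile$lapse_rate_w3
  rt_mean <- if (wave == 1) profile$rt_mean_w1 else profile$rt_mean_w3

  set.seed(rng_seed %% 2147483647)
  lapsed <- stats::runif(23) < lapse
  p_wrong <- ifelse(rep(lapsed, each = 9),
                    profile$p_mistake_lapsed, profile$p_mistake_normal)
  wrong <- stats::runif(207) < p_wrong
  digit <- rep(1:9, times = 23)
  nogo <- digit == 3
  responded <- ifelse(nogo, wrong, !wrong)
  rt <- rep(NA_real_, 207)
  rt[responded] <- rtnorm_lower(sum(responded), rt_mean, profile$rt_sd)

  structure(list(
    participant_id = rep.int(participant_id, 207),
    wave = rep.int(as.integer(wave), 207),
    cycle = rep(1:23, each = 9),
    position = rep.int(1:9, 23),
    digit = digit,
    responded = responded,
    rt_ms = rt
  ), class = "data.frame", row.names = c(NA, -207L))
}

# Class-conditional covariates for one participant (wide, both waves).
generate_participant_covariates <- function(profile, rng_seed) {
  set.seed(rng_seed %% 2147483647)
  base <- profile$covariate_base
  shift <- profile$covariate_shift
  draw <- function(v) stats::rnorm(1, base[[v]][1], base[[v]][2])
  # residual wave-3 noise around the class shift, per variable
  resid <- c(tug = 0.8, ugs = 8, dtgs = 8, mmse = 1.0, moca = 1.2)
  w3 <- function(v, x1) x1 + shift[[v]] + stats::rnorm(1, 0, resid[[v]])

  tug1 <- max(draw("tug"), 3);           tug3 <- max(w3("tug", tug1), 3)
  ugs1 <- max(draw("ugs"), 20);          ugs3 <- max(w3("ugs", ugs1), 20)
  dtgs1 <- max(draw("dtgs"), 20);        dtgs3 <- max(w3("dtgs", dtgs1), 20)
  clamp30 <- function(x) as.integer(pmin(pmax(round(x), 0), 30))
  mmse1 <- clamp30(draw("mmse"));        mmse3 <- clamp30(w3("mmse", mmse1))
  moca1 <- clamp30(draw("moca"));        moca3 <- clamp30(w3("moca", moca1))
  age1 <- max(round(draw("age")), 50)
  falls1 <- stats::rpois(1, profile$falls_rate_w1)
  falls3 <- stats::rpois(1, profile$falls_rate_w3)
  anx1 <- min(max(round(stats::rnorm(1, 5.4, 3.5)), 0), 21)
  anx3 <- min(max(round(stats::rnorm(1, 8.0, 2.6)), 0), 21)
  dep1 <- min(max(round(stats::rnorm(1, 5.3, 6.6)), 0), 60)
  dep3 <- min(max(round(stats::rnorm(1, 3.0, 3.6)), 0), 60)
  pick <- function(levels, probs) {
    levels[1 + findInterval(stats::runif(1), cumsum(probs / sum(probs)))]
  }

  data.frame(
    tug1 = tug1, tug3 = tug3, ugs1 = ugs1, ugs3 = ugs3,
    dtgs1 = dtgs1, dtgs3 = dtgs3, falls1 = falls1, falls3 = falls3,
    mmse1 = mmse1, mmse3 = mmse3, moca1 = moca1, moca3 = moca3,
    age1 = age1, age3 = age1 + 4L,
    anxiety1 = anx1, anxiety3 = anx3,
    depression1 = dep1, depression3 = dep3,
    sex = pick(c("female", "male"), c(profile$p_female, 1 - profile$p_female)),
    education = pick(c("primary/none", "secondary", "third/higher"),
                     profile$education_probs),
    antihypertensives = stats::runif(1) < profile$p_antihypertensives,
    diabetes = stats::runif(1) < profile$p_diabetes,
    smoker = pick(c("never", "past", "current"), profile$smoker_probs),
    drinking = pick(c("no", "dont_know", "yes"), profile$drinking_probs),
    ipaq = pick(c("low", "medium", "high"), profile$ipaq_probs),
    stringsAsFactors = FALSE
  )
}

#' Generate a full two-wave synthetic cohort
#'
#' Draws each participant into a latent trajectory class, generates both
#' waves' raw SART sessions from that class, and draws covariates with
#' class- and wave-specific means so that decliners preferentially cross the
#' clinical decline cut-offs. Per-participant random streams are derived from
#' the master seed by fixed offsets, so enlarging the cohort never reshuffles
#' earlier participants.
#'
#' @param profiles named list of [class_profile()] objects whose weights sum
#'   to 1 (tolerance 1e-9); defaults to [default_profiles()].
#' @param n cohort size (>= 1).
#' @param rng_seed master integer seed.
#' @return an object of class `sart_cohort`: a list with `trials` (trial-log
#'   rows for both waves), `covariates` (wide, one row per participant),
#'   `labels` (true latent classes, for recovery testing), `n`, `seed`.
#' @examples
#' coh <- generate_cohort(n = 20, rng_seed = 1)
#' table(coh$labels)
#' @export
generate_cohort <- function(profiles = default_profiles(), n, rng_seed) {
  stopifnot(n >= 1)
  weights <- vapply(profiles, function(p) p$weight, numeric(1))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("class profile weights must sum to 1 (tolerance 1e-9)")
  }
  labels <- character(n)
  cum <- cumsum(weights)
  trials <- vector("list", 2L * n)
  covs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(participant_seed(rng_seed, i, 9L))
    lab <- names(profiles)[1 + findInterval(stats::runif(1), cum,
                                            rightmost.closed = TRUE)]
    labels[i] <- lab
    prof <- profiles[[lab]]
    pid <- sprintf("P%05d", i)
    trials[[2 * i - 1]] <- generate_session(
      prof, 1, participant_seed(rng_seed, i, 1L), pid)
    trials[[2 * i]] <- generate_session(
      prof, 3, participant_seed(rng_seed, i, 3L), pid)
    cov <- generate_participant_covariates(
      prof, participant_seed(rng_seed, i, 0L))
    covs[[i]] <- cbind(participant_id = pid, cov, stringsAsFactors = FALSE)
  }
  structure(list(
    trials = do.call(rbind, trials),
    covariates = do.call(rbind, covs),
    labels = labels,
    n = n,
    seed = rng_seed
  ), class = "sart_cohort")
}

#' @export
print.sart_cohort <- function(x, ...) {
  cat("Synthetic SART cohort:", x$n, "participants, two waves\n")
  cat("Latent classes:\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' Writes `trial_logs.csv` (one row per presentation, both waves),
#' `covariates_wave1.csv` / `covariates_wave3.csv`, and a JSON sidecar
#' `cohort_meta.json` holding the true latent labels and the master seed.
#'
#' @param cohort a `sart_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sart_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("trial_logs.csv", "covariates_wave1.csv",
                            "covariates_wave3.csv", "cohort_meta.json"))
  utils::write.csv(cohort$trials, paths[1], row.names = FALSE, na = "")
  cv <- cohort$covariates
  w1 <- cv[, c("participant_id", "tug1", "ugs1", "dtgs1", "falls1", "mmse1",
               "moca1", "age1", "anxiety1", "depression1", "sex", "education",
               "antihypertensives", "diabetes", "smoker", "drinking", "ipaq")]
  names(w1) <- sub("1$", "", names(w1))
  w3 <- cv[, c("participant_id", "tug3", "ugs3", "dtgs3", "falls3", "mmse3",
               "moca3", "age3", "anxiety3", "depression3")]
  names(w3) <- sub("3$", "", names(w3))
  utils::write.csv(w1, paths[2], row.names = FALSE)
  utils::write.csv(w3, paths[3], row.names = FALSE)
  jsonlite::write_json(
    list(n = cohort$n, seed = cohort$seed,
         labels = stats::setNames(as.list(cohort$labels),
                                  cohort$covariates$participant_id)),
    paths[4], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
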