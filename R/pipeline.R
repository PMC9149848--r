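#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: cohort size and seed, the
#' bad-performance threshold (mistakes per cycle, default 4 of 9), fuzzy
#' clustering settings, the clinical decline cut-offs (TUG 12 s, gait
#' 100 cm/s, MMSE/MoCA 2 points) and the significance level. The object
#' round-trips through YAML unchanged.
#'
#' @param seed master RNG seed.
#' @param n cohort size.
#' @param bp_threshold mistakes per cycle that make a bad performance
#'   (1..9).
#' @param clusters fixed cluster count (NULL = take the elbow suggestion).
#' @param c_max elbow scan upper bound.
#' @param fuzzifier FCM fuzzifier m (> 1).
#' @param restarts FCM restarts per c.
#' @param min_cluster_size smallest admissible hard cluster in the scan.
#' @param tug_cutoff,gait_cutoff,score_drop decline cut-offs.
#' @param alpha significance level.
#' @param out_dir output directory for [run_pipeline()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n = 1000, bp_threshold = 4,
                            clusters = NULL, c_max = 10, fuzzifier = 2,
                            restarts = 5, min_cluster_size = 5,
                            tug_cutoff = 12, gait_cutoff = 100,
                            score_drop = 2, alpha = 0.05,
                            out_dir = "sartdysreg_run") {
  stopifnot(bp_threshold >= 1, bp_threshold <= 9, fuzzifier > 1,
            tug_cutoff > 0, gait_cutoff > 0, score_drop > 0, n >= 1)
  structure(list(seed = seed, n = n, bp_threshold = bp_threshold,
                 clusters = clusters, c_max = c_max, fuzzifier = fuzzifier,
                 restarts = restarts, min_cluster_size = min_cluster_size,
                 tug_cutoff = tug_cutoff, gait_cutoff = gait_cutoff,
                 score_drop = score_drop, alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `load_config` returns the configuration; `save_config` the path,
#'   invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Read trial logs from delimited text
#'
#' Reads the trial-log CSV schema (`participant_id, wave, cycle, position,
#' digit, responded, rt_ms`) and validates every session against the
#' 207-record protocol invariants; a malformed session is rejected with the
#' offending participant and wave named.
#'
#' @param path CSV file.
#' @return long trial-log data frame.
#' @export
read_trial_logs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (nrow(df) == 0) {
    warning("empty trial-log file: ", path)
    return(df)
  }
  need <- c("participant_id", "wave", "cycle", "position", "digit",
            "responded", "rt_ms")
  if (!all(need %in% names(df))) {
    stop("trial-log file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$responded <- as.logical(df$responded)
  for (key in split(seq_len(nrow(df)),
                    list(df$participant_id, df$wave), drop = TRUE)) {
    log <- df[key, ]
    ok <- tryCatch({ validate_trial_log(log); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      stop("invalid session for participant ", log$participant_id[1],
           " wave ", log$wave[1], " (rows ", min(key), "-", max(key), "): ",
           conditionMessage(ok))
    }
  }
  df
}

#' Read per-wave covariate tables
#'
#' Reads the two per-wave covariate CSVs written by [write_cohort()] and
#' merges them into the wide per-participant layout used throughout the
#' package.
#'
#' @param path_w1,path_w3 wave-1 and wave-3 covariate files.
#' @return wide covariate data frame.
#' @export
read_covariates <- function(path_w1, path_w3) {
  w1 <- utils::read.csv(path_w1, stringsAsFactors = FALSE)
  w3 <- utils::read.csv(path_w3, stringsAsFactors = FALSE)
  per_wave <- c("tug", "ugs", "dtgs", "falls", "mmse", "moca", "age",
                "anxiety", "depression")
  for (v in per_wave) {
    if (v %in% names(w1)) names(w1)[names(w1) == v] <- paste0(v, "1")
    if (v %in% names(w3)) names(w3)[names(w3) == v] <- paste0(v, "3")
  }
  if (anyDuplicated(w1$participant_id) || anyDuplicated(w3$participant_id)) {
    stop("duplicate participant ids in covariate tables")
  }
  merge(w1, w3, by = "participant_id")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' simulate -> extract features -> elbow scan + fuzzy clustering ->
#' characterise clusters -> fit prediction models -> render figures.
#' All tables are written as comma-separated UTF-8 text with a header row,
#' figures as PNG with JSON render manifests, plus a provenance record
#' (config, seed, per-stage row counts). Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built `sart_cohort` (e.g. read from
#'   disk); by default one is generated from the config.
#' @return invisibly, a list with every stage's in-memory results and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  if (is.null(cohort)) {
    cohort <- generate_cohort(default_profiles(), n = config$n,
                              rng_seed = config$seed)
  }
  log_stage("simulate", "%d participants, seed %d", cohort$n, config$seed)
  write_cohort(cohort, out("cohort"))

  ext <- extract_features(cohort$trials, threshold = config$bp_threshold)
  feats <- ext$features
  f1 <- feats[feats$wave == 1, ]; f3 <- feats[feats$wave == 3, ]
  log_stage("features", "%d sessions, %d participants",
            nrow(feats), length(unique(feats$participant_id)))
  utils::write.csv(feats, out("features.csv"), row.names = FALSE)

  dist_tab <- mistake_distribution(ext$cycles[ext$cycles$wave == 1, ],
                                   ext$cycles[ext$cycles$wave == 3, ])
  utils::write.csv(dist_tab, out("mistake_distribution.csv"),
                   row.names = FALSE)
  ages <- data.frame(participant_id = cohort$covariates$participant_id,
                     age1 = cohort$covariates$age1)
  trans <- bp_transition(f1, f3, ages)
  utils::write.csv(trans$pair_density, out("bp_pair_density.csv"),
                   row.names = FALSE)

  pts <- cbind(bp1 = f1$bp[match(f3$participant_id, f1$participant_id)],
               bp3 = f3$bp)
  scan <- elbow_scan(pts, c_max = config$c_max, m = config$fuzzifier,
                     restarts = config$restarts, seed = config$seed,
                     min_cluster_size = config$min_cluster_size)
  n_clusters <- config$clusters %||% scan$suggested_c
  log_stage("cluster", "elbow suggests c = %d; using c = %d",
            scan$suggested_c, n_clusters)
  utils::write.csv(scan$table, out("wss_scan.csv"), row.names = FALSE)
  fit <- fcm_restarts(pts, c = n_clusters, m = config$fuzzifier,
                      seed = config$seed, restarts = config$restarts)
  hard <- assign_hard(fit)
  semantics <- if (n_clusters == 3) label_semantics(fit$centroids) else NULL
  labels <- if (!is.null(semantics)) semantics[hard] else as.character(hard)
  memb <- as.data.frame(fit$memberships)
  names(memb) <- paste0("p_C", seq_len(ncol(memb)))
  utils::write.csv(
    cbind(participant_id = f3$participant_id, memb, cluster = labels),
    out("memberships.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(cluster = seq_len(n_clusters), bp1 = fit$centroids[, 1],
               bp3 = fit$centroids[, 2],
               label = if (!is.null(semantics)) semantics else
                 as.character(seq_len(n_clusters))),
    out("centroids.csv"), row.names = FALSE)

  cv <- cohort$covariates[match(f3$participant_id,
                                cohort$covariates$participant_id), ]
  report <- characterize_clusters(cv, labels, alpha = config$alpha)
  log_stage("characterize", "%d decline tests", nrow(report$decline_tests))
  utils::write.csv(report$within_waves, out("within_wave_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$between_changes, out("between_cluster_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$decline_tests, out("decline_tests.csv"),
                   row.names = FALSE)

  design <- data.frame(
    bad_performances = f1$bp[match(f3$participant_id, f1$participant_id)],
    total_mistakes = f1$total_mistakes[match(f3$participant_id,
                                             f1$participant_id)],
    mistakes_good = f1$mistakes_good[match(f3$participant_id,
                                           f1$participant_id)],
    mean_rt = f1$mean_rt[match(f3$participant_id, f1$participant_id)],
    sd_rt = f1$sd_rt[match(f3$participant_id, f1$participant_id)],
    age1 = cv$age1, sex = cv$sex, education = cv$education,
    anxiety1 = cv$anxiety1, depression1 = cv$depression1,
    antihypertensives = cv$antihypertensives, diabetes = cv$diabetes,
    smoker = cv$smoker, drinking = cv$drinking, ugs1 = cv$ugs1,
    ipaq = cv$ipaq, stringsAsFactors = FALSE)
  outcome <- dichotomise_bp3(f3)
  pred_tab <- compare_predictors(outcome, design)
  log_stage("predict", "%d of 12 model fits available",
            sum(pred_tab$available))
  utils::write.csv(pred_tab, out("predictor_comparison.csv"),
                   row.names = FALSE)

  renders <- list(
    multimodal_w1 = multimodal_plot(feats, ext$cycles, cv, wave = 1),
    thresholded_w3 = thresholded_plot(feats, ext$cycles, cv, wave = 3,
                                      threshold = config$bp_threshold),
    longitudinal = longitudinal_overlay(feats, ext$cycles, cv,
                                        threshold = config$bp_threshold),
    evolution = bp_evolution_plot(trans)
  )
  for (nm in names(renders)) {
    save_render(renders[[nm]], out(paste0(nm, ".png")))
  }
  log_stage("viz", "%d figures rendered", length(renders))

  provenance <- list(
    config = unclass(config),
    generated = format(Sys.time(), tz = "UTC"),
    r_version = R.version.string,
    stage_rows = list(trials = nrow(cohort$trials), features = nrow(feats),
                      covariates = nrow(cohort$covariates),
                      clusters = as.list(table(labels))),
    transition = trans[c("n_bp_w1", "n_bp_w3", "n_persist", "n_improved",
                         "n_worsened")]
  )
  jsonlite::write_json(provenance, out("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, features = feats, cycles = ext$cycles,
                 distribution = dist_tab, transition = trans, scan = scan,
                 fcm = fit, labels = labels, semantics = semantics,
                 report = report, predictors = pred_tab, renders = renders,
                 out_dir = config$out_dir))
}
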