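#' Multimodal cloud plot of raw SART performance
#'
#' One spot per participant-cycle: participants are ordered left-to-right by
#' wave-1 age, the y position is the cycle's mean RT, and spot size and
#' colour encode the cycle's mistake count. Overlay curves trace each
#' participant's total mistakes, MMSE and TUG (secondary axis scaling);
#' a missing overlay variable drops its curve with a warning. Every render
#' returns a machine-readable manifest (spot and curve counts, participant
#' set) so correctness is testable without image comparison.
#'
#' @param features per-participant feature rows for the plotted wave.
#' @param cycles per-cycle rows for the plotted wave.
#' @param covariates wide covariate table (for age ordering and overlays).
#' @param wave 1 or 3 (labelling and which covariate wave feeds overlays).
#' @param threshold_only if TRUE renders only bad-performance cycles
#'   (mistakes >= `threshold`) and restricts overlay curves to participants
#'   with at least one bad performance.
#' @param threshold bad-performance threshold.
#' @param colormap viridis option name for the mistake colour scale
#'   (`"plasma"` approximates the wave-3 palette; `"inferno"`/copper-like for
#'   wave 1).
#' @return list with `plot` (a ggplot) and `manifest` (list: `wave`,
#'   `n_spots`, `n_participants`, `participants`, `curves` with per-curve
#'   participant counts).
#' @export
multimodal_plot <- function(features, cycles, covariates, wave,
                            threshold_only = FALSE, threshold = 4,
                            colormap = if (wave == 1) "inferno" else "plasma") {
  feats <- features[features$wave == wave, ]
  cyc <- cycles[cycles$wave == wave, ]
  cv <- covariates[match(feats$participant_id, covariates$participant_id), ]
  ord <- order(cv$age1, feats$participant_id)
  feats <- feats[ord, ]; cv <- cv[ord, ]
  feats$x <- seq_len(nrow(feats))

  if (threshold_only) {
    keep_ids <- feats$participant_id[feats$bp >= 1]
    cyc <- cyc[cyc$n_mistakes >= threshold, ]
  } else {
    keep_ids <- feats$participant_id
  }
  cyc <- cyc[cyc$participant_id %in% keep_ids, ]
  cyc$x <- feats$x[match(cyc$participant_id, feats$participant_id)]

  overlays <- list(
    total_mistakes = feats$total_mistakes,
    mmse = cv[[paste0("mmse", wave)]],
    tug = cv[[paste0("tug", wave)]]
  )
  missing <- names(overlays)[vapply(overlays, is.null, logical(1))]
  if (length(missing)) {
    warning("overlay variable(s) missing, curve omitted: ",
            paste(missing, collapse = ", "))
    overlays <- overlays[!names(overlays) %in% missing]
  }
  curve_mask <- feats$participant_id %in% keep_ids
  curves <- lapply(overlays, function(v) {
    data.frame(x = feats$x[curve_mask], y = v[curve_mask])
  })

  p <- ggplot2::ggplot(cyc, ggplot2::aes(x = .data$x, y = .data$mean_rt,
                                         size = .data$n_mistakes,
                                         colour = .data$n_mistakes)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_viridis_c(option = colormap,
                                    name = "mistakes/cycle") +
    ggplot2::scale_size_continuous(range = c(0.3, 4), guide = "none") +
    ggplot2::labs(
      x = "participants (sorted by wave-1 age)",
      y = "cycle mean RT (ms)",
      title = sprintf("%sSART multimodal visualisation, wave %d",
                      if (threshold_only) "Thresholded " else "", wave)) +
    ggplot2::theme_minimal()
  curve_cols <- c(total_mistakes = "red", mmse = "blue", tug = "darkgreen")
  for (nm in names(curves)) {
    cd <- curves[[nm]]
    cd$y_scaled <- cd$y / max(cd$y, 1, na.rm = TRUE) *
      max(cyc$mean_rt, 500, na.rm = TRUE)
    p <- p + ggplot2::geom_line(
      data = cd, ggplot2::aes(x = .data$x, y = .data$y_scaled),
      colour = curve_cols[[nm]], linewidth = 0.3, inherit.aes = FALSE,
      na.rm = TRUE)
  }

  list(plot = p, manifest = list(
    wave = wave,
    threshold_only = threshold_only,
    n_spots = nrow(cyc),
    n_participants = length(unique(cyc$participant_id)),
    participants = sort(unique(cyc$participant_id)),
    curves = lapply(curves, function(cd) sum(!is.na(cd$y))),
    spot_sizes = stats::setNames(cyc$n_mistakes,
                                 paste(cyc$participant_id, cyc$cycle))
  ))
}

#' Thresholded multimodal plot (bad performances only)
#'
#' Convenience wrapper around [multimodal_plot()] rendering only the "big
#' spots": cycles with at least `threshold` mistakes, with overlay curves
#' restricted to participants holding at least one bad performance.
#'
#' @inheritParams multimodal_plot
#' @return list with `plot` and `manifest` (see [multimodal_plot()]).
#' @export
thresholded_plot <- function(features, cycles, covariates, wave,
                             threshold = 4) {
  multimodal_plot(features, cycles, covariates, wave,
                  threshold_only = TRUE, threshold = threshold)
}

#' Longitudinal overlay of both waves' bad performances
#'
#' Renders the thresholded visualisation for waves 1 and 3 in one graph over
#' the union of participants with at least one bad performance in either
#' wave, on a shared x-axis of wave-1 age order. The waves use distinct
#' colour families (dark brown/black for wave 1, blue for wave 3); wave-3
#' overlay curves are drawn as lines for participants bad only at wave 3 and
#' as star markers for those with wave-1 bad performances. Unpaired
#' participants are excluded with their count recorded in the manifest.
#'
#' @param features,cycles feature and per-cycle tables holding both waves.
#' @param covariates wide covariate table.
#' @param threshold bad-performance threshold.
#' @return list with `plot` and `manifest` (`n_spots_w1`, `n_spots_w3`,
#'   `participants`, `n_unpaired`, `wave3_star_participants`).
#' @export
longitudinal_overlay <- function(features, cycles, covariates,
                                 threshold = 4) {
  f1 <- features[features$wave == 1, ]
  f3 <- features[features$wave == 3, ]
  paired <- intersect(f1$participant_id, f3$participant_id)
  n_unpaired <- length(setdiff(union(f1$participant_id, f3$participant_id),
                               paired))
  f1 <- f1[f1$participant_id %in% paired, ]
  f3 <- f3[f3$participant_id %in% paired, ]
  keep <- union(f1$participant_id[f1$bp >= 1], f3$participant_id[f3$bp >= 1])

  cv <- covariates[match(keep, covariates$participant_id), ]
  ord <- order(cv$age1, keep)
  keep <- keep[ord]
  xpos <- stats::setNames(seq_along(keep), keep)

  cyc <- cycles[cycles$participant_id %in% keep &
                  cycles$n_mistakes >= threshold, ]
  cyc$x <- xpos[cyc$participant_id]
  cyc$wave_lab <- factor(paste("wave", cyc$wave))

  stars <- intersect(keep, f1$participant_id[f1$bp >= 1])

  p <- ggplot2::ggplot(cyc, ggplot2::aes(x = .data$x, y = .data$mean_rt,
                                         size = .data$n_mistakes,
                                         colour = .data$wave_lab)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("wave 1" = "#3b2300",
                                            "wave 3" = "#1f4fff"),
                                 name = NULL) +
    ggplot2::scale_size_continuous(range = c(0.5, 4), guide = "none") +
    ggplot2::labs(x = "participants with any bad performance (by wave-1 age)",
                  y = "cycle mean RT (ms)",
                  title = "Longitudinal thresholded visualisation") +
    ggplot2::theme_minimal()

  list(plot = p, manifest = list(
    n_spots = nrow(cyc),
    n_spots_w1 = sum(cyc$wave == 1),
    n_spots_w3 = sum(cyc$wave == 3),
    participants = keep,
    n_unpaired = n_unpaired,
    wave3_star_participants = sort(stars)
  ))
}

#' Evolution plot of (BP1, BP3) pair density
#'
#' One spot per distinct (BP1, BP3) pair observed in the cohort; spot size
#' is the participant count on a log scale (a linear scale would hide the
#' singleton pairs against the dominant (0, 0) mass), colour is the mean
#' wave-1 age of the pair's participants.
#'
#' @param transition a [bp_transition()] result.
#' @return list with `plot` and `manifest` (`n_pairs`, `pair_density`,
#'   `sizes` strictly increasing in count).
#' @export
bp_evolution_plot <- function(transition) {
  stopifnot(inherits(transition, "bp_transition"))
  pd <- transition$pair_density
  if (nrow(pd) == 0) stop("pair density is empty")
  pd$size <- log1p(pd$count)
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$bp1, y = .data$bp3,
                                        size = .data$size,
                                        colour = .data$mean_age_w1)) +
    ggplot2::geom_point(alpha = 0.8, na.rm = TRUE) +
    ggplot2::scale_size_continuous(range = c(1, 10),
                                   name = "log(1 + count)") +
    ggplot2::scale_colour_viridis_c(name = "mean age w1", na.value = "grey60") +
    ggplot2::labs(x = "bad performances, wave 1",
                  y = "bad performances, wave 3",
                  title = "Evolution of bad performances between waves") +
    ggplot2::theme_minimal()
  list(plot = p, manifest = list(
    n_pairs = nrow(pd),
    pair_density = pd[, c("bp1", "bp3", "count")],
    sizes = stats::setNames(pd$size, paste(pd$bp1, pd$bp3))
  ))
}

#' Save a rendered figure and its manifest
#'
#' @param render a list with `plot` and `manifest` from any of the plot
#'   functions.
#' @param path figure path (`.png` or `.svg`); the manifest is written next
#'   to it with extension `.json`.
#' @param width,height inches.
#' @return invisibly, the two paths.
#' @export
save_render <- function(render, path, width = 9, height = 5) {
  ggplot2::ggsave(path, render$plot, width = width, height = height, dpi = 150)
  mpath <- sub("\\.[a-zA-Z]+$", ".json", path)
  jsonlite::write_json(render$manifest, mpath, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(c(path, mpath))
}
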