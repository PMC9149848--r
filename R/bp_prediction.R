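#' Nested model specification for bad-performance prediction
#'
#' Defines one of the four nested binary logistic regression models
#' predicting presence of bad performances at wave 3 from wave-1 variables:
#' tier 1 enters the main predictor alone; tier 2 adds mean and SD of RT;
#' tier 3 adds age, sex and education; tier 4 is the fully adjusted model
#' (anxiety, depression, anti-hypertensives, diabetes, smoking, drinking,
#' baseline UGS, IPAQ). Exactly one main SART predictor is entered per
#' model; the three candidates are never co-entered.
#'
#' @param main_predictor one of `"bad_performances"`, `"total_mistakes"`,
#'   `"mistakes_good"`.
#' @param tier 1 to 4.
#' @return a `model_spec` list with the predictor, tier and term names.
#' @export
model_spec <- function(main_predictor = c("bad_performances",
                                          "total_mistakes",
                                          "mistakes_good"),
                       tier = 1) {
  main_predictor <- match.arg(main_predictor)
  stopifnot(tier %in% 1:4)
  terms <- main_predictor
  if (tier >= 2) terms <- c(terms, "mean_rt", "sd_rt")
  if (tier >= 3) terms <- c(terms, "age1", "sex", "education")
  if (tier >= 4) terms <- c(terms, "anxiety1", "depression1",
                            "antihypertensives", "diabetes", "smoker",
                            "drinking", "ugs1", "ipaq")
  structure(list(main_predictor = main_predictor, tier = tier,
                 terms = terms), class = "model_spec")
}

# Reference levels matching the reporting convention: education primary/none,
# smoker never, drinking "no", IPAQ low.
blr_design_frame <- function(data) {
  refactor <- function(x, levels) factor(x, levels = levels)
  if ("sex" %in% names(data))
    data$sex <- refactor(data$sex, c("male", "female"))
  if ("education" %in% names(data))
    data$education <- refactor(data$education,
                               c("primary/none", "secondary", "third/higher"))
  if ("smoker" %in% names(data))
    data$smoker <- refactor(data$smoker, c("never", "past", "current"))
  if ("drinking" %in% names(data))
    data$drinking <- refactor(data$drinking, c("no", "dont_know", "yes"))
  if ("ipaq" %in% names(data))
    data$ipaq <- refactor(data$ipaq, c("low", "medium", "high"))
  data
}

#' Fit one binary logistic regression model
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary outcome on the design implied by a
#' [model_spec()], reporting per term the odds ratio `exp(coef)`, the Wald
#' 95% confidence interval `exp(coef +/- 1.96 SE)` and the Wald p-value.
#' Listwise deletion is applied within the model and the n actually used is
#' reported. Quasi-complete separation (detected through diverging
#' coefficients or fitted probabilities collapsing to 0/1) fails explicitly.
#'
#' @param outcome binary 0/1 vector.
#' @param data data frame holding the model terms (see [model_spec()]).
#' @param spec a `model_spec`.
#' @param conf_level Wald confidence level.
#' @return an object of class `blr_fit`: `results` data frame (term,
#'   estimate, `or`, `ci_low`, `ci_high`, `p_value`), `n_used`, `converged`,
#'   `log_lik`, `spec`.
#' @export
fit_blr <- function(outcome, data, spec, conf_level = 0.95) {
  stopifnot(inherits(spec, "model_spec"))
  outcome <- as.integer(outcome)
  if (length(unique(stats::na.omit(outcome))) < 2) {
    stop("outcome must contain both classes")
  }
  missing_terms <- setdiff(spec$terms, names(data))
  if (length(missing_terms)) {
    stop("design lacks columns: ", paste(missing_terms, collapse = ", "))
  }
  df <- blr_design_frame(data[, spec$terms, drop = FALSE])
  df$.y <- outcome
  df <- stats::na.omit(df)
  if (length(unique(df$.y)) < 2) stop("outcome single-class after deletion")
  fml <- stats::as.formula(paste(".y ~", paste(spec$terms, collapse = " + ")))
  saw_boundary <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        saw_boundary <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- summary(fit)$coefficients
  degenerate <- any(!is.finite(coefs[, "Std. Error"])) ||
    any(coefs[, "Std. Error"] > 100) || any(abs(coefs[, "Estimate"]) > 15)
  if (saw_boundary && (degenerate || !fit$converged)) {
    stop("quasi/complete separation suspected: fitted probabilities at the ",
         "0/1 boundary with diverging coefficients or standard errors")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    results = data.frame(
      term = rownames(coefs),
      estimate = coefs[, "Estimate"],
      or = exp(coefs[, "Estimate"]),
      ci_low = exp(coefs[, "Estimate"] - z * coefs[, "Std. Error"]),
      ci_high = exp(coefs[, "Estimate"] + z * coefs[, "Std. Error"]),
      p_value = coefs[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    n_used = nrow(df),
    converged = fit$converged,
    log_lik = as.numeric(stats::logLik(fit)),
    spec = spec
  ), class = "blr_fit")
}

#' @export
print.blr_fit <- function(x, ...) {
  cat(sprintf("Binary logistic model (tier %d, predictor %s), n = %d\n",
              x$spec$tier, x$spec$main_predictor, x$n_used))
  print(transform(x$results,
                  or = round(or, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3),
                  p_value = signif(p_value, 3),
                  estimate = NULL),
        row.names = FALSE)
  invisible(x)
}

#' Multicollinearity screen on a model design
#'
#' Pairwise Spearman rank correlations among the continuous/ordinal columns
#' of a design; the screen fails if any pair exceeds the threshold in
#' absolute value.
#'
#' @param design data frame of predictors (non-numeric columns ignored).
#' @param threshold |rho| above which the screen fails (default 0.7).
#' @return list: `rho` (absolute correlation matrix), `max_abs_rho`,
#'   `pass`.
#' @export
multicollinearity_screen <- function(design, threshold = 0.7) {
  num <- design[, vapply(design, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) < 2) stop("need at least two numeric predictors")
  rho <- abs(stats::cor(num, method = "spearman",
                        use = "pairwise.complete.obs"))
  off <- rho[upper.tri(rho)]
  list(rho = rho, max_abs_rho = max(off), pass = all(off <= threshold))
}

#' Compare the three main predictors across the four tiers
#'
#' Fits all twelve models (three main predictors x four nested tiers) and
#' tabulates the main predictor's OR, CI and p per fit, with a per-tier
#' indicator of whether the three predictors' confidence intervals overlap.
#' A failed fit is marked unavailable rather than aborting the table.
#'
#' @param outcome binary 0/1 vector (bad performances present at wave 3).
#' @param data design data frame holding all tier-4 terms.
#' @return data frame: predictor, tier, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `n_used`, `available`, `ci_overlap` (per tier).
#' @export
compare_predictors <- function(outcome, data) {
  preds <- c("bad_performances", "total_mistakes", "mistakes_good")
  rows <- list()
  for (tier in 1:4) {
    tier_rows <- lapply(preds, function(p) {
      fit <- tryCatch(fit_blr(outcome, data, model_spec(p, tier)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        return(data.frame(predictor = p, tier = tier, or = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, n_used = NA_integer_,
                          available = FALSE, stringsAsFactors = FALSE))
      }
      r <- fit$results[fit$results$term == p, ]
      data.frame(predictor = p, tier = tier, or = r$or, ci_low = r$ci_low,
                 ci_high = r$ci_high, p_value = r$p_value,
                 n_used = fit$n_used, available = TRUE,
                 stringsAsFactors = FALSE)
    })
    tier_df <- do.call(rbind, tier_rows)
    avail <- tier_df[tier_df$available, ]
    overlap <- if (nrow(avail) >= 2) {
      max(avail$ci_low) <= min(avail$ci_high)
    } else NA
    tier_df$ci_overlap <- overlap
    rows[[tier]] <- tier_df
  }
  do.call(rbind, rows)
}
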