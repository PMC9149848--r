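#' Round half away from zero
#'
#' Standard commercial rounding: halves move away from zero, unlike
#' [base::round()]'s banker's rounding. Used for all printed percentages so
#' that e.g. 20.45 formats as 20.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits`.
#' @export
round_half_out <- function(x, digits = 0) {
  scale <- 10^digits
  # pre-round at 9 decimals so binary representation error (e.g. 20.45
  # stored as 20.4499...) cannot pull a true half downward
  sign(x) * floor(round(abs(x) * scale, 9) + 0.5) / scale
}

#' Percentage of a count over a total
#'
#' @param x numerator count.
#' @param n denominator count.
#' @param digits decimal places (half-away-from-zero rounding).
#' @return numeric percentage on the 0-100 scale.
#' @examples
#' percent(565, 4864, 1) # 11.6
#' @export
percent <- function(x, n, digits = 1) {
  stopifnot(n > 0)
  round_half_out(100 * x / n, digits)
}

#' Percent change between two wave counts
#'
#' Computes `100 * (w3 - w1) / w1`, rounded to one decimal half away from
#' zero. Undefined (NA) when the wave-1 count is zero.
#'
#' @param w1,w3 counts at wave 1 and wave 3.
#' @return numeric percent change (NA when `w1 == 0`).
#' @export
pct_change <- function(w1, w3) {
  out <- ifelse(w1 == 0, NA_real_, 100 * (w3 - w1) / w1)
  round_half_out(out, 1)
}

#' Format a percent change the way summary tables print it
#'
#' Sign-prefixed, one decimal unless the value is an integer, thousands
#' separated by commas; `"undefined"` when the baseline count was zero.
#'
#' @param pc numeric percent change as returned by [pct_change()].
#' @return character vector.
#' @examples
#' format_pct_change(pct_change(4, 494)) # "+12,250%"
#' @export
format_pct_change <- function(pc) {
  vapply(pc, function(p) {
    if (is.na(p)) return("undefined")
    dec <- if (abs(p - round(p)) < 1e-9) 0L else 1L
    body <- formatC(abs(p), format = "f", digits = dec, big.mark = ",")
    paste0(if (p < 0) "−" else "+", body, "%")
  }, character(1))
}

# Derive a per-participant RNG seed from the master seed so that growing the
# cohort never reshuffles earlier participants. Kept below 2^31.
participant_seed <- function(master_seed, index, wave = 0L) {
  (as.numeric(master_seed) * 7919 + index * 104729 + wave * 15485863) %%
    2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
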