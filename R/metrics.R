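#' Weight balance of a stimulus pair
#'
#' Ratio of the negative subunit's weight to the positive subunit's weight,
#' \eqn{\omega_-/\omega_+}; values below -1 mean negative evidence
#' outweighs positive evidence.
#'
#' @param omega_neg weight of the negative subunit.
#' @param omega_pos weight of the positive subunit (non-zero).
#' @return The ratio (full precision; summaries round to one decimal).
#' @export
weight_ratio <- function(omega_neg, omega_pos) {
  if (omega_pos == 0) stop("undefined ratio: omega_pos is 0")
  omega_neg / omega_pos
}

#' Noise-free subunit count to reach a threshold
#'
#' The smallest number of consecutive identical subunits whose accumulated
#' weight strictly exceeds the threshold (crossing is strict, so an exact
#' multiple does not fix the decision): `floor(|theta|/|omega|) + 1`.
#'
#' @param omega subunit weight (non-zero, same sign as `theta`).
#' @param theta threshold (`theta_plus` or `theta_minus`).
#' @return Integer count (>= 1).
#' @export
subunits_to_threshold <- function(omega, theta) {
  if (omega == 0) stop("undefined count: omega is 0")
  if (sign(omega) != sign(theta))
    stop("threshold unreachable: omega and theta have opposite signs")
  as.integer(floor(abs(theta) / abs(omega))) + 1L
}

#' Weight-to-threshold ratio
#'
#' The absolute ratio of a threshold to a subunit weight, `|theta|/|omega|`
#' — the (fractional) number of subunits of accumulated drift spanned by
#' the threshold.
#'
#' @param omega subunit weight (non-zero).
#' @param theta threshold.
#' @return Nonnegative ratio.
#' @export
threshold_ratio <- function(omega, theta) {
  if (omega == 0) stop("undefined ratio: omega is 0")
  abs(theta) / abs(omega)
}

#' Noise-to-signal ratio
#'
#' Ratio of the integrator's noise SD to a subunit weight magnitude,
#' `sigma/|omega|`; values above 1 mean single-step noise exceeds the
#' per-subunit drift.
#'
#' @param sigma integrator noise SD (>= 0).
#' @param omega subunit weight (non-zero).
#' @return Nonnegative ratio.
#' @export
noise_to_signal <- function(sigma, omega) {
  if (omega == 0) stop("undefined ratio: omega is 0")
  if (sigma < 0) stop("'sigma' must be >= 0")
  sigma / abs(omega)
}

#' Per-set decision-balance metrics
#'
#' Tabulates, for each stimulus pair, the weight balance
#' \eqn{\omega_-/\omega_+}, the noise-free subunit counts to each
#' threshold, the raw weight-to-threshold ratios, and the noise-to-signal
#' ratios.  Counts to a threshold of the opposite sign are `NA`
#' (unreachable without noise); both the integer count and the raw ratio
#' are reported because they answer different questions (subunits needed to
#' strictly cross vs. threshold span in drift units).
#'
#' @param params a [ddm_params()].
#' @param sets list of stimulus pairs as from [paper_stimulus_pairs()].
#' @return `data.frame`, one row per set.
#' @export
set_metrics <- function(params, sets = paper_stimulus_pairs()) {
  w <- params$weights
  rows <- lapply(sets, function(s) {
    wp <- w[[s$pair[["positive"]]]]
    wn <- w[[s$pair[["negative"]]]]
    data.frame(
      set_id = s$set_id,
      omega_pos = wp, omega_neg = wn,
      omega_ratio = weight_ratio(wn, wp),
      n_to_lower = if (wn < 0) subunits_to_threshold(wn, params$theta_minus) else NA_integer_,
      n_to_upper = if (wp > 0) subunits_to_threshold(wp, params$theta_plus) else NA_integer_,
      threshold_ratio_lower = threshold_ratio(wn, params$theta_minus),
      threshold_ratio_upper = threshold_ratio(wp, params$theta_plus),
      nsr_negative = noise_to_signal(params$sigma, wn),
      nsr_positive = noise_to_signal(params$sigma, wp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decision probabilities by song third
#'
#' Sums a first-passage profile's threshold-crossing masses within the
#' first, second, and last third of the song, and carries the non-crosser
#' (sign-rule) masses through.  All seven entries sum to 1.
#'
#' @param profile a [first_passage_profile()] result.
#' @param L song length; must be divisible by 3 (default taken from the
#'   profile).
#' @return Object of class `thirds_decomposition`: list with `upper` and
#'   `lower` (length-3 per-third crossing masses), `end_respond`,
#'   `end_reject`.
#' @export
thirds_decomposition <- function(profile, L = profile$L) {
  if (L %% 3 != 0) stop("song length not divisible by 3: cannot partition into thirds")
  if (length(profile$p_upper) != L)
    stop("profile length does not match L")
  third <- rep(1:3, each = L / 3)
  structure(list(
    upper = as.numeric(tapply(profile$p_upper, third, sum)),
    lower = as.numeric(tapply(profile$p_lower, third, sum)),
    end_respond = profile$p_end_respond,
    end_reject = profile$p_end_reject),
    class = "thirds_decomposition")
}

#' @export
print.thirds_decomposition <- function(x, ...) {
  cat("<thirds_decomposition>  (P of fixing the decision per song third)\n")
  cat(sprintf("  upper: %s\n", paste(sprintf("%.4f", x$upper), collapse = "  ")))
  cat(sprintf("  lower: %s\n", paste(sprintf("%.4f", x$lower), collapse = "  ")))
  cat(sprintf("  non-crossers: respond %.4f, reject %.4f\n",
              x$end_respond, x$end_reject))
  invisible(x)
}
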