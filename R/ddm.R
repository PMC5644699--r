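#' Parameters of the subunit-weighted decision model
#'
#' @param weights named numeric vector mapping subunit labels to their
#'   evidence weight \eqn{\omega} (evidence units per subunit).  The standard
#'   `block` subunit's weight is fixed to 1 by convention; if a `block`
#'   entry is present it must equal 1.
#' @param sigma standard deviation \eqn{\sigma \ge 0} of the Gaussian noise
#'   added at each subunit step.
#' @param theta_plus upper (respond) threshold \eqn{\theta_+ > 0}.
#' @param theta_minus lower (reject) threshold \eqn{\theta_- < 0}.
#' @return Object of class `ddm_params`.
#' @examples
#' p <- ddm_params(c(block = 1, mollis = -87), sigma = 142,
#'                 theta_plus = 420, theta_minus = -803)
#' @export
ddm_params <- function(weights, sigma, theta_plus, theta_minus) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("'weights' must be a fully named numeric vector")
  stopifnot_scalar_number(sigma, "sigma")
  stopifnot_scalar_number(theta_plus, "theta_plus")
  stopifnot_scalar_number(theta_minus, "theta_minus")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (!(theta_minus < 0 && theta_plus > 0))
    stop("thresholds must satisfy theta_minus < 0 < theta_plus")
  if ("block" %in% names(weights) && weights[["block"]] != 1)
    stop("the standard block subunit's weight is fixed to 1.0")
  structure(list(weights = weights, sigma = sigma,
                 theta_plus = theta_plus, theta_minus = theta_minus),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>\n  weights:\n")
  w <- x$weights
  cat(paste(sprintf("    %-18s %8.2f", names(w), w), collapse = "\n"), "\n")
  cat(sprintf("  sigma: %.2f   theta_plus: %.2f   theta_minus: %.2f\n",
              x$sigma, x$theta_plus, x$theta_minus))
  invisible(x)
}

#' Published mean parameter estimates for *C. biguttulus* females
#'
#' The mean fitted subunit weights and integrator parameters from the
#' cross-validated model fit to the behavioral playback data (weights per
#' subunit type; noise SD 142, upper threshold 420, lower threshold -803;
#' block weight fixed at 1).  Useful as a realistic ground truth for
#' synthetic cohorts and for the decision-dynamics examples.
#'
#' @return A [ddm_params()] object.
#' @export
reference_ddm_params <- function() {
  ddm_params(
    weights = c(block = 1, block76ms = 1,
                dorsatus = -82, mollis = -87, gap = -55,
                offset8dB = -51, pause4ms = -53,
                onset3dB_pause4ms = -40, onset9dB = 15,
                accent_offset = -34, accent_onset = 7),
    sigma = 142, theta_plus = 420, theta_minus = -803)
}

#' Settings for the dynamics backends
#'
#' @param n_reps Monte-Carlo repetitions (default 50,000, the resolution
#'   used for the mean-trajectory figures).
#' @param seed integer seed for Monte-Carlo runs (`NULL` = current RNG).
#' @param grid_bins_per_sigma resolution of the density-propagation grid:
#'   number of bins per noise SD.
#' @param max_bins safety cap on the total number of grid bins.
#' @param n_bins optional fixed integer 2-vector `c(neg, pos)` of grid-bin
#'   counts, overriding the per-sigma rule (useful when `sigma` is tiny
#'   relative to the thresholds, e.g. near the noise-free limit).
#' @return Object of class `dynamics_config`.
#' @export
dynamics_config <- function(n_reps = 50000, seed = NULL,
                            grid_bins_per_sigma = 20, max_bins = 6000,
                            n_bins = NULL) {
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  structure(list(n_reps = as.integer(n_reps), seed = seed,
                 grid_bins_per_sigma = grid_bins_per_sigma,
                 max_bins = as.integer(max_bins),
                 n_bins = if (!is.null(n_bins)) as.integer(n_bins)),
            class = "dynamics_config")
}

# map a song's labels to integer indices into a weight vector; errors on a
# missing weight
song_weight_indices <- function(song, params) {
  idx <- match(song$labels, names(params$weights))
  if (anyNA(idx)) {
    bad <- unique(song$labels[is.na(idx)])
    stop(sprintf("no weight for subunit label(s): %s", paste(bad, collapse = ", ")))
  }
  idx
}

# choose interior grid-bin counts (negative side, positive side) for the
# density-propagation backend
grid_bin_counts <- function(params, cfg) {
  if (!is.null(cfg$n_bins))
    return(c(n_neg = cfg$n_bins[1], n_pos = cfg$n_bins[2]))
  h <- params$sigma / cfg$grid_bins_per_sigma
  n_neg <- max(2L, as.integer(ceiling(-params$theta_minus / h)))
  n_pos <- max(2L, as.integer(ceiling(params$theta_plus / h)))
  if (n_neg + n_pos > cfg$max_bins)
    stop(sprintf(paste0("density grid would need %d bins (cap %d); lower ",
                        "grid_bins_per_sigma or raise max_bins"),
                 n_neg + n_pos, cfg$max_bins))
  c(n_neg = n_neg, n_pos = n_pos)
}

# full density-propagation pass for one song
propagate_exact <- function(song, params, cfg = dynamics_config()) {
  if (params$sigma <= 0)
    stop("sigma = 0: use integrate_deterministic() for the noise-free model")
  idx <- song_weight_indices(song, params)
  nb <- grid_bin_counts(params, cfg)
  .ddm_propagate_cpp(as.integer(idx), as.numeric(params$weights), params$sigma,
                     params$theta_minus, params$theta_plus,
                     nb[["n_neg"]], nb[["n_pos"]])
}

#' Noise-free evidence integration
#'
#' Accumulates the subunit weights without noise.  The decision is fixed at
#' the first step whose evidence is strictly above `theta_plus` or strictly
#' below `theta_minus`; afterwards the trajectory is clamped at the crossed
#' threshold.  If no threshold is crossed, the outcome is given by the sign
#' of the evidence at song end (`respond` iff `E_L > 0`; a value of exactly
#' 0 counts as reject — the no-response default, and a measure-zero event
#' once noise is present).
#'
#' @param song a [song_model()].
#' @param params a [ddm_params()].
#' @return Object of class `ddm_trajectory`: list with `evidence` (clamped,
#'   `E_0 = 0` to `E_L`), `absorbed_at` (step index or `NA`), `crossed`
#'   (`"upper"`, `"lower"`, `"none"`), `outcome` (`"respond"`/`"reject"`).
#' @export
integrate_deterministic <- function(song, params) {
  idx <- song_weight_indices(song, params)
  inc <- as.numeric(params$weights)[idx]
  E <- cumsum(inc)
  up <- which(E > params$theta_plus)
  lo <- which(E < params$theta_minus)
  k_up <- if (length(up)) up[1] else Inf
  k_lo <- if (length(lo)) lo[1] else Inf
  L <- length(E)
  if (is.finite(k_up) && k_up <= k_lo) {
    crossed <- "upper"; k <- k_up; E[k:L] <- params$theta_plus
  } else if (is.finite(k_lo)) {
    crossed <- "lower"; k <- k_lo; E[k:L] <- params$theta_minus
  } else {
    crossed <- "none"; k <- NA_integer_
  }
  outcome <- switch(crossed,
                    upper = "respond",
                    lower = "reject",
                    none = if (L > 0 && E[L] > 0) "respond" else "reject")
  structure(list(evidence = c(0, E), absorbed_at = k, crossed = crossed,
                 outcome = outcome),
            class = "ddm_trajectory")
}

#' Simulate noisy decision trials
#'
#' Per step, the evidence gains the subunit's weight plus Gaussian noise
#' (one joint increment), then the absorbing thresholds are tested (strict
#' crossing).  Unabsorbed trials are decided by the sign rule at song end.
#'
#' @param song a [song_model()].
#' @param params a [ddm_params()].
#' @param n number of independent trials.
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return `data.frame` with one row per trial: `outcome`
#'   (`"respond"`/`"reject"`), `crossed` (`"upper"`/`"lower"`/`"none"`),
#'   `step` (absorption step, or `L` for non-crossers).
#' @export
simulate_trials <- function(song, params, n = 1, seed = NULL) {
  idx <- song_weight_indices(song, params)
  inc <- as.numeric(params$weights)[idx]
  L <- length(inc)
  with_seed(seed, {
    E <- numeric(n)
    crossed <- rep("none", n)
    step <- rep(L, n)
    active <- rep(TRUE, n)
    for (t in seq_len(L)) {
      na <- sum(active)
      if (na == 0L) break
      noise <- if (params$sigma > 0) rnorm(na, 0, params$sigma) else 0
      E[active] <- E[active] + inc[t] + noise
      hit_up <- active & E > params$theta_plus
      hit_lo <- active & E < params$theta_minus
      crossed[hit_up] <- "upper"; crossed[hit_lo] <- "lower"
      step[hit_up | hit_lo] <- t
      E[hit_up] <- params$theta_plus; E[hit_lo] <- params$theta_minus
      active <- active & !(hit_up | hit_lo)
    }
    outcome <- ifelse(crossed == "upper", "respond",
                      ifelse(crossed == "lower", "reject",
                             ifelse(E > 0, "respond", "reject")))
    data.frame(outcome = outcome, crossed = crossed, step = step)
  })
}

#' One simulated decision
#'
#' @inheritParams simulate_trials
#' @return List with `outcome`, `crossed`, `step`.
#' @export
simulate_trial <- function(song, params, seed = NULL) {
  as.list(simulate_trials(song, params, n = 1, seed = seed)[1, ])
}

#' Monte-Carlo response probability
#'
#' @param song a [song_model()].
#' @param params a [ddm_params()].
#' @param cfg a [dynamics_config()]; `cfg$n_reps` trials are simulated under
#'   `cfg$seed`.
#' @return List with `p_hat` (fraction of respond outcomes), `se` (binomial
#'   standard error `sqrt(p(1-p)/n)`), `n_reps`, `seed`.
#' @export
response_probability_mc <- function(song, params, cfg = dynamics_config()) {
  tr <- simulate_trials(song, params, n = cfg$n_reps, seed = cfg$seed)
  p <- mean(tr$outcome == "respond")
  list(p_hat = p, se = sqrt(p * (1 - p) / cfg$n_reps),
       n_reps = cfg$n_reps, seed = cfg$seed)
}

#' Exact response probability by density propagation
#'
#' Propagates the evidence density step by step over a bin grid spanning
#' `[theta_minus, theta_plus]` (a Gaussian-kernel convolution shifted by the
#' subunit weight per step), bookkeeping the mass absorbed beyond each
#' threshold.  The returned probability is the absorbed-upper mass plus the
#' unabsorbed mass with positive evidence at song end.  The first step is
#' taken analytically from the initial point mass at 0, so single-step
#' probabilities are exact to CDF accuracy.
#'
#' @param song a [song_model()].
#' @param params a [ddm_params()] with `sigma > 0` (for `sigma = 0` use
#'   [integrate_deterministic()]).
#' @param cfg a [dynamics_config()]; `grid_bins_per_sigma` sets the
#'   resolution.
#' @return Probability of a respond decision (numeric scalar).
#' @export
response_probability_exact <- function(song, params, cfg = dynamics_config()) {
  propagate_exact(song, params, cfg)$p_respond
}

#' First-passage profile of a song
#'
#' Per-step probabilities of fixing the decision at the upper or the lower
#' threshold, plus the terminal (non-crosser) respond and reject masses.
#'
#' @param song a [song_model()].
#' @param params a [ddm_params()].
#' @param cfg a [dynamics_config()].
#' @param backend `"exact"` (density propagation; conservation holds
#'   exactly) or `"mc"` (Monte-Carlo at `cfg$n_reps`).  With `sigma = 0`
#'   the deterministic limit is returned for either backend.
#' @return Object of class `fp_profile`: list with `p_upper`, `p_lower`
#'   (length-`L` step masses), `p_end_respond`, `p_end_reject`, `L`,
#'   `backend`.
#' @export
first_passage_profile <- function(song, params, cfg = dynamics_config(),
                                  backend = c("exact", "mc")) {
  backend <- match.arg(backend)
  L <- length(song$labels)
  if (params$sigma == 0) {
    tr <- integrate_deterministic(song, params)
    pu <- numeric(L); pl <- numeric(L); er <- 0; ej <- 0
    if (tr$crossed == "upper") pu[tr$absorbed_at] <- 1
    else if (tr$crossed == "lower") pl[tr$absorbed_at] <- 1
    else if (tr$outcome == "respond") er <- 1 else ej <- 1
    return(structure(list(p_upper = pu, p_lower = pl, p_end_respond = er,
                          p_end_reject = ej, L = L, backend = "deterministic"),
                     class = "fp_profile"))
  }
  if (backend == "exact") {
    pr <- propagate_exact(song, params, cfg)
    structure(list(p_upper = pr$abs_upper, p_lower = pr$abs_lower,
                   p_end_respond = pr$end_respond, p_end_reject = pr$end_reject,
                   L = L, backend = "exact"),
              class = "fp_profile")
  } else {
    tr <- simulate_trials(song, params, n = cfg$n_reps, seed = cfg$seed)
    pu <- tabulate(tr$step[tr$crossed == "upper"], L) / cfg$n_reps
    pl <- tabulate(tr$step[tr$crossed == "lower"], L) / cfg$n_reps
    er <- mean(tr$crossed == "none" & tr$outcome == "respond")
    ej <- mean(tr$crossed == "none" & tr$outcome == "reject")
    structure(list(p_upper = pu, p_lower = pl, p_end_respond = er,
                   p_end_reject = ej, L = L, backend = "mc"),
              class = "fp_profile")
  }
}

#' Mean clamped evidence trajectory
#'
#' The expected value, per subunit step, of the evidence with absorbed
#' paths held at their threshold value — the quantity plotted when the
#' noisy integration is averaged over many repetitions.
#'
#' @inheritParams first_passage_profile
#' @return Numeric vector of length `L` (steps 1..`L`); every value lies in
#'   `[theta_minus, theta_plus]`.
#' @export
mean_trajectory <- function(song, params, cfg = dynamics_config(),
                            backend = c("exact", "mc")) {
  backend <- match.arg(backend)
  if (params$sigma == 0)
    return(integrate_deterministic(song, params)$evidence[-1])
  if (backend == "exact") return(propagate_exact(song, params, cfg)$mean_traj)
  idx <- song_weight_indices(song, params)
  inc <- as.numeric(params$weights)[idx]
  L <- length(inc)
  with_seed(cfg$seed, {
    n <- cfg$n_reps
    E <- numeric(n); active <- rep(TRUE, n); out <- numeric(L)
    for (t in seq_len(L)) {
      na <- sum(active)
      if (na > 0L) {
        E[active] <- E[active] + inc[t] + rnorm(na, 0, params$sigma)
        hit_up <- active & E > params$theta_plus
        hit_lo <- active & E < params$theta_minus
        E[hit_up] <- params$theta_plus; E[hit_lo] <- params$theta_minus
        active <- active & !(hit_up | hit_lo)
      }
      out[t] <- mean(E)
    }
    out
  })
}
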