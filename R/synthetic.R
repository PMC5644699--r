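#' Configuration for a synthetic behavioral cohort
#'
#' Mirrors the playback design: each female hears every song of her set
#' `n_cycles` times (18 in the experiments), responses are conditionally
#' independent Bernoulli draws from the ground-truth model's response
#' probability, and a 3-s unmodulated-noise negative control excludes
#' unselective females (more than `exclusion_threshold` control responses).
#'
#' @param truth a [ddm_params()]: the ground-truth generating model.
#' @param songs list of [song_model()]s (e.g. from
#'   [build_paper_stimulus_sets()]).
#' @param n_females females per cohort (12-22 in the experiments).
#' @param n_cycles presentation cycles per female.
#' @param control_response_prob per-presentation probability of responding
#'   to the negative control.
#' @param exclusion_threshold maximum tolerated control responses.
#' @param female_sd SD of an optional per-female logit-normal perturbation
#'   of the response probability (0 = homogeneous cohort, the default).
#' @param seed integer seed.
#' @return Object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(truth, songs, n_females = 20, n_cycles = 18,
                                    control_response_prob = 0.02,
                                    exclusion_threshold = 2,
                                    female_sd = 0, seed = 1L) {
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  if (exclusion_threshold < 0) stop("'exclusion_threshold' must be >= 0")
  structure(list(truth = truth, songs = songs,
                 n_females = as.integer(n_females),
                 n_cycles = as.integer(n_cycles),
                 control_response_prob = control_response_prob,
                 exclusion_threshold = as.integer(exclusion_threshold),
                 female_sd = female_sd, seed = seed),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic behavioral dataset
#'
#' For every song, the ground-truth response probability is computed with
#' the exact density-propagation backend (or the deterministic model when
#' `sigma = 0`); each retained female's response count is a binomial draw
#' over her presentation cycles.  Females exceeding the negative-control
#' exclusion threshold are dropped before response rates are averaged.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param dyn_cfg a [dynamics_config()] for the ground-truth probabilities.
#' @return Object of class `synthetic_dataset`: `dataset` (a
#'   [response_dataset()] of per-song mean response rates over retained
#'   females), `per_female` (songs x females response-count matrix, `NA`
#'   for excluded females), `excluded_females` (indices),
#'   `control_responses`, `p_truth`, and `truth` (carried for recovery
#'   scoring).
#' @export
generate_cohort <- function(cfg, dyn_cfg = dynamics_config()) {
  songs <- cfg$songs
  p_truth <- vapply(songs, function(s) {
    if (cfg$truth$sigma == 0) {
      as.numeric(integrate_deterministic(s, cfg$truth)$outcome == "respond")
    } else {
      response_probability_exact(s, cfg$truth, dyn_cfg)
    }
  }, numeric(1))
  names(p_truth) <- vapply(songs, `[[`, character(1), "id")
  with_seed(cfg$seed, {
    control <- rbinom(cfg$n_females, cfg$n_cycles, cfg$control_response_prob)
    excluded <- which(control > cfg$exclusion_threshold)
    retained <- setdiff(seq_len(cfg$n_females), excluded)
    if (length(retained) == 0L)
      stop("empty cohort: all females excluded by the negative control")
    counts <- matrix(NA_integer_, nrow = length(songs), ncol = cfg$n_females,
                     dimnames = list(vapply(songs, `[[`, character(1), "id"), NULL))
    for (f in retained) {
      p_f <- if (cfg$female_sd > 0)
        plogis(qlogis(pmin(pmax(p_truth, 1e-9), 1 - 1e-9)) +
                 rnorm(1, 0, cfg$female_sd))
      else p_truth
      counts[, f] <- rbinom(length(songs), cfg$n_cycles, p_f)
    }
    rates <- rowMeans(counts[, retained, drop = FALSE]) / cfg$n_cycles
    ds <- response_dataset(songs, rates, n_females = length(retained),
                           n_cycles = cfg$n_cycles)
    structure(list(dataset = ds, per_female = counts,
                   excluded_females = excluded,
                   control_responses = control,
                   p_truth = p_truth, truth = cfg$truth),
              class = "synthetic_dataset")
  })
}

#' Noise-free ("ideal") response dataset
#'
#' Response rates set exactly to the model's response probabilities: the
#' infinite-data limit of [generate_cohort()], used for self-consistency
#' and recovery checks.
#'
#' @param songs list of [song_model()]s.
#' @param params a [ddm_params()].
#' @param dyn_cfg a [dynamics_config()].
#' @param n_females,n_cycles trial structure recorded in the dataset.
#' @return A [response_dataset()].
#' @export
ideal_response_dataset <- function(songs, params, dyn_cfg = dynamics_config(),
                                   n_females = 20, n_cycles = 18) {
  p <- vapply(songs, function(s) {
    if (params$sigma == 0)
      as.numeric(integrate_deterministic(s, params)$outcome == "respond")
    else response_probability_exact(s, params, dyn_cfg)
  }, numeric(1))
  response_dataset(songs, p, n_females = n_females, n_cycles = n_cycles)
}

#' Score parameter recovery against the generating truth
#'
#' @param result a `crossval_result` (fold-wise parameters) or a `ddm_fit`.
#' @param truth the generating [ddm_params()].
#' @param tolerance relative tolerance defining per-fold coverage.
#' @return `data.frame` with one row per parameter: `truth`, `mean_fitted`,
#'   `bias` (`mean_fitted - truth`), `rel_error` (`|bias|/|truth|`, `NA`
#'   for a zero truth), `coverage` (fraction of folds within `tolerance`;
#'   `NA` for a single fit), and a `note` column flagging the lower
#'   threshold as `bounded_only` when it is fitted deeper than the truth
#'   (its loss profile is flat below the data's constraint, so depth is
#'   not evidence of bias).
#' @export
recovery_report <- function(result, truth, tolerance = 0.2) {
  truth_vec <- c(truth$weights, sigma = truth$sigma,
                 theta_plus = truth$theta_plus, theta_minus = truth$theta_minus)
  if (inherits(result, "crossval_result")) {
    pm <- result$params_matrix
  } else if (inherits(result, "ddm_fit")) {
    pm <- matrix(result$theta, nrow = 1, dimnames = list(NULL, names(result$theta)))
  } else stop("'result' must be a crossval_result or ddm_fit")
  common <- intersect(colnames(pm), names(truth_vec))
  rows <- lapply(common, function(nm) {
    tv <- truth_vec[[nm]]
    fitted <- pm[, nm]
    bias <- mean(fitted) - tv
    rel <- if (tv == 0) NA_real_ else abs(bias) / abs(tv)
    cover <- if (nrow(pm) > 1 && tv != 0)
      mean(abs(fitted - tv) / abs(tv) <= tolerance) else NA_real_
    note <- ""
    if (nm == "theta_minus" && mean(fitted) < tv) note <- "bounded_only"
    data.frame(parameter = nm, truth = tv, mean_fitted = mean(fitted),
               bias = bias, rel_error = rel, coverage = cover, note = note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
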