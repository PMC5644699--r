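#' Behavioral response dataset
#'
#' Couples song models with their observed (or simulated) response rates:
#' the fraction of presentations a female cohort answered with a response
#' song.
#'
#' @param songs list of [song_model()]s.
#' @param response_rate numeric vector in `[0, 1]`, one value per song.
#' @param n_females number of females contributing to each rate (recycled).
#' @param n_cycles presentation cycles per female (recycled; 18 in the
#'   playback design).
#' @return Object of class `response_dataset` with elements `songs` (named
#'   list) and `data` (`data.frame` of `song_id`, `set_id`, `response_rate`,
#'   `n_females`, `n_cycles`).
#' @export
response_dataset <- function(songs, response_rate, n_females = 20, n_cycles = 18) {
  if (length(songs) != length(response_rate))
    stop("'songs' and 'response_rate' lengths differ")
  if (any(response_rate < 0 | response_rate > 1))
    stop("'response_rate' must lie in [0, 1]")
  ids <- vapply(songs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate song ids")
  names(songs) <- ids
  data <- data.frame(
    song_id = ids,
    set_id = vapply(songs, `[[`, character(1), "set_id"),
    response_rate = as.numeric(response_rate),
    n_females = rep_len(n_females, length(songs)),
    n_cycles = rep_len(n_cycles, length(songs)),
    row.names = NULL)
  structure(list(songs = songs, data = data), class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf("<response_dataset> %d songs, %d set(s)\n", nrow(x$data),
              length(unique(x$data$set_id))))
  print(utils::head(x$data))
  invisible(x)
}

#' Fitting configuration
#'
#' Bounds and genetic-algorithm settings for [fit_ddm()].  The GA is a
#' real-coded elitist GA: tournament selection, uniform crossover, Gaussian
#' mutation with a per-generation decaying SD, and an early stop once the
#' best loss improves by less than `convergence_tol` over
#' `convergence_window` generations.  An optional bounded quasi-Newton
#' polish (`polish = TRUE`) restarts from the GA's best individuals; the
#' exact-propagation objective is deterministic, so polishing is safe and
#' sharpens the estimates considerably at small GA budgets.
#'
#' @param bounds named list of 2-vectors: `weights`, `sigma`, `theta_plus`,
#'   `theta_minus` (defaults `[-200, 50]`, `(0, 500]`, `(0, 2000]`,
#'   `[-5000, 0)`).
#' @param population,generations GA population size and generation cap.
#' @param tournament_size,crossover_rate,elitism selection and variation
#'   settings.
#' @param mutation_sd_frac initial mutation SD as a fraction of each
#'   parameter's bound range; decays by `mutation_decay` per generation.
#' @param mutation_decay per-generation decay of the mutation SD.
#' @param convergence_window,convergence_tol early-stopping rule.
#' @param polish,polish_starts,polish_maxit quasi-Newton refinement of the
#'   GA optimum (L-BFGS-B on the unit-scaled parameters).
#' @param objective `"mse"` (default; mean squared error between predicted
#'   probability and observed rate) or `"binomial"` (negative log-likelihood
#'   weighted by `n_females * n_cycles`).
#' @param n_bins integer 2-vector `c(neg, pos)`: fixed interior-grid bin
#'   counts for the density propagation used during fitting.  A fixed count
#'   keeps the objective smooth in `sigma` and the thresholds (a
#'   bins-per-sigma grid makes the bin count jump with the parameters).
#' @param fixed_weights named numeric vector of weights held fixed (default:
#'   both block variants at 1, the model's unit of evidence).
#' @param free_weights optional character vector restricting which subunit
#'   weights are fitted; labels absent from the data are flagged and
#'   reported as unconstrained (`NA`).
#' @param seed integer seed making the whole fit deterministic.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(weights = c(-200, 50),
                                     sigma = c(1e-3, 500),
                                     theta_plus = c(1e-3, 2000),
                                     theta_minus = c(-5000, -1e-3)),
                       population = 200, generations = 300,
                       tournament_size = 3, crossover_rate = 0.7,
                       elitism = 2, mutation_sd_frac = 0.05,
                       mutation_decay = 0.99,
                       convergence_window = 25, convergence_tol = 1e-6,
                       polish = TRUE, polish_starts = 2, polish_maxit = 300,
                       objective = c("mse", "binomial"),
                       n_bins = c(neg = 120L, pos = 64L),
                       fixed_weights = c(block = 1, block76ms = 1),
                       free_weights = NULL, seed = 1L) {
  if (population < 10) stop("'population' must be >= 10")
  structure(list(bounds = bounds, population = as.integer(population),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate, elitism = as.integer(elitism),
                 mutation_sd_frac = mutation_sd_frac,
                 mutation_decay = mutation_decay,
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol,
                 polish = polish, polish_starts = as.integer(polish_starts),
                 polish_maxit = as.integer(polish_maxit),
                 objective = match.arg(objective),
                 n_bins = as.integer(n_bins),
                 fixed_weights = fixed_weights,
                 free_weights = free_weights, seed = seed),
            class = "fit_config")
}

# ---- internal fitting machinery ---------------------------------------------

# integer label sequences for all songs, indices into `labels`
dataset_sequences <- function(data, labels) {
  lapply(data$songs, function(s) {
    idx <- match(s$labels, labels)
    if (anyNA(idx))
      stop(sprintf("no weight for subunit label(s): %s",
                   paste(unique(s$labels[is.na(idx)]), collapse = ", ")))
    as.integer(idx)
  })
}

# model-predicted response probabilities for all songs at one parameter set
predict_probs <- function(weights, sigma, theta_plus, theta_minus,
                          seqs, set_of_song = NULL, per_set = NULL,
                          n_bins = c(120L, 64L)) {
  if (is.null(per_set)) {
    .ddm_dataset_probs_cpp(seqs, as.numeric(weights), sigma,
                           theta_minus, theta_plus, n_bins[1], n_bins[2])
  } else {
    p <- numeric(length(seqs))
    for (s in names(per_set)) {
      sel <- set_of_song == s
      ig <- per_set[[s]]
      p[sel] <- .ddm_dataset_probs_cpp(seqs[sel], as.numeric(weights),
                                       ig["sigma"], ig["theta_minus"],
                                       ig["theta_plus"], n_bins[1], n_bins[2])
    }
    p
  }
}

objective_value <- function(p, data, objective) {
  r <- data$data$response_rate
  if (objective == "mse") return(mean((p - r)^2))
  pc <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  n <- data$data$n_females * data$data$n_cycles
  -sum(n * (r * log(pc) + (1 - r) * log(1 - pc))) / sum(n)
}

# Real-coded GA over the unit cube [0,1]^d; returns the best point, its
# loss, the best-of-generation trace and the final population.
ga_optimize <- function(fn, d, cfg) {
  P <- cfg$population
  pop <- matrix(runif(P * d), nrow = P)
  fit <- apply(pop, 1, fn)
  trace <- numeric(0)
  sd0 <- cfg$mutation_sd_frac
  best_hist <- Inf
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    trace <- c(trace, fit[ord[1]])
    # convergence: best loss improved < tol over the window
    if (gen > cfg$convergence_window) {
      w <- cfg$convergence_window
      if (trace[gen - w] - trace[gen] < cfg$convergence_tol) break
    }
    newpop <- matrix(0, nrow = P, ncol = d)
    n_elite <- min(cfg$elitism, P)
    newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    sd_gen <- sd0 * cfg$mutation_decay^(gen - 1)
    for (i in seq(n_elite + 1, P)) {
      pick <- function() {
        cand <- sample.int(P, cfg$tournament_size)
        cand[which.min(fit[cand])]
      }
      a <- pop[pick(), ]; b <- pop[pick(), ]
      child <- if (runif(1) < cfg$crossover_rate)
        ifelse(runif(d) < 0.5, a, b) else a
      child <- child + rnorm(d, 0, sd_gen)
      newpop[i, ] <- pmin(pmax(child, 0), 1)
    }
    pop <- newpop
    fit <- apply(pop, 1, fn)
  }
  ord <- order(fit)
  list(best = pop[ord[1], ], best_loss = fit[ord[1]],
       trace = cummin(trace), pop = pop[ord, , drop = FALSE],
       fit = fit[ord])
}

polish_optimize <- function(fn, starts, maxit) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], fn, method = "L-BFGS-B",
            lower = rep(1e-9, ncol(starts)), upper = rep(1 - 1e-9, ncol(starts)),
            # the loss ridge along the model's near scale-invariance is very
            # shallow: tight tolerances + fine FD steps are required
            control = list(maxit = maxit, factr = 10, pgtol = 0,
                           ndeps = rep(1e-5, ncol(starts)))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  best
}

# layout of the optimized parameter vector
param_layout <- function(free_labels, set_ids, per_set_integrator, fixed_theta_minus) {
  nm <- free_labels
  if (!per_set_integrator) {
    nm <- c(nm, "sigma", "theta_plus", if (is.null(fixed_theta_minus)) "theta_minus")
  } else {
    for (s in set_ids)
      nm <- c(nm, paste0("sigma.", s), paste0("theta_plus.", s),
              if (is.null(fixed_theta_minus)) paste0("theta_minus.", s))
  }
  nm
}

layout_bounds <- function(nm, bounds) {
  lo <- numeric(length(nm)); hi <- numeric(length(nm))
  for (i in seq_along(nm)) {
    b <- if (startsWith(nm[i], "sigma")) bounds$sigma
    else if (startsWith(nm[i], "theta_plus")) bounds$theta_plus
    else if (startsWith(nm[i], "theta_minus")) bounds$theta_minus
    else bounds$weights
    lo[i] <- b[1]; hi[i] <- b[2]
  }
  list(lower = lo, upper = hi)
}

fit_internal <- function(data, cfg, per_set_integrator = FALSE,
                         fixed_theta_minus = NULL) {
  df <- data$data
  labels_in_data <- unique(unlist(lapply(data$songs, `[[`, "labels")))
  fixed <- cfg$fixed_weights[names(cfg$fixed_weights) %in% labels_in_data]
  free_labels <- setdiff(labels_in_data, names(fixed))
  unconstrained <- character(0)
  if (!is.null(cfg$free_weights)) {
    unconstrained <- setdiff(cfg$free_weights, labels_in_data)
    if (length(unconstrained))
      warning(sprintf("weight(s) unidentifiable (subunit absent from data): %s",
                      paste(unconstrained, collapse = ", ")))
    free_labels <- intersect(cfg$free_weights, labels_in_data)
  }
  all_labels <- c(names(fixed), free_labels)
  seqs <- dataset_sequences(data, all_labels)
  set_ids <- unique(df$set_id)
  if (per_set_integrator && length(set_ids) < 2)
    stop("per-set integrator comparison needs data spanning >= 2 stimulus sets")
  nm <- param_layout(free_labels, set_ids, per_set_integrator, fixed_theta_minus)
  b <- layout_bounds(nm, cfg$bounds)
  nw <- length(free_labels)
  unscale <- function(u) b$lower + u * (b$upper - b$lower)

  make_eval <- function() {
    force(seqs)
    function(u) {
      th <- unscale(u)
      w <- c(fixed, setNames(th[seq_len(nw)], free_labels))
      if (!per_set_integrator) {
        tm <- if (is.null(fixed_theta_minus)) th[nw + 3] else fixed_theta_minus
        p <- predict_probs(w[all_labels], th[nw + 1], th[nw + 2], tm,
                           seqs, n_bins = cfg$n_bins)
      } else {
        k <- if (is.null(fixed_theta_minus)) 3L else 2L
        per_set <- list()
        for (j in seq_along(set_ids)) {
          off <- nw + (j - 1) * k
          per_set[[set_ids[j]]] <- c(
            sigma = th[off + 1], theta_plus = th[off + 2],
            theta_minus = if (k == 3L) th[off + 3] else fixed_theta_minus)
        }
        p <- predict_probs(w[all_labels], NA, NA, NA, seqs,
                           set_of_song = df$set_id, per_set = per_set,
                           n_bins = cfg$n_bins)
      }
      objective_value(p, data, cfg$objective)
    }
  }
  fn <- make_eval()

  res <- with_seed(cfg$seed, {
    ga <- ga_optimize(fn, length(nm), cfg)
    if (cfg$polish) {
      k <- min(cfg$polish_starts, nrow(ga$pop))
      pol <- polish_optimize(fn, ga$pop[seq_len(k), , drop = FALSE],
                             cfg$polish_maxit)
      if (!is.null(pol) && pol$value <= ga$best_loss) {
        ga$best <- pol$par; ga$best_loss <- pol$value
        ga$trace <- c(ga$trace, pol$value)
      }
    }
    ga
  })

  th <- unscale(res$best)
  names(th) <- nm
  weights <- c(fixed, setNames(th[seq_len(nw)], free_labels))
  if (length(unconstrained))
    weights <- c(weights, setNames(rep(NA_real_, length(unconstrained)), unconstrained))
  out <- list(theta = th, weights = weights, loss = res$best_loss,
              trace = cummin(res$trace), free_labels = free_labels,
              unconstrained = unconstrained, set_ids = set_ids,
              per_set_integrator = per_set_integrator,
              fixed_theta_minus = fixed_theta_minus,
              seqs_labels = all_labels, cfg = cfg)
  if (!per_set_integrator) {
    out$params <- ddm_params(
      weights[!is.na(weights)], sigma = unname(th[nw + 1]),
      theta_plus = unname(th[nw + 2]),
      theta_minus = unname(if (is.null(fixed_theta_minus)) th[nw + 3] else fixed_theta_minus))
  } else {
    k <- if (is.null(fixed_theta_minus)) 3L else 2L
    out$integrators <- lapply(seq_along(set_ids), function(j) {
      off <- nw + (j - 1) * k
      c(sigma = unname(th[off + 1]), theta_plus = unname(th[off + 2]),
        theta_minus = unname(if (k == 3L) th[off + 3] else fixed_theta_minus))
    })
    names(out$integrators) <- set_ids
  }
  class(out) <- "ddm_fit"
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> loss = %.6g after %d GA generations%s\n", x$loss,
              length(x$trace), if (x$cfg$polish) " (+ polish)" else ""))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

# held-out predictions for songs under a fitted model
predict_fit <- function(fit, data) {
  seqs <- dataset_sequences(data, fit$seqs_labels)
  w <- fit$weights[fit$seqs_labels]
  if (!fit$per_set_integrator) {
    predict_probs(w, fit$params$sigma, fit$params$theta_plus,
                  fit$params$theta_minus, seqs, n_bins = fit$cfg$n_bins)
  } else {
    per_set <- fit$integrators
    predict_probs(w, NA, NA, NA, seqs, set_of_song = data$data$set_id,
                  per_set = per_set, n_bins = fit$cfg$n_bins)
  }
}

# ---- exported operations ----------------------------------------------------

#' Fitting objective for a parameter set
#'
#' Mean squared error (default) between the model's exact response
#' probabilities and the observed response rates, or the
#' trial-count-weighted binomial negative log-likelihood.
#'
#' @param params a [ddm_params()].
#' @param data a [response_dataset()].
#' @param objective `"mse"` or `"binomial"`.
#' @param n_bins density-propagation grid bins `c(neg, pos)`.
#' @return Nonnegative scalar.
#' @export
ddm_loss <- function(params, data, objective = c("mse", "binomial"),
                     n_bins = c(120L, 64L)) {
  objective <- match.arg(objective)
  labels <- names(params$weights)
  seqs <- dataset_sequences(data, labels)
  p <- predict_probs(params$weights, params$sigma, params$theta_plus,
                     params$theta_minus, seqs, n_bins = as.integer(n_bins))
  objective_value(p, data, objective)
}

#' Fit the decision model to response rates
#'
#' Genetic-algorithm estimation of the free subunit weights and the shared
#' integrator parameters (`sigma`, `theta_plus`, `theta_minus`), with the
#' standard block weight fixed at 1.  The objective uses the exact
#' density-propagation backend, so the fit is deterministic given
#' `cfg$seed`.
#'
#' @param data a [response_dataset()] with at least two distinct songs.
#' @param cfg a [fit_config()].
#' @return Object of class `ddm_fit`: `params` (a [ddm_params()]), `loss`,
#'   `trace` (best-of-generation losses, non-increasing), and bookkeeping.
#' @export
fit_ddm <- function(data, cfg = fit_config()) {
  if (nrow(data$data) < 2) stop("need >= 2 songs to fit")
  fit_internal(data, cfg)
}

#' Leave-one-out cross-validation of the model fit
#'
#' One fold per song: the model is fitted to the remaining songs and the
#' held-out song's response rate predicted.  If a fold's training set lacks
#' a subunit entirely, that weight is carried over from a full-data fit and
#' the fold flagged.
#'
#' @param data a [response_dataset()] with >= 3 songs.
#' @param cfg a [fit_config()].
#' @return Object of class `crossval_result`: `folds` (`data.frame` of
#'   `song_id`, `observed`, `predicted`, `carried` flag), `params_matrix`
#'   (fold x parameter), `summary` (per-parameter mean and sd over folds),
#'   `r_squared` (coefficient of determination of held-out predictions,
#'   `1 - SS_res/SS_tot`).
#' @export
loocv <- function(data, cfg = fit_config()) {
  df <- data$data
  N <- nrow(df)
  if (N < 3) stop("need >= 3 songs for leave-one-out cross-validation")
  full_fit <- NULL
  preds <- numeric(N); carried <- logical(N)
  params_list <- vector("list", N)
  for (i in seq_len(N)) {
    train <- structure(list(songs = data$songs[-i],
                            data = df[-i, , drop = FALSE]),
                       class = "response_dataset")
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    f <- fit_internal(train, cfg_i)
    held <- data$songs[[i]]
    missing_lab <- setdiff(unique(held$labels), names(f$weights))
    if (length(missing_lab)) {
      if (is.null(full_fit)) full_fit <- fit_internal(data, cfg)
      f$weights <- c(f$weights, full_fit$weights[missing_lab])
      f$seqs_labels <- c(f$seqs_labels, missing_lab)
      f$params$weights <- f$weights[!is.na(f$weights)]
      carried[i] <- TRUE
    }
    held_data <- structure(list(songs = data$songs[i],
                                data = df[i, , drop = FALSE]),
                           class = "response_dataset")
    preds[i] <- predict_fit(f, held_data)
    params_list[[i]] <- f$theta
  }
  pm <- do.call(rbind, params_list)
  obs <- df$response_rate
  ss_res <- sum((obs - preds)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  structure(list(
    folds = data.frame(song_id = df$song_id, observed = obs,
                       predicted = preds, carried = carried),
    params_matrix = pm,
    summary = data.frame(parameter = colnames(pm),
                         mean = colMeans(pm),
                         sd = apply(pm, 2, sd), row.names = NULL),
    r_squared = 1 - ss_res / ss_tot,
    n_folds = N),
    class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds, held-out r^2 = %.4f\n",
              x$n_folds, x$r_squared))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Shared vs per-set integrator model comparison
#'
#' Cross-validates the default model (one `sigma`, `theta_plus`,
#' `theta_minus` shared by all stimulus sets) against a variant giving each
#' set its own integrator, on identical folds.  No selection is forced; the
#' held-out losses and their difference are reported.
#'
#' @param data a [response_dataset()] spanning >= 2 stimulus sets.
#' @param cfg a [fit_config()].
#' @return List with `loss_shared`, `loss_per_set` (mean held-out squared
#'   errors), `difference` (`shared - per_set`; positive favors the per-set
#'   model), and `folds` (per-fold held-out squared errors for both).
#' @export
compare_integrator_models <- function(data, cfg = fit_config()) {
  df <- data$data
  if (length(unique(df$set_id)) < 2)
    stop("per-set integrator comparison needs data spanning >= 2 stimulus sets")
  N <- nrow(df)
  err <- matrix(NA_real_, N, 2, dimnames = list(NULL, c("shared", "per_set")))
  for (i in seq_len(N)) {
    train <- structure(list(songs = data$songs[-i],
                            data = df[-i, , drop = FALSE]),
                       class = "response_dataset")
    held <- structure(list(songs = data$songs[i],
                           data = df[i, , drop = FALSE]),
                      class = "response_dataset")
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    f1 <- fit_internal(train, cfg_i, per_set_integrator = FALSE)
    f2 <- fit_internal(train, cfg_i, per_set_integrator = TRUE)
    obs <- df$response_rate[i]
    err[i, "shared"] <- (predict_fit(f1, held) - obs)^2
    err[i, "per_set"] <- (predict_fit(f2, held) - obs)^2
  }
  list(loss_shared = mean(err[, "shared"]),
       loss_per_set = mean(err[, "per_set"]),
       difference = mean(err[, "shared"]) - mean(err[, "per_set"]),
       folds = as.data.frame(err))
}

#' Loss profile over the lower threshold
#'
#' Refits all remaining parameters at each fixed `theta_minus` value.  The
#' lower threshold is identifiable only up to a minimal magnitude: the
#' profile is expected to rise steeply once `|theta_minus|` is small enough
#' for early spurious rejections, and to be nearly flat below the data's
#' constraint.
#'
#' @param data a [response_dataset()].
#' @param cfg a [fit_config()].
#' @param theta_grid numeric vector of (negative) `theta_minus` values.
#' @return `data.frame` with columns `theta_minus` and `loss`, in the order
#'   of `sort(theta_grid)` (the profile itself is invariant to grid order).
#' @export
profile_theta_minus <- function(data, cfg = fit_config(), theta_grid) {
  if (any(theta_grid >= 0)) stop("'theta_grid' values must be negative")
  if (any(theta_grid < cfg$bounds$theta_minus[1]))
    stop("'theta_grid' outside bounds")
  grid <- sort(theta_grid)
  losses <- vapply(grid, function(tm) {
    fit_internal(data, cfg, fixed_theta_minus = tm)$loss
  }, numeric(1))
  data.frame(theta_minus = grid, loss = losses)
}
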