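test_that("the objective is zero for perfect predictions", {
  # rates generated from the parameters themselves
  ds <- small_ideal_dataset(n_songs = 6)
  expect_lt(ddm_loss(ref_params(), ds), 1e-6)
  # constant 0.5 prediction against constant 0.5 data
  pz <- ddm_params(c(u = 0, v = 0), sigma = 5, theta_plus = 30,
                   theta_minus = -30)
  songs <- list(song_model("a", rep("u", 6), "s"),
                song_model("b", rep("v", 6), "s"))
  ds2 <- response_dataset(songs, c(0.5, 0.5))
  expect_equal(ddm_loss(pz, ds2, n_bins = c(64L, 64L)), 0, tolerance = 1e-15)
  # missing weight is a lookup error
  expect_error(ddm_loss(ddm_params(c(u = 1), 5, 30, -30), ds2, ), "no weight")
})

test_that("a single free weight is recovered from noise-free data", {
  ds <- small_ideal_dataset("mollis", n_songs = 12, seed = 3)
  cfg <- fit_config(population = 24, generations = 30, polish = TRUE,
                    polish_maxit = 200, n_bins = c(60L, 32L), seed = 11)
  f <- fit_ddm(ds, cfg)
  expect_lt(abs(f$params$weights[["mollis"]] - (-87)) / 87, 0.02)
  expect_equal(f$params$weights[["block"]], 1)  # fixed, never fitted
  expect_true(all(diff(f$trace) <= 0))          # best-of-generation loss
})

test_that("fits are deterministic given the seed and respect bounds", {
  ds <- small_ideal_dataset("accent", n_songs = 8, seed = 5)
  cfg <- tiny_fit_config()
  f1 <- fit_ddm(ds, cfg)
  f2 <- fit_ddm(ds, cfg)
  expect_identical(f1$theta, f2$theta)
  b <- cfg$bounds
  w <- f1$params$weights[f1$free_labels]
  expect_true(all(w >= b$weights[1] & w <= b$weights[2]))
  expect_true(f1$params$sigma <= b$sigma[2] && f1$params$sigma > 0)
  expect_true(f1$params$theta_plus <= b$theta_plus[2])
  expect_true(f1$params$theta_minus >= b$theta_minus[1])
})

test_that("the GA beats random search at an equal evaluation budget", {
  ds <- small_ideal_dataset("pause4", n_songs = 8, seed = 9)
  cfg <- fit_config(population = 16, generations = 12, polish = FALSE,
                    n_bins = c(60L, 32L), seed = 21)
  f <- fit_ddm(ds, cfg)
  budget <- 16 * 13  # initial population + per-generation evaluations
  rnd <- local({
    set.seed(21)
    best <- Inf
    for (i in seq_len(budget)) {
      w <- runif(1, -200, 50)
      p <- ddm_params(c(block = 1, pause4ms = w),
                      sigma = runif(1, 1e-3, 500),
                      theta_plus = runif(1, 1e-3, 2000),
                      theta_minus = runif(1, -5000, -1e-3))
      best <- min(best, ddm_loss(p, ds, n_bins = c(60L, 32L)))
    }
    best
  })
  expect_lte(f$loss, rnd)
})

test_that("weights for subunits absent from the data are flagged unconstrained", {
  ds <- small_ideal_dataset("mollis", n_songs = 5, seed = 2)
  cfg <- tiny_fit_config(free_weights = c("mollis", "dorsatus"))
  expect_warning(f <- fit_ddm(ds, cfg), "unidentifiable")
  expect_true(is.na(f$weights[["dorsatus"]]))
  expect_false(is.na(f$weights[["mollis"]]))
})

test_that("leave-one-out cross-validation yields one fold per song", {
  ds <- small_ideal_dataset("offset8", n_songs = 5, seed = 7)
  cv <- loocv(ds, tiny_fit_config())
  expect_equal(cv$n_folds, 5)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(nrow(cv$params_matrix), 5)
  expect_true(all(c("mean", "sd") %in% names(cv$summary)))
  expect_lte(cv$r_squared, 1)
  expect_error(loocv(small_ideal_dataset(n_songs = 2), tiny_fit_config()),
               ">= 3")
})

test_that("the per-set integrator comparison runs on matched folds", {
  params <- ref_params()
  songs <- c(build_stimulus_set(stimulus_set_config(
    paper_stimulus_pairs()$mollis$pair, "mollis", n_songs = 5, seed = 1)),
    build_stimulus_set(stimulus_set_config(
      paper_stimulus_pairs()$pause4$pair, "pause4", n_songs = 5, seed = 2)))
  ds <- ideal_response_dataset(songs, params)
  cfg <- tiny_fit_config()
  cmp1 <- compare_integrator_models(ds, cfg)
  cmp2 <- compare_integrator_models(ds, cfg)
  expect_identical(cmp1$folds, cmp2$folds)   # same folds + seed: same losses
  expect_equal(nrow(cmp1$folds), 10)
  expect_true(is.finite(cmp1$difference))
  # single-set data cannot be compared
  expect_error(compare_integrator_models(small_ideal_dataset(n_songs = 4),
                                         cfg), ">= 2 stimulus sets")
})

test_that("grossly different per-set noise favors the per-set integrator", {
  pairs <- paper_stimulus_pairs()
  songs_a <- build_stimulus_set(stimulus_set_config(pairs$mollis$pair,
                                                    "mollis", n_songs = 5,
                                                    seed = 1))
  songs_b <- build_stimulus_set(stimulus_set_config(pairs$pause4$pair,
                                                    "pause4", n_songs = 5,
                                                    seed = 2))
  pa <- ddm_params(c(block = 1, mollis = -87), sigma = 40,
                   theta_plus = 420, theta_minus = -803)
  pb <- ddm_params(c(block = 1, pause4ms = -53), sigma = 400,
                   theta_plus = 420, theta_minus = -803)
  ra <- vapply(songs_a, response_probability_exact, numeric(1), params = pa)
  rb <- vapply(songs_b, response_probability_exact, numeric(1), params = pb)
  ds <- response_dataset(c(songs_a, songs_b), c(ra, rb))
  cfg <- fit_config(population = 16, generations = 10, polish = TRUE,
                    polish_maxit = 40, n_bins = c(60L, 32L), seed = 42)
  cmp <- compare_integrator_models(ds, cfg)
  expect_lt(cmp$loss_per_set, cmp$loss_shared)
  expect_gt(cmp$difference, 0)
})

test_that("the lower threshold is constrained only up to a minimal magnitude", {
  truth <- ref_params()
  pr <- paper_stimulus_pairs()$mollis
  songs <- build_stimulus_set(stimulus_set_config(pr$pair, "mollis",
                                                  n_songs = 10, seed = 4))
  coh <- generate_cohort(synthetic_cohort_config(truth, songs,
                                                 n_females = 20, seed = 21))
  cfg <- fit_config(population = 16, generations = 12, polish = TRUE,
                    polish_maxit = 80, n_bins = c(60L, 32L), seed = 13)
  grid <- c(-2500, -1600, -1200, -803, -1)
  prof <- profile_theta_minus(coh$dataset, cfg, grid)
  # relative to the behavioral noise floor the profile is flat at and below
  # the generating value, but clearly worse when the threshold sits inside
  # the first subunit's reach (early spurious vetoes cannot be refit away)
  deep <- prof$loss[prof$theta_minus <= -803]
  shallow <- prof$loss[prof$theta_minus == -1]
  expect_lt(max(deep) - min(deep), 0.5 * min(deep))
  expect_gt(shallow, 1.5 * max(deep))
  # profile invariant to grid ordering
  prof2 <- profile_theta_minus(coh$dataset, cfg, rev(grid))
  expect_equal(prof, prof2)
  expect_error(profile_theta_minus(coh$dataset, cfg, c(-10, 10)), "negative")
})
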