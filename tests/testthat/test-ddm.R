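params <- ref_params()

test_that("noise-free integration fixes decisions at strict threshold crossings", {
  # ten heterospecific subunits fix a rejection against the lower threshold
  tr <- integrate_deterministic(pure_song("dorsatus"), params)
  expect_equal(tr$absorbed_at, 10)
  expect_equal(tr$crossed, "lower")
  expect_equal(tr$outcome, "reject")
  expect_true(all(tr$evidence[11:34] == params$theta_minus))
  # the standard block song never reaches a threshold; sign rule responds
  tb <- integrate_deterministic(pure_song("block"), params)
  expect_equal(tb$crossed, "none")
  expect_equal(tb$evidence[34], 33)
  expect_equal(tb$outcome, "respond")
  # 28 * 15 = 420 equals the threshold but does not strictly exceed it:
  # the 29th positive-onset subunit fixes the response
  to <- integrate_deterministic(pure_song("onset9dB"), params)
  expect_equal(to$absorbed_at, 29)
  expect_equal(to$crossed, "upper")
  expect_error(integrate_deterministic(song_model("x", "nosuch"), params),
               "no weight")
})

test_that("simulation reduces to deterministic integration without noise", {
  p0 <- ddm_params(params$weights, sigma = 0, theta_plus = params$theta_plus,
                   theta_minus = params$theta_minus)
  for (lab in c("dorsatus", "block", "onset9dB", "mollis")) {
    det <- integrate_deterministic(pure_song(lab), p0)
    tr <- simulate_trials(pure_song(lab), p0, n = 3, seed = 1)
    expect_true(all(tr$outcome == det$outcome))
    mc <- response_probability_mc(pure_song(lab), p0,
                                  dynamics_config(n_reps = 10, seed = 1))
    expect_equal(mc$p_hat, as.numeric(det$outcome == "respond"))
    expect_equal(mc$se, 0)
  }
})

test_that("Monte-Carlo runs are seed-reproducible and symmetric under zero drift", {
  sz <- song_model("z", rep("u", 10))
  pz <- ddm_params(c(u = 0), sigma = 5, theta_plus = 20, theta_minus = -20)
  mc1 <- response_probability_mc(sz, pz, dynamics_config(n_reps = 20000, seed = 8))
  mc2 <- response_probability_mc(sz, pz, dynamics_config(n_reps = 20000, seed = 8))
  expect_identical(mc1$p_hat, mc2$p_hat)
  expect_lt(abs(mc1$p_hat - 0.5), 3 * mc1$se)
})

test_that("density propagation matches closed forms and symmetry exactly", {
  # one step with unreachable thresholds: p = Phi(omega / sigma)
  for (case in list(c(w = 1, s = 2), c(w = -0.7, s = 0.5), c(w = 0.3, s = 1.5))) {
    pp <- ddm_params(c(a = case[["w"]]), sigma = case[["s"]],
                     theta_plus = abs(case[["w"]]) + 10 * case[["s"]],
                     theta_minus = -(abs(case[["w"]]) + 10 * case[["s"]]))
    p <- response_probability_exact(song_model("one", "a"), pp)
    expect_equal(p, pnorm(case[["w"]] / case[["s"]]), tolerance = 1e-6)
  }
  # zero drift between symmetric thresholds: p = 1/2
  pz <- ddm_params(c(u = 0), sigma = 10, theta_plus = 30, theta_minus = -30)
  expect_equal(response_probability_exact(song_model("z", rep("u", 12)), pz),
               0.5, tolerance = 1e-9)
  # sigma = 0 is the deterministic model's job
  p0 <- ddm_params(c(u = 1), sigma = 0, theta_plus = 5, theta_minus = -5)
  expect_error(response_probability_exact(song_model("z", "u"), p0),
               "integrate_deterministic")
})

test_that("a pure mollis song is rejected nearly always", {
  # density-propagation oracle: P(respond) = 0.0132 (noise occasionally
  # drives the evidence over the upper threshold in the first few steps)
  pe <- response_probability_exact(pure_song("mollis"), params)
  expect_equal(pe, 0.0132, tolerance = 1e-2)
  tr <- simulate_trials(pure_song("mollis"), params, n = 1e4, seed = 12)
  rej <- mean(tr$outcome == "reject")
  expect_gt(rej, 0.98)
  expect_lt(abs(rej - (1 - pe)), 3 * sqrt(pe * (1 - pe) / 1e4))
})

test_that("Monte-Carlo and density propagation agree on random instances", {
  set.seed(31)
  for (i in 1:8) {
    inst <- random_instance()
    pe <- response_probability_exact(inst$song, inst$params)
    mc <- response_probability_mc(inst$song, inst$params,
                                  dynamics_config(n_reps = 2e4, seed = 100 + i))
    se <- sqrt(max(pe * (1 - pe), 1e-6) / 2e4)
    expect_lt(abs(mc$p_hat - pe), 3 * se + 1e-4)
  }
})

test_that("halving the bin width leaves the probability stable", {
  song <- build_song(list(type = "uniform_random", p = 0.3),
                     c(positive = "block", negative = "mollis"), seed = 5)
  p20 <- response_probability_exact(song, params)
  p40 <- response_probability_exact(song, params,
                                    dynamics_config(grid_bins_per_sigma = 40))
  expect_lt(abs(p20 - p40), 1e-4)
})

test_that("first-passage masses and terminal masses conserve probability", {
  set.seed(19)
  for (i in 1:5) {
    inst <- random_instance()
    pr <- first_passage_profile(inst$song, inst$params)
    expect_equal(sum(pr$p_upper) + sum(pr$p_lower) +
                   pr$p_end_respond + pr$p_end_reject, 1, tolerance = 1e-9)
    expect_true(all(pr$p_upper >= 0) && all(pr$p_lower >= 0))
  }
  # deterministic limit: all mass at the lower crossing step
  p0 <- ddm_params(params$weights, sigma = 0, theta_plus = params$theta_plus,
                   theta_minus = params$theta_minus)
  prof <- first_passage_profile(pure_song("dorsatus"), p0)
  expect_equal(prof$p_lower[10], 1)
  expect_equal(sum(prof$p_upper) + sum(prof$p_lower[-10]) +
                 prof$p_end_respond + prof$p_end_reject, 0)
})

test_that("first-passage profiles agree between backends step by step", {
  song <- build_song("switch_at_11", c(positive = "onset9dB",
                                       negative = "onset3dB_pause4ms"))
  ex <- first_passage_profile(song, params)
  mc <- first_passage_profile(song, params,
                              dynamics_config(n_reps = 4e4, seed = 3),
                              backend = "mc")
  se <- sqrt(pmax(ex$p_upper * (1 - ex$p_upper), 1e-6) / 4e4)
  expect_true(all(abs(ex$p_upper - mc$p_upper) < 3 * se + 1e-3))
  se <- sqrt(pmax(ex$p_lower * (1 - ex$p_lower), 1e-6) / 4e4)
  expect_true(all(abs(ex$p_lower - mc$p_lower) < 3 * se + 1e-3))
})

test_that("the noise-free limit of the exact backend matches the deterministic outcome", {
  set.seed(47)
  for (i in 1:5) {
    inst <- random_instance()
    det <- integrate_deterministic(inst$song, inst$params)
    # shrink noise to 1e-3 of the smallest weight magnitude
    wmin <- min(abs(inst$params$weights[inst$params$weights != 0]))
    if (!is.finite(wmin)) next
    ps <- ddm_params(inst$params$weights, sigma = 1e-3 * wmin,
                     theta_plus = inst$params$theta_plus,
                     theta_minus = inst$params$theta_minus)
    p <- response_probability_exact(inst$song, ps,
                                    dynamics_config(n_bins = c(400L, 400L)))
    expect_equal(p, as.numeric(det$outcome == "respond"), tolerance = 0.01)
  }
})

test_that("raising a subunit weight never lowers the response probability", {
  set.seed(61)
  for (i in 1:6) {
    inst <- random_instance()
    p1 <- response_probability_exact(inst$song, inst$params)
    w2 <- inst$params$weights
    j <- sample(seq_along(w2), 1)
    w2[j] <- w2[j] + 0.8
    p2 <- response_probability_exact(
      inst$song, ddm_params(w2, inst$params$sigma, inst$params$theta_plus,
                            inst$params$theta_minus))
    expect_gte(p2, p1 - 1e-6)
  }
})

test_that("mean clamped trajectories stay bounded and match limits", {
  song <- build_song("switch_at_11_reversed",
                     c(positive = "block", negative = "mollis"))
  mt <- mean_trajectory(song, params)
  expect_true(all(mt >= params$theta_minus & mt <= params$theta_plus))
  # negative drift phase: mean evidence non-increasing over the first third
  expect_true(all(diff(mt[1:11]) <= 0))
  # sigma = 0 equals the clamped deterministic trajectory
  p0 <- ddm_params(params$weights, sigma = 0, theta_plus = params$theta_plus,
                   theta_minus = params$theta_minus)
  expect_equal(mean_trajectory(song, p0),
               integrate_deterministic(song, p0)$evidence[-1])
  # zero drift, symmetric thresholds: mean stays at 0 (exact backend)
  pz <- ddm_params(c(u = 0), sigma = 5, theta_plus = 25, theta_minus = -25)
  expect_equal(mean_trajectory(song_model("z", rep("u", 8)), pz),
               rep(0, 8), tolerance = 1e-9)
  # MC backend agrees with the exact one within its sampling error
  mtmc <- mean_trajectory(song, params, dynamics_config(n_reps = 2e4, seed = 5),
                          backend = "mc")
  expect_true(all(abs(mt - mtmc) < 5 * params$sigma * sqrt(33) / sqrt(2e4) + 1))
})
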