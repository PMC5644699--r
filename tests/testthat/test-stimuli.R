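catalog <- subunit_catalog()

test_that("subunit durations match the song-model timing table", {
  expected <- c(block = 84, block76ms = 90, dorsatus = 90, mollis = 240,
                gap = 84, offset8dB = 84, pause4ms = 76,
                onset3dB_pause4ms = 76, onset9dB = 84,
                accent_offset = 84, accent_onset = 84)
  got <- vapply(names(expected), function(n) subunit_duration(catalog[[n]]),
                numeric(1))
  expect_equal(got, expected)
  # single-segment identity
  expect_equal(subunit_duration(subunit_spec("x", 10, 64)), 10)
  # empty segment list is an invalid spec
  expect_error(subunit_spec("x", numeric(0), numeric(0)), "empty")
})

test_that("song durations sum subunit durations and match the design range", {
  expect_equal(song_duration(pure_song("mollis"), catalog), 7920)
  expect_equal(song_duration(pure_song("block"), catalog), 33 * 84)
  expect_equal(song_duration(song_model("e", character(0)), catalog), 0)
  expect_error(song_duration(song_model("b", "nosuch"), catalog), "unknown")
  # all pure non-mollis 33-subunit songs lie in the 2.5 - ~3 s design window
  others <- setdiff(names(catalog), "mollis")
  durs <- vapply(others, function(n) song_duration(pure_song(n), catalog),
                 numeric(1))
  expect_true(all(durs >= 2508 & durs <= 2970))
})

test_that("duration additivity holds for random label sequences", {
  set.seed(7)
  for (i in 1:20) {
    labs <- sample(names(catalog), sample(1:40, 1), replace = TRUE)
    song <- song_model("r", labs)
    expect_equal(song_duration(song, catalog),
                 sum(vapply(labs, function(l) subunit_duration(catalog[[l]]),
                            numeric(1))))
  }
})

test_that("build_song realizes the placement descriptors exactly", {
  pair <- c(positive = "block", negative = "mollis")
  expect_equal(build_song("pure_positive", pair)$labels, rep("block", 33))
  sw <- build_song("switch_at_11", pair)
  expect_equal(sw$labels, c(rep("block", 11), rep("mollis", 22)))
  swr <- build_song("switch_at_11_reversed", pair)
  expect_equal(swr$labels, c(rep("mollis", 11), rep("block", 22)))
  expect_equal(build_song(list(type = "uniform_random", p = 1), pair,
                          seed = 1)$labels, rep("mollis", 33))
  # proportion patterns place exactly round(p*L) negative subunits
  for (p in c(0.1, 0.3, 0.5, 0.8)) {
    s <- build_song(list(type = "uniform_random", p = p), pair, seed = 5)
    expect_equal(sum(s$labels == "mollis"), round(p * 33))
  }
  # deterministic given (pattern, seed)
  a <- build_song(list(type = "uniform_random", p = 0.4), pair, seed = 9)
  b <- build_song(list(type = "uniform_random", p = 0.4), pair, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_error(build_song(list(type = "wiggle"), pair), "malformed")
  expect_error(build_song(list(type = "uniform_random", p = 2), pair),
               "malformed")
})

test_that("build_stimulus_set returns the full reproducible song list", {
  pr <- paper_stimulus_pairs()$mollis
  cfg <- stimulus_set_config(pr$pair, pr$set_id, seed = 4)
  songs <- build_stimulus_set(cfg)
  expect_length(songs, 35)
  seqs <- lapply(songs, `[[`, "labels")
  expect_true(any(vapply(seqs, function(x) all(x == "block"), logical(1))))
  expect_true(any(vapply(seqs, function(x) all(x == "mollis"), logical(1))))
  # same config twice: identical song lists
  expect_identical(lapply(build_stimulus_set(cfg), `[[`, "labels"), seqs)
  # two-song config with only pure patterns
  cfg2 <- stimulus_set_config(pr$pair, "m2", n_songs = 2)
  expect_equal(unname(vapply(build_stimulus_set(cfg2), function(s)
    s$labels[1], character(1))), c("block", "mollis"))
  # duplicate ids rejected
  cfg3 <- stimulus_set_config(pr$pair, "m3", n_songs = 2,
                              patterns = list(list(type = "pure_positive", tag = "a"),
                                              list(type = "pure_negative", tag = "a")))
  expect_error(build_stimulus_set(cfg3), "duplicate")
})

test_that("rendered envelopes follow the subunit level annotations", {
  song <- song_model("b1", "block")
  env <- render_envelope(song, catalog, dt_ms = 1)
  expect_equal(nrow(env), 84)
  expect_equal(env$level_db[1:72], rep(64, 72))
  expect_true(all(is.na(env$level_db[73:84])))
  # 9-dB onset accent: first 10 ms at 73 dB
  env9 <- render_envelope(song_model("o", "onset9dB"), catalog, dt_ms = 1)
  expect_equal(env9$level_db[1:10], rep(73, 10))
  expect_equal(env9$level_db[11], 64)
  empty <- render_envelope(song_model("e", character(0)), catalog)
  expect_equal(nrow(empty), 0)
  # envelope span equals song duration for a mixed song
  mix <- song_model("m", c("dorsatus", "block76ms"))
  expect_equal(nrow(render_envelope(mix, catalog, dt_ms = 1)),
               song_duration(mix, catalog))
})
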