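# shared fixtures: built in code, no files

ref_params <- function() reference_ddm_params()

pure_song <- function(label, L = 33, set_id = label) {
  song_model(paste0("pure_", label), rep(label, L), set_id)
}

# a small single-pair stimulus set with ideal (noise-free) response rates
small_ideal_dataset <- function(set = "mollis", n_songs = 12, seed = 3L,
                                params = ref_params()) {
  pr <- paper_stimulus_pairs()[[set]]
  cfg <- stimulus_set_config(pr$pair, pr$set_id, n_songs = n_songs, seed = seed)
  songs <- build_stimulus_set(cfg)
  ideal_response_dataset(songs, params)
}

# fast fitting settings for unit tests (not the study-scale defaults)
tiny_fit_config <- function(...) {
  fit_config(population = 16, generations = 10, polish = TRUE,
             polish_maxit = 60, n_bins = c(60L, 32L), seed = 42L, ...)
}

# random weights/params generator for property-style tests
random_instance <- function(L = 12, n_labels = 2) {
  labs <- paste0("u", seq_len(n_labels))
  w <- setNames(round(runif(n_labels, -3, 3), 2), labs)
  params <- ddm_params(w, sigma = runif(1, 0.5, 3),
                       theta_plus = runif(1, 3, 12),
                       theta_minus = -runif(1, 3, 12))
  song <- song_model("rand", sample(labs, L, replace = TRUE), "rand")
  list(song = song, params = params)
}
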