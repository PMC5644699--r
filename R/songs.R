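#' A song model: an ordered sequence of subunit labels
#'
#' @param id song identifier (unique within a stimulus set).
#' @param labels character vector of subunit labels; the experiments use 33
#'   subunits per song, tests may use other lengths.
#' @param set_id identifier of the stimulus pair the song belongs to.
#' @return Object of class `song_model`.
#' @export
song_model <- function(id, labels, set_id = "set1") {
  if (!is.character(labels)) stop("'labels' must be a character vector")
  structure(list(id = id, labels = labels, set_id = set_id),
            class = "song_model")
}

#' @export
print.song_model <- function(x, ...) {
  cat(sprintf("<song_model> %s (set %s), %d subunits\n", x$id, x$set_id,
              length(x$labels)))
  cat(" ", paste(rle(x$labels)$lengths, rle(x$labels)$values,
                 sep = "x", collapse = " | "), "\n")
  invisible(x)
}

#' Total duration of a song model
#'
#' @param song a [song_model()].
#' @param catalog named list of [subunit_spec()].
#' @return Duration in ms: the sum of subunit durations over the sequence.
#' @export
song_duration <- function(song, catalog) {
  if (length(song$labels) == 0L) return(0)
  durs <- vapply(song$labels, function(lab) {
    spec <- catalog[[lab]]
    if (is.null(spec)) stop(sprintf("unknown subunit label '%s'", lab))
    subunit_duration(spec)
  }, numeric(1))
  sum(durs)
}

# normalize a pattern descriptor into list(type, ...)
normalize_pattern <- function(pattern) {
  if (is.character(pattern)) pattern <- list(type = pattern)
  if (!is.list(pattern) || is.null(pattern$type))
    stop("malformed pattern descriptor: need a type")
  known <- c("pure_positive", "pure_negative", "uniform_random",
             "negative_block", "switch_at_11", "switch_at_11_reversed")
  if (!pattern$type %in% known)
    stop(sprintf("malformed pattern descriptor: unknown type '%s'", pattern$type))
  pattern
}

#' Build one song from a placement descriptor
#'
#' Patterns cover the families used in the playback series: the two pure
#' songs, uniform-random placement of a given proportion of negative
#' subunits, a contiguous negative block in the first/middle/last part of
#' the song, and the valence-switch songs in which the subunit type changes
#' after one third (11 subunits of a 33-subunit song).
#'
#' @param pattern a descriptor: either a type string
#'   (`"pure_positive"`, `"pure_negative"`, `"switch_at_11"`,
#'   `"switch_at_11_reversed"`) or a list such as
#'   `list(type = "uniform_random", p = 0.4)` or
#'   `list(type = "negative_block", n_neg = 11, position = "middle")`.
#'   `switch_at_11` places `L/3` positive then `2L/3` negative subunits;
#'   the reversed variant starts with the negative third.
#' @param pair named character vector `c(positive = ..., negative = ...)`
#'   giving the two subunit labels of the stimulus pair.
#' @param L song length in subunits (default 33).
#' @param seed integer seed controlling random placement; the result is
#'   deterministic given `(pattern, seed)`.
#' @param id,set_id identifiers for the resulting [song_model()].
#' @return A [song_model()] whose negative-subunit count equals
#'   `round(p * L)` for proportion patterns.
#' @export
build_song <- function(pattern, pair, L = 33, seed = NULL,
                       id = NULL, set_id = "set1") {
  pattern <- normalize_pattern(pattern)
  if (L < 1) stop("'L' must be >= 1")
  if (!all(c("positive", "negative") %in% names(pair)))
    stop("'pair' must have elements named 'positive' and 'negative'")
  pos <- pair[["positive"]]; neg <- pair[["negative"]]
  labels <- switch(
    pattern$type,
    pure_positive = rep(pos, L),
    pure_negative = rep(neg, L),
    uniform_random = {
      p <- pattern$p
      if (is.null(p) || p < 0 || p > 1)
        stop("malformed pattern descriptor: uniform_random needs p in [0,1]")
      n_neg <- round(p * L)
      sel <- with_seed(seed, sample.int(L, n_neg))
      out <- rep(pos, L); out[sel] <- neg; out
    },
    negative_block = {
      n_neg <- pattern$n_neg
      if (is.null(n_neg) || n_neg < 0 || n_neg > L)
        stop("malformed pattern descriptor: negative_block needs n_neg in [0,L]")
      position <- if (is.null(pattern$position)) "first" else pattern$position
      start <- switch(position,
                      first = 1L,
                      middle = as.integer(floor((L - n_neg) / 2)) + 1L,
                      last = L - as.integer(n_neg) + 1L,
                      stop("malformed pattern descriptor: position must be first/middle/last"))
      out <- rep(pos, L)
      if (n_neg > 0) out[seq(start, length.out = n_neg)] <- neg
      out
    },
    switch_at_11 = {
      k <- max(1L, round(L / 3))
      c(rep(pos, k), rep(neg, L - k))
    },
    switch_at_11_reversed = {
      k <- max(1L, round(L / 3))
      c(rep(neg, k), rep(pos, L - k))
    }
  )
  if (is.null(id)) id <- pattern$type
  song_model(id, labels, set_id)
}

#' Default sequence-pattern list for a 35-song stimulus set
#'
#' A parametric stand-in for the published mixture series: both pure songs,
#' two uniform-random replicates of negative proportions 1/11 ... 10/11,
#' extreme proportions near 0 and 1, contiguous negative blocks of one and
#' two thirds, and both valence-switch songs.
#'
#' @param L song length in subunits.
#' @return List of 35 pattern descriptors with name tags.
#' @export
default_sequence_patterns <- function(L = 33) {
  pats <- list()
  add <- function(tag, p) { p$tag <- tag; pats[[length(pats) + 1L]] <<- p }
  add("purepos", list(type = "pure_positive"))
  add("pureneg", list(type = "pure_negative"))
  for (rep_i in 1:2)
    for (k in 1:10)
      add(sprintf("u%02d_r%d", k, rep_i),
          list(type = "uniform_random", p = k / 11))
  add("blk11mid", list(type = "negative_block", n_neg = round(L / 3), position = "middle"))
  add("blk11last", list(type = "negative_block", n_neg = round(L / 3), position = "last"))
  add("blk22first", list(type = "negative_block", n_neg = round(2 * L / 3), position = "first"))
  add("blk22mid", list(type = "negative_block", n_neg = round(2 * L / 3), position = "middle"))
  add("swPN", list(type = "switch_at_11"))
  add("swNP", list(type = "switch_at_11_reversed"))
  extreme <- c(1, 2, 4, 16.5, 29, 31, 32) / 33
  for (i in seq_along(extreme))
    add(sprintf("ux%02d", i), list(type = "uniform_random", p = extreme[i]))
  pats
}

#' Configuration of one stimulus set
#'
#' @param pair named character vector `c(positive=, negative=)` of subunit
#'   labels.
#' @param set_id identifier for the set.
#' @param n_songs number of songs (default 35, the playback-cycle size).
#' @param patterns list of placement descriptors (default
#'   [default_sequence_patterns()], truncated/recycled is an error: length
#'   must equal `n_songs`).
#' @param L song length in subunits.
#' @param seed integer seed for random placements.
#' @return Object of class `stimulus_set_config`.
#' @export
stimulus_set_config <- function(pair, set_id, n_songs = 35,
                                patterns = NULL, L = 33, seed = 1L) {
  if (n_songs < 2) stop("'n_songs' must be >= 2")
  if (is.null(patterns)) {
    patterns <- default_sequence_patterns(L)
    if (n_songs < length(patterns)) patterns <- patterns[seq_len(n_songs)]
  }
  if (length(patterns) != n_songs)
    stop("length(patterns) must equal n_songs")
  structure(list(pair = pair, set_id = set_id, n_songs = n_songs,
                 patterns = patterns, L = L, seed = seed),
            class = "stimulus_set_config")
}

#' Build all songs of a stimulus set
#'
#' @param cfg a [stimulus_set_config()].
#' @return List of [song_model()]s, reproducible from `cfg$seed`; song ids
#'   are `<set_id>_<index>_<tag>` and must be unique.
#' @export
build_stimulus_set <- function(cfg) {
  if (!inherits(cfg, "stimulus_set_config")) stop("'cfg' must be a stimulus_set_config")
  songs <- vector("list", cfg$n_songs)
  for (i in seq_len(cfg$n_songs)) {
    pat <- normalize_pattern(cfg$patterns[[i]])
    tag <- if (!is.null(pat$tag)) pat$tag else pat$type
    songs[[i]] <- build_song(pat, cfg$pair, L = cfg$L,
                             seed = derive_seed(cfg$seed, i),
                             id = sprintf("%s_%s", cfg$set_id, tag),
                             set_id = cfg$set_id)
  }
  ids <- vapply(songs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate song ids in stimulus set")
  names(songs) <- ids
  songs
}

#' The subunit pairs of the behavioral test series
#'
#' Seven stimulus pairs cover the ten tested subunit types (the gap set is
#' carried over from the predecessor mixture study): each heterospecific or
#' degraded subunit is paired with the standard block (the dorsatus-like
#' subunit with the duration-matched 76 + 14 ms block), and the two accent
#' sets pair an unattractive with an attractive accent variant.
#'
#' @return Named list; each element has `set_id` and a `pair` vector.
#' @export
paper_stimulus_pairs <- function() {
  list(
    dorsatus = list(set_id = "dorsatus",
                    pair = c(positive = "block76ms", negative = "dorsatus")),
    mollis = list(set_id = "mollis",
                  pair = c(positive = "block", negative = "mollis")),
    gap = list(set_id = "gap",
               pair = c(positive = "block", negative = "gap")),
    offset8 = list(set_id = "offset8",
                   pair = c(positive = "block", negative = "offset8dB")),
    pause4 = list(set_id = "pause4",
                  pair = c(positive = "block", negative = "pause4ms")),
    onset = list(set_id = "onset",
                 pair = c(positive = "onset9dB", negative = "onset3dB_pause4ms")),
    accent = list(set_id = "accent",
                  pair = c(positive = "accent_onset", negative = "accent_offset"))
  )
}

#' Build the full multi-set stimulus collection
#'
#' @param n_songs songs per set.
#' @param L song length in subunits.
#' @param seed integer seed.
#' @param sets subset of set names from [paper_stimulus_pairs()]; default all.
#' @return Named flat list of [song_model()]s across all sets.
#' @export
build_paper_stimulus_sets <- function(n_songs = 35, L = 33, seed = 1L,
                                      sets = names(paper_stimulus_pairs())) {
  pairs <- paper_stimulus_pairs()[sets]
  out <- list()
  for (i in seq_along(pairs)) {
    cfg <- stimulus_set_config(pairs[[i]]$pair, pairs[[i]]$set_id,
                               n_songs = n_songs, L = L,
                               seed = derive_seed(seed, 1000 + i))
    out <- c(out, build_stimulus_set(cfg))
  }
  out
}
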