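#' Describe one song subunit
#'
#' A subunit is the repeating syllable + pause building block of a grasshopper
#' song model.  It is described purely by its amplitude envelope: an ordered
#' list of segments, each a duration in milliseconds at a sound level in
#' dB SPL, with `NA` marking silence (silence is a distinguished state, not a
#' level of \eqn{-\infty}).
#'
#' @param name subunit label (character scalar).
#' @param durations_ms segment durations in ms, all `> 0`.
#' @param levels_db segment sound levels in dB SPL; `NA` = silent.  Same
#'   length as `durations_ms`.
#' @param role `"positive"` or `"negative"`: the valence of the subunit
#'   within the stimulus pair it is tested in.
#' @return An object of class `subunit_spec`.
#' @examples
#' mollis <- subunit_spec("mollis", c(120, 120), c(64, NA), "negative")
#' subunit_duration(mollis)  # 240
#' @export
subunit_spec <- function(name, durations_ms, levels_db, role = c("positive", "negative")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty character scalar")
  if (length(durations_ms) == 0L)
    stop("invalid subunit spec: segment list is empty")
  if (length(durations_ms) != length(levels_db))
    stop("'durations_ms' and 'levels_db' must have the same length")
  if (!is.numeric(durations_ms) || any(!is.finite(durations_ms)) || any(durations_ms <= 0))
    stop("all segment durations must be finite and > 0")
  structure(
    list(name = name,
         segments = data.frame(duration_ms = as.numeric(durations_ms),
                               level_db = as.numeric(levels_db)),
         role = role),
    class = "subunit_spec")
}

#' @export
print.subunit_spec <- function(x, ...) {
  cat(sprintf("<subunit_spec> %s (%s), %g ms\n", x$name, x$role,
              subunit_duration(x)))
  seg <- x$segments
  lev <- ifelse(is.na(seg$level_db), "silent", sprintf("%g dB", seg$level_db))
  cat(paste(sprintf("  %g ms @ %s", seg$duration_ms, lev), collapse = "\n"), "\n")
  invisible(x)
}

#' Total duration of a subunit
#'
#' @param spec a [subunit_spec()].
#' @return Duration in milliseconds (sum of segment durations).
#' @export
subunit_duration <- function(spec) {
  if (!inherits(spec, "subunit_spec")) stop("'spec' must be a subunit_spec")
  if (nrow(spec$segments) == 0L) stop("invalid subunit spec: no segments")
  sum(spec$segments$duration_ms)
}

#' Catalog of the tested subunit types
#'
#' Returns the full set of subunit envelopes used in the playback
#' experiments.  The standard `block` subunit is a 72-ms noise syllable at
#' 64 dB SPL followed by a 12-ms silent pause; `block76ms` is the duration-
#' matched variant (76 + 14 ms) paired with the dorsatus-like subunit.  The
#' heterospecific subunits mimic *C. dorsatus* (four 8-ms pulses separated by
#' three 6-ms gaps, then a 40-ms pause) and *C. mollis* (120-ms syllable +
#' 120-ms pause).  The conspecific-range subunits degrade or accentuate the
#' block pattern: a shallow (8-dB-offset) pause, a very short 4-ms pause, a
#' 3-dB onset accent combined with a 4-ms pause, a 9-dB onset accent, and a
#' 70-dB syllable carrying a 10-ms 82-dB accent at its start or end.  The
#' gap subunit keeps the 72-ms syllable window but carves silent gaps into
#' the plateau (an emulation of the earlier gap stimuli; count and width are
#' configurable).
#'
#' @param gap_count number of silent gaps carved into the gap subunit's
#'   syllable plateau.
#' @param gap_width_ms width of each gap in ms.
#' @return Named list of [subunit_spec()] objects.
#' @export
subunit_catalog <- function(gap_count = 2, gap_width_ms = 2) {
  plateau <- 64
  # split the sounded part of the 72-ms window into gap_count + 1 chunks
  sound_total <- 72 - gap_count * gap_width_ms
  if (sound_total <= gap_count) stop("gaps leave no room for sound in the syllable")
  chunk <- diff(round(seq(0, sound_total, length.out = gap_count + 2)))
  gap_dur <- numeric(0); gap_lev <- numeric(0)
  for (i in seq_len(gap_count + 1)) {
    gap_dur <- c(gap_dur, chunk[i]); gap_lev <- c(gap_lev, plateau)
    if (i <= gap_count) { gap_dur <- c(gap_dur, gap_width_ms); gap_lev <- c(gap_lev, NA) }
  }
  list(
    block = subunit_spec("block", c(72, 12), c(plateau, NA), "positive"),
    block76ms = subunit_spec("block76ms", c(76, 14), c(plateau, NA), "positive"),
    dorsatus = subunit_spec("dorsatus",
                            c(8, 6, 8, 6, 8, 6, 8, 40),
                            c(plateau, NA, plateau, NA, plateau, NA, plateau, NA),
                            "negative"),
    mollis = subunit_spec("mollis", c(120, 120), c(plateau, NA), "negative"),
    gap = subunit_spec("gap", c(gap_dur, 12), c(gap_lev, NA), "negative"),
    offset8dB = subunit_spec("offset8dB", c(72, 12), c(plateau, plateau - 8),
                             "negative"),
    pause4ms = subunit_spec("pause4ms", c(72, 4), c(plateau, NA), "negative"),
    onset3dB_pause4ms = subunit_spec("onset3dB_pause4ms",
                                     c(4, 10, 62), c(NA, plateau + 3, plateau),
                                     "negative"),
    onset9dB = subunit_spec("onset9dB", c(10, 62, 12),
                            c(plateau + 9, plateau, NA), "positive"),
    accent_offset = subunit_spec("accent_offset", c(62, 10, 12),
                                 c(70, 82, 58), "negative"),
    accent_onset = subunit_spec("accent_onset", c(10, 62, 12),
                                c(82, 70, 58), "positive")
  )
}

#' Piecewise-constant amplitude envelope of a song
#'
#' Samples the song's amplitude envelope on a regular time grid — a QC /
#' plotting aid, not audio synthesis.
#'
#' @param song a [song_model()].
#' @param catalog named list of [subunit_spec()] (see [subunit_catalog()]).
#' @param dt_ms sampling interval in ms (`> 0`).
#' @return `data.frame` with columns `t_ms` (sample start time) and
#'   `level_db` (`NA` = silent); empty for an empty song.
#' @export
render_envelope <- function(song, catalog, dt_ms = 1) {
  if (dt_ms <= 0) stop("'dt_ms' must be > 0")
  segs_dur <- numeric(0); segs_lev <- numeric(0)
  for (lab in song$labels) {
    spec <- catalog[[lab]]
    if (is.null(spec)) stop(sprintf("unknown subunit label '%s'", lab))
    segs_dur <- c(segs_dur, spec$segments$duration_ms)
    segs_lev <- c(segs_lev, spec$segments$level_db)
  }
  total <- sum(segs_dur)
  if (length(segs_dur) == 0L || total == 0)
    return(data.frame(t_ms = numeric(0), level_db = numeric(0)))
  t <- seq(0, total - dt_ms / 2, by = dt_ms)
  ends <- cumsum(segs_dur)
  idx <- findInterval(t, c(0, ends), rightmost.closed = FALSE, left.open = FALSE)
  data.frame(t_ms = t, level_db = segs_lev[pmin(idx, length(segs_lev))])
}
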