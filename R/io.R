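# Plain-text interchange: songs and response datasets as TSV, model
# parameters as JSON.  Song sequences are stored as P/N strings together
# with the pair's label mapping, so files round-trip without the catalog.

#' Write songs as a delimited table
#'
#' Columns: `song_id`, `set_id`, `positive_label`, `negative_label`,
#' `sequence` (a string of `P`/`N` characters, one per subunit).
#'
#' @param songs list of [song_model()]s.
#' @param path output TSV path.
#' @export
write_song_table <- function(songs, path) {
  set_ids <- vapply(songs, `[[`, character(1), "set_id")
  # the label pair is a property of the stimulus set: infer it from the
  # union of labels used across each set's songs
  pairs <- lapply(split(lapply(songs, `[[`, "labels"), set_ids),
                  function(ls) infer_pair(unique(unlist(ls))))
  rows <- lapply(songs, function(s) {
    pr <- pairs[[s$set_id]]
    seqstr <- paste(ifelse(s$labels == pr[["positive"]], "P", "N"),
                    collapse = "")
    data.frame(song_id = s$id, set_id = s$set_id,
               positive_label = pr[["positive"]],
               negative_label = pr[["negative"]],
               sequence = seqstr)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# infer which of (at most) two labels is the positive one, using the
# catalog's role annotation; falls back to first-seen order
infer_pair <- function(u) {
  if (length(u) > 2) stop("a stimulus set uses more than two subunit labels")
  cat_all <- subunit_catalog()
  roles <- vapply(u, function(l) {
    if (!is.null(cat_all[[l]])) cat_all[[l]]$role else NA_character_
  }, character(1))
  pos <- u[which(roles == "positive")]
  neg <- u[which(roles == "negative")]
  if (length(pos) == 1 && length(neg) == 1) return(c(positive = pos, negative = neg))
  if (length(u) == 1) {
    if (identical(unname(roles[1]), "negative"))
      return(c(positive = "", negative = u))
    return(c(positive = u, negative = ""))
  }
  c(positive = u[1], negative = u[2])
}

#' Read songs from a delimited table
#'
#' @param path TSV written by [write_song_table()].
#' @return Named list of [song_model()]s.
#' @export
read_song_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = character(0))
  songs <- lapply(seq_len(nrow(df)), function(i) {
    chars <- strsplit(df$sequence[i], "")[[1]]
    labels <- ifelse(chars == "P", df$positive_label[i], df$negative_label[i])
    song_model(df$song_id[i], labels, df$set_id[i])
  })
  names(songs) <- df$song_id
  songs
}

#' Write / read a response dataset
#'
#' Two TSV files: `<stem>_songs.tsv` (see [write_song_table()]) and
#' `<stem>_responses.tsv` (`song_id`, `set_id`, `response_rate`,
#' `n_females`, `n_cycles`).
#'
#' @param ds a [response_dataset()].
#' @param stem path stem (without suffix).
#' @return `stem`, invisibly.
#' @export
write_response_dataset <- function(ds, stem) {
  write_song_table(ds$songs, paste0(stem, "_songs.tsv"))
  write.table(ds$data, paste0(stem, "_responses.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_response_dataset
#' @export
read_response_dataset <- function(stem) {
  songs <- read_song_table(paste0(stem, "_songs.tsv"))
  df <- read.table(paste0(stem, "_responses.tsv"), sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  songs <- songs[df$song_id]
  response_dataset(songs, df$response_rate, df$n_females, df$n_cycles)
}

#' Read stimulus-set configurations from YAML
#'
#' The file holds a list of sets; each set has `set_id`, `pair`
#' (`positive:`/`negative:` subunit labels), and optionally `n_songs`, `L`,
#' `seed`.  Patterns are the default 35-song family; custom pattern lists
#' are constructed in code with [stimulus_set_config()].
#'
#' ```yaml
#' sets:
#'   - set_id: mollis
#'     pair: {positive: block, negative: mollis}
#'     n_songs: 35
#'     seed: 1
#' ```
#'
#' @param path YAML file path.
#' @return List of [stimulus_set_config()] objects.
#' @export
read_stimulus_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$sets)) stop("config error at sets: section missing")
  lapply(obj$sets, function(s) {
    if (is.null(s$set_id) || is.null(s$pair))
      stop("config error at sets: each set needs set_id and pair")
    stimulus_set_config(
      pair = c(positive = s$pair$positive, negative = s$pair$negative),
      set_id = s$set_id,
      n_songs = if (is.null(s$n_songs)) 35 else s$n_songs,
      L = if (is.null(s$L)) 33 else s$L,
      seed = if (is.null(s$seed)) 1L else as.integer(s$seed))
  })
}

#' Write / read model parameters as JSON
#'
#' @param params a [ddm_params()].
#' @param path JSON path.
#' @param extra optional named list of metadata (seed, backend, ...) stored
#'   alongside the parameters.
#' @export
write_ddm_params <- function(params, path, extra = NULL) {
  obj <- c(list(weights = as.list(params$weights), sigma = params$sigma,
                theta_plus = params$theta_plus,
                theta_minus = params$theta_minus), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ddm_params
#' @export
read_ddm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ddm_params(unlist(obj$weights), obj$sigma, obj$theta_plus, obj$theta_minus)
}
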