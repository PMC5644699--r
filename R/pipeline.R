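#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: build stimulus sets, generate a
#' synthetic cohort from a ground-truth model, fit (optionally
#' cross-validate) the decision model, and derive metrics and
#' decision-dynamics profiles for the two valence-switch songs.  Every
#' output file is listed, with an MD5 hash, in `manifest.json`; all
#' stochastic stages derive their seeds from the global seed, so a rerun
#' with the same configuration reproduces the outputs bit-exactly.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one.  Recognised sections (all optional unless noted):
#'   \describe{
#'     \item{`seed`}{global integer seed (default 1).}
#'     \item{`stimuli`}{`sets` (names from [paper_stimulus_pairs()]),
#'       `n_songs`, `L`.}
#'     \item{`truth`}{`weights` (named list), `sigma`, `theta_plus`,
#'       `theta_minus`; default [reference_ddm_params()].}
#'     \item{`cohort`}{`n_females`, `n_cycles`, `control_response_prob`,
#'       `exclusion_threshold`, `female_sd`.}
#'     \item{`fit`}{any [fit_config()] argument (e.g. a reduced
#'       `population`/`generations`), plus `do_loocv` (logical).}
#'     \item{`dynamics`}{`n_reps` for the Monte-Carlo backend check.}
#'   }
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  need <- function(section, key, default) {
    v <- config[[section]][[key]]
    if (is.null(v)) default else v
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) { files <<- c(files, name); file.path(out_dir, name) }

  # stage 1: stimuli
  sets <- need("stimuli", "sets", names(paper_stimulus_pairs()))
  bad <- setdiff(sets, names(paper_stimulus_pairs()))
  if (length(bad))
    stop(sprintf("config error at stimuli$sets: unknown set(s) %s",
                 paste(bad, collapse = ", ")))
  songs <- build_paper_stimulus_sets(
    n_songs = need("stimuli", "n_songs", 35),
    L = need("stimuli", "L", 33),
    seed = derive_seed(seed, 1), sets = sets)
  write_song_table(songs, emit("songs.tsv"))

  # stage 2: truth + synthetic cohort
  truth <- if (is.null(config$truth)) reference_ddm_params() else
    ddm_params(unlist(config$truth$weights), config$truth$sigma,
               config$truth$theta_plus, config$truth$theta_minus)
  write_ddm_params(truth, emit("params_truth.json"),
                   extra = list(role = "ground_truth", seed = seed))
  cohort_cfg <- synthetic_cohort_config(
    truth, songs,
    n_females = need("cohort", "n_females", 20),
    n_cycles = need("cohort", "n_cycles", 18),
    control_response_prob = need("cohort", "control_response_prob", 0.02),
    exclusion_threshold = need("cohort", "exclusion_threshold", 2),
    female_sd = need("cohort", "female_sd", 0),
    seed = derive_seed(seed, 2))
  cohort <- generate_cohort(cohort_cfg)
  write_response_dataset(cohort$dataset, file.path(out_dir, "cohort"))
  files <- c(files, "cohort_songs.tsv", "cohort_responses.tsv")

  # stage 3: fit / cross-validate
  fit_args <- config$fit
  fit_args$do_loocv <- NULL
  fit_args <- fit_args[names(fit_args) %in% names(formals(fit_config))]
  fcfg <- do.call(fit_config, c(fit_args, list(seed = derive_seed(seed, 3))))
  fit <- fit_ddm(cohort$dataset, fcfg)
  write_ddm_params(fit$params, emit("params_fit.json"),
                   extra = list(loss = fit$loss, seed = fcfg$seed,
                                backend = "exact",
                                objective = fcfg$objective))
  write.table(data.frame(generation = seq_along(fit$trace), loss = fit$trace),
              emit("fit_trace.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- recovery_report(fit, truth)
  write.table(rec, emit("recovery.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cv <- NULL
  if (isTRUE(need("fit", "do_loocv", FALSE))) {
    cv <- loocv(cohort$dataset, fcfg)
    write.table(cv$folds, emit("loocv_folds.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(r_squared = cv$r_squared,
                              summary = cv$summary),
                         emit("loocv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # stage 4: metrics + switch-song dynamics
  used_sets <- paper_stimulus_pairs()[sets]
  write.table(set_metrics(fit$params, used_sets), emit("metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  L <- need("stimuli", "L", 33)
  if (L %% 3 == 0) {
    dyn <- lapply(used_sets, function(s) {
      lapply(c(pos_first = "switch_at_11", neg_first = "switch_at_11_reversed"),
             function(type) {
               song <- build_song(type, s$pair, L = L, set_id = s$set_id)
               prof <- first_passage_profile(song, fit$params)
               td <- thirds_decomposition(prof)
               list(upper = td$upper, lower = td$lower,
                    end_respond = td$end_respond, end_reject = td$end_reject)
             })
    })
    jsonlite::write_json(dyn, emit("switch_dynamics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(packageVersion("songddm")),
    seed = seed,
    stage_seeds = list(stimuli = derive_seed(seed, 1),
                       cohort = derive_seed(seed, 2),
                       fit = derive_seed(seed, 3)),
    config = config,
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
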