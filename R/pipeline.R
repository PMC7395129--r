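## ---------------------------------------------------------------------------
## Orchestration: simulate -> extract (fNIRS cardiac, EEG blinks) ->
## features -> predict -> report, with one global seed fanned out into
## per-stage streams, cached stage outputs and a run manifest.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param sim a [simulation_config()]; its `seed` is overridden by the
#'   pipeline seed.
#' @param seed global integer seed, fanned out deterministically to the
#'   stages via [derive_seed()].
#' @param use_eeg run the full EEG blink chain per subject (otherwise
#'   blink features come from the generator's ground-truth blink times).
#' @param net a [cf_net_spec()] for the prediction stage.
#' @param repeats cross-validation repeats in the prediction stage.
#' @param write_signals also write per-subject signal files (delimited
#'   text + JSON sidecar) under the output directory.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), seed = 1L,
                            use_eeg = FALSE, net = cf_net_spec(),
                            repeats = 100, write_signals = FALSE) {
  structure(list(sim = sim, seed = as.integer(seed), use_eeg = use_eeg,
                 net = net, repeats = repeats, write_signals = write_signals),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulation, per-subject signal extraction, feature
#' summarisation, target prediction and report rendering, writing stage
#' outputs and a manifest (seeds, file hashes, wall time per stage) under
#' `out_dir`. With `resume = TRUE`, stages whose outputs already exist
#' are loaded from cache instead of recomputed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param resume reuse cached stage outputs when present.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  stage_files <- list(features = file.path(out_dir, "features.csv"),
                      targets = file.path(out_dir, "targets.csv"))
  t_all <- Sys.time()
  tic <- function() Sys.time()
  rec_stage <- function(name, t0, status = "ok", files = character(0)) {
    manifest$stages[[name]] <<- list(
      status = status,
      seconds = as.numeric(Sys.time() - t0, units = "secs"),
      files = as.list(tools::md5sum(files[file.exists(files)]))
    )
  }

  cached <- resume && all(file.exists(unlist(stage_files)))
  if (cached) {
    features <- read.csv(stage_files$features)
    targets <- read.csv(stage_files$targets)
    rec_stage("simulate", tic(), "cached")
    rec_stage("extract_fnirs", tic(), "cached")
    rec_stage("extract_eeg", tic(), "cached")
    rec_stage("features", tic(), "cached", unlist(stage_files))
  } else {
    t0 <- tic()
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, "simulate")
    feat_list <- list(); targ_list <- list()
    # subjects are generated, extracted and discarded one at a time to
    # bound memory (a full-session EEG is ~200 MB)
    for (s in seq_len(cfg$n_subjects)) {
      cfg1 <- cfg
      cfg1$n_subjects <- 1
      cfg1$seed <- derive_seed(cfg$seed, "subject", s)
      bundle <- simulate_cohort(cfg1, include_eeg = config$use_eeg)[[1]]
      bundle$subject_id <- sprintf("S%02d", s)
      if (config$write_signals) {
        sigdir <- file.path(out_dir, "signals")
        dir.create(sigdir, showWarnings = FALSE)
        write_recording(bundle$optical,
                        file.path(sigdir, paste0(bundle$subject_id, "_fnirs.tsv")),
                        layout = bundle$layout, seed = cfg1$seed)
      }
      events <- NULL
      if (config$use_eeg) {
        chain <- eeg_blinks_chain(bundle$eeg, layout = bundle$layout,
                                  seed = derive_seed(cfg$seed, "ica", s),
                                  nc = min(10, nrow(bundle$eeg$samples)),
                                  est_subsample = 3L)
        events <- chain$events
      }
      ex <- extract_subject_features(bundle, eeg_events = events)
      feat_list[[s]] <- ex$features
      targ_list[[s]] <- ex$targets
    }
    features <- do.call(rbind, feat_list)
    targets <- do.call(rbind, targ_list)
    write.csv(features, stage_files$features, row.names = FALSE)
    write.csv(targets, stage_files$targets, row.names = FALSE)
    # downstream stages consume the written tables, so a resumed run sees
    # bit-identical inputs
    features <- read.csv(stage_files$features)
    targets <- read.csv(stage_files$targets)
    rec_stage("simulate", t0)
    rec_stage("extract_fnirs", t0)
    rec_stage("extract_eeg", t0,
              if (config$use_eeg) "ok" else "skipped (truth blinks)")
    rec_stage("features", t0, "ok", unlist(stage_files))
  }

  t0 <- tic()
  tabs <- assemble_feature_target_tables(features, targets)
  pred <- build_prediction_table(
    tabs$features, tabs$targets, spec = config$net,
    repeats = config$repeats, seed = derive_seed(config$seed, "predict"))
  pred_file <- file.path(out_dir, "prediction_table.csv")
  write.csv(pred, pred_file, row.names = FALSE)
  rec_stage("predict", t0, "ok", pred_file)

  t0 <- tic()
  render_report(list(prediction_table = pred, features = tabs$features,
                     targets = tabs$targets),
                file.path(out_dir, "report"))
  rec_stage("report", t0, "ok",
            file.path(out_dir, "report",
                      c("prediction_table.csv", "report.md")))

  manifest$total_seconds <- as.numeric(Sys.time() - t_all, units = "secs")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
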