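# Workbench: one reproducible simulate -> quantify -> deconvolve -> fit
# pipeline with manifested CSV/JSON artifacts, plus the run configuration
# object the command-line interface consumes.

#' Run configuration
#'
#' Bundles the design, EVC parameters, generator parameters, IRF parameters
#' and analysis options of one pipeline run. Fully serializable; its hash is
#' recorded in every output manifest.
#'
#' @param design A [design_config()].
#' @param evc [evc_params()].
#' @param generator [generator_config()].
#' @param irf [irf_params()].
#' @param waveform_subjects Number of subjects for which full 512 Hz epochs
#'   are rendered and re-quantified (the waveform path validation subset).
#' @param pupil_subjects Number of subjects for which continuous 500 Hz
#'   pupil traces are simulated and deconvolved.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = design_config(), evc = evc_params(),
                       generator = generator_config(), irf = irf_params(),
                       waveform_subjects = 2L, pupil_subjects = 2L,
                       seed = 1L) {
  structure(list(design = design, evc = evc, generator = generator,
                 irf = irf, waveform_subjects = as.integer(waveform_subjects),
                 pupil_subjects = as.integer(pupil_subjects),
                 seed = as.integer(seed)),
            class = "run_config")
}

write_manifest_csv <- function(x, path, manifest, stage) {
  utils::write.csv(x, path, row.names = FALSE)
  manifest$files[[basename(path)]] <- list(path = basename(path), stage = stage)
  manifest
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a complete study, renders and re-quantifies waveform epochs for
#' a subject subset (verifying that quantification reproduces the planted
#' amplitude layer), simulates and deconvolves continuous pupil traces for a
#' subject subset, fits the model families, and writes every artifact with a
#' manifest. Identical config and seed produce byte-identical tables.
#'
#' @param rc A [run_config()].
#' @param outdir Output directory (created; existing files overwritten).
#' @param models Models to fit (see [fit_study()]).
#' @return Invisibly, a list with the simulated study, fits, and manifest.
#' @export
run_pipeline <- function(rc = run_config(), outdir, models = c("rt", "accuracy",
                                                               "p3b", "cnv",
                                                               "ern", "frn",
                                                               "pupil_cue")) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(unclass(rc)), seed = rc$seed,
                   timings = list(), files = list())
  stage_t <- function(expr, name) {
    t0 <- Sys.time()
    v <- force(expr)
    manifest$timings[[name]] <<- round(as.numeric(Sys.time() - t0,
                                                  units = "secs"), 3)
    v
  }

  sim <- stage_t(simulate_study(rc$design, rc$evc, rc$generator, rc$seed),
                 "simulate")
  manifest <- write_manifest_csv(sim$records, file.path(outdir, "trials.csv"),
                                 manifest, "simulate")
  manifest <- write_manifest_csv(sim$erp,
                                 file.path(outdir, "erp_amplitudes.csv"),
                                 manifest, "simulate")
  jsonlite::write_json(sim$truth, file.path(outdir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest$files[["ground_truth.json"]] <-
    list(path = "ground_truth.json", stage = "simulate")

  # Waveform path on a subject subset: render 512 Hz epochs, write the
  # binary container, quantify, and compare with the planted amplitudes.
  wf_sub <- seq_len(min(rc$waveform_subjects, rc$design$n_subjects))
  quantified <- NULL
  if (length(wf_sub) > 0) {
    quantified <- stage_t({
      keep <- sim$records$subject %in% wf_sub
      eps <- simulate_eeg_epochs(sim$records[keep, ], sim$erp[keep, ],
                                 rc$generator,
                                 anchors = c("cue", "response", "feedback"),
                                 seed = rc$seed)
      for (a in c("cue", "response", "feedback"))
        write_epochs(eps[[a]], file.path(outdir, paste0("epochs_", a)))
      quantify_epochs(eps)
    }, "quantify")
    manifest <- write_manifest_csv(quantified,
                                   file.path(outdir, "erp_quantified.csv"),
                                   manifest, "quantify")
  }

  pup_sub <- seq_len(min(rc$pupil_subjects, rc$design$n_subjects))
  if (length(pup_sub) > 0) {
    deconv <- stage_t({
      out <- vector("list", length(pup_sub))
      for (s in pup_sub) {
        recs <- sim$records[sim$records$subject == s, ]
        ps <- simulate_pupil(recs, sim$subjects[s, ], rc$generator, rc$irf,
                             derive_seed(rc$seed, 500L + s))
        utils::write.csv(
          data.frame(time = series_times(ps$series),
                     diameter = ps$series$diameter,
                     blink = as.integer(ps$series$blink)),
          file.path(outdir, sprintf("pupil_trace_s%02d.csv", s)),
          row.names = FALSE)
        utils::write.csv(ps$events[, c("time", "type", "trial", "group")],
                         file.path(outdir,
                                   sprintf("pupil_events_s%02d.csv", s)),
                         row.names = FALSE)
        s20 <- preprocess_pupil(interpolate_blinks(ps$series), 20,
                                normalize = FALSE)
        fit <- deconvolve_pupil(s20, ps$events, rc$irf)
        out[[s]] <- cbind(subject = s, fit$coefficients)
      }
      dplyr::bind_rows(out)
    }, "deconvolve")
    manifest <- write_manifest_csv(deconv,
                                   file.path(outdir, "pupil_deconvolved.csv"),
                                   manifest, "deconvolve")
  }
  manifest <- write_manifest_csv(sim$pupil,
                                 file.path(outdir, "pupil_coefficients.csv"),
                                 manifest, "deconvolve")

  fits <- stage_t(fit_study(sim, models), "fit")
  est <- tidy_fits(fits)
  manifest <- write_manifest_csv(est, file.path(outdir, "model_estimates.csv"),
                                 manifest, "fit")
  jsonlite::write_json(
    lapply(fits, function(f) list(formula = f$formula, nobs = f$nobs,
                                  logLik = f$logLik, singular = f$singular,
                                  pruning_path = f$pruning_path,
                                  terms = f$terms, random = as.list(f$random))),
    file.path(outdir, "model_fits.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  manifest$files[["model_fits.json"]] <- list(path = "model_fits.json",
                                              stage = "fit")

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, quantified = quantified, fits = fits,
                 manifest = manifest))
}
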