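#' Resolve a run configuration
#'
#' A run configuration is a flat named list (or a YAML file holding one)
#' controlling a full pipeline run. Unknown keys are rejected so a saved
#' config reproduces a run exactly.
#'
#' Fields and defaults: `out_dir` (required), `seed` (1), `tol_ppm` (2.5),
#' `ratio_min` (1.5), `tol_da` (0.01, MS/MS matching),
#' `n_adduct` (20), `n_positive` (30), `n_shared_negative` (15),
#' `library` (NULL: bundled), `reagent` (NULL: bundled), `image_top` (3,
#' number of annotated adducts to render as ion images), plus any
#' [sim_config()] override under `sim` (a nested list).
#'
#' @param config A named list or path to a YAML file.
#' @return The resolved config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config), class = "msipair_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(out_dir = NULL, seed = 1L, tol_ppm = 2.5, ratio_min = 1.5,
                   tol_da = 0.01, n_adduct = 20L, n_positive = 30L,
                   n_shared_negative = 15L, library = NULL, reagent = NULL,
                   image_top = 3L, sim = list())
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "msipair_config_error")
  }
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$out_dir)) {
    abort("config must set out_dir", class = "msipair_config_error")
  }
  if (cfg$tol_ppm <= 0 || cfg$ratio_min <= 0 || cfg$tol_da <= 0) {
    abort("tolerances and ratio_min must be positive",
          class = "msipair_config_error")
  }
  cfg
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate / find peaks / annotate / report pipeline
#'
#' Simulates (or, when `library`/`reagent` paths are configured, loads) the
#' paired three-mode experiment, finds tissue-specific peaks in each mode,
#' annotates them, and writes all artifacts to `out_dir`: the resolved
#' config manifest (`manifest.yaml`), ground truth, per-mode consensus peak
#' and annotation tables, the cross-polarity overlap, the coverage report,
#' and ion images of the top annotated adducts. Logs per-stage counts.
#'
#' @param config A config list or YAML path (see [run_config()]).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the key results (`truth`, `peaks`,
#'   `annotations`, `overlap`, `coverage`, `artifacts`).
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  reagent <- if (is.null(cfg$reagent)) default_reagent() else {
    if (!file.exists(cfg$reagent)) {
      abort(paste0("reagent file not found: ", cfg$reagent),
            class = "msipair_data_error")
    }
    read_reagent(cfg$reagent)
  }
  library_tb <- if (is.null(cfg$library)) metabolite_library(reagent = reagent) else {
    if (!file.exists(cfg$library)) {
      abort(paste0("library file not found: ", cfg$library),
            class = "msipair_data_error")
    }
    metabolite_library(cfg$library, reagent = reagent)
  }

  scfg <- do.call(sim_config, modifyList(list(seed = cfg$seed), cfg$sim))
  truth <- default_truth(cfg$n_adduct, cfg$n_positive, cfg$n_shared_negative,
                         seed = cfg$seed, library = library_tb)
  say("simulate: %d species (%d adduct formers), seed %d",
      nrow(truth), sum(truth$adduct_former), cfg$seed)
  runs <- simulate_paired_runs(truth, scfg, reagent)
  write_tsv(truth, file.path(cfg$out_dir, "truth.tsv"))

  peaks <- lapply(runs, function(r) {
    find_tissue_peaks(r$dataset, r$roi, ratio_min = cfg$ratio_min,
                      tol_ppm = cfg$tol_ppm)
  })
  for (m in names(peaks)) {
    say("findpeaks [%s]: %d peaks in -> %d tissue-specific clusters",
        m, nrow(runs[[m]]$dataset$peaks), nrow(peaks[[m]]))
    write_tsv(peaks[[m]], file.path(cfg$out_dir, paste0("peaks_", m, ".tsv")))
  }

  annotations <- list(
    negative = annotate_peaks(peaks$negative, "negative", library_tb, reagent,
                              tol_ppm = cfg$tol_ppm),
    positive = annotate_peaks(peaks$positive, "positive", library_tb, reagent,
                              tol_ppm = cfg$tol_ppm),
    adducted_positive = annotate_peaks(peaks$adducted_positive,
                                       "adducted_positive", library_tb, reagent,
                                       paired_positive = peaks$positive,
                                       tol_ppm = cfg$tol_ppm))
  for (m in names(annotations)) {
    n_ann <- sum(!is.na(annotations[[m]]$name))
    say("annotate [%s]: %d/%d peaks annotated", m, n_ann,
        nrow(peaks[[m]]))
    write_tsv(annotations[[m]],
              file.path(cfg$out_dir, paste0("annotations_", m, ".tsv")))
  }

  adduct_ann <- annotations$adducted_positive
  adduct_only <- adduct_ann[!is.na(adduct_ann$name) &
                              adduct_ann$ion_label == "[M-H+reagent]+", ]
  overlap <- cross_mode_overlap(adduct_only, annotations$negative)
  coverage <- coverage_report(annotations$positive, adduct_ann)
  say("report: %d adducted (%d shared with negative mode), coverage +%d%%",
      nrow(overlap) * 0 + (overlap$a_only + overlap$shared), overlap$shared,
      coverage$percent_increase)
  jsonlite::write_json(as.list(overlap), file.path(cfg$out_dir, "overlap.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(unclass(tidy(coverage))[1:4],
                       file.path(cfg$out_dir, "coverage.json"), auto_unbox = TRUE)
  writeLines(utils::capture.output(print(coverage)),
             file.path(cfg$out_dir, "coverage.txt"))

  img_dir <- file.path(cfg$out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  top <- head(dplyr::arrange(adduct_only, -.data$mean_on), cfg$image_top)
  for (i in seq_len(nrow(top))) {
    img <- ion_image(runs$adducted_positive$dataset, top$observed_mz[i],
                     tol_ppm = cfg$tol_ppm)
    write_ion_image(img, file.path(img_dir, sprintf("mz_%.4f.tsv",
                                                    top$observed_mz[i])))
  }

  manifest <- c(cfg[setdiff(names(cfg), "sim")],
                list(sim = scfg,
                     package_version = as.character(utils::packageVersion("msipair"))))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  say("done: artifacts in %s", cfg$out_dir)
  invisible(list(truth = truth, peaks = peaks, annotations = annotations,
                 overlap = overlap, coverage = coverage,
                 artifacts = list.files(cfg$out_dir, recursive = TRUE)))
}
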