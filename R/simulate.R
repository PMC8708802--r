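#' Simulation configuration
#'
#' Defaults emulate the acquisition design the pipeline targets: a
#' quasi-homogeneous tissue ROI of 20 x 20 on-tissue scans next to a
#' 10 x 10 off-tissue block at 150 um raster pitch, ~1 ppm Gaussian mass
#' jitter (appropriate for a 240k-resolving-power Orbitrap), lognormal
#' abundance noise at 20% CV, ten background ions planted at equal
#' intensity on and off tissue, and isotope envelopes simulated to M+2.
#' The default m/z window c(150, 1800) is the union of the two acquisition
#' windows (150-600 and 450-1800) the design acquires per mode, so one
#' simulated run covers both.
#'
#' @param ... Overrides for any default listed above.
#' @return A named list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    on_dim = c(20L, 20L),
    off_dim = c(10L, 10L),
    pixel_pitch = 150,
    mz_window = c(150, 1800),
    mass_jitter_ppm = 1.0,
    abundance_noise_cv = 0.2,
    n_background = 10L,
    isotope_depth = 2L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  cfg <- modifyList(cfg, over)
  if (cfg$mass_jitter_ppm < 0 || cfg$abundance_noise_cv < 0) {
    abort("noise parameters must be non-negative")
  }
  cfg
}

# Full scanned grid: on-tissue block at x [0, on_w), off-tissue ROI block at
# x [on_w, on_w + off_w), y [0, off_h); the rest of the bounding rectangle is
# scanned too (off tissue, outside the ROI) so the grid is rectangular.
sim_grid <- function(config) {
  on_w <- config$on_dim[1]; on_h <- config$on_dim[2]
  off_w <- config$off_dim[1]; off_h <- config$off_dim[2]
  nx <- on_w + off_w; ny <- max(on_h, off_h)
  coords <- tidyr::expand_grid(y = 0:(ny - 1L), x = 0:(nx - 1L))[, c("x", "y")]
  on <- coords[coords$x < on_w & coords$y < on_h, ]
  off <- coords[coords$x >= on_w & coords$y < off_h, ]
  list(coords = coords, on = on, off = off)
}

#' Default ROI mask for the simulated design
#'
#' @param config A [sim_config()] list.
#' @return A mask from [roi_mask()]: 20 x 20 on-tissue, 10 x 10 off-tissue
#'   by default.
#' @export
default_roi <- function(config = sim_config()) {
  g <- sim_grid(config)
  roi_mask(g$on, g$off)
}

#' Ground-truth species list for a simulated experiment
#'
#' Draws species from the bundled library respecting class-to-mode rules:
#' adduct formers are anion-polarity species (fatty acids in the majority,
#' with some PA/PE/PI — FA entries carry triple sampling weight), of which
#' `n_shared_negative` are also detectable in negative mode; positive-mode
#' species come from the protonating classes (PC, DG, TG, plus leftover
#' PEs) and remain detectable, as `[M+H]+`, when the reagent is doped in.
#'
#' @param n_adduct Number of adduct-forming species (default 20).
#' @param n_positive Number of positive-mode species (default 30).
#' @param n_shared_negative How many adduct formers are also detectable in
#'   negative mode (default 15; at most `n_adduct`).
#' @param seed RNG seed.
#' @param library Library tibble (see [metabolite_library()]).
#' @param n_blob Number of adduct formers given a focal ("follicle-like")
#'   two-blob spatial pattern instead of uniform (default 0; alternates
#'   between the two blobs).
#' @return A tibble of ground-truth species: `name`, `formula`, `class`,
#'   `adduct_former`, `modes` (comma-joined), `pattern`, `base_abundance`.
#' @export
default_truth <- function(n_adduct = 20L, n_positive = 30L,
                          n_shared_negative = 15L, seed = 1L,
                          library = metabolite_library(), n_blob = 0L) {
  stopifnot(n_adduct >= 0, n_positive >= 0,
            n_shared_negative >= 0, n_shared_negative <= n_adduct)
  withr::with_seed(seed, {
    anion_pool <- library[library$polarity %in% c("negative", "both"), ]
    w <- ifelse(anion_pool$class == "FA", 3, 1)
    if (n_adduct > nrow(anion_pool)) abort("n_adduct exceeds anionic library pool")
    add_idx <- sample(nrow(anion_pool), n_adduct, prob = w)
    adduct <- anion_pool[add_idx, ]
    shared <- rep(FALSE, n_adduct)
    if (n_adduct > 0) shared[sample(n_adduct, n_shared_negative)] <- TRUE

    pos_pool <- library[library$polarity == "positive" |
                          (library$polarity == "both" &
                             !library$name %in% adduct$name), ]
    if (n_positive > nrow(pos_pool)) abort("n_positive exceeds positive library pool")
    pos <- pos_pool[sample(nrow(pos_pool), n_positive), ]

    pattern <- rep("uniform", n_adduct)
    if (n_blob > 0 && n_adduct > 0) {
      blobs <- c("blob:5,6,3.5", "blob:13,12,4.5")
      pattern[seq_len(min(n_blob, n_adduct))] <-
        rep(blobs, length.out = min(n_blob, n_adduct))
    }
    truth <- dplyr::bind_rows(
      tibble(name = adduct$name, formula = adduct$formula, class = adduct$class,
             adduct_former = TRUE,
             modes = as.character(ifelse(shared, "negative,adducted_positive",
                                         "adducted_positive")),
             pattern = pattern),
      tibble(name = pos$name, formula = pos$formula, class = pos$class,
             adduct_former = FALSE, modes = "positive,adducted_positive",
             pattern = "uniform"))
    truth$base_abundance <- 10^stats::runif(nrow(truth), 3.8, 5)
    truth
  })
}

parse_pattern <- function(pattern, x, y) {
  if (pattern == "uniform") return(rep(1, length(x)))
  if (grepl("^blob:", pattern)) {
    p <- as.numeric(strsplit(sub("^blob:", "", pattern), ",")[[1]])
    return(as.numeric((x - p[1])^2 + (y - p[2])^2 <= p[3]^2))
  }
  abort(paste0("unknown spatial pattern: ", pattern))
}

#' Simulate one MSI acquisition from a ground truth
#'
#' Plants, for each species detectable in `mode`, the mode-appropriate ion
#' (deprotonated, protonated, or reagent adduct) in every on-tissue pixel:
#' theoretical m/z perturbed by Gaussian ppm jitter, abundance = base x
#' spatial pattern x lognormal noise, and isotope envelope members (M+1,
#' M+2) at the theoretical relative abundances of the full ion composition.
#' Background ions are planted on *and* off tissue at equal intensity (so
#' the on/off-ratio filter removes them by construction); in adducted mode
#' every pixel additionally carries the reagent's own peaks — the dication
#' at m/z 162.1747 (z = 2) and its fluoride ion pair at 343.3483.
#'
#' @param truth Truth tibble from [default_truth()].
#' @param mode One of `"negative"`, `"positive"`, `"adducted_positive"`.
#' @param config A [sim_config()] list.
#' @param reagent A `reagent` object.
#' @return A list: `dataset` (an [msi_dataset()]), `ions` (provenance table
#'   of every planted theoretical peak: species, ion label, isotope, m/z,
#'   background flag), `roi` (the [roi_mask()]), `truth` (as supplied).
#' @export
simulate_msi <- function(truth, mode = c("negative", "positive", "adducted_positive"),
                         config = sim_config(), reagent = default_reagent()) {
  mode <- match.arg(mode)
  g <- sim_grid(config)
  seed <- config$seed + 7919L * (match(mode, c("negative", "positive",
                                               "adducted_positive")) - 1L)
  lo <- config$mz_window[1]; hi <- config$mz_window[2]
  n_iso <- config$isotope_depth + 1L

  # assemble the planted-ion table (species x isotope)
  ion_rows <- list()
  for (i in seq_len(nrow(truth))) {
    modes_i <- strsplit(truth$modes[i], ",")[[1]]
    if (!mode %in% modes_i) next
    label <- if (mode == "negative") "[M-H]-"
      else if (mode == "positive") "[M+H]+"
      else if (truth$adduct_former[i]) "[M-H+reagent]+" else "[M+H]+"
    comp <- ion_composition(truth$formula[i], label, reagent)
    z <- ion_charge(label)
    base_mz <- switch(label,
      "[M-H]-" = deprotonated_mz(truth$formula[i]),
      "[M+H]+" = protonated_mz(truth$formula[i]),
      "[M-H+reagent]+" = adduct_mz(truth$formula[i], reagent))
    pat <- isotope_pattern(comp, n_peaks = n_iso)
    ion_rows[[length(ion_rows) + 1L]] <- tibble(
      name = truth$name[i], class = truth$class[i], label = label,
      isotope = seq_len(nrow(pat)) - 1L,
      mz = base_mz + pat$mz_offset / abs(z),
      rel_abundance = pat$abundance,
      base_abundance = truth$base_abundance[i],
      pattern = truth$pattern[i], background = FALSE)
  }
  ions <- dplyr::bind_rows(ion_rows)
  if (nrow(ions)) {
    out_of_window <- ions$mz < lo | ions$mz > hi
    if (any(out_of_window)) {
      warn(sprintf("%d planted ion peak(s) outside the m/z window were omitted",
                   sum(out_of_window)))
      ions <- ions[!out_of_window, ]
    }
  }

  reagent_rows <- NULL
  if (mode == "adducted_positive") {
    dication_pat <- isotope_pattern(reagent$dication_formula, n_peaks = 2L)
    pair <- formula_add(reagent$dication_formula, reagent$counterion_formula)
    pair_pat <- isotope_pattern(pair, n_peaks = 2L)
    reagent_rows <- dplyr::bind_rows(
      tibble(name = reagent$name, class = "reagent", label = "[reagent]2+",
             isotope = 0:1,
             mz = ion_mz(reagent$dication_formula, 2L) + dication_pat$mz_offset / 2,
             rel_abundance = dication_pat$abundance,
             base_abundance = 1e6, pattern = "everywhere", background = FALSE),
      tibble(name = paste0(reagent$name, "+F"), class = "reagent",
             label = "[reagent+F]+", isotope = 0:1,
             mz = ion_mz(pair, 1L) + pair_pat$mz_offset,
             rel_abundance = pair_pat$abundance,
             base_abundance = 1e5, pattern = "everywhere", background = FALSE))
    reagent_rows <- reagent_rows[reagent_rows$mz >= lo & reagent_rows$mz <= hi, ]
  }

  sim <- withr::with_seed(seed, {
    bg <- tibble(
      name = sprintf("background_%02d", seq_len(config$n_background)),
      class = "background", label = "background", isotope = 0L,
      mz = sort(stats::runif(config$n_background, lo + 50, hi - 50)),
      rel_abundance = 1,
      base_abundance = 10^stats::runif(config$n_background, 3.5, 4.5),
      pattern = "everywhere", background = TRUE)
    all_ions <- dplyr::bind_rows(ions, reagent_rows, bg)

    sigma <- sqrt(log(1 + config$abundance_noise_cv^2))
    on_px <- g$on; all_px <- g$coords
    plant <- function(row) {
      px <- if (row$pattern == "everywhere") all_px else on_px
      fac <- if (row$pattern == "everywhere") rep(1, nrow(px))
        else parse_pattern(row$pattern, px$x, px$y)
      keep <- fac > 0
      if (!any(keep)) return(NULL)
      px <- px[keep, ]; fac <- fac[keep]
      n <- nrow(px)
      noise <- if (sigma > 0) rlnorm(n, -sigma^2 / 2, sigma) else rep(1, n)
      jit <- if (config$mass_jitter_ppm > 0) {
        rnorm(n, 0, config$mass_jitter_ppm * 1e-6)
      } else rep(0, n)
      tibble(x = px$x, y = px$y,
             mz = row$mz * (1 + jit),
             intensity = row$base_abundance * row$rel_abundance * fac * noise)
    }
    peaks <- dplyr::bind_rows(lapply(seq_len(nrow(all_ions)),
                                     function(i) plant(all_ions[i, ])))
    list(peaks = peaks, all_ions = all_ions)
  })
  # clamp jittered peaks to the declared window (jitter is ppm-scale; only
  # peaks planted at the very edge could cross)
  peaks <- sim$peaks[sim$peaks$mz >= lo & sim$peaks$mz <= hi, ]
  ds <- msi_dataset(peaks, coords = g$coords, polarity = mode,
                    mz_window = config$mz_window,
                    pixel_pitch = config$pixel_pitch)
  list(dataset = ds, ions = sim$all_ions, roi = default_roi(config),
       truth = truth)
}

#' Simulate an MS/MS spectrum of a dication adduct
#'
#' Builds a centroided fragment spectrum from [predict_fragments()]: each
#' predicted fragment at a class-typical relative abundance with lognormal
#' noise, plus uniform-random noise peaks. `drop` removes fragments by rule
#' name, e.g. `drop = "neutral_loss"` emulates the case where a
#' low-abundance precursor suppresses its neutral-loss peak while the
#' headgroup evidence survives.
#'
#' @param metabolite Neutral metabolite formula.
#' @param lipid_class Lipid class for the headgroup rule.
#' @param reagent A `reagent` object.
#' @param n_noise Number of uniform-random noise peaks (default 0).
#' @param noise_intensity Noise peak intensity relative to the base fragment
#'   (default 0.1).
#' @param abundance_cv Lognormal CV on fragment abundances (default 0.1).
#' @param drop Character vector of rule names to omit.
#' @param seed RNG seed (NULL: use current RNG state).
#' @return A tibble with `mz` and `abundance`.
#' @export
simulate_msms <- function(metabolite, lipid_class, reagent = default_reagent(),
                          n_noise = 0L, noise_intensity = 0.1,
                          abundance_cv = 0.1, drop = character(), seed = NULL) {
  pred <- predict_fragments(metabolite, lipid_class, reagent)
  precursor <- attr(pred, "precursor_mz")
  pred <- pred[!pred$rule %in% drop, ]
  heights <- c(neutral_loss = 0.8, reagent_fragment = 1.0,
               headgroup = 0.6, headgroup_secondary = 0.3)
  run <- function() {
    sigma <- sqrt(log(1 + abundance_cv^2))
    ab <- heights[pred$rule] *
      (if (sigma > 0) rlnorm(nrow(pred), -sigma^2 / 2, sigma) else 1)
    sp <- tibble(mz = pred$mz, abundance = 1e5 * unname(ab))
    if (n_noise > 0) {
      sp <- dplyr::bind_rows(sp, tibble(
        mz = stats::runif(n_noise, 100, precursor),
        abundance = noise_intensity * 1e5 * stats::runif(n_noise, 0.2, 1)))
    }
    dplyr::arrange(sp, .data$mz)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the full paired three-mode experiment
#'
#' One ground truth acquired in negative, positive, and adducted-positive
#' mode with a shared configuration — the paired design on which the
#' pipeline's end-to-end recovery is assessed.
#'
#' @param truth Truth tibble (default: [default_truth()] with the config
#'   seed).
#' @param config A [sim_config()] list.
#' @param reagent A `reagent` object.
#' @return Named list of [simulate_msi()] results: `negative`, `positive`,
#'   `adducted_positive`.
#' @export
simulate_paired_runs <- function(truth = NULL, config = sim_config(),
                                 reagent = default_reagent()) {
  truth <- truth %||% default_truth(seed = config$seed)
  lapply(setNames(nm = c("negative", "positive", "adducted_positive")),
         function(m) simulate_msi(truth, m, config, reagent))
}

#' Write a ground-truth table to a tab-delimited file
#'
#' @param truth Truth tibble from [default_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
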