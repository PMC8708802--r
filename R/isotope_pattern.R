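#' Aggregated isotope pattern of a formula
#'
#' Computes the isotopic envelope (M, M+1, M+2, ...) by convolving the
#' per-element isotope distributions, aggregating isotopologues by integer
#' neutron offset from the all-lightest species. Abundances are exact (the
#' convolution is over full multinomial distributions, not truncated to
#' single substitutions); the m/z offset reported for each aggregated peak is
#' the abundance-weighted mean mass of its isotopologues, which is what a
#' centroiding instrument reports when fine structure is unresolved.
#'
#' @param f Formula (string or `elemental_formula`).
#' @param n_peaks Number of envelope peaks to return (>= 2).
#' @return A tibble with columns `peak` ("M", "M+1", ...), `mz_offset`
#'   (Da from the monoisotopic peak), and `abundance` (relative to the base
#'   peak = 1; for formulas below ~90 carbons the base peak is M itself).
#' @examples
#' isotope_pattern("C18H32O2")
#' @export
isotope_pattern <- function(f, n_peaks = 3L) {
  f <- parse_formula(f)
  if (!is.numeric(n_peaks) || n_peaks < 2) abort("n_peaks must be >= 2")
  n_peaks <- as.integer(n_peaks)
  dist <- isotopologue_distribution(f, max_offset = n_peaks - 1L)
  keep <- seq_len(min(n_peaks, length(dist$prob)))
  prob <- dist$prob[keep]
  mzoff <- dist$mean_mass[keep] - dist$mean_mass[1]
  tibble(
    peak = c("M", paste0("M+", seq_len(length(keep) - 1L))),
    mz_offset = mzoff,
    abundance = prob / max(prob)
  )
}

# Exact aggregated isotopologue distribution by neutron offset 0..max_offset.
# Returns prob (renormalised over the window is NOT applied; truncation only
# drops mass beyond max_offset) and mean mass per offset bin.
isotopologue_distribution <- function(f, max_offset = 2L) {
  f <- parse_formula(f)
  # per-bin probability P and probability-weighted mass sum S
  P <- 1; S <- 0 # zero-atom identity: offset 0, mass 0
  nmax <- max_offset + 1L
  for (el in names(f)) {
    iso <- element_isotopes(el)
    pe <- numeric(nmax); se <- numeric(nmax)
    ok <- iso$offset < nmax
    pe[iso$offset[ok] + 1L] <- iso$prob[ok]
    se[iso$offset[ok] + 1L] <- iso$prob[ok] * iso$mass[ok]
    for (i in seq_len(unclass(f)[[el]])) {
      newP <- numeric(nmax); newS <- numeric(nmax)
      for (k in seq_along(P)) {
        if (P[k] == 0 && S[k] == 0) next
        lim <- nmax - k + 1L
        idx <- k:(k + lim - 1L)
        newP[idx] <- newP[idx] + P[k] * pe[seq_len(lim)]
        newS[idx] <- newS[idx] + P[k] * se[seq_len(lim)] + S[k] * pe[seq_len(lim)]
      }
      P <- newP; S <- newS
    }
  }
  list(prob = P, mean_mass = ifelse(P > 0, S / P, NA_real_))
}

#' Estimate carbon count from the M+1 relative abundance
#'
#' The number of carbons in a molecule is estimated by dividing the relative
#' abundance of the M+1 peak (one heavy carbon) by the natural abundance of
#' carbon-13, conventionally taken as ~1.11% for this estimate. Contributions
#' of 2H/15N/17O to M+1 make the estimate biased slightly high, which the
#' 1.11% divisor (above the tabulated 1.07%) partly compensates.
#'
#' @param m1_rel_abundance M+1 abundance relative to M (0..1.2).
#' @param c13_abundance Divisor; defaults to 0.0111.
#' @return Integer carbon estimate.
#' @examples
#' estimate_carbon_count(0.0222) # 2
#' @export
estimate_carbon_count <- function(m1_rel_abundance,
                                  c13_abundance = DEFAULT_C13_ABUNDANCE) {
  if (any(m1_rel_abundance < 0)) abort("M+1 relative abundance cannot be negative")
  if (any(m1_rel_abundance > 1.2)) {
    abort("M+1 relative abundance above 1.2 is outside the usable range")
  }
  as.integer(round(m1_rel_abundance / c13_abundance))
}

#' Spectral-accuracy check of an observed isotope envelope
#'
#' Pairs the observed M, M+1 (and M+2 when present) peaks of an ion against
#' the theoretical envelope of a candidate composition and reports the
#' relative deviation of each isotopologue abundance. Spectral accuracy —
#' how faithfully the instrument reproduces the isotopic distribution — is
#' the second gate (after ppm mass accuracy) on an elemental-composition
#' assignment.
#'
#' @param observed A data frame with columns `mz` and `abundance`
#'   (a centroided spectrum or consensus peak list).
#' @param f Candidate composition of the detected ion (string or
#'   `elemental_formula`); use the full ion composition, e.g. including the
#'   reagent atoms for an adducted ion.
#' @param charge Ion charge (spacing of isotope peaks is 1/|z|).
#' @param tol_ppm Match tolerance for locating envelope peaks (default 2.5).
#' @param max_m1_deviation Pass threshold on the M+1 relative deviation
#'   (default 0.2, i.e. 20%).
#' @return A `spectral_accuracy` object: a list with `status`
#'   ("ok" or "no_match"), `pass`, and `peaks`, a tibble of per-isotopologue
#'   observed/theoretical relative abundances and deviations.
#' @export
spectral_accuracy <- function(observed, f, charge = 1L, tol_ppm = 2.5,
                              max_m1_deviation = 0.2) {
  stopifnot(is.data.frame(observed), all(c("mz", "abundance") %in% names(observed)))
  f <- parse_formula(f)
  theo <- isotope_pattern(f, n_peaks = 3L)
  mono_mz <- ion_mz(f, charge = charge)
  target_mz <- mono_mz + theo$mz_offset / abs(charge)
  find_peak <- function(mz) {
    if (nrow(observed) == 0) return(NA_integer_)
    d <- abs(observed$mz - mz)
    i <- which.min(d)
    if (d[i] <= mz * tol_ppm * 1e-6) i else NA_integer_
  }
  idx <- vapply(target_mz, find_peak, integer(1))
  if (is.na(idx[1])) {
    out <- list(status = "no_match", pass = NA,
                peaks = tibble(peak = character(), theoretical = numeric(),
                               observed = numeric(), deviation = numeric()))
    class(out) <- "spectral_accuracy"
    return(out)
  }
  obs_ab <- ifelse(is.na(idx), NA_real_, observed$abundance[idx])
  obs_rel <- obs_ab / obs_ab[1]
  dev <- abs(obs_rel - theo$abundance) / theo$abundance
  peaks <- tibble(peak = theo$peak, mz = target_mz,
                  theoretical = theo$abundance,
                  observed = obs_rel, deviation = dev)
  m1_dev <- dev[2]
  out <- list(status = "ok",
              pass = !is.na(m1_dev) && m1_dev <= max_m1_deviation,
              peaks = peaks)
  class(out) <- "spectral_accuracy"
  out
}

#' @export
print.spectral_accuracy <- function(x, ...) {
  cat("<spectral_accuracy> status:", x$status,
      if (x$status == "ok") paste0(" pass: ", x$pass), "\n")
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' @rdname spectral_accuracy
#' @param x A `spectral_accuracy` object.
#' @param ... Unused.
#' @method tidy spectral_accuracy
#' @export
tidy.spectral_accuracy <- function(x, ...) x$peaks

#' @rdname spectral_accuracy
#' @method glance spectral_accuracy
#' @export
glance.spectral_accuracy <- function(x, ...) {
  tibble(status = x$status, pass = x$pass,
         m1_deviation = if (nrow(x$peaks) >= 2) x$peaks$deviation[2] else NA_real_)
}
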