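#' Region-of-interest mask
#'
#' Labels pixels as on-tissue or off-tissue for tissue-specific peak
#' finding. The two sets must be disjoint and non-empty.
#'
#' @param on,off Data frames of pixel coordinates (`x`, `y`).
#' @return A tibble with columns `x`, `y`, `region` ("on"/"off").
#' @export
roi_mask <- function(on, off) {
  on <- as_tibble(on)[, c("x", "y")]
  off <- as_tibble(off)[, c("x", "y")]
  if (nrow(on) == 0 || nrow(off) == 0) abort("both ROI regions must be non-empty")
  if (nrow(dplyr::inner_join(on, off, by = c("x", "y"))) > 0) {
    abort("on- and off-tissue regions overlap")
  }
  dplyr::bind_rows(dplyr::mutate(on, region = "on"),
                   dplyr::mutate(off, region = "off"))
}

# Greedy abundance-ranked ppm clustering. Peaks are visited in order of
# decreasing intensity; a peak joins the nearest existing cluster whose
# running abundance-weighted mean m/z is within tol_ppm (ppm evaluated
# against the cluster mean, the conventional MMA direction) and which does
# not yet hold a peak from the same pixel; otherwise it seeds a new cluster.
# Deterministic and invariant to pixel order by the (intensity, mz, x, y)
# sort.
greedy_cluster <- function(mz, intensity, pixel_id, tol_ppm) {
  ord <- order(-intensity, mz, pixel_id)
  mz <- mz[ord]; intensity <- intensity[ord]; pixel_id <- pixel_id[ord]
  n <- length(mz)
  assign <- integer(n)
  mu <- numeric(n); wsum <- numeric(n); wmzsum <- numeric(n)
  members <- vector("list", n)
  nc <- 0L
  for (i in seq_len(n)) {
    k <- 0L
    if (nc > 0L) {
      m <- mu[seq_len(nc)]
      d <- abs(m - mz[i])
      cand <- which(d <= m * tol_ppm * 1e-6)
      if (length(cand)) {
        # among qualifying clusters prefer the most abundant (ties: nearest):
        # seeds are the strongest peaks, so the dominant cluster absorbs the
        # jitter tail instead of bifurcating it into satellites
        cand <- cand[order(-wsum[cand], d[cand])]
        for (cc in cand) {
          if (!pixel_id[i] %in% members[[cc]]) { k <- cc; break }
        }
      }
    }
    if (k == 0L) {
      nc <- nc + 1L
      k <- nc
    }
    assign[i] <- k
    wsum[k] <- wsum[k] + intensity[i]
    wmzsum[k] <- wmzsum[k] + intensity[i] * mz[i]
    mu[k] <- wmzsum[k] / wsum[k]
    members[[k]] <- c(members[[k]], pixel_id[i])
  }
  list(cluster = assign[order(ord)], n_clusters = nc)
}

#' Cluster peaks across pixels into consensus peaks
#'
#' Groups centroided peaks from all pixels in `cells` into consensus peaks
#' by greedy abundance-ranked clustering at a ppm tolerance. Mean abundances
#' are computed over *all* cells in the mask — a pixel lacking the peak
#' contributes zero — so sporadic noise is penalised.
#'
#' @param dataset An `msi_dataset`.
#' @param cells Data frame of pixel coordinates defining the mask.
#' @param tol_ppm Clustering tolerance in ppm (default 2.5, matching a
#'   high-resolving-power Orbitrap mass measurement accuracy gate).
#' @return A tibble of consensus peaks sorted by m/z: `mz`
#'   (abundance-weighted mean), `mean_abundance` (zeros included),
#'   `pixel_frequency` (fraction of mask cells containing the peak),
#'   `n_pixels`, `total_intensity`.
#' @export
cluster_peaks <- function(dataset, cells, tol_ppm = 2.5) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (tol_ppm <= 0) abort("tol_ppm must be positive")
  cells <- as_tibble(cells)[, c("x", "y")]
  if (nrow(cells) == 0) abort("empty mask")
  pk <- dplyr::inner_join(dataset$peaks, cells, by = c("x", "y"))
  if (nrow(pk) == 0) {
    return(tibble(mz = numeric(), mean_abundance = numeric(),
                  pixel_frequency = numeric(), n_pixels = integer(),
                  total_intensity = numeric()))
  }
  pid <- match(paste(pk$x, pk$y), paste(cells$x, cells$y))
  cl <- greedy_cluster(pk$mz, pk$intensity, pid, tol_ppm)
  g <- cl$cluster
  n_cells <- nrow(cells)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(g = g, mz = pk$mz, intensity = pk$intensity, pid = pid), g),
    mz = weighted.mean(.data$mz, .data$intensity),
    total_intensity = sum(.data$intensity),
    n_pixels = dplyr::n_distinct(.data$pid), .groups = "drop")
  out <- dplyr::arrange(dplyr::mutate(agg,
    mean_abundance = .data$total_intensity / n_cells,
    pixel_frequency = .data$n_pixels / n_cells), .data$mz)
  out[, c("mz", "mean_abundance", "pixel_frequency", "n_pixels", "total_intensity")]
}

# Flag clusters that sit one (or, for z=2, half a) 13C spacing above a more
# abundant cluster: these are isotope envelope members, not independent
# species. The child/parent abundance ratio must also be plausible for an
# isotope peak (<= max_ratio; the M+1/M ratio of even a ~75-carbon ion stays
# below ~0.85), so a genuine species that happens to sit one 13C spacing
# above an unrelated stronger envelope is not swallowed.
flag_isotopes <- function(tb, abundance_col = "mean_abundance", tol_da = 0.006,
                          max_ratio = 0.85) {
  spacing <- 1.0033548378
  ab <- tb[[abundance_col]]
  iso <- vapply(seq_len(nrow(tb)), function(i) {
    for (z in c(1, 2)) {
      parent <- tb$mz[i] - spacing / z
      j <- which(abs(tb$mz - parent) <= tol_da & ab > ab[i] &
                   ab[i] <= max_ratio * ab)
      if (length(j)) return(TRUE)
    }
    FALSE
  }, logical(1))
  iso
}

#' Find tissue-specific consensus peaks
#'
#' Clusters peaks over the union of on- and off-tissue ROI cells and keeps
#' those whose mean on-tissue abundance is at least `ratio_min` times the
#' mean off-tissue abundance (default 1.5x). When a cluster has zero
#' off-tissue signal the divisor falls back to the smallest positive
#' off-tissue mean among all clusters (then to machine-tiny), so genuinely
#' tissue-specific peaks survive without infinite ratios.
#'
#' @param dataset An `msi_dataset`.
#' @param mask A mask from [roi_mask()].
#' @param ratio_min Minimum on/off abundance ratio (default 1.5).
#' @param tol_ppm Clustering tolerance in ppm (default 2.5).
#' @param keep_all Return all clusters with a `retained` column instead of
#'   only the retained ones.
#' @return A tibble of consensus peaks: `mz`, `mean_on`, `mean_off`,
#'   `ratio`, `pixel_frequency` (over on-tissue cells), `n_pixels`,
#'   `is_isotope` (envelope member of a stronger cluster).
#' @export
find_tissue_peaks <- function(dataset, mask, ratio_min = 1.5, tol_ppm = 2.5,
                              keep_all = FALSE) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (ratio_min <= 0) abort("ratio_min must be positive")
  on_cells <- mask[mask$region == "on", c("x", "y")]
  off_cells <- mask[mask$region == "off", c("x", "y")]
  if (nrow(on_cells) == 0 || nrow(off_cells) == 0) {
    abort("mask must contain both on- and off-tissue cells")
  }
  cells <- dplyr::bind_rows(on_cells, off_cells)
  pk <- dplyr::inner_join(dataset$peaks, mask, by = c("x", "y"))
  if (nrow(pk) == 0) abort("no peaks inside the ROI mask")
  pid <- match(paste(pk$x, pk$y), paste(cells$x, cells$y))
  cl <- greedy_cluster(pk$mz, pk$intensity, pid, tol_ppm)
  df <- tibble(g = cl$cluster, mz = pk$mz, intensity = pk$intensity,
               pid = pid, region = pk$region)
  n_on <- nrow(on_cells); n_off <- nrow(off_cells)
  agg <- dplyr::summarise(dplyr::group_by(df, g),
    mz = weighted.mean(.data$mz, .data$intensity),
    mean_on = sum(.data$intensity[.data$region == "on"]) / n_on,
    mean_off = sum(.data$intensity[.data$region == "off"]) / n_off,
    n_pixels = dplyr::n_distinct(.data$pid[.data$region == "on"]),
    .groups = "drop")
  agg$pixel_frequency <- agg$n_pixels / n_on
  pos_off <- agg$mean_off[agg$mean_off > 0]
  eps <- if (length(pos_off)) min(pos_off) else .Machine$double.xmin
  agg$ratio <- agg$mean_on / pmax(agg$mean_off, eps)
  agg <- dplyr::arrange(agg, .data$mz)
  agg$is_isotope <- flag_isotopes(agg, "mean_on")
  agg$retained <- agg$ratio >= ratio_min
  out <- agg[, c("mz", "mean_on", "mean_off", "ratio", "pixel_frequency",
                 "n_pixels", "is_isotope", "retained")]
  if (keep_all) out else dplyr::select(out[out$retained, ], -"retained")
}
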