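#' Ion image of a target m/z
#'
#' Sums, per pixel, the abundances of all peaks within a ppm tolerance of
#' the target m/z, over the dataset's full rectangular grid. Pixels without
#' a matching peak are zero. A target outside the acquisition window yields
#' an all-zero image with a warning.
#'
#' @param dataset An `msi_dataset`.
#' @param target_mz Target m/z.
#' @param tol_ppm Extraction tolerance in ppm (default 2.5).
#' @return An `ion_image`: a numeric matrix with rows = y (top row first)
#'   and columns = x, with attributes `target_mz`, `tol_ppm`, and `origin`
#'   (the (x, y) grid offset). Use [autoplot()] for a heatmap or
#'   [write_ion_image()] for a delimited grid.
#' @export
ion_image <- function(dataset, target_mz, tol_ppm = 2.5) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (tol_ppm <= 0) abort("tol_ppm must be positive")
  xs <- range(dataset$coords$x); ys <- range(dataset$coords$y)
  nx <- xs[2] - xs[1] + 1L; ny <- ys[2] - ys[1] + 1L
  img <- matrix(0, nrow = ny, ncol = nx)
  if (target_mz < dataset$mz_window[1] || target_mz > dataset$mz_window[2]) {
    warn(sprintf("target m/z %.4f outside acquisition window [%g, %g]: all-zero image",
                 target_mz, dataset$mz_window[1], dataset$mz_window[2]))
  } else {
    tol <- target_mz * tol_ppm * 1e-6
    hit <- dataset$peaks[abs(dataset$peaks$mz - target_mz) <= tol, ]
    if (nrow(hit)) {
      agg <- dplyr::summarise(dplyr::group_by(hit, .data$x, .data$y),
                              intensity = sum(.data$intensity), .groups = "drop")
      img[cbind(agg$y - ys[1] + 1L, agg$x - xs[1] + 1L)] <- agg$intensity
    }
  }
  structure(img, class = c("ion_image", "matrix"),
            target_mz = target_mz, tol_ppm = tol_ppm,
            origin = c(x = xs[1], y = ys[1]))
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f +/- %g ppm, %d x %d pixels, max %.3g\n",
              attr(x, "target_mz"), attr(x, "tol_ppm"), ncol(x), nrow(x),
              max(x)))
  invisible(x)
}

#' @rdname ion_image
#' @param object An `ion_image`.
#' @param ... Unused.
#' @method autoplot ion_image
#' @export
autoplot.ion_image <- function(object, ...) {
  org <- attr(object, "origin")
  df <- tidyr::expand_grid(y = seq_len(nrow(object)) - 1L + org[["y"]],
                           x = seq_len(ncol(object)) - 1L + org[["x"]])
  df$intensity <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("m/z %.4f", attr(object, "target_mz")),
                  fill = "abundance") +
    ggplot2::theme_minimal()
}

#' Export an ion image as a delimited numeric grid
#'
#' Row-major, (0,0) top-left, tab-delimited — a fixed layout so seeded runs
#' are byte-identical.
#'
#' @param image An `ion_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ion_image <- function(image, path) {
  write.table(format(unclass(image), digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Mean spectrum over a set of pixels
#'
#' Convenience for plotting: clusters the peaks in `cells` (default: whole
#' grid) and returns the consensus peak list as a tibble suitable for a
#' stick-spectrum ggplot.
#'
#' @inheritParams cluster_peaks
#' @return A tibble from [cluster_peaks()].
#' @export
mean_spectrum <- function(dataset, cells = NULL, tol_ppm = 2.5) {
  cluster_peaks(dataset, cells %||% dataset$coords, tol_ppm = tol_ppm)
}

#' Stick-spectrum plot of a consensus peak list
#'
#' @param peaks A tibble with `mz` and an abundance column (`mean_abundance`
#'   or `mean_on`).
#' @return A ggplot.
#' @export
plot_spectrum <- function(peaks) {
  ab <- if ("mean_abundance" %in% names(peaks)) "mean_abundance" else "mean_on"
  ggplot2::ggplot(peaks, ggplot2::aes(.data$mz, .data[[ab]])) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = "mean abundance") +
    ggplot2::theme_minimal()
}
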