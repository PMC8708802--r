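test_that("peaks within tolerance merge into one abundance-weighted cluster", {
  peaks <- tibble::tibble(x = c(0L, 1L), y = 0L,
                          mz = c(500.0000, 500.0010),
                          intensity = c(100, 300))
  ds <- toy_dataset(peaks, nx = 2L)
  cl <- cluster_peaks(ds, ds$coords, tol_ppm = 2.5)
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$mz, weighted.mean(peaks$mz, peaks$intensity),
               tolerance = 1e-12)
  expect_equal(cl$pixel_frequency, 1)
  expect_equal(cl$mean_abundance, 200)
})

test_that("peaks beyond tolerance stay separate", {
  peaks <- tibble::tibble(x = c(0L, 1L), y = 0L,
                          mz = c(500.0000, 500.0025), # 5 ppm apart
                          intensity = c(100, 100))
  ds <- toy_dataset(peaks, nx = 2L)
  cl <- cluster_peaks(ds, ds$coords, tol_ppm = 2.5)
  expect_identical(nrow(cl), 2L)
})

test_that("each pixel contributes at most one peak per cluster", {
  # two near-identical peaks in the same pixel must not collapse
  peaks <- tibble::tibble(x = c(0L, 0L, 1L), y = 0L,
                          mz = c(600.0000, 600.0006, 600.0001),
                          intensity = c(100, 90, 80))
  ds <- toy_dataset(peaks, nx = 2L)
  cl <- cluster_peaks(ds, ds$coords, tol_ppm = 2.5)
  expect_identical(nrow(cl), 2L)
  expect_identical(sum(cl$n_pixels), 3L)
})

test_that("clustering is invariant to pixel and row order", {
  sim <- simulate_msi(default_truth(4, 6, 2, seed = 12), "adducted_positive",
                      sim_config(seed = 12, on_dim = c(8L, 8L),
                                 off_dim = c(4L, 4L)))
  ds <- sim$dataset
  shuffled <- ds
  set.seed(99)
  shuffled$peaks <- ds$peaks[sample(nrow(ds$peaks)), ]
  a <- cluster_peaks(ds, ds$coords)
  b <- cluster_peaks(shuffled, ds$coords)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("planted species form one cluster each at the planted prevalence", {
  truth <- default_truth(3, 0, 0, seed = 21)
  sim <- simulate_msi(truth, "adducted_positive",
                      sim_config(seed = 21, n_background = 0L))
  cl <- cluster_peaks(sim$dataset, sim$roi[sim$roi$region == "on", ])
  for (f in truth$formula) {
    target <- adduct_mz(f)
    hits <- cl[abs(cl$mz - target) <= target * 2.5e-6, ]
    # one dominant cluster; at most a tiny jitter-tail satellite beside it
    expect_identical(sum(hits$pixel_frequency > 0.5), 1L)
    # the dominant cluster holds the planted prevalence up to the ~1.2%
    # of pixels whose 1 ppm jitter draw falls outside the 2.5 ppm gate
    expect_gte(max(hits$pixel_frequency), 0.95)
    expect_gte(sum(hits$pixel_frequency), 0.95)
  }
  expect_error(cluster_peaks(sim$dataset, sim$roi[0, ]), "empty mask")
})

test_that("the on/off abundance ratio filter implements the 1.5x rule", {
  on <- expand.grid(x = 0:4, y = 0:4)
  off <- expand.grid(x = 5:7, y = 0:4)
  cells <- rbind(on, off)
  # ratio 2.0: on-tissue 100, off-tissue 50 -> retained
  # ratio 1.0: uniform 80 everywhere -> removed
  peaks <- dplyr::bind_rows(
    tibble::tibble(x = cells$x, y = cells$y, mz = 700.4,
                   intensity = ifelse(cells$x < 5, 100, 50)),
    tibble::tibble(x = cells$x, y = cells$y, mz = 800.8, intensity = 80))
  ds <- toy_dataset(peaks, nx = 8L, ny = 5L)
  mask <- roi_mask(on, off)
  kept <- find_tissue_peaks(ds, mask, ratio_min = 1.5)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$mz, 700.4, tolerance = 1e-9)
  expect_equal(kept$ratio, 2, tolerance = 1e-9)
  all_cl <- find_tissue_peaks(ds, mask, keep_all = TRUE)
  expect_identical(nrow(all_cl), 2L)
  expect_equal(all_cl$ratio[all_cl$mz > 800], 1, tolerance = 1e-9)
})

test_that("zero off-tissue signal falls back to the epsilon floor", {
  on <- expand.grid(x = 0:2, y = 0)
  off <- expand.grid(x = 3:5, y = 0)
  peaks <- dplyr::bind_rows(
    tibble::tibble(x = 0:2, y = 0L, mz = 500.1, intensity = 100),
    tibble::tibble(x = c(0:2, 3:5), y = 0L, mz = 650.2,
                   intensity = c(90, 90, 90, 60, 60, 60)))
  ds <- toy_dataset(peaks, nx = 6L)
  kept <- find_tissue_peaks(ds, roi_mask(on, off), keep_all = TRUE)
  tissue_only <- kept[abs(kept$mz - 500.1) < 0.01, ]
  expect_identical(tissue_only$mean_off, 0)
  expect_true(tissue_only$retained) # finite but large ratio via epsilon
  expect_true(is.finite(tissue_only$ratio))
})

test_that("ROI masks must be disjoint and non-empty", {
  on <- data.frame(x = 0:1, y = 0L)
  expect_error(roi_mask(on, on), "overlap")
  expect_error(roi_mask(on, on[0, ]), "non-empty")
})

test_that("isotope envelope members are flagged, genuine overlaps are not", {
  tb <- tibble::tibble(
    mz = c(700.0000, 701.0034, 702.0067, 703.0100),
    mean_abundance = c(1000, 450, 100, 950))
  # 701/702 are envelope members; 703 sits one spacing above 702 but is far
  # too abundant to be its isotope
  flags <- msipair:::flag_isotopes(tb)
  expect_identical(flags, c(FALSE, TRUE, TRUE, FALSE))
})
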