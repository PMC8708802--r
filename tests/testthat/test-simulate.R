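test_that("ground truth construction respects the requested counts", {
  t1 <- default_truth(3, 10, 2, seed = 1)
  expect_identical(sum(t1$adduct_former), 3L)
  expect_identical(sum(!t1$adduct_former), 10L)
  expect_identical(sum(grepl("negative", t1$modes)), 2L)
  expect_true(all(grepl("adducted_positive", t1$modes)))

  t2 <- default_truth(0, 5, 0, seed = 2)
  expect_identical(sum(t2$adduct_former), 0L)

  # fatty acids dominate the adduct formers under the default weights
  t3 <- default_truth(seed = 3)
  cls <- table(t3$class[t3$adduct_former])
  expect_identical(names(which.max(cls)), "FA")
  expect_true(all(t3$class[t3$adduct_former] %in% c("FA", "PA", "PE", "PI")))
  expect_true(all(t3$class[!t3$adduct_former] %in% c("PC", "PE", "DG", "TG")))
})

test_that("truth generation is reproducible per seed", {
  expect_identical(default_truth(seed = 5), default_truth(seed = 5))
  expect_false(identical(default_truth(seed = 5)$name,
                         default_truth(seed = 6)$name))
})

test_that("the noise-free limit plants every peak at its theoretical m/z", {
  truth <- default_truth(2, 2, 1, seed = 9)
  cfg <- sim_config(seed = 9, mass_jitter_ppm = 0, abundance_noise_cv = 0,
                    n_background = 0L)
  sim <- simulate_msi(truth, "adducted_positive", cfg)
  planted <- sim$ions$mz
  off <- vapply(sim$dataset$peaks$mz,
                function(m) min(abs(planted - m)), numeric(1))
  expect_true(all(off < 1e-9))
})

test_that("every simulated non-background peak traces to the provenance table", {
  truth <- default_truth(5, 5, 3, seed = 14)
  sim <- simulate_msi(truth, "adducted_positive", sim_config(seed = 14))
  planted <- sim$ions$mz # includes background rows
  rel_off <- vapply(sim$dataset$peaks$mz,
                    function(m) min(abs(planted / m - 1)), numeric(1))
  expect_true(all(rel_off < 10e-6)) # 10 ppm >> the 1 ppm jitter
  expect_true(all(c("name", "label", "isotope", "mz", "background") %in%
                    names(sim$ions)))
})

test_that("the reagent dication appears in every pixel of an adducted run", {
  sim <- simulate_msi(default_truth(2, 2, 1, seed = 10), "adducted_positive",
                      sim_config(seed = 10))
  r <- default_reagent()
  target <- ion_mz(r$dication_formula, 2)
  hits <- sim$dataset$peaks[abs(sim$dataset$peaks$mz - target) <
                              target * 5e-6, ]
  per_pixel <- dplyr::distinct(hits[, c("x", "y")])
  expect_identical(nrow(per_pixel), nrow(sim$dataset$coords))
  # negative mode never carries reagent peaks
  simn <- simulate_msi(default_truth(2, 2, 1, seed = 10), "negative",
                       sim_config(seed = 10))
  expect_identical(nrow(simn$dataset$peaks[
    abs(simn$dataset$peaks$mz - target) < target * 5e-6, ]), 0L)
})

test_that("simulation is bit-for-bit reproducible for a given config", {
  truth <- default_truth(3, 3, 2, seed = 4)
  cfg <- sim_config(seed = 4)
  a <- simulate_msi(truth, "positive", cfg)
  b <- simulate_msi(truth, "positive", cfg)
  expect_identical(a$dataset$peaks, b$dataset$peaks)
  f1 <- withr::local_tempfile(fileext = ".imzML")
  f2 <- withr::local_tempfile(fileext = ".imzML")
  set.seed(1); write_imzml(a$dataset, f1)
  set.seed(1); write_imzml(b$dataset, f2)
  expect_identical(unname(tools::md5sum(sub("imzML$", "ibd", f1))),
                   unname(tools::md5sum(sub("imzML$", "ibd", f2))))
})

test_that("simulated MS/MS spectra contain exactly the predicted fragments", {
  sp <- simulate_msms("C43H78NO8P", "PE", abundance_cv = 0, seed = 2)
  pred <- predict_fragments("C43H78NO8P", "PE")
  expect_identical(nrow(sp), nrow(pred))
  expect_equal(sort(sp$mz), sort(pred$mz), tolerance = 1e-9)
})

test_that("dropping the precursor-loss fragment mirrors its real-data absence", {
  sp <- simulate_msms("C47H83O13P", "PI", drop = "neutral_loss", seed = 3)
  v <- match_msms(predict_fragments("C47H83O13P", "PI"), sp)
  expect_identical(v$tier, "high")
  expect_identical(tidy(v)$rule[!tidy(v)$found], "neutral_loss")
})

test_that("validation tiers are robust to added noise peaks", {
  pred <- predict_fragments("C41H71O8P", "PA")
  tiers <- vapply(1:100, function(i) {
    sp <- simulate_msms("C41H71O8P", "PA", n_noise = 50L,
                        noise_intensity = 0.1, seed = 1000L + i)
    match_msms(pred, sp)$tier
  }, character(1))
  expect_gte(mean(tiers == "high"), 0.95)
})

test_that("species outside the acquisition window are omitted with a warning", {
  truth <- default_truth(2, 2, 1, seed = 16)
  cfg <- sim_config(seed = 16, mz_window = c(150, 600))
  expect_warning(sim <- simulate_msi(truth, "adducted_positive", cfg),
                 "outside")
  expect_true(all(sim$dataset$peaks$mz <= 600))
})

test_that("unknown config fields are rejected", {
  expect_error(sim_config(bogus = 1), "unknown config")
  expect_error(sim_config(mass_jitter_ppm = -1), "non-negative")
})
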