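test_that("library search finds the constructed adduct query at its ppm error", {
  query <- adduct_mz("C18H32O2")
  anion <- deprotonated_mz("C18H32O2")
  # +1.0 ppm on the anion scale, where the mass error is evaluated
  mz <- query + anion * 1.0e-6
  hits <- library_search(mz, ion_label = "[M-H+reagent]+")
  expect_true("FA(18:2)" %in% hits$name)
  expect_equal(hits$mma_ppm[hits$name == "FA(18:2)"], 1.0, tolerance = 0.01)
})

test_that("a query far from every library entry returns no candidates", {
  lib <- metabolite_library()
  mz <- lib$protonated_mz[1] * (1 + 10e-6)
  near <- min(abs(lib$protonated_mz / mz - 1)) * 1e6
  expect_gt(near, 2.5) # sanity: really off every entry
  expect_identical(nrow(library_search(mz, ion_label = "[M+H]+")), 0L)
})

test_that("isomeric library entries are both returned with identical error", {
  # PE(36:1) and PC(33:1) share the composition C41H80NO8P
  lib <- metabolite_library()
  iso <- lib[lib$formula == "C41H80NO8P", ]
  expect_gte(nrow(iso), 2L)
  hits <- library_search(iso$protonated_mz[1], ion_label = "[M+H]+")
  expect_true(all(iso$name %in% hits$name))
  expect_equal(diff(range(hits$mma_ppm[hits$name %in% iso$name])), 0,
               tolerance = 1e-12)
})

test_that("adduct assignment requires absence from the paired positive run", {
  pk <- tibble::tibble(mz = c(adduct_mz("C18H32O2"),
                              protonated_mz("C42H82NO8P")),
                       mean_on = c(1000, 2000))
  # without a paired run: adduct assigned, evidence flag NA
  ann <- annotate_peaks(pk, "adducted_positive")
  adduct_rows <- ann[!is.na(ann$ion_label) &
                       ann$ion_label == "[M-H+reagent]+", ]
  expect_true("FA(18:2)" %in% adduct_rows$name)
  expect_true(all(is.na(adduct_rows$cross_polarity_confirmed)))

  # with a paired run lacking that m/z: adduct confirmed
  ann2 <- annotate_peaks(pk, "adducted_positive",
                         paired_positive = protonated_mz("C42H82NO8P"))
  adduct2 <- ann2[!is.na(ann2$ion_label) & ann2$ion_label == "[M-H+reagent]+", ]
  expect_true(all(adduct2$cross_polarity_confirmed))

  # a peak present in the paired run is never assigned as adduct
  ann3 <- annotate_peaks(pk, "adducted_positive", paired_positive = pk$mz)
  expect_false(any(ann3$ion_label == "[M-H+reagent]+", na.rm = TRUE))
  # ... but the protonated assignment of the PC survives
  expect_true("PC(34:1)" %in% ann3$name)
})

test_that("a corrupted isotope envelope fails spectral accuracy but keeps its record", {
  f <- "C18H32O2"
  comp <- formula_add(formula_subtract(f, "H"), "C21H44N2")
  pat <- isotope_pattern(comp)
  mz0 <- adduct_mz(f)
  pk <- tibble::tibble(
    mz = mz0 + pat$mz_offset,
    mean_on = c(1000, 1000 * pat$abundance[2] * 1.8, 1000 * pat$abundance[3]))
  ann <- annotate_peaks(pk, "adducted_positive")
  rec <- ann[!is.na(ann$name) & ann$name == "FA(18:2)", ]
  expect_identical(rec$spectral_accuracy, "fail")
  expect_gt(rec$m1_deviation, 0.2)
  # the carbon estimate implied by the corrupted M+1 is far from the truth
  expect_gt(abs(rec$carbon_estimate - 39L), 5L)
})

test_that("an intact envelope passes spectral accuracy with the right carbons", {
  f <- "C18H32O2"
  comp <- formula_add(formula_subtract(f, "H"), "C21H44N2")
  pat <- isotope_pattern(comp)
  pk <- tibble::tibble(mz = adduct_mz(f) + pat$mz_offset,
                       mean_on = 1000 * pat$abundance)
  ann <- annotate_peaks(pk, "adducted_positive")
  rec <- ann[!is.na(ann$name) & ann$name == "FA(18:2)", ]
  expect_identical(rec$spectral_accuracy, "pass")
  expect_lte(abs(rec$carbon_estimate - 39L), 1L) # 18 lipid + 21 reagent carbons
})

test_that("unannotated peaks are carried through with empty candidates", {
  pk <- tibble::tibble(mz = 777.7777, mean_on = 10)
  ann <- annotate_peaks(pk, "negative")
  expect_identical(nrow(ann), 1L)
  expect_true(is.na(ann$name))
  expect_equal(ann$observed_mz, 777.7777)
})

test_that("cross-mode overlap performs exact set algebra on identity", {
  a <- tibble::tibble(name = c("FA(18:2)", "PA(38:5)", "PI(38:4)"),
                      formula = c("C18H32O2", "C41H71O8P", "C47H83O13P"))
  expect_equal(cross_mode_overlap(a, a),
               tibble::tibble(a_only = 0L, shared = 3L, b_only = 0L))
  b <- tibble::tibble(name = "PE(38:4)", formula = "C43H78NO8P")
  expect_equal(cross_mode_overlap(a, b),
               tibble::tibble(a_only = 3L, shared = 0L, b_only = 1L))
  expect_equal(cross_mode_overlap(a[1:2, ], a[2:3, ]),
               tibble::tibble(a_only = 1L, shared = 1L, b_only = 1L))
})

test_that("coverage arithmetic reproduces the worked example", {
  cov <- coverage_report(n_positive = 167, n_adduct_new = 73)
  expect_identical(cov$percent_increase, 44)
  expect_identical(coverage_report(n_positive = 20,
                                   n_adduct_new = 5)$percent_increase, 25)
  expect_identical(coverage_report(n_positive = 20,
                                   n_adduct_new = 0)$percent_increase, 0)
  expect_error(coverage_report(n_positive = 0, n_adduct_new = 3), "zero")
  out <- capture.output(print(cov))
  expect_true(any(grepl("n_adduct_new / n_positive", out)))
  expect_identical(tidy(cov)$percent_increase, 44)
})
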