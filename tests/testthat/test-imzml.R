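test_that("imzML round trip preserves peaks, empty pixels, and metadata", {
  peaks <- tibble::tibble(
    x = c(0L, 0L, 1L, 2L, 2L),
    y = c(0L, 0L, 0L, 0L, 0L),
    mz = c(400.123456789, 612.98765, 500.5, 723.331, 1500.0001),
    intensity = c(1e4, 2e3, 5e5, 7.123, 42))
  ds <- toy_dataset(peaks, nx = 3L, ny = 3L, polarity = "adducted_positive")
  expect_identical(nrow(ds$coords), 9L) # 8 of them empty

  f <- withr::local_tempfile(fileext = ".imzML")
  set.seed(5)
  write_imzml(ds, f)
  ds2 <- read_imzml(f)

  expect_identical(ds2$polarity, "adducted_positive")
  expect_equal(ds2$mz_window, ds$mz_window)
  expect_identical(nrow(ds2$coords), 9L)
  ord <- function(p) p[order(p$y, p$x, p$mz), ]
  expect_equal(ord(ds2$peaks)$mz, ord(ds$peaks)$mz, tolerance = 1e-12)
  expect_identical(ord(ds2$peaks)$intensity, ord(ds$peaks)$intensity)
})

test_that("a simulated acquisition writes one spectrum per grid pixel", {
  sim <- simulate_msi(default_truth(3, 5, 2, seed = 3), "positive",
                      sim_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".imzML")
  set.seed(9)
  write_imzml(sim$dataset, f)
  n_spec <- length(xml2::xml_find_all(
    xml2::xml_ns_strip(xml2::read_xml(f)), ".//spectrum"))
  expect_identical(n_spec, 600L) # 30 x 20 grid
  ds2 <- read_imzml(f)
  expect_identical(dplyr::arrange(ds2$coords, y, x),
                   dplyr::arrange(sim$dataset$coords, y, x))
})

test_that("coordinate gaps are filled as empty pixels with a warning", {
  peaks <- tibble::tibble(x = c(0L, 2L), y = c(0L, 0L),
                          mz = c(500, 600), intensity = c(1, 2))
  ds <- msi_dataset(peaks, coords = peaks[, c("x", "y")],
                    polarity = "positive")
  f <- withr::local_tempfile(fileext = ".imzML")
  set.seed(2)
  write_imzml(ds, f)
  expect_warning(ds2 <- read_imzml(f), "gap")
  expect_identical(nrow(ds2$coords), 3L)
})

test_that("seeded writes are byte-identical", {
  sim <- simulate_msi(default_truth(2, 3, 1, seed = 4), "negative",
                      sim_config(seed = 4))
  f1 <- withr::local_tempfile(fileext = ".imzML")
  f2 <- withr::local_tempfile(fileext = ".imzML")
  set.seed(77); write_imzml(sim$dataset, f1)
  set.seed(77); write_imzml(sim$dataset, f2)
  ibd <- function(p) sub("\\.imzML$", ".ibd", p)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(ibd(f1))),
                   unname(tools::md5sum(ibd(f2))))
})

test_that("missing files produce clear errors", {
  expect_error(read_imzml("nonexistent.imzML"), "no such imzML")
  peaks <- tibble::tibble(x = 0L, y = 0L, mz = 500, intensity = 1)
  ds <- toy_dataset(peaks, nx = 1L, ny = 1L)
  f <- withr::local_tempfile(fileext = ".imzML")
  set.seed(1); write_imzml(ds, f)
  file.remove(sub("\\.imzML$", ".ibd", f))
  expect_error(read_imzml(f), "ibd")
})

test_that("written imzML is readable by an independent parser", {
  sim <- simulate_msi(default_truth(2, 2, 1, seed = 6), "positive",
                      sim_config(seed = 6, on_dim = c(4L, 4L),
                                 off_dim = c(2L, 2L)))
  f <- withr::local_tempfile(fileext = ".imzML")
  set.seed(13)
  write_imzml(sim$dataset, f)
  script <- paste(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, ii = p.getspectrum(0)",
    "print(json.dumps({'n': len(p.coordinates),",
    "                  'coord0': list(p.coordinates[0][:2]),",
    "                  'mz0': list(map(float, mz[:3])),",
    "                  'i0': list(map(float, ii[:3]))}))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(f)),
            stdout = TRUE, stderr = FALSE))
  res <- jsonlite::fromJSON(out[length(out)])
  expect_identical(res$n, nrow(sim$dataset$coords))
  # parser coordinates are 1-based
  first <- dplyr::arrange(sim$dataset$coords, y, x)[1, ]
  expect_identical(res$coord0, c(first$x + 1L, first$y + 1L))
  own <- dplyr::arrange(read_imzml(f)$peaks, y, x, mz)
  expect_equal(res$mz0, own$mz[1:3], tolerance = 1e-12)
  expect_equal(res$i0, own$intensity[1:3], tolerance = 1e-12)
})

test_that("reading a single mzML MS/MS spectrum goes through mzR", {
  skip_if_not_installed("mzR")
  # write a minimal valid mzML via mzR is not supported; exercise the
  # wrapper against a spectrum serialized by the copy routine below
  sp <- simulate_msms("C43H78NO8P", "PE", seed = 8)
  f <- withr::local_tempfile(fileext = ".mzML")
  writeLines(minimal_mzml(sp$mz, sp$abundance), f)
  got <- read_mzml_spectrum(f)
  expect_equal(got$mz, sp$mz, tolerance = 1e-9)
  expect_equal(got$abundance, sp$abundance, tolerance = 1e-6)
})
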