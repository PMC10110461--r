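make_record <- function(ny = 8, nx = 8, nt = 6, fill_par = 4, fill_perp = 2,
                        seed = NULL) {
  cp <- array(fill_par, dim = c(ny, nx, nt))
  cq <- array(fill_perp, dim = c(ny, nx, nt))
  if (!is.null(seed)) {
    set.seed(seed)
    cp[] <- rpois(length(cp), fill_par)
    cq[] <- rpois(length(cq), fill_perp)
  }
  starss_record(cp, cq, pixel_size = 50e-9,
                bin_edges = seq(0, nt) * 1e-5,
                scheme = list(method = "method1"), seed = seed)
}

test_that("intensity bands assign the documented half-open classes", {
  img <- matrix(c(3, 20, 60, 100, 30, 50, 0, 5, 100), 3, 3)
  m <- segment_by_intensity(img, median_radius = 0)
  lab <- function(v) m$labels[which(img == v)[1]]
  expect_equal(lab(20), m$legend[["cytosol"]])     # 0.20 in (0.05, 0.30]
  expect_equal(lab(60), m$legend[["cluster"]])     # 0.60 > 0.5
  expect_equal(lab(3), m$legend[["background"]])   # 0.03 below all bands
  expect_equal(lab(30), m$legend[["cytosol"]])     # boundary 0.30 inclusive
  expect_equal(lab(50), m$legend[["background"]])  # boundary 0.50 exclusive
  expect_equal(lab(5), m$legend[["background"]])   # boundary 0.05 exclusive
})

test_that("segmentation is scale-invariant, idempotent and hot-pixel robust", {
  set.seed(5)
  img <- matrix(runif(400, 0, 100), 20, 20)
  m1 <- segment_by_intensity(img)
  m2 <- segment_by_intensity(img * 7.3)
  expect_identical(m1$labels, m2$labels)
  m3 <- segment_by_intensity(img)
  expect_identical(m1$labels, m3$labels)
  expect_error(segment_by_intensity(matrix(0, 4, 4)), "all-zero")
  # a single hot pixel must not become the normalizer
  img2 <- matrix(100, 10, 10)
  img2[5, 5] <- 5000
  m4 <- segment_by_intensity(img2)
  expect_lt(m4$provenance$normalizer, 200)
  # generic two-class Otsu segmentation separates a bimodal image
  img3 <- matrix(c(rep(5, 50), rep(80, 50)), 10, 10)
  m5 <- segment_by_intensity(img3, method = "otsu")
  expect_equal(sum(m5$labels == 1), 50)
})

test_that("region aggregation conserves photons exactly", {
  rec <- make_record(seed = 1)
  img <- intensity_image(rec)
  # single label covering everything reproduces the whole-frame curve
  all_map <- structure(list(labels = matrix(1L, 8, 8),
                            legend = c(background = 0L, all = 1L),
                            provenance = list()),
                       class = "segmentation_map")
  expect_warning(cur <- aggregate_region_decays(rec, all_map),
                 "background")
  whole <- vapply(1:6, function(k) sum(rec$counts_parallel[, , k]), 0)
  expect_identical(cur$all$counts_parallel, whole)
  # two disjoint labels plus background sum to the whole frame
  labels <- matrix(0L, 8, 8)
  labels[1:4, ] <- 1L
  labels[5:6, ] <- 2L
  two_map <- structure(list(labels = labels,
                            legend = c(background = 0L, a = 1L, b = 2L),
                            provenance = list()),
                       class = "segmentation_map")
  curves <- aggregate_region_decays(rec, two_map)
  tot <- curves$a$counts_parallel + curves$b$counts_parallel +
    curves$background$counts_parallel
  expect_identical(tot, whole)
  # linearity: doubling one region's counts doubles its curve only
  rec2 <- rec
  rec2$counts_parallel[1:4, , ] <- rec$counts_parallel[1:4, , ] * 2L
  curves2 <- aggregate_region_decays(rec2, two_map)
  expect_identical(curves2$a$counts_parallel, curves$a$counts_parallel * 2)
  expect_identical(curves2$b$counts_parallel, curves$b$counts_parallel)
})

test_that("anisotropy maps recover per-region generative values", {
  ny <- 12; nx <- 12; nt <- 10
  r_true <- matrix(0.1, ny, nx)
  r_true[, 1:6] <- 0.3
  total <- 3000                           # photons per pixel per bin
  set.seed(9)
  cp <- array(rpois(ny * nx * nt, total * (1 + 2 * c(r_true)) / 3),
              dim = c(ny, nx, nt))
  cq <- array(rpois(ny * nx * nt, total * (1 - c(r_true)) / 3),
              dim = c(ny, nx, nt))
  rec <- starss_record(cp, cq, 50e-9, seq(0, nt) * 1e-5)
  m <- anisotropy_map(rec)
  expect_true(all(m$valid))
  expect_equal(mean(m$r[, 1:6]), 0.3, tolerance = 0.02)
  expect_equal(mean(m$r[, 7:12]), 0.1, tolerance = 0.03)
  # isotropic record: r ~ 0 everywhere
  iso <- make_record(fill_par = 500, fill_perp = 500, seed = 2)
  mi <- anisotropy_map(iso)
  expect_lt(max(abs(mi$r[mi$valid])), 0.1)
  expect_equal(mean(mi$r[mi$valid]), 0, tolerance = 0.01)
  # masking: zero threshold keeps every positive pixel, a huge one none
  expect_true(all(anisotropy_map(iso, min_counts = 0)$valid))
  expect_false(any(anisotropy_map(iso, min_counts = 1e9)$valid))
  # window selection uses only the requested bins
  mw <- anisotropy_map(rec, time_window = c(0, 3e-5))
  expect_length(mw$bins_used, 3)
})

test_that("records round-trip through TIFF + sidecar bit-exactly", {
  rec <- make_record(seed = 3)
  stem <- file.path(withr::local_tempdir(), "rec")
  write_record(rec, stem)
  back <- read_record(stem)
  expect_identical(back$counts_parallel, rec$counts_parallel + 0)
  expect_identical(back$counts_perpendicular, rec$counts_perpendicular + 0)
  expect_equal(back$bin_edges, rec$bin_edges)
  expect_equal(back$pixel_size, rec$pixel_size)
  # missing sidecar names the expected file
  expect_error(read_record(file.path(tempdir(), "nope")), "nope.json")
  # sidecar/page mismatch reports both numbers
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  side$shape[3] <- 99
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(read_record(stem), "99.*6|6.*99")
  # counts beyond 16 bits are refused at write time
  rec$counts_parallel[1] <- 70000
  expect_error(write_record(rec, stem), "65535")
})

test_that("record construction validates shapes and bin edges", {
  cp <- array(0, dim = c(4, 4, 3))
  expect_error(starss_record(cp, array(0, dim = c(4, 4, 2)), 1e-7,
                             seq(0, 3) * 1e-5))
  expect_error(starss_record(cp, cp, 1e-7, c(0, 1e-5)), "bin_edges")
  expect_error(starss_record(cp, cp, 1e-7, c(0, 2e-5, 1e-5, 3e-5)),
               "bin_edges")
})
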