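make_m <- function(x, ppm = NULL, groups = NULL) {
  if (is.null(ppm)) ppm <- seq(ncol(x), 1) / 100
  rownames(x) <- NULL
  spectrum_matrix(x, ppm, groups = groups)
}

test_that("spectra TSV writer and reader are inverse", {
  tr <- make_small_truth(seed = 3, noise_sd = 0.01)
  m <- render_spectra(tr$truth, tr$lib, tr$design, resolution = 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(m, path)
  m2 <- load_spectra(path)
  expect_equal(m2$intensities, m$intensities, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(m2$sample_ids, m$sample_ids)
  expect_identical(m2$groups, m$groups)
  expect_equal(m2$ppm, m$ppm)
})

test_that("malformed spectra files are rejected with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample = c("a", "b", "c"), group = "g",
                   `9.0000` = 1:3, `8.9000` = 4:6, `8.8000` = 7:9,
                   `8.7000` = 2:4, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- load_spectra(path)
  expect_equal(dim(m), c(3L, 4L))

  # dropping an interior bucket column breaks axis uniformity
  write.table(df[, -4], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_spectra(path), "uniform")

  df2 <- df; df2[["8.9000"]][2] <- "oops"
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_spectra(path), "non-numeric intensity.*'b'")

  df3 <- df; df3$sample <- c("a", "a", "c")
  write.table(df3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_spectra(path), "duplicate sample ids")
})

test_that("region exclusion zeroes exactly the window and is idempotent", {
  set.seed(1)
  m <- make_m(matrix(runif(3 * 900, 1, 2), 3), ppm = seq(8.995, 0.005, by = -0.01))
  e1 <- exclude_region(m, 4.6, 5.7)
  inwin <- m$ppm >= 4.6 & m$ppm <= 5.7
  expect_true(all(e1$intensities[, inwin] == 0))
  expect_identical(e1$intensities[, !inwin], m$intensities[, !inwin])
  expect_identical(exclude_region(e1, 4.6, 5.7)$intensities, e1$intensities)
  # window outside the occupied axis: identity
  expect_identical(exclude_region(m, 10, 11)$intensities, m$intensities)
  expect_error(exclude_region(m, 5.7, 4.6), "lo < hi")
})

test_that("total-sum normalisation preserves proportions and reports rows", {
  m <- make_m(rbind(c(1, 1, 2), c(2, 2, 4), c(10, 0, 0)))
  n <- normalize_total_sum(m, 100)
  expect_equal(unname(n$intensities[1, ]), c(25, 25, 50))
  expect_equal(unname(rowSums(n$intensities)), rep(100, 3), tolerance = 1e-9)
  expect_true(n$normalized)
  # idempotent
  expect_equal(normalize_total_sum(n, 100)$intensities, n$intensities,
               tolerance = 1e-12)
  set.seed(2)
  big <- make_m(matrix(runif(50 * 40, 0.1, 5), 50))
  expect_equal(unname(rowSums(normalize_total_sum(big)$intensities)),
               rep(100, 50), tolerance = 1e-9)
  bad <- make_m(rbind(c(1, 2, 3), c(0, 0, 0)))
  expect_error(normalize_total_sum(bad), "S2")
})

test_that("segment alignment recovers forced shifts and reduces jitter error", {
  set.seed(3)
  base <- exp(-((1:200) - 100)^2 / 50)
  x <- rbind(base, base, base, base)
  m <- make_m(x)
  a <- align_segments(m, max_shift = 5)
  expect_true(all(attr(a, "shifts") == 0))

  # one sample displaced by +3 buckets: alignment shifts it back by -3
  x2 <- x
  x2[2, ] <- c(rep(0, 3), base[1:197])
  a2 <- align_segments(make_m(x2), max_shift = 5)
  expect_equal(unname(attr(a2, "shifts")[2, 1]), -3)
  expect_error(align_segments(m, segment_bounds = list(c(0.99, 1.0)),
                              max_shift = 5), "narrower")

  # jittered synthetic spectra: post-alignment peak-centre error shrinks
  lib <- make_metabolite_library(4, seed = 6, max_peaks = 1)
  d <- simulation_design(group_sizes = c(A = 10, B = 10), noise_sd = 0.001,
                         jitter_sd = 0.003, background = NULL, seed = 6)
  tr <- simulate_concentrations(d, lib)
  msp <- render_spectra(tr, lib, d, resolution = 0.001)
  segs <- lapply(tr$assignment_map, function(w)
    c(min(w[, "lo"]) - 0.006, max(w[, "hi"]) + 0.006))
  al <- align_segments(msp, segment_bounds = segs, max_shift = 5)
  err <- function(mm) {
    e <- 0
    for (met in names(lib)) {
      ctr <- lib[[met]]$peaks[1, "center"]
      w <- lib[[met]]$window
      sel <- which(mm$ppm >= w[1] - 0.006 & mm$ppm <= w[2] + 0.006)
      for (i in seq_len(nrow(mm$intensities)))
        e <- e + abs(mm$ppm[sel][which.max(mm$intensities[i, sel])] - ctr)
    }
    e
  }
  expect_lt(err(al), err(msp))
})

test_that("relative integrals recover planted concentrations", {
  # single metabolite occupying the whole axis integrates to the row total
  m <- normalize_total_sum(make_m(matrix(runif(12, 1, 2), 3)))
  map1 <- assignment_map(list(all = list(c(0, 1))))
  ri <- relative_integrals(m, map1)
  expect_equal(ri$all, rep(100, 3), tolerance = 1e-9)

  # zero-intensity window integrates to zero
  x <- matrix(1, 3, 10); x[, 1:5] <- 0
  m2 <- make_m(x, ppm = seq(0.95, 0.05, by = -0.1))
  map2 <- assignment_map(list(hi = list(c(0.55, 0.95)), lo = list(c(0.05, 0.45))))
  ri2 <- suppressWarnings(relative_integrals(m2, map2))
  expect_equal(ri2$hi, rep(0, 3))
  expect_equal(ri2$lo, rep(5, 3))
  expect_error(suppressWarnings(
    relative_integrals(m2, assignment_map(list(out = list(c(2, 3)))))),
    "no window")

  # integrals proportional to planted concentrations at zero noise
  # (raw intensities: total-sum normalisation would fold every metabolite
  # into each integral through the shared row total)
  tr <- make_small_truth(seed = 8, noise_sd = 0, jitter_sd = 0)
  msp <- render_spectra(tr$truth, tr$lib, tr$design, resolution = 0.001)
  ri3 <- suppressWarnings(relative_integrals(msp, tr$truth$assignment_map))
  for (met in names(tr$lib))
    expect_gt(cor(ri3[[met]], tr$truth$concentrations[, met]), 0.99)
})

test_that("assignment maps reject overlapping windows and round-trip JSON", {
  expect_error(assignment_map(list(m = list(c(1, 2), c(1.5, 3)))), "overlap")
  map <- assignment_map(list(a = list(c(1.2, 1.4)), b = list(c(2, 2.1), c(2.5, 2.6))))
  path <- withr::local_tempfile(fileext = ".json")
  write_assignment_map(map, path)
  map2 <- read_assignment_map(path)
  expect_equal(unclass(map2), unclass(map), tolerance = 1e-12)
})
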