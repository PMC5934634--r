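test_that("construction folds the lower triangle and rejects bad input", {
  m <- tiny_matrix()
  expect_equal(contact_at(m, c(0, 0, 1, 1), c(0, 1, 0, 1)), c(5, 3, 3, 2))

  # lower-triangle input is folded
  m2 <- contact_matrix(m$bins, data.frame(bin1 = c(0, 1, 1),
                                          bin2 = c(0, 0, 1),
                                          count = c(5, 3, 2)))
  expect_equal(m2$pixels, m$pixels)

  # duplicate after folding is an error, as are range/negative violations
  expect_error(contact_matrix(m$bins,
                              data.frame(bin1 = c(0, 1), bin2 = c(1, 0),
                                         count = c(3, 3))),
               "duplicate")
  expect_error(contact_matrix(m$bins,
                              data.frame(bin1 = 0, bin2 = 5, count = 1)),
               "out of range")
  expect_error(contact_matrix(m$bins,
                              data.frame(bin1 = 0, bin2 = 1, count = -2)),
               "negative")
})

test_that("triplet round-trip is the identity on entries", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- tiny_matrix()
  write_contacts(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# resolution=100$")
  expect_length(lines, 4)                      # header + 3 sorted entries
  expect_equal(read_contacts(path, m$bins)$pixels, m$pixels)

  # empty matrix writes a valid, readable file
  e <- contact_matrix(m$bins, NULL)
  write_contacts(e, path)
  expect_equal(nrow(read_contacts(path, m$bins)$pixels), 0L)

  # larger simulated matrix round-trips too
  bins <- bin_table(c(chr1 = 60L, chr2 = 40L), resolution = 1e5)
  big <- random_matrix(bins, seed = 3)
  write_contacts(big, path)
  expect_equal(read_contacts(path, bins)$pixels, big$pixels)

  # resolution mismatch between header and bin table is caught
  wrong <- bin_table(c(chr1 = 60L, chr2 = 40L), resolution = 5e4)
  expect_error(read_contacts(path, wrong), "resolution")
})

test_that("contact profile is the genome-wide row sum, diagonal once", {
  expect_equal(contact_profile(tiny_matrix()), c(8, 5))
  bins <- bin_table(c(chrA = 5L), resolution = 100)
  expect_equal(contact_profile(contact_matrix(bins, NULL)), rep(0, 5))

  # dense row-sum oracle on a 200-bin simulated matrix
  bins <- bin_table(c(chr1 = 120L, chr2 = 80L), resolution = 1e5)
  m <- random_matrix(bins, density = 0.2, seed = 11)
  expect_equal(contact_profile(m), rowSums(as.matrix(m)))

  # masked bins are NA and contribute nothing
  mm <- set_mask(m, seq_len(200) %in% c(1, 50))
  t <- contact_profile(mm)
  expect_true(all(is.na(t[c(1, 50)])))
  M <- as.matrix(m)
  M[c(1, 50), ] <- 0; M[, c(1, 50)] <- 0
  expect_equal(t[-c(1, 50)], rowSums(M)[-c(1, 50)])
})

test_that("auto_mask flags empty and low-signal bins", {
  bins <- bin_table(c(chrA = 3L), resolution = 100)
  m <- contact_matrix(bins, data.frame(bin1 = c(0, 0), bin2 = c(0, 2),
                                       count = c(4, 5)))
  expect_equal(auto_mask(m), c(FALSE, TRUE, FALSE))     # profile (8, 0, 5)
  expect_equal(auto_mask(m, min_total = 100), rep(TRUE, 3))

  # capture-style design: signal in 60 of 600 bins, exactly the rest masked
  bins <- bin_table(c(chr1 = 600L), resolution = 1e5)
  on_target <- 200:259
  ut <- expand.grid(i = on_target, j = on_target)
  ut <- ut[ut$i <= ut$j, ]
  set.seed(4)
  cap <- contact_matrix(bins, data.frame(bin1 = ut$i, bin2 = ut$j,
                                         count = rpois(nrow(ut), 5) + 1))
  expect_equal(which(!auto_mask(cap)) - 1L, on_target)
})

test_that("apply_bin_correction divides by sqrt(v_i v_j)", {
  m <- tiny_matrix()
  expect_equal(apply_bin_correction(m, c(1, 1))$pixels, m$pixels)
  expect_equal(apply_bin_correction(m, c(4, 4))$pixels$count, c(5, 3, 2) / 4)
  # v = (1, 4): x00 / 1, x01 / 2, x11 / 4
  expect_equal(apply_bin_correction(m, c(1, 4))$pixels$count,
               c(5, 3 / 2, 2 / 4))
  expect_error(apply_bin_correction(m, c(1, 0)), "unmasked")
  expect_error(apply_bin_correction(m, c(1, NA)), "unmasked")

  # inverse round-trip recovers the matrix to 1e-10
  bins <- bin_table(c(chr1 = 50L), resolution = 1e5)
  big <- random_matrix(bins, seed = 2)
  v <- runif(50, 0.5, 2)
  back <- apply_bin_correction(apply_bin_correction(big, v), 1 / v)
  expect_equal(back$pixels$count, big$pixels$count, tolerance = 1e-10)

  # masked bins receive no correction and their entries are dropped
  mm <- set_mask(big, seq_len(50) == 3)
  corr <- apply_bin_correction(mm, v)
  expect_false(any(corr$pixels$bin1 == 2 | corr$pixels$bin2 == 2))
})

test_that("rank-1 matrices flatten under the squared-profile correction", {
  # no-noise outer-product matrix: v = (t_i / mean(t))^2 gives a flat profile
  n <- 40
  b <- runif(n, 0.5, 3)
  M <- outer(b, b)
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  bins <- bin_table(c(chrA = as.integer(n)), resolution = 1e5)
  m <- contact_matrix(bins, data.frame(bin1 = ut[, 1] - 1L,
                                       bin2 = ut[, 2] - 1L, count = M[ut]))
  t <- contact_profile(m)
  flat <- contact_profile(apply_bin_correction(m, (t / mean(t))^2))
  expect_lt(diff(range(flat)) / mean(flat), 1e-10)
})

test_that("symmetry holds for random index pairs", {
  bins <- bin_table(c(chr1 = 70L, chr2 = 30L), resolution = 1e5)
  m <- random_matrix(bins, seed = 9)
  set.seed(1)
  i <- sample(0:99, 1000, replace = TRUE)
  j <- sample(0:99, 1000, replace = TRUE)
  expect_equal(contact_at(m, i, j), contact_at(m, j, i))
})

test_that("BED bin tables and bedGraph tracks round-trip through files", {
  bins <- bin_table(c(chr1 = 30L, chr2 = 20L), resolution = 1e5)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bins(bins, bed)
  expect_equal(read_bins(bed), bins)

  bg <- withr::local_tempfile(fileext = ".bedGraph")
  v <- round(runif(50), 4)
  write_track(v, bins, bg)
  expect_equal(read_track(bg, bins), v)

  # a track that does not tile the bin table exactly is rejected
  half <- bin_table(c(chr1 = 30L), resolution = 1e5)
  write_track(round(runif(30), 4), half, bg)
  expect_error(read_track(bg, bins), "tile")
})
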