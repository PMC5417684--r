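test_that("segmentation recovers phantom boundaries within two pixels", {
  b <- simulate_bscan(mid_phantom_spec(seed = 21))
  seg <- segment_layers(b)
  tr <- b$truth
  for (nm in c("epithelium_row", "bowman_row", "endothelium_row")) {
    err <- abs(seg[[nm]] - tr[[nm]])
    expect_gte(mean(err <= 2, na.rm = TRUE), 0.95)
  }
  expect_lte(abs(seg$apex_column - b$spec$apex_column), 2)
})

test_that("layer ordering invariant holds across random phantoms", {
  for (seed in 1:100) {
    b <- simulate_bscan(random_small_spec(seed))
    seg <- segment_layers(b)
    ok <- !is.na(seg$epithelium_row)
    expect_true(all(seg$epithelium_row[ok] < seg$bowman_row[ok]))
    expect_true(all(seg$bowman_row[ok] < seg$endothelium_row[ok]))
    expect_true(seg$apex_column %in% which(ok))
  }
})

test_that("segmentation fails loudly on a featureless image", {
  flat <- bscan(matrix(0.5, 300, 400))
  expect_error(segment_layers(flat),
               class = "octspeckle_segmentation_failure")
})

test_that("shifting the apex shifts the recovered curves identically", {
  b1 <- simulate_bscan(mid_phantom_spec(seed = 33, apex_column = 256))
  b2 <- simulate_bscan(mid_phantom_spec(seed = 33, apex_column = 156))
  # ground truth is an exact translation over the common span
  cols <- 30:350
  expect_identical(b2$truth$epithelium_row[cols],
                   b1$truth$epithelium_row[cols + 100L])
  s1 <- segment_layers(b1)
  s2 <- segment_layers(b2)
  expect_equal(s2$apex_column, s1$apex_column - 100L, tolerance = 2)
  d <- s2$epithelium_row[cols] - s1$epithelium_row[cols + 100L]
  expect_lt(max(abs(d), na.rm = TRUE), 2)
})

test_that("apex finding: symmetry, phantom truth, monotone failure", {
  cols <- seq_len(1024)
  arc <- 200 + (cols - 512)^2 / 2000
  expect_identical(find_apex(arc), 512L)
  expect_error(find_apex(seq(100, 300, length.out = 200)),
               class = "octspeckle_apex_error")
  expect_error(find_apex(c(NA, NA, 1, 2)),
               class = "octspeckle_apex_error")
  b <- simulate_bscan(mid_phantom_spec(seed = 44, apex_column = 200))
  expect_lte(abs(find_apex(segment_layers(b)) - 200), 2)
})

test_that("the ROI is pure stroma and its placement is deterministic", {
  b <- simulate_bscan(mid_phantom_spec(seed = 55))
  seg <- segment_layers(b)
  roi <- select_roi(b, seg)
  expect_identical(roi$n_rows, 250L)
  expect_identical(roi$n_columns, 450L)
  tr <- b$truth
  cols <- roi$left_column:(roi$left_column + roi$n_columns - 1L)
  rows <- roi$top_row:(roi$top_row + roi$n_rows - 1L)
  expect_true(all(roi$top_row >= tr$bowman_row[cols]))
  expect_true(all(max(rows) <= tr$endothelium_row[cols] - 1L))
  roi2 <- select_roi(b, segment_layers(b))
  expect_identical(unclass(roi), unclass(roi2))
})

test_that("a cornea too thin for the ROI raises roi-out-of-tissue", {
  sp <- mid_phantom_spec(seed = 66, cct_um = 300, epithelium_um = 55)
  b <- simulate_bscan(sp)
  expect_error(select_roi(b, segment_layers(b)),
               class = "octspeckle_roi_error")
})

test_that("ROI selection ignores a constant intensity offset", {
  b <- simulate_bscan(mid_phantom_spec(seed = 10))
  r1 <- select_roi(b, segment_layers(b))
  b$pixels <- b$pixels + 5
  r2 <- select_roi(b, segment_layers(b))
  expect_identical(unclass(r1), unclass(r2))
})

test_that("intensity extraction: size, order, linearity guard", {
  b <- simulate_bscan(mid_phantom_spec(seed = 3))
  roi <- select_roi(b, segment_layers(b))
  v <- extract_intensities(b, roi)
  expect_length(v, 250L * 450L)
  expect_true(all(v >= 0))
  # row-major: first n_columns values are the first ROI row
  expect_identical(v[seq_len(450)],
                   b$pixels[roi$top_row,
                            roi$left_column:(roi$left_column + 449L)])
  # constant image returns the constant
  cb <- bscan(matrix(7, 400, 500))
  roi_c <- structure(list(top_row = 10L, left_column = 10L, n_rows = 250L,
                          n_columns = 450L), class = "oct_roi")
  expect_true(all(extract_intensities(cb, roi_c) == 7))
  # log-compressed images are refused, never silently de-compressed
  lg <- bscan(matrix(1, 300, 500), intensity_scale = "log-compressed")
  expect_error(extract_intensities(lg, roi_c),
               class = "octspeckle_log_compressed_error")
  # saturation mask drops the brightest tail when enabled
  v99 <- extract_intensities(b, roi, saturation_percentile = 99)
  expect_lt(length(v99), length(v))
  expect_lte(max(v99), quantile(v, 0.99, names = FALSE))
})

test_that("ROI speckle is KS-consistent with the generating GG law", {
  b <- simulate_bscan(mid_phantom_spec(seed = 91), gg = table2_gg)
  roi <- select_roi(b, segment_layers(b))
  v <- sort(extract_intensities(b, roi))
  n <- length(v)
  Fv <- pgg(v, table2_gg["a"], table2_gg["v"], table2_gg["p"])
  D <- max(abs(Fv - (seq_len(n) - 1) / n), abs(Fv - seq_len(n) / n))
  expect_lt(D, 1.628 / sqrt(n))  # 1% KS critical value
})
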