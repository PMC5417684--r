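test_that("phantom construction identities hold", {
  sp <- mid_phantom_spec(seed = 1)
  b <- simulate_bscan(sp)
  tr <- b$truth
  apex <- sp$apex_column
  # stroma thickness at the apex is the rounded axial extent of the stroma
  expect_identical(
    tr$endothelium_row[apex] - tr$bowman_row[apex],
    as.integer(round((sp$cct_um - sp$epithelium_um) / sp$axial_pixel_um)))
  # anterior surface is lowest (smallest row) at the apex; the rounded sag
  # is flat near the apex, so assert membership in the minimum plateau and
  # its symmetry around the apex
  expect_identical(tr$epithelium_row[apex], min(tr$epithelium_row))
  plateau <- which(tr$epithelium_row == min(tr$epithelium_row))
  expect_equal(mean(range(plateau)), apex, tolerance = 1)
  # boundary ordering everywhere
  expect_true(all(tr$epithelium_row < tr$bowman_row))
  expect_true(all(tr$bowman_row < tr$endothelium_row))
  expect_true(all(b$pixels >= 0))
})

test_that("phantom generation is deterministic under a seed", {
  b1 <- simulate_bscan(mid_phantom_spec(seed = 77))
  b2 <- simulate_bscan(mid_phantom_spec(seed = 77))
  expect_identical(b1$pixels, b2$pixels)
  b3 <- simulate_bscan(mid_phantom_spec(seed = 78))
  expect_false(identical(b1$pixels, b3$pixels))
})

test_that("true-stroma pixels carry the generating GG statistics", {
  sp <- phantom_spec(seed = 12)  # full size: >= 1e5 stroma pixels
  b <- simulate_bscan(sp, gg = table2_gg)
  tr <- b$truth
  stroma <- unlist(lapply(seq_len(nrow(tr)), function(j)
    b$pixels[tr$bowman_row[j]:(tr$endothelium_row[j] - 1L), j]))
  expect_gt(length(stroma), 1e5)
  fit <- fit_gg(stroma)
  expect_lt(max(abs(coef(fit) / table2_gg - 1)), 0.05)
})

test_that("impossible phantom geometry is refused", {
  expect_error(phantom_spec(cct_um = 50, epithelium_um = 55),
               class = "octspeckle_domain_error")
  expect_error(phantom_spec(apex_column = 3000),
               class = "octspeckle_domain_error")
  # cornea deeper than the raster
  sp <- phantom_spec(n_axial = 300, apex_row = 200)
  expect_error(simulate_bscan(sp), class = "octspeckle_geometry_error")
  # lateral aperture wider than the anterior radius
  sp2 <- phantom_spec(lateral_pixel_um = 40, anterior_radius_mm = 7.75)
  expect_error(simulate_bscan(sp2), class = "octspeckle_geometry_error")
})

test_that("B-scan images round-trip through TIFF and PNG with sidecars", {
  sp <- random_small_spec(5)
  b <- simulate_bscan(sp)
  for (ext in c("tif", "png")) {
    path <- file.path(withr::local_tempdir(), paste0("phantom.", ext))
    write_bscan(b, path)
    expect_true(file.exists(paste0(path, ".json")))
    truth_csv <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
    expect_true(file.exists(truth_csv))
    tr <- utils::read.csv(truth_csv)
    expect_identical(tr$column, b$truth$column - 1L)  # 0-based on disk
    expect_identical(tr$bowman_row, b$truth$bowman_row - 1L)
    r <- read_bscan(path)
    expect_identical(dim(r$pixels), dim(b$pixels))
    expect_identical(r$axial_pixel_um, b$axial_pixel_um)
    # quantisation error is bounded by one step (16-bit TIFF, 8-bit PNG)
    step <- max(b$pixels) / if (ext == "tif") 65535 else 255
    expect_lt(max(abs(r$pixels - b$pixels)), step)
  }
  expect_error(read_bscan("does/not/exist.tif"),
               class = "octspeckle_io_error")
  expect_error(write_bscan(b, "phantom.bmp"),
               class = "octspeckle_io_error")
})
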