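test_that("simulated stacks round-trip through multi-page TIFF with sidecar", {
  sim <- simulate_stack(sim_scene(width = 16, height = 12, n_frames = 20,
                                  coverage_fraction = 0.5, seed = 5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path, bit_depth = 8)
  back <- read_stack(path)
  expect_equal(back$fps, 500)
  expect_equal(dim(back$frames), dim(sim$stack$frames))
  expect_equal(as.numeric(back$frames), as.numeric(sim$stack$frames))

  path16 <- withr::local_tempfile(fileext = ".tif")
  st16 <- frame_stack(sim$stack$frames * 256, fps = 250)
  write_stack(st16, path16, bit_depth = 16)
  back16 <- read_stack(path16)
  expect_equal(back16$fps, 250)
  expect_equal(as.numeric(back16$frames), as.numeric(st16$frames))
})

test_that("a 3-frame 8x8 simulator TIFF round-trips its geometry and rate", {
  sc <- sim_scene(width = 8, height = 8, n_frames = 3, coverage_fraction = 0,
                  noise_sd = 0, seed = 1)
  # frame_stack itself requires T >= 2; 3 frames is written and read verbatim
  sim <- simulate_stack(sc)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  fs <- read_stack(path)
  expect_equal(n_frames(fs), 3)
  expect_equal(unname(frame_dim(fs)), c(8, 8))
  expect_equal(fs$fps, 500)
})

test_that("raw binaries derive the frame count from the byte count", {
  tmp <- withr::local_tempfile(fileext = ".raw")
  H <- 16L; W <- 12L; T <- 25L
  set.seed(3)
  vals <- sample(0:65535, T * H * W, replace = TRUE)
  writeBin(as.integer(vals), tmp, size = 2, endian = "little")
  meta <- stack_metadata(fps = 500, width = W, height = H, bit_depth = 16)
  fs <- read_stack(tmp, metadata = meta)
  expect_equal(n_frames(fs), file.info(tmp)$size / (H * W * 2))
  expect_equal(n_frames(fs), T)
  # frame layout: frame-major, row-major within a frame
  expect_equal(as.numeric(fs$frames[1, 1, ]), as.numeric(vals[1:W]))
  expect_equal(as.numeric(fs$frames[2, 1, 1]), as.numeric(vals[H * W + 1]))

  # truncated file: error names the failing frame index
  writeBin(as.integer(vals[1:(2 * H * W + 7)]), tmp, size = 2, endian = "little")
  expect_error(read_stack(tmp, metadata = meta), "frame 2")
})

test_that("a missing frame rate is an explicit error, never a default", {
  sim <- simulate_stack(sim_scene(width = 8, height = 8, n_frames = 16, seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  file.remove(paste0(path, ".meta.txt"))
  expect_error(read_stack(path), "frame rate unknown")
  expect_error(stack_metadata(), "frame rate unknown")
  # explicit metadata rescues the same file
  fs <- read_stack(path, metadata = stack_metadata(fps = 500))
  expect_equal(fs$fps, 500)
})

test_that("multi-channel TIFF pages collapse to channel-mean luminance", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  set.seed(8)
  rgb <- array(sample(0:255, 6 * 5 * 3, replace = TRUE) / 255, dim = c(6, 5, 3))
  tiff::writeTIFF(list(rgb, rgb), tmp, bits.per.sample = 8)
  fs <- read_stack(tmp, metadata = stack_metadata(fps = 100))
  expect_equal(unname(frame_dim(fs)), c(6, 5))
  expect_equal(fs$frames[1, , ], apply(round(rgb * 255), c(1, 2), mean))
})

test_that("frequency maps render on the 0-25 Hz monochrome ramp", {
  png_of <- function(map) {
    path <- withr::local_tempfile(fileext = ".png")
    write_cbf_map_image(map, path, cell_px = 1)
    png::readPNG(path)
  }
  # all blocks non-moving: all black
  expect_true(all(png_of(make_fake_map(4, 4)) == 0))
  # a single 12.5 Hz block renders mid-grey (50% of the ramp), rest black
  img <- png_of(make_fake_map(4, 4, moving_freqs = 12.5))
  expect_equal(sum(img > 0), 1)
  expect_lt(abs(img[1, 1] - 0.5), 1 / 255)
  # 25 Hz renders white; 30 Hz (in-band, above the ramp top) clips to white
  expect_equal(max(png_of(make_fake_map(4, 4, moving_freqs = 25))), 1)
  img30 <- png_of(make_fake_map(4, 4, moving_freqs = 30))
  expect_equal(img30[1, 1], 1)
})

test_that("rendering is a pure function of the map", {
  map <- make_fake_map(6, 6, moving_freqs = c(5, 10, 20, 40))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_cbf_map_image(map, p1)
  write_cbf_map_image(map, p2)
  expect_identical(readBin(p1, "raw", file.info(p1)$size),
                   readBin(p2, "raw", file.info(p2)$size))
})

test_that("map tables and ground truth round-trip through tabular text", {
  sim <- simulate_stack(sim_scene(width = 24, height = 24, n_frames = 64, seed = 4))
  m <- compute_cbf_map(sim$stack, fov_id = "fov3")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_cbf_map_table(m, tp)
  m2 <- read_cbf_map_table(tp)
  expect_equal(m2$fov_id, "fov3")
  expect_equal(m2$fps, m$fps)
  expect_equal(m2$grid$n_blocks, m$grid$n_blocks)
  expect_equal(m2$results$is_moving, m$results$is_moving)
  expect_equal(m2$results$freq_hz, m$results$freq_hz)
  expect_equal(m2$results$peak_power, m$results$peak_power, tolerance = 1e-6)

  gp <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, gp)
  t2 <- read_ground_truth(gp)
  expect_identical(t2$moving_mask, sim$truth$moving_mask)
  expect_equal(t2$freq_map, sim$truth$freq_map)
  expect_equal(t2$realized_coverage, sim$truth$realized_coverage)
})
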