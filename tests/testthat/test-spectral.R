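test_that("tiling follows floor division and reports residual pixels", {
  g <- tile(128, 128, spectral_params())
  expect_equal(c(g$n_rows, g$n_cols, g$n_blocks, g$residual_pixels),
               c(32, 32, 1024, 0))
  g <- tile(10, 10, spectral_params())
  expect_equal(c(g$n_rows, g$n_cols, g$n_blocks, g$residual_pixels), c(2, 2, 4, 36))
  g <- tile(4, 4, spectral_params())
  expect_equal(g$n_blocks, 1)
  expect_error(tile(3, 10, spectral_params()), "smaller than one")
  expect_error(spectral_params(block_size = 3), ">= 4")
  expect_error(spectral_params(f_min = 10, f_max = 5), "f_min < f_max")
})

test_that("block power spectrum matches a naive DFT oracle", {
  set.seed(41)
  for (T in c(16, 24, 33, 64)) {
    for (win in c("none", "hann")) {
      for (det in c(TRUE, FALSE)) {
        arr <- array(100 + 20 * stats::rnorm(T * 16), dim = c(T, 4, 4))
        st <- frame_stack(abs(arr), fps = 500)
        p <- spectral_params(window = win, detrend = det, f_max = 50)
        got <- block_spectrum(st, 0, 0, p)
        want <- naive_dft_power(matrix(st$frames, T, 16), 500,
                                detrend = det, window = win)
        expect_equal(got$frequencies, want$frequencies)
        scale <- max(want$power)
        expect_lt(max(abs(got$power - want$power)) / scale, 1e-9)
      }
    }
  }
})

test_that("spectral power sums to detrended signal energy (rectangular window)", {
  set.seed(42)
  arr <- array(100 + 15 * stats::rnorm(64 * 16), dim = c(64, 4, 4))
  st <- frame_stack(abs(arr), fps = 500)
  b <- block_spectrum(st, 0, 0, spectral_params(window = "none"))
  xt <- matrix(st$frames, 64, 16)
  energy <- mean(colSums(sweep(xt, 2, colMeans(xt))^2))
  expect_lt(abs(sum(b$power) - energy) / energy, 1e-9)
})

test_that("bin-aligned tone concentrates in its bin and phase shifts cannot cancel it", {
  # 14 Hz at fps 500, T 250: bin 7 of the 2 Hz grid
  st <- make_sine_stack(250, 4, 4, freq = 14, fps = 500)
  p <- spectral_params(window = "none")
  b <- block_spectrum(st, 0, 0, p)
  i14 <- which(b$frequencies == 14)
  expect_equal(which.max(b$power), i14)
  expect_gt(b$power[i14] / sum(b$power), 0.999)

  # two half-blocks in phase opposition: power averaging keeps the peak,
  # amplitude averaging (the block-mean signal) cancels to nothing
  tt <- 0:249
  s1 <- 120 + 30 * sin(2 * pi * 14 * tt / 500)
  s2 <- 120 + 30 * sin(2 * pi * 14 * tt / 500 + pi)
  arr <- array(0, dim = c(250, 4, 4))
  arr[, , 1:2] <- rep(s1, 8)
  arr[, , 3:4] <- rep(s2, 8)
  st2 <- frame_stack(arr, fps = 500)
  b2 <- block_spectrum(st2, 0, 0, p)
  expect_equal(b2$frequencies[which.max(b2$power)], 14)
  expect_equal(b2$power[i14], b$power[i14], tolerance = 1e-12)
  mean_sig <- rowMeans(matrix(arr, 250, 16))     # amplitude-averaged signal
  expect_lt(max(abs(mean_sig - 120)), 1e-10)     # cancels exactly
  d <- classify_block(b2, p)
  expect_true(d$is_moving)
})

test_that("dominant frequency respects inclusive band edges and breaks ties downward", {
  # rectangular window: bin-aligned tones have zero leakage, so the band
  # edges are probed exactly
  p <- spectral_params(window = "none")
  for (f in c(2, 50)) {  # edges are inclusive
    st <- make_sine_stack(500, 4, 4, freq = f, fps = 500)
    b <- block_spectrum(st, 0, 0, p)
    dom <- dominant_frequency(b, p)
    expect_equal(dom$freq_hz, f)
    expect_true(classify_block(b, p)$is_moving)
  }
  for (f in c(1, 60)) {  # outside the detection threshold
    st <- make_sine_stack(500, 4, 4, freq = f, fps = 500)
    b <- block_spectrum(st, 0, 0, p)
    expect_false(classify_block(b, p)$is_moving)
  }
  # exact tie: lower frequency wins
  spec <- make_fake_spectrum(frequencies = seq(0, 50, by = 2),
                             power = c(0, rep(1, 25)))
  expect_equal(dominant_frequency(spec, p)$freq_hz, 2)
  # zero in-band power: absent
  spec0 <- make_fake_spectrum(frequencies = seq(0, 50, by = 2),
                              power = c(5, rep(0, 25)))
  expect_null(dominant_frequency(spec0, p))
})

test_that("classification separates oscillation from constant and noise blocks", {
  p <- spectral_params()
  const <- frame_stack(array(100, dim = c(64, 4, 4)), fps = 500)
  b <- block_spectrum(const, 0, 0, p)
  expect_equal(sum(b$power[-1]), 0)              # zero variance, zero power
  expect_false(classify_block(b, p)$is_moving)

  tone <- make_sine_stack(250, 4, 4, freq = 14, fps = 500)
  expect_true(classify_block(block_spectrum(tone, 0, 0, p), p)$is_moving)

  set.seed(11)
  fp <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    arr <- array(abs(120 + 10 * stats::rnorm(64 * 16)), dim = c(64, 4, 4))
    r <- classify_block(block_spectrum(frame_stack(arr, fps = 500), 0, 0, p), p)
    fp <- fp + r$is_moving
  }
  expect_lt(fp / n_rep, 0.02)
})

test_that("whole-field map agrees with the per-block reference path and is deterministic", {
  sim <- simulate_stack(sim_scene(width = 32, height = 32, n_frames = 80,
                                  coverage_fraction = 0.4, seed = 9))
  p <- spectral_params()
  m <- compute_cbf_map(sim$stack, p, fov_id = "f")
  expect_equal(nrow(m$results), m$grid$n_blocks)
  for (i in seq_len(nrow(m$results))) {
    r <- m$results[i, ]
    cb <- classify_block(block_spectrum(sim$stack, r$row, r$col, p), p)
    expect_equal(r$is_moving, cb$is_moving)
    expect_equal(r$peak_power, cb$peak_power, tolerance = 1e-9)
    expect_equal(r$noise_floor, cb$noise_floor, tolerance = 1e-9)
    if (r$is_moving) expect_equal(r$freq_hz, cb$freq_hz)
  }
  m2 <- compute_cbf_map(sim$stack, p, fov_id = "f")
  expect_identical(m$results, m2$results)
})

test_that("half-field motion maps to the correct blocks", {
  tt <- 0:249
  sig <- 120 + 30 * sin(2 * pi * 14 * tt / 500)
  arr <- array(120, dim = c(250, 16, 16))
  arr[, , 1:8] <- rep(sig, 16 * 8)               # left half beats
  m <- compute_cbf_map(frame_stack(arr, fps = 500), fov_id = "half")
  left <- m$results$col < 2
  expect_true(all(m$results$is_moving[left]))
  expect_true(all(!m$results$is_moving[!left]))
  expect_true(all(m$results$freq_hz[left] == 14))
})

test_that("off-bin tones are recovered within one frequency-grid step", {
  for (f in c(14.3, 23.7, 41.1)) {
    st <- make_sine_stack(250, 4, 4, freq = f, fps = 500)
    b <- block_spectrum(st, 0, 0, spectral_params())
    dom <- dominant_frequency(b, spectral_params())
    expect_lte(abs(dom$freq_hz - f), 500 / 250)
  }
})

test_that("added noise never increases detected movement in expectation", {
  count_moving <- function(noise_sd, seeds) {
    mean(vapply(seeds, function(s) {
      sc <- sim_scene(width = 64, height = 64, n_frames = 128,
                      coverage_fraction = 0.3, amplitude = 8,
                      noise_sd = noise_sd, seed = s)
      sum(compute_cbf_map(simulate_stack(sc)$stack)$results$is_moving)
    }, numeric(1)))
  }
  seeds <- 101:106
  lo <- count_moving(3, seeds)
  hi <- count_moving(16, seeds)
  expect_lte(hi, lo)
})

test_that("analysis preconditions are enforced", {
  short <- frame_stack(array(100, dim = c(8, 4, 4)), fps = 500)
  expect_error(block_spectrum(short, 0, 0), "insufficient frames")
  expect_error(compute_cbf_map(short), "insufficient frames")
  slow <- frame_stack(array(100, dim = c(64, 4, 4)), fps = 60)
  expect_error(compute_cbf_map(slow), "Nyquist")
})
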