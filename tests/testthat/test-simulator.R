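test_that("zero and full coverage are exact degenerate cases", {
  sim0 <- simulate_stack(sim_scene(width = 16, height = 16, n_frames = 32,
                                   coverage_fraction = 0, noise_sd = 0, seed = 1))
  expect_false(any(sim0$truth$moving_mask))
  expect_true(all(sim0$stack$frames == 120))
  expect_equal(sim0$truth$realized_coverage, 0)

  # full field at 20 Hz, fps 500: every pixel exactly periodic, period 25 frames
  sim1 <- simulate_stack(sim_scene(width = 8, height = 8, n_frames = 75,
                                   coverage_fraction = 1, freq_field = 20,
                                   noise_sd = 0, seed = 1))
  expect_true(all(sim1$truth$moving_mask))
  expect_equal(sim1$stack$frames[1:50, , ], sim1$stack$frames[26:75, , ])
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- sim_scene(width = 32, height = 32, n_frames = 48, seed = 12)
  a <- simulate_stack(sc)
  b <- simulate_stack(sc)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$moving_mask, b$truth$moving_mask)
  c <- simulate_stack(sim_scene(width = 32, height = 32, n_frames = 48, seed = 13))
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("realised coverage lands within 0.01 of the target", {
  for (f in c(0.15, 0.389, 0.5, 0.8)) {
    sim <- simulate_stack(sim_scene(width = 128, height = 128, n_frames = 16,
                                    coverage_fraction = f, seed = round(100 * f)))
    expect_lte(abs(sim$truth$realized_coverage - f), 0.01)
    expect_equal(sim$truth$realized_coverage,
                 sum(sim$truth$moving_mask) / (128 * 128))
    expect_equal(!is.na(sim$truth$freq_map), sim$truth$moving_mask)
  }
})

test_that("field-of-view series are independent but reproducible", {
  sc <- sim_scene(width = 32, height = 32, n_frames = 32,
                  coverage_fraction = 0.389, seed = 40)
  series <- simulate_fov_series(sc, n_fov = 3)
  expect_length(series, 3)
  expect_false(identical(series[[1]]$stack$frames, series[[2]]$stack$frames))
  again <- simulate_fov_series(sc, n_fov = 3)
  for (i in 1:3) expect_identical(series[[i]]$stack$frames, again[[i]]$stack$frames)
  single <- simulate_fov_series(sc, n_fov = 1)
  expect_identical(single[[1]]$stack$frames, series[[1]]$stack$frames)
})

test_that("noiseless scenes recover the scene frequency block by block", {
  sc <- sim_scene(width = 64, height = 64, n_frames = 125, fps = 500,
                  coverage_fraction = 0.5, freq_field = c(8, 16, 24),
                  noise_sd = 0, seed = 33)
  sim <- simulate_stack(sc)
  m <- compute_cbf_map(sim$stack)
  res <- m$results
  bs <- m$grid$block_size
  for (i in which(res$is_moving)) {
    rows <- res$row[i] * bs + 1:bs
    cols <- res$col[i] * bs + 1:bs
    tf <- unique(stats::na.omit(as.vector(sim$truth$freq_map[rows, cols])))
    if (length(tf) == 1) {  # blocks of a single patch: within one grid step
      expect_lte(abs(res$freq_hz[i] - tf), 500 / 125)
    }
  }
  # every fully moving uniform-frequency block must be detected
  fully <- vapply(seq_len(nrow(res)), function(i) {
    rows <- res$row[i] * bs + 1:bs
    cols <- res$col[i] * bs + 1:bs
    all(sim$truth$moving_mask[rows, cols])
  }, logical(1))
  expect_true(all(res$is_moving[fully]))
})

test_that("a metachronal phase gradient does not degrade detection", {
  base <- sim_scene(width = 64, height = 64, n_frames = 128,
                    coverage_fraction = 0.4, noise_sd = 0,
                    freq_field = 15.625,  # bin centre at this frame count
                    phase_gradient = 0, seed = 71)
  steep <- base
  steep$phase_gradient <- 0.8
  m0 <- compute_cbf_map(simulate_stack(base)$stack)
  m1 <- compute_cbf_map(simulate_stack(steep)$stack)
  expect_identical(m0$results$is_moving, m1$results$is_moving)
  expect_equal(m0$results$freq_hz, m1$results$freq_hz)
})

test_that("a dominant fundamental wins over its second harmonic", {
  sc <- sim_scene(width = 16, height = 16, n_frames = 250,
                  coverage_fraction = 1, freq_field = 14, noise_sd = 0,
                  harmonic_weight = 0.4, seed = 5)
  m <- compute_cbf_map(simulate_stack(sc)$stack)
  expect_true(all(m$results$freq_hz == 14))
})

test_that("slow drifting particulates stay below the detection band", {
  sc <- sim_scene(width = 64, height = 64, n_frames = 250,
                  coverage_fraction = 0,
                  artifact_spec = list(n = 3, intensity = 40, sigma_px = 6,
                                       speed_px_per_frame = 0.01),
                  seed = 19)
  sim <- simulate_stack(sc)
  expect_gt(max(sim$stack$frames), 150)  # blobs really are rendered
  pam <- percent_area_moving(compute_cbf_map(sim$stack))
  expect_lte(pam$percent_moving, 2)
})

test_that("super-Nyquist beat frequencies are rejected", {
  expect_error(sim_scene(freq_field = 260, fps = 500), "Nyquist")
  expect_error(sim_scene(freq_field = 0), "Nyquist|positive")
  expect_error(sim_scene(coverage_fraction = 1.2), "0, 1")
})
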