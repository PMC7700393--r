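# Independent oracles and fixture builders. Nothing here touches the
# package's spectral internals: the DFT oracle is a literal sum over time
# points, and sine stacks are assembled directly in R.

# naive one-sided power spectrum of a T x P pixel matrix: per pixel,
# power_k = c_k |sum_t x~_t w_t exp(-2*pi*i*k*t/T)|^2 / T, averaged over
# pixels; c_k doubles every bin except DC and (even T) Nyquist.
naive_dft_power <- function(xt, fps, detrend = TRUE, window = "none") {
  T <- nrow(xt)
  if (detrend) xt <- sweep(xt, 2, colMeans(xt))
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(T - 1)) / (T - 1))) else rep(1, T)
  xt <- xt * w
  ks <- 0:(T %/% 2)
  tt <- 0:(T - 1)
  power <- vapply(ks, function(k) {
    re <- colSums(xt * cos(2 * pi * k * tt / T))
    im <- colSums(xt * sin(2 * pi * k * tt / T))
    ck <- if (k == 0 || (T %% 2 == 0 && k == T / 2)) 1 else 2
    mean(re^2 + im^2) * ck / T
  }, numeric(1))
  list(frequencies = ks * fps / T, power = power)
}

# uniform-field sinusoidal stack built directly in R
make_sine_stack <- function(T, H, W, freq, fps, amplitude = 30, baseline = 120,
                            phase = 0) {
  tt <- 0:(T - 1)
  sig <- baseline + amplitude * sin(2 * pi * freq * tt / fps + phase)
  frame_stack(array(rep(sig, H * W), dim = c(T, H, W)), fps = fps)
}

# hand-built beat-frequency map with a given number of moving blocks
make_fake_map <- function(n_rows, n_cols, moving_freqs = numeric(0),
                          fov_id = "fake", block_size = 4) {
  n <- n_rows * n_cols
  stopifnot(length(moving_freqs) <= n)
  is_moving <- c(rep(TRUE, length(moving_freqs)), rep(FALSE, n - length(moving_freqs)))
  ids <- 0:(n - 1)
  structure(
    list(
      results = tibble::tibble(
        row = as.integer(ids %% n_rows), col = as.integer(ids %/% n_rows),
        is_moving = is_moving,
        freq_hz = c(moving_freqs, rep(NA_real_, n - length(moving_freqs))),
        peak_power = ifelse(is_moving, 100, 0), noise_floor = 1
      ),
      grid = structure(list(block_size = block_size, n_rows = n_rows,
                            n_cols = n_cols, n_blocks = n, residual_pixels = 0L),
                       class = "block_grid"),
      params = spectral_params(block_size = block_size),
      fps = 500, fov_id = fov_id
    ),
    class = "cbf_map"
  )
}

# hand-built block spectrum (for deterministic edge-case checks)
make_fake_spectrum <- function(frequencies, power, noise_floor = 0) {
  structure(list(row = 0L, col = 0L, frequencies = frequencies, power = power,
                 noise_floor = noise_floor, fps = 2 * max(frequencies)),
            class = "block_spectrum")
}

run_cli <- function(args, env = character()) {
  script <- system.file("cli", "ciliometry", package = "ciliometry")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  res <- suppressWarnings(system2(
    rscript, c(script, args),
    env = c(sprintf("R_LIBS=%s", libs), sprintf("R_LIBS_USER=%s", libs), env),
    stdout = TRUE, stderr = TRUE
  ))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
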