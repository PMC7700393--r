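#' Spectral analysis parameters
#'
#' Bundles the tunable parameters of the block-wise Fourier analysis.
#'
#' @param block_size pixels per side of a square analysis block. The minimum
#'   (and default) is 4: smaller boxes leave too few pixels for a stable
#'   block-average spectrum.
#' @param f_min lower edge of the beat-frequency detection band in Hz
#'   (default 2). Peaks below this band (stage drift, slowly translating
#'   debris) are never reported as ciliary movement.
#' @param f_max upper edge of the detection band in Hz (default 50). Must not
#'   exceed the Nyquist frequency `fps / 2` at analysis time.
#' @param power_ratio_k movement-significance multiplier (default 8): a block
#'   counts as moving only when its in-band spectral peak exceeds
#'   `power_ratio_k` times the block's noise floor (the median in-band
#'   power). The default keeps the pure-noise false-positive rate below 1%.
#' @param detrend remove each pixel's temporal mean before the transform
#'   (default `TRUE`), suppressing the DC term and slow offsets.
#' @param window taper applied to each pixel series: `"hann"` (default,
#'   suppresses spectral leakage for beat frequencies that fall between bin
#'   centres) or `"none"` (rectangular; exact for bin-aligned tones).
#'
#' @return An object of class `spectral_params`.
#' @export
#' @examples
#' spectral_params()
#' spectral_params(block_size = 8, window = "none")
spectral_params <- function(block_size = 4, f_min = 2, f_max = 50,
                            power_ratio_k = 8, detrend = TRUE,
                            window = c("hann", "none")) {
  window <- match.arg(window)
  if (!is.numeric(block_size) || length(block_size) != 1L ||
      block_size < 4 || block_size != round(block_size)) {
    stop("`block_size` must be a whole number >= 4 (the minimum box size)", call. = FALSE)
  }
  if (!(is.numeric(f_min) && is.numeric(f_max) && length(f_min) == 1L &&
        length(f_max) == 1L && f_min > 0 && f_min < f_max)) {
    stop("detection band must satisfy 0 < f_min < f_max", call. = FALSE)
  }
  if (!is.numeric(power_ratio_k) || length(power_ratio_k) != 1L || power_ratio_k <= 0) {
    stop("`power_ratio_k` must be positive", call. = FALSE)
  }
  structure(
    list(block_size = as.integer(block_size), f_min = as.numeric(f_min),
         f_max = as.numeric(f_max), power_ratio_k = as.numeric(power_ratio_k),
         detrend = isTRUE(detrend), window = window),
    class = "spectral_params"
  )
}

#' @export
print.spectral_params <- function(x, ...) {
  cat(sprintf(
    "<spectral_params> block %dx%d px, band [%g, %g] Hz, k = %g, detrend = %s, window = %s\n",
    x$block_size, x$block_size, x$f_min, x$f_max, x$power_ratio_k,
    x$detrend, x$window))
  invisible(x)
}

#' Tile a field of view into analysis blocks
#'
#' Partitions an `height x width` field into non-overlapping square blocks of
#' `params$block_size` pixels. Edge residuals smaller than a full block are
#' excluded from analysis; their pixel count is reported so that area
#' accounting stays explicit.
#'
#' @param height,width frame dimensions in pixels.
#' @param params a [spectral_params()] object (only `block_size` is used).
#'
#' @return An object of class `block_grid`: list with `block_size`, `n_rows`,
#'   `n_cols`, `n_blocks` and `residual_pixels`.
#' @export
#' @examples
#' tile(128, 128, spectral_params())  # 32 x 32 = 1024 blocks
#' tile(10, 10, spectral_params())    # 4 blocks, 36 residual pixels
tile <- function(height, width, params = spectral_params()) {
  stopifnot(inherits(params, "spectral_params"))
  bs <- params$block_size
  if (height < bs || width < bs) {
    stop(sprintf("frame (%d x %d) is smaller than one %d x %d block",
                 height, width, bs, bs), call. = FALSE)
  }
  n_rows <- height %/% bs
  n_cols <- width %/% bs
  structure(
    list(block_size = bs, n_rows = n_rows, n_cols = n_cols,
         n_blocks = n_rows * n_cols,
         residual_pixels = height * width - n_rows * n_cols * bs * bs),
    class = "block_grid"
  )
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %d x %d blocks of %d px (%d residual pixels excluded)\n",
              x$n_rows, x$n_cols, x$block_size, x$residual_pixels))
  invisible(x)
}

# --- shared spectral plumbing -----------------------------------------------

.taper <- function(n, window) {
  if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))) else rep(1, n)
}

# one-sided frequency grid and normalisation for a length-T series:
# power_k = c_k |X_k|^2 / T with c_k = 2 except at DC and (even T) Nyquist,
# so that with a rectangular window sum(power) equals the series' energy.
.freq_grid <- function(T, fps) {
  k <- 0:(T %/% 2)
  coef <- rep(2 / T, length(k))
  coef[1] <- 1 / T
  if (T %% 2 == 0) coef[length(k)] <- 1 / T
  list(k = k, freq = k * fps / T, coef = coef)
}

.band_tol <- 1e-9

# reference path: full one-sided pixel-averaged power spectrum via stats::mvfft
.spectrum_core <- function(xt, fps, params) {
  T <- nrow(xt)
  if (params$detrend) xt <- xt - rep(colMeans(xt), each = T)
  xt <- xt * .taper(T, params$window)  # recycles down columns
  X <- stats::mvfft(xt)
  g <- .freq_grid(T, fps)
  P <- Mod(X[g$k + 1L, , drop = FALSE])^2 * g$coef
  power <- if (ncol(P) > 1L) rowMeans(P) else as.numeric(P)
  list(frequencies = g$freq, power = power,
       noise_floor = .noise_floor(g$freq, power, params))
}

.noise_floor <- function(freq, power, params) {
  strict <- freq > params$f_min + .band_tol & freq < params$f_max - .band_tol
  if (any(strict)) return(stats::median(power[strict]))
  inband <- freq >= params$f_min - .band_tol & freq <= params$f_max + .band_tol
  if (any(inband)) return(stats::median(power[inband]))
  0
}

.check_analysis_pre <- function(T, fps, params) {
  if (T < 16L) {
    stop(sprintf("insufficient frames: %d < 16 (frequency resolution would be useless)", T),
         call. = FALSE)
  }
  if (params$f_max > fps / 2 + .band_tol) {
    stop(sprintf("f_max = %g Hz exceeds the Nyquist frequency %g Hz", params$f_max, fps / 2),
         call. = FALSE)
  }
  invisible(TRUE)
}

# --- per-block operations ---------------------------------------------------

#' Power spectrum of one analysis block
#'
#' Extracts the pixel time series of one grid block, optionally removes each
#' pixel's temporal mean, applies the taper, and averages the per-pixel power
#' spectra (squared DFT magnitudes) across the block's pixels. Power — not
#' complex amplitude — is averaged so that spatially phase-shifted cilia (a
#' metachronal wave running across the block) reinforce rather than cancel.
#'
#' The noise floor is the median power over frequencies strictly inside the
#' detection band; for a block dominated by one or a few beating peaks this
#' is a robust estimate of the background level.
#'
#' @param stack a [frame_stack()] with at least 16 frames.
#' @param row,col 0-based block indices within the grid returned by [tile()].
#' @param params a [spectral_params()].
#'
#' @return An object of class `block_spectrum`: list with `row`, `col`,
#'   `frequencies` (Hz, 0 to `fps/2`), `power`, `noise_floor` and `fps`.
#' @export
block_spectrum <- function(stack, row, col, params = spectral_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  T <- n_frames(stack)
  .check_analysis_pre(T, stack$fps, params)
  d <- frame_dim(stack)
  grid <- tile(d[["height"]], d[["width"]], params)
  if (row < 0 || row >= grid$n_rows || col < 0 || col >= grid$n_cols) {
    stop(sprintf("block (%d, %d) outside the %d x %d grid", row, col,
                 grid$n_rows, grid$n_cols), call. = FALSE)
  }
  bs <- grid$block_size
  rows <- row * bs + seq_len(bs)      # 1-based pixel rows
  cols <- col * bs + seq_len(bs)
  xt <- matrix(stack$frames[, rows, cols], nrow = T)
  sc <- .spectrum_core(xt, stack$fps, params)
  structure(
    list(row = as.integer(row), col = as.integer(col),
         frequencies = sc$frequencies, power = sc$power,
         noise_floor = sc$noise_floor, fps = stack$fps),
    class = "block_spectrum"
  )
}

#' @export
print.block_spectrum <- function(x, ...) {
  cat(sprintf("<block_spectrum> block (%d, %d), %d bins to %g Hz, noise floor %.4g\n",
              x$row, x$col, length(x$frequencies), max(x$frequencies), x$noise_floor))
  invisible(x)
}

#' Dominant in-band frequency of a block spectrum
#'
#' Returns the frequency of maximal power among bins inside the detection
#' band (inclusive at both edges; the DC bin is never a candidate). Ties
#' break to the lower frequency. Returns `NULL` when the band contains no
#' bins or the total in-band power is zero.
#'
#' @param spec a [block_spectrum()].
#' @param params a [spectral_params()].
#' @return `NULL`, or a list with `freq_hz` and `peak_power`.
#' @export
dominant_frequency <- function(spec, params = spectral_params()) {
  stopifnot(inherits(spec, "block_spectrum"))
  f <- spec$frequencies
  inband <- f >= params$f_min - .band_tol & f <= params$f_max + .band_tol & f > .band_tol
  if (!any(inband)) return(NULL)
  p <- spec$power[inband]
  # numerically zero band power (e.g. pure out-of-band tones leave only
  # floating-point residue in the band) counts as absent
  if (sum(p) <= 0 || max(p) <= 1e-12 * sum(spec$power)) return(NULL)
  i <- which.max(p)  # first maximum = lowest frequency on ties
  list(freq_hz = f[inband][i], peak_power = p[i])
}

#' Classify a block as moving or non-moving
#'
#' A block is moving when a dominant in-band frequency exists and its peak
#' power exceeds `power_ratio_k` times the block's noise floor. The dominant
#' frequency is recorded only for moving blocks; non-moving blocks
#' contribute to the non-movement area.
#'
#' @inheritParams dominant_frequency
#' @return A one-row tibble with columns `row`, `col`, `is_moving`,
#'   `freq_hz` (NA when non-moving), `peak_power`, `noise_floor`.
#' @export
classify_block <- function(spec, params = spectral_params()) {
  stopifnot(inherits(spec, "block_spectrum"))
  dom <- dominant_frequency(spec, params)
  moving <- !is.null(dom) && dom$peak_power > params$power_ratio_k * spec$noise_floor
  tibble::tibble(
    row = as.integer(spec$row), col = as.integer(spec$col),
    is_moving = moving,
    freq_hz = if (moving) dom$freq_hz else NA_real_,
    peak_power = if (is.null(dom)) 0 else dom$peak_power,
    noise_floor = spec$noise_floor
  )
}

#' Block-wise beat-frequency map of a field of view
#'
#' Applies [tile()], the block power spectrum and the movement
#' classification to every complete block of the field, producing the
#' colour-map substrate: per block the dominant beat frequency, peak power,
#' noise floor and a moving/non-moving call. Deterministic for a fixed stack
#' and parameters.
#'
#' Internally the per-pixel power is evaluated only on the detection-band
#' bins via a compiled direct transform; the values agree with
#' [block_spectrum()] bin for bin.
#'
#' @param stack a [frame_stack()] with at least 16 frames.
#' @param params a [spectral_params()].
#' @param fov_id label for this field of view.
#'
#' @return An object of class `cbf_map`: list with `results` (tibble, one
#'   row per block: `row`, `col`, `is_moving`, `freq_hz`, `peak_power`,
#'   `noise_floor`), `grid`, `params`, `fps`, `fov_id`.
#' @export
#' @examples
#' sc <- sim_scene(width = 32, height = 32, n_frames = 64, coverage_fraction = 0.5,
#'                 seed = 1)
#' sim <- simulate_stack(sc)
#' m <- compute_cbf_map(sim$stack, fov_id = "demo")
#' head(m$results)
compute_cbf_map <- function(stack, params = spectral_params(), fov_id = "") {
  stopifnot(inherits(stack, "frame_stack"))
  T <- n_frames(stack)
  .check_analysis_pre(T, stack$fps, params)
  d <- frame_dim(stack)
  H <- d[["height"]]; W <- d[["width"]]
  grid <- tile(H, W, params)
  bs <- grid$block_size

  g <- .freq_grid(T, stack$fps)
  inband <- g$freq >= params$f_min - .band_tol & g$freq <= params$f_max + .band_tol &
    g$freq > .band_tol
  if (!any(inband)) {
    stop("detection band contains no frequency bins at this fps and frame count",
         call. = FALSE)
  }
  kb <- g$k[inband]
  fb <- g$freq[inband]
  strict <- fb > params$f_min + .band_tol & fb < params$f_max - .band_tol

  st <- .cpp_block_band_stats(stack$frames, H, W, bs, .taper(T, params$window),
                              params$detrend, kb, g$coef[inband], strict)
  # same zero-power guard as dominant_frequency(): by Parseval, st$energy is
  # the total one-sided spectral power of the block
  moving <- st$peak_power > pmax(0, 1e-12 * st$energy) &
    st$peak_power > params$power_ratio_k * st$noise_floor

  ids <- seq_len(grid$n_blocks) - 1L  # row-fastest block order
  results <- tibble::tibble(
    row = as.integer(ids %% grid$n_rows),
    col = as.integer(ids %/% grid$n_rows),
    is_moving = as.logical(moving),
    freq_hz = ifelse(moving, fb[st$peak_idx], NA_real_),
    peak_power = as.numeric(st$peak_power),
    noise_floor = as.numeric(st$noise_floor)
  )
  results <- dplyr::arrange(results, .data$row, .data$col)
  structure(
    list(results = results, grid = grid, params = params,
         fps = stack$fps, fov_id = fov_id),
    class = "cbf_map"
  )
}

#' @export
print.cbf_map <- function(x, ...) {
  nm <- sum(x$results$is_moving)
  cat(sprintf("<cbf_map> '%s': %d x %d blocks, %d moving (%.1f%%)\n",
              x$fov_id, x$grid$n_rows, x$grid$n_cols, nm,
              100 * nm / x$grid$n_blocks))
  if (nm > 0) {
    cat(sprintf("  mean moving frequency: %.2f Hz\n",
                mean(x$results$freq_hz[x$results$is_moving])))
  }
  invisible(x)
}
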