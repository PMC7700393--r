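# run code with a locally seeded RNG, restoring any prior state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Describe a synthetic beating-epithelium scene
#'
#' A `sim_scene` is the generative description of a synthetic high-speed
#' video: elliptical patches ("strips" of ciliated epithelium) of
#' sinusoidally oscillating pixels on a static background, with additive
#' Gaussian camera noise and an optional metachronal phase gradient along
#' each strip. Defaults emulate the clinical acquisition regime this package
#' targets: 500 fps, 0.5 s recordings, ~39% of the field beating at a
#' normal-range frequency of 14 Hz, and a signal amplitude three times the
#' noise standard deviation.
#'
#' @param width,height field size in pixels.
#' @param fps acquisition frame rate in Hz (default 500).
#' @param n_frames frames to render (default 250, i.e. 0.5 s at 500 fps).
#' @param coverage_fraction target fraction of pixels beating, 0-1.
#' @param freq_field beat frequency in Hz: a single value applied to every
#'   patch, or a vector cycled over patches. All values must be below the
#'   Nyquist frequency `fps / 2`.
#' @param amplitude oscillation amplitude in grey levels.
#' @param baseline mean background intensity in grey levels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param phase_gradient metachronal-wave surrogate: phase advance in
#'   radians per pixel along each patch's major axis.
#' @param harmonic_weight relative weight of a second harmonic at `2f`,
#'   emulating non-sinusoidal ciliary waveforms (default 0).
#' @param semi_major,aspect patch geometry: mean semi-major axis in pixels
#'   and major:minor aspect ratio (strips are elongated, default 3:1).
#' @param n_patches maximum number of patches placed while approaching the
#'   target coverage.
#' @param align_blocks snap patch masks to the `block_px` analysis grid
#'   (default `TRUE`), so pixel-level ground truth and block-level coverage
#'   estimates share one granularity; set `FALSE` for free-form ellipses.
#' @param block_px grid pitch used when `align_blocks` is on (default 4,
#'   the minimum analysis box).
#' @param bit_depth camera bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]` and rounded to whole grey levels.
#' @param artifact_spec optional drifting-particulate model: a list with
#'   `n` (number of blobs), `intensity` (grey levels), `sigma_px` (Gaussian
#'   radius) and `speed_px_per_frame`. Blobs translate slowly so their
#'   temporal energy falls below the 2 Hz detection edge.
#' @param seed integer seed; the whole simulation is reproducible from it.
#'
#' @return An object of class `sim_scene`.
#' @export
#' @examples
#' sim_scene(coverage_fraction = 0.5, freq_field = 12, seed = 7)
sim_scene <- function(width = 128, height = 128, fps = 500, n_frames = 250,
                      coverage_fraction = 0.389, freq_field = 14,
                      amplitude = 30, baseline = 120, noise_sd = 10,
                      phase_gradient = 0.1, harmonic_weight = 0,
                      semi_major = 18, aspect = 3, n_patches = 500,
                      align_blocks = TRUE, block_px = 4, bit_depth = 8,
                      artifact_spec = NULL, seed = 1) {
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    stop("`coverage_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (amplitude < 0 || noise_sd < 0) {
    stop("`amplitude` and `noise_sd` must be non-negative", call. = FALSE)
  }
  if (any(freq_field <= 0) || max(freq_field) >= fps / 2) {
    stop(sprintf("beat frequencies must lie in (0, %g) Hz (below Nyquist)", fps / 2),
         call. = FALSE)
  }
  if (!bit_depth %in% c(8, 12, 16)) stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         fps = fps, n_frames = as.integer(n_frames),
         coverage_fraction = coverage_fraction, freq_field = freq_field,
         amplitude = amplitude, baseline = baseline, noise_sd = noise_sd,
         phase_gradient = phase_gradient, harmonic_weight = harmonic_weight,
         semi_major = semi_major, aspect = aspect, n_patches = as.integer(n_patches),
         align_blocks = isTRUE(align_blocks), block_px = as.integer(block_px),
         bit_depth = as.integer(bit_depth), artifact_spec = artifact_spec,
         seed = as.integer(seed)),
    class = "sim_scene"
  )
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf(
    "<sim_scene> %d x %d px, %d frames @ %g fps, target coverage %.1f%%, %s Hz, seed %d\n",
    x$width, x$height, x$n_frames, x$fps, 100 * x$coverage_fraction,
    paste(x$freq_field, collapse = "/"), x$seed))
  invisible(x)
}

# 0-based pixel indices (p = r + H*c) covered by an ellipse
.ellipse_pixels <- function(H, W, cx, cy, a, b, theta) {
  r0 <- floor(max(0, cy - a)):ceiling(min(H - 1, cy + a))
  c0 <- floor(max(0, cx - a)):ceiling(min(W - 1, cx + a))
  if (length(r0) == 0L || length(c0) == 0L) return(integer(0))
  cc <- rep(c0, each = length(r0))
  rr <- rep(r0, times = length(c0))
  dx <- cc - cx
  dy <- rr - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  (rr + H * cc)[keep]
}

# snap a pixel set to the block grid: keep blocks with majority coverage
.snap_to_blocks <- function(px, H, W, bs) {
  n_rows <- H %/% bs
  n_cols <- W %/% bs
  r <- px %% H
  c <- px %/% H
  inside <- r %/% bs < n_rows & c %/% bs < n_cols
  px <- px[inside]
  if (length(px) == 0L) return(integer(0))
  blk <- (px %% H) %/% bs + n_rows * ((px %/% H) %/% bs)
  counts <- table(blk)
  keep <- as.integer(names(counts))[counts >= bs * bs / 2]
  if (length(keep) == 0L) return(integer(0))
  br <- keep %% n_rows
  bc <- keep %/% n_rows
  unlist(lapply(seq_along(keep), function(i) {
    rows <- br[i] * bs + 0:(bs - 1)
    cols <- bc[i] * bs + 0:(bs - 1)
    as.vector(outer(rows, H * cols, `+`))
  }), use.names = FALSE)
}

.block_containing <- function(cx, cy, H, W, bs) {
  n_rows <- H %/% bs
  n_cols <- W %/% bs
  br <- min(max(0, floor(cy / bs)), n_rows - 1)
  bc <- min(max(0, floor(cx / bs)), n_cols - 1)
  rows <- br * bs + 0:(bs - 1)
  cols <- bc * bs + 0:(bs - 1)
  as.vector(outer(rows, H * cols, `+`))
}

#' Simulate a synthetic high-speed video stack with ground truth
#'
#' Places elliptical beating patches at seeded random positions and
#' orientations until the realised moving-pixel fraction is within 0.01 of
#' the scene's target (or the patch budget is exhausted; the realised value
#' is always reported). Moving pixels oscillate as
#' `baseline + amplitude * sin(2*pi*f*t/fps + phi(x, y))`, with the phase
#' advancing along each patch's major axis by `phase_gradient` radians per
#' pixel; all pixels receive additive Gaussian noise, and intensities are
#' clipped to the bit-depth range and rounded to whole grey levels.
#' Fully reproducible from `scene$seed`.
#'
#' @param scene a [sim_scene()].
#' @return A list with elements
#'   \describe{
#'     \item{stack}{a [frame_stack()] of the rendered video,}
#'     \item{truth}{a `ground_truth` object: `moving_mask` (H x W logical),
#'       `freq_map` (H x W Hz, `NA` off the mask) and `realized_coverage`,}
#'     \item{patches}{tibble of placed patches (centre, axes, orientation,
#'       frequency).}
#'   }
#' @export
simulate_stack <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"))
  H <- scene$height; W <- scene$width
  npix <- H * W
  target <- scene$coverage_fraction * npix
  tol <- 0.01 * npix

  place <- .with_seed(scene$seed, {
    moving <- integer(0)
    freq <- numeric(0)
    phase <- numeric(0)
    patches <- list()
    if (scene$coverage_fraction >= 1) {
      moving <- 0:(npix - 1)
      f <- scene$freq_field[1]
      freq <- rep(f, npix)
      phase <- scene$phase_gradient * (moving %/% H)
      patches[[1]] <- list(cx = (W - 1) / 2, cy = (H - 1) / 2,
                           a = Inf, b = Inf, theta = 0, freq_hz = f)
    } else if (scene$coverage_fraction > 0) {
      i <- 0L
      while (target - length(moving) > tol && i < scene$n_patches) {
        i <- i + 1L
        deficit <- target - length(moving)
        a <- scene$semi_major * stats::runif(1, 0.7, 1.3)
        b <- a / scene$aspect
        # shrink the patch when little area is left to fill
        if (pi * a * b > deficit) {
          s <- sqrt(max(deficit, scene$block_px^2) / (pi * a * b))
          a <- max(a * s, scene$block_px)
          b <- max(b * s, scene$block_px / scene$aspect)
        }
        cx <- stats::runif(1, 0, W - 1)
        cy <- stats::runif(1, 0, H - 1)
        theta <- stats::runif(1, 0, pi)
        f <- scene$freq_field[(i - 1L) %% length(scene$freq_field) + 1L]
        px <- .ellipse_pixels(H, W, cx, cy, a, b, theta)
        if (scene$align_blocks) {
          px <- .snap_to_blocks(px, H, W, scene$block_px)
          if (length(px) == 0L) px <- .block_containing(cx, cy, H, W, scene$block_px)
        }
        px <- setdiff(px, moving)
        if (length(px) == 0L) next
        if (length(moving) + length(px) > target + tol) {
          # over-shooting patch: at block granularity trim whole blocks
          # (nearest the patch centre first), otherwise trim pixels
          avail <- floor(target + tol - length(moving))
          if (scene$align_blocks) {
            bs <- scene$block_px
            n_rows <- H %/% bs
            blk <- (px %% H) %/% bs + n_rows * ((px %/% H) %/% bs)
            ub <- unique(blk)
            n_keep <- min(avail %/% (bs * bs), length(ub))
            if (n_keep <= 0) next
            bcy <- (ub %% n_rows) * bs + (bs - 1) / 2
            bcx <- (ub %/% n_rows) * bs + (bs - 1) / 2
            keep_b <- ub[order((bcy - cy)^2 + (bcx - cx)^2)][seq_len(n_keep)]
            px <- px[blk %in% keep_b]
          } else {
            if (avail <= 0) next
            d2 <- ((px %% H) - cy)^2 + ((px %/% H) - cx)^2
            px <- px[order(d2)][seq_len(min(avail, length(px)))]
          }
        }
        proj <- ((px %/% H) - cx) * cos(theta) + ((px %% H) - cy) * sin(theta)
        moving <- c(moving, px)
        freq <- c(freq, rep(f, length(px)))
        phase <- c(phase, scene$phase_gradient * proj)
        patches[[length(patches) + 1L]] <-
          list(cx = cx, cy = cy, a = a, b = b, theta = theta, freq_hz = f)
      }
    }
    list(moving = moving, freq = freq, phase = phase, patches = patches)
  })

  clip_hi <- 2^scene$bit_depth - 1
  has_artifacts <- !is.null(scene$artifact_spec)
  frames <- .cpp_render_frames(
    H, W, scene$n_frames, scene$fps, scene$baseline, scene$amplitude,
    as.integer(place$moving), place$freq, place$phase,
    scene$noise_sd, scene$harmonic_weight,
    0, clip_hi, quantize = !has_artifacts, seed = scene$seed
  )
  if (has_artifacts) {
    frames <- .add_artifacts(frames, scene)
    frames <- round(pmin(pmax(frames, 0), clip_hi))
    dim(frames) <- c(scene$n_frames, H, W)
  }

  mask <- matrix(FALSE, H, W)
  mask[place$moving + 1L] <- TRUE
  fmap <- matrix(NA_real_, H, W)
  fmap[place$moving + 1L] <- place$freq

  truth <- structure(
    list(moving_mask = mask, freq_map = fmap,
         realized_coverage = length(place$moving) / npix),
    class = "ground_truth"
  )
  patches <- if (length(place$patches)) {
    dplyr::bind_rows(lapply(place$patches, tibble::as_tibble))
  } else {
    tibble::tibble(cx = numeric(), cy = numeric(), a = numeric(),
                   b = numeric(), theta = numeric(), freq_hz = numeric())
  }
  list(
    stack = .frame_stack_fast(frames, fps = scene$fps,
                              source_id = sprintf("sim(seed=%d)", scene$seed)),
    truth = truth,
    patches = patches
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d x %d px, realised coverage %.2f%%\n",
              nrow(x$moving_mask), ncol(x$moving_mask), 100 * x$realized_coverage))
  invisible(x)
}

# slow bright translating Gaussian blobs (sub-2 Hz energy)
.add_artifacts <- function(frames, scene) {
  spec <- scene$artifact_spec
  n <- spec$n %||% 1L
  inten <- spec$intensity %||% 40
  sig <- spec$sigma_px %||% 6
  speed <- spec$speed_px_per_frame %||% 0.01
  H <- scene$height; W <- scene$width; T <- scene$n_frames
  .with_seed(scene$seed + 10000L, {
    for (j in seq_len(n)) {
      x0 <- stats::runif(1, 0, W - 1); y0 <- stats::runif(1, 0, H - 1)
      ang <- stats::runif(1, 0, 2 * pi)
      vx <- speed * cos(ang); vy <- speed * sin(ang)
      for (t in seq_len(T)) {
        cx <- x0 + vx * (t - 1); cy <- y0 + vy * (t - 1)
        gy <- exp(-((0:(H - 1)) - cy)^2 / (2 * sig^2))
        gx <- exp(-((0:(W - 1)) - cx)^2 / (2 * sig^2))
        frames[t, , ] <- frames[t, , ] + inten * outer(gy, gx)
      }
    }
  })
  frames
}

#' Simulate a series of fields of view across one insert
#'
#' Renders `n_fov` independent scenes sharing all parameters but seeded
#' `seed, seed + 1, ...`, mirroring the multi-field sampling of a culture
#' insert (16 fields along the midline by default in the analysis workflow).
#'
#' @param scene a [sim_scene()]; its seed starts the series.
#' @param n_fov number of fields of view (default 16).
#' @return A list of `n_fov` results as returned by [simulate_stack()].
#' @export
simulate_fov_series <- function(scene, n_fov = 16) {
  stopifnot(inherits(scene, "sim_scene"), n_fov >= 1)
  lapply(seq_len(n_fov) - 1L, function(i) {
    s <- scene
    s$seed <- scene$seed + i
    simulate_stack(s)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
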