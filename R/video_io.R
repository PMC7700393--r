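#' Acquisition metadata for a video stack
#'
#' Minimal acquisition context needed to interpret a stack on disk. `fps` is
#' mandatory everywhere in this package — a beat frequency is meaningless
#' without the acquisition rate — while the geometry fields are required
#' only for raw frame binaries, whose layout cannot be inferred from the
#' file alone.
#'
#' @param fps acquisition frame rate in Hz.
#' @param width,height frame size in pixels.
#' @param bit_depth bits per pixel: 8, 12 or 16.
#' @param frame_count number of frames.
#' @param objective free-text objective description (e.g. "x20").
#' @return An object of class `stack_metadata`.
#' @export
stack_metadata <- function(fps, width = NULL, height = NULL, bit_depth = NULL,
                           frame_count = NULL, objective = "") {
  if (missing(fps) || !is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("frame rate unknown: `fps` must be a positive number in Hz", call. = FALSE)
  }
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || x < 1 || x != round(x))) {
      stop(sprintf("`%s` must be a positive whole number", nm), call. = FALSE)
    }
  }
  chk(width, "width"); chk(height, "height"); chk(frame_count, "frame_count")
  if (!is.null(bit_depth) && !bit_depth %in% c(8, 12, 16)) {
    stop("`bit_depth` must be one of 8, 12, 16", call. = FALSE)
  }
  structure(
    list(fps = as.numeric(fps), width = width, height = height,
         bit_depth = bit_depth, frame_count = frame_count, objective = objective),
    class = "stack_metadata"
  )
}

.sidecar_path <- function(path) paste0(path, ".meta.txt")

#' Read and write plain-text metadata sidecars
#'
#' The sidecar is a flat `key = value` text file placed next to the video
#' file (`<video>.meta.txt`) carrying `fps`, `width`, `height`, `bit_depth`,
#' `frame_count` and `objective`.
#'
#' @param path path of the *video* file the sidecar accompanies.
#' @return `read_stack_metadata()` returns a [stack_metadata()] or `NULL` if
#'   no sidecar exists.
#' @export
read_stack_metadata <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  get_num <- function(k) if (k %in% keys) as.numeric(vals[match(k, keys)]) else NULL
  if (!"fps" %in% keys) {
    stop(sprintf("frame rate unknown: sidecar %s has no `fps` entry", sp), call. = FALSE)
  }
  stack_metadata(
    fps = get_num("fps"), width = get_num("width"), height = get_num("height"),
    bit_depth = get_num("bit_depth"), frame_count = get_num("frame_count"),
    objective = if ("objective" %in% keys) vals[match("objective", keys)] else ""
  )
}

#' @rdname read_stack_metadata
#' @param meta a [stack_metadata()] to write.
#' @export
write_stack_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "stack_metadata"))
  fields <- c("fps", "width", "height", "bit_depth", "frame_count", "objective")
  lines <- unlist(lapply(fields, function(k) {
    v <- meta[[k]]
    if (is.null(v) || identical(v, "")) NULL else sprintf("%s = %s", k, format(v, scientific = FALSE))
  }))
  writeLines(lines, .sidecar_path(path))
  invisible(.sidecar_path(path))
}

#' Read a video stack from disk
#'
#' Supports two interchange formats: multi-page grayscale TIFF (8/16-bit),
#' and raw frame binaries (unsigned 8- or 16-bit little-endian, frames
#' stored consecutively, each frame row-major). The frame rate must come
#' from an explicit `metadata` argument or a `<path>.meta.txt` sidecar —
#' it is never silently defaulted. Raw binaries additionally need `width`,
#' `height` and `bit_depth`; the frame count is derived from the file size
#' and a short or trailing partial frame raises an error naming the failing
#' frame index. Multi-channel TIFF pages are converted to single-channel
#' luminance by averaging channels.
#'
#' @param path video file path (`.tif`/`.tiff` for TIFF, anything else is
#'   treated as raw binary).
#' @param metadata optional [stack_metadata()]; overrides the sidecar.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  meta <- metadata %||% read_stack_metadata(path)
  if (is.null(meta) || is.null(meta$fps)) {
    stop(sprintf("frame rate unknown for '%s': supply `metadata` or a %s sidecar",
                 path, basename(.sidecar_path(path))), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 1L) stop(sprintf("'%s' contains no frames", path), call. = FALSE)
    pages <- lapply(seq_along(pages), function(i) {
      pg <- pages[[i]]
      if (is.double(pg)) {
        # multi-channel pages come back scaled to [0, 1]; restore grey levels
        bits <- attr(pg, "bits.per.sample") %||% 8
        pg <- round(pg * (2^bits - 1))
      }
      if (length(dim(pg)) == 3L) pg <- apply(pg, c(1, 2), mean)  # channel luminance
      if (!is.matrix(pg)) {
        stop(sprintf("unreadable frame %d in '%s'", i - 1L, path), call. = FALSE)
      }
      pg
    })
    d1 <- dim(pages[[1]])
    for (i in seq_along(pages)) {
      if (!identical(dim(pages[[i]]), d1)) {
        stop(sprintf("inconsistent frame dimensions at frame %d in '%s'", i - 1L, path),
             call. = FALSE)
      }
    }
    frames <- aperm(array(unlist(pages, use.names = FALSE),
                          dim = c(d1[1], d1[2], length(pages))), c(3, 1, 2))
  } else {
    need <- c("width", "height", "bit_depth")
    miss <- need[vapply(need, function(k) is.null(meta[[k]]), TRUE)]
    if (length(miss)) {
      stop(sprintf("raw stack '%s' needs metadata fields: %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    bytes <- if (meta$bit_depth > 8) 2L else 1L
    fsize <- file.info(path)$size
    frame_bytes <- meta$width * meta$height * bytes
    if (fsize %% frame_bytes != 0) {
      stop(sprintf("truncated raw stack '%s': file ends inside frame %d", path,
                   fsize %/% frame_bytes), call. = FALSE)
    }
    T <- as.integer(fsize %/% frame_bytes)
    if (!is.null(meta$frame_count) && meta$frame_count != T) {
      stop(sprintf("'%s': sidecar declares %d frames but file holds %d", path,
                   meta$frame_count, T), call. = FALSE)
    }
    v <- readBin(path, what = "integer", n = T * meta$width * meta$height,
                 size = bytes, signed = FALSE, endian = "little")
    # file layout: frame-major, rows within a frame, columns within a row
    frames <- aperm(array(as.numeric(v), dim = c(meta$width, meta$height, T)), c(3, 2, 1))
  }
  frame_stack(frames, fps = meta$fps, source_id = path)
}

#' Write a video stack to multi-page TIFF with a metadata sidecar
#'
#' Intensities must already lie in `[0, 2^bit_depth - 1]`; whole-number
#' intensities round-trip exactly through [read_stack()].
#'
#' @param stack a [frame_stack()].
#' @param path output `.tif` path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bit_depth = 8) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!bit_depth %in% c(8, 16)) stop("TIFF `bit_depth` must be 8 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (max(stack$frames) > maxv) {
    stop(sprintf("intensities exceed the %d-bit range", bit_depth), call. = FALSE)
  }
  T <- n_frames(stack)
  pages <- lapply(seq_len(T), function(t) stack$frames[t, , ] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth, compression = "none")
  d <- frame_dim(stack)
  write_stack_metadata(
    stack_metadata(fps = stack$fps, width = d[["width"]], height = d[["height"]],
                   bit_depth = bit_depth, frame_count = T),
    path
  )
  invisible(path)
}

#' Render a beat-frequency map as a grayscale image
#'
#' One rendered cell per analysis block. Non-moving blocks are black; moving
#' blocks lie on a linear monochrome ramp from 0 Hz (black) to `ramp_max_hz`
#' (white, default 25 Hz). Frequencies above the ramp top but within the
#' detection band clip to white: the display scale tops out at 25 Hz while
#' the data model keeps the full band distinct. Rendering is a pure function
#' of the map — identical maps produce byte-identical files.
#'
#' @param map a `cbf_map` from [compute_cbf_map()].
#' @param path output PNG path.
#' @param ramp_max_hz frequency rendered as white (default 25).
#' @param cell_px rendered cell size in pixels per block side (defaults to
#'   the map's block size, so the image matches the field's analysed area).
#' @return `path`, invisibly.
#' @export
write_cbf_map_image <- function(map, path, ramp_max_hz = 25, cell_px = NULL) {
  stopifnot(inherits(map, "cbf_map"))
  res <- map$results
  if (anyNA(res$is_moving)) stop("map is incomplete: unclassified blocks", call. = FALSE)
  cell_px <- cell_px %||% map$grid$block_size
  g <- matrix(0, map$grid$n_rows, map$grid$n_cols)
  g[cbind(res$row + 1L, res$col + 1L)] <-
    ifelse(res$is_moving, pmin(res$freq_hz / ramp_max_hz, 1), 0)
  img <- kronecker(g, matrix(1, cell_px, cell_px))
  ok <- tryCatch({ png::writePNG(img, path); TRUE },
                 error = function(e) stop(sprintf("cannot write image '%s': %s",
                                                  path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Serialise a beat-frequency map as tabular text
#'
#' One row per block (`row`, `col`, `is_moving`, `freq_hz`, `peak_power`,
#' `noise_floor`) preceded by `#`-commented header lines carrying the field
#' id, fps, grid geometry and analysis parameters.
#'
#' @param map a `cbf_map`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_cbf_map_table <- function(map, path) {
  stopifnot(inherits(map, "cbf_map"))
  hdr <- c(
    sprintf("# fov_id = %s", map$fov_id),
    sprintf("# fps = %g", map$fps),
    sprintf("# block_size = %d", map$grid$block_size),
    sprintf("# n_rows = %d", map$grid$n_rows),
    sprintf("# n_cols = %d", map$grid$n_cols),
    sprintf("# residual_pixels = %d", map$grid$residual_pixels),
    sprintf("# f_min = %g", map$params$f_min),
    sprintf("# f_max = %g", map$params$f_max),
    sprintf("# power_ratio_k = %g", map$params$power_ratio_k),
    sprintf("# window = %s", map$params$window)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(map$results), collapse = "\t"), con)
  utils::write.table(map$results, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a beat-frequency map table written by [write_cbf_map_table()]
#'
#' @param path table path.
#' @return A `cbf_map` object.
#' @export
read_cbf_map_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  getv <- function(k, default = NA) if (k %in% keys) vals[match(k, keys)] else default
  res <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                           sep = "\t", na.strings = "NA")
  res <- tibble::as_tibble(res)
  res$row <- as.integer(res$row); res$col <- as.integer(res$col)
  res$is_moving <- as.logical(res$is_moving)
  params <- spectral_params(
    block_size = as.numeric(getv("block_size", 4)),
    f_min = as.numeric(getv("f_min", 2)), f_max = as.numeric(getv("f_max", 50)),
    power_ratio_k = as.numeric(getv("power_ratio_k", 8)),
    window = getv("window", "hann")
  )
  n_rows <- as.integer(getv("n_rows")); n_cols <- as.integer(getv("n_cols"))
  grid <- structure(
    list(block_size = params$block_size, n_rows = n_rows, n_cols = n_cols,
         n_blocks = n_rows * n_cols,
         residual_pixels = as.integer(getv("residual_pixels", 0))),
    class = "block_grid"
  )
  structure(
    list(results = dplyr::arrange(res, .data$row, .data$col), grid = grid,
         params = params, fps = as.numeric(getv("fps")), fov_id = getv("fov_id", "")),
    class = "cbf_map"
  )
}

#' Serialise simulator ground truth as tabular text
#'
#' The moving mask is run-length encoded in column-major pixel order
#' (1-based start offsets) with the beat frequency of each run; the realised
#' coverage and field geometry travel in `#`-commented header lines.
#'
#' @param truth a `ground_truth` from [simulate_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  H <- nrow(truth$moving_mask); W <- ncol(truth$moving_mask)
  v <- as.vector(truth$freq_map)
  v[is.na(v)] <- -1
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0
  runs <- data.frame(start = starts[keep], length = r$lengths[keep],
                     freq_hz = r$values[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# height = %d", H), sprintf("# width = %d", W),
               sprintf("# realized_coverage = %.17g", truth$realized_coverage)), con)
  writeLines("start\tlength\tfreq_hz", con)
  if (nrow(runs)) {
    utils::write.table(runs, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- as.numeric(vapply(kv, function(x) trimws(x[2]), ""))
  H <- as.integer(vals[match("height", keys)])
  W <- as.integer(vals[match("width", keys)])
  runs <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE, sep = "\t")
  fmap <- rep(NA_real_, H * W)
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i] + seq_len(runs$length[i]) - 1L
    fmap[idx] <- runs$freq_hz[i]
  }
  fmap <- matrix(fmap, H, W)
  structure(
    list(moving_mask = !is.na(fmap), freq_map = fmap,
         realized_coverage = sum(!is.na(fmap)) / (H * W)),
    class = "ground_truth"
  )
}
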