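#' Beat frequency of a single region-of-interest trace
#'
#' Applies the block-spectrum machinery — detrend, taper, one-sided power
#' spectrum, dominant in-band frequency, and the peak-to-noise-floor
#' significance criterion — to one intensity time series, treated as a
#' one-pixel block. A trace whose in-band peak fails the significance test
#' (or whose energy lies outside the 2-50 Hz detection band, such as slow
#' drift) is reported non-moving (`NA`).
#'
#' @param intensity numeric intensity time series, length >= 16.
#' @param fps acquisition frame rate in Hz.
#' @param params a [spectral_params()].
#' @return Beat frequency in Hz, or `NA_real_` for a non-moving trace.
#' @export
#' @examples
#' t <- 0:249
#' roi_cbf(120 + 30 * sin(2 * pi * 14 * t / 500), fps = 500)  # 14 Hz
roi_cbf <- function(intensity, fps, params = spectral_params()) {
  if (!is.numeric(intensity) || length(intensity) < 16L) {
    stop("insufficient frames: an ROI trace needs at least 16 samples", call. = FALSE)
  }
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  .check_analysis_pre(length(intensity), fps, params)
  sc <- .spectrum_core(matrix(intensity, ncol = 1), fps, params)
  spec <- structure(
    list(row = 0L, col = 0L, frequencies = sc$frequencies, power = sc$power,
         noise_floor = sc$noise_floor, fps = fps),
    class = "block_spectrum"
  )
  r <- classify_block(spec, params)
  if (r$is_moving) r$freq_hz else NA_real_
}

#' Summarise ciliary beat frequency across regions of interest
#'
#' Computes per-ROI beat frequencies and the sample-level mean CBF with the
#' service conventions for nasal-brushing and air-liquid-interface culture
#' assessments: the mean is taken over moving ROIs; a sample whose ROIs are
#' all static is recorded with a mean CBF of 0 Hz and status `static`;
#' fewer than `min_rois` ROIs give status `insufficient` (the mean is still
#' reported when computable); otherwise the mean is flagged against the
#' normal range, 11-20 Hz inclusive by default. Samples mixing static and
#' moving ROIs keep their mean but carry a `mixed_motility` warning flag,
#' since a variable beat pattern makes a single mean less interpretable.
#'
#' @param traces a data frame of ROI intensity time series: either wide
#'   (one numeric column per ROI, rows are frames) or long with columns
#'   `roi` and `intensity` (rows in time order within each ROI).
#' @param fps acquisition frame rate in Hz (taken from a `fps` attribute of
#'   `traces` when absent, as set by [read_roi_traces()]).
#' @param params a [spectral_params()].
#' @param sample_id label for the sample.
#' @param normal_range inclusive normal CBF range in Hz (default `c(11, 20)`).
#' @param min_rois minimum ROI count for a sufficient assessment (default 6).
#' @return An object of class `cbf_summary`: list with `sample_id`,
#'   `per_roi` (tibble: `roi`, `freq_hz`, `is_moving`), `mean_cbf_hz`,
#'   `n_rois`, `n_static`, `status` (one of `within_normal`, `below_normal`,
#'   `above_normal`, `static`, `insufficient`), `mixed_motility`,
#'   `normal_range_hz`.
#' @export
#' @examples
#' t <- 0:249
#' tr <- as.data.frame(replicate(6, 120 + 30 * sin(2 * pi * 14 * t / 500)))
#' summarise_cbf(tr, fps = 500)
summarise_cbf <- function(traces, fps = attr(traces, "fps"),
                          params = spectral_params(), sample_id = "",
                          normal_range = c(11, 20), min_rois = 6) {
  if (is.null(fps)) stop("frame rate unknown: supply `fps`", call. = FALSE)
  traces <- as.data.frame(traces)
  if (all(c("roi", "intensity") %in% names(traces))) {
    split_tr <- split(traces$intensity, factor(traces$roi, levels = unique(traces$roi)))
  } else {
    num <- vapply(traces, is.numeric, TRUE)
    split_tr <- as.list(traces[num])
  }
  if (length(split_tr) == 0L) stop("no ROI traces supplied", call. = FALSE)
  freq <- vapply(split_tr, roi_cbf, numeric(1), fps = fps, params = params)
  per_roi <- tibble::tibble(roi = names(split_tr), freq_hz = unname(freq),
                            is_moving = !is.na(freq))
  n <- nrow(per_roi)
  n_static <- sum(!per_roi$is_moving)
  moving <- per_roi$freq_hz[per_roi$is_moving]
  mean_cbf <- if (length(moving) > 0) mean(moving) else 0  # all-static convention: 0 Hz
  status <- if (n < min_rois) {
    "insufficient"
  } else if (n_static == n) {
    "static"
  } else if (mean_cbf < normal_range[1]) {
    "below_normal"
  } else if (mean_cbf > normal_range[2]) {
    "above_normal"
  } else {
    "within_normal"
  }
  structure(
    list(sample_id = sample_id, per_roi = per_roi, mean_cbf_hz = mean_cbf,
         n_rois = n, n_static = as.integer(n_static), status = status,
         mixed_motility = n_static > 0 && n_static < n,
         normal_range_hz = normal_range),
    class = "cbf_summary"
  )
}

#' @export
print.cbf_summary <- function(x, ...) {
  cat(sprintf("<cbf_summary> %s%d ROIs, mean CBF %.2f Hz, status: %s\n",
              if (nzchar(x$sample_id)) paste0(x$sample_id, ": ") else "",
              x$n_rois, x$mean_cbf_hz, x$status))
  if (x$mixed_motility) {
    cat(sprintf("  warning: mixed motility (%d of %d ROIs static)\n",
                x$n_static, x$n_rois))
  }
  invisible(x)
}

#' Read and write ROI trace tables
#'
#' Tab-separated text with the frame rate on a leading comment line
#' (`# fps = 500`), a header row of ROI labels, and one row per frame
#' (time index implicit).
#'
#' @param path file path.
#' @return `read_roi_traces()`: a tibble (one column per ROI) with an `fps`
#'   attribute.
#' @export
read_roi_traces <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  fps <- NULL
  for (h in hdr) {
    m <- regmatches(h, regexec("fps\\s*=\\s*([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 2) fps <- as.numeric(m[2])
  }
  if (is.null(fps)) {
    stop(sprintf("frame rate unknown: '%s' has no `# fps = ...` header line", path),
         call. = FALSE)
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE, sep = "\t",
                           check.names = FALSE)
  out <- tibble::as_tibble(tab)
  attr(out, "fps") <- fps
  out
}

#' @rdname read_roi_traces
#' @param traces wide data frame, one numeric column per ROI.
#' @param fps acquisition frame rate in Hz.
#' @export
write_roi_traces <- function(traces, path, fps) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps = %g", fps), con)
  writeLines(paste(names(traces), collapse = "\t"), con)
  utils::write.table(as.data.frame(traces), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a CBF summary as flat key-value text plus a per-ROI table
#'
#' @param summary a `cbf_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cbf_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cbf_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("sample_id = %s", summary$sample_id),
    sprintf("n_rois = %d", summary$n_rois),
    sprintf("n_static = %d", summary$n_static),
    sprintf("mean_cbf_hz = %.10g", summary$mean_cbf_hz),
    sprintf("status = %s", summary$status),
    sprintf("mixed_motility = %s", summary$mixed_motility),
    sprintf("normal_range_hz = %g-%g", summary$normal_range_hz[1], summary$normal_range_hz[2]),
    ""
  ), con)
  writeLines(paste(names(summary$per_roi), collapse = "\t"), con)
  utils::write.table(summary$per_roi, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
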