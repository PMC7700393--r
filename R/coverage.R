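#' Percent area of ciliary movement in one field of view
#'
#' The analysis unit of area is the block, not the pixel: coverage is the
#' share of complete analysis blocks classified as moving. Residual edge
#' pixels excluded by [tile()] are excluded from the denominator.
#'
#' @param map a `cbf_map` from [compute_cbf_map()].
#' @return A one-row tibble: `fov_id`, `percent_moving` (0-100),
#'   `n_blocks_moving`, `n_blocks_total`, `mean_moving_freq_hz` (NA when no
#'   block moves).
#' @export
#' @examples
#' sim <- simulate_stack(sim_scene(width = 32, height = 32, n_frames = 64, seed = 2))
#' percent_area_moving(compute_cbf_map(sim$stack, fov_id = "fov0"))
percent_area_moving <- function(map) {
  stopifnot(inherits(map, "cbf_map"))
  res <- map$results
  if (nrow(res) == 0L) stop("empty map: no blocks to summarise", call. = FALSE)
  n_mov <- sum(res$is_moving)
  tibble::tibble(
    fov_id = map$fov_id,
    percent_moving = 100 * n_mov / nrow(res),
    n_blocks_moving = as.integer(n_mov),
    n_blocks_total = nrow(res),
    mean_moving_freq_hz = if (n_mov > 0) mean(res$freq_hz[res$is_moving]) else NA_real_
  )
}

#' Aggregate per-field coverage across a culture insert
#'
#' Per-field percentages are averaged unweighted — each field counts once
#' even if block counts differ — matching the workflow in which the percent
#' area of movement within the sampled fields of view is averaged to give a
#' surrogate for cilia coverage. Fields judged unusable (significant moving
#' particulates or mucus debris) are excluded via an explicit `exclude`
#' column; there is deliberately no automatic debris detector.
#'
#' @param per_fov data frame of per-field rows as returned by
#'   [percent_area_moving()]; an optional logical `exclude` column drops
#'   fields from the aggregate.
#' @return An object of class `coverage_summary`: list with `per_fov`
#'   (tibble, with `excluded` flag), `mean_percent`, `sd_percent` (sample
#'   SD; `NA` for a single field) and `n_fov`.
#' @export
#' @examples
#' aggregate_coverage(data.frame(fov_id = c("a", "b"),
#'                               percent_moving = c(30, 50),
#'                               n_blocks_moving = c(3L, 5L),
#'                               n_blocks_total = c(10L, 10L)))
aggregate_coverage <- function(per_fov) {
  per_fov <- tibble::as_tibble(per_fov)
  if (nrow(per_fov) == 0L) stop("no fields of view to aggregate", call. = FALSE)
  if (!"percent_moving" %in% names(per_fov)) {
    stop("`per_fov` must have a `percent_moving` column", call. = FALSE)
  }
  excl <- if ("exclude" %in% names(per_fov)) per_fov$exclude %in% TRUE
          else rep(FALSE, nrow(per_fov))
  used <- per_fov$percent_moving[!excl]
  if (length(used) == 0L) stop("all fields of view are excluded", call. = FALSE)
  structure(
    list(per_fov = dplyr::mutate(per_fov, excluded = excl),
         mean_percent = mean(used),
         sd_percent = if (length(used) > 1L) stats::sd(used) else NA_real_,
         n_fov = length(used)),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %d fields of view\n", x$n_fov))
  cat(sprintf("  mean cilia coverage: %.1f%%", x$mean_percent))
  if (!is.na(x$sd_percent)) cat(sprintf(" (SD %.1f)", x$sd_percent))
  cat("\n")
  invisible(x)
}

#' Midline sampling plan for a culture insert
#'
#' Deterministic selection of every `step`-th field position (0-based, from
#' position 0) along the insert midline, truncated at `max_fields`. Defaults
#' mirror the sampling design for 12 mm inserts: every 3rd field of view,
#' up to 16 fields.
#'
#' @param n_positions_available number of candidate field positions.
#' @param step take every `step`-th position (default 3).
#' @param max_fields cap on selected fields (default 16).
#' @return An object of class `sampling_plan` with `selected_indices`
#'   (0-based).
#' @export
#' @examples
#' make_sampling_plan(48)$selected_indices  # 0, 3, ..., 45
make_sampling_plan <- function(n_positions_available, step = 3, max_fields = 16) {
  if (n_positions_available < 1) stop("need at least one field position", call. = FALSE)
  if (step < 1) stop("`step` must be >= 1", call. = FALSE)
  idx <- seq(0L, n_positions_available - 1L, by = as.integer(step))
  idx <- utils::head(idx, max_fields)
  structure(
    list(n_positions_available = as.integer(n_positions_available),
         step = as.integer(step), max_fields = as.integer(max_fields),
         selected_indices = as.integer(idx)),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> every %d%s of %d positions, max %d: %s\n",
              x$step, switch(as.character(x$step), "1" = "st", "2" = "nd", "3" = "rd", "th"),
              x$n_positions_available, x$max_fields,
              paste(x$selected_indices, collapse = ", ")))
  invisible(x)
}

#' Serialise a coverage summary as tabular text
#'
#' Writes per-field rows followed by a `summary` row holding the unweighted
#' mean and SD across included fields.
#'
#' @param summary a `coverage_summary`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_coverage_summary <- function(summary, path) {
  stopifnot(inherits(summary, "coverage_summary"))
  pf <- summary$per_fov
  out <- data.frame(
    kind = "fov", fov_id = as.character(pf$fov_id),
    percent_moving = pf$percent_moving,
    n_blocks_moving = pf$n_blocks_moving, n_blocks_total = pf$n_blocks_total,
    mean_moving_freq_hz = if ("mean_moving_freq_hz" %in% names(pf)) pf$mean_moving_freq_hz else NA,
    excluded = pf$excluded
  )
  out <- rbind(out, data.frame(
    kind = "summary", fov_id = sprintf("n=%d", summary$n_fov),
    percent_moving = summary$mean_percent,
    n_blocks_moving = NA, n_blocks_total = NA,
    mean_moving_freq_hz = summary$sd_percent,  # column reused: SD on summary row
    excluded = FALSE
  ))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coverage summary; summary row: percent_moving = mean, mean_moving_freq_hz = sd", con)
  writeLines(paste(names(out), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
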