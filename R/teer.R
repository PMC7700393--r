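#' Blank-corrected trans-epithelial electrical resistance
#'
#' TEER of a culture insert: the mean of the test-well readings minus the
#' mean of the cell-free blank-insert readings, normalised to the membrane
#' growth area — `(mean(test) - mean(blank)) * area_cm2`, in ohm cm^2.
#' Readings are conventionally taken in triplicate; other counts are
#' accepted with a warning. A negative corrected resistance (blank above
#' test, e.g. probe drift) is returned but flagged.
#'
#' The membrane area is a required input: common Transwell formats are
#' 12 mm (1.12 cm^2) and 6.5 mm (0.33 cm^2) inserts, but the growth area of
#' the actual lot should be supplied.
#'
#' @param test resistance readings of the cell-bearing insert, in ohm.
#' @param blank readings of the cell-free control insert, in ohm.
#' @param area_cm2 membrane growth area in cm^2 (must be positive).
#' @return A numeric scalar of class `teer_result` (ohm cm^2) with
#'   attributes `mean_test_ohm`, `mean_blank_ohm`, `area_cm2` and
#'   `negative` (logical flag).
#' @export
#' @examples
#' compute_teer(c(400, 410, 390), c(300, 300, 300), area_cm2 = 1.12)  # 112 ohm cm^2
compute_teer <- function(test, blank, area_cm2) {
  for (nm in c("test", "blank")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
      stop(sprintf("`%s` must hold at least one finite non-negative reading (ohm)", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(area_cm2) || length(area_cm2) != 1L || !is.finite(area_cm2) || area_cm2 <= 0) {
    stop("`area_cm2` must be a positive membrane area in cm^2", call. = FALSE)
  }
  if (length(test) != 3L) {
    warning(sprintf("%d test readings (triplicate is the convention)", length(test)),
            call. = FALSE)
  }
  if (length(blank) != 3L) {
    warning(sprintf("%d blank readings (triplicate is the convention)", length(blank)),
            call. = FALSE)
  }
  value <- (mean(test) - mean(blank)) * area_cm2
  if (value < 0) {
    warning(sprintf("negative corrected resistance (%.4g ohm cm^2): blank exceeds test", value),
            call. = FALSE)
  }
  structure(value, class = "teer_result",
            mean_test_ohm = mean(test), mean_blank_ohm = mean(blank),
            area_cm2 = area_cm2, negative = value < 0)
}

#' @export
print.teer_result <- function(x, ...) {
  cat(sprintf("TEER: %.4g ohm cm^2 (test %.4g ohm, blank %.4g ohm, area %.3g cm^2)%s\n",
              as.numeric(x), attr(x, "mean_test_ohm"), attr(x, "mean_blank_ohm"),
              attr(x, "area_cm2"),
              if (isTRUE(attr(x, "negative"))) " [negative: flagged]" else ""))
  invisible(x)
}

#' TEER for a table of inserts, with per-group mean and SD
#'
#' @param data data frame, one row per insert, with numeric columns whose
#'   names start with `test` (test readings) and `blank` (blank readings),
#'   an `area_cm2` column, and optionally `insert_id` and `group`.
#' @return An object of class `teer_batch`: list with `per_insert` (tibble:
#'   `insert_id`, `group`, `teer_ohm_cm2`, `negative`) and `by_group`
#'   (tibble: `group`, `mean_ohm_cm2`, `sd_ohm_cm2`, `n`).
#' @export
#' @examples
#' df <- data.frame(insert_id = c("i1", "i2"), group = "control",
#'                  test1 = c(400, 380), test2 = c(410, 385), test3 = c(390, 381),
#'                  blank1 = 300, blank2 = 300, blank3 = 300, area_cm2 = 1.12)
#' teer_batch(df)
teer_batch <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("no inserts in `data`", call. = FALSE)
  test_cols <- grep("^test", names(data), value = TRUE)
  blank_cols <- grep("^blank", names(data), value = TRUE)
  if (length(test_cols) == 0L || length(blank_cols) == 0L || !"area_cm2" %in% names(data)) {
    stop("`data` needs test* and blank* reading columns and an `area_cm2` column",
         call. = FALSE)
  }
  ids <- if ("insert_id" %in% names(data)) as.character(data$insert_id)
         else sprintf("insert%d", seq_len(nrow(data)))
  grp <- if ("group" %in% names(data)) as.character(data$group) else rep("all", nrow(data))
  vals <- vapply(seq_len(nrow(data)), function(i) {
    as.numeric(compute_teer(as.numeric(data[i, test_cols]),
                            as.numeric(data[i, blank_cols]),
                            data$area_cm2[i]))
  }, numeric(1))
  per_insert <- tibble::tibble(insert_id = ids, group = grp,
                               teer_ohm_cm2 = vals, negative = vals < 0)
  by_group <- dplyr::summarise(
    dplyr::group_by(per_insert, .data$group),
    mean_ohm_cm2 = mean(.data$teer_ohm_cm2),
    sd_ohm_cm2 = if (dplyr::n() > 1) stats::sd(.data$teer_ohm_cm2) else NA_real_,
    n = dplyr::n(), .groups = "drop"
  )
  structure(list(per_insert = per_insert, by_group = by_group), class = "teer_batch")
}

#' @export
print.teer_batch <- function(x, ...) {
  cat(sprintf("<teer_batch> %d inserts in %d group(s)\n",
              nrow(x$per_insert), nrow(x$by_group)))
  print(x$by_group)
  invisible(x)
}
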