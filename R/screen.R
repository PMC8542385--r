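# Plate-level screen analysis: well summaries over replicate fields, the
# DMSO baseline, fractional aggregate reduction, inclusive-cut-off hit
# calling, dose-response trends for the secondary screen, and the
# colour-coded plate representation.

.WELL_ROWS <- LETTERS[1:8]
.WELL_COLS <- sprintf("%02d", 1:12)

.valid_wells <- function() as.vector(outer(.WELL_ROWS, .WELL_COLS, paste0))

# normalize e.g. "b3" -> "B03"; error on anything outside the 8x12 grid
.normalize_well <- function(w) {
  w <- toupper(trimws(w))
  m <- regmatches(w, regexec("^([A-H])0?([0-9]{1,2})$", w))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("invalid well id(s): ", paste(w[bad], collapse = ", "))
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > 12L))
    stop("well column out of 1..12: ", paste(w[col < 1 | col > 12],
                                             collapse = ", "))
  paste0(vapply(m, `[`, "", 2L), sprintf("%02d", col))
}

#' Plate layout for a 96-well screen
#'
#' @param wells Data frame with columns `well`, `role` (one of
#'   `negative_control`, `positive_control`, `test`), and optionally
#'   `compound`, `concentration_uM`, `replicate`.
#' @return A validated `plate_layout`.
#' @export
plate_layout <- function(wells) {
  req <- c("well", "role")
  if (!all(req %in% names(wells)))
    stop("layout needs columns: ", paste(req, collapse = ", "))
  wells$well <- .normalize_well(wells$well)
  if (anyDuplicated(wells$well))
    stop("duplicate well ids in layout")
  ok_roles <- c("negative_control", "positive_control", "test")
  if (!all(wells$role %in% ok_roles))
    stop("role must be one of: ", paste(ok_roles, collapse = ", "))
  for (col in c("compound", "concentration_uM", "replicate"))
    if (is.null(wells[[col]])) wells[[col]] <- NA
  structure(list(wells = wells[c("well", "role", "compound",
                                 "concentration_uM", "replicate")]),
            class = "plate_layout")
}

#' Read a plate layout from CSV
#'
#' Expected columns: `well`, `role`, optionally `compound`,
#' `concentration_uM`, `replicate`.
#'
#' @param path CSV file path.
#' @return A `plate_layout`.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  plate_layout(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Summarize per-well field results
#'
#' Mean and standard deviation of the percent-positive readout over the
#' QC-accepted fields of each well (single-field wells get `sd = 0` by
#' convention); wells whose fields were all rejected are flagged `usable =
#' FALSE` and excluded from the baseline and hit calling.
#'
#' @param field_results Named list: well id -> list of `field_result`.
#' @param layout A `plate_layout` containing every referenced well.
#' @return Data frame of class `well_summaries`, one row per well.
#' @export
summarize_wells <- function(field_results, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  ids <- .normalize_well(names(field_results))
  unknown <- setdiff(ids, layout$wells$well)
  if (length(unknown))
    stop("well(s) absent from layout: ", paste(unknown, collapse = ", "))
  rows <- lapply(seq_along(field_results), function(i) {
    frs <- field_results[[i]]
    if (inherits(frs, "field_result")) frs <- list(frs)
    ok <- vapply(frs, function(f) f$status == "ok", TRUE)
    pp <- vapply(frs[ok], `[[`, 0, "percent_positive")
    data.frame(well = ids[i],
               n_fields = length(frs),
               n_fields_rejected = sum(!ok),
               mean_percent_positive = if (length(pp)) mean(pp) else NA_real_,
               sd_percent_positive = if (length(pp) > 1) stats::sd(pp) else
                 if (length(pp) == 1) 0 else NA_real_,
               usable = length(pp) > 0)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, layout$wells, by = "well", sort = TRUE)
  class(out) <- c("well_summaries", "data.frame")
  out
}

#' Call screen hits against the DMSO baseline
#'
#' The baseline is the unweighted mean of the negative-control well means.
#' Each test well's fractional reduction is
#' `(baseline - well mean) / baseline`; a well is a hit when its reduction
#' is at least `cutoff` (boundary inclusive, default 0.25). Positive
#' controls are reported but never enter the baseline or the hit set.
#'
#' @param summaries `well_summaries` from [summarize_wells()].
#' @param layout The `plate_layout` (defaults to roles carried in
#'   `summaries`).
#' @param cutoff Fractional-reduction cut-off in `(0, 1]`, inclusive.
#' @return A `screen_result` with the baseline, per-well reductions and
#'   the hit set.
#' @export
call_hits <- function(summaries, layout = NULL, cutoff = 0.25) {
  stopifnot(inherits(summaries, "well_summaries"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  neg <- summaries[summaries$role == "negative_control" & summaries$usable, ]
  if (nrow(neg) == 0L)
    stop("no usable negative-control wells: baseline undefined")
  baseline <- mean(neg$mean_percent_positive)
  if (baseline == 0)
    stop("DMSO baseline is 0%: fractional reduction undefined")
  test <- summaries[summaries$role == "test" & summaries$usable, ]
  reduction <- (baseline - test$mean_percent_positive) / baseline
  names(reduction) <- test$well
  hits <- sort(test$well[reduction >= cutoff])
  structure(list(layout = layout,
                 summaries = summaries,
                 dmso_baseline = baseline,
                 reductions = reduction,
                 hits = hits,
                 cutoff = cutoff),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result baseline %.1f%%, cutoff %.0f%%, %d hit(s): %s>\n",
    x$dmso_baseline, 100 * x$cutoff, length(x$hits),
    paste(x$hits, collapse = ", ")))
  invisible(x)
}

#' Dose-response series for a secondary-screen compound
#'
#' Sorts points by concentration (averaging duplicate concentrations),
#' flags non-strict monotone decrease of the mean percent positive, and
#' reports the Spearman rank correlation between concentration and percent
#' positive (negative values mean aggregate reduction with dose).
#'
#' @param points Data frame or 2-column matrix of
#'   `(concentration_uM, mean_percent_positive)`.
#' @param compound Optional compound id carried in the result.
#' @return A `dose_response` object.
#' @export
dose_response <- function(points, compound = NA_character_) {
  pts <- as.data.frame(points)
  names(pts)[1:2] <- c("concentration_uM", "mean_percent_positive")
  pts <- stats::aggregate(mean_percent_positive ~ concentration_uM,
                          data = pts, FUN = mean)
  if (nrow(pts) < 3L)
    stop("dose_response needs >= 3 distinct concentrations")
  pts <- pts[order(pts$concentration_uM), ]
  mono <- all(diff(pts$mean_percent_positive) <= 0)
  trend <- if (stats::sd(pts$mean_percent_positive) == 0) 0 else
    suppressWarnings(stats::cor(pts$concentration_uM,
                                pts$mean_percent_positive,
                                method = "spearman"))
  structure(list(compound = compound, points = pts,
                 monotone_decreasing = mono, trend_statistic = trend),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "<dose_response %s: %d points, monotone=%s, rank corr %.2f>\n",
    x$compound, nrow(x$points), x$monotone_decreasing, x$trend_statistic))
  invisible(x)
}

#' Colour-coded plate representation
#'
#' Writes an 8x12 grid coloured by each well's mean percent positive
#' (missing wells as explicit NA), with hit wells outlined, as a PNG plus a
#' CSV twin holding exactly the plotted values.
#'
#' @param result A `screen_result`.
#' @param path Output path without extension (writes `path.png` and
#'   `path.csv`), or a `.png`/`.csv` path (the twin gets the other
#'   extension).
#' @return Invisibly, a list with the written `png` and `csv` paths.
#' @export
plate_heatmap <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  base <- sub("\\.(png|csv)$", "", path)
  png_path <- paste0(base, ".png")
  csv_path <- paste0(base, ".csv")
  s <- result$summaries
  grid <- matrix(NA_real_, 8, 12, dimnames = list(.WELL_ROWS, .WELL_COLS))
  for (i in seq_len(nrow(s))) {
    if (!s$usable[i]) next
    r <- match(substr(s$well[i], 1, 1), .WELL_ROWS)
    c <- match(substr(s$well[i], 2, 3), .WELL_COLS)
    grid[r, c] <- s$mean_percent_positive[i]
  }
  df <- data.frame(well = as.vector(outer(.WELL_ROWS, .WELL_COLS, paste0)),
                   mean_percent_positive = as.vector(grid),
                   is_hit = as.vector(outer(.WELL_ROWS, .WELL_COLS,
                                            paste0)) %in% result$hits)
  utils::write.csv(df, csv_path, row.names = FALSE)
  grDevices::png(png_path, width = 900, height = 640)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(100, "viridis")
  old <- graphics::par(mar = c(3, 3, 3, 6))
  on.exit(graphics::par(old), add = TRUE)
  graphics::image(x = 1:12, y = 1:8, z = t(grid[8:1, ]),
                  zlim = c(0, 100), col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%% aggregate-positive (baseline %.1f%%)",
                                 result$dmso_baseline))
  graphics::axis(1, at = 1:12, labels = .WELL_COLS)
  graphics::axis(2, at = 8:1, labels = .WELL_ROWS, las = 1)
  for (r in 1:8) for (c in 1:12) {
    if (is.na(grid[r, c]))
      graphics::text(c, 9 - r, "NA", col = "grey40", cex = 0.8)
  }
  for (h in result$hits) {
    r <- match(substr(h, 1, 1), .WELL_ROWS)
    c <- match(substr(h, 2, 3), .WELL_COLS)
    graphics::rect(c - 0.5, 9 - r - 0.5, c + 0.5, 9 - r + 0.5,
                   border = "red", lwd = 3)
  }
  invisible(list(png = png_path, csv = csv_path))
}

#' Serialize a screen result
#'
#' @param result A `screen_result`.
#' @param csv_path,json_path Optional output paths.
#' @return Invisibly, the per-well table.
#' @export
write_screen_result <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "screen_result"))
  s <- result$summaries
  s$reduction <- result$reductions[s$well]
  s$is_hit <- s$well %in% result$hits
  if (!is.null(csv_path)) utils::write.csv(s, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(dmso_baseline = result$dmso_baseline, cutoff = result$cutoff,
           hits = result$hits,
           reductions = as.list(result$reductions)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
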