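# LIVE/DEAD viability counting: total nuclei from the Hoechst channel,
# dead nuclei from the EthD-1 channel, live cells by subtraction. The two
# channels are counted independently with the same nuclei segmentation (no
# colocalization matching), mirroring the assay's counting procedure.

#' Count nuclei in a single channel
#'
#' Runs [segment_nuclei()] and returns the number of labels; a blank
#' channel counts zero. With Otsu thresholding the count is invariant to a
#' global intensity scale.
#'
#' @param channel `channel_image` or matrix.
#' @param seg [segmentation_params()].
#' @return Integer count.
#' @export
count_nuclei <- function(channel, seg = segmentation_params()) {
  segment_nuclei(channel, seg)$n_labels
}

#' LIVE/DEAD viability of one field
#'
#' Counts total nuclei in the `"hoechst"` channel and dead nuclei in the
#' `"ethd1"` channel; `n_live = n_total - n_dead`. If independent counting
#' ever yields more dead than total nuclei, `n_live` is clamped to 0 and
#' the result is flagged inconsistent.
#'
#' @param field `mc_image` with channels `"hoechst"` and `"ethd1"`.
#' @param seg [segmentation_params()].
#' @return A `viability_result` with `n_total`, `n_dead`, `n_live`,
#'   `percent_dead` and `consistent`.
#' @export
viability <- function(field, seg = segmentation_params()) {
  n_total <- count_nuclei(get_channel(field, "hoechst"), seg)
  n_dead <- count_nuclei(get_channel(field, "ethd1"), seg)
  consistent <- n_dead <= n_total
  n_live <- max(0L, n_total - n_dead)
  structure(list(n_total = n_total, n_dead = n_dead, n_live = n_live,
                 percent_dead = if (n_total > 0) 100 * n_dead / n_total
                                else NA_real_,
                 consistent = consistent),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result %d total, %d dead (%.1f%%), %d live%s>\n",
              x$n_total, x$n_dead, x$percent_dead, x$n_live,
              if (x$consistent) "" else ", INCONSISTENT"))
  invisible(x)
}

#' Batch viability counting over a directory
#'
#' Each field is a multi-page TIFF whose pages map to channels via
#' `channel_map` (defaults: page 1 = hoechst, page 2 = ethd1, page 3 =
#' calcein). Files are processed in filename order.
#'
#' @param dir Directory of viability fields.
#' @param seg [segmentation_params()].
#' @param channel_map Named page map for [read_field()].
#' @param csv_path Optional output CSV.
#' @return Data frame: file, n_total, n_dead, n_live, percent_dead.
#' @export
viability_batch <- function(dir, seg = segmentation_params(),
                            channel_map = c(hoechst = 1, ethd1 = 2,
                                            calcein = 3),
                            csv_path = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff)$",
                           ignore.case = TRUE))
  rows <- lapply(files, function(f) {
    field <- read_field(file.path(dir, f), channel_map)
    v <- viability(field, seg)
    data.frame(file = f, n_total = v$n_total, n_dead = v$n_dead,
               n_live = v$n_live, percent_dead = v$percent_dead)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), n_total = integer(0),
               n_dead = integer(0), n_live = integer(0),
               percent_dead = numeric(0))
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}
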