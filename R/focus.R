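# Blur rejection: every analysis field passes an edge-filter quality gate
# before any segmentation happens.

#' Focus metric of an image
#'
#' Mean Sobel gradient magnitude over all pixels (reflect boundary). The
#' mean (rather than the sum) makes the metric independent of image size;
#' it is invariant under a constant intensity offset and scales linearly
#' with contrast. Out-of-focus images score low and are rejected by
#' [qc_filter()].
#'
#' @param image A `channel_image` or numeric matrix.
#' @return A non-negative scalar.
#' @export
focus_metric <- function(image) {
  m <- .as_pixels(image)
  mean(sobel_magnitude(m))
}

#' Focus report for one field
#'
#' @param metric Measured focus metric.
#' @param threshold Acceptance threshold.
#' @return A `focus_report` with `accepted = metric >= threshold`.
#' @export
focus_report <- function(metric, threshold) {
  structure(list(metric = metric, threshold = threshold,
                 accepted = metric >= threshold),
            class = "focus_report")
}

#' @export
print.focus_report <- function(x, ...) {
  cat(sprintf("<focus_report metric=%.4g threshold=%.4g %s>\n",
              x$metric, x$threshold,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Partition fields into in-focus and blurred
#'
#' Applies [focus_metric()] to the named channel of every field and splits
#' the input at `threshold`. One report is returned per input, in input
#' order, so `length(accepted) + number rejected == length(fields)`.
#'
#' @param fields List of `mc_image` objects.
#' @param channel Channel to score (default `"gfp"`).
#' @param threshold Minimum metric to accept; see [default_qc_threshold()].
#' @return List with `accepted` (the passing fields) and `reports`
#'   (a `focus_report` per input field).
#' @export
qc_filter <- function(fields, channel = "gfp",
                      threshold = default_qc_threshold()) {
  stopifnot(threshold >= 0)
  reports <- lapply(fields, function(f)
    focus_report(focus_metric(get_channel(f, channel)), threshold))
  keep <- vapply(reports, `[[`, TRUE, "accepted")
  list(accepted = fields[keep], reports = reports)
}

#' Default focus-acceptance threshold
#'
#' Calibrated on the synthetic fixtures: sharp generated reporter fields
#' score ~0.14, while defocus at a blur scale that destroys few-pixel
#' puncta (sigma >= 4 px) scores below ~0.02; the default sits in the gap.
#' Real acquisitions should recalibrate on a handful of accepted/rejected
#' examples.
#'
#' @return Scalar threshold on the mean Sobel gradient magnitude.
#' @export
default_qc_threshold <- function() 0.04
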