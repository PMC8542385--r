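# Dispase dissociation assay: count detached-monolayer fragments inside a
# dish image. More fragments after agitation means weaker cell-cell
# adhesion; only fragments of at least the minimum area are counted
# (boundary inclusive: an area equal to the minimum counts).

#' Fragment-counting parameters
#'
#' @param min_fragment_area Minimum fragment area in pixels, inclusive
#'   (default 500, the assay's published minimum).
#' @param threshold_method `"otsu"` (within the dish mask) or `"fixed"`.
#' @param fixed_threshold Intensity threshold when `"fixed"`.
#' @param dish_detection `"auto"` (locate the dish) or `"full_frame"`.
#' @param min_contrast Minimum intensity contrast (max minus median) the
#'   in-dish pixels must show for Otsu thresholding to be attempted; an
#'   essentially flat dish — empty but for noise, which Otsu would
#'   bisect into percolating speckle — counts zero fragments. Ignored by
#'   `"fixed"` thresholding.
#' @return A validated `fragment_params`.
#' @export
fragment_params <- function(min_fragment_area = 500L,
                            threshold_method = c("otsu", "fixed"),
                            fixed_threshold = 0.5,
                            dish_detection = c("auto", "full_frame"),
                            min_contrast = 0.1) {
  threshold_method <- match.arg(threshold_method)
  dish_detection <- match.arg(dish_detection)
  if (min_fragment_area < 1) stop("min_fragment_area must be >= 1")
  structure(list(min_fragment_area = as.integer(min_fragment_area),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 dish_detection = dish_detection,
                 min_contrast = min_contrast),
            class = "fragment_params")
}

#' Locate the dish in a dissociation-assay image
#'
#' In `auto` mode the image is thresholded (Otsu), the largest connected
#' bright component is taken as the dish, and its filled convex hull is
#' returned as the mask. A dish fills a substantial share of the frame, so
#' if the largest component covers less than a quarter of the image (e.g.
#' Otsu isolated only the bright fragments) a second Otsu on the
#' sub-threshold pixels separates the dim dish glow from the dark
#' background instead. In `full_frame` mode the whole image is the mask.
#'
#' @param image `channel_image` or matrix.
#' @param mode `"auto"` or `"full_frame"`.
#' @return Logical matrix mask.
#' @export
detect_dish <- function(image, mode = c("auto", "full_frame")) {
  mode <- match.arg(mode)
  m <- .as_pixels(image)
  if (mode == "full_frame") return(matrix(TRUE, nrow(m), ncol(m)))
  if (max(m) - min(m) < 1e-9)
    stop("no dish candidate found in a blank image; ",
         "use dish_detection = 'full_frame'")
  # first Otsu may isolate only the bright fragments; if the resulting
  # largest component is too small to be a dish, cascade a second Otsu on
  # the sub-threshold pixels to separate the dim dish glow from the dark
  # background
  t1 <- otsu_threshold(.clip01(m))
  cand <- .largest_component(m > t1)
  if (sum(cand) < 0.25 * length(m)) {
    lower <- m[m <= t1]
    if (length(lower) && max(lower) - min(lower) > 1e-9) {
      t2 <- otsu_threshold(matrix(.clip01(lower), ncol = 1))
      cand <- .largest_component(m > t2)
    }
  }
  if (sum(cand) < 0.25 * length(m))
    stop("no dish candidate found; use dish_detection = 'full_frame'")
  .convex_fill(cand)
}

# largest 8-connected component of a mask (empty mask -> all-FALSE)
.largest_component <- function(bin) {
  if (!any(bin)) return(bin & FALSE)
  comp <- label_components(bin, 8L)
  areas <- tabulate(comp[comp > 0L], nbins = max(comp))
  comp == which.max(areas)
}

# filled convex hull of a logical mask
.convex_fill <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  # point-in-polygon per row: for each row, find column intersections
  # (robust enough for the convex case; vertices included)
  rows <- seq_len(h)
  poly_r <- hull[, 1]; poly_c <- hull[, 2]
  n <- length(poly_r)
  for (r in rows) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      r1 <- poly_r[i]; r2 <- poly_r[j]
      if ((r1 <= r && r2 >= r) || (r2 <= r && r1 >= r)) {
        if (r1 == r2) xs <- c(xs, poly_c[i], poly_c[j])
        else xs <- c(xs, poly_c[i] + (r - r1) / (r2 - r1) *
                       (poly_c[j] - poly_c[i]))
      }
    }
    if (length(xs) >= 1) {
      c1 <- max(1L, floor(min(xs)))
      c2 <- min(w, ceiling(max(xs)))
      if (c1 <= c2) out[r, c1:c2] <- TRUE
    }
  }
  out
}

#' Count fragments in a dissociation-assay dish image
#'
#' Thresholds within the dish mask, labels connected components
#' (8-connectivity) and keeps those with area at least
#' `min_fragment_area`. Fragments clipped by the dish edge count if their
#' in-dish area passes the minimum. An empty dish gives zero fragments.
#'
#' @param image `channel_image` or matrix.
#' @param params [fragment_params()].
#' @return A `fragment_result` with `n_fragments`, sorted
#'   `fragment_areas`, and `dish_mask_area`.
#' @export
count_fragments <- function(image, params = fragment_params()) {
  stopifnot(inherits(params, "fragment_params"))
  m <- .as_pixels(image)
  dish <- detect_dish(m, params$dish_detection)
  inside <- m[dish]
  thr <- if (params$threshold_method == "otsu") {
    if (max(inside) - stats::median(inside) < params$min_contrast) Inf
    else otsu_threshold(matrix(.clip01(inside), ncol = 1))
  } else params$fixed_threshold
  fgmask <- (m > thr) & dish
  result_areas <- integer(0)
  if (any(fgmask)) {
    comp <- label_components(fgmask, 8L)
    areas <- tabulate(comp[comp > 0L], nbins = max(comp))
    result_areas <- sort(areas[areas >= params$min_fragment_area])
  }
  structure(list(n_fragments = length(result_areas),
                 fragment_areas = as.integer(result_areas),
                 dish_mask_area = sum(dish),
                 min_fragment_area = params$min_fragment_area),
            class = "fragment_result")
}

#' @export
print.fragment_result <- function(x, ...) {
  cat(sprintf("<fragment_result %d fragment(s) >= %d px>\n",
              x$n_fragments, x$min_fragment_area))
  invisible(x)
}

#' Batch fragment counting over a directory
#'
#' Processes every TIFF/PNG in `dir` in filename order; per-image results
#' do not depend on batch order.
#'
#' @param dir Directory of single-channel dish images.
#' @param params [fragment_params()].
#' @param csv_path Optional output CSV (file, n_fragments, areas).
#' @param overlay_dir Optional directory for overlay PNGs with the counted
#'   fragments outlined in yellow.
#' @return Data frame of per-file results.
#' @export
fragment_batch <- function(dir, params = fragment_params(),
                           csv_path = NULL, overlay_dir = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE))
  if (!is.null(overlay_dir))
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(files, function(f) {
    img <- .read_raster(file.path(dir, f))[[1]]
    res <- count_fragments(img, params)
    if (!is.null(overlay_dir))
      write_fragment_overlay(img, res, params,
                             file.path(overlay_dir,
                                       paste0(tools::file_path_sans_ext(f),
                                              "_overlay.png")))
    data.frame(file = f, n_fragments = res$n_fragments,
               areas = paste(res$fragment_areas, collapse = ";"))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), n_fragments = integer(0),
               areas = character(0))
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Overlay image of counted fragments
#'
#' Writes the dish image as PNG with the counted fragments (those passing
#' the minimum area) outlined in yellow, the assay's display convention.
#'
#' @param image `channel_image` or matrix.
#' @param result The `fragment_result` for that image.
#' @param params The [fragment_params()] used.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_fragment_overlay <- function(image, result, params, path) {
  m <- .as_pixels(image)
  dish <- detect_dish(m, params$dish_detection)
  inside <- m[dish]
  thr <- if (params$threshold_method == "otsu") {
    if (max(inside) - stats::median(inside) < params$min_contrast) Inf
    else otsu_threshold(matrix(.clip01(inside), ncol = 1))
  } else params$fixed_threshold
  fgmask <- (m > thr) & dish
  rgb <- array(rep(m, 3), c(dim(m), 3))
  if (any(fgmask)) {
    comp <- label_components(fgmask, 8L)
    areas <- tabulate(comp[comp > 0L], nbins = max(comp))
    kept <- which(areas >= params$min_fragment_area)
    keepmask <- matrix(comp %in% kept & comp > 0L, nrow(m))
    # boundary: kept pixels adjacent to non-kept
    pad <- function(sh_r, sh_c) {
      out <- matrix(FALSE, nrow(m), ncol(m))
      src_r <- seq_len(nrow(m)) - sh_r
      src_c <- seq_len(ncol(m)) - sh_c
      ok_r <- src_r >= 1 & src_r <= nrow(m)
      ok_c <- src_c >= 1 & src_c <= ncol(m)
      out[ok_r, ok_c] <- keepmask[src_r[ok_r], src_c[ok_c]]
      out
    }
    nb <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
    edge <- keepmask & !nb
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[edge] <- c(1, 1, 0)[k]
      rgb[, , k] <- plane
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
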