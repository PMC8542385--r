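#' Single-channel fluorescence image
#'
#' A lightweight container for one 2-D intensity plane. Pixels are stored as
#' a numeric matrix in `[0, 1]`, indexed `[row, col]` with origin at the top
#' left; bit depth only exists at file I/O.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param name Channel label (e.g. `"nuclei"`, `"gfp"`).
#' @param pixel_size Optional pixel size in micrometres per pixel.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, name = "channel", pixel_size = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height and width >= 1")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite values")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("intensities must lie in [0, 1]")
  structure(
    list(pixels = pmin(pmax(pixels, 0), 1), name = as.character(name),
         pixel_size = pixel_size),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s' %dx%d px, range [%.3f, %.3f]>\n",
              x$name, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# accept a channel_image or a bare matrix
.as_pixels <- function(image) {
  if (inherits(image, "channel_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected a channel_image or numeric matrix")
}

#' Multi-channel field
#'
#' Named channels sharing one pixel grid. Aggregate analysis requires
#' channels `"nuclei"` and `"gfp"`; viability analysis requires `"hoechst"`
#' and `"ethd1"`.
#'
#' @param channels Named list of `channel_image` objects (or matrices).
#' @param provenance Free-form record of where the field came from (a file
#'   path or a generator configuration).
#' @return An object of class `mc_image`.
#' @export
multichannel_image <- function(channels, provenance = NULL) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  channels <- lapply(names(channels), function(nm) {
    ch <- channels[[nm]]
    if (is.matrix(ch)) ch <- channel_image(ch, name = nm)
    if (!inherits(ch, "channel_image")) stop("invalid channel: ", nm)
    ch$name <- nm
    ch
  })
  names(channels) <- vapply(channels, `[[`, "", "name")
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share identical dimensions")
  structure(list(channels = channels, provenance = provenance),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]]$pixels)
  cat(sprintf("<mc_image %dx%d px, channels: %s>\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Fetch one channel of a field
#'
#' @param field An `mc_image`.
#' @param name Channel name.
#' @return The `channel_image`; error if absent.
#' @export
get_channel <- function(field, name) {
  if (!inherits(field, "mc_image")) stop("expected an mc_image")
  ch <- field$channels[[name]]
  if (is.null(ch))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(field$channels), collapse = ", ")))
  ch
}

.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, .collapse_gray)
  } else if (ext == "png") {
    list(.collapse_gray(png::readPNG(path)))
  } else {
    stop("unreadable format '", ext, "' (TIFF or PNG expected): ", path)
  }
}

# grey-scale a H x W x k array by averaging colour planes
.collapse_gray <- function(a) {
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  if (!is.matrix(a)) a <- as.matrix(a)
  a
}

#' Read a multi-channel field from image files
#'
#' Intensities are normalized to `[0, 1]` (16-bit and 8-bit files map their
#' full integer range onto the unit interval).
#'
#' @param path A single TIFF/PNG file (with `channel_map` giving page
#'   numbers), or a directory (with `channel_map` giving file names).
#' @param channel_map Named vector mapping channel names to page indices
#'   (single multi-page file) or to file names/paths (one file per channel).
#' @return An `mc_image` with provenance recording `path`.
#' @export
read_field <- function(path, channel_map) {
  if (length(channel_map) < 1L || is.null(names(channel_map)))
    stop("channel_map must be a named vector")
  chans <- list()
  if (length(path) == 1L && dir.exists(path)) {
    for (nm in names(channel_map))
      chans[[nm]] <- .read_raster(file.path(path, channel_map[[nm]]))[[1]]
  } else if (is.numeric(channel_map) ||
             all(!is.na(suppressWarnings(as.numeric(channel_map))))) {
    pages <- .read_raster(path)
    idx <- as.numeric(channel_map)
    if (any(idx < 1 | idx > length(pages)))
      stop(sprintf("channel_map asks for page %d but '%s' has %d page(s)",
                   max(idx), path, length(pages)))
    for (i in seq_along(channel_map))
      chans[[names(channel_map)[i]]] <- pages[[idx[i]]]
  } else {
    for (nm in names(channel_map))
      chans[[nm]] <- .read_raster(file.path(dirname(path),
                                            channel_map[[nm]]))[[1]]
  }
  multichannel_image(chans, provenance = list(path = path,
                                              channel_map = channel_map))
}

#' Write a field as a multi-page 16-bit TIFF
#'
#' @param field An `mc_image`.
#' @param path Output file path (`.tif`).
#' @return Invisibly, the channel names in page order.
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "mc_image")) stop("expected an mc_image")
  pages <- lapply(field$channels, function(ch) ch$pixels)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L)
  invisible(names(field$channels))
}
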