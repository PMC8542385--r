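# Synthetic fluorescence fields with exact ground truth.
#
# The generator emulates subconfluent GFP-K14 reporter keratinocyte
# colonies: a nuclei channel of Gaussian blobs and a GFP channel of dim
# oriented filamentous texture within the colony footprint, plus bright
# circular puncta (keratin aggregates) planted in a controlled fraction of
# cells, biased toward the cell periphery. Every stochastic choice is
# driven by the seed in the configuration, so identical configurations
# give bit-identical images and scenes.

#' Configuration for the reporter-field generator
#'
#' Defaults describe the assay's baseline regime: mutant reporter cells in
#' which roughly three quarters of cells carry aggregates (the untreated
#' condition shows 70--80% aggregate-positive cells), aggregates much
#' brighter than the filament texture, and moderate peripheral placement
#' bias.
#'
#' @param image_height,image_width Field size in pixels.
#' @param n_cells Number of cells (nuclei) to place.
#' @param aggregate_fraction Fraction of cells carrying aggregates, in
#'   `[0, 1]`. The positive count is `round half up` of
#'   `aggregate_fraction * n_cells`.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius (px).
#' @param cell_radius_mean Cell footprint radius (px); footprints are the
#'   Voronoi cell of each nucleus centre clipped to this radius.
#' @param aggregates_per_positive_cell Puncta planted per positive cell.
#' @param aggregate_radius Punctum radius (px).
#' @param aggregate_peak_intensity Peak punctum intensity (relative units);
#'   must exceed `filament_texture_intensity`.
#' @param filament_texture_intensity Amplitude of the filament texture;
#'   must exceed `background_level`.
#' @param background_level Background intensity outside the colony.
#' @param noise_sd Additive Gaussian noise s.d. (clipped to `[0, 1]`).
#' @param peripheral_bias Probability that a punctum is drawn from the
#'   outer half of the cell radius (1 = all peripheral).
#' @param seed Integer seed; equal config + seed gives identical output.
#' @return A validated `generation_config`.
#' @export
generation_config <- function(image_height = 320L, image_width = 320L,
                              n_cells = 80L,
                              aggregate_fraction = 0.75,
                              nucleus_radius_mean = 4,
                              nucleus_radius_sd = 0.5,
                              cell_radius_mean = 12,
                              aggregates_per_positive_cell = 2L,
                              aggregate_radius = 2,
                              aggregate_peak_intensity = 0.85,
                              filament_texture_intensity = 0.15,
                              background_level = 0.04,
                              noise_sd = 0.01,
                              peripheral_bias = 0.6,
                              seed = 1L) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              n_cells = as.integer(n_cells),
              aggregate_fraction = aggregate_fraction,
              nucleus_radius_mean = nucleus_radius_mean,
              nucleus_radius_sd = nucleus_radius_sd,
              cell_radius_mean = cell_radius_mean,
              aggregates_per_positive_cell =
                as.integer(aggregates_per_positive_cell),
              aggregate_radius = aggregate_radius,
              aggregate_peak_intensity = aggregate_peak_intensity,
              filament_texture_intensity = filament_texture_intensity,
              background_level = background_level,
              noise_sd = noise_sd,
              peripheral_bias = peripheral_bias,
              seed = as.integer(seed))
  if (cfg$aggregate_fraction < 0 || cfg$aggregate_fraction > 1)
    stop("aggregate_fraction must lie in [0, 1]")
  if (cfg$peripheral_bias < 0 || cfg$peripheral_bias > 1)
    stop("peripheral_bias must lie in [0, 1]")
  if (!(cfg$aggregate_peak_intensity > cfg$filament_texture_intensity &&
        cfg$filament_texture_intensity > cfg$background_level))
    stop("need aggregate_peak_intensity > filament_texture_intensity > ",
         "background_level")
  if (cfg$nucleus_radius_mean <= 0 || cfg$cell_radius_mean <= 0 ||
      cfg$aggregate_radius <= 0)
    stop("all radii must be positive")
  if (cfg$n_cells < 1L) stop("n_cells must be >= 1")
  if (cfg$aggregates_per_positive_cell < 1L)
    stop("aggregates_per_positive_cell must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "generation_config")
}

# round half up (2.5 -> 3), used for the planted-positive count
.round_half_up <- function(x) floor(x + 0.5)

# rejection-sample n centres with minimum spacing inside a sampler's
# domain; a coarse bucket grid keeps each proposal's neighbour check O(1)
.place_centres <- function(n, spacing, draw, max_tries = 400L * n) {
  centres <- matrix(NA_real_, n, 2)
  cell <- spacing  # bucket side >= spacing: check 3x3 neighbourhood
  buckets <- new.env(parent = emptyenv())
  bkey <- function(i, j) paste(i, j)
  placed <- 0L
  tries <- 0L
  s2 <- spacing^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(paste0("could not place %d centres with minimum spacing ",
                          "%.1f px after %d attempts: requested density ",
                          "exceeds the packing limit"), n, spacing, max_tries))
    p <- draw()
    bi <- floor(p[1] / cell); bj <- floor(p[2] / cell)
    ok <- TRUE
    for (di in -1:1) {
      for (dj in -1:1) {
        ids <- buckets[[bkey(bi + di, bj + dj)]]
        if (!is.null(ids)) {
          d2 <- (centres[ids, 1] - p[1])^2 + (centres[ids, 2] - p[2])^2
          if (min(d2) < s2) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    centres[placed, ] <- p
    k <- bkey(bi, bj)
    buckets[[k]] <- c(buckets[[k]], placed)
  }
  centres
}

# add amp * exp(-d^2 / (2 sigma^2)) at (r0, c0), evaluated on a local window
.add_gaussian_blob <- function(img, r0, c0, sigma, amp, extent = 3) {
  h <- nrow(img); w <- ncol(img)
  e <- ceiling(extent * sigma)
  rr <- max(1L, floor(r0 - e)):min(h, ceiling(r0 + e))
  cc <- max(1L, floor(c0 - e)):min(w, ceiling(c0 + e))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
  img
}

# oriented band-pass noise, unit-sd, orientation chosen by current RNG
# state; strong elongation (~10:1) makes streaks locally one-dimensional,
# like filament bundles, so they respond far less to blob filters than
# compact puncta of equal amplitude
.filament_texture <- function(h, w) {
  raw <- matrix(stats::rnorm(h * w), h, w)
  if (stats::runif(1) < 0.5) sig <- c(0.8, 8) else sig <- c(8, 0.8)
  lowR <- .conv_operator(h, .gauss_kernel(sig[1]))
  lowC <- .conv_operator(w, .gauss_kernel(sig[2]))
  sm <- lowR %*% raw %*% t(lowC)
  bp <- sm - gaussian_blur(sm, 6)
  bp / stats::sd(bp)
}

.clip01 <- function(m) pmin(pmax(m, 0), 1)

.add_noise <- function(m, sd) {
  if (sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
  .clip01(m)
}

#' Generate a synthetic two-channel reporter field
#'
#' Produces an `mc_image` with channels `"nuclei"` and `"gfp"` plus a
#' `synthetic_scene` holding the exact ground truth (nucleus centres and
#' label map, per-cell footprints, the positive-cell set and every planted
#' punctum). Cells form a round subconfluent colony; footprints are
#' nucleus-centre Voronoi cells clipped to `cell_radius_mean`, so planted
#' puncta always lie inside their own cell's footprint.
#'
#' @param config A [generation_config()].
#' @return A list with elements `image` (`mc_image`) and `scene`
#'   (`synthetic_scene`).
#' @export
generate_reporter_field <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$seed)
  h <- config$image_height; w <- config$image_width
  n <- config$n_cells
  spacing <- max(2.4 * config$nucleus_radius_mean + 2,
                 0.9 * config$cell_radius_mean)
  r_colony <- min(spacing * sqrt(0.6 * n),
                  min(h, w) / 2 - config$cell_radius_mean - 2)
  if (r_colony <= spacing)
    stop("image too small for requested n_cells: density exceeds the ",
         "packing limit")
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  draw <- function() {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- r_colony * sqrt(stats::runif(1))
    ctr + rad * c(cos(ang), sin(ang))
  }
  centres <- .place_centres(n, spacing, draw)
  radii <- pmax(1.5, stats::rnorm(n, config$nucleus_radius_mean,
                                  config$nucleus_radius_sd))

  # ground-truth footprints: nearest nucleus centre, clipped to cell
  # radius. Only pixels within cell_radius of a centre can be owned, so
  # each cell is resolved on a local window.
  best_d2 <- matrix(Inf, h, w)
  footprints <- matrix(0L, h, w)
  nuc_map <- matrix(0L, h, w)
  r_cell <- config$cell_radius_mean
  for (i in seq_len(n)) {
    rr <- max(1L, floor(centres[i, 1] - r_cell)):
          min(h, ceiling(centres[i, 1] + r_cell))
    cc <- max(1L, floor(centres[i, 2] - r_cell)):
          min(w, ceiling(centres[i, 2] + r_cell))
    d2 <- outer((rr - centres[i, 1])^2, (cc - centres[i, 2])^2, "+")
    upd <- d2 <= r_cell^2 & d2 < best_d2[rr, cc]  # strict: smaller label
    bw <- best_d2[rr, cc]; bw[upd] <- d2[upd]; best_d2[rr, cc] <- bw
    fw <- footprints[rr, cc]; fw[upd] <- i; footprints[rr, cc] <- fw
    nw <- nuc_map[rr, cc]; nw[d2 <= radii[i]^2] <- i; nuc_map[rr, cc] <- nw
  }

  # positive cells and aggregate placement
  n_pos <- as.integer(.round_half_up(config$aggregate_fraction * n))
  positive <- if (n_pos > 0L) sort(sample.int(n, n_pos)) else integer(0)
  n_agg_max <- length(positive) * config$aggregates_per_positive_cell
  agg_cell <- integer(n_agg_max); agg_r <- agg_c <- numeric(n_agg_max)
  n_agg <- 0L
  for (cell in positive) {
    for (k in seq_len(config$aggregates_per_positive_cell)) {
      pos <- NULL
      for (try in 1:200) {
        peripheral <- stats::runif(1) < config$peripheral_bias
        frac <- if (peripheral) stats::runif(1, 0.5, 0.9)
                else stats::runif(1, 0.15, 0.9)
        ang <- stats::runif(1, 0, 2 * pi)
        p <- centres[cell, ] + frac * config$cell_radius_mean *
          c(cos(ang), sin(ang))
        pr <- round(p[1]); pc <- round(p[2])
        if (pr >= 1 && pr <= h && pc >= 1 && pc <= w &&
            footprints[pr, pc] == cell) { pos <- p; break }
      }
      if (is.null(pos)) {  # dense packing: fall back to any footprint pixel
        idx <- which(footprints == cell)
        if (length(idx) == 0L) next
        pick <- idx[1 + (length(idx) %/% 2)]
        pos <- c((pick - 1) %% h + 1, (pick - 1) %/% h + 1)
      }
      n_agg <- n_agg + 1L
      agg_cell[n_agg] <- cell; agg_r[n_agg] <- pos[1]; agg_c[n_agg] <- pos[2]
    }
  }
  agg <- data.frame(cell = agg_cell[seq_len(n_agg)],
                    row = agg_r[seq_len(n_agg)],
                    col = agg_c[seq_len(n_agg)],
                    radius = rep(config$aggregate_radius, n_agg))

  # nuclei channel
  nuch <- matrix(0, h, w)
  for (i in seq_len(n))
    nuch <- .add_gaussian_blob(nuch, centres[i, 1], centres[i, 2],
                               radii[i] / 1.4, 0.8)
  nuch <- .add_noise(.clip01(nuch + 0.02), config$noise_sd)

  # gfp channel: colony base + filament texture + planted puncta
  tex <- .filament_texture(h, w)
  fg <- footprints > 0L
  gfp <- matrix(config$background_level, h, w)
  gfp[fg] <- gfp[fg] + 0.6 * config$filament_texture_intensity +
    0.35 * config$filament_texture_intensity * tex[fg]
  if (nrow(agg) > 0L)
    for (j in seq_len(nrow(agg)))
      gfp <- .add_gaussian_blob(gfp, agg$row[j], agg$col[j],
                                agg$radius[j] / 1.5,
                                config$aggregate_peak_intensity)
  gfp <- .add_noise(.clip01(gfp), config$noise_sd)

  scene <- structure(
    list(nucleus_centres = centres, nucleus_radii = radii,
         nucleus_label_map = nuc_map, cell_footprints = footprints,
         positive_cells = positive, aggregate_coords = agg,
         dead_cells = integer(0), n_positive_planted = n_pos,
         config = config),
    class = "synthetic_scene")
  image <- multichannel_image(list(nuclei = nuch, gfp = gfp),
                              provenance = list(generator = "reporter_field",
                                                config = unclass(config)))
  list(image = image, scene = scene)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene %d cells, %d positive, %d puncta, %d dead>\n",
    nrow(x$nucleus_centres), length(x$positive_cells),
    nrow(x$aggregate_coords), length(x$dead_cells)))
  invisible(x)
}

# deterministically grow a connected blob of exactly n_px pixels around the
# origin; jitter makes the outline irregular. Offsets returned as (row, col).
.grow_blob <- function(n_px) {
  cap <- max(4L * n_px, 64L)
  key <- function(r, c) paste(r, c)
  chosen_r <- integer(n_px); chosen_c <- integer(n_px)
  in_set <- new.env(parent = emptyenv(), size = cap)
  fr_r <- c(0L); fr_c <- c(0L)
  fr_score <- c(0)
  seen <- new.env(parent = emptyenv(), size = cap)
  assign(key(0L, 0L), TRUE, envir = seen)
  for (i in seq_len(n_px)) {
    j <- which.min(fr_score)
    r <- fr_r[j]; c <- fr_c[j]
    fr_r <- fr_r[-j]; fr_c <- fr_c[-j]; fr_score <- fr_score[-j]
    chosen_r[i] <- r; chosen_c[i] <- c
    assign(key(r, c), TRUE, envir = in_set)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nr <- r + d[1]; nc <- c + d[2]
      k <- key(nr, nc)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        fr_r <- c(fr_r, nr); fr_c <- c(fr_c, nc)
        fr_score <- c(fr_score,
                      sqrt(nr^2 + nc^2) * (1 + 0.35 * stats::runif(1)))
      }
    }
  }
  cbind(chosen_r, chosen_c)
}

#' Generate a synthetic dispase dish image
#'
#' A dim bright dish disk on a dark background, containing one connected
#' bright fragment per requested pixel area. Fragment shapes are irregular
#' blobs grown pixel-by-pixel to exactly the requested area, placed with at
#' least 2 px separation, so downstream thresholding recovers the planted
#' areas exactly.
#'
#' @param areas Integer vector of fragment areas in pixels (may be empty).
#' @param dish_radius Dish radius in pixels.
#' @param seed Integer seed.
#' @param image_size Optional square image side (default fits the dish).
#' @return A list with `image` (`channel_image`), `labels` (ground-truth
#'   fragment label map) and `dish_centre`/`dish_radius`.
#' @export
generate_fragment_dish <- function(areas, dish_radius = 150, seed = 1L,
                                   image_size = NULL) {
  set.seed(as.integer(seed))
  if (is.null(image_size)) image_size <- as.integer(ceiling(2.35 * dish_radius))
  h <- w <- as.integer(image_size)
  ctr <- (h + 1) / 2
  if (length(areas) && any(areas < 1)) stop("fragment areas must be >= 1")
  if (length(areas) && any(areas >= pi * dish_radius^2))
    stop("fragment larger than the dish")
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  dish <- (rowg - ctr)^2 + (colg - ctr)^2 <= dish_radius^2
  img <- matrix(0.03, h, w)
  img[dish] <- 0.18
  labels <- matrix(0L, h, w)
  occupied <- matrix(FALSE, h, w)
  for (i in seq_along(areas)) {
    blob <- .grow_blob(as.integer(areas[i]))
    br <- max(abs(blob))  # bounding radius of the blob
    placed <- FALSE
    for (try in 1:400) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- max(dish_radius - br - 4, 0) * sqrt(stats::runif(1))
      r0 <- round(ctr + rad * cos(ang)); c0 <- round(ctr + rad * sin(ang))
      rr <- blob[, 1] + r0; cc <- blob[, 2] + c0
      if (any(rr < 3 | rr > h - 2 | cc < 3 | cc > w - 2)) next
      # require 2-px clearance around previously placed fragments
      clear <- TRUE
      for (dr in -2:2) {
        for (dc in -2:2) {
          if (any(occupied[cbind(rr + dr, cc + dc)])) { clear <- FALSE; break }
        }
        if (!clear) break
      }
      if (!clear) next
      idx <- cbind(rr, cc)
      labels[idx] <- i
      occupied[idx] <- TRUE
      img[idx] <- 0.85 + 0.04 * (stats::runif(length(rr)) - 0.5)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place fragment ", i,
           " inside the dish with 2-px separation")
  }
  img <- .add_noise(img, 0.005)
  list(image = channel_image(img, name = "dish"), labels = labels,
       dish_centre = c(ctr, ctr), dish_radius = dish_radius)
}

#' Generate a synthetic LIVE/DEAD viability field
#'
#' Three channels: `"hoechst"` (all nuclei), `"ethd1"` (dead-cell nuclei,
#' co-located with their Hoechst blobs) and `"calcein"` (cytoplasm of live
#' cells only).
#'
#' @param n_cells Total number of cells.
#' @param n_dead Number of dead cells (must be `<= n_cells`).
#' @param seed Integer seed.
#' @param image_height,image_width Field size in pixels.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius (px).
#' @return A list with `image` (`mc_image`) and `scene` (`synthetic_scene`
#'   with `dead_cells` filled in).
#' @export
generate_viability_field <- function(n_cells, n_dead, seed = 1L,
                                     image_height = 360L, image_width = 360L,
                                     nucleus_radius_mean = 4,
                                     nucleus_radius_sd = 0.5) {
  if (n_dead > n_cells) stop("n_dead must not exceed n_cells")
  set.seed(as.integer(seed))
  h <- as.integer(image_height); w <- as.integer(image_width)
  # sparse monolayer: generous spacing keeps nuclei resolvable
  spacing <- 3.2 * nucleus_radius_mean + 2
  margin <- 2 * nucleus_radius_mean + 2
  draw <- function() c(stats::runif(1, margin, h - margin),
                       stats::runif(1, margin, w - margin))
  centres <- .place_centres(n_cells, spacing, draw)
  radii <- pmax(1.5, stats::rnorm(n_cells, nucleus_radius_mean,
                                  nucleus_radius_sd))
  dead <- if (n_dead > 0L) sort(sample.int(n_cells, n_dead)) else integer(0)
  live <- setdiff(seq_len(n_cells), dead)
  hoechst <- matrix(0, h, w)
  ethd1 <- matrix(0, h, w)
  calcein <- matrix(0, h, w)
  nuc_map <- matrix(0L, h, w)
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_cells)) {
    hoechst <- .add_gaussian_blob(hoechst, centres[i, 1], centres[i, 2],
                                  radii[i] / 1.4, 0.8)
    d2 <- (rowg - centres[i, 1])^2 + (colg - centres[i, 2])^2
    nuc_map[d2 <= radii[i]^2] <- i
    if (i %in% dead)
      ethd1 <- .add_gaussian_blob(ethd1, centres[i, 1], centres[i, 2],
                                  radii[i] / 1.4, 0.8)
    else
      calcein <- .add_gaussian_blob(calcein, centres[i, 1], centres[i, 2],
                                    2.2 * radii[i], 0.5, extent = 1.6)
  }
  noise <- 0.01
  img <- multichannel_image(
    list(hoechst = .add_noise(.clip01(hoechst + 0.02), noise),
         ethd1 = .add_noise(.clip01(ethd1 + 0.02), noise),
         calcein = .add_noise(.clip01(calcein + 0.02), noise)),
    provenance = list(generator = "viability_field", n_cells = n_cells,
                      n_dead = n_dead, seed = seed))
  scene <- structure(
    list(nucleus_centres = centres, nucleus_radii = radii,
         nucleus_label_map = nuc_map, cell_footprints = nuc_map,
         positive_cells = integer(0),
         aggregate_coords = data.frame(cell = integer(0), row = numeric(0),
                                       col = numeric(0), radius = numeric(0)),
         dead_cells = dead, live_cells = live, config = NULL),
    class = "synthetic_scene")
  list(image = img, scene = scene)
}

#' Defocus an image
#'
#' Gaussian-smooths a copy of the image; `sigma = 0` returns it unchanged.
#' Used to build blur-rejection test inputs for [qc_filter()].
#'
#' @param image A `channel_image` or numeric matrix.
#' @param sigma Blur scale in pixels, `>= 0`.
#' @return Same type as the input.
#' @export
degrade_focus <- function(image, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  m <- .as_pixels(image)
  out <- if (sigma == 0) m else .clip01(gaussian_blur(m, sigma))
  if (inherits(image, "channel_image"))
    channel_image(out, name = image$name, pixel_size = image$pixel_size)
  else out
}
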