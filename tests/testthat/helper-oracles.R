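# Brute-force reference implementations, independent of the package's
# optimized paths. Only used on small fixtures.

# nearest labelled component per pixel, ties to the smaller label
brute_voronoi <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  sites <- which(labels > 0, arr.ind = TRUE)
  assign <- matrix(0L, h, w)
  dist2 <- matrix(Inf, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      d2 <- (sites[, 1] - r)^2 + (sites[, 2] - c)^2
      best <- min(d2)
      labs <- labels[sites[d2 == best, , drop = FALSE]]
      assign[r, c] <- min(labs)
      dist2[r, c] <- best
    }
  }
  list(assign = assign, dist2 = dist2)
}

# connected components by explicit flood fill (stack-based)
brute_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# per-pixel reimplementation of region calling: threshold, flood-fill
# components, assign each to the region of its max-response pixel
# (smallest linear index on ties), keep by inclusive area window
brute_call_regions <- function(response, regions, intensity_min,
                               area_min, area_max) {
  lab <- regions$region_labels$labels
  mask <- response >= intensity_min
  comp <- brute_components(mask, 8)
  n_puncta <- integer(regions$region_labels$n_labels)
  if (max(comp) > 0) {
    for (k in seq_len(max(comp))) {
      px <- which(comp == k)
      area <- length(px)
      vmax <- max(response[px])
      owner_px <- px[response[px] == vmax][1]
      reg <- lab[owner_px]
      if (area >= area_min && area <= area_max &&
          reg > 0 && reg %in% regions$analyzable)
        n_puncta[reg] <- n_puncta[reg] + 1L
    }
  }
  data.frame(region_label = regions$analyzable,
             has_aggregates = n_puncta[regions$analyzable] >= 1L,
             n_puncta = n_puncta[regions$analyzable])
}

# direct 2-D convolution of an image with a centred Gaussian, values only
# needed far from the border (no padding applied)
brute_gauss_response <- function(m, sigma_small, sigma_large) {
  kern <- function(sigma) {
    r <- max(1L, ceiling(3 * sigma))
    x <- (-r):r
    k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
    outer(k1, k1)
  }
  conv <- function(m, K) {
    r <- (nrow(K) - 1) / 2
    out <- matrix(NA_real_, nrow(m), ncol(m))
    for (i in (1 + r):(nrow(m) - r)) {
      for (j in (1 + r):(ncol(m) - r)) {
        out[i, j] <- sum(m[(i - r):(i + r), (j - r):(j + r)] * K)
      }
    }
    out
  }
  conv(m, kern(sigma_small)) - conv(m, kern(sigma_large))
}

# small reporter-field configuration used across tests (fast to generate)
small_config <- function(...) {
  args <- utils::modifyList(list(image_height = 160L, image_width = 160L,
                                 n_cells = 16L), list(...))
  do.call(generation_config, args)
}

# map analyzable regions of a field_result to ground-truth cells via the
# region label found at each true nucleus centre
truth_by_region <- function(result, scene) {
  lab <- result$regions$region_labels$labels
  n <- result$regions$region_labels$n_labels
  truth <- rep(NA_integer_, n)
  for (i in seq_len(nrow(scene$nucleus_centres))) {
    r <- round(scene$nucleus_centres[i, 1])
    c <- round(scene$nucleus_centres[i, 2])
    l <- lab[r, c]
    if (l > 0) truth[l] <- i
  }
  truth
}

# pooled per-cell confusion counts over one analyzed field
confusion_counts <- function(result, scene) {
  truth <- truth_by_region(result, scene)
  tp <- fp <- fn <- tn <- 0L
  for (k in seq_len(nrow(result$calls))) {
    gt <- truth[result$calls$region_label[k]]
    if (is.na(gt)) next
    pos_true <- gt %in% scene$positive_cells
    pos_pred <- result$calls$has_aggregates[k]
    if (pos_pred && pos_true) tp <- tp + 1L
    else if (pos_pred) fp <- fp + 1L
    else if (pos_true) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
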