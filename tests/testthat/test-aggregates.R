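# Difference-of-Gaussians enhancement, per-region calling, percent
# positive, and the composed per-field pipeline.

# one-region fixture: a single nucleus so the whole image is one region,
# forced analyzable by disabling edge exclusion effects via a 1-region map
one_region_set <- function(h, w) {
  lab <- matrix(1L, h, w)
  vor <- keragg:::.label_map(lab, 1L)
  structure(list(region_labels = vor, excluded_edge = integer(0),
                 excluded_background = integer(0), analyzable = 1L,
                 nucleus_of_region = 1L, region_areas = h * w,
                 nucleus_areas = 50L, gfp_coverage = 1),
            class = "cell_region_set")
}

test_that("DoG response of a constant image is zero", {
  resp <- enhance_puncta(matrix(0.4, 32, 32))
  expect_lt(max(abs(resp)), 1e-12)
})

test_that("DoG matches direct convolution away from the border", {
  set.seed(3)
  m <- matrix(0, 21, 21)
  m[11, 11] <- 1
  m <- m + matrix(runif(441, 0, 0.05), 21, 21)
  got <- enhance_puncta(m, aggregate_params(dog_sigma_small = 1,
                                            dog_sigma_large = 2))
  ref <- brute_gauss_response(m, 1, 2)
  interior <- !is.na(ref)
  expect_equal(got[interior], ref[interior], tolerance = 1e-10)
  expect_equal(which.max(got), which.max(replace(ref, is.na(ref), -Inf)))
})

test_that("puncta outscore broad blobs of equal peak intensity", {
  h <- 41
  d2 <- outer((1:h - 21)^2, (1:h - 21)^2, "+")
  punctum <- 0.8 * exp(-d2 / (2 * 1.2^2))     # radius ~ sigma_small
  blob <- 0.8 * exp(-d2 / (2 * 12^2))         # radius >> sigma_large
  p <- aggregate_params()
  expect_gt(max(enhance_puncta(punctum, p)), max(enhance_puncta(blob, p)))
  expect_error(aggregate_params(dog_sigma_small = 4, dog_sigma_large = 2),
               "dog_sigma_small")
})

test_that("region calling honours the inclusive area window", {
  regions <- one_region_set(30, 30)
  resp <- matrix(0, 30, 30)
  resp[10:11, 10:11] <- 1  # 4-pixel component
  p4 <- aggregate_params(intensity_min = 0.5, punctum_area_min = 4,
                         punctum_area_max = 100)
  calls <- call_regions(resp, regions, p4)
  expect_true(calls$has_aggregates)
  expect_equal(calls$n_puncta, 1L)

  p5 <- aggregate_params(intensity_min = 0.5, punctum_area_min = 5,
                         punctum_area_max = 100)
  expect_false(call_regions(resp, regions, p5)$has_aggregates)

  # sub-threshold response: negative call
  quiet <- call_regions(matrix(0.01, 30, 30), regions,
                        aggregate_params(intensity_min = 0.5,
                                         punctum_area_max = 100))
  expect_false(quiet$has_aggregates)

  no_regions <- one_region_set(30, 30)
  no_regions$analyzable <- integer(0)
  no_regions$excluded_edge <- 1L
  expect_error(call_regions(resp, no_regions, p4), "nothing to call")
})

test_that("raising thresholds never increases the positive count", {
  gen <- generate_reporter_field(small_config(n_cells = 14, seed = 9))
  nuc <- segment_nuclei(get_channel(gen$image, "nuclei"))
  vor <- voronoi_regions(nuc)
  regs <- exclude_background_and_edge(vor, get_channel(gen$image, "gfp"),
                                      segmentation_params(), nuc)
  resp <- enhance_puncta(get_channel(gen$image, "gfp"))
  pos_at <- function(imin, amin) {
    sum(call_regions(resp, regs,
                     aggregate_params(intensity_min = imin,
                                      punctum_area_min = amin,
                                      punctum_area_max = 1e6)
                     )$has_aggregates)
  }
  by_intensity <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), pos_at, 0,
                         amin = 4)
  expect_true(all(diff(by_intensity) <= 0))
  by_area <- vapply(c(1, 4, 10, 30, 80), function(a) pos_at(0.05, a), 0)
  expect_true(all(diff(by_area) <= 0))
})

test_that("region calling matches the brute-force reimplementation", {
  for (seed in 1:4) {
    gen <- generate_reporter_field(
      generation_config(image_height = 64L, image_width = 64L,
                        n_cells = 5L, cell_radius_mean = 10,
                        seed = seed))
    nuc <- segment_nuclei(get_channel(gen$image, "nuclei"))
    vor <- voronoi_regions(nuc)
    regs <- exclude_background_and_edge(vor, get_channel(gen$image, "gfp"),
                                        segmentation_params(), nuc)
    if (length(regs$analyzable) == 0) next
    resp <- enhance_puncta(get_channel(gen$image, "gfp"))
    params <- aggregate_params(intensity_min = 0.1,
                               punctum_area_min = 4,
                               punctum_area_max = 60)
    got <- call_regions(resp, regs, params)
    ref <- brute_call_regions(resp, regs, 0.1, 4, 60)
    expect_identical(got$region_label, ref$region_label)
    expect_identical(got$has_aggregates, ref$has_aggregates)
    expect_identical(got$n_puncta, ref$n_puncta)
  }
})

test_that("percent_positive implements the published formula", {
  expect_equal(percent_positive(3, 4), 75)
  expect_equal(percent_positive(0, 10), 0)
  expect_equal(percent_positive(7, 28), 25)
  expect_error(percent_positive(1, 0), "undefined")
  expect_error(percent_positive(5, 4), "n_positive")
})

test_that("analyze_field composes the stages and respects QC", {
  gen0 <- generate_reporter_field(small_config(aggregate_fraction = 0,
                                               seed = 2))
  r0 <- analyze_field(gen0$image)
  expect_equal(r0$percent_positive, 0)
  expect_equal(r0$n_positive + r0$n_negative, r0$n_regions_total)

  gen <- generate_reporter_field(small_config(seed = 2))
  blurred <- multichannel_image(list(
    nuclei = get_channel(gen$image, "nuclei")$pixels,
    gfp = degrade_focus(get_channel(gen$image, "gfp"), 6)$pixels))
  rb <- analyze_field(blurred)
  expect_equal(rb$status, "rejected")
  expect_false(rb$qc$accepted)
  expect_null(rb$calls)

  # determinism of the whole pipeline
  ra <- analyze_field(gen$image)
  rc <- analyze_field(gen$image)
  expect_identical(ra$calls, rc$calls)
  expect_identical(ra$percent_positive, rc$percent_positive)
})

test_that("planted percentages are recovered across seeds", {
  errs <- vapply(1:10, function(s) {
    gen <- generate_reporter_field(
      generation_config(n_cells = 20L, aggregate_fraction = 0.7,
                        image_height = 192L, image_width = 192L, seed = s))
    analyze_field(gen$image)$percent_positive - 70
  }, 0)
  expect_lte(mean(abs(errs)), 10)
})
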