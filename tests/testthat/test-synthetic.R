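# Synthetic generators: determinism, ground-truth bookkeeping, and the
# geometric invariants the detection pipeline relies on.

test_that("identical config and seed give bit-identical fields", {
  cfg <- small_config(seed = 1)
  a <- generate_reporter_field(cfg)
  b <- generate_reporter_field(cfg)
  expect_identical(get_channel(a$image, "nuclei")$pixels,
                   get_channel(b$image, "nuclei")$pixels)
  expect_identical(get_channel(a$image, "gfp")$pixels,
                   get_channel(b$image, "gfp")$pixels)
  expect_identical(a$scene$positive_cells, b$scene$positive_cells)
  expect_identical(a$scene$aggregate_coords, b$scene$aggregate_coords)
})

test_that("planted positive count follows round-half-up of the fraction", {
  s0 <- generate_reporter_field(small_config(n_cells = 10,
                                             aggregate_fraction = 0))$scene
  expect_length(s0$positive_cells, 0)
  expect_equal(nrow(s0$aggregate_coords), 0)

  s7 <- generate_reporter_field(small_config(n_cells = 10,
                                             aggregate_fraction = 0.7))$scene
  expect_length(s7$positive_cells, 7)

  # 10 * 0.65 = 6.5 rounds half up to 7
  s65 <- generate_reporter_field(small_config(n_cells = 10,
                                              aggregate_fraction = 0.65))$scene
  expect_length(s65$positive_cells, 7)
  expect_equal(s65$n_positive_planted, 7L)
})

test_that("aggregates lie inside their own cell footprint", {
  for (seed in 1:3) {
    sc <- generate_reporter_field(small_config(seed = seed))$scene
    agg <- sc$aggregate_coords
    for (j in seq_len(nrow(agg)))
      expect_equal(sc$cell_footprints[round(agg$row[j]), round(agg$col[j])],
                   agg$cell[j])
    expect_true(all(sc$positive_cells %in%
                      seq_len(nrow(sc$nucleus_centres))))
  }
})

test_that("full peripheral bias confines aggregates to the outer half", {
  gen <- generate_reporter_field(small_config(peripheral_bias = 1, seed = 4))
  sc <- gen$scene
  agg <- sc$aggregate_coords
  r_cell <- sc$config$cell_radius_mean
  d <- sqrt((agg$row - sc$nucleus_centres[agg$cell, 1])^2 +
            (agg$col - sc$nucleus_centres[agg$cell, 2])^2)
  expect_true(all(d >= 0.5 * r_cell - 1e-9))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generation_config(aggregate_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generation_config(aggregate_peak_intensity = 0.1,
                                 filament_texture_intensity = 0.2),
               "aggregate_peak_intensity")
  expect_error(generation_config(cell_radius_mean = -1), "radii")
  expect_error(
    generate_reporter_field(generation_config(image_height = 64,
                                              image_width = 64,
                                              n_cells = 500)),
    "packing")
})

test_that("fragment dishes carry exactly the requested fragment areas", {
  empty <- generate_fragment_dish(integer(0), dish_radius = 60, seed = 1)
  expect_equal(max(empty$labels), 0)

  one <- generate_fragment_dish(1200, dish_radius = 80, seed = 1)
  comp <- brute_components(one$labels > 0, 8)
  expect_equal(max(comp), 1)
  expect_equal(sum(comp == 1), 1200)

  three <- generate_fragment_dish(c(499, 500, 1200), dish_radius = 100,
                                  seed = 2)
  areas <- sort(tabulate(three$labels[three$labels > 0]))
  expect_equal(length(areas), 3)
  # requested within 5% (construction is in fact exact)
  expect_true(all(abs(areas - c(499, 500, 1200)) <=
                    0.05 * c(499, 500, 1200)))

  expect_error(generate_fragment_dish(1e6, dish_radius = 50, seed = 1),
               "larger than the dish")
})

test_that("viability fields co-locate dead nuclei and omit dead cytoplasm", {
  v <- generate_viability_field(100, 12, seed = 3)
  expect_length(v$scene$dead_cells, 12)
  expect_true(all(v$scene$dead_cells %in% seq_len(100)))
  hoechst <- get_channel(v$image, "hoechst")$pixels
  ethd1 <- get_channel(v$image, "ethd1")$pixels
  for (i in v$scene$dead_cells) {
    r <- round(v$scene$nucleus_centres[i, 1])
    c <- round(v$scene$nucleus_centres[i, 2])
    expect_gt(ethd1[r, c], 0.5)   # dead nucleus present in EthD-1
    expect_gt(hoechst[r, c], 0.5) # and co-stained in Hoechst
  }

  none_dead <- generate_viability_field(50, 0, seed = 1)
  expect_lt(max(get_channel(none_dead$image, "ethd1")$pixels), 0.1)

  all_dead <- generate_viability_field(20, 20, seed = 2)
  expect_lt(max(get_channel(all_dead$image, "calcein")$pixels), 0.1)

  expect_error(generate_viability_field(10, 11), "n_dead")
})

test_that("degrade_focus is the identity at sigma 0 and rejects negatives", {
  g <- get_channel(generate_reporter_field(small_config())$image, "gfp")
  expect_identical(degrade_focus(g, 0)$pixels, g$pixels)
  expect_error(degrade_focus(g, -1), "sigma")
  flat <- channel_image(matrix(0.5, 32, 32))
  expect_equal(degrade_focus(flat, 3)$pixels, flat$pixels, tolerance = 1e-12)
})
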