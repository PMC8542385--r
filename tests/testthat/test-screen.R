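# Plate-level screen logic: summaries, DMSO baseline, hit calling at the
# inclusive 25% reduction cut-off, dose-response trends, plate heatmap.

fake_field <- function(pp) {
  structure(list(n_regions_total = 100L, n_positive = round(pp),
                 n_negative = 100L - round(pp), percent_positive = pp,
                 calls = NULL, regions = NULL,
                 qc = focus_report(1, 0), status = "ok",
                 params_used = NULL),
            class = "field_result")
}
rejected_field <- function() {
  structure(list(n_regions_total = 0L, n_positive = 0L, n_negative = 0L,
                 percent_positive = NA_real_, calls = NULL, regions = NULL,
                 qc = focus_report(0, 1), status = "rejected",
                 params_used = NULL),
            class = "field_result")
}
toy_layout <- function() {
  plate_layout(data.frame(
    well = c("A01", "B01", "A02", "A03", "A04", "A12"),
    role = c("negative_control", "negative_control", "test", "test",
             "test", "positive_control")))
}

test_that("well summaries average accepted fields only", {
  layout <- toy_layout()
  s <- summarize_wells(list(
    A01 = list(fake_field(80)),
    B01 = list(fake_field(50), fake_field(70)),
    A02 = list(fake_field(60), rejected_field()),
    A03 = list(rejected_field(), rejected_field()),
    A04 = list(fake_field(40)),
    A12 = list(fake_field(5))), layout)
  expect_equal(s$mean_percent_positive[s$well == "A01"], 80)
  expect_equal(s$sd_percent_positive[s$well == "A01"], 0)   # single field
  expect_equal(s$mean_percent_positive[s$well == "B01"], 60)
  expect_equal(s$n_fields_rejected[s$well == "A02"], 1)
  expect_false(s$usable[s$well == "A03"])
  expect_error(summarize_wells(list(C05 = list(fake_field(10))), layout),
               "C05")
})

test_that("hit boundary is inclusive at 25% reduction from baseline", {
  layout <- toy_layout()
  s <- summarize_wells(list(
    A01 = list(fake_field(80)), B01 = list(fake_field(80)),
    A02 = list(fake_field(60)),   # reduction exactly 0.25 -> hit
    A03 = list(fake_field(79)),   # reduction 0.0125 -> not a hit
    A04 = list(fake_field(90)),   # reduction -0.125 -> not a hit
    A12 = list(fake_field(5))), layout)
  res <- call_hits(s, layout)
  expect_equal(res$dmso_baseline, 80)
  expect_identical(res$hits, "A02")
  expect_equal(unname(res$reductions["A02"]), 0.25)
  expect_equal(unname(res$reductions["A04"]), -0.125)
  # positive control neither hit nor baseline contributor
  expect_false("A12" %in% names(res$reductions))
})

test_that("hit calling fails without usable controls or baseline", {
  layout <- toy_layout()
  s <- summarize_wells(list(
    A01 = list(rejected_field()), B01 = list(rejected_field()),
    A02 = list(fake_field(60))), layout)
  expect_error(call_hits(s, layout), "negative-control")
  s0 <- summarize_wells(list(
    A01 = list(fake_field(0)), B01 = list(fake_field(0)),
    A02 = list(fake_field(0))), layout)
  expect_error(call_hits(s0, layout), "baseline")
})

test_that("hit set shrinks monotonically as the cutoff rises", {
  layout <- toy_layout()
  s <- summarize_wells(list(
    A01 = list(fake_field(80)), B01 = list(fake_field(80)),
    A02 = list(fake_field(30)), A03 = list(fake_field(55)),
    A04 = list(fake_field(70))), layout)
  cuts <- c(0.1, 0.2, 0.3, 0.5, 0.7)
  hitsets <- lapply(cuts, function(ct) call_hits(s, layout, ct)$hits)
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(hitsets[[i + 1]] %in% hitsets[[i]]))
})

test_that("dose-response trends follow the rank correlation", {
  d1 <- dose_response(data.frame(conc = c(1, 3, 10),
                                 pp = c(70, 50, 20)))
  expect_true(d1$monotone_decreasing)
  expect_equal(d1$trend_statistic, -1)

  d2 <- dose_response(data.frame(conc = c(1, 3, 10), pp = c(50, 50, 50)))
  expect_true(d2$monotone_decreasing)   # non-strict ties
  expect_equal(d2$trend_statistic, 0)

  d3 <- dose_response(data.frame(conc = c(1, 3, 10), pp = c(40, 60, 20)))
  expect_false(d3$monotone_decreasing)
  # exhaustive-rank oracle: spearman = pearson on ranks
  ref <- cor(rank(c(1, 3, 10)), rank(c(40, 60, 20)))
  expect_equal(d3$trend_statistic, ref)

  # duplicate concentrations averaged before sorting
  d4 <- dose_response(data.frame(conc = c(3, 1, 3, 10),
                                 pp = c(40, 70, 60, 20)))
  expect_equal(d4$points$mean_percent_positive, c(70, 50, 20))
  expect_error(dose_response(data.frame(conc = c(1, 3), pp = c(1, 2))),
               ">= 3")
})

test_that("plate heatmap writes a faithful 8x12 csv twin", {
  wells <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0))
  layout <- plate_layout(data.frame(
    well = wells,
    role = c(rep("negative_control", 8), rep("test", 88))))
  drop_well <- "D07"
  fr <- lapply(setdiff(wells, drop_well), function(w) list(fake_field(75)))
  names(fr) <- setdiff(wells, drop_well)
  fr[["E05"]] <- list(fake_field(40))  # one clear hit
  s <- summarize_wells(fr, layout)
  res <- call_hits(s, layout)
  base <- withr::local_tempfile()
  out <- plate_heatmap(res, base)
  expect_true(file.exists(out$png))
  twin <- read.csv(out$csv)
  expect_equal(nrow(twin), 96)
  expect_equal(sum(is.na(twin$mean_percent_positive)), 1)
  expect_equal(twin$well[is.na(twin$mean_percent_positive)], drop_well)
  expect_true(twin$is_hit[twin$well == "E05"])
  m <- merge(twin, s[c("well", "mean_percent_positive")], by = "well")
  expect_equal(m$mean_percent_positive.x, m$mean_percent_positive.y)
})

test_that("well ids are validated and normalized", {
  expect_equal(keragg:::.normalize_well(c("b3", "A01", "h12")),
               c("B03", "A01", "H12"))
  expect_error(keragg:::.normalize_well("I01"), "invalid")
  expect_error(keragg:::.normalize_well("A13"), "well")
  expect_error(plate_layout(data.frame(well = c("A01", "A01"),
                                       role = c("test", "test"))),
               "duplicate")
})
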