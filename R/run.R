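# Run configuration and batch orchestration: the programmatic surface
# behind the command-line interface. Every run echoes its fully resolved
# configuration into the output directory so results are reproducible from
# the artifacts alone.

#' Resolve a run configuration
#'
#' Precedence: `overrides` > `config_file` (YAML) > documented defaults.
#' Unknown keys at either level are rejected.
#'
#' @param config_file Optional YAML file.
#' @param overrides Optional named list (e.g. parsed CLI flags).
#' @return A `run_config`: list with `segmentation`, `aggregates`,
#'   `fragments` parameter objects plus `qc_threshold`, `cutoff`,
#'   `channel_map` and `seed`.
#' @export
run_config <- function(config_file = NULL, overrides = list()) {
  defaults <- list(
    segmentation = list(), aggregates = list(), fragments = list(),
    generation = list(),
    qc_threshold = default_qc_threshold(),
    cutoff = 0.25,
    channel_map = list(nuclei = 1, gfp = 2),
    seed = 1L)
  merge_level <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          nm %in% c("segmentation", "aggregates", "fragments", "generation",
                    "channel_map")) {
        if (nm == "channel_map") base[[nm]] <- upd[[nm]]
        else {
          sub_ok <- names(formals(switch(nm,
            segmentation = segmentation_params,
            aggregates = aggregate_params,
            fragments = fragment_params,
            generation = generation_config)))
          bad <- setdiff(names(upd[[nm]]), sub_ok)
          if (length(bad))
            stop("unknown ", nm, " key(s) in ", where, ": ",
                 paste(bad, collapse = ", "))
          base[[nm]] <- utils::modifyList(base[[nm]], upd[[nm]])
        }
      } else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file)
    cfg <- merge_level(cfg, yaml::read_yaml(config_file), config_file)
  }
  cfg <- merge_level(cfg, overrides, "overrides")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.materialize <- function(cfg) {
  list(segmentation = do.call(segmentation_params, cfg$segmentation),
       aggregates = do.call(aggregate_params, cfg$aggregates),
       fragments = do.call(fragment_params, cfg$fragments),
       qc_threshold = cfg$qc_threshold,
       cutoff = cfg$cutoff,
       channel_map = unlist(cfg$channel_map),
       seed = cfg$seed)
}

# echo the resolved config + package version into an output directory
.write_run_log <- function(cfg, out_dir) {
  yaml::write_yaml(
    c(unclass(cfg),
      list(package_version =
             as.character(utils::packageVersion("keragg")))),
    file.path(out_dir, "run_config.yaml"))
}

#' Simulate reporter fields to disk
#'
#' Writes `n_fields` synthetic two-channel fields as multi-page 16-bit
#' TIFFs (page 1 nuclei, page 2 gfp) with a JSON ground-truth sidecar per
#' field and a manifest listing every written file. Field `i` uses seed
#' `base seed + i - 1`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_fields Number of fields.
#' @param config A [generation_config()] (its seed is the base seed).
#' @return Invisibly, the manifest data frame.
#' @export
simulate_fields <- function(out_dir, n_fields,
                            config = generation_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n_fields)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    gen <- generate_reporter_field(cfg_i)
    stem <- sprintf("field_%03d", i)
    tif <- file.path(out_dir, paste0(stem, ".tif"))
    js <- file.path(out_dir, paste0(stem, "_truth.json"))
    write_field(gen$image, tif)
    jsonlite::write_json(
      list(seed = cfg_i$seed,
           n_cells = cfg_i$n_cells,
           n_positive_planted = gen$scene$n_positive_planted,
           positive_cells = gen$scene$positive_cells,
           nucleus_centres = gen$scene$nucleus_centres,
           aggregates = gen$scene$aggregate_coords),
      js, digits = NA)
    rows[[i]] <- data.frame(field = stem, image = basename(tif),
                            truth = basename(js))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = character(0), image = character(0),
               truth = character(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "run_config.yaml"))
  invisible(manifest)
}

#' Simulate a 96-well screen plate
#'
#' Builds a full-plate layout (column 1: DMSO negative controls at the
#' baseline aggregate fraction; wells A12/B12: wild-type-like positive
#' controls; all other wells: test compounds), designates `n_active` test
#' wells as true aggregate reducers at `active_fraction`, and draws the
#' remaining test wells' fractions uniformly from the untreated regime
#' (0.70--0.80). Returns one [generation_config()] per well (images are
#' generated on demand by [generate_reporter_field()]); with `out_dir` the
#' fields are also written as `<well>.tif` plus `layout.csv`.
#'
#' @param seed Integer seed driving the active-well choice, per-well
#'   fractions and per-well image seeds.
#' @param n_active Number of designated active (hit) wells.
#' @param active_fraction Aggregate fraction in active wells (<= 0.5).
#' @param base_config Per-well field configuration template.
#' @param out_dir Optional directory to materialize the plate to disk.
#' @return A list with `layout` (`plate_layout`), `well_configs` (named
#'   list well -> `generation_config`), `fractions` (named numeric) and
#'   `active_wells` (character).
#' @export
simulate_screen_plate <- function(seed = 1L, n_active = 8L,
                                  active_fraction = 0.42,
                                  base_config = generation_config(
                                    image_height = 256L, image_width = 256L,
                                    n_cells = 90L),
                                  out_dir = NULL) {
  stopifnot(active_fraction <= 0.5)
  set.seed(as.integer(seed))
  wells <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0))
  neg <- paste0(LETTERS[1:8], "01")
  posc <- c("A12", "B12")
  test <- setdiff(wells, c(neg, posc))
  active <- sort(sample(test, n_active))
  role <- ifelse(wells %in% neg, "negative_control",
                 ifelse(wells %in% posc, "positive_control", "test"))
  fractions <- stats::setNames(numeric(length(wells)), wells)
  fractions[neg] <- 0.75
  fractions[posc] <- 0.05
  fractions[test] <- stats::runif(length(test), 0.70, 0.80)
  fractions[active] <- active_fraction
  wseed <- sample.int(2^30, length(wells))
  well_configs <- lapply(seq_along(wells), function(i) {
    cfg <- base_config
    cfg$aggregate_fraction <- unname(fractions[wells[i]])
    cfg$seed <- wseed[i]
    cfg
  })
  names(well_configs) <- wells
  layout <- plate_layout(data.frame(
    well = wells, role = role,
    compound = ifelse(role == "test", paste0("CPD", seq_along(wells)), NA),
    concentration_uM = ifelse(role == "test", 10, NA),
    replicate = 1L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (wname in wells)
      write_field(generate_reporter_field(well_configs[[wname]])$image,
                  file.path(out_dir, paste0(wname, ".tif")))
    utils::write.csv(layout$wells, file.path(out_dir, "layout.csv"),
                     row.names = FALSE)
  }
  list(layout = layout, well_configs = well_configs,
       fractions = fractions, active_wells = active)
}

#' Analyze a plate of fields against a layout
#'
#' Images must be named by well (`<well>.tif`, or `<well>_<k>.tif` for
#' multiple fields per well). Runs [analyze_field()] per field,
#' [summarize_wells()], [call_hits()] and [plate_heatmap()], writing a
#' per-well CSV, a JSON screen result, the heatmap pair and the resolved
#' configuration into `out_dir`.
#'
#' @param image_dir Directory of per-well field images.
#' @param layout Path to a layout CSV or a `plate_layout`.
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return The `screen_result`, invisibly.
#' @export
analyze_plate <- function(image_dir, layout, cfg = run_config(),
                          out_dir = file.path(image_dir, "results")) {
  if (is.character(layout)) layout <- read_plate_layout(layout)
  stopifnot(inherits(layout, "plate_layout"))
  p <- .materialize(cfg)
  files <- sort(list.files(image_dir, pattern = "\\.(tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no TIFF fields found in ", image_dir)
  well_of <- .normalize_well(sub("[_.].*$", "", files))
  results <- list()
  for (i in seq_along(files)) {
    fr <- analyze_field(read_field(file.path(image_dir, files[i]),
                                   p$channel_map),
                        seg = p$segmentation, agg = p$aggregates,
                        qc_threshold = p$qc_threshold)
    w <- well_of[i]
    results[[w]] <- c(results[[w]], list(fr))
  }
  summaries <- summarize_wells(results, layout)
  screen <- call_hits(summaries, layout, cutoff = p$cutoff)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_screen_result(screen,
                      csv_path = file.path(out_dir, "wells.csv"),
                      json_path = file.path(out_dir, "screen.json"))
  plate_heatmap(screen, file.path(out_dir, "plate_heatmap"))
  .write_run_log(cfg, out_dir)
  invisible(screen)
}
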