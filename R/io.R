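#' Write / read experimental-format bud traces
#'
#' Long-format delimited text with header `explant_id, label, day, bud,
#' length_mm, excluded` (`bud` in `{"top", "bottom"}`), the single input
#' format of the trace pipeline. Internally the columns are named `t` and
#' `length`; the writer/reader translate.
#'
#' @param traces long-format trace tibble (`explant_id, label, t, bud,
#'   length`, optional `excluded`).
#' @param path TSV file path.
#' @return `path` (writer) / the trace tibble (reader).
#' @export
write_bud_traces <- function(traces, path) {
  traces <- check_traces_cols(traces)
  out <- dplyr::transmute(traces,
                          explant_id = .data$explant_id, label = .data$label,
                          day = .data$t, bud = .data$bud,
                          length_mm = .data$length,
                          excluded = .data$excluded)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_bud_traces
#' @export
read_bud_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("explant_id", "label", "day", "bud", "length_mm", "excluded")
  if (!all(need %in% names(tab))) {
    stop("trace file must have header ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$bud %in% c("top", "bottom"))) {
    stop("`bud` must be \"top\" or \"bottom\"", call. = FALSE)
  }
  dplyr::transmute(tab, explant_id = .data$explant_id, label = .data$label,
                   t = .data$day, bud = .data$bud, length = .data$length_mm,
                   excluded = as.logical(.data$excluded))
}

check_traces_cols <- function(traces) {
  need <- c("explant_id", "label", "t", "bud", "length")
  if (!all(need %in% names(traces))) {
    stop("traces must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"excluded" %in% names(traces)) traces$excluded <- FALSE
  traces
}

grid_mask_cols <- c("failed", "repaired", "boundary")

grid_channels <- function(map) {
  drop <- c("i", "j", "v0", "mu", grid_mask_cols)
  setdiff(names(map$cells), drop)
}

cells_channel_matrix <- function(map, channel) {
  ni <- length(map$v0_values); nj <- length(map$mu_values)
  matrix(map$cells[[channel]][order(map$cells$j, map$cells$i)], ni, nj)
}

#' Write / read a grid map as matrix files plus a JSON sidecar
#'
#' One plain-text delimited matrix file per payload channel (rows indexed by
#' `v0`, columns by `mu`), named `<stem>-<channel>.tsv`, plus a sidecar
#' `<stem>.json` holding the axes, kind, masks (failed / repaired / boundary)
#' and provenance. Numeric serialization is full precision.
#'
#' @param map a `grid_map`.
#' @param stem file-path stem (no extension).
#' @return `stem` (writer) / the reconstructed `grid_map` (reader).
#' @export
write_grid_map <- function(map, stem) {
  stopifnot(inherits(map, "grid_map"))
  channels <- grid_channels(map)
  for (ch in channels) {
    m <- cells_channel_matrix(map, ch)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = NA),
                       paste0(stem, "-", ch, ".tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  prov <- map$provenance
  if (!is.null(prov$base_params)) {
    prov$base_params <- lapply(unclass(prov$base_params), as.numeric)
  }
  sidecar <- list(kind = map$kind,
                  v0_values = map$v0_values, mu_values = map$mu_values,
                  channels = channels,
                  masks = lapply(stats::setNames(grid_mask_cols, grid_mask_cols),
                                 function(ch) cells_channel_matrix(map, ch)),
                  provenance = prov)
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(stem)
}

#' @rdname write_grid_map
#' @export
read_grid_map <- function(stem) {
  side_path <- paste0(stem, ".json")
  if (!file.exists(side_path)) stop("sidecar not found: ", side_path,
                                    call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ni <- length(side$v0_values); nj <- length(side$mu_values)
  cells <- grid_cells_skeleton(side$v0_values, side$mu_values)
  # cells vary j fastest, so fill channels with the row-major flatten t(m)
  for (ch in side$channels) {
    m <- as.matrix(utils::read.table(paste0(stem, "-", ch, ".tsv"),
                                     sep = "\t", header = FALSE,
                                     na.strings = c("NA", "NaN")))
    stopifnot(nrow(m) == ni, ncol(m) == nj)
    cells[[ch]] <- as.vector(t(m))
  }
  for (ch in grid_mask_cols) {
    m <- matrix(as.logical(side$masks[[ch]]), ni, nj)
    cells[[ch]] <- as.vector(t(m))
  }
  if ("class_id" %in% names(cells)) cells$class_id <- as.integer(cells$class_id)
  if ("n_stable" %in% names(cells)) cells$n_stable <- as.integer(cells$n_stable)
  prov <- side$provenance
  if (!is.null(prov$base_params)) {
    prov$base_params <- do.call(bud_params, as.list(prov$base_params))
  }
  new_grid_map(cells, side$v0_values, side$mu_values, side$kind, prov)
}

#' Load and validate a run configuration
#'
#' A run configuration is a single YAML file with a `stage` name, an output
#' directory, and per-stage settings; see [run_stage()] for the schema. Every
#' referenced file must exist at load time and every numeric field is
#' validated here, before dispatch.
#'
#' @param path YAML config path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

cfg_fail <- function(field, msg) {
  stop(sprintf("invalid config: field `%s` %s", field, msg), call. = FALSE)
}

cfg_num <- function(cfg, field, default, lo = -Inf, hi = Inf, len = 1,
                    allow_na = FALSE) {
  x <- cfg[[field]] %||% default
  if (allow_na && length(x) == len && all(is.na(x))) return(as.numeric(x))
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    cfg_fail(field, sprintf("must be numeric of length %d", len))
  }
  if (any(x < lo) || any(x > hi)) {
    cfg_fail(field, sprintf("must lie in [%g, %g]", lo, hi))
  }
  x
}

stage_names <- c("simulate", "map", "heatmap", "metrics", "fit", "predict",
                 "synth", "sensitivity")

validate_run_config <- function(cfg) {
  if (is.null(cfg$stage) || !cfg$stage %in% stage_names) {
    cfg_fail("stage", paste("must be one of:", paste(stage_names, collapse = ", ")))
  }
  if (is.null(cfg$out_dir) || !is.character(cfg$out_dir)) {
    cfg_fail("out_dir", "must be a directory path")
  }
  if (!is.null(cfg$params_file)) {
    if (!file.exists(cfg$params_file)) cfg_fail("params_file", "does not exist")
    cfg$params <- read_bud_params(cfg$params_file)
  } else if (!is.null(cfg$params)) {
    cfg$params <- do.call(bud_params, cfg$params)
  } else {
    cfg$params <- bud_params()
  }
  cfg$seed <- as.integer(cfg_num(cfg, "seed", 1, lo = 1, hi = 2^31 - 1))

  g <- cfg$grid %||% list()
  grid <- list(n_v0 = as.integer(cfg_num(g, "n_v0", 30, lo = 2)),
               n_mu = as.integer(cfg_num(g, "n_mu", 30, lo = 2)),
               v0_range = cfg_num(g, "v0_range", c(0.005, 0.35), lo = 0, len = 2),
               mu_range = cfg_num(g, "mu_range", c(0.25, 2.0), lo = 0, len = 2))
  if (grid$v0_range[1] >= grid$v0_range[2]) cfg_fail("grid.v0_range", "must increase")
  if (grid$mu_range[1] >= grid$mu_range[2]) cfg_fail("grid.mu_range", "must increase")
  cfg$grid <- grid

  s <- cfg$sim %||% list()
  cfg$sim <- list(n_sims = as.integer(cfg_num(s, "n_sims", 100, lo = 1)),
                  t_end = cfg_num(s, "t_end", 120, lo = 1),
                  dt = cfg_num(s, "dt", 0.1, lo = 1e-6, hi = 1))

  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    activity = cfg_num(th, "activity", NA_real_, lo = 0, allow_na = TRUE),
    active_class = cfg_num(th, "active_class", 0.4, lo = 0),
    distinguish = cfg_num(th, "distinguish", 0.24, lo = 0),
    match_tolerance = cfg_num(th, "match_tolerance", NA_real_, lo = 0,
                              allow_na = TRUE))

  for (f in c("traces_file", "placement_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) cfg_fail(f, "does not exist")
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

axis_values <- function(grid) {
  list(v0 = seq(grid$v0_range[1], grid$v0_range[2], length.out = grid$n_v0),
       mu = seq(grid$mu_range[1], grid$mu_range[2], length.out = grid$n_mu))
}

#' Run one pipeline stage from a configuration
#'
#' The package's command-line surface: each stage reads its inputs, writes
#' its module's output files into `out_dir` plus a provenance record
#' (`provenance.json`: config echo, seed, package version), and logs the
#' seed, grid size and any failed/repaired pixels. Identical config and seed
#' give byte-identical numeric outputs.
#'
#' Stages and their extra config fields:
#' \describe{
#'   \item{simulate}{one stochastic trajectory -> `trajectory.tsv` (+ JSON
#'     sidecar). Uses `sim` and `seed`.}
#'   \item{map}{behavior or outcome map over the grid -> `map-*.tsv` +
#'     `map.json`. Field `map_kind`: `"behavior"` (default) or `"outcome"`.}
#'   \item{heatmap}{mean-lag and mean-max-rate maps -> `lag-*`, `max_rate-*`.}
#'   \item{metrics}{trace metrics of `traces_file` (experimental format) ->
#'     `buds.tsv`, `explants.tsv`, `summary.json`. Field `mode`:
#'     `"experimental"` (default) or `"simulated"`.}
#'   \item{fit}{genotype placement from `observations` (list of label /
#'     p_both / p_one / p_none / n) and `constraints` (mu_groups, v0_groups,
#'     mu_order, v0_order) on an outcome map -> `placement.tsv` plus the map
#'     files.}
#'   \item{predict}{ensemble predictions at placed values (from
#'     `placement_file`, TSV with label/v0/mu, or the package presets) ->
#'     `summary.tsv`, `buds.tsv`, `explants.tsv`, `mitchison.tsv`.}
#'   \item{synth}{synthetic cohort from the `archetype` fields and
#'     `n_explants` -> `traces.tsv` (experimental format), `truth.tsv`.}
#'   \item{sensitivity}{behavior-map sensitivity scan (`fraction`,
#'     `parameters`) -> one map file set per perturbation.}
#' }
#'
#' @param config a `run_config` from [read_run_config()], a config file path,
#'   or an equivalent list.
#' @return Invisibly, a character vector of written files. Invalid configs
#'   and stage failures raise errors carrying the stage name.
#' @export
run_stage <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  message(sprintf("stage `%s`: seed %d, output -> %s",
                  config$stage, config$seed, config$out_dir))
  handler <- get(paste0("stage_", config$stage), mode = "function")
  files <- tryCatch(handler(config), error = function(e) {
    stop(sprintf("stage `%s` failed: %s", config$stage, conditionMessage(e)),
         call. = FALSE)
  })
  prov <- list(config = unclass_config(config),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("budcanal")))
  prov_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, prov_path))
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$params <- lapply(unclass(cfg$params), as.numeric)
  cfg
}

out_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

stage_simulate <- function(cfg) {
  tr <- simulate_explant(cfg$params, t_end = cfg$sim$t_end, dt = cfg$sim$dt,
                         seed = cfg$seed)
  p <- out_path(cfg, "trajectory.tsv")
  write_trajectory(tr, p)
  c(p, sidecar_path(p))
}

log_map <- function(map) {
  message(sprintf("grid %d x %d: %d failed, %d repaired, %d boundary pixels",
                  length(map$v0_values), length(map$mu_values),
                  sum(map$cells$failed), sum(map$cells$repaired),
                  sum(map$cells$boundary)))
}

stage_map <- function(cfg) {
  ax <- axis_values(cfg$grid)
  kind <- cfg$map_kind %||% "behavior"
  map <- if (kind == "outcome") {
    outcome_fraction_map(ax$v0, ax$mu, cfg$params, n_sims = cfg$sim$n_sims,
                         t_end = cfg$sim$t_end, dt = cfg$sim$dt,
                         base_seed = cfg$seed,
                         active_threshold = cfg$thresholds$active_class,
                         distinguish_threshold = cfg$thresholds$distinguish)
  } else if (kind == "behavior") {
    behavior_map(ax$v0, ax$mu, cfg$params,
                 active_threshold = cfg$thresholds$active_class,
                 distinguish_threshold = cfg$thresholds$distinguish)
  } else {
    cfg_fail("map_kind", "must be \"behavior\" or \"outcome\"")
  }
  map <- repair_pixels(map)
  log_map(map)
  stem <- out_path(cfg, "map")
  write_grid_map(map, stem)
  paste0(stem, c(".json", paste0("-", grid_channels(map), ".tsv")))
}

stage_heatmap <- function(cfg) {
  ax <- axis_values(cfg$grid)
  hm <- metric_heatmaps(ax$v0, ax$mu, cfg$params, n_sims = cfg$sim$n_sims,
                        t_end = cfg$sim$t_end, dt = cfg$sim$dt,
                        base_seed = cfg$seed)
  log_map(hm$lag)
  stems <- out_path(cfg, c("lag", "max_rate"))
  write_grid_map(hm$lag, stems[1])
  write_grid_map(hm$max_rate, stems[2])
  paste0(rep(stems, each = 2), c(".json", "-mean_lag.tsv", ".json",
                                 "-mean_max_rate.tsv"))
}

stage_metrics <- function(cfg) {
  if (is.null(cfg$traces_file)) cfg_fail("traces_file", "is required")
  traces <- read_bud_traces(cfg$traces_file)
  mode <- cfg$mode %||% "experimental"
  thr <- cfg$thresholds$activity
  m <- trace_metrics(traces, mode = mode,
                     threshold = if (is.na(thr)) NULL else thr)
  files <- out_path(cfg, c("buds.tsv", "explants.tsv", "summary.json"))
  readr::write_tsv(m$buds, files[1])
  readr::write_tsv(m$explants, files[2])
  summ <- m$explants |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(~outcome_summary(.x)) |>
    dplyr::ungroup()
  jsonlite::write_json(summ, files[3], auto_unbox = TRUE, digits = NA)
  files
}

stage_fit <- function(cfg) {
  if (is.null(cfg$observations)) cfg_fail("observations", "is required")
  if (is.null(cfg$constraints)) cfg_fail("constraints", "is required")
  obs <- dplyr::bind_rows(lapply(cfg$observations, function(o) {
    do.call(genotype_observation, o)
  }))
  cons <- constraint_set(
    mu_groups = cfg$constraints$mu_groups,
    v0_groups = cfg$constraints$v0_groups,
    mu_order = cfg$constraints$mu_order %||% names(cfg$constraints$mu_groups),
    v0_order = cfg$constraints$v0_order %||% names(cfg$constraints$v0_groups))
  ax <- axis_values(cfg$grid)
  map <- outcome_fraction_map(ax$v0, ax$mu, cfg$params,
                              n_sims = cfg$sim$n_sims, t_end = cfg$sim$t_end,
                              dt = cfg$sim$dt, base_seed = cfg$seed)
  map <- repair_pixels(map)
  log_map(map)
  placement <- place_genotypes(obs, cons, map)
  stem <- out_path(cfg, "map")
  write_grid_map(map, stem)
  pfile <- out_path(cfg, "placement.tsv")
  readr::write_tsv(tibble::as_tibble(placement), pfile)
  c(pfile, paste0(stem, ".json"),
    paste0(stem, "-", grid_channels(map), ".tsv"))
}

stage_predict <- function(cfg) {
  placement <- if (!is.null(cfg$placement_file)) {
    readr::read_tsv(cfg$placement_file, show_col_types = FALSE)
  } else {
    genotype_presets()
  }
  pred <- predict_metrics(placement, cfg$params, n_sims = cfg$sim$n_sims,
                          t_end = cfg$sim$t_end, dt = cfg$sim$dt,
                          base_seed = cfg$seed)
  files <- out_path(cfg, c("summary.tsv", "buds.tsv", "explants.tsv",
                           "mitchison.tsv"))
  readr::write_tsv(pred$summary, files[1])
  readr::write_tsv(pred$buds, files[2])
  readr::write_tsv(pred$explants, files[3])
  readr::write_tsv(pred$mitchison, files[4])
  files
}

stage_synth <- function(cfg) {
  arch <- do.call(explant_archetype, cfg$archetype %||% list())
  n <- as.integer(cfg_num(cfg, "n_explants", 50, lo = 1))
  cohort <- generate_explants(arch, n, seed = cfg$seed)
  files <- out_path(cfg, c("traces.tsv", "truth.tsv"))
  write_bud_traces(cohort$traces, files[1])
  readr::write_tsv(cohort$truth, files[2])
  files
}

stage_sensitivity <- function(cfg) {
  ax <- axis_values(cfg$grid)
  frac <- cfg_num(cfg, "fraction", 0.05, lo = 0, hi = 0.99)
  pars <- cfg$parameters %||% c("S", "D", "v", "K", "Q", "n", "eta")
  scan <- sensitivity_scan(behavior_map, ax$v0, ax$mu, cfg$params,
                           fraction = frac, parameters = pars,
                           active_threshold = cfg$thresholds$active_class,
                           distinguish_threshold = cfg$thresholds$distinguish)
  files <- character(0)
  for (k in seq_len(nrow(scan))) {
    map <- scan$map[[k]]
    if (is.null(map)) next
    log_map(map)
    stem <- out_path(cfg, sprintf("sens-%s-%s", scan$parameter[k],
                                  scan$direction[k]))
    write_grid_map(map, stem)
    files <- c(files, paste0(stem, ".json"),
               paste0(stem, "-", grid_channels(map), ".tsv"))
  }
  files
}
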