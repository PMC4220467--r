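#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate -> preprocess -> affinity staging ->
#' association network -> home range chain. Either `input` (a fix-table
#' path) or `synth` (a [synth_config()]) supplies the data. Explicit SAC
#' threshold overrides, when given, bypass the communication-geometry
#' derivation (useful to reuse a reference calibration such as
#' 0.1139/0.4571).
#'
#' @param input Optional path to a delimited fix table.
#' @param synth Optional [synth_config()]; defaults to the study-condition
#'   generator when no `input` is given.
#' @param grid Optional [time_grid()] (required with `input`).
#' @param max_dop DOP removal threshold (default 8).
#' @param smooth_window Smoothing window in fixes (default 15).
#' @param comm_distance_m Effective communication distance d (default
#'   513.12 m).
#' @param persistence Stage persistence in segments (default 3).
#' @param standardizer_method `"quadratic"` (default) or `"linear"`.
#' @param sac_fusion,sac_fission Optional explicit threshold overrides.
#' @param lag_max Largest lag (slots) for the lagged association rate.
#' @param linkage Dendrogram linkage (default `"average"`).
#' @param isopleth Home-range isopleth level (default 0.95).
#' @param overlap_mode `"union"` (default) or `"of-first"`.
#' @param kde_grid_n KDE grid points per axis (default 150).
#' @param stages Pipeline stages to run, a subset of
#'   `c("simulate", "validate", "preprocess", "sac", "sna", "homerange")`.
#' @param seed Top-level seed; the generator draws its substreams from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, synth = NULL, grid = NULL,
                       max_dop = 8, smooth_window = 15,
                       comm_distance_m = 513.12, persistence = 3,
                       standardizer_method = "quadratic",
                       sac_fusion = NULL, sac_fission = NULL,
                       lag_max = 100, linkage = "average",
                       isopleth = 0.95, overlap_mode = "union",
                       kde_grid_n = 150,
                       stages = c("simulate", "validate", "preprocess",
                                  "sac", "sna", "homerange"),
                       seed = 1L) {
  if (!is.null(sac_fusion) || !is.null(sac_fission)) {
    if (is.null(sac_fusion) || is.null(sac_fission) ||
        !(sac_fusion < sac_fission))
      stop("explicit overrides need sac_fusion < sac_fission", call. = FALSE)
  }
  if (is.null(input)) {
    if (is.null(synth)) synth <- synth_config(seed = seed)
  } else {
    if (!file.exists(input)) stop("input not found: ", input, call. = FALSE)
    if (is.null(grid)) stop("a time_grid is required with input", call. = FALSE)
    stages <- setdiff(stages, "simulate")
  }
  structure(list(
    input = input, synth = synth, grid = grid, max_dop = max_dop,
    smooth_window = smooth_window, comm_distance_m = comm_distance_m,
    persistence = persistence, standardizer_method = standardizer_method,
    sac_fusion = sac_fusion, sac_fission = sac_fission,
    lag_max = lag_max, linkage = linkage, isopleth = isopleth,
    overlap_mode = overlap_mode, kde_grid_n = kde_grid_n,
    stages = stages, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' The file is flat YAML (`key: value` per line). Generator keys are
#' prefixed `synth_` (e.g. `synth_n_days: 60`); grid keys `grid_`
#' (`grid_start_date`, `grid_n_days`). Unknown keys are an error.
#'
#' @param path Configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  kv <- yaml::read_yaml(path)
  if (!is.list(kv)) stop("config must be flat key: value lines", call. = FALSE)
  synth_keys <- grepl("^synth_", names(kv))
  grid_keys <- grepl("^grid_", names(kv))
  main <- kv[!synth_keys & !grid_keys]
  known <- setdiff(names(formals(run_config)), c("synth", "grid"))
  bad <- setdiff(names(main), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  synth <- NULL
  if (any(synth_keys)) {
    sargs <- kv[synth_keys]
    names(sargs) <- sub("^synth_", "", names(sargs))
    if (!is.null(main$seed) && is.null(sargs$seed)) sargs$seed <- main$seed
    synth <- do.call(synth_config, sargs)
  }
  grid <- NULL
  if (any(grid_keys)) {
    gargs <- kv[grid_keys]
    names(gargs) <- sub("^grid_", "", names(gargs))
    grid <- do.call(time_grid, gargs)
  }
  if (!is.null(main$stages))
    main$stages <- strsplit(main$stages, "[, ]+")[[1]]
  do.call(run_config, c(main, list(synth = synth, grid = grid)))
}

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  if (!is.null(df$timestamp))
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in fixed order, writes every
#' figure-adjacent table under `out_dir` with stable names, and finishes by
#' writing `manifest.json` (configuration echo, per-stage record counts,
#' standardizer calibration, output checksums) atomically. Identical
#' configuration and seed give byte-identical outputs.
#'
#' Output files (when the owning stage runs): `fixes_raw.csv`,
#' `ground_truth.csv`, `sac_series.csv`, `stages.csv`,
#' `stage_fractions.csv`, `dyad_distances.csv`, `hwi_matrix.csv`,
#' `hwi_counts.csv`, `dendrogram.nwk`, `lagged_rates.csv`,
#' `pcoa_coordinates.csv`, `ud_<component>.asc`, `range_<component>.geojson`,
#' `overlaps.csv`, `manifest.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("telemsoc")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   stages_run = character(0), counts = list())
  manifest$config <- config_echo(config)
  outputs <- character(0)
  stage_names <- config$stages
  run_stage <- function(name, fn) {
    if (!(name %in% stage_names)) return(NULL)
    res <- tryCatch(fn(), error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      write_manifest(manifest, outputs, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages_run <<- c(manifest$stages_run, name)
    res
  }

  truth <- NULL; raw_path <- NULL; grid <- NULL
  run_stage("simulate", function() {
    gen <- generate_trackset(config$synth)
    truth <<- gen$truth
    grid <<- config$synth$grid
    raw <- degrade(gen$trackset, config$synth)
    raw_path <<- file.path(out_dir, "fixes_raw.csv")
    write_fixes(raw, raw_path)
    gt <- data.frame(slot = seq_along(truth$stage_per_slot),
                     stage = truth$stage_per_slot)
    outputs <<- c(outputs, raw_path,
                  write_table(gt, file.path(out_dir, "ground_truth.csv")))
    manifest$counts$simulate <<- list(
      fixes_written = nrow(raw),
      components = config$synth$n_components,
      slots = n_slots(grid))
    NULL
  })
  if (is.null(raw_path)) {
    raw_path <- config$input
    grid <- config$grid
  }
  if (is.null(raw_path))
    stop("no input: enable the simulate stage or supply input", call. = FALSE)

  run_stage("validate", function() {
    rep <- validate_fixes(raw_path, grid)
    manifest$counts$validate <<- list(rows = rep$n_rows,
                                      fatal = nrow(rep$fatal),
                                      warnings = nrow(rep$warnings))
    if (nrow(rep$fatal) > 0)
      stop("fix table has ", nrow(rep$fatal), " fatal issue(s); first: ",
           rep$fatal$issue[1])
    NULL
  })

  ts <- NULL
  run_stage("preprocess", function() {
    raw <- read_fixes(raw_path)
    ts0 <- trackset(raw, grid)
    ts <<- preprocess_trackset(ts0, config$max_dop, config$smooth_window)
    manifest$counts$preprocess <<- c(
      list(fixes_read = nrow(raw)), ts$log$dop_filter["removed"],
      ts$log$interpolate, ts$log$align)
    NULL
  })
  if (is.null(ts)) return(invisible(write_manifest(manifest, outputs, out_dir)))

  seg <- NULL
  run_stage("sac", function() {
    sac <- sac_series(ts)
    std <- attr(sac, "standardizer")
    th <- sac_thresholds(std, d = config$comm_distance_m,
                         n = length(ts$components),
                         persistence = config$persistence,
                         sac_fusion = config$sac_fusion,
                         sac_fission = config$sac_fission)
    seg <<- classify_stages(sac$sac, th, slots = sac$slot)
    fr <- stage_fractions(seg)
    dist <- pairwise_component_distances(ts)
    outputs <<- c(outputs,
      write_table(sac, file.path(out_dir, "sac_series.csv")),
      write_table(seg$segments, file.path(out_dir, "stages.csv")),
      write_table(data.frame(stage = names(fr), fraction = as.vector(fr)),
                  file.path(out_dir, "stage_fractions.csv")),
      write_table(summarize_dyads(dist),
                  file.path(out_dir, "dyad_distances.csv")))
    manifest$counts$sac <<- list(
      slots = nrow(sac), segments = nrow(seg$segments),
      standardizer = list(method = std$method, a_max_deg = std$a_max),
      sac_fusion = th$sac_fusion, sac_fission = th$sac_fission)
    NULL
  })

  run_stage("sna", function() {
    nn <- nearest_neighbours(ts)
    am <- hwi_matrix(nn)
    dend <- cluster_dendrogram(am, linkage = config$linkage)
    lar <- lagged_association_rate(nn, lags = 0:config$lag_max)
    fits <- tryCatch(fit_decay_models(lar), error = function(e) NULL)
    pc <- assoc_pcoa(am)
    hw <- as.data.frame(am$hwi)
    hw <- cbind(component_id = rownames(am$hwi), hw)
    nwk <- file.path(out_dir, "dendrogram.nwk")
    write_dendrogram_newick(dend, nwk)
    pcdf <- data.frame(component_id = rownames(pc$points),
                       round(pc$points, 8))
    lar_df <- as.data.frame(lar)
    lar_df$null_rate <- attr(lar, "null_rate")
    outputs <<- c(outputs,
      write_table(hw, file.path(out_dir, "hwi_matrix.csv")),
      write_table(am$counts, file.path(out_dir, "hwi_counts.csv")),
      nwk,
      write_table(lar_df, file.path(out_dir, "lagged_rates.csv")),
      write_table(pcdf, file.path(out_dir, "pcoa_coordinates.csv")))
    manifest$counts$sna <<- list(
      dyads = nrow(am$counts), cutoff_k = dend$cutoff_k,
      max_modularity = if (!is.null(dend$modularity))
        max(dend$modularity$modularity) else NA,
      null_rate = attr(lar, "null_rate"),
      decay_preferred = if (!is.null(fits)) fits$preferred else NA)
    NULL
  })

  run_stage("homerange", function() {
    # shared planar frame so overlaps compare like with like
    located <- ts$fixes[ts$fixes$slot %in% ts$slots & !is.na(ts$fixes$lon), ]
    ref <- c(lon = mean(located$lon), lat = mean(located$lat))
    uds <- lapply(ts$components, function(cp)
      kde_utilization(ts, cp, grid_n = config$kde_grid_n,
                      lon0 = ref[["lon"]], lat0 = ref[["lat"]]))
    names(uds) <- ts$components
    rps <- lapply(uds, ud_contour, q = config$isopleth)
    for (cp in ts$components) {
      pa <- file.path(out_dir, sprintf("ud_%s.asc", cp))
      write_esri_ascii(uds[[cp]], pa)
      pg <- file.path(out_dir, sprintf("range_%s.geojson", cp))
      write_geojson(rps[[cp]], pg, lon0 = uds[[cp]]$lon0,
                    lat0 = uds[[cp]]$lat0)
      outputs <<- c(outputs, pa, pg)
    }
    om <- overlap_matrix(rps, mode = config$overlap_mode, resolution = 250)
    dy <- utils::combn(ts$components, 2)
    ov <- data.frame(
      comp_i = dy[1, ], comp_j = dy[2, ],
      overlap_pct = om[cbind(dy[1, ], dy[2, ])],
      mode = config$overlap_mode,
      isopleth = config$isopleth, stringsAsFactors = FALSE)
    outputs <<- c(outputs,
                  write_table(ov, file.path(out_dir, "overlaps.csv")))
    areas <- vapply(rps, `[[`, 0, "area_ha")
    manifest$counts$homerange <<- list(
      isopleth = config$isopleth,
      area_ha = as.list(stats::setNames(areas, ts$components)))
    NULL
  })

  invisible(write_manifest(manifest, outputs, out_dir))
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synth)) {
    s <- unclass(out$synth)
    s$grid <- unclass(s$grid)
    s$grid$start_date <- format(s$grid$start_date)
    out$synth <- s
  }
  if (!is.null(out$grid)) {
    out$grid <- unclass(out$grid)
    out$grid$start_date <- format(out$grid$start_date)
  }
  out
}

write_manifest <- function(manifest, outputs, out_dir) {
  outputs <- unique(outputs)
  sums <- list()
  if (length(outputs)) {
    sums <- as.list(tools::md5sum(outputs))
    names(sums) <- basename(names(sums))
  }
  manifest$output_md5 <- sums
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  manifest
}
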