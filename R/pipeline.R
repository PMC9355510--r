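# Configuration-driven orchestration: simulate -> (render + track | direct
# tracks) -> unwrap -> per-cell metrics -> MSD -> group stats -> report
# bundle, deterministic given the configured seeds.

#' Pipeline run configuration
#'
#' A list of cohort blocks (each: \code{name}, \code{phenotype},
#' \code{surface}, \code{n_cells}, \code{seed}) plus pipeline options.
#'
#' @slot cohorts list of cohort blocks.
#' @slot options list of switches: \code{use_rendered_movies},
#'   \code{remap_policy}, \code{msd_fit_window_h},
#'   \code{alignment_threshold_deg}, \code{dy_floor_um},
#'   \code{min_step_um}, \code{dt_h}, \code{duration_h},
#'   \code{min_track_frames}.
#' @seealso [runConfig()], [readRunConfig()], [runPipeline()]
#' @export
setClass("RunConfig", slots = c(cohorts = "list", options = "list"))

setValidity("RunConfig", function(object) {
  msg <- character()
  for (co in object@cohorts) {
    need <- c("name", "phenotype", "surface", "n_cells", "seed")
    miss <- setdiff(need, names(co))
    if (length(miss))
      msg <- c(msg, paste("cohort block missing field(s):",
                          paste(miss, collapse = ", ")))
    else if (!is(co$surface, "CylinderSpec"))
      msg <- c(msg, "cohort 'surface' must be a CylinderSpec")
  }
  seeds <- vapply(object@cohorts, function(co) as.numeric(co$seed %||% NA), 1)
  if (anyDuplicated(stats::na.omit(seeds)))
    msg <- c(msg, "cohort seeds must be distinct")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_options <- function() {
  list(use_rendered_movies = FALSE, remap_policy = "always",
       msd_fit_window_h = c(NA, 5), alignment_threshold_deg = 30,
       dy_floor_um = 1, min_step_um = 1e-3,
       dt_h = 1 / 3, duration_h = 22, min_track_frames = 10L)
}

#' Construct a run configuration
#'
#' @param cohorts list of cohort blocks; each block is a list with
#'   \code{name}, \code{phenotype} (preset name), \code{surface}
#'   ([CylinderSpec-class]), \code{n_cells}, \code{seed}.
#' @param ... option overrides, see [RunConfig-class].
#' @return A [RunConfig-class].
#' @export
runConfig <- function(cohorts, ...) {
  opts <- utils::modifyList(.default_options(), list(...))
  new("RunConfig", cohorts = cohorts, options = opts)
}

#' Default demonstration configuration
#'
#' Two phenotypes on the flat control and the five-cylinder diameter series
#' (125, 250, 500, 1000, 2000 um), \code{n_cells} cells per cohort, with
#' distinct per-cohort seeds derived from \code{base_seed}.
#'
#' @param n_cells cells per cohort.
#' @param base_seed integer; cohort i uses \code{base_seed * 1000 + i}.
#' @param diameters_um cylinder diameter series.
#' @param ... option overrides passed to [runConfig()].
#' @return A [RunConfig-class] with 12 cohorts at the defaults.
#' @export
demoRunConfig <- function(n_cells = 30, base_seed = 1,
                          diameters_um = c(125, 250, 500, 1000, 2000), ...) {
  phen <- c("fibroblastic", "myofibroblastic")
  cohorts <- list()
  i <- 0L
  for (ph in phen) {
    for (d in c(NA, diameters_um)) {
      i <- i + 1L
      surf <- if (is.na(d)) flatSpec() else cylinderSpec(d)
      dlab <- if (is.na(d)) "flat" else sprintf("D%g", d)
      cohorts[[i]] <- list(name = paste(ph, dlab, sep = "_"),
                           phenotype = ph, surface = surf,
                           n_cells = n_cells,
                           seed = base_seed * 1000 + i)
    }
  }
  runConfig(cohorts, ...)
}

#' Read a run configuration from YAML
#'
#' Expected structure: a top-level \code{cohorts} list whose entries carry
#' \code{name}, \code{phenotype}, \code{n_cells}, \code{seed} and a
#' \code{surface} block (\code{diameter_um}, \code{concavity},
#' \code{length_um}, \code{depth_um}, \code{axis_angle_deg}), plus an
#' optional \code{options} block.
#'
#' @param path YAML file path.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohorts <- lapply(y$cohorts, function(co) {
    s <- co$surface %||% list()
    co$surface <- cylinderSpec(
      diameter_um = s$diameter_um %||% NA_real_,
      concavity = s$concavity %||% "flat",
      length_um = s$length_um %||% 1000,
      depth_um = s$depth_um %||% 170,
      axis_angle_deg = s$axis_angle_deg %||% 0)
    co
  })
  do.call(runConfig, c(list(cohorts = cohorts), y$options %||% list()))
}

# --- track CSV interchange --------------------------------------------------

#' Read/write the canonical track CSV
#'
#' The package's interchange format: one row per cell per frame with
#' columns \code{cell_id}, \code{frame}, \code{time_h}, \code{x_um},
#' \code{y_um}, \code{surface_id}, \code{phenotype}, \code{diameter_um},
#' \code{concavity} (UTF-8, '.' decimal separator, header required).
#'
#' @param ts a [TrackSet-class].
#' @param path CSV path.
#' @param surface_id identifier written to the \code{surface_id} column.
#' @return \code{path} invisibly (write) or a [TrackSet-class] (read).
#' @export
writeTrackCSV <- function(ts, path, surface_id = "surface1") {
  tr <- tracks(ts)
  sp <- surface(ts)
  out <- data.frame(cell_id = tr$cell_id, frame = tr$frame,
                    time_h = tr$time_h, x_um = tr$x_um, y_um = tr$y_um,
                    surface_id = surface_id,
                    phenotype = ts@metadata$phenotype %||% NA_character_,
                    diameter_um = sp@diameter_um,
                    concavity = sp@concavity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackCSV
#' @param unwrapped whether the stored coordinates are unwrapped arc
#'   lengths (\code{TRUE} for files written by the pipeline).
#' @export
readTrackCSV <- function(path, unwrapped = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  conc <- if ("concavity" %in% names(d)) d$concavity[1] else "flat"
  dia <- if ("diameter_um" %in% names(d)) d$diameter_um[1] else NA_real_
  surf <- cylinderSpec(diameter_um = dia, concavity = conc)
  md <- list()
  if ("phenotype" %in% names(d)) md$phenotype <- d$phenotype[1]
  trackSet(d[, .track_columns], surface = surf, unwrapped = unwrapped,
           metadata = md)
}

# --- orchestration ----------------------------------------------------------

.simulate_cohort <- function(co, opts) {
  cfg <- simConfig(surface = co$surface, n_cells = co$n_cells,
                   preset = co$phenotype, dt_h = opts$dt_h,
                   duration_h = opts$duration_h, seed = co$seed)
  ts <- simulatePRWTracks(cfg)
  ts@metadata$phenotype <- co$phenotype
  if (isTRUE(opts$use_rendered_movies)) {
    proj <- projectTracks(ts)
    stack <- generateTimelapse(proj, photon_scale = 500,
                               seed = co$seed + 500000)
    ts <- trackTimelapse(stack, surface = co$surface, unwrapped = FALSE,
                         min_frames = opts$min_track_frames)
    ts <- unwrapTracks(ts, policy = opts$remap_policy)
    ts@metadata$phenotype <- co$phenotype
  }
  ts
}

#' Run the full analysis pipeline
#'
#' For every cohort block: simulate the cohort (optionally render a movie
#' and recover the tracks by detection + linking), unwrap, compute the
#' per-cell migration summary and the ensemble MSD with its fitted
#' exponent, then compare cohorts metric-by-metric with Kruskal-Wallis and
#' Dunn/BH statistics. Writes \code{per_cell_summary.csv}, one
#' \code{msd_<cohort>.csv} per cohort, one \code{stats_<metric>.csv} per
#' metric and a deterministic \code{manifest.json}; re-running an identical
#' configuration reproduces the CSVs byte for byte.
#'
#' @param config a [RunConfig-class].
#' @param out_dir output directory (created if missing); \code{NULL}
#'   disables writing.
#' @return Invisible list: \code{summary} (per-cell table), \code{msd}
#'   (named list of [MSDCurve-class]), \code{stats} (named list of
#'   [StatsResult-class]), \code{manifest}.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  validObject(config)
  opts <- config@options
  summaries <- list()
  msds <- list()
  for (co in config@cohorts) {
    ts <- tryCatch(.simulate_cohort(co, opts),
                   error = function(e) stop(sprintf(
                     "stage 'simulate/track' failed for cohort '%s': %s",
                     co$name, conditionMessage(e)), call. = FALSE))
    summ <- migrationSummary(
      ts, threshold_deg = opts$alignment_threshold_deg,
      min_step_um = opts$min_step_um, dy_floor_um = opts$dy_floor_um)
    summ <- cbind(cohort = co$name, summ, seed = co$seed)
    summaries[[co$name]] <- summ
    msds[[co$name]] <- fitMSDExponent(ensembleMSD(ts),
                                      window = opts$msd_fit_window_h)
  }
  summary_df <- do.call(rbind, summaries)
  rownames(summary_df) <- NULL
  metrics <- c("mean_speed_umh", "directionality", "aligned_fraction")
  stats_list <- list()
  for (m in metrics) {
    v <- summary_df[[m]]
    ok <- is.finite(v)
    if (length(unique(summary_df$cohort[ok])) >= 2L)
      stats_list[[m]] <- groupStats(v[ok], summary_df$cohort[ok], metric = m)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("curvtracks")),
    config_digest = .config_digest(config),
    n_cohorts = length(config@cohorts),
    cells_per_cohort = vapply(summaries, nrow, 1L),
    options = opts[order(names(opts))])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "per_cell_summary.csv"),
                     row.names = FALSE)
    for (nm in names(msds))
      utils::write.csv(msdTable(msds[[nm]]),
                       file.path(out_dir, sprintf("msd_%s.csv", nm)),
                       row.names = FALSE)
    for (m in metrics) {
      st <- stats_list[[m]]
      tab <- cbind(metric = m, st@pairwise,
                   H = st@H, p_omnibus = st@p_omnibus)
      utils::write.csv(tab, file.path(out_dir, sprintf("stats_%s.csv", m)),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(summary = summary_df, msd = msds, stats = stats_list,
                 manifest = manifest))
}

# md5 of the serialized configuration (version-stable fields only)
.config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  desc <- lapply(config@cohorts, function(co) list(
    name = co$name, phenotype = co$phenotype, n_cells = co$n_cells,
    seed = co$seed, diameter = co$surface@diameter_um,
    concavity = co$surface@concavity))
  writeLines(yaml::as.yaml(list(cohorts = desc,
                                options = config@options[order(names(config@options))])),
             tmp)
  unname(tools::md5sum(tmp))
}
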