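#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration of the end-to-end run:
#' preprocessing rescale, boundary prediction (a trained checkpoint, or
#' \code{"skip"} to accept a precomputed boundary map as input), watershed
#' oversegmentation, graph partitioning, and export. Unspecified fields take
#' the defaults shown; \code{checkpoint} must either name a file or be
#' \code{"skip"}.
#'
#' @param x a YAML file path, a list with (subsets of) the fields below, or
#'   nothing for pure defaults.
#' @return an object of class \code{pipeline_config}: list with fields
#'   \code{input}, \code{preprocessing} (factors, order), \code{cnn}
#'   (checkpoint, patch_shape, overlap_fraction), \code{watershed} (delta,
#'   seed_sigma, min_region_voxels, use_2d_slices), \code{partitioning}
#'   (algorithm, beta_bias), \code{export} (format, directory, basename).
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (!is.list(x)) stop("x must be a YAML path or a list")
  def <- list(
    input = NULL,
    preprocessing = list(factors = c(1, 1, 1), order = 1L),
    cnn = list(checkpoint = "skip", patch_shape = c(32L, 32L, 32L),
               overlap_fraction = 0.5),
    watershed = list(delta = 0.4, seed_sigma = 2.0, min_region_voxels = 50L,
                     use_2d_slices = FALSE),
    partitioning = list(algorithm = "gasp", beta_bias = 0.6),
    export = list(format = "hdf5", directory = ".", basename = "volume")
  )
  cfg <- utils::modifyList(def, x, keep.null = TRUE)
  if (any(cfg$preprocessing$factors <= 0)) stop("rescale factors must be > 0")
  if (!cfg$export$format %in% c("hdf5", "tiff")) {
    stop("export format must be 'hdf5' or 'tiff'")
  }
  if (is.null(cfg$cnn$checkpoint) ||
      (cfg$cnn$checkpoint != "skip" && !nzchar(cfg$cnn$checkpoint))) {
    stop("cnn$checkpoint must be a checkpoint path or 'skip'")
  }
  if (!cfg$partitioning$algorithm %in%
      c("gasp", "mutex", "multicut", "multicut_exact", "dtws")) {
    stop("unknown partitioning algorithm: ", cfg$partitioning$algorithm)
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#'
#' Round-trips with [pipeline_config()]: serialize, parse, serialize is a
#' fixed point.
#'
#' @param config a \code{pipeline_config}.
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full segmentation pipeline
#'
#' Chains preprocessing (per-axis rescale), boundary prediction (CNN
#' checkpoint, or pass-through of a precomputed boundary map when
#' \code{checkpoint = "skip"}), distance-transform watershed, region
#' adjacency graph partitioning and export. The final segmentation is
#' returned on the voxel grid of the ORIGINAL input (inverse rescale,
#' order 0); the boundary map is exported at processing resolution. A JSON
#' run log with all parameters, graph statistics and stage timings is
#' written next to the outputs.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by it).
#' @param volume optional in-memory input volume (bypasses \code{input}).
#' @return (invisibly) list with \code{boundary_map}, \code{supervoxels},
#'   \code{segmentation}, \code{paths}, \code{log}.
#' @export
run_pipeline <- function(config, volume = NULL) {
  config <- pipeline_config(if (inherits(config, "pipeline_config"))
    unclass(config) else config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(nm, t_start) {
    timings[[nm]] <<- round(proc.time()[["elapsed"]] - t_start, 3)
  }

  ts <- proc.time()[["elapsed"]]
  vol <- stage("read", {
    if (!is.null(volume)) as_vol3d(volume)
    else {
      if (is.null(config$input)) stop("no input path and no in-memory volume")
      read_volume(config$input,
                  kind = if (config$cnn$checkpoint == "skip") "boundary"
                         else "intensity")
    }
  })
  tick("read", ts)
  orig_dim <- dim(vol)

  ts <- proc.time()[["elapsed"]]
  vol <- stage("preprocess", {
    f <- config$preprocessing$factors
    if (all(f == 1)) vol
    else rescale_volume(vol, f, as.integer(config$preprocessing$order))
  })
  tick("preprocess", ts)

  ts <- proc.time()[["elapsed"]]
  bmap <- stage("predict", {
    if (config$cnn$checkpoint == "skip") {
      .clamp(vol, 0, 1)
    } else {
      model <- load_model(config$cnn$checkpoint)
      icfg <- inference_config(config$cnn$patch_shape,
                               config$cnn$overlap_fraction)
      predict_tiled(model, standardize(vol), icfg)
    }
  })
  tick("predict", ts)

  ts <- proc.time()[["elapsed"]]
  wp <- watershed_params(config$watershed$delta, config$watershed$seed_sigma,
                         config$watershed$min_region_voxels,
                         config$watershed$use_2d_slices)
  sv <- stage("watershed", dt_watershed(bmap, wp))
  tick("watershed", ts)

  ts <- proc.time()[["elapsed"]]
  alg <- config$partitioning$algorithm
  if (alg == "dtws") {
    seg <- sv
    rag <- NULL
  } else {
    rag <- stage("rag", build_rag(sv, bmap))
    part <- stage("partition",
                  partition_rag(rag, alg, config$partitioning$beta_bias))
    seg <- stage("project", project_partition(sv, part))
  }
  tick("partition", ts)

  ts <- proc.time()[["elapsed"]]
  seg_out <- stage("postprocess", resample_to(seg, orig_dim, 0L))
  tick("postprocess", ts)

  ts <- proc.time()[["elapsed"]]
  dir.create(config$export$directory, showWarnings = FALSE, recursive = TRUE)
  ext <- if (config$export$format == "hdf5") ".h5" else ".tiff"
  base <- file.path(config$export$directory, config$export$basename)
  paths <- list(predictions = paste0(base, "_predictions", ext),
                segmentation = paste0(base, "_segmentation", ext),
                log = paste0(base, "_run.json"))
  stage("export", {
    write_volume(bmap, paths$predictions, kind = "boundary")
    write_volume(seg_out, paths$segmentation, kind = "labels")
  })
  tick("export", ts)

  log <- list(config = unclass(config),
              input_shape = orig_dim,
              processed_shape = dim(bmap),
              n_supervoxels = max(sv),
              n_segments = max(seg_out),
              rag = if (is.null(rag)) NULL else
                list(n_nodes = nrow(rag$nodes), n_edges = nrow(rag$edges)),
              timings = timings,
              total_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(list(boundary_map = bmap, supervoxels = sv, segmentation = seg_out,
                 paths = paths, log = log))
}
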