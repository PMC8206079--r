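# Orchestration: one call reproduces the full analysis from a directory
# of input tables, writing every stage's artifact plus a manifest of
# seeds and settings.  All inputs are validated before any computation;
# a stage failure aborts with the stage name.

#' Assemble and validate a pipeline configuration
#'
#' @param edna_detections path to a long-format eDNA detection table
#'   (see [read_detection_matrix()]; effort column `volume_l`), or `NULL`
#'   when a MOTU table is supplied instead.
#' @param samples path to the water-sample metadata CSV.
#' @param cameras path to the camera-records CSV.
#' @param costs path to the cost table CSV (one `edna` and one `camera`
#'   row).
#' @param motu_counts,motu_libraries optional paths to a raw MOTU table
#'   (see [read_motu_table()]); when given, the MOTU filter chain builds
#'   the eDNA detection matrix.
#' @param out_dir output directory (created; must not already contain a
#'   manifest — runs are write-once).
#' @param seed integer seed for all stochastic stages.
#' @param n_boot bootstrap iterations for accumulation curves.
#' @param engine posterior engine for [estimate_detection()].
#' @param prior Beta prior hyperparameters.
#' @param unit reference effort (litres / trap-days).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(edna_detections = NULL, samples, cameras,
                            costs, motu_counts = NULL,
                            motu_libraries = NULL, out_dir,
                            seed = 1, n_boot = 1000,
                            engine = c("grid", "mcmc"), prior = c(1, 1),
                            unit = 60) {
  engine <- match.arg(engine)
  paths <- c(edna_detections = edna_detections, samples = samples,
             cameras = cameras, costs = costs, motu_counts = motu_counts,
             motu_libraries = motu_libraries)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = "; "))
  if (is.null(edna_detections) && is.null(motu_counts))
    stop("supply either edna_detections or motu_counts/motu_libraries")
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 engine = engine, prior = prior, unit = unit),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full survey-comparison pipeline
#'
#' Stages: (optional) MOTU filtering, detection-probability estimation
#' for the eDNA and camera surveys, diversity summaries, bootstrap
#' accumulation and cost curves per method, and the between-method
#' comparison regression.  Artifacts written to `cfg$out_dir`:
#' `detection_estimates.csv`, `diversity_summary.csv`,
#' `accumulation.csv`, `cost_curves.csv`, `comparisons.csv`,
#' `manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (file.exists(file.path(cfg$out_dir, "manifest.json")))
    stop("output directory already holds a completed run; ",
         "runs are write-once")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  samples <- .stage("read-samples", read_water_samples(cfg$paths$samples))
  cameras <- .stage("read-cameras", read_camera_records(cfg$paths$cameras))
  costs <- .stage("read-costs", read_cost_model(cfg$paths$costs))

  edna <- .stage("filter-motus", {
    if (!is.null(cfg$paths$motu_counts)) {
      mt <- read_motu_table(cfg$paths$motu_counts,
                            cfg$paths$motu_libraries)
      filter_motus(mt, samples)
    } else {
      read_detection_matrix(cfg$paths$edna_detections,
                            effort_column = "volume_l")
    }
  })
  cam_m <- .stage("camera-matrix", cameras_to_matrix(cameras))

  est <- .stage("estimate-detection", {
    design <- unique(samples$design)[1]
    rbind(
      estimate_detection(edna, paste0("edna_", design),
                         year = unique(samples$year)[1],
                         prior = cfg$prior, engine = cfg$engine,
                         cfg = mcmc_config(seed = cfg$seed),
                         unit = cfg$unit),
      estimate_detection(cam_m, "camera",
                         year = unique(cameras$year)[1],
                         prior = cfg$prior, engine = cfg$engine,
                         cfg = mcmc_config(seed = cfg$seed + 1000L),
                         unit = cfg$unit))
  })

  div <- .stage("diversity", {
    do.call(rbind, lapply(list(edna = edna, camera = cam_m), function(m) {
      s <- diversity_summary(m)
      data.frame(gamma = s$gamma, alpha_bar = round(s$alpha_bar, 1),
                 turnover = round(s$turnover, 2))
    }))
  })
  div <- cbind(method = rownames(div), div)
  rownames(div) <- NULL

  curves <- .stage("cost-curves", {
    out <- lapply(c(edna = "edna", camera = "camera"), function(mth) {
      m <- if (mth == "edna") edna else cam_m
      ac <- bootstrap_accumulation(m, n_iter = cfg$n_boot,
                                   seed = cfg$seed)
      cr <- costs[costs$method == mth, , drop = FALSE][1, ]
      list(ac = cbind(method = mth, ac$curve),
           cc = cbind(method = mth, cost_curve(ac, cr)))
    })
    list(ac = do.call(rbind, lapply(out, `[[`, "ac")),
         cc = do.call(rbind, lapply(out, `[[`, "cc")))
  })

  shared <- intersect(rownames(edna$y), rownames(cam_m$y))
  comp <- if (length(shared) >= 3) {
    .stage("compare",
           compare_estimates(est[est$method != "camera", ],
                             est[est$method == "camera", ],
                             name = "edna_vs_camera"))
  } else {
    data.frame(comparison = character(0), n = integer(0),
               slope = numeric(0), intercept = numeric(0),
               r_squared = numeric(0))
  }

  utils::write.csv(est, file.path(cfg$out_dir, "detection_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(div, file.path(cfg$out_dir, "diversity_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(curves$ac, file.path(cfg$out_dir, "accumulation.csv"),
                   row.names = FALSE)
  utils::write.csv(curves$cc, file.path(cfg$out_dir, "cost_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(comp, file.path(cfg$out_dir, "comparisons.csv"),
                   row.names = FALSE)
  manifest <- list(package = "ednacam",
                   version = as.character(utils::packageVersion("ednacam")),
                   seed = cfg$seed, n_boot = cfg$n_boot,
                   engine = cfg$engine, prior = cfg$prior,
                   unit = cfg$unit, inputs = cfg$paths,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$out_dir)
}
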