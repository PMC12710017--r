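#' Derive a per-stage seed from the global seed
#'
#' Stable fan-out: hashes the stage name into an offset so each stage is
#' individually reproducible from the single pipeline seed. Result stays
#' below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483647L)
}

#' Pipeline configuration
#'
#' Materializes every default into one nested list so that the run manifest
#' records the complete resolved configuration. The `mini` preset shrinks
#' the grid and the orchard for desk-scale runs; `orchard1` / `orchard2`
#' use the full default grid and the large orchards.
#'
#' @param preset `"mini"`, `"orchard1"` or `"orchard2"`.
#' @param seed global seed.
#' @param outdir output directory.
#' @param overrides named list merged over the preset (top-level keys).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("mini", "orchard1", "orchard2"),
                            seed = 1L, outdir = tempfile("crownshade_run_"),
                            overrides = list()) {
  preset <- match.arg(preset)
  mini <- preset == "mini"
  cfg <- list(
    preset = preset, seed = as.integer(seed), outdir = outdir,
    site = site_defaults(),
    grid = if (mini) c(n_struct = 2, cab = 8, cw = 2, lai = 4)
           else c(n_struct = 8, cab = 70, cw = 4, lai = 9),
    times = 9:16,
    lut_resolution = 0.08, lut_supersample = 2, fesc_photons = 2000,
    mixing = unclass(mixing_params()),
    selection = list(k_max = 8, rel_tol = 0.01, max_train = if (mini) 400 else 800,
                     n_val = if (mini) 1500 else 3000),
    survey = list(time = 12, resolution = if (mini) 0.05 else 0.05,
                  supersample = 2, noise_std = 0.01, jitter = 0.15,
                  n_lai_calibration = 85, lai_noise_sd = 0.3)
  )
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Serialize / parse a pipeline configuration
#'
#' JSON round-trip used by the command-line interface; `parse(serialize(x))`
#' is idempotent.
#'
#' @param cfg a `pipeline_config`.
#' @param path JSON path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$grid <- as.list(x$grid)    # keep parameter names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$grid <- unlist(cfg$grid)
  cfg$times <- as.numeric(cfg$times)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.stage_outputs <- function(outdir) {
  list("simulate-lut" = file.path(outdir, "lut.csv"),
       "rank-vis" = file.path(outdir, "ranking.csv"),
       "select-vis" = file.path(outdir, "selection.json"),
       "train" = file.path(outdir, "model_lcc.rds"),
       "synth-survey" = file.path(outdir, "survey_truth.csv"),
       "invert" = file.path(outdir, "predictions.csv"),
       "map" = file.path(outdir, "lcc_map.asc"))
}

.stage_deps <- c("simulate-lut" = "", "rank-vis" = "simulate-lut",
                 "select-vis" = "rank-vis", "train" = "select-vis",
                 "synth-survey" = "", "invert" = "train",
                 "map" = "invert")

.require_stage <- function(stage, outdir) {
  dep <- .stage_deps[[stage]]
  if (nzchar(dep) && !file.exists(.stage_outputs(outdir)[[dep]]))
    stop("run_stage: missing artifact for stage '", stage,
         "'; run stage '", dep, "' first", call. = FALSE)
  if (nzchar(dep)) .require_stage(dep, outdir)
}

#' Run one pipeline stage
#'
#' Stages: `simulate-lut`, `rank-vis`, `select-vis`, `train`,
#' `synth-survey`, `invert`, `map`. Each stage reads its upstream artifacts
#' from `cfg$outdir`, writes its own artifacts there and appends a manifest
#' entry (file digests + seed) to `manifest.json`.
#'
#' @param stage stage name.
#' @param cfg a [pipeline_config()].
#' @return list of written artifact paths, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- .stage_outputs(outdir)
  if (!stage %in% names(paths)) stop("run_stage: unknown stage ", stage)
  .require_stage(stage, outdir)
  sseed <- stage_seed(cfg$seed, stage)
  t0 <- Sys.time()
  written <- character(0)

  if (stage == "simulate-lut") {
    lut <- build_lut(grid = lut_grid(n_levels = cfg$grid), times = cfg$times,
                     site = cfg$site, mixing = do.call(mixing_params, cfg$mixing),
                     resolution = cfg$lut_resolution,
                     supersample = cfg$lut_supersample,
                     fesc_photons = cfg$fesc_photons, seed = sseed)
    write_lut(lut, paths[[stage]])
    written <- paths[[stage]]
  } else if (stage == "rank-vis") {
    lut <- utils::read.csv(paths[["simulate-lut"]], check.names = FALSE)
    rk <- rank_vis(vi_case_r2(lut))
    utils::write.csv(cbind(rk$table,
                           as.data.frame(rk$r2[rk$table$vi, , drop = FALSE])),
                     paths[[stage]], row.names = FALSE)
    written <- paths[[stage]]
  } else if (stage == "select-vis") {
    lut <- utils::read.csv(paths[["simulate-lut"]], check.names = FALSE)
    rk <- utils::read.csv(paths[["rank-vis"]], check.names = FALSE)
    sel <- iterative_vi_selection(rk$vi, lut, seed = sseed,
                                  k_max = cfg$selection$k_max,
                                  rel_tol = cfg$selection$rel_tol,
                                  max_train = cfg$selection$max_train,
                                  n_val = cfg$selection$n_val)
    jsonlite::write_json(list(chosen = sel$chosen,
                              ranked_vis = sel$ranked_vis,
                              step_rmse = sel$step_rmse, seed = sseed),
                         paths[[stage]], auto_unbox = FALSE, digits = NA)
    written <- paths[[stage]]
  } else if (stage == "train") {
    lut <- utils::read.csv(paths[["simulate-lut"]], check.names = FALSE)
    sel <- jsonlite::read_json(paths[["select-vis"]], simplifyVector = TRUE)
    m <- train_lcc_model(lut, sel$chosen, seed = sseed,
                         max_train = cfg$selection$max_train)
    saveRDS(m, paths[[stage]])
    jsonlite::write_json(list(features = m$feature_names,
                              lengthscales = m$lengthscales, sf2 = m$sf2,
                              sn2 = m$sn2, nll = m$nll),
                         file.path(outdir, "model_lcc.json"),
                         auto_unbox = FALSE, digits = NA)
    written <- c(paths[[stage]], file.path(outdir, "model_lcc.json"))
  } else if (stage == "synth-survey") {
    layout <- orchard_preset(cfg$preset, jitter = cfg$survey$jitter,
                             seed = sseed)
    truth <- sample_truth(nrow(layout), seed = sseed + 1L)
    survey <- render_survey(layout, truth, time = cfg$survey$time,
                            site = cfg$site,
                            resolution = cfg$survey$resolution,
                            supersample = cfg$survey$supersample,
                            noise_std = cfg$survey$noise_std,
                            mixing = do.call(mixing_params, cfg$mixing),
                            seed = sseed + 2L)
    written <- write_survey(survey, outdir, "survey")  # includes survey_truth.csv
    saveRDS(survey, file.path(outdir, "survey.rds"))
    written <- unique(c(written, file.path(outdir, "survey.rds")))
  } else if (stage == "invert") {
    m_lcc <- readRDS(paths[["train"]])
    survey <- readRDS(file.path(outdir, "survey.rds"))
    cr <- extract_crown_reflectance(survey)
    vis <- compute_vis(cr[, uav_bands()$name])
    vis$tree_id <- cr$tree_id
    set.seed(sseed)
    ncal <- min(cfg$survey$n_lai_calibration, nrow(survey$truth))
    cal <- sort(sample.int(nrow(survey$truth), ncal))
    lai_meas <- survey$truth$lai[cal] +
      stats::rnorm(ncal, 0, cfg$survey$lai_noise_sd)
    m_lai <- train_lai_model(vis[cal, ], lai_meas, seed = sseed + 1L)
    est <- predict_traits(m_lcc, m_lai, vis)
    utils::write.csv(est, paths[[stage]], row.names = FALSE)
    met <- list(lcc = evaluate_accuracy(survey$truth$lcc, est$lcc),
                lai = evaluate_accuracy(survey$truth$lai, est$lai),
                ccc = evaluate_accuracy(survey$truth$ccc, est$ccc))
    jsonlite::write_json(met, file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(paths[[stage]], file.path(outdir, "metrics.json"))
  } else if (stage == "map") {
    est <- utils::read.csv(paths[["invert"]])
    survey <- readRDS(file.path(outdir, "survey.rds"))
    for (v in c("lcc", "ccc")) {
      mp <- map_traits(est, survey$crown_id, var = v)
      write_ascii_grid(mp, file.path(outdir, paste0(v, "_map.asc")),
                       survey$extent["xmin"], survey$extent["ymin"],
                       survey$resolution)
      written <- c(written, file.path(outdir, paste0(v, "_map.asc")))
    }
  }

  .append_manifest(outdir, stage, sseed, written, cfg,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(written)
}

.append_manifest <- function(outdir, stage, sseed, files, cfg, secs) {
  mpath <- file.path(outdir, "manifest.json")
  man <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else
      list(config = unclass(cfg), stages = list())
  dig <- as.list(tools::md5sum(files))
  man$stages[[stage]] <- list(seed = sseed, seconds = round(secs, 2),
                              outputs = dig)
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order; the final per-tree CSV holds
#' `tree_id`, `lcc`, `lai`, `ccc` for every tree of the preset orchard.
#'
#' @param cfg a [pipeline_config()].
#' @return path of the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  for (st in c("simulate-lut", "rank-vis", "select-vis", "train",
               "synth-survey", "invert", "map"))
    run_stage(st, cfg)
  invisible(file.path(cfg$outdir, "manifest.json"))
}

#' Rasterize per-tree trait estimates
#'
#' Piecewise-constant map: every crown pixel takes its tree's estimate;
#' background is `NA`.
#'
#' @param estimates data.frame with `tree_id` and the trait column.
#' @param crown_id integer crown-id matrix (0 = background).
#' @param var trait column name.
#' @return numeric matrix of the trait map.
#' @export
map_traits <- function(estimates, crown_id, var = "lcc") {
  if (!var %in% names(estimates)) stop("map_traits: no column ", var)
  ids <- sort(unique(crown_id[crown_id > 0]))
  orphan <- setdiff(ids, estimates$tree_id)
  if (length(orphan))
    stop("map_traits: crown ids without estimates: ",
         paste(orphan, collapse = ", "))
  lut <- rep(NA_real_, max(ids))
  lut[estimates$tree_id] <- estimates[[var]]
  out <- matrix(NA_real_, nrow(crown_id), ncol(crown_id))
  sel <- crown_id > 0
  out[sel] <- lut[crown_id[sel]]
  out
}
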