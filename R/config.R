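# Configuration-driven pipeline stages. One config file drives all stages;
# every run writes its resolved configuration beside its outputs, and all
# randomness flows from the single seed.

.defaultConfig <- function() {
  list(
    seed = 1L,
    pixel_size_um = 9.56,
    n_points = 500L,
    bands = list(surface_um = 9.56, thickness_um = 19.12),
    cohort = list(n_mice = 6L, load_levels = c(0, 2, 4, 6, 8, 10, 12),
                  shape_jitter_sd_um = 5, phase_jitter_sd_rad = 0.05,
                  contour_noise_sd_um = 2, rotation_jitter_sd_deg = 2),
    schedule = list(sn_pre_days = 5, loading_days = 14, sn_post_days = 2,
                    dt_days = 1),
    load = list(point_um = c(0, -1000), tibial_share = 0.9,
                youngs_modulus_pa = 14.8e9),
    model = list(id = "M4", k_pt = 2.148, k_pc = 0.981, k_et = 7.055,
                 k_ec = 0.794, eps_hom_p = 2785, eps_hom_e = 1100,
                 k_sn = 1.398),
    optimize = list(stages = "table", budget_hi = 2,
                    budget_increment = 0.5, calibration_load_n = 10),
    out_dir = "mechanoct-out")
}

.deepMerge <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]]))
      base[[nm]] <- .deepMerge(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

.validateConfig <- function(cfg) {
  if (cfg$pixel_size_um <= 0) stop("config: pixel_size_um must be positive")
  if (cfg$n_points < 8) stop("config: n_points must be at least 8")
  if (cfg$cohort$n_mice < 2) stop("config: n_mice must be at least 2")
  if (!cfg$model$id %in% c("M1", "M2", "M3", "M4"))
    stop("config: model id must be one of M1..M4")
  if (any(unlist(cfg$bands) <= 0)) stop("config: bands must be positive")
  if (!cfg$optimize$stages %in% c("table", "budget"))
    stop("config: optimize$stages must be 'table' or 'budget'")
  cfg
}

#' Read and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, fills unspecified keys from
#' the package defaults, and validates it. With `path = NULL` the default
#' configuration is returned.
#'
#' @param path configuration file (.yaml/.yml/.json), or `NULL`.
#' @param overrides named list applied on top of the file (flag-style
#'   overrides).
#' @return the resolved configuration list (class `RunConfig`).
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    cfg <- .deepMerge(cfg, user)
  }
  cfg <- .deepMerge(cfg, overrides)
  structure(.validateConfig(cfg), class = "RunConfig")
}

.cohortSpecFromConfig <- function(cfg) {
  m <- cfg$model
  cohortSpec(
    nMice = cfg$cohort$n_mice, loadLevels = cfg$cohort$load_levels,
    shapeJitterSD = cfg$cohort$shape_jitter_sd_um,
    phaseJitterSD = cfg$cohort$phase_jitter_sd_rad,
    contourNoiseSD = cfg$cohort$contour_noise_sd_um,
    rotationJitterSD = cfg$cohort$rotation_jitter_sd_deg,
    seed = cfg$seed,
    truthParams = mechanostatParams(m$id, kPT = m$k_pt, kPC = m$k_pc,
                                    kET = m$k_et, kEC = m$k_ec,
                                    epsHomP = m$eps_hom_p,
                                    epsHomE = m$eps_hom_e, kSN = m$k_sn),
    geometry = geometrySpec(pixelSize = cfg$pixel_size_um),
    loadPoint = cfg$load$point_um, nPoints = cfg$n_points,
    snPre = cfg$schedule$sn_pre_days,
    loadingDays = cfg$schedule$loading_days,
    snPost = cfg$schedule$sn_post_days, dt = cfg$schedule$dt_days)
}

.writeResolvedConfig <- function(cfg, dir) {
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Generate a synthetic cohort on disk
#'
#' Writes every slice as PNG + JSON sidecar and the per-animal ground-truth
#' adaptation fields as CSV, together with the resolved configuration.
#' Re-running with an identical configuration reproduces the outputs.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @param dir output directory (default `cfg$out_dir`).
#' @return the directory, invisibly.
#' @export
runSynth <- function(cfg, dir = cfg$out_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- makeCohort(.cohortSpecFromConfig(cfg))
  truthRows <- list()
  for (g in cohort$groups) {
    for (m in seq_along(g$mice)) {
      mouse <- g$mice[[m]]
      if (mouse$flagged) next
      for (limb in c("left", "right")) {
        fn <- file.path(dir, sprintf("F%g_m%d_%s.png", g$load, m,
                                     if (limb == "left") "L" else "R"))
        writeSlice(mouse[[limb]], fn,
                   meta = list(limb = if (limb == "left") "L" else "R",
                               mouse_id = m, load_N = g$load,
                               seed = cfg$seed))
      }
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        load_N = g$load, mouse_id = m,
        surface = rep(c("periosteal", "endosteal"),
                      each = length(mouse$truth$P)),
        P = rep(mouse$truth$P, 2L),
        delta_eta_um = c(mouse$truth$deltaEtaP, mouse$truth$deltaEtaE))
    }
  }
  utils::write.csv(do.call(rbind, truthRows),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  .writeResolvedConfig(cfg, dir)
  invisible(dir)
}

#' Measure adaptation for every loading group of a cohort directory
#'
#' Reads the slices written by [runSynth()], runs the measurement pipeline
#' per animal, and writes one CSV of group statistics per load level.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @param dir cohort directory (default `cfg$out_dir`).
#' @return named list of per-group measurement lists, invisibly.
#' @export
runMeasure <- function(cfg, dir = cfg$out_dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) stop("no slices found in ", dir)
  meta <- lapply(files, function(f) {
    sc <- paste0(f, ".json")
    if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
    jsonlite::read_json(sc, simplifyVector = TRUE)
  })
  info <- data.frame(file = files,
                     load = vapply(meta, `[[`, numeric(1), "load_N"),
                     mouse = vapply(meta, `[[`, numeric(1), "mouse_id"),
                     limb = vapply(meta, `[[`, character(1), "limb"))
  out <- list()
  for (F in sort(unique(info$load))) {
    sub <- info[info$load == F, ]
    pairs <- lapply(sort(unique(sub$mouse)), function(m) {
      list(left = readSlice(sub$file[sub$mouse == m & sub$limb == "L"]),
           right = readSlice(sub$file[sub$mouse == m & sub$limb == "R"]))
    })
    gs <- measureGroup(pairs, n = cfg$n_points)
    writeMeasurement(gs, file.path(dir, sprintf("measured_F%g.csv", F)))
    out[[paste0("F", F)]] <- gs
  }
  invisible(out)
}

#' Simulate the adaptation endpoint for each configured load
#'
#' Runs the forward mechanostat simulation from the default baseline
#' geometry for every load level and writes the endpoint contours.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @param dir output directory (default `cfg$out_dir`).
#' @return named list of endpoint pairs, invisibly.
#' @export
runSimulate <- function(cfg, dir = cfg$out_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cfg$model
  params <- mechanostatParams(m$id, kPT = m$k_pt, kPC = m$k_pc,
                              kET = m$k_et, kEC = m$k_ec,
                              epsHomP = m$eps_hom_p, epsHomE = m$eps_hom_e,
                              kSN = m$k_sn)
  base <- makeBaselineGeometry(geometrySpec(pixelSize = cfg$pixel_size_um),
                               n = cfg$n_points)
  out <- list()
  for (F in cfg$cohort$load_levels) {
    sched <- simulationSchedule(
      loadCase(F, loadPoint = cfg$load$point_um,
               tibialShare = cfg$load$tibial_share,
               youngsModulus = cfg$load$youngs_modulus_pa),
      snPre = cfg$schedule$sn_pre_days,
      loadingDays = cfg$schedule$loading_days,
      snPost = cfg$schedule$sn_post_days, dt = cfg$schedule$dt_days)
    end <- simulateAdaptation(base$periosteal, base$endosteal, params,
                              sched, n = cfg$n_points, audit = FALSE)
    writeContours(end[c("periosteal", "endosteal")],
                  file.path(dir, sprintf("sim_F%g.csv", F)))
    out[[paste0("F", F)]] <- end
  }
  .writeResolvedConfig(cfg, dir)
  invisible(out)
}

#' Calibrate the configured mechanostat model against a measured target
#'
#' Fits the configured model's formation rates to the measured periosteal
#' and endosteal fields of the calibration load group by staged grid
#' search, writing the fit and the full search log.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @param target list with `periosteal` and `endosteal` measured fields.
#' @param dir output directory (default `cfg$out_dir`).
#' @return the [MechanostatFit-class], invisibly.
#' @export
runOptimize <- function(cfg, target, dir = cfg$out_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (cfg$optimize$stages == "budget") {
    budgetStages(cfg$model$id, hi = cfg$optimize$budget_hi,
                 increment = cfg$optimize$budget_increment)
  } else tableStages(cfg$model$id)
  base <- makeBaselineGeometry(geometrySpec(pixelSize = cfg$pixel_size_um),
                               n = length(target$periosteal))
  sched <- simulationSchedule(
    loadCase(cfg$optimize$calibration_load_n,
             loadPoint = cfg$load$point_um,
             tibialShare = cfg$load$tibial_share,
             youngsModulus = cfg$load$youngs_modulus_pa),
    snPre = cfg$schedule$sn_pre_days,
    loadingDays = cfg$schedule$loading_days,
    snPost = cfg$schedule$sn_post_days, dt = cfg$schedule$dt_days)
  fit <- optimizeRates(cfg$model$id, base, sched, target, stages = stages,
                       epsHomP = cfg$model$eps_hom_p,
                       epsHomE = cfg$model$eps_hom_e, kSN = cfg$model$k_sn)
  utils::write.csv(searchLog(fit), file.path(dir, "search_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(model = modelId(bestParams(fit)),
         rates = as.list(formationRates(bestParams(fit))),
         rms = as.list(rmsErrors(fit))),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Score simulated fields against measured fields
#'
#' Computes prediction accuracies at the configured bands and the regional
#' summaries, writing both to disk.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @param sim list with simulated `deltaEtaP`, `deltaEtaE`, `deltaCtTh`
#'   fields.
#' @param measured list of three [AdaptationMeasurement-class] objects as
#'   returned per group by [runMeasure()].
#' @param dir output directory (default `cfg$out_dir`).
#' @return list with `accuracy` and `regional`, invisibly.
#' @export
runEvaluate <- function(cfg, sim, measured, dir = cfg$out_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- list(
    deltaEtaP = predictionAccuracy(sim$deltaEtaP,
                                   fieldMean(measured$deltaEtaP),
                                   cfg$bands$surface_um),
    deltaEtaE = predictionAccuracy(sim$deltaEtaE,
                                   fieldMean(measured$deltaEtaE),
                                   cfg$bands$surface_um),
    deltaCtTh = predictionAccuracy(sim$deltaCtTh,
                                   fieldMean(measured$deltaCtTh),
                                   cfg$bands$thickness_um))
  reg <- do.call(rbind, lapply(names(measured), function(nm) {
    cbind(measure = nm, regionalSummary(measured[[nm]], sim[[nm]]))
  }))
  jsonlite::write_json(acc, file.path(dir, "accuracy.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(reg, file.path(dir, "regional_summary.csv"),
                   row.names = FALSE)
  invisible(list(accuracy = acc, regional = reg))
}
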