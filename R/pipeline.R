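# End-to-end orchestration: validated configuration -> simulated (or read)
# cohorts -> detection + thickness -> per-capillary metrics -> group
# comparisons -> JSON/CSV report. Deterministic under a fixed seed.

CONFIG_KEYS <- c("seed", "out_dir", "n_per_group", "n_slices", "effect",
                 "detector_params", "test", "rasterize", "thickness",
                 "group_labels", "stacks", "image_px", "bm_base_sd_nm")

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a named list and returns a typed
#' \linkS4class{RunConfig}, or stops with the complete list of violations
#' (not just the first). Referenced stack paths must exist (fail fast).
#'
#' @param x path to a YAML/JSON config or a named list.
#' @return A \linkS4class{RunConfig}.
#' @examples
#' cfg <- validateRunConfig(list(seed = 7, n_per_group = 3, n_slices = 20))
#' @export
validateRunConfig <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    ext <- tolower(tools::file_ext(x))
    x <- switch(ext,
      yaml = , yml = yaml::read_yaml(x),
      json = jsonlite::fromJSON(x, simplifyVector = TRUE),
      stop("unsupported config format: .", ext))
  }
  if (!is.list(x)) stop("config must be a list or a YAML/JSON file")
  viol <- character()
  unknown <- setdiff(names(x), CONFIG_KEYS)
  if (length(unknown))
    viol <- c(viol, paste0("unknown config key: ", unknown))
  gv <- function(key, default) if (is.null(x[[key]])) default else x[[key]]

  seed <- gv("seed", 1L)
  if (!is.numeric(seed) || seed != round(seed))
    viol <- c(viol, "seed must be an integer")
  nPer <- gv("n_per_group", 9L)
  if (!is.numeric(nPer) || nPer < 1)
    viol <- c(viol, "n_per_group must be >= 1")
  nSl <- gv("n_slices", 300L)
  if (!is.numeric(nSl) || nSl < 1 || nSl > 10000)
    viol <- c(viol, "n_slices must lie in [1, 10000]")
  eff <- unlist(gv("effect", diabeticEffect()))
  if (any(!names(eff) %in% c("peg", "detachment", "tubule", "gap")))
    viol <- c(viol, paste0("unknown effect multiplier: ",
                           setdiff(names(eff),
                                   c("peg", "detachment", "tubule", "gap"))))
  if (any(eff < 0)) viol <- c(viol, "effect multipliers must be non-negative")
  dp <- gv("detector_params", list())
  known <- names(defaultDetectorParams())
  for (nm in setdiff(names(dp), known))
    viol <- c(viol, paste0("unknown detector parameter: ", nm))
  for (nm in intersect(names(dp), known))
    if (!is.numeric(dp[[nm]]) || dp[[nm]] <= 0)
      viol <- c(viol, paste0(nm, " must be > 0"))
  test <- gv("test", "auto")
  if (!test %in% c("auto", "student_t", "mann_whitney"))
    viol <- c(viol, "test must be auto, student_t or mann_whitney")
  labs <- gv("group_labels", c("non_diabetic", "diabetic"))
  if (length(labs) != 2) viol <- c(viol, "group_labels must have length 2")
  for (st in gv("stacks", list())) {
    for (f in c(st$tiff, st$role_map))
      if (!is.null(f) && !file.exists(f))
        viol <- c(viol, paste0("referenced path does not exist: ", f))
  }
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  template <- phantomSpec(nSlices = as.integer(nSl))
  new("RunConfig", seed = as.integer(seed),
      outDir = as.character(gv("out_dir", NA_character_)),
      nPerGroup = as.integer(nPer), nSlices = as.integer(nSl),
      effect = eff, detectorParams = dp, testChoice = test,
      rasterize = isTRUE(gv("rasterize", TRUE)),
      thickness = isTRUE(gv("thickness", TRUE)),
      groupLabels = as.character(labs), template = template)
}

PIPELINE_METRICS <- c("peg_per_10um", "peg_detached_per_10um",
                      "detachment_endothelium_per_10um",
                      "detachment_pericyte_per_10um",
                      "detachment_macroglia_per_10um", "detachment_per_10um",
                      "tubule_per_10um", "bm_mean_nm", "bm_max_nm")

#' Run the full analysis pipeline
#'
#' Simulates a control and an effect cohort from the configured template,
#' analyses every stack (detectors and, if configured, BM thickness on the
#' rasterised volumes; otherwise the generative ground truth), assembles the
#' per-capillary metrics table and compares every metric between groups.
#' Deterministic given the seed. If \code{out_dir} is set, writes
#' \code{report.json}, \code{metrics.csv}, \code{events.csv} and
#' \code{comparisons.csv}.
#'
#' @param config a \linkS4class{RunConfig} (or anything
#'   \code{\link{validateRunConfig}} accepts).
#' @return An \linkS4class{AnalysisReport}.
#' @examples
#' \donttest{
#' rep <- runPipeline(list(seed = 1, n_per_group = 3, n_slices = 12,
#'                         rasterize = FALSE))
#' metricsTable(rep)
#' }
#' @export
runPipeline <- function(config) {
  if (!is(config, "RunConfig")) config <- validateRunConfig(config)
  warns <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage <- "cohort_generation"
  report <- tryCatch({
    src <- if (config@rasterize) "measured" else "ground_truth"
    ctl <- makeCohort(config@template, config@nPerGroup,
                      rngSeed = config@seed,
                      meanCounts = cohortMeanCounts(),
                      pegDetachedFraction = 0.1,
                      metricsOnly = !config@rasterize,
                      rasterize = config@rasterize)
    eff <- makeCohort(config@template, config@nPerGroup,
                      effect = config@effect,
                      rngSeed = config@seed + 1L,
                      meanCounts = cohortMeanCounts(),
                      pegDetachedFraction = 0.5,
                      metricsOnly = !config@rasterize,
                      rasterize = config@rasterize)
    stage <- "per_capillary_analysis"
    mt <- rbind(
      wh(cohortMetricsTable(ctl, config@groupLabels[1], src,
                            config@detectorParams, config@thickness)),
      wh(cohortMetricsTable(eff, config@groupLabels[2], src,
                            config@detectorParams, config@thickness)))
    mt$capillary <- seq_len(nrow(mt))
    events <- emptyEvents()
    if (config@rasterize) {
      stage <- "event_collection"
      for (grp in list(ctl, eff)) for (el in grp) {
        ev <- wh(summarizeCapillary(el$volume, el$roleMap,
                                    config@detectorParams))
        events <- rbind(events, featureEvents(ev))
      }
      if (any(events$boundary))
        warns <- c(warns, sprintf("%d event(s) touch the stack boundary",
                                  sum(events$boundary)))
    }
    stage <- "group_comparison"
    metrics <- PIPELINE_METRICS
    if (!config@thickness && config@rasterize)
      metrics <- setdiff(metrics, c("bm_mean_nm", "bm_max_nm"))
    cmps <- lapply(metrics, function(m)
      compareMetricTable(mt, m, config@testChoice))
    names(cmps) <- metrics
    ct <- do.call(rbind, lapply(cmps, function(r) data.frame(
      metric = r@metric, test = r@testName, method = r@method,
      group_1 = r@groupLabels[1], group_2 = r@groupLabels[2],
      mean_1 = r@groupMeans[1], sem_1 = r@groupSems[1], n_1 = r@groupNs[1],
      mean_2 = r@groupMeans[2], sem_2 = r@groupSems[2], n_2 = r@groupNs[2],
      statistic = r@statistic, p_two_tailed = r@pTwoTailed,
      significance = r@stars)))
    rownames(ct) <- NULL
    new("AnalysisReport", metrics = mt, events = events, comparisons = cmps,
        comparisonTable = ct, seed = config@seed,
        configEcho = list(
          seed = config@seed, n_per_group = config@nPerGroup,
          n_slices = config@nSlices, effect = as.list(config@effect),
          detector_params = config@detectorParams, test = config@testChoice,
          rasterize = config@rasterize, thickness = config@thickness,
          group_labels = config@groupLabels),
        warnings = warns,
        version = as.character(packageVersion("nvumorph")))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.na(config@outDir)) writeReport(report, config@outDir)
  report
}

#' Write an AnalysisReport to disk
#'
#' @param report an \linkS4class{AnalysisReport}.
#' @param outDir output directory (created if missing).
#' @return invisibly, the report path.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report@events, file.path(outDir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(report@comparisonTable,
                   file.path(outDir, "comparisons.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(version = report@version, seed = report@seed,
         config = report@configEcho,
         comparisons = report@comparisonTable,
         metrics = report@metrics, warnings = report@warnings),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(file.path(outDir, "report.json"))
}
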