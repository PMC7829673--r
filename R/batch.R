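#' @include synthetic.R
NULL

#' Read a batch configuration
#'
#' Batch configs are YAML with blocks:
#' \preformatted{
#' subjects:            # file list/glob, OR a simulate block
#'   files: ["data/*.snirf"]       # or
#'   simulate: {scenario: rest44, n: 9}
#' input: {format: snirf, fs: 10}  # fs needed for csv input
#' qc: {max_missing_frac: 0.2, max_spike_frac: 0.1}
#' pipeline:
#'   steps:
#'     - {name: detrend, params: {order: 1}}
#' analysis:
#'   type: rest                    # or task
#'   band: [0.01, 0.08]
#'   chromophore: HbO
#'   design: design.tsv            # task only
#'   contrast: [1]                 # task only (condition columns)
#' group: {model: one_sample, correction: fdr_bh, q: 0.05, mask: null}
#' out_dir: out
#' seed: 1
#' strict: false
#' }
#'
#' @param path YAML file.
#' @return the config as a named list (validated lightly).
#' @export
readBatchConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  if (is.null(cfg$subjects)) stop("config needs a subjects block")
  cfg
}

.resolveSubjects <- function(cfg, baseDir = ".") {
  s <- cfg$subjects
  if (!is.null(s$simulate)) {
    scen <- standardScenarios()[[s$simulate$scenario]]
    if (is.null(scen)) stop("unknown scenario: ", s$simulate$scenario)
    specs <- if (is.list(scen) && !is(scen, "ScenarioSpec")) scen
             else if (!is.null(s$simulate$n)) expandSubjects(scen, s$simulate$n)
             else list(scen)
    if (!is.null(s$simulate$n) && is.list(specs))
      specs <- specs[seq_len(min(s$simulate$n, length(specs)))]
    simDir <- file.path(cfg$out_dir, "simulated")
    fmt <- cfg$input$format %||% "snirf"
    writeScenarioFiles(specs, simDir, format = fmt)
  } else {
    files <- unlist(lapply(s$files, function(f) {
      g <- Sys.glob(file.path(baseDir, f))
      if (!length(g)) f else g
    }))
    files
  }
}

.readSubject <- function(path, cfg) {
  if (grepl("\\.snirf$", path)) readSnirf(path)
  else readManualCsv(path, fs = cfg$input$fs %||% stop("csv input needs input$fs"),
                     kind = cfg$input$kind %||% "hb")
}

#' Run the full batch pipeline
#'
#' Executes data preparation, quality control, preprocessing,
#' individual-level analysis per subject and the group-level stage, writing
#' per-stage TSV outputs and a machine-readable run log (step names and
#' parameters; no wall-clock content, so identical configs and seeds
#' reproduce all outputs bitwise). Subjects failing the QC thresholds are
#' excluded and listed in the log; a subject-level error is recorded without
#' aborting the batch unless \code{strict} is set in the config.
#'
#' @param cfg a config list from \code{\link{readBatchConfig}} (or built in
#'   code).
#' @param baseDir directory that relative subject paths resolve against.
#' @return invisibly, a list with \code{outputs} (paths), \code{log},
#'   \code{excluded}, \code{errors}.
#' @export
runPipeline <- function(cfg, baseDir = ".") {
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  files <- .resolveSubjects(cfg, baseDir)
  log <- list(config = cfg[setdiff(names(cfg), "out_dir")],
              subjects = list())
  excluded <- character(0); errors <- list(); outputs <- character(0)
  perSubject <- list()
  pspec <- pipelineSpec(cfg$pipeline$steps %||% list())
  qcMaxMissing <- cfg$qc$max_missing_frac %||% 0.2
  strict <- isTRUE(cfg$strict)
  analysisType <- cfg$analysis$type %||% "rest"

  for (i in seq_along(files)) {
    subj <- sprintf("sub%02d", i)
    res <- tryCatch({
      rec <- .readSubject(files[i], cfg)
      qc <- qcSummary(rec)
      qcPath <- file.path(outDir, paste0(subj, "_qc.tsv"))
      writeQcReport(qc, qcPath)
      outputs <- c(outputs, qcPath)
      if (any(qc@channelTable$missing_frac > qcMaxMissing)) {
        excluded <- c(excluded, subj)
        log$subjects[[subj]] <- list(file = basename(files[i]),
                                     status = "excluded_qc")
        NULL
      } else {
        rec <- applyPipeline(rec, pspec)
        stepLog <- lapply(processingHistory(rec), function(h)
          list(name = h$name, params = h$params))
        if (analysisType == "rest") {
          alff <- computeALFF(rec, band = .num(cfg$analysis$band) %||% c(0.01, 0.08),
                              chromophore = cfg$analysis$chromophore %||% "HbO")
          ap <- file.path(outDir, paste0(subj, "_alff.tsv"))
          writeAlffTable(alff, ap)
          cm <- fcMatrix(rec, chromophore = cfg$analysis$chromophore %||% "HbO")
          fp <- file.path(outDir, paste0(subj, "_fc.txt"))
          exportNetwork(cm, fp)
          outputs <- c(outputs, ap, fp)
          stat <- alff@table$zalff
        } else {
          design <- if (!is.null(cfg$analysis$design))
            readTaskDesign(file.path(baseDir, cfg$analysis$design))
          else stop("task analysis needs analysis$design")
          dm <- buildDesign(design, nTimepoints(rec), samplingRate(rec))
          fit <- fitGlm(rec, dm,
                        chromophore = cfg$analysis$chromophore %||% "HbO")
          cvec <- .num(cfg$analysis$contrast) %||% 1
          cfull <- c(cvec, numeric(ncol(dm@X) - length(cvec)))
          con <- glmContrast(fit, cfull)
          gp <- file.path(outDir, paste0(subj, "_contrast.tsv"))
          utils::write.table(con, gp, sep = "\t", row.names = FALSE,
                             quote = FALSE)
          outputs <- c(outputs, gp)
          stat <- con$effect
        }
        log$subjects[[subj]] <- list(file = basename(files[i]),
                                     status = "ok", steps = stepLog)
        stat
      }
    }, error = function(e) {
      if (strict) stop(e)
      errors[[subj]] <<- conditionMessage(e)
      log$subjects[[subj]] <<- list(file = basename(files[i]),
                                    status = "error",
                                    message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) perSubject[[subj]] <- res
  }

  if (length(perSubject) >= 3 && !is.null(cfg$group)) {
    G <- do.call(rbind, perSubject)
    map <- groupTest(G, cfg$group$model %||% "one_sample")
    if (!is.null(cfg$group$correction) &&
        !identical(cfg$group$correction, "none")) {
      mask <- if (!is.null(cfg$group$mask)) as.integer(unlist(cfg$group$mask))
      map <- correctMultiple(map, cfg$group$correction %||% "fdr_bh",
                             q = cfg$group$q %||% 0.05, mask = mask)
    }
    gpath <- file.path(outDir, "group_stats.tsv")
    writeStatMap(map, gpath)
    outputs <- c(outputs, gpath)
    log$group <- list(model = cfg$group$model %||% "one_sample",
                      n_subjects = length(perSubject))
  }
  log$excluded <- excluded
  logPath <- file.path(outDir, "run_log.yml")
  yaml::write_yaml(log, logPath, precision = 15)
  outputs <- c(outputs, logPath)
  invisible(list(outputs = outputs, log = log, excluded = excluded,
                 errors = errors))
}

.num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
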