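#' Sum a 20-item side-effects checklist
#'
#' @param items exactly 20 integer severity scores, each in 0..4.
#' @return Integer sum in [0, 80].
#' @export
sideEffectSum <- function(items) {
  if (length(items) != 20L)
    stop("sideEffectSum: expected exactly 20 items, got ", length(items))
  if (anyNA(items) || any(items != round(items)) ||
      any(items < 0 | items > 4))
    stop("sideEffectSum: items must be integers in 0..4")
  as.integer(sum(items))
}

#' Validate a study manifest
#'
#' A manifest is a list (typically read from YAML) with a
#' \code{participants} list; each participant has \code{id}, \code{rmt}
#' (%MSO), and \code{sessions}, each session a list of \code{targets} with
#' \code{label}, optional \code{sham} flag, \code{pain} (0-10),
#' \code{side_effects} (20 items, 0-4), and input file paths. Exactly one
#' target per participant must be flagged sham.
#'
#' @param manifest manifest list.
#' @return The manifest, invisibly, after validation; errors otherwise.
#' @export
validateManifest <- function(manifest) {
  if (is.null(manifest$participants) || !length(manifest$participants))
    stop("manifest: no participants")
  for (p in manifest$participants) {
    if (is.null(p$id) || is.null(p$rmt))
      stop("manifest: participant entries need id and rmt")
    if (p$rmt <= 0 || p$rmt > 100)
      stop("manifest: rmt out of range for ", p$id)
    if (is.null(p$sessions) || !length(p$sessions))
      stop("manifest: participant ", p$id, " has no sessions")
    for (s in p$sessions) {
      labs <- vapply(s$targets, `[[`, "", "label")
      if (anyDuplicated(labs))
        stop("manifest: duplicate target labels for ", p$id)
      shams <- vapply(s$targets, function(x) isTRUE(x$sham), logical(1))
      if (sum(shams) != 1L)
        stop("manifest: exactly one sham target required per session (",
             p$id, ")")
      for (tg in s$targets) {
        if (!is.null(tg$pain) && (tg$pain < 0 || tg$pain > 10))
          stop("manifest: pain out of [0, 10] for ", p$id, "/", tg$label)
        if (!is.null(tg$side_effects)) sideEffectSum(tg$side_effects)
      }
    }
  }
  invisible(manifest)
}

#' @rdname validateManifest
#' @param path YAML manifest file.
#' @export
readManifest <- function(path) {
  validateManifest(yaml::read_yaml(path))
}

#' Run the full HBC analysis pipeline on a simulated study
#'
#' Orchestrates the stages end to end: block table (beat series ->
#' instantaneous HR -> per-block entrainment power -> baseline
#' correction), Gamma mixed-effects fits (GLMM and optionally GAM),
#' FDR-corrected summaries, marginal contrasts versus sham, ICC tables
#' (across sessions and pairwise), and post-train HR-change tables. Each
#' recording is processed independently; failures are recorded in the run
#' log and do not abort the pipeline.
#'
#' @param study a \code{StudySimulation} (see \code{\link{simulateStudy}}),
#'   or a validated manifest (not simulated; recordings loaded from the
#'   referenced beat-time CSVs).
#' @param fitGam also fit the spline (GAM) variant and compare by AIC.
#' @param outDir optional directory; when given, every result table is
#'   written as CSV before the next stage begins.
#' @param fsOut instantaneous-HR sampling rate, Hz.
#' @return list of class \code{HbcPipelineResult}: blockTable, fitGlmm,
#'   fitGam (or NULL), comparison, contrasts, iccAll, iccPairwise,
#'   hrChange, directionSummary, log (character vector; empty on a clean
#'   run).
#' @export
runPipeline <- function(study, fitGam = FALSE, outDir = NULL, fsOut = 4) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stopifnot(inherits(study, "StudySimulation"))
  emit <- function(obj, name) {
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(obj, file.path(outDir, paste0(name, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  blockTable <- tryCatch(studyHbcTable(study, fsOut = fsOut),
                         error = function(e) {
                           note("ERROR block table: ", conditionMessage(e))
                           NULL
                         })
  if (is.null(blockTable))
    return(structure(list(log = log), class = "HbcPipelineResult"))
  emit(blockTable, "block_table")

  frame <- hbcModelFrame(blockTable)
  fitG <- tryCatch(fitGammaMixed(frame, "glmm"),
                   error = function(e) {
                     note("ERROR glmm fit: ", conditionMessage(e)); NULL
                   })
  fitS <- NULL
  comparison <- NULL
  if (fitGam) {
    fitS <- tryCatch(fitGammaMixed(frame, "gam"),
                     error = function(e) {
                       note("ERROR gam fit: ", conditionMessage(e)); NULL
                     })
    if (!is.null(fitG) && !is.null(fitS))
      comparison <- compareModels(glmm = fitG, gam = fitS)
  }
  if (!is.null(fitG)) emit(fitG$coefTable, "glmm_coefficients")
  contrasts <- if (!is.null(fitG))
    marginalContrasts(fitG, atMt = c(60, 100, "average")) else NULL
  if (!is.null(contrasts)) emit(contrasts, "marginal_contrasts")

  iccAll <- tryCatch(iccByTargetBlock(blockTable),
                     error = function(e) {
                       note("ERROR icc: ", conditionMessage(e)); NULL
                     })
  if (!is.null(iccAll)) emit(iccAll, "icc_by_target_block")
  iccPair <- tryCatch(pairwiseSessionIcc(blockTable),
                      error = function(e) {
                        note("ERROR pairwise icc: ", conditionMessage(e))
                        NULL
                      })
  if (!is.null(iccPair)) emit(iccPair, "icc_pairwise")

  hrChange <- tryCatch(studyHrChange(study, fsOut = fsOut),
                       error = function(e) {
                         note("ERROR hr change: ", conditionMessage(e)); NULL
                       })
  dirSummary <- if (!is.null(hrChange)) directionSummary(hrChange) else NULL
  if (!is.null(hrChange)) emit(hrChange, "hr_change")
  if (!is.null(dirSummary)) emit(dirSummary$cells, "direction_summary")

  structure(list(blockTable = blockTable, fitGlmm = fitG, fitGam = fitS,
                 comparison = comparison, contrasts = contrasts,
                 iccAll = iccAll, iccPairwise = iccPair,
                 hrChange = hrChange, directionSummary = dirSummary,
                 log = log),
            class = "HbcPipelineResult")
}

#' @method print HbcPipelineResult
#' @export
print.HbcPipelineResult <- function(x, ...) {
  cat("HbcPipelineResult:",
      if (!is.null(x$blockTable)) paste0(nrow(x$blockTable), " block rows")
      else "no block table", "|",
      length(x$log), "logged error(s)\n")
  invisible(x)
}
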