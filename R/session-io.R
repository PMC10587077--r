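# Session data model, archive I/O, validation, configuration.

TASK_TYPES <- c("manual", "baseline", "bmi")

TRIAL_COLUMNS <- c("target_direction", "go_cue_time", "target_acquired_time",
                   "success", "self_initiated", "attempt_index")

#' Construct an analysis configuration
#'
#' @param bands named list of \code{c(low, high)} Hz pairs; defaults to the
#'   five canonical bands theta (4--8), alpha (8--13), beta (13--35), gamma
#'   (35--75) and highgamma (75--150).
#' @param windowWidth event window width in seconds.
#' @param cvFolds cross-validation folds.
#' @param nPermutations label shuffles for chance calibration.
#' @param arOrder AR order for Granger causality.
#' @param alpha significance level.
#' @param seed master seed.
#' @return a [StudyConfig-class] object.
#' @examples
#' cfg <- studyConfig(seed = 1)
#' names(cfg@bands)
#' @export
studyConfig <- function(bands = defaultBands(), windowWidth = 0.5,
                        cvFolds = 10L, nPermutations = 1000L,
                        arOrder = 13L, alpha = 0.05, seed = 1L) {
  new("StudyConfig", bands = bands, windowWidth = windowWidth,
      cvFolds = as.integer(cvFolds),
      nPermutations = as.integer(nPermutations),
      arOrder = as.integer(arOrder), alpha = alpha,
      seed = as.integer(seed))
}

#' @rdname studyConfig
#' @export
defaultBands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 35),
       gamma = c(35, 75), highgamma = c(75, 150))
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file may set any of the [studyConfig()] arguments; `bands` is a
#' mapping from band name to a two-element `[low, high]` list. Unset fields
#' keep their defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [StudyConfig-class] object.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required to read %s", path)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$bands))
    args$bands <- lapply(raw$bands, function(b) as.numeric(unlist(b)))
  for (f in c("windowWidth", "cvFolds", "nPermutations", "arOrder",
              "alpha", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(studyConfig, args)
}

#' Construct a session record
#'
#' @param lfp channels x samples numeric matrix.
#' @param samplingRate Hz.
#' @param channelMap data.frame with columns `channel`, `roi`,
#'   `direct_unit`.
#' @param taskType `"manual"`, `"baseline"` or `"bmi"`.
#' @param dayIndex non-negative integer.
#' @param trials trial table (see [SessionRecord-class]); defaults to an
#'   empty table.
#' @param sessionId identifier; defaults to `"<taskType>-day<dayIndex>"`.
#' @param validate check invariants and fail on violation (default TRUE).
#' @return a [SessionRecord-class].
#' @export
sessionRecord <- function(lfp, samplingRate, channelMap, taskType, dayIndex,
                          trials = emptyTrials(), sessionId = NULL,
                          validate = TRUE) {
  if (is.null(sessionId))
    sessionId <- sprintf("%s-day%03d", taskType, as.integer(dayIndex))
  rec <- new("SessionRecord", lfp = lfp, samplingRate = samplingRate,
             channelMap = channelMap, taskType = taskType,
             dayIndex = as.integer(dayIndex), trials = trials,
             sessionId = sessionId)
  if (validate) {
    v <- validateSession(rec)
    if (length(v))
      stopf("invalid SessionRecord:\n  %s", paste(v, collapse = "\n  "))
  }
  rec
}

#' @rdname sessionRecord
#' @export
emptyTrials <- function() {
  data.frame(target_direction = integer(), go_cue_time = numeric(),
             target_acquired_time = numeric(), success = logical(),
             self_initiated = logical(), attempt_index = integer())
}

#' Validate a session record
#'
#' Pure function returning a character vector of invariant violations, one
#' per violated rule, each naming the offending field. An empty vector means
#' the record is valid. Never throws.
#'
#' @param record a [SessionRecord-class] (validity is not re-entered).
#' @return character vector of violation descriptions (possibly empty).
#' @export
validateSession <- function(record) {
  v <- character()
  lfp <- record@lfp
  if (!is.numeric(lfp)) v <- c(v, "lfp: must be a numeric matrix")
  if (length(record@samplingRate) != 1L || is.na(record@samplingRate) ||
      record@samplingRate <= 0)
    return(c(v, "samplingRate: must be a positive scalar"))
  cm <- record@channelMap
  need <- c("channel", "roi", "direct_unit")
  miss <- setdiff(need, names(cm))
  if (length(miss))
    return(c(v, sprintf("channelMap: missing column(s) %s",
                        paste(miss, collapse = ", "))))
  if (nrow(cm) != nrow(lfp))
    v <- c(v, sprintf("channelMap: %d rows but lfp has %d channels",
                      nrow(cm), nrow(lfp)))
  bad_roi <- !cm$roi %in% roi_levels()
  if (any(bad_roi))
    v <- c(v, sprintf(
      "channelMap: roi label(s) outside {M1, DLPFC, Cd} on channel(s) %s: %s",
      paste(cm$channel[bad_roi], collapse = ", "),
      paste(unique(cm$roi[bad_roi]), collapse = ", ")))
  bad_direct <- cm$direct_unit & cm$roi != "M1"
  if (any(bad_direct))
    v <- c(v, sprintf(
      "channelMap: direct_unit = TRUE on non-M1 channel(s) %s",
      paste(cm$channel[bad_direct], collapse = ", ")))
  if (length(record@taskType) != 1L || !record@taskType %in% TASK_TYPES)
    v <- c(v, "taskType: must be one of manual, baseline, bmi")
  if (is.na(record@dayIndex) || record@dayIndex < 0L)
    v <- c(v, "dayIndex: must be a non-negative integer")

  tr <- record@trials
  miss <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(miss))
    return(c(v, sprintf("trials: missing column(s) %s",
                        paste(miss, collapse = ", "))))
  if (identical(record@taskType, "baseline") && nrow(tr) > 0)
    v <- c(v, "trials: baseline sessions must have an empty trial table")
  if (nrow(tr) > 0) {
    dur <- ncol(lfp) / record@samplingRate
    if (any(tr$target_direction < 0 | tr$target_direction > 7))
      v <- c(v, "trials: target_direction must be in 0..7")
    times <- c(tr$go_cue_time, tr$target_acquired_time[!is.na(tr$target_acquired_time)])
    if (any(times < 0 | times >= dur))
      v <- c(v, sprintf(
        "trials: event time(s) outside [0, %.3f) (session duration)", dur))
    bad <- tr$success & (is.na(tr$target_acquired_time) |
                           tr$target_acquired_time <= tr$go_cue_time)
    if (any(bad))
      v <- c(v, sprintf(
        "trials: success=TRUE requires target_acquired_time > go_cue_time (row %s)",
        paste(which(bad), collapse = ", ")))
    if (any(tr$attempt_index < 1 | tr$attempt_index > 10))
      v <- c(v, "trials: attempt_index must be in 1..10")
    if (is.unsorted(tr$go_cue_time))
      v <- c(v, "trials: must be ordered by go_cue_time")
    # pairwise interval overlap; one violation per overlapping pair
    lo <- tr$go_cue_time
    hi <- ifelse(is.na(tr$target_acquired_time), tr$go_cue_time,
                 tr$target_acquired_time)
    n <- nrow(tr)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (lo[j] < hi[i] && lo[i] < hi[j])
          v <- c(v, sprintf("trials: rows %d and %d overlap in time", i, j))
      }
    }
  }
  v
}

# ---------------------------------------------------------------------------
# Archive I/O
#
# One session is one unit of analysis, stored as one directory container:
#   <path>/meta.json         session id, task type, day, sampling rate, dims
#   <path>/channel_map.tsv   channel, roi, direct_unit
#   <path>/trials.tsv        trial table, times printed with %.17g
#   <path>/lfp.bin           float64 little-endian, channel index fastest
# Numeric payloads roundtrip bit-identically.
# ---------------------------------------------------------------------------

#' Write a session archive
#'
#' Serializes a validated [SessionRecord-class] to a directory container
#' (see the package README for the layout). Numeric payloads roundtrip
#' bit-identically through [readSession()]; writing the same record twice
#' produces byte-identical payload files.
#'
#' @param record a valid [SessionRecord-class].
#' @param path target directory (created; must not be an existing file).
#' @return `path`, invisibly.
#' @export
writeSession <- function(record, path) {
  v <- validateSession(record)
  if (length(v))
    stopf("refusing to write invalid record:\n  %s",
          paste(v, collapse = "\n  "))
  if (file.exists(path) && !dir.exists(path))
    stopf("cannot write session archive: '%s' exists and is not a directory",
          path)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stopf("cannot create session archive directory '%s'", path)

  meta <- list(session_id = record@sessionId,
               task_type = record@taskType,
               day_index = record@dayIndex,
               sampling_rate_hz = record@samplingRate,
               n_channels = nrow(record@lfp),
               n_samples = ncol(record@lfp),
               lfp_storage = "float64-le, channel-fastest")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "meta.json"))

  cm <- record@channelMap
  writeLines(c("channel\troi\tdirect_unit",
               sprintf("%s\t%s\t%s", cm$channel, cm$roi,
                       ifelse(cm$direct_unit, "TRUE", "FALSE"))),
             file.path(path, "channel_map.tsv"))

  tr <- record@trials
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  writeLines(c(paste(TRIAL_COLUMNS, collapse = "\t"),
               if (nrow(tr)) sprintf("%d\t%s\t%s\t%s\t%s\t%d",
                 tr$target_direction, num(tr$go_cue_time),
                 num(tr$target_acquired_time),
                 ifelse(tr$success, "TRUE", "FALSE"),
                 ifelse(tr$self_initiated, "TRUE", "FALSE"),
                 tr$attempt_index)),
             file.path(path, "trials.tsv"))

  con <- file(file.path(path, "lfp.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(record@lfp), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a session archive
#'
#' Inverse of [writeSession()]; the returned record passes
#' [validateSession()] and equals the written record field by field
#' (numeric fields bit-identical).
#'
#' @param path archive directory written by [writeSession()].
#' @return a [SessionRecord-class].
#' @export
readSession <- function(path) {
  if (!dir.exists(path)) stopf("session archive not found: %s", path)
  metafile <- file.path(path, "meta.json")
  if (!file.exists(metafile)) stopf("archive missing meta.json: %s", path)
  meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
  for (f in c("session_id", "task_type", "day_index", "sampling_rate_hz",
              "n_channels", "n_samples"))
    if (is.null(meta[[f]]))
      stopf("archive schema error: meta.json missing required field '%s'", f)

  cm <- utils::read.delim(file.path(path, "channel_map.tsv"),
                          colClasses = c("character", "character", "logical"))
  for (f in c("channel", "roi", "direct_unit"))
    if (is.null(cm[[f]]))
      stopf("archive schema error: channel_map.tsv missing column '%s'", f)

  tr <- utils::read.delim(file.path(path, "trials.tsv"),
                          colClasses = c("integer", "numeric", "numeric",
                                         "logical", "logical", "integer"))
  con <- file(file.path(path, "lfp.bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n)
    stopf("archive corrupt: lfp.bin holds %d values, expected %d",
          length(x), n)
  lfp <- matrix(x, nrow = meta$n_channels, ncol = meta$n_samples)
  rownames(lfp) <- cm$channel
  sessionRecord(lfp = lfp, samplingRate = as.numeric(meta$sampling_rate_hz),
                channelMap = cm, taskType = meta$task_type,
                dayIndex = meta$day_index, trials = tr,
                sessionId = meta$session_id, validate = TRUE)
}

#' Load a complete recording day
#'
#' A day is the triple (manual, baseline, bmi) of sessions sharing a day
#' index; common median referencing and Granger-causality normalization are
#' defined per day, so incomplete days are refused.
#'
#' @param dir directory containing session archives (subdirectories).
#' @param dayIndex the day to assemble.
#' @return named list with elements `manual`, `baseline`, `bmi`.
#' @export
loadDay <- function(dir, dayIndex) {
  dayIndex <- as.integer(dayIndex)
  paths <- list.dirs(dir, recursive = FALSE)
  paths <- paths[file.exists(file.path(paths, "meta.json"))]
  out <- list()
  for (p in paths) {
    meta <- jsonlite::read_json(file.path(p, "meta.json"),
                                simplifyVector = TRUE)
    if (identical(as.integer(meta$day_index), dayIndex))
      out[[meta$task_type]] <- readSession(p)
  }
  miss <- setdiff(TASK_TYPES, names(out))
  if (length(miss))
    stopf("day %d is incomplete: missing %s session(s)",
          dayIndex, paste(miss, collapse = ", "))
  out[TASK_TYPES]
}
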