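#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------------------
# StudyConfig
# ---------------------------------------------------------------------------

#' Analysis configuration
#'
#' Holds the tunable parameters of the analysis pipeline: the frequency band
#' definitions, the event-window width, cross-validation and permutation
#' settings, the autoregressive model order used for Granger causality, the
#' significance level, and the master seed.
#'
#' The default bands are the five canonical LFP bands: theta (4--8 Hz),
#' alpha (8--13 Hz), beta (13--35 Hz), gamma (35--75 Hz) and highgamma
#' (75--150 Hz). Band intervals are half-open \code{[low, high)} so adjacent
#' bands never share a frequency bin.
#'
#' @slot bands named list of two-element numeric vectors \code{c(low, high)},
#'   in Hz.
#' @slot windowWidth event window width in seconds (default 0.5).
#' @slot cvFolds number of cross-validation folds (default 10).
#' @slot nPermutations label permutations for chance calibration
#'   (default 1000).
#' @slot arOrder autoregressive order for Granger causality (default 13).
#' @slot alpha significance level before Bonferroni correction
#'   (default 0.05).
#' @slot seed master seed for stochastic steps.
#'
#' @seealso [studyConfig()]
#' @export
setClass("StudyConfig",
  slots = c(
    bands = "list",
    windowWidth = "numeric",
    cvFolds = "integer",
    nPermutations = "integer",
    arOrder = "integer",
    alpha = "numeric",
    seed = "integer"
  )
)

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (length(object@bands) == 0L)
    msg <- c(msg, "bands must be non-empty")
  for (nm in names(object@bands)) {
    b <- object@bands[[nm]]
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2])
      msg <- c(msg, sprintf("band '%s' must be c(low, high) with low < high",
                            nm))
  }
  if (object@windowWidth <= 0) msg <- c(msg, "windowWidth must be positive")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (object@arOrder < 1L) msg <- c(msg, "arOrder must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SessionRecord
# ---------------------------------------------------------------------------

#' One recording session
#'
#' Container for a single session: the LFP matrix (channels x samples), the
#' channel-to-region map, the trial table, the task type and the day index.
#' A recording day consists of three sessions sharing a \code{dayIndex}:
#' one under manual control, one baseline rest period, and one under BMI
#' control.
#'
#' Time is measured in seconds from session start; sample indexing is
#' 0-based and analysis windows are half-open \code{[t, t + w)}.
#'
#' @slot lfp numeric matrix, channels x samples.
#' @slot samplingRate sampling rate in Hz (1000 after conditioning).
#' @slot channelMap data.frame with columns \code{channel} (character id),
#'   \code{roi} (one of \code{"M1"}, \code{"DLPFC"}, \code{"Cd"}) and
#'   \code{direct_unit} (logical; may be TRUE only for M1 channels, marking
#'   channels that recorded units driving the BMI decoder).
#' @slot taskType one of \code{"manual"}, \code{"baseline"}, \code{"bmi"}.
#' @slot dayIndex non-negative integer day label.
#' @slot trials data.frame of trial events (empty for baseline sessions)
#'   with columns \code{target_direction} (0--7; angle = direction x 45
#'   degrees), \code{go_cue_time}, \code{target_acquired_time} (NA when not
#'   acquired), \code{success}, \code{self_initiated}, \code{attempt_index}.
#' @slot sessionId character identifier.
#'
#' @seealso [sessionRecord()], [validateSession()], [readSession()]
#' @export
setClass("SessionRecord",
  slots = c(
    lfp = "matrix",
    samplingRate = "numeric",
    channelMap = "data.frame",
    taskType = "character",
    dayIndex = "integer",
    trials = "data.frame",
    sessionId = "character"
  )
)

setValidity("SessionRecord", function(object) {
  v <- validateSession(object)
  if (length(v)) v else TRUE
})

# ---------------------------------------------------------------------------
# EpochSet
# ---------------------------------------------------------------------------

#' Event-locked signal epochs
#'
#' Fixed-width multichannel signal segments cut around task events (go cue,
#' target acquisition) or sampled from the baseline rest period, together
#' with per-epoch labels.
#'
#' @slot data numeric array, channels x samples x epochs.
#' @slot info data.frame, one row per epoch: \code{task_type}, \code{event}
#'   (\code{"go_cue"}, \code{"target_acq"} or \code{"baseline"}),
#'   \code{day_index}, \code{start_time} (s), \code{trial} (row index into
#'   the source session's trial table, NA for baseline windows) and
#'   \code{target_direction} (NA for baseline windows).
#' @slot samplingRate Hz.
#' @slot windowWidth seconds.
#' @slot channelMap channel map inherited from the source session.
#' @export
setClass("EpochSet",
  slots = c(
    data = "array",
    info = "data.frame",
    samplingRate = "numeric",
    windowWidth = "numeric",
    channelMap = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (channels x samples x epochs)")
  else {
    if (nrow(object@info) != d[3])
      msg <- c(msg, "info rows must match epoch count")
    if (nrow(object@channelMap) != d[1])
      msg <- c(msg, "channelMap rows must match channel count")
  }
  need <- c("task_type", "event", "day_index", "start_time")
  miss <- setdiff(need, names(object@info))
  if (length(miss))
    msg <- c(msg, paste("info missing columns:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# BandPowerTable
# ---------------------------------------------------------------------------

#' Band-power feature table
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"power"} holds one
#' row per (ROI, band) feature and one column per epoch; \code{colData}
#' carries the epoch labels (task type, event, day, target direction).
#' Feature rows are named \code{"<roi>.<band>"}. Powers are band-integrated
#' PSD values (signal-units squared) and are non-negative; after
#' [normalizeToTotal()] they are fractions of each ROI's total power.
#'
#' @seealso [buildFeatureTable()], [welchBandPower()]
#' @export
setClass("BandPowerTable", contains = "SummarizedExperiment")

setValidity("BandPowerTable", function(object) {
  msg <- character()
  if (!"power" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'power' is required")
  else if (any(SummarizedExperiment::assay(object, "power") < 0))
    msg <- c(msg, "band powers must be non-negative")
  if (is.null(rownames(object)) || !all(grepl("\\.", rownames(object))))
    msg <- c(msg, "feature rows must be named '<roi>.<band>'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ClassifierReport
# ---------------------------------------------------------------------------

#' Cross-validated classifier evaluation
#'
#' Result of a stratified k-fold evaluation of a Gaussian discriminant
#' classifier (QDA or LDA), optionally with a shuffled-label permutation
#' null.
#'
#' @slot modelKind \code{"qda"} or \code{"lda"}.
#' @slot classes class labels in fixed order.
#' @slot foldAccuracies one accuracy per fold.
#' @slot meanAccuracy mean of fold accuracies.
#' @slot confusion row-normalized confusion matrix over pooled held-out
#'   predictions (rows = true class).
#' @slot nullAccuracies permutation-null accuracies (may be empty).
#' @slot pVsChance empirical permutation p-value (NA when no null was run).
#' @slot featureSpec list describing the features used (ROIs, bands, event).
#' @slot dayIndex day the report belongs to (NA_integer_ when pooled).
#' @export
setClass("ClassifierReport",
  slots = c(
    modelKind = "character",
    classes = "character",
    foldAccuracies = "numeric",
    meanAccuracy = "numeric",
    confusion = "matrix",
    nullAccuracies = "numeric",
    pVsChance = "numeric",
    featureSpec = "list",
    dayIndex = "integer"
  )
)

setValidity("ClassifierReport", function(object) {
  msg <- character()
  if (!object@modelKind %in% c("qda", "lda"))
    msg <- c(msg, "modelKind must be 'qda' or 'lda'")
  if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  cm <- object@confusion
  if (nrow(cm) > 0) {
    rs <- rowSums(cm)
    ok <- abs(rs - 1) < 1e-12 | rs == 0   # all-zero rows: class absent in test
    if (!all(ok))
      msg <- c(msg, "confusion rows must sum to 1 (or 0 for absent classes)")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GCNetwork
# ---------------------------------------------------------------------------

#' Directed Granger-causality network summary
#'
#' Per (day, ordered ROI pair, task type, event): mean Granger causality
#' over trial segments, artifact-null comparison, baseline-normalized values
#' and net normalized values per unordered pair, with directionality tests
#' across days.
#'
#' @slot estimates data.frame: \code{day_index}, \code{source},
#'   \code{target}, \code{task_type}, \code{event}, \code{mean_g},
#'   \code{n_segments}, \code{null_mean}, \code{p_vs_null}.
#' @slot normalized data.frame: per (day, direction, task in bmi/manual,
#'   event) \code{normalized_g} = (G_task - G_baseline) / G_baseline.
#' @slot net data.frame: per (day, ordered direction, task, event)
#'   \code{net_g} = normalized_g(a to b) - normalized_g(b to a);
#'   antisymmetric under direction swap.
#' @slot directed data.frame: across-day one-sample t-test of net values
#'   against zero with Bonferroni-corrected p and a significance flag.
#' @slot arOrder AR order used.
#' @export
setClass("GCNetwork",
  slots = c(
    estimates = "data.frame",
    normalized = "data.frame",
    net = "data.frame",
    directed = "data.frame",
    arOrder = "integer"
  )
)

# ---------------------------------------------------------------------------
# KalmanDecoder
# ---------------------------------------------------------------------------

#' Velocity Kalman-filter decoder
#'
#' Linear-Gaussian state-space decoder mapping binned spike counts to cursor
#' kinematics. The state is \code{[px, py, vx, vy, 1]}; the observation
#' model ties spike counts to the velocity (and constant) components only,
#' so the position columns of \code{C} are zero ("velocity KF").
#'
#' State-transition model: \code{x[t+1] = A x[t] + w}, \code{w ~ N(0, W)}.
#' Observation model: \code{y[t+1] = C x[t] + q}, \code{q ~ N(0, Q)}.
#'
#' @slot A 5 x 5 state-transition matrix; the constant row preserves 1.
#' @slot W 5 x 5 symmetric positive-semidefinite state-noise covariance.
#' @slot C units x 5 observation matrix.
#' @slot Q units x units symmetric positive-semidefinite observation-noise
#'   covariance.
#' @slot binWidth bin width in seconds (0.1).
#' @slot units character ids of the direct units.
#' @export
setClass("KalmanDecoder",
  slots = c(
    A = "matrix", W = "matrix", C = "matrix", Q = "matrix",
    binWidth = "numeric", units = "character"
  )
)

setValidity("KalmanDecoder", function(object) {
  msg <- character()
  d <- nrow(object@A)
  if (ncol(object@A) != d) msg <- c(msg, "A must be square")
  if (!all(dim(object@W) == d)) msg <- c(msg, "W must match A")
  if (ncol(object@C) != d) msg <- c(msg, "C column count must match state dim")
  u <- nrow(object@C)
  if (!all(dim(object@Q) == u)) msg <- c(msg, "Q must be units x units")
  if (max(abs(object@W - t(object@W))) > 1e-8)
    msg <- c(msg, "W must be symmetric")
  if (max(abs(object@Q - t(object@Q))) > 1e-8)
    msg <- c(msg, "Q must be symmetric")
  if (min(eigen(object@W, symmetric = TRUE, only.values = TRUE)$values)
      < -1e-8)
    msg <- c(msg, "W must be positive semidefinite")
  if (min(eigen(object@Q, symmetric = TRUE, only.values = TRUE)$values)
      < -1e-8)
    msg <- c(msg, "Q must be positive semidefinite")
  # constant-state row of A preserves the 1
  if (max(abs(object@A[d, ] - c(rep(0, d - 1), 1))) > 1e-8)
    msg <- c(msg, "constant-state row of A must be (0, ..., 0, 1)")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TaskParams
# ---------------------------------------------------------------------------

#' Center-out task parameters
#'
#' Geometry and timing of the self-initiated eight-target center-out task:
#' a trial is initiated by moving the cursor to the center target, requires
#' a short center hold, a reach to the cued peripheral target within the
#' timeout, and a brief target hold. Failed targets are repeated up to
#' \code{maxRepeats} times before a new target is presented; directions are
#' pseudo-randomized in blocks of eight.
#'
#' @slot nTargets number of peripheral targets (8).
#' @slot targetRadius,cursorRadius,reachDistance workspace units.
#' @slot centerHold,targetHold,reachTimeout seconds.
#' @slot maxRepeats maximum presentations of a failed target (10).
#' @export
setClass("TaskParams",
  slots = c(
    nTargets = "integer",
    targetRadius = "numeric",
    cursorRadius = "numeric",
    reachDistance = "numeric",
    centerHold = "numeric",
    targetHold = "numeric",
    reachTimeout = "numeric",
    maxRepeats = "integer"
  )
)

setValidity("TaskParams", function(object) {
  msg <- character()
  if (object@nTargets != 8L) msg <- c(msg, "nTargets must be 8")
  for (s in c("targetRadius", "cursorRadius", "reachDistance",
              "centerHold", "targetHold", "reachTimeout"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (object@maxRepeats < 1L) msg <- c(msg, "maxRepeats must be >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SimStudyConfig
# ---------------------------------------------------------------------------

#' Synthetic study configuration
#'
#' Parameters of the multi-day synthetic study generator: region-level
#' vector-autoregressive (VAR) latent dynamics with known directed coupling,
#' channel embedding with task-dependent band-limited oscillations,
#' direction-dependent event modulation, trial streams and behavior.
#'
#' @slot nDays number of recording days; each day yields a manual, a
#'   baseline and a BMI session.
#' @slot channelsPerRoi named integer vector (M1, DLPFC, Cd).
#' @slot nDirectM1 number of M1 channels flagged as recording direct units.
#' @slot selfCoef autoregressive self-coefficients shared by the three
#'   latent region signals; their companion spectral radius (with coupling)
#'   must be < 1.
#' @slot coupling data.frame with columns \code{source}, \code{target},
#'   \code{gain}, \code{lag} (samples); directed dependence exists from a to
#'   b iff gain(a to b) > 0. May have zero rows.
#' @slot bandProfile data.frame (\code{task_type}, \code{roi}, \code{band},
#'   \code{amplitude}): amplitude of the band-centered oscillation added to
#'   each channel, per task type.
#' @slot directionEffect data.frame (\code{roi}, \code{band}, \code{depth},
#'   \code{preferred}): multiplicative cosine modulation of the band
#'   oscillation inside the event windows, by target direction.
#' @slot noiseSd per-channel white-noise SD.
#' @slot commonMode numeric \code{c(freq_hz, amplitude)}; an oscillatory
#'   common-mode artifact added identically to all channels (amplitude 0
#'   disables it). Used to exercise the referencing step.
#' @slot trialsPerSession trials per task session.
#' @slot baselineDuration baseline session length in seconds (default 240,
#'   the four-minute rest period).
#' @slot behavior list of behavioral generator parameters (success
#'   probabilities and acquisition-time models per control type; see
#'   [simStudyConfig()]).
#' @slot seed master seed; each session derives its own stream from
#'   (seed, day, task type).
#' @export
setClass("SimStudyConfig",
  slots = c(
    nDays = "integer",
    channelsPerRoi = "integer",
    nDirectM1 = "integer",
    selfCoef = "numeric",
    coupling = "data.frame",
    bandProfile = "data.frame",
    directionEffect = "data.frame",
    noiseSd = "numeric",
    commonMode = "numeric",
    trialsPerSession = "integer",
    baselineDuration = "numeric",
    behavior = "list",
    seed = "integer"
  )
)

setValidity("SimStudyConfig", function(object) {
  msg <- character()
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (!all(roi_levels() %in% names(object@channelsPerRoi)))
    msg <- c(msg, "channelsPerRoi must name M1, DLPFC and Cd")
  if (any(object@channelsPerRoi < 1L))
    msg <- c(msg, "channelsPerRoi must be >= 1")
  if (object@nDirectM1 < 1L ||
      object@nDirectM1 > object@channelsPerRoi[["M1"]])
    msg <- c(msg, "nDirectM1 must be in 1..channelsPerRoi['M1']")
  if (nrow(object@coupling) > 0) {
    gc_cols <- intersect(c("gain_manual", "gain_baseline", "gain_bmi"),
                         names(object@coupling))
    if (length(gc_cols) != 3L)
      msg <- c(msg, "coupling must carry gain_manual/gain_baseline/gain_bmi")
    else if (any(as.matrix(object@coupling[gc_cols]) < 0))
      msg <- c(msg, "coupling gains must be >= 0")
    if (any(object@coupling$lag < 1)) msg <- c(msg, "coupling lags must be >= 1")
  }
  rad <- var_spectral_radius(object)
  if (!is.na(rad) && rad >= 1)
    msg <- c(msg, sprintf(
      "latent VAR is non-stationary (companion spectral radius %.3f >= 1)",
      rad))
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@trialsPerSession < 1L)
    msg <- c(msg, "trialsPerSession must be >= 1")
  if (object@baselineDuration <= 0)
    msg <- c(msg, "baselineDuration must be positive")
  if (length(msg)) msg else TRUE
})
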