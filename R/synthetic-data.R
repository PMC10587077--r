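# Multi-day synthetic study generator with known ground truth.
#
# Architecture: a region-level VAR(p) drives one latent series per ROI
# (M1, DLPFC, Cd) at 1 kHz; channels are the ROI latent plus band-centered
# oscillations (amplitude set per task type, random phase per channel) plus
# independent white noise, optionally plus a common-mode artifact shared by
# every channel. Directed ground-truth coupling therefore lives entirely in
# the latent layer, while task-type and target-direction structure lives in
# the oscillation amplitudes.

BAND_CENTER <- function(band, bands = defaultBands()) {
  b <- bands[[band]]
  sqrt(b[1] * b[2])   # geometric mean of the band edges
}

#' Construct a synthetic study configuration
#'
#' Defaults describe the emulated study: 12 recording days, three sessions
#' per day (manual, four-minute baseline, BMI), 120 trials per task session
#' (15 per direction), a DLPFC-to-M1 latent coupling present during both
#' control types and a Cd-to-M1 coupling elevated only during BMI control,
#' theta elevated and beta suppressed during control relative to baseline,
#' an extra DLPFC modulation at the go cue and M1 modulation at target
#' acquisition distinguishing the two control types, and
#' direction-dependent M1 beta/gamma modulation inside the event windows.
#'
#' @param nDays,channelsPerRoi,nDirectM1,selfCoef,noiseSd,trialsPerSession,baselineDuration,seed
#'   see [SimStudyConfig-class].
#' @param coupling data.frame with columns `source`, `target`, `lag` and
#'   either a single `gain` column (applied to every task type) or
#'   per-task columns `gain_manual`, `gain_baseline`, `gain_bmi`.
#' @param bandProfile data.frame (`task_type`, `roi`, `band`, `amplitude`);
#'   missing combinations default to amplitude 1.
#' @param eventEffect data.frame (`task_type`, `roi`, `band`, `event`,
#'   `factor`): extra multiplicative amplitude factor applied inside the
#'   matching event windows only.
#' @param directionEffect data.frame (`roi`, `band`, `depth`, `preferred`):
#'   inside event windows the band amplitude is multiplied by
#'   `1 + depth * cos(angle - preferred)` where `angle` is the trial's
#'   target angle (direction x 45 degrees).
#' @param commonMode `c(freq_hz, amplitude)` common-mode artifact
#'   (amplitude 0 disables).
#' @param behavior list of behavioral parameters; unset entries keep
#'   defaults (manual success 0.92 and ~0.7 s reaches; BMI success and
#'   acquisition time improving across days from 0.60 and 2.2 s).
#' @return a validated [SimStudyConfig-class].
#' @export
simStudyConfig <- function(nDays = 12L,
                           channelsPerRoi = c(M1 = 8L, DLPFC = 6L, Cd = 4L),
                           nDirectM1 = 4L,
                           selfCoef = c(0.35, 0.2),
                           coupling = defaultCoupling(),
                           bandProfile = defaultBandProfile(),
                           eventEffect = defaultEventEffect(),
                           directionEffect = defaultDirectionEffect(),
                           noiseSd = 1,
                           commonMode = c(60, 0),
                           trialsPerSession = 120L,
                           baselineDuration = 240,
                           behavior = list(),
                           seed = 1L) {
  if (nrow(coupling) > 0 && !"gain_bmi" %in% names(coupling)) {
    if (!"gain" %in% names(coupling))
      stopf("coupling needs a 'gain' column or per-task gain columns")
    coupling$gain_manual <- coupling$gain
    coupling$gain_baseline <- coupling$gain
    coupling$gain_bmi <- coupling$gain
    coupling$gain <- NULL
  }
  if (nrow(coupling) > 0) {
    bad <- !coupling$source %in% roi_levels() |
      !coupling$target %in% roi_levels()
    if (any(bad)) stopf("coupling: unknown ROI in row(s) %s",
                        paste(which(bad), collapse = ", "))
  }
  beh <- list(manual_success = 0.92, manual_acq_mean = 0.7,
              manual_acq_sd = 0.08,
              bmi_success_base = 0.60, bmi_success_gain = 0.02,
              bmi_success_max = 0.95,
              bmi_acq_base = 2.2, bmi_acq_slope = -0.04, bmi_acq_sd = 0.35,
              acq_min = 0.7, iti = 0.8, fail_timeout = 2.0,
              self_init_prob = 1.0)
  beh[names(behavior)] <- behavior
  new("SimStudyConfig",
      nDays = as.integer(nDays),
      channelsPerRoi = vapply(channelsPerRoi, as.integer, integer(1)),
      nDirectM1 = as.integer(nDirectM1),
      selfCoef = selfCoef, coupling = coupling,
      bandProfile = bandProfile, behavior = beh,
      directionEffect = directionEffect, noiseSd = noiseSd,
      commonMode = commonMode,
      trialsPerSession = as.integer(trialsPerSession),
      baselineDuration = baselineDuration,
      seed = as.integer(seed)) -> cfg
  # eventEffect is carried inside behavior to keep the slot count stable
  cfg@behavior$event_effect <- eventEffect
  validObject(cfg)
  cfg
}

#' @rdname simStudyConfig
#' @export
defaultCoupling <- function() {
  data.frame(source = c("DLPFC", "Cd"), target = c("M1", "M1"),
             lag = c(8L, 12L),
             gain_manual = c(0.30, 0.10),
             gain_baseline = c(0.15, 0.10),
             gain_bmi = c(0.30, 0.30))
}

#' @rdname simStudyConfig
#' @export
defaultBandProfile <- function() {
  base <- expand.grid(task_type = TASK_TYPES, roi = roi_levels(),
                      band = names(defaultBands()),
                      stringsAsFactors = FALSE)
  amp <- c(baseline = NA_real_)
  # theta up and beta down during control vs. rest; mild bmi/manual contrast
  lut <- rbind(
    baseline = c(theta = 1.0, alpha = 0.80, beta = 1.6, gamma = 0.60,
                 highgamma = 0.40),
    manual   = c(theta = 1.6, alpha = 0.80, beta = 1.0, gamma = 0.70,
                 highgamma = 0.45),
    bmi      = c(theta = 1.8, alpha = 0.85, beta = 0.9, gamma = 0.80,
                 highgamma = 0.50))
  base$amplitude <- mapply(function(tt, b) lut[tt, b],
                           base$task_type, base$band)
  base
}

#' @rdname simStudyConfig
#' @export
defaultEventEffect <- function() {
  data.frame(task_type = c("bmi", "bmi"),
             roi = c("DLPFC", "M1"),
             band = c("theta", "beta"),
             event = c("go_cue", "target_acq"),
             factor = c(1.35, 0.75))
}

#' @rdname simStudyConfig
#' @export
defaultDirectionEffect <- function() {
  data.frame(roi = c("M1", "M1", "DLPFC"),
             band = c("beta", "gamma", "beta"),
             depth = c(0.5, 0.5, 0.2),
             preferred = c(0, pi / 2, 0))
}

# Companion-matrix spectral radius of the latent VAR implied by a config,
# using each coupling's largest per-task gain (worst case).
var_spectral_radius <- function(config) {
  rois <- roi_levels()
  p <- length(config@selfCoef)
  if (nrow(config@coupling) > 0)
    p <- max(p, max(config@coupling$lag))
  if (p == 0) return(NA_real_)
  A <- array(0, c(3, 3, p))
  for (k in seq_along(config@selfCoef))
    diag(A[, , k]) <- config@selfCoef[k]
  cp <- config@coupling
  if (nrow(cp) > 0 && is.null(cp$gain_bmi)) return(NA_real_)
  if (nrow(cp) > 0) for (i in seq_len(nrow(cp))) {
    g <- max(cp$gain_manual[i], cp$gain_baseline[i], cp$gain_bmi[i])
    A[match(cp$target[i], rois), match(cp$source[i], rois), cp$lag[i]] <-
      A[match(cp$target[i], rois), match(cp$source[i], rois), cp$lag[i]] + g
  }
  comp <- matrix(0, 3 * p, 3 * p)
  for (k in seq_len(p)) comp[1:3, (3 * k - 2):(3 * k)] <- A[, , k]
  if (p > 1) comp[4:(3 * p), 1:(3 * (p - 1))] <- diag(3 * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# VAR coefficient array for a given task type.
var_coefficients <- function(config, task_type) {
  rois <- roi_levels()
  p <- length(config@selfCoef)
  if (nrow(config@coupling) > 0) p <- max(p, max(config@coupling$lag))
  A <- array(0, c(3, 3, p))
  for (k in seq_along(config@selfCoef))
    diag(A[, , k]) <- config@selfCoef[k]
  cp <- config@coupling
  gcol <- paste0("gain_", task_type)
  if (nrow(cp) > 0) for (i in seq_len(nrow(cp))) {
    A[match(cp$target[i], rois), match(cp$source[i], rois), cp$lag[i]] <-
      A[match(cp$target[i], rois), match(cp$source[i], rois), cp$lag[i]] +
      cp[[gcol]][i]
  }
  A
}

#' Simulate the latent region-level VAR
#'
#' Generates the three latent ROI series at 1 kHz from the configured
#' vector autoregression. Directed dependence exists from ROI a to ROI b
#' iff the configured coupling gain a-to-b is positive for the task type.
#'
#' @param config a [SimStudyConfig-class].
#' @param duration_s duration in seconds.
#' @param taskType task type selecting the per-task coupling gains.
#' @param seed RNG seed (defaults to the config seed).
#' @return samples x 3 matrix with columns M1, DLPFC, Cd.
#' @export
simulateRoiVar <- function(config, duration_s, taskType = "baseline",
                           seed = config@seed) {
  rad <- var_spectral_radius(config)
  if (!is.na(rad) && rad >= 1)
    stopf("latent VAR is non-stationary (spectral radius %.3f >= 1)", rad)
  A <- var_coefficients(config, taskType)
  p <- dim(A)[3]
  fs <- 1000
  n <- round(duration_s * fs)
  burn <- 500L
  with_seed(seed, {
    N <- n + burn
    innov <- matrix(rnorm(N * 3), N, 3)
    rois <- roi_levels()
    sc <- config@selfCoef
    # cross-coupling edges active for this task type
    cp <- config@coupling
    gcol <- paste0("gain_", taskType)
    edges <- if (nrow(cp)) cp[cp[[gcol]] > 0, , drop = FALSE] else cp
    incoming <- function(r) if (nrow(edges))
      edges[edges$target == r, , drop = FALSE] else edges
    # topological order over the coupling graph; acyclic graphs use exact
    # recursive filtering per region (C speed), cyclic ones the full
    # sample-by-sample recursion
    done <- character(); order <- character()
    pending <- rois
    while (length(pending)) {
      ready <- pending[vapply(pending, function(r) {
        inc <- incoming(r); all(inc$source %in% done)
      }, TRUE)]
      if (!length(ready)) break
      order <- c(order, ready); done <- c(done, ready)
      pending <- setdiff(pending, ready)
    }
    if (!length(pending)) {
      X <- matrix(0, N, 3, dimnames = list(NULL, rois))
      for (r in order) {
        drive <- innov[, match(r, rois)]
        inc <- incoming(r)
        if (nrow(inc)) for (e in seq_len(nrow(inc))) {
          lag <- inc$lag[e]
          shifted <- c(rep(0, lag), X[1:(N - lag), inc$source[e]])
          drive <- drive + inc[[gcol]][e] * shifted
        }
        X[, r] <- if (any(sc != 0))
          as.vector(stats::filter(drive, sc, method = "recursive"))
        else drive
      }
    } else {
      # cyclic coupling: explicit recursion over samples
      X <- innov
      B <- matrix(0, 3, 3 * p)
      for (k in seq_len(p)) B[, (3 * k - 2):(3 * k)] <- A[, , k]
      B2 <- matrix(0, 3, 3 * p)   # reordered for column-major vec()
      for (j in 1:3) for (i in seq_len(p))
        B2[, (j - 1) * p + i] <- A[, j, p - i + 1]
      for (t in (p + 1):N) {
        past <- as.vector(X[(t - p):(t - 1), ])
        X[t, ] <- X[t, ] + B2 %*% past
      }
      colnames(X) <- rois
    }
    out <- X[(burn + 1):N, , drop = FALSE]
    colnames(out) <- roi_levels()
    out
  })
}

#' Embed latent region signals into channels
#'
#' Each channel is its region's latent series plus band-centered
#' oscillations (amplitudes from the configured band profile for the
#' session's task type, random phase per channel), independent white noise,
#' and optionally an identical common-mode artifact on all channels.
#'
#' @param latent samples x 3 latent matrix from [simulateRoiVar()].
#' @param config a [SimStudyConfig-class].
#' @param taskType task type (selects the band profile).
#' @param seed RNG seed.
#' @param envelopes optional list: `envelopes[[roi]][[band]]` is a
#'   per-sample amplitude multiplier (used for event-locked direction
#'   effects); defaults to 1 everywhere.
#' @return list with `lfp` (channels x samples) and `channelMap`.
#' @export
embedChannels <- function(latent, config, taskType, seed = config@seed,
                          envelopes = NULL) {
  fs <- 1000
  n <- nrow(latent)
  rois <- roi_levels()
  nch <- config@channelsPerRoi[rois]
  bands <- names(defaultBands())
  bp <- config@bandProfile
  tt <- seq_len(n) / fs
  with_seed(seed, {
    lfp <- matrix(0, sum(nch), n)
    channel <- character(sum(nch)); roi <- character(sum(nch))
    row <- 0L
    for (r in rois) {
      for (j in seq_len(nch[[r]])) {
        row <- row + 1L
        channel[row] <- sprintf("%s%02d", tolower(r), j)
        roi[row] <- r
        sig <- latent[, r]
        for (b in bands) {
          amp <- bp$amplitude[bp$task_type == taskType & bp$roi == r &
                                bp$band == b]
          amp <- if (length(amp)) amp[1] else 1
          if (amp <= 0) next
          env <- if (!is.null(envelopes) && !is.null(envelopes[[r]][[b]]))
            envelopes[[r]][[b]] else 1
          phase <- runif(1, 0, 2 * pi)
          # stochastic amplitude modulation (AR(1)-smoothed noise, ~2 Hz
          # bandwidth): band components are narrowband processes rather
          # than deterministic tones, so channels are not mutually
          # phase-locked
          a1 <- exp(-2 * pi * 2 / fs)
          am <- as.vector(stats::filter(rnorm(n), a1, method = "recursive"))
          am <- 1 + 0.5 * am / (sd(am) + 1e-12)
          sig <- sig + amp * env * am *
            sin(2 * pi * BAND_CENTER(b) * tt + phase)
        }
        if (config@noiseSd > 0) sig <- sig + rnorm(n, sd = config@noiseSd)
        lfp[row, ] <- sig
      }
    }
    if (config@commonMode[2] > 0)
      lfp <- sweep(lfp, 2,
                   config@commonMode[2] *
                     sin(2 * pi * config@commonMode[1] * tt), "+")
    direct <- roi == "M1" &
      ave(seq_along(roi), roi, FUN = seq_along) <= config@nDirectM1
    rownames(lfp) <- channel
    list(lfp = lfp,
         channelMap = data.frame(channel = channel, roi = roi,
                                 direct_unit = direct))
  })
}

# Pseudo-randomized target sequence: directions shuffled within blocks of 8.
block_randomized_directions <- function(n_trials) {
  n_blocks <- ceiling(n_trials / 8)
  dirs <- unlist(lapply(seq_len(n_blocks), function(i) sample(0:7)))
  dirs[seq_len(n_trials)]
}

#' Simulate one session
#'
#' Produces a [SessionRecord-class] for one (day, task type) cell of the
#' study, with trials whose events satisfy the session invariants, target
#' directions pseudo-randomized in blocks of eight, task-dependent band
#' amplitudes, event-locked direction effects, and behavior (success rates,
#' acquisition times) following the configured across-day learning model.
#' Each session draws from its own RNG stream derived from
#' (seed, day, task type), so any single session can be regenerated
#' independently.
#'
#' @param config a [SimStudyConfig-class].
#' @param dayIndex non-negative day index.
#' @param taskType `"manual"`, `"baseline"` or `"bmi"`.
#' @return list with `session` (a [SessionRecord-class]) and `truth`
#'   (per-trial directions and the injected effect tables).
#' @export
simulateSession <- function(config, dayIndex, taskType) {
  stopifnot(taskType %in% TASK_TYPES)
  fs <- 1000
  seed_s <- derive_seed(config@seed, dayIndex, taskType)
  beh <- config@behavior
  if (taskType == "baseline") {
    latent <- simulateRoiVar(config, config@baselineDuration, taskType,
                             seed = seed_s)
    emb <- embedChannels(latent, config, taskType, seed = seed_s + 1L)
    sess <- sessionRecord(emb$lfp, fs, emb$channelMap, taskType, dayIndex)
    return(list(session = sess,
                truth = list(directions = integer(), seed = seed_s)))
  }
  if (config@trialsPerSession < 8L)
    warnf("trials_per_session < 8: not every direction can appear")

  with_seed(seed_s, {
    n_tr <- config@trialsPerSession
    dirs <- block_randomized_directions(n_tr)
    if (taskType == "manual") {
      p_succ <- beh$manual_success
      acq_mu <- beh$manual_acq_mean; acq_sd <- beh$manual_acq_sd
    } else {
      p_succ <- min(beh$bmi_success_max,
                    beh$bmi_success_base + beh$bmi_success_gain * dayIndex)
      acq_mu <- max(beh$acq_min + 0.2,
                    beh$bmi_acq_base + beh$bmi_acq_slope * dayIndex)
      acq_sd <- beh$bmi_acq_sd
    }
    success <- runif(n_tr) < p_succ
    acq_time <- pmax(beh$acq_min, rnorm(n_tr, acq_mu, acq_sd))
    go <- numeric(n_tr); acq <- rep(NA_real_, n_tr)
    t <- 1.0
    for (i in seq_len(n_tr)) {
      go[i] <- t
      if (success[i]) {
        acq[i] <- go[i] + acq_time[i]
        t <- acq[i] + beh$iti
      } else t <- go[i] + beh$fail_timeout + beh$iti
    }
    duration <- t + 1.0
    trials <- data.frame(target_direction = as.integer(dirs),
                         go_cue_time = go, target_acquired_time = acq,
                         success = success,
                         self_initiated = runif(n_tr) < beh$self_init_prob,
                         attempt_index = 1L)
    n_samp <- round(duration * fs)

    # event-locked amplitude envelopes: direction tuning + event effects
    de <- config@directionEffect
    ee <- beh$event_effect
    envelopes <- NULL
    win <- round(0.5 * fs)
    set_window <- function(env, start_s, fac) {
      i0 <- floor(start_s * fs) + 1L
      i1 <- min(i0 + win - 1L, n_samp)
      env[i0:i1] <- env[i0:i1] * fac
      env
    }
    touched <- unique(rbind(
      if (nrow(de)) de[c("roi", "band")],
      if (!is.null(ee) && nrow(ee)) ee[c("roi", "band")]))
    if (!is.null(touched) && nrow(touched)) {
      envelopes <- list()
      for (k in seq_len(nrow(touched))) {
        r <- touched$roi[k]; b <- touched$band[k]
        env <- rep(1, n_samp)
        dk <- de[de$roi == r & de$band == b, , drop = FALSE]
        ek <- if (!is.null(ee))
          ee[ee$roi == r & ee$band == b & ee$task_type == taskType, ,
             drop = FALSE] else NULL
        for (i in seq_len(n_tr)) {
          ang <- dirs[i] * pi / 4
          for (ev in c("go_cue", "target_acq")) {
            start <- if (ev == "go_cue") go[i]
                     else if (success[i]) acq[i] - 0.5 else NA
            if (is.na(start)) next
            fac <- 1
            if (nrow(dk))
              fac <- fac * prod(1 + dk$depth * cos(ang - dk$preferred))
            if (!is.null(ek) && nrow(ek))
              fac <- fac * prod(ek$factor[ek$event == ev], 1)
            if (fac != 1) env <- set_window(env, start, fac)
          }
        }
        if (is.null(envelopes[[r]])) envelopes[[r]] <- list()
        envelopes[[r]][[b]] <- env
      }
    }

    latent <- simulateRoiVar(config, duration, taskType, seed = seed_s + 1L)
    emb <- embedChannels(latent, config, taskType, seed = seed_s + 2L,
                         envelopes = envelopes)
    sess <- sessionRecord(emb$lfp, fs, emb$channelMap, taskType, dayIndex,
                          trials = trials)
    list(session = sess,
         truth = list(directions = dirs, success = success,
                      envelopes_applied = !is.null(envelopes),
                      seed = seed_s))
  })
}

#' Simulate a complete multi-day study
#'
#' @param config a [SimStudyConfig-class].
#' @param days which day indices to generate (default all).
#' @return list with `days` (per day: list(manual, baseline, bmi) of
#'   [SessionRecord-class]) and `truth` (the config plus per-session truth).
#' @export
simulateStudy <- function(config, days = seq_len(config@nDays) - 1L) {
  out <- list(); truth <- list()
  for (d in days) {
    day <- list(); dt <- list()
    for (tt in TASK_TYPES) {
      sim <- simulateSession(config, d, tt)
      day[[tt]] <- sim$session
      dt[[tt]] <- sim$truth
    }
    out[[as.character(d)]] <- day
    truth[[as.character(d)]] <- dt
  }
  list(days = out, truth = list(config = config, sessions = truth))
}

#' Simulate cosine-tuned Poisson spiking
#'
#' Spike counts in `binWidth`-second bins for units with cosine velocity
#' tuning: rate (Hz) = max(0, baseline + depth * (v . u(preferred))),
#' counts ~ Poisson(rate * binWidth).
#'
#' @param tuning data.frame, one row per unit: `baseline_rate` (Hz, >= 0),
#'   `depth` (Hz per unit speed), `preferred` (radians).
#' @param velocity bins x 2 matrix of (vx, vy).
#' @param binWidth bin width in seconds (default 0.1).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return units x bins integer matrix of spike counts.
#' @export
simulateTunedUnits <- function(tuning, velocity, binWidth = 0.1,
                               seed = NULL) {
  if (any(tuning$baseline_rate < 0))
    stopf("baseline_rate must be non-negative")
  velocity <- as.matrix(velocity)
  n_bins <- nrow(velocity)
  n_units <- nrow(tuning)
  proj <- velocity %*% rbind(cos(tuning$preferred), sin(tuning$preferred))
  rate <- pmax(0, sweep(sweep(proj, 2, tuning$depth, "*"),
                        2, tuning$baseline_rate, "+"))
  with_seed(seed, {
    counts <- matrix(rpois(n_bins * n_units, lambda = rate * binWidth),
                     n_bins, n_units)
    t(counts)
  })
}

#' @rdname simulateTunedUnits
#' @param nUnits number of units to draw.
#' @param baselineRange,depthRange uniform ranges for baseline rate and
#'   modulation depth (Hz).
#' @export
randomTuning <- function(nUnits, baselineRange = c(5, 20),
                         depthRange = c(3, 10), seed = NULL) {
  with_seed(seed, data.frame(
    unit = sprintf("u%02d", seq_len(nUnits)),
    baseline_rate = runif(nUnits, baselineRange[1], baselineRange[2]),
    depth = runif(nUnits, depthRange[1], depthRange[2]),
    preferred = runif(nUnits, 0, 2 * pi)))
}
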