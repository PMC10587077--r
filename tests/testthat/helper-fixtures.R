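# Shared fixtures: tiny sessions and configs built in code.

make_channel_map <- function(n_m1 = 2L, n_dlpfc = 2L, n_cd = 1L,
                             n_direct = 1L) {
  roi <- c(rep("M1", n_m1), rep("DLPFC", n_dlpfc), rep("Cd", n_cd))
  data.frame(
    channel = sprintf("%s%02d", tolower(roi),
                      ave(seq_along(roi), roi, FUN = seq_along)),
    roi = roi,
    direct_unit = roi == "M1" &
      ave(seq_along(roi), roi, FUN = seq_along) <= n_direct)
}

make_trials <- function(go = c(1, 4, 7), acq = go + 0.9,
                        dir = seq_along(go) %% 8L,
                        success = rep(TRUE, length(go))) {
  data.frame(target_direction = as.integer(dir), go_cue_time = go,
             target_acquired_time = ifelse(success, acq, NA_real_),
             success = success,
             self_initiated = rep(TRUE, length(go)),
             attempt_index = rep(1L, length(go)))
}

make_session <- function(task = "bmi", day = 0L, duration = 10,
                         cm = make_channel_map(), trials = NULL,
                         fs = 1000, seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  lfp <- matrix(rnorm(nrow(cm) * n), nrow(cm), n,
                dimnames = list(cm$channel, NULL))
  if (is.null(trials)) {
    trials <- if (task == "baseline") emptyTrials() else {
      go <- seq(1, by = 3, length.out = max(0, floor((duration - 2) / 3) + 1))
      if (length(go)) make_trials(go = go, acq = go + 0.9,
                                  dir = seq_along(go) %% 8L)
      else emptyTrials()
    }
  }
  sessionRecord(lfp, fs, cm, task, day, trials = trials)
}

# flat-profile config variants used by recovery experiments
flat_band_profile <- function(amplitude = 0) {
  b <- defaultBandProfile()
  b$amplitude <- amplitude
  b
}

no_event_effect <- function() {
  data.frame(task_type = character(), roi = character(),
             band = character(), event = character(), factor = numeric())
}

no_direction_effect <- function() {
  data.frame(roi = character(), band = character(), depth = numeric(),
             preferred = numeric())
}

no_coupling <- function() {
  data.frame(source = character(), target = character(), lag = integer(),
             gain_manual = numeric(), gain_baseline = numeric(),
             gain_bmi = numeric())
}

# stripped configuration for connectivity ground-truth studies: one channel
# per region, no oscillations, fast trials
gc_study_config <- function(seed, nDays = 20L, gain_bmi = 0.3,
                            trials = 10L) {
  simStudyConfig(
    nDays = nDays, channelsPerRoi = c(M1 = 1L, DLPFC = 1L, Cd = 1L),
    nDirectM1 = 1L,
    coupling = if (gain_bmi > 0)
      data.frame(source = "DLPFC", target = "M1", lag = 8L,
                 gain_manual = 0, gain_baseline = 0, gain_bmi = gain_bmi)
    else no_coupling(),
    bandProfile = flat_band_profile(0), eventEffect = no_event_effect(),
    directionEffect = no_direction_effect(),
    noiseSd = 0.3, trialsPerSession = trials, baselineDuration = 20,
    behavior = list(bmi_acq_base = 1.2, bmi_acq_slope = 0),
    seed = seed)
}

# brute-force Gaussian discriminant posterior oracle (equal priors)
oracle_gaussian_predict <- function(Xtr, ytr, Xte, kind) {
  classes <- sort(unique(ytr))
  mus <- lapply(classes, function(cl) colMeans(Xtr[ytr == cl, , drop = FALSE]))
  covs <- lapply(classes, function(cl) cov(Xtr[ytr == cl, , drop = FALSE]))
  if (kind == "lda") {
    Sp <- Reduce(`+`, lapply(classes, function(cl)
      cov(Xtr[ytr == cl, , drop = FALSE]) * (sum(ytr == cl) - 1)))
    Sp <- Sp / (nrow(Xtr) - length(classes))
    covs <- rep(list(Sp), length(classes))
  }
  apply(Xte, 1, function(x) {
    lp <- vapply(seq_along(classes), function(k) {
      d <- x - mus[[k]]
      -0.5 * (determinant(covs[[k]])$modulus +
                drop(t(d) %*% solve(covs[[k]]) %*% d))
    }, numeric(1))
    classes[which.max(lp)]
  })
}
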