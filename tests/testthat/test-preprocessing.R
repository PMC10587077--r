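# Conditioning, common median referencing, epoching.

test_that("conditioning attenuates out-of-band and line components", {
  fs <- 5000
  t <- seq_len(2 * fs) / fs
  rms <- function(x) sqrt(mean(x^2))
  # trim filter edge transients before measuring
  trim <- function(x) x[500:(length(x) - 500)]

  y300 <- conditionLfp(sin(2 * pi * 300 * t), fs)
  expect_lte(rms(trim(y300[1, ])), 0.01)           # >= 40 dB above 250 Hz

  y10 <- conditionLfp(sin(2 * pi * 10 * t), fs)
  ds <- sin(2 * pi * 10 * t[seq(1, length(t), by = 5)])  # same time base
  expect_equal(rms(trim(y10[1, ])), rms(trim(ds)), tolerance = 0.01)
  # zero-phase: peak alignment preserved against the ideal downsampled tone
  expect_gt(cor(trim(y10[1, ]), trim(ds)), 0.9999)

  y60 <- conditionLfp(sin(2 * pi * 60 * t), fs)
  expect_lte(rms(trim(y60[1, ])), 0.1)             # >= 20 dB notch

  expect_equal(ncol(y10), 2000L)                   # downsampled to 1 kHz
  expect_error(conditionLfp(rnorm(100), 1500), "2000")
})

test_that("referencing implements the four-step day-level procedure", {
  cm <- make_channel_map(3, 2, 2)
  sessions <- lapply(c("manual", "baseline", "bmi"), function(tt)
    make_session(tt, duration = 4, cm = cm,
                 trials = if (tt == "baseline") emptyTrials()
                          else make_trials(go = 1, acq = 1.9),
                 seed = match(tt, c("manual", "baseline", "bmi"))))
  ref <- commonMedianReference(sessions)
  # step-4 invariant: per-channel pooled mean 0 and SD 1 across the day
  pooled <- do.call(cbind, lapply(ref, lfp))
  expect_lt(max(abs(rowMeans(pooled))), 1e-6)
  expect_equal(unname(apply(pooled, 1, sd)), rep(1, nrow(cm)),
               tolerance = 1e-6)
})

test_that("the cross-channel median of the intermediate signal is zero", {
  # re-derive steps 1-2 directly and check the median is removed exactly
  s <- make_session(duration = 2, cm = make_channel_map(3, 2, 2))
  x <- lfp(s)
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  zp <- sweep(z, 2, apply(z, 2, median), "-")
  expect_lt(max(abs(apply(zp, 2, median))), 1e-12)
})

test_that("identical channels collapse to zero within-session variance", {
  cm <- make_channel_map(2, 1, 1)
  mk <- function(seed, offset) {
    set.seed(seed)
    row <- rnorm(2000) + offset
    lfp <- matrix(rep(row, each = 4), 4, 2000,
                  dimnames = list(cm$channel, NULL))
    sessionRecord(lfp, 1000, cm, if (seed == 1) "manual" else "bmi", 0L,
                  trials = emptyTrials())
  }
  # two sessions with different means so the day-level SD is non-zero
  ref <- commonMedianReference(list(mk(1, 0), mk(2, 5)))
  expect_lt(sd(lfp(ref[[1]])[1, ]), 1e-12)
  expect_lt(sd(lfp(ref[[2]])[3, ]), 1e-12)
})

test_that("zero-variance channels are refused by name", {
  s <- make_session(duration = 1)
  s@lfp[2, ] <- 7
  expect_error(commonMedianReference(list(s)),
               channelMap(s)$channel[2])
})

test_that("injected common-mode artifacts are removed, specifics kept", {
  # channel counts matching the recorded array (27 M1 / 22 DLPFC / 8 Cd)
  cfg <- simStudyConfig(
    nDays = 1L, trialsPerSession = 8L, baselineDuration = 30,
    channelsPerRoi = c(M1 = 27L, DLPFC = 22L, Cd = 8L), nDirectM1 = 14L,
    commonMode = c(60, 2), seed = 11L)
  study <- simulateStudy(cfg, days = 0)
  ref <- commonMedianReference(study$days[["0"]])
  fs <- 1000
  for (k in seq_along(ref)) {
    raw <- lfp(study$days[["0"]][[k]]); out <- lfp(ref[[k]])
    artifact <- 2 * sin(2 * pi * 60 * (seq_len(ncol(raw)) / fs))
    specific <- sweep(raw, 2, artifact, "-")
    for (i in seq_len(nrow(raw))) {
      expect_lte(abs(cor(out[i, ], artifact)), 0.05)
      expect_gte(cor(out[i, ], specific[i, ]), 0.9)
    }
  }
})

test_that("event epochs use half-open windows with exact index arithmetic", {
  s <- make_session(duration = 12,
                    trials = make_trials(go = 10.0, acq = 11.2))
  es <- extractEventEpochs(s, "go_cue", 0.5)
  expect_identical(nEpochs(es), 1L)
  # go cue at 10.0 s -> 0-based samples [10000, 10500) -> rows 10001:10500
  expect_identical(epochData(es)[, , 1], unname(lfp(s)[, 10001:10500]))
  ea <- extractEventEpochs(s, "target_acq", 0.5)
  expect_identical(epochData(ea)[, , 1], unname(lfp(s)[, 10701:11200]))
})

test_that("failed trials are excluded and empty epoch sets are allowed", {
  tr <- make_trials(go = c(1, 3, 5), acq = c(1.9, 3.9, 5.9),
                    success = c(TRUE, FALSE, TRUE))
  s <- make_session(duration = 8, trials = tr)
  es <- extractEventEpochs(s, "go_cue")
  expect_identical(nEpochs(es), 2L)
  expect_identical(epochInfo(es)$trial, c(1L, 3L))

  s0 <- make_session(duration = 8,
                     trials = make_trials(go = 2, acq = 2.9,
                                          success = FALSE))
  expect_identical(nEpochs(extractEventEpochs(s0, "go_cue")), 0L)
})

test_that("epoching is translation-equivariant", {
  set.seed(8)
  seg <- matrix(rnorm(5 * 3000), 5, 3000)
  cm <- make_channel_map(2, 2, 1)
  mk <- function(shift_s) {
    n <- 6000
    lfp <- matrix(0, 5, n, dimnames = list(cm$channel, NULL))
    lfp[, (shift_s * 1000 + 1):(shift_s * 1000 + 3000)] <- seg
    sessionRecord(lfp, 1000, cm, "bmi", 0L,
                  trials = make_trials(go = 0.8 + shift_s,
                                       acq = 2.1 + shift_s))
  }
  e0 <- extractEventEpochs(mk(0), "go_cue")
  e2 <- extractEventEpochs(mk(2), "go_cue")
  expect_identical(epochData(e0), epochData(e2))
})

test_that("baseline windows never overlap and respect the packing bound", {
  s <- make_session("baseline", duration = 240)
  expect_error(sampleBaselineEpochs(s, 481, 0.5, seed = 1), "480")
  tiled <- sampleBaselineEpochs(s, 480, 0.5, seed = 1)
  starts <- sort(epochInfo(tiled)$start_time)
  expect_equal(starts, seq(0, 239.5, by = 0.5))    # exact tiling

  e1 <- sampleBaselineEpochs(s, 10, 0.5, seed = 33)
  e2 <- sampleBaselineEpochs(s, 10, 0.5, seed = 33)
  expect_identical(epochInfo(e1)$start_time, epochInfo(e2)$start_time)

  s2 <- make_session("baseline", duration = 2)
  overlaps <- 0L
  for (i in 1:2000) {
    st <- epochInfo(sampleBaselineEpochs(s2, 2, 0.5, seed = i))$start_time
    if (round(abs(st[1] - st[2]) * 1000) < 500) overlaps <- overlaps + 1L
  }
  expect_identical(overlaps, 0L)
})
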