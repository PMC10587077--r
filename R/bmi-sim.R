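# Velocity Kalman-filter decoder, SmoothBatch closed-loop adaptation,
# center-out task engine, behavioral metrics.

STATE_NAMES <- c("px", "py", "vx", "vy", "one")

#' Center-out task parameters
#'
#' @param targetRadius,cursorRadius,reachDistance workspace units (cm).
#' @param centerHold,targetHold,reachTimeout seconds.
#' @param maxRepeats maximum presentations of a failed target.
#' @return a [TaskParams-class].
#' @export
taskParams <- function(targetRadius = 1.7, cursorRadius = 0.5,
                       reachDistance = 10, centerHold = 0.25,
                       targetHold = 0.25, reachTimeout = 3,
                       maxRepeats = 10L) {
  new("TaskParams", nTargets = 8L, targetRadius = targetRadius,
      cursorRadius = cursorRadius, reachDistance = reachDistance,
      centerHold = centerHold, targetHold = targetHold,
      reachTimeout = reachTimeout, maxRepeats = as.integer(maxRepeats))
}

# shared observation-model estimator: y[t+1] = C x[t] + q. With
# velocityOnly (the velocity-KF convention) the position columns of C are
# constrained to zero and only velocity + constant regressors are fit.
estimate_obs_model <- function(kin, spikes, velocityOnly = TRUE) {
  T <- nrow(kin)
  X <- kin[1:(T - 1), , drop = FALSE]
  Y <- spikes[2:T, , drop = FALSE]
  cols <- if (velocityOnly) 3:5 else 1:5
  Xc <- X[, cols, drop = FALSE]
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) stopf("rank-deficient kinematics")
  Ct <- qr.coef(qrX, Y)                  # (cols) x units
  C <- matrix(0, ncol(Y), 5)
  C[, cols] <- t(Ct)
  E <- Y - Xc %*% Ct
  Q <- crossprod(E) / nrow(E)
  Q <- (Q + t(Q)) / 2
  list(C = C, Q = Q)
}

#' Fit a Kalman-filter decoder by maximum likelihood
#'
#' Least-squares estimation of the state-transition model (A, W) from the
#' kinematics and of the observation model (C, Q) from spike counts
#' regressed on the preceding kinematic state, as used to initialize the
#' decoder from manual-control data. The constant-state row of A is fixed
#' to preserve 1 and, per the velocity-KF convention, the position columns
#' of C are zero.
#'
#' @param kinematics bins x 5 matrix `[px, py, vx, vy, 1]`.
#' @param spikes bins x units matrix of counts in `binWidth` bins.
#' @param binWidth seconds per bin (default 0.1).
#' @param velocityOnly constrain position columns of C to zero
#'   (default TRUE).
#' @return a [KalmanDecoder-class].
#' @export
fitKfMl <- function(kinematics, spikes, binWidth = 0.1,
                    velocityOnly = TRUE) {
  kinematics <- as.matrix(kinematics); spikes <- as.matrix(spikes)
  T <- nrow(kinematics)
  if (T < 10 * ncol(kinematics))
    stopf("need at least 10 bins per state dimension (got %d)", T)
  if (ncol(kinematics) != 5L)
    stopf("kinematics must have 5 columns [px, py, vx, vy, 1]")
  X1 <- kinematics[1:(T - 1), , drop = FALSE]
  X2 <- kinematics[2:T, , drop = FALSE]
  # the constant column carries no variance; fit the dynamic block with the
  # constant as an intercept-like regressor
  qrX <- qr(X1)
  if (qrX$rank < 4L) stopf("rank-deficient kinematics")
  At <- qr.coef(qrX, X2)
  At[is.na(At)] <- 0
  A <- t(At)
  A[5, ] <- c(0, 0, 0, 0, 1)
  EA <- X2 - X1 %*% t(A)
  W <- crossprod(EA) / nrow(EA)
  W <- (W + t(W)) / 2
  W[5, ] <- 0; W[, 5] <- 0
  obs <- estimate_obs_model(kinematics, spikes, velocityOnly)
  units <- colnames(spikes)
  if (is.null(units)) units <- sprintf("u%02d", seq_len(ncol(spikes)))
  # Class= named in full: a slot named "C" would otherwise partially
  # match new()'s Class argument
  new(Class = "KalmanDecoder", A = A, W = W, C = obs$C, Q = obs$Q,
      binWidth = binWidth, units = units)
}

#' One Kalman predict-update step
#'
#' Standard linear-Gaussian recursion: predict with (A, W), then update
#' the prediction with the spike-count observation through (C, Q). The
#' posterior covariance never exceeds the predicted covariance, and an
#' uninformative observation (Q very large) leaves the prediction
#' unchanged.
#'
#' @param decoder a [KalmanDecoder-class].
#' @param belief list with `mean` (state vector) and `cov` (state
#'   covariance).
#' @param y spike-count vector for the new bin.
#' @return updated belief list.
#' @export
kfStep <- function(decoder, belief, y) {
  A <- decoder@A; W <- decoder@W; C <- decoder@C; Q <- decoder@Q
  m <- A %*% belief$mean
  P <- A %*% belief$cov %*% t(A) + W
  S <- C %*% P %*% t(C) + Q
  Si <- tryCatch(solve(S), error = function(e)
    stopf("singular innovation covariance"))
  K <- P %*% t(C) %*% Si
  m2 <- m + K %*% (y - C %*% m)
  P2 <- (diag(nrow(P)) - K %*% C) %*% P
  P2 <- (P2 + t(P2)) / 2
  list(mean = as.vector(m2), cov = P2)
}

#' SmoothBatch closed-loop decoder adaptation
#'
#' Re-estimates the observation model (C, Q) from a batch of intended
#' kinematics and observed spikes, then blends it smoothly with the
#' current model: `C_new = lambda C_old + (1 - lambda) C_batch` (and
#' likewise Q). The state-transition model (A, W) is unchanged.
#' `lambda = 1` is the identity; `lambda = 0` adopts the batch estimates
#' exactly.
#'
#' @param decoder a [KalmanDecoder-class].
#' @param intendedKin bins x 5 intended-kinematics matrix.
#' @param spikes bins x units spike counts.
#' @param lambda smoothing weight in \[0, 1\].
#' @return the adapted [KalmanDecoder-class].
#' @export
cldaSmoothBatch <- function(decoder, intendedKin, spikes, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
    stopf("lambda must lie in [0, 1]")
  if (nrow(intendedKin) < 10 * ncol(intendedKin))
    stopf("batch too short: need >= 10 bins per state dimension")
  obs <- estimate_obs_model(intendedKin, spikes,
                            velocityOnly = all(decoder@C[, 1:2] == 0))
  decoder@C <- lambda * decoder@C + (1 - lambda) * obs$C
  decoder@Q <- lambda * decoder@Q + (1 - lambda) * obs$Q
  validObject(decoder)
  decoder
}

#' Intention estimation for closed-loop adaptation
#'
#' Infers the subject's intended velocity from task goals: the current
#' speed redirected along the cursor-to-target unit vector (speed
#' preserved, direction rotated); the zero vector while holding inside
#' the target region.
#'
#' @param cursor length-2 cursor position.
#' @param velocity length-2 current velocity.
#' @param target length-2 target position.
#' @param targetRadius hold region radius.
#' @return length-2 intended velocity.
#' @export
estimateIntent <- function(cursor, velocity, target, targetRadius = 0) {
  d <- target - cursor
  dist <- sqrt(sum(d^2))
  if (dist <= targetRadius) return(c(0, 0))
  speed <- sqrt(sum(velocity^2))
  if (dist == 0 || speed == 0) return(c(0, 0))
  speed * d / dist
}

# ---------------------------------------------------------------------------
# Controllers
# ---------------------------------------------------------------------------

#' Task controllers for the center-out engine
#'
#' `idealController` moves straight toward the target at a fixed speed and
#' never fails. `armController` is a kinematic arm model for manual
#' control: proportional velocity toward the target with a speed cap,
#' smooth ramp-down near the target and motor noise. `bmiController`
#' closes the loop through a decoder: each bin the subject's intent is
#' estimated from the task goal, an encoder population
#' (cosine-tuned Poisson units, see [simulateTunedUnits()]) fires
#' accordingly, and the Kalman decoder's velocity estimate moves the
#' cursor. The belief's position components are re-anchored to the true
#' cursor each bin (position feedback).
#'
#' @param speed movement / intended speed (workspace units per second).
#' @param noiseSd arm velocity noise SD.
#' @param decoder a [KalmanDecoder-class].
#' @param tuning encoder tuning table (see [randomTuning()]); its
#'   preferred directions may differ from those used to fit the decoder,
#'   emulating tuning changes between manual and BMI control.
#' @return a controller object for [runCenterOut()].
#' @export
idealController <- function(speed = 15) {
  structure(list(kind = "ideal", speed = speed), class = "bmilfpController")
}

#' @rdname idealController
#' @export
armController <- function(speed = 15, noiseSd = 1.5) {
  structure(list(kind = "arm", speed = speed, noiseSd = noiseSd),
            class = "bmilfpController")
}

#' @rdname idealController
#' @export
bmiController <- function(decoder, tuning, speed = 15) {
  structure(list(kind = "bmi", decoder = decoder, tuning = tuning,
                 speed = speed),
            class = "bmilfpController")
}

# one control step; env carries controller state (belief); returns velocity
# plus optional logs
controller_step <- function(ctrl, env, cursor, velocity, target, inTarget,
                            binWidth) {
  if (ctrl$kind == "ideal") {
    d <- target - cursor; dist <- sqrt(sum(d^2))
    v <- if (inTarget || dist == 0) c(0, 0) else ctrl$speed * d / dist
    return(list(vel = v))
  }
  if (ctrl$kind == "arm") {
    d <- target - cursor; dist <- sqrt(sum(d^2))
    v <- if (inTarget || dist == 0) c(0, 0) else {
      sp <- ctrl$speed * min(1, dist / 2)   # ramp down near target
      sp * d / dist
    }
    return(list(vel = v + rnorm(2, sd = ctrl$noiseSd)))
  }
  # bmi: intent -> spikes -> decode
  intent <- {
    d <- target - cursor; dist <- sqrt(sum(d^2))
    if (inTarget || dist == 0) c(0, 0) else ctrl$speed * d / dist
  }
  y <- as.vector(simulateTunedUnits(ctrl$tuning, matrix(intent, 1, 2),
                                    binWidth = binWidth))
  bel <- env$belief
  bel$mean[1:2] <- cursor                  # position feedback
  bel <- kfStep(ctrl$decoder, bel, y)
  list(vel = bel$mean[3:4], spikes = y,
       intent = c(cursor, intent, 1), post = bel)
}

#' Run the center-out task engine
#'
#' Simulates the self-initiated eight-target center-out task under a
#' given controller: center acquisition, center hold, go cue, reach
#' within the timeout, target hold. Failed targets are repeated up to
#' `task@maxRepeats` presentations before a new target is drawn;
#' directions are pseudo-randomized in blocks of eight. Time advances in
#' decoder bins (0.1 s).
#'
#' @param controller a controller from [idealController()],
#'   [armController()] or [bmiController()].
#' @param task a [TaskParams-class].
#' @param nTrials number of target presentations to record.
#' @param seed RNG seed.
#' @param binWidth control-loop bin width in seconds.
#' @return list with `trials` (trial table as in
#'   [SessionRecord-class]), `log` (per-bin `kin` bins x 5 actual
#'   kinematics, and for BMI control `intent` bins x 5 and `spikes`
#'   bins x units), and `duration` (s).
#' @export
runCenterOut <- function(controller, task = taskParams(), nTrials = 80L,
                         seed = NULL, binWidth = 0.1) {
  stopifnot(inherits(controller, "bmilfpController"))
  with_seed(seed, {
    env <- new.env()
    if (controller$kind == "bmi")
      env$belief <- list(mean = c(0, 0, 0, 0, 1),
                         cov = diag(c(1, 1, 1, 1, 0)))
    cursor <- c(0, 0); velocity <- c(0, 0)
    t <- 0
    kin <- list(); intent <- list(); spikes <- list()
    record_bin <- function(step) {
      kin[[length(kin) + 1L]] <<- c(cursor, velocity, 1)
      if (!is.null(step$spikes)) {
        spikes[[length(spikes) + 1L]] <<- step$spikes
        intent[[length(intent) + 1L]] <<- step$intent
      }
    }
    advance <- function(target, inTarget) {
      step <- controller_step(controller, env, cursor, velocity, target,
                              inTarget, binWidth)
      if (!is.null(step$post)) env$belief <- step$post
      velocity <<- step$vel
      cursor <<- cursor + velocity * binWidth
      t <<- t + binWidth
      record_bin(step)
    }
    center <- c(0, 0)
    trials <- list()
    queue <- integer(0)
    attempt <- 0L; current_dir <- NA_integer_
    # session time budget: a controller that cannot even initiate trials
    # ends the session early rather than hanging
    t_budget <- nTrials * (task@reachTimeout + task@centerHold +
                             task@targetHold + 12)
    while (length(trials) < nTrials) {
      if (t > t_budget) {
        message(sprintf(
          "runCenterOut: time budget exhausted after %d/%d presentations",
          length(trials), nTrials))
        break
      }
      if (attempt == 0L || attempt >= task@maxRepeats ||
          (length(trials) && trials[[length(trials)]]$success)) {
        if (!length(queue)) queue <- sample(0:7)
        current_dir <- queue[1]; queue <- queue[-1]
        attempt <- 1L
      } else attempt <- attempt + 1L
      # --- center acquisition (self-initiation) ---
      self_init <- TRUE
      t_start <- t
      while (sqrt(sum((cursor - center)^2)) > task@targetRadius) {
        advance(center, FALSE)
        if (t - t_start > 10) { self_init <- FALSE; break }
      }
      if (!self_init) next                 # presentation not initiated
      hold_end <- t + task@centerHold
      ok <- TRUE
      while (t < hold_end) {
        advance(center, TRUE)
        if (sqrt(sum((cursor - center)^2)) > task@targetRadius) {
          ok <- FALSE; break
        }
      }
      if (!ok) next                        # center hold broken; re-initiate
      # --- go cue ---
      go_t <- t
      ang <- current_dir * pi / 4
      target <- task@reachDistance * c(cos(ang), sin(ang))
      success <- FALSE; acq_t <- NA_real_
      deadline <- go_t + task@reachTimeout
      while (t < deadline) {
        advance(target, FALSE)
        if (sqrt(sum((cursor - target)^2)) <= task@targetRadius) {
          # --- target hold ---
          hold_end <- t + task@targetHold
          held <- TRUE
          while (t < hold_end) {
            advance(target, TRUE)
            if (sqrt(sum((cursor - target)^2)) > task@targetRadius) {
              held <- FALSE; break
            }
          }
          if (held) { success <- TRUE; acq_t <- t; break }
        }
      }
      trials[[length(trials) + 1L]] <- data.frame(
        target_direction = current_dir, go_cue_time = go_t,
        target_acquired_time = acq_t, success = success,
        self_initiated = self_init, attempt_index = attempt)
      # inter-trial interval
      for (i in seq_len(round(0.5 / binWidth))) advance(cursor, TRUE)
    }
    trials <- if (length(trials)) do.call(rbind, trials) else {
      tr <- emptyTrials(); tr
    }
    list(trials = trials,
         log = list(kin = do.call(rbind, kin),
                    intent = if (length(intent)) do.call(rbind, intent),
                    spikes = if (length(spikes)) do.call(rbind, spikes)),
         duration = t)
  })
}

#' Behavioral performance metrics
#'
#' Per day: the fraction of self-initiated trials that were successful;
#' per successful trial: the acquisition time (go cue to target
#' acquisition). Each metric is regressed against day index by ordinary
#' least squares (day-level for the success fraction, trial-level for
#' acquisition time), reporting slope, R-squared and p-value.
#'
#' @param daysTrials list of trial tables, one per day (in day order);
#'   names, when present, give the day indices.
#' @return list with `perDay` (data.frame day, n_self_initiated,
#'   success_fraction), `acquisitions` (data.frame day, acq_time) and
#'   `regressions` (per metric: slope, r_squared, p_value).
#' @export
behavioralMetrics <- function(daysTrials) {
  if (length(daysTrials) < 2L) stopf("need >= 2 days")
  day_ids <- if (!is.null(names(daysTrials)))
    as.numeric(names(daysTrials)) else seq_along(daysTrials) - 1
  per_day <- list(); acq <- list()
  for (i in seq_along(daysTrials)) {
    tr <- daysTrials[[i]]
    si <- tr[tr$self_initiated, , drop = FALSE]
    if (!nrow(si)) {
      message(sprintf("day %s has no self-initiated trials; excluded",
                      day_ids[i]))
      next
    }
    per_day[[length(per_day) + 1L]] <- data.frame(
      day = day_ids[i], n_self_initiated = nrow(si),
      success_fraction = mean(si$success))
    succ <- tr[tr$success, , drop = FALSE]
    if (nrow(succ))
      acq[[length(acq) + 1L]] <- data.frame(
        day = day_ids[i],
        acq_time = succ$target_acquired_time - succ$go_cue_time)
  }
  per_day <- do.call(rbind, per_day)
  acq <- do.call(rbind, acq)
  regress <- function(df, yname) {
    if (length(unique(df$day)) < 2L || nrow(df) < 2L)
      return(list(slope = NA_real_, r_squared = NA_real_,
                  p_value = NA_real_))
    yv <- df[[yname]]
    if (sd(yv) == 0)        # constant metric: flat line, no variance explained
      return(list(slope = 0, r_squared = 0, p_value = NA_real_))
    fit <- lm(yv ~ df$day)
    # summary() warns on exactly-collinear (perfect) fits; legitimate here
    sm <- suppressWarnings(summary(fit))
    list(slope = unname(coef(fit)[2]), r_squared = sm$r.squared,
         p_value = if (nrow(sm$coefficients) > 1)
           sm$coefficients[2, 4] else NA_real_)
  }
  list(perDay = per_day, acquisitions = acq,
       regressions = list(
         success_fraction = regress(per_day, "success_fraction"),
         acq_time = regress(acq, "acq_time")))
}

#' Closed-loop decoder adaptation experiment
#'
#' End-to-end learning simulation: (1) a manual-control block under the
#' kinematic arm model provides kinematics and cosine-tuned spikes to
#' initialize the decoder by maximum likelihood; (2) the encoder's tuning
#' is perturbed (preferred directions rotated), emulating the tuning
#' changes observed between manual and BMI control, so the initial
#' decoder is mismatched; (3) BMI blocks run before and after
#' `nBatches` SmoothBatch updates computed from intended kinematics.
#'
#' @param seed RNG seed.
#' @param nUnits encoder population size (default 15 direct units).
#' @param nBatches SmoothBatch updates (default 3).
#' @param lambda SmoothBatch smoothing weight (default 0.5).
#' @param rotation encoder preferred-direction rotation between manual
#'   and BMI control, radians.
#' @param nTrials presentations per evaluation block.
#' @param task a [TaskParams-class].
#' @return list with `pre` and `post` (success_fraction,
#'   mean_acq_time), the fitted decoders, and the per-batch trial
#'   tables.
#' @export
runCldaExperiment <- function(seed = 1L, nUnits = 15L, nBatches = 3L,
                              lambda = 0.5, rotation = 0.9,
                              nTrials = 40L, task = taskParams()) {
  tuning <- randomTuning(nUnits, seed = derive_seed(seed, "tuning"))
  manual <- runCenterOut(armController(), task, nTrials = 60L,
                         seed = derive_seed(seed, "manual"))
  spikes_mc <- t(simulateTunedUnits(tuning, manual$log$kin[, 3:4],
                                    seed = derive_seed(seed, "mc-spikes")))
  dec <- fitKfMl(manual$log$kin, spikes_mc)
  tuning_bmi <- tuning
  tuning_bmi$preferred <- (tuning$preferred + rotation) %% (2 * pi)

  eval_block <- function(decoder, tag) {
    run <- runCenterOut(bmiController(decoder, tuning_bmi), task,
                        nTrials = nTrials, seed = derive_seed(seed, tag))
    si <- run$trials[run$trials$self_initiated, , drop = FALSE]
    succ <- run$trials[run$trials$success, , drop = FALSE]
    list(run = run,
         success_fraction = if (nrow(si)) mean(si$success) else 0,
         mean_acq_time = if (nrow(succ))
           mean(succ$target_acquired_time - succ$go_cue_time) else NA_real_)
  }
  pre <- eval_block(dec, "pre")
  dec_i <- dec
  batches <- list()
  for (b in seq_len(nBatches)) {
    run <- runCenterOut(bmiController(dec_i, tuning_bmi), task,
                        nTrials = nTrials,
                        seed = derive_seed(seed, "batch", b))
    if (!is.null(run$log$spikes) && nrow(run$log$spikes) >= 50)
      dec_i <- cldaSmoothBatch(dec_i, run$log$intent, run$log$spikes,
                               lambda)
    batches[[b]] <- run$trials
  }
  post <- eval_block(dec_i, "post")
  list(pre = pre[c("success_fraction", "mean_acq_time")],
       post = post[c("success_fraction", "mean_acq_time")],
       decoderInitial = dec, decoderAdapted = dec_i,
       batchTrials = batches)
}
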