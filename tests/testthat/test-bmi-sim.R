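# Kalman decoder, SmoothBatch adaptation, task engine, behavior.

# simulate bins from a known state-space model
sim_ssm <- function(A, W, C, Q, n, seed = 1) {
  set.seed(seed)
  d <- nrow(A); u <- nrow(C)
  X <- matrix(0, n, d); X[1, ] <- c(0, 0, 0, 0, 1)
  cw <- chol(W + diag(1e-12, d)); cq <- chol(Q + diag(1e-12, u))
  Y <- matrix(0, n, u)
  for (t in 2:n) {
    X[t, ] <- A %*% X[t - 1, ] + t(cw) %*% rnorm(d)
    X[t, 5] <- 1
    Y[t, ] <- C %*% X[t - 1, ] + t(cq) %*% rnorm(u)
  }
  list(X = X, Y = Y)
}

true_model <- function(u = 8, seed = 2) {
  set.seed(seed)
  A <- diag(5)
  A[1, 3] <- A[2, 4] <- 0.1
  A[3, 3] <- A[4, 4] <- 0.85
  W <- diag(c(0, 0, 0.15, 0.15, 0))
  C <- cbind(0, 0, matrix(rnorm(u * 3), u, 3))
  Q <- diag(runif(u, 0.5, 1.5))
  list(A = A, W = W, C = C, Q = Q)
}

test_that("a noiseless observation model is identified exactly", {
  # y = C x with zero observation noise: the regression residual vanishes
  # and C, Q are recovered exactly. (Exact recovery of A requires
  # persistent excitation that a noiseless autonomous linear system cannot
  # provide; A's consistency is asserted at 10^4 bins below.)
  m <- true_model()
  sim <- sim_ssm(m$A, diag(c(0, 0, 0.2, 0.2, 0)), m$C, m$Q * 0, 400,
                 seed = 3)
  dec <- fitKfMl(sim$X, sim$Y)
  expect_lt(max(abs(dec@C - m$C)), 1e-6)
  expect_lt(max(abs(dec@Q)), 1e-10)
  expect_lt(max(abs(dec@A[5, ] - c(0, 0, 0, 0, 1))), 1e-12)
})

test_that("fitting is consistent at 10^4 bins (5% relative error)", {
  m <- true_model(u = 10, seed = 5)
  sim <- sim_ssm(m$A, m$W, m$C, m$Q, 1e4, seed = 6)
  dec <- fitKfMl(sim$X, sim$Y)
  rel <- function(got, want) norm(got - want, "F") / norm(want, "F")
  expect_lt(rel(dec@A[3:4, 3:4], m$A[3:4, 3:4]), 0.05)
  expect_lt(rel(dec@C, m$C), 0.05)
  expect_lt(rel(dec@W[3:4, 3:4], m$W[3:4, 3:4]), 0.05)
  expect_lt(rel(dec@Q, m$Q), 0.05)
  expect_error(fitKfMl(sim$X[1:20, ], sim$Y[1:20, ]), "10 bins")
})

test_that("kfStep matches a brute-force joint-Gaussian conditioning oracle", {
  set.seed(9)
  m <- true_model(u = 4, seed = 7)
  dec <- new(Class = "KalmanDecoder", A = m$A, W = m$W, C = m$C, Q = m$Q,
             binWidth = 0.1, units = sprintf("u%d", 1:4))
  bel <- list(mean = c(0.3, -0.2, 0.5, 0.1, 1),
              cov = crossprod(matrix(rnorm(25, sd = 0.3), 5)))
  y <- rnorm(4)
  got <- kfStep(dec, bel, y)
  # oracle: joint Gaussian of (x_pred, y) conditioned on y
  mp <- m$A %*% bel$mean
  Pp <- m$A %*% bel$cov %*% t(m$A) + m$W
  S <- m$C %*% Pp %*% t(m$C) + m$Q
  cross <- Pp %*% t(m$C)
  mu_post <- mp + cross %*% solve(S, y - m$C %*% mp)
  P_post <- Pp - cross %*% solve(S, t(cross))
  expect_lt(max(abs(got$mean - mu_post)), 1e-8)
  expect_lt(max(abs(got$cov - P_post)), 1e-8)
  # posterior covariance never exceeds the prediction along any direction
  eg <- eigen(Pp - got$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(eg), -1e-10)
})

test_that("observation limits behave correctly", {
  u <- 5
  A <- diag(5); A[5, 5] <- 1
  dec_perfect <- new(Class = "KalmanDecoder", A = A,
                     W = diag(c(1, 1, 1, 1, 0)),
                     C = diag(5), Q = diag(1e-12, 5),
                     binWidth = 0.1, units = sprintf("u%d", 1:5))
  bel <- list(mean = c(0, 0, 0, 0, 1), cov = diag(c(1, 1, 1, 1, 0)))
  y <- c(1, 2, 3, 4, 1)
  got <- kfStep(dec_perfect, bel, y)
  expect_equal(got$mean, y, tolerance = 1e-5)

  dec_blind <- new(Class = "KalmanDecoder", A = A,
                   W = diag(c(1, 1, 1, 1, 0)),
                   C = diag(5), Q = diag(1e12, 5),
                   binWidth = 0.1, units = sprintf("u%d", 1:5))
  got2 <- kfStep(dec_blind, bel, y)
  expect_equal(got2$mean, as.vector(A %*% bel$mean), tolerance = 1e-6)
})

test_that("SmoothBatch blends the observation model as specified", {
  m <- true_model(u = 6, seed = 11)
  sim <- sim_ssm(m$A, m$W, m$C, m$Q, 500, seed = 12)
  dec <- fitKfMl(sim$X, sim$Y)
  sim2 <- sim_ssm(m$A, m$W, m$C * 1.3, m$Q, 500, seed = 13)

  same <- cldaSmoothBatch(dec, sim2$X, sim2$Y, lambda = 1)
  expect_identical(same@C, dec@C)
  expect_identical(same@Q, dec@Q)

  batch <- cldaSmoothBatch(dec, sim2$X, sim2$Y, lambda = 0)
  obs <- bmilfp:::estimate_obs_model(sim2$X, sim2$Y, velocityOnly = TRUE)
  expect_identical(batch@C, obs$C)
  expect_identical(batch@Q, obs$Q)
  expect_identical(batch@A, dec@A)           # transition model untouched

  half <- cldaSmoothBatch(dec, sim2$X, sim2$Y, lambda = 0.5)
  expect_equal(half@C, 0.5 * dec@C + 0.5 * obs$C, tolerance = 1e-12)
  expect_error(cldaSmoothBatch(dec, sim2$X, sim2$Y, lambda = 1.2), "0, 1")
})

test_that("repeated SmoothBatch updates contract toward the true encoder", {
  m <- true_model(u = 10, seed = 21)
  sim0 <- sim_ssm(m$A, m$W, m$C * 0.4, m$Q, 600, seed = 22)  # mismatched
  dec <- fitKfMl(sim0$X, sim0$Y)
  err <- norm(dec@C - m$C, "F")
  for (b in 1:3) {
    simb <- sim_ssm(m$A, m$W, m$C, m$Q, 600, seed = 22 + b)
    dec <- cldaSmoothBatch(dec, simb$X, simb$Y, lambda = 0.5)
    new_err <- norm(dec@C - m$C, "F")
    expect_lt(new_err, err)
    err <- new_err
  }
})

test_that("intent estimation preserves speed and respects holds", {
  expect_equal(estimateIntent(c(0, 0), c(1, 0), c(5, 0)), c(1, 0))
  expect_equal(estimateIntent(c(0, 0), c(0, 1), c(5, 0)), c(1, 0))
  expect_equal(estimateIntent(c(4.9, 0), c(1, 1), c(5, 0),
                              targetRadius = 0.5), c(0, 0))
  set.seed(31)
  for (i in 1:20) {
    v <- rnorm(2); cur <- rnorm(2); tgt <- rnorm(2, sd = 3)
    intent <- estimateIntent(cur, v, tgt)
    expect_equal(sqrt(sum(intent^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("an ideal controller completes every trial at the geometric time", {
  task <- taskParams()
  run <- runCenterOut(idealController(speed = 15), task, nTrials = 16L,
                      seed = 2)
  expect_identical(nrow(run$trials), 16L)
  expect_true(all(run$trials$success))
  acq <- run$trials$target_acquired_time - run$trials$go_cue_time
  # reach (distance - target radius)/speed plus the target hold, within a bin
  expected <- (task@reachDistance - task@targetRadius) / 15 + task@targetHold
  # start may sit anywhere inside the center region: one target radius of
  # path slack plus one bin of time quantization
  slack <- task@targetRadius / 15 + 0.1 + 1e-9
  expect_true(all(abs(acq - expected) <= slack))
  # block randomization: first 8 and next 8 presentations cover 0..7
  expect_setequal(run$trials$target_direction[1:8], 0:7)
  expect_setequal(run$trials$target_direction[9:16], 0:7)
})

test_that("a controller that never reaches repeats each target 10 times", {
  run <- runCenterOut(idealController(speed = 0), taskParams(),
                      nTrials = 25L, seed = 3)
  expect_identical(nrow(run$trials), 25L)
  expect_true(!any(run$trials$success))
  r <- rle(run$trials$target_direction)
  expect_identical(r$lengths[1:2], c(10L, 10L))
  expect_identical(run$trials$attempt_index[1:10], 1:10)
})

test_that("behavioral metrics recover trivial and linear structures", {
  mk_day <- function(n, acq, success = TRUE) {
    go <- seq(1, by = 3, length.out = n)
    data.frame(target_direction = 0L, go_cue_time = go,
               target_acquired_time = ifelse(rep(success, n), go + acq, NA),
               success = success, self_initiated = TRUE,
               attempt_index = 1L)
  }
  days <- list(`0` = mk_day(10, 1), `1` = mk_day(10, 1))
  bm <- behavioralMetrics(days)
  expect_identical(bm$perDay$success_fraction, c(1, 1))
  expect_identical(bm$regressions$success_fraction$slope, 0)

  days2 <- list(`0` = mk_day(10, 2.0), `1` = mk_day(10, 1.8),
                `2` = mk_day(10, 1.6))
  bm2 <- behavioralMetrics(days2)
  expect_equal(bm2$regressions$acq_time$slope, -0.2, tolerance = 1e-10)
  expect_equal(bm2$regressions$acq_time$r_squared, 1, tolerance = 1e-10)

  # known slope with noise: recovered within 2 standard errors most times
  set.seed(51)
  hits <- 0L
  for (rep in 1:200) {
    # independent trial-level noise around a linear across-day trend
    daysr <- lapply(0:5, function(d) mk_day(15, 2 - 0.1 * d + rnorm(15, 0, 0.2)))
    names(daysr) <- 0:5
    fit <- lm(acq_time ~ day, behavioralMetrics(daysr)$acquisitions)
    se <- summary(fit)$coefficients[2, 2]
    if (abs(coef(fit)[2] - (-0.1)) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("offline decoding of cosine-tuned activity tracks true velocity", {
  task <- taskParams()
  manual <- runCenterOut(armController(), task, nTrials = 60L, seed = 41)
  tuning <- randomTuning(20, seed = 42)
  spikes <- t(simulateTunedUnits(tuning, manual$log$kin[, 3:4], seed = 43))
  half <- floor(nrow(manual$log$kin) / 2)
  dec <- fitKfMl(manual$log$kin[1:half, ], spikes[1:half, ])
  bel <- list(mean = c(0, 0, 0, 0, 1), cov = diag(c(1, 1, 1, 1, 0)))
  test_idx <- (half + 1):nrow(manual$log$kin)
  vhat <- matrix(0, length(test_idx), 2)
  for (j in seq_along(test_idx)) {
    bel <- kfStep(dec, bel, spikes[test_idx[j], ])
    vhat[j, ] <- bel$mean[3:4]
  }
  vtrue <- manual$log$kin[test_idx, 3:4]
  expect_gte(cor(vhat[, 1], vtrue[, 1]), 0.7)
  expect_gte(cor(vhat[, 2], vtrue[, 2]), 0.7)
})

test_that("three SmoothBatch updates improve closed-loop performance", {
  res <- runCldaExperiment(seed = 101L, nTrials = 24L)
  expect_gt(res$post$success_fraction, res$pre$success_fraction)
  expect_lt(res$post$mean_acq_time, res$pre$mean_acq_time)
})
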