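# Granger causality, artifact null, normalization, directionality.

# independent least-squares oracle via lm() on explicit lag columns
oracle_granger <- function(x, y, p) {
  n <- length(x)
  xd <- x - mean(x); yd <- y - mean(y)
  df <- data.frame(r = xd[(p + 1):n])
  for (k in seq_len(p)) {
    df[[paste0("xl", k)]] <- xd[(p + 1 - k):(n - k)]
    df[[paste0("yl", k)]] <- yd[(p + 1 - k):(n - k)]
  }
  f_full <- lm(r ~ . - 1, df)
  f_red <- lm(r ~ . - 1, df[, c("r", paste0("xl", seq_len(p)))])
  log(sum(resid(f_red)^2) / sum(resid(f_full)^2))
}

ar_series <- function(n, coefs = 0.5, seed) {
  set.seed(seed)
  as.vector(stats::filter(rnorm(n + 100), coefs,
                          method = "recursive"))[(100 + 1):(100 + n)]
}

test_that("grangerPair matches the least-squares oracle on 100 instances", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(50:100, 1); p <- sample(1:3, 1)
    x <- ar_series(n, 0.4, seed = i)
    y <- ar_series(n, 0.3, seed = i + 1000)
    expect_lt(abs(grangerPair(x, y, p) - oracle_granger(x, y, p)), 1e-8)
  }
})

test_that("G is invariant to positive rescaling of either series", {
  x <- ar_series(400, 0.5, seed = 1); y <- ar_series(400, 0.4, seed = 2)
  g <- grangerPair(x, y, 13)
  expect_lt(abs(grangerPair(3.7 * x, y, 13) - g), 1e-8)
  expect_lt(abs(grangerPair(x, 0.002 * y, 13) - g), 1e-8)
  expect_gte(g, 0)
})

test_that("a lagged driver produces strongly asymmetric G", {
  set.seed(77)
  fwd <- rev <- numeric(30)
  for (i in 1:30) {
    y <- rnorm(520)
    x <- 0.8 * c(0, 0, y[1:518]) + rnorm(520, sd = 0.3)
    fwd[i] <- grangerPair(x[21:520], y[21:520], 5)
    rev[i] <- grangerPair(y[21:520], x[21:520], 5)
  }
  expect_gte(mean(fwd) / mean(rev), 10)
})

test_that("granger_both equals two grangerPair calls", {
  z <- cbind(ar_series(300, 0.4, seed = 5), ar_series(300, 0.5, seed = 6))
  gb <- bmilfp:::granger_both(z, 7)
  expect_lt(abs(gb[1] - grangerPair(z[, 1], z[, 2], 7)), 1e-10)
  expect_lt(abs(gb[2] - grangerPair(z[, 2], z[, 1], 7)), 1e-10)
})

test_that("BIC order selection recovers low-order structure", {
  mk_var3_segments <- function(n_seg, len, seed) {
    set.seed(seed)
    lapply(seq_len(n_seg), function(i) {
      x <- as.vector(stats::filter(rnorm(len + 50),
                                   c(0.4, -0.3, 0.35),
                                   method = "recursive"))
      y <- as.vector(stats::filter(rnorm(len + 50) + 0.3 * c(0, x[-(len + 50)]),
                                   c(0.3, -0.2, 0.3),
                                   method = "recursive"))
      cbind(x, y)[51:(50 + len), ]
    })
  }
  hits <- 0L
  for (run in 1:10) {
    segs <- mk_var3_segments(20, 400, seed = run)
    if (selectArOrder(segs, 8L) %in% 2:4) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # white noise: the BIC penalty favors order 1 most often
  set.seed(99)
  wins <- integer(8)
  for (run in 1:10) {
    segs <- lapply(1:10, function(i) matrix(rnorm(600), 300, 2))
    sel <- selectArOrder(segs, 8L)
    wins[sel] <- wins[sel] + 1L
  }
  expect_identical(which.max(wins), 1L)
  expect_identical(selectArOrder(list(matrix(rnorm(400), 200, 2)), 1L), 1L)
  expect_error(selectArOrder(list(matrix(rnorm(40), 20, 2)), 15L), "short")
})

test_that("the artifact null is reproducible and blind to within-task coupling", {
  set.seed(3)
  base <- lapply(1:10, function(i) rnorm(400))
  task <- lapply(1:10, function(i) rnorm(400))
  n1 <- artifactNull(base, task, 5L, 30L, seed = 8)
  n2 <- artifactNull(base, task, 5L, 30L, seed = 8)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0))

  # strong coupling inside task segments cannot cross the pairing
  task_y <- lapply(1:10, function(i) rnorm(400))
  task_x <- lapply(task_y, function(y)
    0.9 * c(0, 0, y[1:398]) + rnorm(400, sd = 0.2))
  null_g <- artifactNull(base, task_y, 5L, 40L, seed = 9)
  within_g <- mapply(function(x, y) grangerPair(x, y, 5L), task_x, task_y)
  expect_gt(mean(within_g), mean(null_g) + 10 * sd(null_g))
  expect_error(artifactNull(base, list(rnorm(200)), 5L, 10L), "length")
})

test_that("normalization and net identities hold exactly", {
  expect_identical(normalizeGc(2, 2), 0)
  expect_identical(normalizeGc(4, 2), 1)
  expect_identical(normalizeGc(1, 2), -0.5)
  expect_error(normalizeGc(1, 0), "degenerate")
  expect_identical(netNormalizedGc(0.4, -0.1), 0.5)
  expect_identical(netNormalizedGc(0.3, 0.3), 0)
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    expect_identical(netNormalizedGc(a, b), -netNormalizedGc(b, a))
  }
})

test_that("directionality tests control the false-directed rate", {
  expect_false(directionalityTest(rep(0, 10))$directed)
  expect_identical(directionalityTest(rep(0, 10))$p_raw, 1)

  set.seed(41)
  strong <- 0.3 + rnorm(20, sd = 0.01)
  res <- directionalityTest(strong, nComparisons = 6L)
  expect_true(res$directed)
  expect_lt(res$p_corrected, 0.05)

  # type-I calibration: N(0,1) net values, 20 days, 6 comparisons
  set.seed(42)
  false_calls <- 0L
  for (i in 1:1000)
    if (directionalityTest(rnorm(20), nComparisons = 6L)$directed)
      false_calls <- false_calls + 1L
  expect_lte(false_calls / 1000, 0.05)
})

test_that("study-level connectivity recovers a BMI-specific coupling", {
  study <- simulateStudy(gc_study_config(71L, nDays = 6L))
  net <- runConnectivityStudy(study$days,
                              config = studyConfig(seed = 4L),
                              events = "go_cue",
                              taskTypes = c("bmi", "manual"))
  nn <- netTable(net)
  fwd_bmi <- nn$net_g[nn$source == "DLPFC" & nn$target == "M1" &
                        nn$task_type == "bmi"]
  fwd_man <- nn$net_g[nn$source == "DLPFC" & nn$target == "M1" &
                        nn$task_type == "manual"]
  expect_gt(mean(fwd_bmi), 0.2)             # coupling present only in bmi
  expect_lt(abs(mean(fwd_man)), mean(fwd_bmi))
  # net antisymmetry on every output row
  for (i in seq_len(nrow(nn))) {
    mirror <- nn$net_g[nn$source == nn$target[i] & nn$target == nn$source[i] &
                         nn$task_type == nn$task_type[i] &
                         nn$event == nn$event[i] &
                         nn$day_index == nn$day_index[i]]
    expect_identical(nn$net_g[i], -mirror)
  }
  # baseline-unchanged couplings normalize to ~0: manual has no coupling
  # change from baseline, so its normalized G is centred near zero
  nrm <- normalizedTable(net)
  man_fwd <- nrm$normalized_g[nrm$source == "DLPFC" & nrm$target == "M1" &
                                nrm$task_type == "manual"]
  expect_lt(abs(mean(man_fwd)), 0.35)
})
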