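# Discriminant classification, balancing, permutation chance, statistics.

# build a BandPowerTable directly from a feature matrix (rows = epochs)
feature_table <- function(X, labels, label = "task_type") {
  stopifnot(ncol(X) %% 5 == 0)
  rois <- c("M1", "DLPFC", "Cd")[seq_len(ncol(X) / 5)]
  power <- t(X)
  rownames(power) <- as.vector(t(outer(rois, names(defaultBands()), paste,
                                       sep = ".")))
  colnames(power) <- sprintf("e%04d", seq_len(ncol(power)))
  info <- data.frame(task_type = "bmi", event = "go_cue", day_index = 0L,
                     start_time = seq_len(nrow(X)))
  info[[label]] <- labels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(power = abs(power)),
    colData = S4Vectors::DataFrame(info))
  new("BandPowerTable", se)
}

gauss_data <- function(n_per, centers, sdev = 1, d = 5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(centers), function(k)
    matrix(rnorm(n_per * d, centers[k], sdev), n_per, d)))
  y <- rep(names(centers), each = n_per)
  list(X = X, y = y)
}

test_that("class balancing reduces every class to the minimum count", {
  g <- gauss_data(100, c(a = 0, b = 0, c = 0))
  y <- c(rep("a", 100), rep("b", 60), rep("c", 80))
  tab <- feature_table(g$X[seq_along(y), ], y)
  b <- balanceClasses(tab, seed = 4)
  expect_identical(as.vector(table(table_lab <- SummarizedExperiment::colData(b)$task_type)),
                   rep(60L, 3))
  # already balanced: identity
  tab2 <- feature_table(g$X[1:90, ], rep(c("a", "b", "c"), each = 30))
  expect_identical(ncol(balanceClasses(tab2, seed = 1)), 90L)
  # deterministic under seed
  b2 <- balanceClasses(tab, seed = 4)
  expect_identical(colnames(b), colnames(b2))
})

test_that("well-separated classes are classified near-perfectly", {
  g <- gauss_data(100, c(lo = 0, hi = 10))
  rep <- fitEvalDiscriminant(feature_table(g$X, g$y), "qda", 10L,
                             seed = 1)
  expect_gte(meanAccuracy(rep), 0.99)
  repl <- fitEvalDiscriminant(feature_table(g$X, g$y), "lda", 10L,
                              seed = 1)
  expect_gte(meanAccuracy(repl), 0.99)
})

test_that("label-independent features stay inside the permutation null", {
  g <- gauss_data(100, c(a = 0, b = 0, c = 0), seed = 7)
  tab <- feature_table(g$X, g$y)
  rep <- evaluateWithChance(tab, "qda", 10L, nPermutations = 200L,
                            seed = 11)
  null <- nullAccuracies(rep)
  expect_gte(meanAccuracy(rep), quantile(null, 0.025))
  expect_lte(meanAccuracy(rep), quantile(null, 0.975))
  expect_gt(rep@pVsChance, 0.05)
})

test_that("fold predictions match the closed-form Gaussian posterior oracle", {
  for (kind in c("qda", "lda")) {
    set.seed(20)
    X <- matrix(rnorm(24 * 2), 24, 2)
    X[13:24, ] <- X[13:24, ] + 1.5
    y <- rep(c("p", "q"), each = 12)
    fold <- rep(rep(1:3, each = 4), 2)
    for (f in 1:3) {
      te <- fold == f
      model <- bmilfp:::fit_gaussian_discriminant(X[!te, ], y[!te], kind)
      got <- bmilfp:::predict_gaussian_discriminant(model, X[te, , drop = FALSE])
      want <- oracle_gaussian_predict(X[!te, ], y[!te], X[te, , drop = FALSE],
                                      kind)
      expect_identical(got, unname(want))
    }
  }
})

test_that("discriminant predictions agree with MASS on clean data", {
  skip_if_not_installed("MASS")
  g <- gauss_data(60, c(a = 0, b = 2, c = 4), sdev = 1.5, d = 3, seed = 3)
  Xte <- matrix(rnorm(90 * 3, 2, 2), 90, 3)
  m <- bmilfp:::fit_gaussian_discriminant(g$X[, 1:3], g$y, "qda")
  got <- bmilfp:::predict_gaussian_discriminant(m, Xte)
  mq <- MASS::qda(g$X[, 1:3], grouping = g$y,
                  prior = rep(1 / 3, 3))
  expect_identical(got, as.character(predict(mq, Xte)$class))
  ml <- bmilfp:::fit_gaussian_discriminant(g$X[, 1:3], g$y, "lda")
  gotl <- bmilfp:::predict_gaussian_discriminant(ml, Xte)
  ml2 <- MASS::lda(g$X[, 1:3], grouping = g$y, prior = rep(1 / 3, 3))
  expect_identical(gotl, as.character(predict(ml2, Xte)$class))
})

test_that("permutation nulls center at 1/K for K balanced classes", {
  g3 <- gauss_data(20, c(a = 0, b = 0, c = 0), seed = 5)
  null3 <- permutationChance(feature_table(g3$X, g3$y),
                             "qda", 5L, nPermutations = 300L, seed = 2)
  expect_equal(mean(null3), 1 / 3, tolerance = 0.02 * 3)
  y8 <- rep(letters[1:8], each = 10)
  set.seed(6)
  X8 <- matrix(rnorm(80 * 5), 80, 5)
  null8 <- permutationChance(feature_table(X8, y8), "lda", 5L,
                             nPermutations = 300L, seed = 3)
  expect_equal(mean(null8), 0.125, tolerance = 0.01 * 8)
})

test_that("stratified folds keep class proportions within one sample", {
  y <- rep(c("a", "b", "c"), times = c(30, 21, 12))
  fold <- bmilfp:::stratified_folds(y, 5L, seed = 2)
  for (f in 1:5) {
    tab <- table(y[fold == f])
    for (cl in names(tab))
      expect_lte(abs(tab[[cl]] - sum(y == cl) / 5), 1)
  }
})

test_that("QDA agrees with LDA when class covariances are shared", {
  g <- gauss_data(400, c(a = 0, b = 1.2), sdev = 1, d = 2, seed = 9)
  mq <- bmilfp:::fit_gaussian_discriminant(g$X[, 1:2], g$y, "qda")
  ml <- bmilfp:::fit_gaussian_discriminant(g$X[, 1:2], g$y, "lda")
  grid <- as.matrix(expand.grid(seq(-2, 3, 0.1), seq(-2, 3, 0.1)))
  pq <- bmilfp:::predict_gaussian_discriminant(mq, grid)
  pl <- bmilfp:::predict_gaussian_discriminant(ml, grid)
  expect_lte(mean(pq != pl), 0.03)
})

test_that("accuracy comparisons reproduce the t-statistic exactly", {
  a <- c(0.7, 0.72, 0.68, 0.75, 0.71)
  expect_identical(compareAccuracy(a, a)$statistic, 0)
  expect_identical(compareAccuracy(a, a)$p_raw, 1)

  shifted <- compareAccuracy(a + 0.1, a)
  expect_true(shifted$degenerate)
  expect_identical(shifted$p_raw, 0)

  set.seed(13)
  x <- rnorm(12, 0.6, 0.05); yv <- rnorm(12, 0.55, 0.05)
  got <- compareAccuracy(x, yv, paired = TRUE, nComparisons = 7L)
  d <- x - yv
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  praw <- 2 * pt(-abs(tstat), length(d) - 1)
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_equal(got$p_raw, praw, tolerance = 1e-10)
  expect_equal(got$p_corrected, min(1, praw * 7), tolerance = 1e-10)
  expect_error(compareAccuracy(x, yv[1:5], paired = TRUE), "mismatch")
})

test_that("learning-stage splits partition days into thirds", {
  sp <- stageSplit(0:11)
  expect_identical(sp$early, 0:3)
  expect_identical(sp$late, 8:11)
  expect_identical(sp$middle, 4:7)
  sp2 <- stageSplit(c(5, 3, 9, 1, 7, 2, 8))    # unsorted, n = 7
  expect_identical(sort(c(sp2$early, sp2$middle, sp2$late)),
                   sort(unique(c(5, 3, 9, 1, 7, 2, 8))))
  expect_length(sp2$early, 2)
  expect_length(sp2$late, 2)
  expect_length(sp2$middle, 3)
})

test_that("task-type studies recover injected spectral contrasts", {
  # DLPFC-only go-cue contrast between bmi and manual
  cfg <- simStudyConfig(
    nDays = 2L, trialsPerSession = 24L,
    bandProfile = flat_band_profile(1),
    eventEffect = data.frame(task_type = "bmi", roi = "DLPFC",
                             band = c("theta", "beta"), event = "go_cue",
                             factor = c(1.8, 0.55)),
    directionEffect = no_direction_effect(),
    coupling = no_coupling(), baselineDuration = 40,
    behavior = list(bmi_success_base = 0.9, bmi_acq_base = 1.2,
                    bmi_acq_slope = 0),
    seed = 21L)
  study <- simulateStudy(cfg, days = 0:1)
  res <- runTaskTypeStudy(study$days, roiCombos = list("M1", "DLPFC", "Cd"),
                          config = studyConfig(cvFolds = 5L, seed = 2L),
                          nClasses = 2L, events = "go_cue")
  acc <- aggregate(mean_accuracy ~ combo, res$summary, mean)
  expect_identical(acc$combo[which.max(acc$mean_accuracy)], "DLPFC")
})

test_that("target-direction studies drop the first five days and match trials", {
  cfg <- simStudyConfig(
    nDays = 7L, trialsPerSession = 40L,
    bandProfile = flat_band_profile(1),
    eventEffect = no_event_effect(),
    directionEffect = data.frame(roi = "M1", band = c("beta", "gamma"),
                                 depth = 0.8, preferred = c(0, pi / 2)),
    coupling = no_coupling(), baselineDuration = 30,
    behavior = list(bmi_success_base = 0.95, bmi_acq_base = 1.0,
                    bmi_acq_slope = 0, manual_success = 0.95),
    seed = 31L)
  study <- simulateStudy(cfg)
  res <- runTargetDirectionStudy(study$days,
                                 roiCombos = list("M1", "Cd"),
                                 config = studyConfig(cvFolds = 3L,
                                                      seed = 5L))
  expect_setequal(unique(res$summary$day_index), c(5L, 6L))
  m1 <- subset(res$summary, combo == "M1")
  cd <- subset(res$summary, combo == "Cd")
  # direction information was injected in M1 bands only
  expect_gt(mean(m1$mean_accuracy), 0.125 + 0.1)
  expect_lt(mean(cd$mean_accuracy), 0.125 + 0.1)
  expect_error(runTargetDirectionStudy(study$days[1:5]), "6 days")
})
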