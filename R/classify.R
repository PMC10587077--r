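# Task-type (QDA) and target-direction (LDA) classification with
# class balancing, stratified tenfold CV, shuffled-label chance
# calibration and chance-comparison statistics.

table_features <- function(table) t(SummarizedExperiment::assay(table, "power"))

table_labels <- function(table, label) {
  cd <- SummarizedExperiment::colData(table)
  if (!label %in% names(cd)) stopf("label column '%s' not in table", label)
  as.character(cd[[label]])
}

#' Balance classes by random subsampling
#'
#' Every class is reduced to the minimum per-class count by uniform
#' sampling without replacement (reproducible under `seed`); a table that
#' is already balanced is returned with all rows retained, in order.
#'
#' @param table a [BandPowerTable-class].
#' @param label colData column holding the class label
#'   (default `"task_type"`).
#' @param seed RNG seed.
#' @return the subset [BandPowerTable-class], epochs in original order.
#' @export
balanceClasses <- function(table, label = "task_type", seed = NULL) {
  y <- table_labels(table, label)
  counts <- table(y)
  if (length(counts) < 2L) stopf("need at least two classes to balance")
  if (any(counts == 0L))
    stopf("class with zero rows: %s",
          paste(names(counts)[counts == 0], collapse = ", "))
  m <- min(counts)
  if (all(counts == m)) return(table)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(y == cl)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
  })
  table[, sort(keep)]
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, so fold class proportions match the table's
# within one sample.
stratified_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Gaussian discriminant fit. QDA: class-specific covariance; LDA: pooled.
# Equal priors (classes are balanced upstream). Numerically singular
# covariances receive a ridge of 1e-6 * trace/dim (escalated tenfold while
# needed), logged via message().
fit_gaussian_discriminant <- function(X, y, kind = c("qda", "lda")) {
  kind <- match.arg(kind)
  classes <- sort(unique(y))
  d <- ncol(X)
  mu <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  regularize <- function(S) {
    ridge <- 1e-6 * sum(diag(S)) / d
    tries <- 0L
    repeat {
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (!is.null(ch)) return(list(chol = ch, ridged = tries > 0L))
      tries <- tries + 1L
      if (tries > 8L) stopf("covariance irreparably singular")
      S <- S + diag(ridge * 10^(tries - 1L), d)
    }
  }
  if (kind == "qda") {
    covs <- lapply(classes, function(cl) {
      Xi <- X[y == cl, , drop = FALSE]
      cov(Xi)
    })
    reg <- lapply(covs, regularize)
    if (any(vapply(reg, `[[`, TRUE, "ridged")))
      message("fit_gaussian_discriminant: singular class covariance, ridge fallback applied")
    list(kind = kind, classes = classes, mu = mu,
         chol = lapply(reg, `[[`, "chol"))
  } else {
    # pooled within-class covariance
    Sp <- matrix(0, d, d)
    for (cl in classes) {
      Xi <- X[y == cl, , drop = FALSE]
      Sp <- Sp + cov(Xi) * (nrow(Xi) - 1L)
    }
    Sp <- Sp / (nrow(X) - length(classes))
    reg <- regularize(Sp)
    if (reg$ridged)
      message("fit_gaussian_discriminant: singular pooled covariance, ridge fallback applied")
    list(kind = kind, classes = classes, mu = mu,
         chol = rep(list(reg$chol), length(classes)))
  }
}

# Maximum-posterior prediction under equal priors; posterior ties broken
# by the lowest class index (which.max takes the first maximum).
predict_gaussian_discriminant <- function(model, X) {
  n <- nrow(X)
  scores <- matrix(0, n, length(model$classes))
  for (k in seq_along(model$classes)) {
    ch <- model$chol[[k]]
    dev <- sweep(X, 2, model$mu[[k]])
    z <- forwardsolve(t(ch), t(dev))
    maha <- colSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    scores[, k] <- -0.5 * (logdet + maha)
  }
  model$classes[apply(scores, 1, which.max)]
}

# One full stratified CV; returns fold accuracies and pooled predictions.
cv_discriminant <- function(X, y, kind, k_folds, seed = NULL) {
  fold <- stratified_folds(y, k_folds, seed)
  pred <- character(length(y))
  acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    te <- fold == f
    model <- fit_gaussian_discriminant(X[!te, , drop = FALSE], y[!te], kind)
    pred[te] <- predict_gaussian_discriminant(model, X[te, , drop = FALSE])
    acc[f] <- mean(pred[te] == y[te])
  }
  list(fold_accuracies = acc, predictions = pred)
}

#' Cross-validated Gaussian discriminant evaluation
#'
#' Stratified k-fold evaluation of a QDA (class-specific covariance) or
#' LDA (pooled covariance) classifier with equal priors; prediction is the
#' maximum-posterior class, ties broken deterministically by the lowest
#' class index. Reports per-fold accuracies and the row-normalized
#' confusion matrix over pooled held-out predictions.
#'
#' @param table a balanced [BandPowerTable-class].
#' @param modelKind `"qda"` or `"lda"`.
#' @param kFolds folds (default 10).
#' @param label colData column with the class label.
#' @param seed RNG seed for fold assignment.
#' @return a [ClassifierReport-class] (no permutation null; see
#'   [permutationChance()]).
#' @export
fitEvalDiscriminant <- function(table, modelKind = c("qda", "lda"),
                                kFolds = 10L, label = "task_type",
                                seed = NULL) {
  modelKind <- match.arg(modelKind)
  X <- table_features(table)
  if (!all(is.finite(X))) stopf("non-finite feature values")
  y <- table_labels(table, label)
  counts <- table(y)
  if (any(counts < kFolds))
    stopf("fewer rows (%d) than folds (%d) for class %s",
          min(counts), kFolds, names(counts)[which.min(counts)])
  res <- cv_discriminant(X, y, modelKind, kFolds, seed)
  classes <- sort(unique(y))
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(y)) cm[y[i], res$predictions[i]] <-
      cm[y[i], res$predictions[i]] + 1
  rs <- rowSums(cm)
  cm[rs > 0, ] <- cm[rs > 0, , drop = FALSE] / rs[rs > 0]
  day <- unique(SummarizedExperiment::colData(table)$day_index)
  new("ClassifierReport", modelKind = modelKind, classes = classes,
      foldAccuracies = res$fold_accuracies,
      meanAccuracy = mean(res$fold_accuracies), confusion = cm,
      nullAccuracies = numeric(), pVsChance = NA_real_,
      featureSpec = list(features = colnames(X), label = label),
      dayIndex = if (length(day) == 1L) as.integer(day) else NA_integer_)
}

#' Shuffled-label permutation null
#'
#' Re-runs the full cross-validated evaluation `nPermutations` times with
#' class labels randomly shuffled, giving the chance distribution of mean
#' accuracy for this exact data set and pipeline.
#'
#' @inheritParams fitEvalDiscriminant
#' @param nPermutations number of label shuffles (1000 in the study
#'   design).
#' @param seed RNG seed; draws are reproducible and independent per
#'   permutation.
#' @return numeric vector of `nPermutations` null mean accuracies.
#' @export
permutationChance <- function(table, modelKind = c("qda", "lda"),
                              kFolds = 10L, nPermutations = 1000L,
                              label = "task_type", seed = NULL) {
  modelKind <- match.arg(modelKind)
  X <- table_features(table)
  y <- table_labels(table, label)
  with_seed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      ys <- sample(y)
      mean(cv_discriminant(X, ys, modelKind, kFolds)$fold_accuracies)
    }, numeric(1))
  })
}

#' Attach a permutation null to a report
#'
#' Convenience wrapper: evaluates the classifier and its permutation
#' chance, storing the empirical p-value
#' `(1 + #(null >= observed)) / (nPermutations + 1)`.
#'
#' @inheritParams permutationChance
#' @return a [ClassifierReport-class] with `nullAccuracies` and
#'   `pVsChance` filled.
#' @export
evaluateWithChance <- function(table, modelKind = c("qda", "lda"),
                               kFolds = 10L, nPermutations = 1000L,
                               label = "task_type", seed = NULL) {
  modelKind <- match.arg(modelKind)
  rep <- fitEvalDiscriminant(table, modelKind, kFolds, label, seed)
  null <- permutationChance(table, modelKind, kFolds, nPermutations, label,
                            seed = if (is.null(seed)) NULL else seed + 1L)
  rep@nullAccuracies <- null
  rep@pVsChance <- (1 + sum(null >= rep@meanAccuracy)) /
    (length(null) + 1)
  validObject(rep)
  rep
}

#' Compare per-day accuracies
#'
#' Paired (or one-sample, when `b` has length one) t-test across days with
#' Bonferroni correction. The degenerate zero-variance case is handled by
#' a documented rule: identical vectors give t = 0, p = 1; a constant
#' non-zero shift gives p = 0 with `degenerate = TRUE`.
#'
#' @param a numeric vector of per-day accuracies.
#' @param b per-day accuracies (paired) or a single reference value.
#' @param paired paired test (requires equal lengths).
#' @param nComparisons Bonferroni multiplier.
#' @return list with `statistic`, `p_raw`, `p_corrected`, `degenerate`.
#' @export
compareAccuracy <- function(a, b, paired = TRUE, nComparisons = 1L) {
  if (length(b) == 1L) {
    diffs <- a - b
  } else {
    if (length(a) != length(b)) stopf("length mismatch for paired test")
    if (!paired)
      return({
        tt <- t.test(a, b)
        list(statistic = unname(tt$statistic), p_raw = tt$p.value,
             p_corrected = bonferroni(tt$p.value, nComparisons),
             degenerate = FALSE)
      })
    diffs <- a - b
  }
  if (sd(diffs) == 0) {
    if (all(diffs == 0))
      return(list(statistic = 0, p_raw = 1, p_corrected = 1,
                  degenerate = TRUE))
    return(list(statistic = sign(mean(diffs)) * Inf, p_raw = 0,
                p_corrected = 0, degenerate = TRUE))
  }
  tt <- t.test(diffs, mu = 0)
  list(statistic = unname(tt$statistic), p_raw = tt$p.value,
       p_corrected = bonferroni(tt$p.value, nComparisons),
       degenerate = FALSE)
}

#' Learning-stage split of recording days
#'
#' Early and late stages are the first and last thirds of days (floor
#' division); the middle takes the remainder. The three stages partition
#' the input.
#'
#' @param days vector of day indices (sorted internally).
#' @return list with `early`, `middle`, `late`.
#' @export
stageSplit <- function(days) {
  days <- sort(unique(days))
  n <- length(days)
  k <- n %/% 3L
  list(early = days[seq_len(k)],
       middle = if (n > 2 * k) days[(k + 1):(n - k)] else days[0],
       late = if (k > 0) days[(n - k + 1):n] else days[0])
}

#' @rdname runTaskTypeStudy
#' @export
defaultRoiCombos <- function() {
  list("M1", "DLPFC", "Cd", c("M1", "DLPFC"), c("M1", "Cd"),
       c("DLPFC", "Cd"), c("M1", "DLPFC", "Cd"))
}

combo_name <- function(combo) paste(combo, collapse = "+")

# Build the per-day feature tables for one event: manual + bmi event epochs
# plus (for 3-class) baseline windows matched in count, referenced per day,
# then balanced.
day_event_table <- function(day, event, config, threeClass,
                            m1DirectOnly = TRUE, seedOffset = 0L) {
  ref <- commonMedianReference(day[TASK_TYPES])
  names(ref) <- TASK_TYPES
  sets <- list(
    extractEventEpochs(ref$manual, event, config@windowWidth),
    extractEventEpochs(ref$bmi, event, config@windowWidth))
  n_task <- vapply(sets, nEpochs, 0L)
  if (threeClass) {
    nb <- min(n_task)
    sets[[3]] <- sampleBaselineEpochs(
      ref$baseline, nb, config@windowWidth,
      seed = derive_seed(config@seed, "baseline-windows",
                         day$baseline@dayIndex, event) + seedOffset)
  }
  tab <- buildFeatureTable(sets, rois = roi_levels(),
                           m1DirectOnly = m1DirectOnly)
  balanceClasses(tab, "task_type",
                 seed = derive_seed(config@seed, "balance",
                                    day$manual@dayIndex, event) + seedOffset)
}

#' Run the task-type classification study
#'
#' For each day and event (go cue, target acquisition), builds channel
#' -averaged band-power features for every requested ROI combination,
#' balances classes, and evaluates a stratified tenfold QDA: the 3-class
#' variant distinguishes BMI control, manual control and baseline; the
#' 2-class variant distinguishes BMI from manual control only. Summaries
#' are ranked by ascending accuracy within day and event.
#'
#' @param days list of complete day triples (each `list(manual, baseline,
#'   bmi)` of raw [SessionRecord-class]; referencing is applied
#'   internally).
#' @param roiCombos list of ROI character vectors (default: singletons,
#'   pairs and the full triple).
#' @param config a [StudyConfig-class].
#' @param nClasses 3 or 2.
#' @param events events to analyze.
#' @param nPermutations permutation draws per model (0 to skip chance
#'   calibration).
#' @return list with `summary` (data.frame: day_index, event, combo,
#'   mean_accuracy, null_mean, p_vs_chance, rank) and `reports` (nested
#'   list of [ClassifierReport-class]).
#' @export
runTaskTypeStudy <- function(days, roiCombos = defaultRoiCombos(),
                             config = studyConfig(),
                             nClasses = 3L,
                             events = c("go_cue", "target_acq"),
                             nPermutations = 0L) {
  stopifnot(nClasses %in% c(2L, 3L))
  rows <- list(); reports <- list()
  for (day in days) {
    d <- day$manual@dayIndex
    for (ev in events) {
      tab <- day_event_table(day, ev, config, threeClass = nClasses == 3L)
      for (combo in roiCombos) {
        feat <- as.vector(t(outer(combo, names(config@bands), paste,
                                  sep = ".")))
        sub <- tab[feat, ]
        rep <- if (nPermutations > 0L)
          evaluateWithChance(sub, "qda", config@cvFolds, nPermutations,
                             seed = derive_seed(config@seed, "cv", d, ev,
                                                combo_name(combo)))
        else
          fitEvalDiscriminant(sub, "qda", config@cvFolds,
                              seed = derive_seed(config@seed, "cv", d, ev,
                                                 combo_name(combo)))
        rep@featureSpec <- list(rois = combo, event = ev,
                                n_classes = nClasses)
        reports[[sprintf("day%03d.%s.%s", d, ev, combo_name(combo))]] <- rep
        rows[[length(rows) + 1L]] <- data.frame(
          day_index = d, event = ev, combo = combo_name(combo),
          mean_accuracy = rep@meanAccuracy,
          null_mean = if (length(rep@nullAccuracies))
            mean(rep@nullAccuracies) else NA_real_,
          p_vs_chance = rep@pVsChance)
      }
    }
  }
  summary <- do.call(rbind, rows)
  summary$rank <- ave(summary$mean_accuracy,
                      summary$day_index, summary$event,
                      FUN = function(x) rank(x, ties.method = "first"))
  summary <- summary[order(summary$day_index, summary$event,
                           summary$rank), ]
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}

#' Run the target-direction classification study
#'
#' 8-class LDA per control type (BMI and manual separately). The first
#' five recording days are excluded; within each remaining day, trial
#' counts are matched per direction across the two control types before
#' fitting. Days where any direction lacks successful trials in either
#' control type are skipped (with a message).
#'
#' @inheritParams runTaskTypeStudy
#' @return list with `summary` (day_index, event, control, combo,
#'   mean_accuracy) and `reports`.
#' @export
runTargetDirectionStudy <- function(days, roiCombos = defaultRoiCombos(),
                                    config = studyConfig(),
                                    events = c("go_cue", "target_acq")) {
  day_idx <- vapply(days, function(d) d$manual@dayIndex, 0L)
  if (length(day_idx) < 6L)
    stopf("target-direction study needs at least 6 days (first 5 excluded)")
  keep <- order(day_idx)[-(1:5)]
  rows <- list(); reports <- list()
  for (di in keep) {
    day <- days[[di]]
    d <- day$manual@dayIndex
    ref <- commonMedianReference(day[TASK_TYPES])
    names(ref) <- TASK_TYPES
    for (ev in events) {
      sets <- list(manual = extractEventEpochs(ref$manual, ev,
                                               config@windowWidth),
                   bmi = extractEventEpochs(ref$bmi, ev,
                                            config@windowWidth))
      # match trial counts per direction across control types
      counts <- lapply(sets, function(es) {
        tabulate(es@info$target_direction + 1L, nbins = 8L)
      })
      per_dir <- pmin(counts$manual, counts$bmi)
      if (any(per_dir == 0L)) {
        message(sprintf(
          "day %d (%s): direction(s) %s lack successful trials in one control type; day skipped",
          d, ev, paste(which(per_dir == 0L) - 1L, collapse = ", ")))
        next
      }
      sel <- lapply(sets, function(es) {
        idx <- with_seed(derive_seed(config@seed, "dirmatch", d, ev,
                                     es@info$task_type[1]), {
          unlist(lapply(0:7, function(dd) {
            cand <- which(es@info$target_direction == dd)
            sort(sample(cand, per_dir[dd + 1L]))
          }))
        })
        sort(idx)
      })
      for (ct in c("manual", "bmi")) {
        es <- sets[[ct]]
        idx <- sel[[ct]]
        sub <- epoch_set(es@data[, , idx, drop = FALSE],
                         es@info[idx, ], es@samplingRate,
                         es@windowWidth, es@channelMap)
        tab <- buildFeatureTable(sub, rois = roi_levels())
        # folds cannot exceed the matched per-direction trial count
        k_eff <- min(config@cvFolds, min(per_dir))
        if (k_eff < config@cvFolds)
          message(sprintf("day %d (%s, %s): %d-fold CV (sparse directions)",
                          d, ev, ct, k_eff))
        for (combo in roiCombos) {
          feat <- as.vector(t(outer(combo, names(config@bands), paste,
                                    sep = ".")))
          rep <- fitEvalDiscriminant(tab[feat, ], "lda", k_eff,
                                     label = "target_direction",
                                     seed = derive_seed(config@seed, "cv8",
                                                        d, ev, ct,
                                                        combo_name(combo)))
          rep@featureSpec <- list(rois = combo, event = ev, control = ct)
          reports[[sprintf("day%03d.%s.%s.%s", d, ev, ct,
                           combo_name(combo))]] <- rep
          rows[[length(rows) + 1L]] <- data.frame(
            day_index = d, event = ev, control = ct,
            combo = combo_name(combo), mean_accuracy = rep@meanAccuracy)
        }
      }
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(day_index = integer(), event = character(),
               control = character(), combo = character(),
               mean_accuracy = numeric())
  list(summary = summary, reports = reports)
}
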