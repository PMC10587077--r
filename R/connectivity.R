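# Bivariate Granger causality with BIC order selection, cross-task
# artifact null, and baseline-normalized directed network summaries.

ordered_pairs <- function() {
  rois <- roi_levels()
  out <- expand.grid(source = rois, target = rois,
                     stringsAsFactors = FALSE)
  out[out$source != out$target, c("source", "target")]
}

# lagged design matrix: columns x[t-1..t-p] (and y lags when given)
lag_design <- function(x, y = NULL, p) {
  n <- length(x)
  resp <- x[(p + 1):n]
  lags <- function(v) {
    m <- matrix(0, n - p, p)
    for (k in seq_len(p)) m[, k] <- v[(p + 1 - k):(n - k)]
    m
  }
  X <- lags(x)
  if (!is.null(y)) X <- cbind(X, lags(y))
  list(y = resp, X = X)
}

# residual sum of squares of least-squares fits from precomputed
# cross-products; cols selects the regressor subset
rss_from_gram <- function(G, c_xy, yy, cols) {
  Gs <- G[cols, cols, drop = FALSE]
  cs <- c_xy[cols]
  ch <- tryCatch(chol(Gs), error = function(e)
    stopf("rank-deficient regression matrix in Granger fit"))
  b <- backsolve(ch, forwardsolve(t(ch), cs))
  yy - sum(cs * b)
}

# both directed G values of one pair from a single shared Gram matrix;
# z is a samples x 2 matrix (already de-meaned or not; de-meaned here)
granger_both <- function(z, p) {
  z <- sweep(z, 2, colMeans(z))
  a <- z[, 1]; b <- z[, 2]
  da <- lag_design(a, b, p)     # columns: a lags then b lags
  G <- crossprod(da$X)
  ya <- da$y
  yb <- b[(p + 1):length(b)]
  ca <- crossprod(da$X, ya)
  cb <- crossprod(da$X, yb)
  ia <- seq_len(p); ib <- p + seq_len(p)
  rss_a_full <- rss_from_gram(G, ca, sum(ya^2), c(ia, ib))
  rss_a_red <- rss_from_gram(G, ca, sum(ya^2), ia)
  rss_b_full <- rss_from_gram(G, cb, sum(yb^2), c(ia, ib))
  rss_b_red <- rss_from_gram(G, cb, sum(yb^2), ib)
  c(max(log(rss_a_red / rss_a_full), 0),    # G_{b -> a}
    max(log(rss_b_red / rss_b_full), 0))    # G_{a -> b}
}

#' Granger causality for one directed pair
#'
#' Fits two least-squares autoregressions of the target series `x`: the
#' reduced model on `p` of its own lags, and the full model adding `p`
#' lags of the source series `y`. The statistic is the Geweke log
#' residual-variance ratio
#' \deqn{G_{y \to x} = \ln(\mathrm{RSS}_{reduced} / \mathrm{RSS}_{full})}
#' over the shared estimation sample, which is non-negative up to
#' numerical tolerance. Both series are de-meaned before fitting.
#'
#' @param x numeric target series.
#' @param y numeric source series (same length).
#' @param p autoregressive order (lags per series).
#' @return the scalar G value.
#' @export
grangerPair <- function(x, y, p) {
  if (length(x) != length(y)) stopf("series lengths differ")
  if (length(x) < 3 * p + 3)
    stopf("series too short (%d) for order %d", length(x), p)
  x <- x - mean(x); y <- y - mean(y)
  full <- lag_design(x, y, p)
  G <- crossprod(full$X)
  cx <- crossprod(full$X, full$y)
  yy <- sum(full$y^2)
  rss_full <- rss_from_gram(G, cx, yy, seq_len(2 * p))
  rss_red <- rss_from_gram(G, cx, yy, seq_len(p))
  g <- log(rss_red / rss_full)
  if (g < -1e-10) stopf("negative Granger statistic beyond tolerance")
  max(g, 0)
}

#' Select the AR order by BIC
#'
#' Fits bivariate vector autoregressions of order 1..`pMax` to each
#' segment over a common estimation sample and returns the order
#' minimizing the mean Bayesian information criterion,
#' `N log det(Sigma) + k log N` with `k = 4p` coefficients.
#'
#' @param segments list of two-column matrices (paired ROI series).
#' @param pMax largest candidate order.
#' @return the selected integer order.
#' @export
selectArOrder <- function(segments, pMax) {
  len <- nrow(segments[[1]])
  if (len <= pMax + 10) stopf("segments too short for pMax = %d", pMax)
  bic <- matrix(0, length(segments), pMax)
  for (s in seq_along(segments)) {
    z <- segments[[s]]
    z <- sweep(z, 2, colMeans(z))
    for (p in seq_len(pMax)) {
      # common sample t = pMax+1 .. len so BICs are comparable across p
      n <- len - pMax
      resp <- z[(pMax + 1):len, , drop = FALSE]
      X <- matrix(0, n, 2 * p)
      for (k in seq_len(p))
        X[, c(2 * k - 1, 2 * k)] <- z[(pMax + 1 - k):(len - k), ]
      E <- resp - X %*% qr.solve(X, resp)
      S <- crossprod(E) / n
      bic[s, p] <- n * determinant(S)$modulus + 4 * p * log(n)
    }
  }
  which.min(colMeans(bic))
}

#' Cross-task artifact null for Granger causality
#'
#' Pairs a target segment recorded during one task (the baseline rest
#' period) with a source segment recorded at a different time during
#' another task, so that any apparent interaction is spurious by
#' construction; `nPairs` random pairings give the null distribution of G
#' for a directed pair.
#'
#' @param targetSegments list of numeric target-ROI series (baseline
#'   windows).
#' @param sourceSegments list of numeric source-ROI series (task
#'   windows).
#' @param p AR order.
#' @param nPairs number of random pairings.
#' @param seed RNG seed.
#' @return numeric vector of `nPairs` null G values.
#' @export
artifactNull <- function(targetSegments, sourceSegments, p, nPairs,
                         seed = NULL) {
  if (!length(targetSegments) || !length(sourceSegments))
    stopf("need non-empty segment sets")
  lt <- lengths(targetSegments); ls <- lengths(sourceSegments)
  if (length(unique(c(lt, ls))) != 1L)
    stopf("all segments must share one length (got %s)",
          paste(unique(c(lt, ls)), collapse = ", "))
  with_seed(seed, {
    i <- sample.int(length(targetSegments), nPairs, replace = TRUE)
    j <- sample.int(length(sourceSegments), nPairs, replace = TRUE)
    vapply(seq_len(nPairs), function(k)
      grangerPair(targetSegments[[i[k]]], sourceSegments[[j[k]]], p),
      numeric(1))
  })
}

#' Baseline-normalized Granger causality
#'
#' `(G_task - G_baseline) / G_baseline`: positive values indicate an
#' increase of directed interaction relative to the baseline rest period,
#' negative values a decrease.
#'
#' @param gTask per-day mean G during the task.
#' @param gBaseline per-day mean G during baseline (> 0).
#' @return normalized G (same length as the inputs).
#' @export
normalizeGc <- function(gTask, gBaseline) {
  if (any(gBaseline <= 0)) stopf("degenerate baseline G (<= 0)")
  (gTask - gBaseline) / gBaseline
}

#' Net normalized Granger causality
#'
#' Difference of the normalized values of a reciprocal pair:
#' `net(a->b) = norm(a->b) - norm(b->a)`; antisymmetric under direction
#' swap. The sign gives the predominant direction of task-specific
#' information flow.
#'
#' @param normAb,normBa normalized G for the two directions of a pair.
#' @return net value for the a-to-b direction.
#' @export
netNormalizedGc <- function(normAb, normBa) normAb - normBa

#' Across-day directionality test
#'
#' One-sample t-test of per-day net normalized G against zero, Bonferroni
#' corrected. Zero variance across days is flagged as degenerate (all
#' zeros: not directed, p = 1; constant non-zero: directed, p reported
#' as 0).
#'
#' @param netValues per-day net normalized G for one direction.
#' @param nComparisons Bonferroni multiplier.
#' @param alpha significance level after correction.
#' @return list with `statistic`, `p_raw`, `p_corrected`, `directed`,
#'   `degenerate`.
#' @export
directionalityTest <- function(netValues, nComparisons = 1L, alpha = 0.05) {
  if (length(netValues) < 2L) stopf("need net values from >= 2 days")
  if (sd(netValues) == 0) {
    if (all(netValues == 0))
      return(list(statistic = 0, p_raw = 1, p_corrected = 1,
                  directed = FALSE, degenerate = TRUE))
    return(list(statistic = sign(mean(netValues)) * Inf, p_raw = 0,
                p_corrected = 0, directed = TRUE, degenerate = TRUE))
  }
  tt <- t.test(netValues, mu = 0)
  pc <- bonferroni(tt$p.value, nComparisons)
  list(statistic = unname(tt$statistic), p_raw = tt$p.value,
       p_corrected = pc, directed = pc < alpha, degenerate = FALSE)
}

# channel-averaged ROI series of a (referenced) session
roi_series <- function(session, m1DirectOnly = TRUE) {
  cmap <- session@channelMap
  out <- matrix(0, 3, ncol(session@lfp),
                dimnames = list(roi_levels(), NULL))
  for (r in roi_levels()) {
    sel <- cmap$roi == r
    if (r == "M1" && m1DirectOnly && any(cmap$direct_unit))
      sel <- sel & cmap$direct_unit
    if (!any(sel)) stopf("no eligible channels for ROI '%s'", r)
    out[r, ] <- colMeans(session@lfp[sel, , drop = FALSE])
  }
  out
}

# event-locked ROI segment list: one samples x 3 matrix per window
roi_event_segments <- function(session, event, width, m1DirectOnly) {
  rs <- roi_series(session, m1DirectOnly)
  fs <- session@samplingRate
  win <- round(width * fs)
  tr <- session@trials
  keep <- which(tr$success)
  segs <- list()
  for (i in keep) {
    t0 <- if (event == "go_cue") tr$go_cue_time[i]
          else tr$target_acquired_time[i] - width
    i0 <- floor(t0 * fs) + 1L
    if (i0 >= 1L && i0 + win - 1L <= ncol(rs))
      segs[[length(segs) + 1L]] <- t(rs[, i0:(i0 + win - 1L)])
  }
  segs
}

roi_baseline_segments <- function(session, n, width, m1DirectOnly, seed) {
  rs <- roi_series(session, m1DirectOnly)
  fs <- session@samplingRate
  win <- round(width * fs)
  max_n <- floor(ncol(rs) / win)
  n <- min(n, max_n)
  with_seed(seed, {
    slack <- ncol(rs) - n * win
    u <- sort(runif(n))
    gaps <- floor(diff(c(0, u)) * slack)
    starts <- cumsum(gaps) + (seq_len(n) - 1L) * win + 1L
    lapply(starts, function(s) t(rs[, s:(s + win - 1L)]))
  })
}

#' Run the directed-connectivity study
#'
#' Per day: channel-averaged ROI series are segmented into the 500 ms
#' windows after the go cue and before target acquisition on successful
#' trials (and matched random non-overlapping baseline windows); segment
#' -wise Granger causality is computed for all six ordered ROI pairs and
#' each task type; each (direction, task) day mean is compared to the
#' cross-task artifact null (unpaired t-test); normalized and net
#' normalized values are formed against the day's baseline; and each
#' direction's net values are tested across days with Bonferroni
#' correction.
#'
#' The baseline G entering the normalization is computed once per day and
#' direction (baseline windows carry no task events) and is shared by
#' both events.
#'
#' @param days list of complete day triples (raw sessions; referencing is
#'   applied internally).
#' @param config a [StudyConfig-class]; `arOrder` sets p (13 by
#'   default).
#' @param events events to analyze.
#' @param taskTypes control types to contrast with baseline.
#' @param m1DirectOnly restrict M1 averaging to direct-unit channels.
#' @param nComparisons Bonferroni multiplier for the directionality
#'   tests; defaults to the number of unique (pair, task, event) tests.
#' @return a [GCNetwork-class].
#' @export
runConnectivityStudy <- function(days, config = studyConfig(),
                                 events = c("go_cue", "target_acq"),
                                 taskTypes = c("bmi", "manual"),
                                 m1DirectOnly = TRUE,
                                 nComparisons = NULL) {
  p <- config@arOrder
  width <- config@windowWidth
  dirs <- ordered_pairs()
  est <- list(); norm <- list(); net <- list()
  for (day in days) {
    d <- day$manual@dayIndex
    ref <- commonMedianReference(day[TASK_TYPES])
    names(ref) <- TASK_TYPES
    task_segs <- list()
    for (tt in taskTypes) for (ev in events)
      task_segs[[paste(tt, ev)]] <-
        roi_event_segments(ref[[tt]], ev, width, m1DirectOnly)
    n_per_task <- vapply(taskTypes, function(tt)
      length(task_segs[[paste(tt, events[1])]]), 0L)
    nb <- max(1L, min(n_per_task))
    base_segs <- roi_baseline_segments(
      ref$baseline, nb, width, m1DirectOnly,
      seed = derive_seed(config@seed, "gc-baseline", d))

    pairs_u <- list(c("M1", "DLPFC"), c("M1", "Cd"), c("DLPFC", "Cd"))
    for (pr in pairs_u) {
      a <- pr[1]; b <- pr[2]
      # granger_both returns c(G_{b->a}, G_{a->b}) per segment
      g_base <- vapply(base_segs, function(s)
        granger_both(s[, c(a, b)], p), numeric(2))
      base_mean <- c(mean(g_base[1, ]), mean(g_base[2, ]))
      srcs <- c(b, a); tgts <- c(a, b)
      for (k in 1:2)
        est[[length(est) + 1L]] <- data.frame(
          day_index = d, source = srcs[k], target = tgts[k],
          task_type = "baseline", event = "baseline",
          mean_g = base_mean[k], n_segments = ncol(g_base),
          null_mean = NA_real_, p_vs_null = NA_real_)
      for (tt in taskTypes) for (ev in events) {
        segs <- task_segs[[paste(tt, ev)]]
        if (!length(segs)) next
        g <- vapply(segs, function(s)
          granger_both(s[, c(a, b)], p), numeric(2))
        for (k in 1:2) {
          src <- srcs[k]; tgt <- tgts[k]
          null <- artifactNull(
            lapply(base_segs, function(s) s[, tgt]),
            lapply(segs, function(s) s[, src]),
            p, nPairs = length(segs),
            seed = derive_seed(config@seed, "gc-null", d, src, tgt, tt, ev))
          pv <- if (ncol(g) > 1 && length(null) > 1)
            t.test(g[k, ], null)$p.value else NA_real_
          est[[length(est) + 1L]] <- data.frame(
            day_index = d, source = src, target = tgt, task_type = tt,
            event = ev, mean_g = mean(g[k, ]), n_segments = ncol(g),
            null_mean = mean(null), p_vs_null = pv)
          norm[[length(norm) + 1L]] <- data.frame(
            day_index = d, source = src, target = tgt, task_type = tt,
            event = ev,
            normalized_g = normalizeGc(mean(g[k, ]), base_mean[k]))
        }
      }
    }
  }
  est <- do.call(rbind, est)
  norm <- do.call(rbind, norm)
  # net values: difference of reciprocal normalized values
  for (i in seq_len(nrow(norm))) {
    rev <- norm$source == norm$target[i] & norm$target == norm$source[i] &
      norm$task_type == norm$task_type[i] & norm$event == norm$event[i] &
      norm$day_index == norm$day_index[i]
    if (any(rev))
      net[[length(net) + 1L]] <- data.frame(
        day_index = norm$day_index[i], source = norm$source[i],
        target = norm$target[i], task_type = norm$task_type[i],
        event = norm$event[i],
        net_g = netNormalizedGc(norm$normalized_g[i],
                                norm$normalized_g[which(rev)[1]]))
  }
  net <- do.call(rbind, net)

  groups <- unique(net[c("source", "target", "task_type", "event")])
  if (is.null(nComparisons)) {
    pairs_u <- unique(t(apply(as.matrix(groups[c("source", "target")]), 1,
                              sort)))
    nComparisons <- nrow(pairs_u) *
      nrow(unique(groups[c("task_type", "event")]))
  }
  directed <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- net$source == groups$source[i] & net$target == groups$target[i] &
      net$task_type == groups$task_type[i] & net$event == groups$event[i]
    vals <- net$net_g[sel]
    res <- if (length(vals) >= 2L)
      directionalityTest(vals, nComparisons, config@alpha)
    else list(statistic = NA_real_, p_raw = NA_real_,
              p_corrected = NA_real_, directed = FALSE, degenerate = TRUE)
    directed[[i]] <- data.frame(
      source = groups$source[i], target = groups$target[i],
      task_type = groups$task_type[i], event = groups$event[i],
      mean_net = mean(vals), n_days = length(vals),
      statistic = res$statistic, p_raw = res$p_raw,
      p_corrected = res$p_corrected,
      significant = isTRUE(res$directed) && mean(vals) > 0)
  }
  directed <- do.call(rbind, directed)
  new("GCNetwork", estimates = est, normalized = norm, net = net,
      directed = directed, arOrder = as.integer(p))
}
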