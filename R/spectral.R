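# Welch band power, ROI averaging, feature tables.

# Welch PSD for a channels x samples matrix: Hann-windowed, 50%-overlap
# segments of `seg` samples, per-segment demeaning, one-sided density.
# Returns list(freq, psd = channels x nfreq). A 500-sample epoch at 1 kHz
# yields three averaged 250-sample segments and a 4 Hz frequency grid.
welch_psd <- function(x, fs, seg = min(250L, ncol(x))) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  seg <- as.integer(seg)
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  U <- sum(w^2)
  nf <- seg %/% 2L + 1L
  acc <- matrix(0, nrow(x), nf)
  for (s in starts) {
    segm <- x[, s:(s + seg - 1L), drop = FALSE]
    segm <- segm - rowMeans(segm)
    ft <- mvfft(t(segm * rep(w, each = nrow(segm))))
    pw <- Mod(ft[seq_len(nf), , drop = FALSE])^2
    acc <- acc + t(pw)
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist for even seg)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (seg %% 2L == 0L) dbl[nf] <- 1
  psd <- sweep(psd, 2, dbl, "*")
  list(freq = (seq_len(nf) - 1L) * fs / seg, psd = psd)
}

#' Welch band power per channel
#'
#' Integrates the Welch power-spectral-density estimate over each band's
#' half-open interval \code{[low, high)}. Estimator parameters: Hann
#' window, 250-sample segments (or the epoch length if shorter), 50
#' percent overlap, per-segment demeaning; a 500-sample epoch at 1 kHz
#' yields three averaged segments and a 4 Hz bin width, so the theta band
#' contains a single bin (its 4 Hz lower edge equals the resolution floor;
#' integration includes the first bin at or above each band's low edge).
#'
#' @param epoch channels x samples numeric matrix (one epoch).
#' @param fs sampling rate, Hz.
#' @param bands named list of \code{c(low, high)} pairs.
#' @return channels x bands matrix of non-negative band powers
#'   (signal-units squared).
#' @export
welchBandPower <- function(epoch, fs, bands = defaultBands()) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  if (any(hi > fs / 2))
    stopf("band edge(s) above Nyquist (%g Hz): %s", fs / 2,
          paste(names(bands)[hi > fs / 2], collapse = ", "))
  w <- welch_psd(epoch, fs)
  df <- w$freq[2] - w$freq[1]
  out <- matrix(0, nrow(epoch), length(bands),
                dimnames = list(rownames(epoch), names(bands)))
  for (b in seq_along(bands)) {
    sel <- w$freq >= bands[[b]][1] & w$freq < bands[[b]][2]
    out[, b] <- rowSums(w$psd[, sel, drop = FALSE]) * df
  }
  out
}

#' Average band power across channels within each region
#'
#' Arithmetic mean over member channels per band. For M1, when
#' `m1DirectOnly` is TRUE (the default, matching the convention that M1
#' analyses use the channels recording the decoder's direct units), only
#' channels flagged `direct_unit` enter the average.
#'
#' @param perChannel channels x bands matrix from [welchBandPower()].
#' @param channelMap channel map aligned with the rows of `perChannel`.
#' @param rois regions to average (default: all present).
#' @param m1DirectOnly restrict M1 to direct-unit channels.
#' @return rois x bands matrix.
#' @export
roiAverage <- function(perChannel, channelMap,
                       rois = intersect(roi_levels(), unique(channelMap$roi)),
                       m1DirectOnly = TRUE) {
  out <- matrix(0, length(rois), ncol(perChannel),
                dimnames = list(rois, colnames(perChannel)))
  for (r in rois) {
    sel <- channelMap$roi == r
    if (r == "M1" && m1DirectOnly && any(channelMap$direct_unit))
      sel <- sel & channelMap$direct_unit
    if (!any(sel))
      stopf("no eligible channels for ROI '%s'", r)
    out[r, ] <- colMeans(perChannel[sel, , drop = FALSE])
  }
  out
}

#' Build a band-power feature table from epoch sets
#'
#' For every epoch: per-channel Welch band power, then ROI averaging
#' (optionally then normalization to each ROI's total power) -- this
#' per-channel-power-first order is the single canonical path used
#' everywhere in the package. Features are 5 bands per ROI, so tables carry
#' 5 to 15 feature rows for one to three ROIs.
#'
#' @param epochSets an [EpochSet-class] or list of them (concatenated in
#'   order).
#' @param rois character subset of M1/DLPFC/Cd.
#' @param bands band definitions.
#' @param normalized divide each ROI's band powers by their sum per epoch
#'   (used for descriptive power summaries; classifier features default to
#'   un-normalized power).
#' @param m1DirectOnly see [roiAverage()].
#' @return a [BandPowerTable-class] (features x epochs) whose `colData`
#'   carries the epoch labels.
#' @export
buildFeatureTable <- function(epochSets, rois = roi_levels(),
                              bands = defaultBands(), normalized = FALSE,
                              m1DirectOnly = TRUE) {
  if (is(epochSets, "EpochSet")) epochSets <- list(epochSets)
  if (!length(epochSets) || all(vapply(epochSets, nEpochs, 0L) == 0L))
    stopf("no epochs to featurize")
  feat_names <- as.vector(t(outer(rois, names(bands), paste, sep = ".")))
  cols <- list(); infos <- list()
  for (es in epochSets) {
    n <- nEpochs(es)
    if (!n) next
    m <- matrix(0, length(feat_names), n)
    for (j in seq_len(n)) {
      pc <- welchBandPower(es@data[, , j, drop = TRUE], es@samplingRate,
                           bands)
      ra <- roiAverage(pc, es@channelMap, rois, m1DirectOnly)
      m[, j] <- as.vector(t(ra))   # roi-major, matching feat_names
    }
    cols[[length(cols) + 1L]] <- m
    infos[[length(infos) + 1L]] <- es@info
  }
  power <- do.call(cbind, cols)
  rownames(power) <- feat_names
  info <- do.call(rbind, infos)
  colnames(power) <- sprintf("epoch%04d", seq_len(ncol(power)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(power = power),
    colData = S4Vectors::DataFrame(info),
    metadata = list(bands = bands, rois = rois, normalized = FALSE))
  tab <- new("BandPowerTable", se)
  if (normalized) tab <- normalizeToTotal(tab)
  tab
}

#' Normalize band powers to each region's total power
#'
#' Divides every (ROI, band) entry by the sum of that ROI's band powers
#' within the same epoch, so each ROI's five fractions sum to 1 per epoch.
#'
#' @param table a [BandPowerTable-class].
#' @return a [BandPowerTable-class] of fractions.
#' @export
normalizeToTotal <- function(table) {
  power <- SummarizedExperiment::assay(table, "power")
  rois <- sub("\\..*$", "", rownames(power))
  for (r in unique(rois)) {
    sel <- rois == r
    tot <- colSums(power[sel, , drop = FALSE])
    if (any(tot <= 0))
      stopf("zero total power for ROI '%s' in epoch(s) %s", r,
            paste(which(tot <= 0), collapse = ", "))
    power[sel, ] <- sweep(power[sel, , drop = FALSE], 2, tot, "/")
  }
  SummarizedExperiment::assay(table, "power") <- power
  S4Vectors::metadata(table)$normalized <- TRUE
  table
}
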