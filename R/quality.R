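#' Moving standard deviation
#'
#' Sample (n-1) standard deviation over a centered sliding window. Edge
#' windows are truncated (minimum 2 samples) so the output aligns with the
#' time axis and has the input's length. Shift-invariant: adding a constant
#' to the series leaves the MSD unchanged.
#'
#' @param x Numeric vector.
#' @param window_s Window length in seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector, same length as `x`.
#' @export
moving_std <- function(x, window_s, fs) {
  n <- length(x)
  if (n < 2L) stop("series must have at least 2 samples")
  win <- round(window_s * fs)
  if (win < 2L) stop("window length must cover at least 2 samples")
  x <- x - mean(x)                       # centering for numerical stability
  half_lo <- (win - 1L) %/% 2L
  half_hi <- win %/% 2L
  lo <- pmax(1L, seq_len(n) - half_lo)
  hi <- pmin(n, seq_len(n) + half_hi)
  # widen one-sample edge windows to the 2-sample minimum
  short <- (hi - lo) < 1L
  lo[short] <- pmax(1L, hi[short] - 1L)
  short <- (hi - lo) < 1L
  hi[short] <- pmin(n, lo[short] + 1L)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  m <- hi - lo + 1L
  s1 <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s1^2 / m) / (m - 1L)
  sqrt(pmax(v, 0))
}

# Flag indices where msd exceeds mean(msd) + threshold_sd * sd(msd) (or an
# absolute threshold), merged into [start, end] sample segments.
.flag_segments <- function(msd, threshold_sd, threshold_abs = NULL) {
  thr <- if (!is.null(threshold_abs)) threshold_abs
         else mean(msd) + threshold_sd * stats::sd(msd)
  flagged <- which(msd > thr)
  .runs_to_segments(flagged)
}

.runs_to_segments <- function(idx) {
  if (length(idx) == 0L) return(matrix(0L, 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  breaks <- which(diff(idx) > 1L)
  starts <- idx[c(1L, breaks + 1L)]
  ends <- idx[c(breaks, length(idx))]
  cbind(start = starts, end = ends)
}

.merge_segments <- function(segs, gap) {
  if (nrow(segs) <= 1L) return(segs)
  out <- segs[1L, , drop = FALSE]
  for (i in 2L:nrow(segs)) {
    if (segs[i, 1] - out[nrow(out), 2] <= gap) {
      out[nrow(out), 2] <- segs[i, 2]
    } else out <- rbind(out, segs[i, , drop = FALSE])
  }
  out
}

#' Detect motion artifacts with the moving-standard-deviation rule
#'
#' Computes the per-channel MSD and flags samples where it exceeds
#' mean(MSD) + `threshold_sd` * sd(MSD) (the default rule), or an absolute
#' MSD threshold when `threshold_abs` is given. Contiguous flagged samples
#' are merged into segments. Defaults: 2 s window, 5 standard deviations.
#'
#' @param x Numeric matrix (channels x time) or vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 2).
#' @param threshold_sd Threshold multiplier (default 5).
#' @param threshold_abs Optional absolute MSD threshold overriding the rule.
#' @return An `artifact_scan`: list with `msd` (channels x time), `segments`
#'   (per-channel matrix of [start, end] sample indices), `window_s`,
#'   `threshold_sd`, and `flagged_fraction` (per channel).
#' @export
detect_motion <- function(x, fs, window_s = 2, threshold_sd = 5,
                          threshold_abs = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  n <- ncol(m)
  msd <- t(apply(m, 1L, moving_std, window_s = window_s, fs = fs))
  segments <- lapply(seq_len(nrow(m)), function(ch)
    .flag_segments(msd[ch, ], threshold_sd, threshold_abs))
  flagged_fraction <- vapply(segments, function(s)
    if (nrow(s) == 0L) 0 else sum(s[, 2] - s[, 1] + 1L) / n, 0)
  structure(list(msd = msd, segments = segments, window_s = window_s,
                 threshold_sd = threshold_sd, threshold_abs = threshold_abs,
                 flagged_fraction = flagged_fraction),
            class = "artifact_scan")
}

#' Per-channel signal-to-noise ratio of raw intensity
#'
#' SNR(c) = mean_t I(c, .) / sd_t I(c, .) with the sample (n-1) standard
#' deviation. A zero-variance channel gets `Inf` with a warning. Invariant
#' to multiplying a channel by a positive constant.
#'
#' @param rec A [raw_recording()] or a channels x time intensity matrix.
#' @return Numeric vector of SNR values, one per row.
#' @export
channel_snr <- function(rec) {
  intensity <- if (inherits(rec, "raw_recording")) rec$intensity else as.matrix(rec)
  if (ncol(intensity) < 2L) stop("need at least 2 time points for SNR")
  mu <- rowMeans(intensity)
  sd_ <- apply(intensity, 1L, stats::sd)
  if (any(sd_ == 0)) warning("zero-variance channel(s): ",
                             paste(which(sd_ == 0), collapse = ", "),
                             "; SNR reported as Inf")
  ifelse(sd_ == 0, Inf, mu / sd_)
}

#' Per-channel mean absolute correlation with the rest of the array
#'
#' A channel carrying mostly instrument noise correlates with nothing, so a
#' near-zero mean |r| against all other channels marks a low-SNR measurement.
#' Computed on a hemoglobin concentration signal.
#'
#' @param conc A [conc_series()] or a channels x time matrix.
#' @param signal Which signal to use: "hbo" (default), "hbr", or "hbt".
#' @return Numeric vector of mean |r| values in [0, 1], one per channel.
#'   Channels with zero variance are reported as 0 (their correlations are
#'   undefined) with a warning.
#' @export
correlation_quality <- function(conc, signal = c("hbo", "hbr", "hbt")) {
  signal <- match.arg(signal)
  m <- if (inherits(conc, "conc_series")) conc[[signal]] else as.matrix(conc)
  if (nrow(m) < 3L) stop("need >= 3 channels for the correlation check")
  sds <- apply(m, 1L, stats::sd)
  zero_var <- sds == 0
  if (any(zero_var)) warning("zero-variance channel(s): ",
                             paste(which(zero_var), collapse = ", "),
                             "; mean |r| reported as 0")
  r <- suppressWarnings(stats::cor(t(m)))
  diag(r) <- NA
  out <- rowMeans(abs(r), na.rm = TRUE)
  out[zero_var] <- 0
  # correlations *with* a zero-variance channel are undefined too
  if (any(zero_var)) {
    rr <- r; rr[, zero_var] <- NA
    out[!zero_var] <- rowMeans(abs(rr[!zero_var, , drop = FALSE]), na.rm = TRUE)
  }
  out
}

#' Quality-control report for one subject
#'
#' Combines the SNR check (raw intensity), the whole-brain correlation check
#' (concentration signal), and the motion check (MSD rule on the
#' concentration signal) into per-channel flags and a subject-level verdict.
#' The subject fails when the flagged-channel fraction exceeds
#' `channel_frac_max` or the motion-flagged time fraction exceeds
#' `time_frac_max`.
#'
#' @param rec A [raw_recording()].
#' @param conc A [conc_series()] for the same subject.
#' @param snr_min SNR floor (default 20).
#' @param corr_min Mean-|r| floor (default 0.05).
#' @param channel_frac_max Maximum tolerated fraction of flagged channels
#'   (default 0.2).
#' @param time_frac_max Maximum tolerated motion-flagged time fraction
#'   (default 0.2).
#' @param window_s,threshold_sd Motion-check MSD parameters (defaults 2 s, 5).
#' @param signal Concentration signal for the correlation and motion checks.
#' @return A `qc_report`: per-channel table (`snr`, `mean_abs_corr`,
#'   `motion_fraction`, `flagged`, `reasons`), `flagged_channels`,
#'   `subject_verdict` ("pass"/"fail") with `verdict_reasons`, and the
#'   thresholds used.
#' @export
qc_report <- function(rec, conc, snr_min = 20, corr_min = 0.05,
                      channel_frac_max = 0.2, time_frac_max = 0.2,
                      window_s = 2, threshold_sd = 5,
                      signal = c("hbo", "hbr", "hbt")) {
  signal <- match.arg(signal)
  stopifnot(inherits(rec, "raw_recording"), inherits(conc, "conc_series"))
  snr <- suppressWarnings(channel_snr(rec))
  # raw rows are per wavelength; take the worst wavelength per channel
  pairs <- measurement_channels(rec$probe)
  snr_ch <- vapply(pairs, function(i) min(snr[i]), 0)
  mac <- suppressWarnings(correlation_quality(conc, signal))
  scan <- detect_motion(conc[[signal]], conc$sampling_rate, window_s, threshold_sd)
  nch <- nrow(conc[[signal]])
  reasons <- vector("list", nch)
  for (ch in seq_len(nch)) {
    rs <- character(0)
    if (is.finite(snr_ch[ch]) && snr_ch[ch] < snr_min) rs <- c(rs, "low-snr")
    if (mac[ch] < corr_min) rs <- c(rs, "low-correlation")
    if (scan$flagged_fraction[ch] > time_frac_max) rs <- c(rs, "motion")
    reasons[[ch]] <- rs
  }
  flagged <- which(lengths(reasons) > 0L)
  channel_frac <- length(flagged) / nch
  time_frac <- mean(scan$flagged_fraction)
  verdict_reasons <- character(0)
  if (channel_frac > channel_frac_max)
    verdict_reasons <- c(verdict_reasons,
                         sprintf("flagged channel fraction %.2f > %.2f",
                                 channel_frac, channel_frac_max))
  if (time_frac > time_frac_max)
    verdict_reasons <- c(verdict_reasons,
                         sprintf("motion time fraction %.2f > %.2f",
                                 time_frac, time_frac_max))
  channels <- data.frame(
    channel = seq_len(nch), snr = snr_ch, mean_abs_corr = mac,
    motion_fraction = scan$flagged_fraction,
    flagged = lengths(reasons) > 0L,
    reasons = vapply(reasons, paste, "", collapse = ";"))
  structure(list(
    subject_id = rec$subject_id, channels = channels,
    flagged_channels = flagged,
    subject_verdict = if (length(verdict_reasons)) "fail" else "pass",
    verdict_reasons = verdict_reasons, motion_scan = scan,
    thresholds = list(snr_min = snr_min, corr_min = corr_min,
                      channel_frac_max = channel_frac_max,
                      time_frac_max = time_frac_max, window_s = window_s,
                      threshold_sd = threshold_sd, signal = signal)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for '%s': %s\n", x$subject_id, toupper(x$subject_verdict)))
  for (r in x$verdict_reasons) cat("  -", r, "\n")
  cat(sprintf("  %d/%d channel(s) flagged\n", length(x$flagged_channels),
              nrow(x$channels)))
  if (length(x$flagged_channels)) {
    bad <- x$channels[x$channels$flagged, c("channel", "snr", "mean_abs_corr",
                                            "motion_fraction", "reasons")]
    print(bad, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write QC reports as a delimited table
#'
#' One row per channel per subject plus one summary row per subject.
#'
#' @param reports A `qc_report` or list of them.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(reports, path) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(rep) {
    ch <- rep$channels
    ch$subject <- rep$subject_id
    ch$row_type <- "channel"
    ch$verdict <- ""
    summary_row <- data.frame(
      channel = NA_integer_, snr = NA_real_, mean_abs_corr = NA_real_,
      motion_fraction = mean(rep$channels$motion_fraction),
      flagged = length(rep$flagged_channels) > 0L,
      reasons = paste(rep$verdict_reasons, collapse = ";"),
      subject = rep$subject_id, row_type = "subject",
      verdict = rep$subject_verdict)
    rbind(ch, summary_row)
  }))
  utils::write.table(rows[, c("subject", "row_type", "channel", "snr",
                              "mean_abs_corr", "motion_fraction", "flagged",
                              "reasons", "verdict")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
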