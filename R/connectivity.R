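#' Pairwise functional connectivity between two time series
#'
#' Pearson product-moment correlation, Spearman rank correlation (average
#' ranks for ties), or normalized cross-correlation maximized over lags.
#' Cross-correlation scans integer-sample lags within `max_lag_s` seconds,
#' computes the Pearson correlation of the overlapping parts at each lag, and
#' returns the signed value at the lag maximizing |r| (ties broken toward the
#' smallest |lag|, then the negative lag). At `max_lag_s = 0` it equals the
#' Pearson correlation exactly.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method "pearson", "spearman", or "crosscorr".
#' @param fs Sampling rate in Hz (needed for crosscorr).
#' @param max_lag_s Maximum lag in seconds for crosscorr (default 10).
#' @return List with `r` and, for crosscorr, `lag` (seconds) and
#'   `lag_samples`. Zero-variance input yields `r = NA` with a warning
#'   (an explicit undefined marker, not a silent 0).
#' @export
pairwise_fc <- function(x, y, method = c("pearson", "spearman", "crosscorr"),
                        fs = NULL, max_lag_s = 10) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance series: correlation undefined")
    return(list(r = NA_real_, lag = if (method == "crosscorr") NA_real_ else NULL))
  }
  if (method == "pearson") {
    list(r = stats::cor(x, y))
  } else if (method == "spearman") {
    list(r = stats::cor(rank(x), rank(y)))
  } else {
    if (is.null(fs)) stop("crosscorr needs the sampling rate fs")
    max_lag <- floor(max_lag_s * fs)
    lags <- -max_lag:max_lag
    lags <- lags[abs(lags) <= n - 3L]
    r <- vapply(lags, function(L) {
      if (L >= 0) stats::cor(x[1:(n - L)], y[(1 + L):n])
      else stats::cor(x[(1 - L):n], y[1:(n + L)])
    }, 0)
    # maximize |r|; ties -> smallest |lag|, then negative lag
    ord <- order(-abs(r), abs(lags), lags)
    best <- ord[1L]
    list(r = r[best], lag = lags[best] / fs, lag_samples = lags[best])
  }
}

.get_signal <- function(obj, signal) {
  if (inherits(obj, "proc_record")) {
    if (is.null(obj$conc)) stop("proc record has no concentration series")
    obj$conc[[signal]]
  } else if (inherits(obj, "conc_series")) {
    obj[[signal]]
  } else as.matrix(obj)
}

.get_fs <- function(obj) {
  if (inherits(obj, "proc_record")) obj$raw$sampling_rate
  else if (inherits(obj, "conc_series")) obj$sampling_rate
  else NULL
}

#' Seed-based functional connectivity
#'
#' Correlation between a seed channel's time series and every channel
#' (including itself, which is 1 by definition for pearson/spearman).
#'
#' @param obj A [proc_record()], [conc_series()], or channels x time matrix.
#' @param seed Seed channel index (1-based).
#' @param method Correlation method, see [pairwise_fc()].
#' @param signal "hbo" (default), "hbr", or "hbt".
#' @param fs Sampling rate, required for crosscorr on a bare matrix.
#' @param max_lag_s Maximum lag in seconds for crosscorr.
#' @return An `fc_result` with `values` (per-channel r vector), `lags`
#'   (crosscorr only), `method`, `signal`, `seed`.
#' @export
seed_fc <- function(obj, seed, method = c("pearson", "spearman", "crosscorr"),
                    signal = c("hbo", "hbr", "hbt"), fs = NULL, max_lag_s = 10) {
  method <- match.arg(method); signal <- match.arg(signal)
  m <- .get_signal(obj, signal)
  if (is.null(fs)) fs <- .get_fs(obj)
  if (seed < 1L || seed > nrow(m)) stop("seed channel ", seed, " out of range")
  if (stats::sd(m[seed, ]) == 0) stop("seed channel ", seed, " has zero variance")
  res <- lapply(seq_len(nrow(m)), function(ch)
    suppressWarnings(pairwise_fc(m[seed, ], m[ch, ], method, fs, max_lag_s)))
  values <- vapply(res, `[[`, 0, "r")
  lags <- if (method == "crosscorr") vapply(res, `[[`, 0, "lag") else NULL
  if (method != "crosscorr") values[seed] <- 1
  structure(list(values = values, lags = lags, method = method, signal = signal,
                 seed = seed, mode = "seed",
                 subject_id = if (inherits(obj, "proc_record")) obj$raw$subject_id else NULL),
            class = "fc_result")
}

#' Whole-brain functional connectivity matrix
#'
#' Symmetric N x N matrix of pairwise correlations between all channels;
#' row k equals [seed_fc()] with seed k.
#'
#' @inheritParams seed_fc
#' @return An `fc_result` with `values` an N x N symmetric matrix (unit
#'   diagonal for pearson/spearman); undefined entries are NA.
#' @export
whole_brain_fc <- function(obj, method = c("pearson", "spearman", "crosscorr"),
                           signal = c("hbo", "hbr", "hbt"), fs = NULL,
                           max_lag_s = 10) {
  method <- match.arg(method); signal <- match.arg(signal)
  m <- .get_signal(obj, signal)
  if (is.null(fs)) fs <- .get_fs(obj)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 channels")
  lags <- NULL
  if (method == "pearson") {
    sds <- apply(m, 1L, stats::sd)
    values <- suppressWarnings(stats::cor(t(m)))
    values[sds == 0, ] <- NA; values[, sds == 0] <- NA
    diag(values)[sds > 0] <- 1
  } else if (method == "spearman") {
    sds <- apply(m, 1L, stats::sd)
    ranks <- t(apply(m, 1L, rank))
    values <- suppressWarnings(stats::cor(t(ranks)))
    values[sds == 0, ] <- NA; values[, sds == 0] <- NA
    diag(values)[sds > 0] <- 1
  } else {
    values <- matrix(NA_real_, n, n)
    lags <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      p <- suppressWarnings(pairwise_fc(m[i, ], m[j, ], "crosscorr", fs, max_lag_s))
      values[i, j] <- p$r; values[j, i] <- p$r
      lags[i, j] <- p$lag; lags[j, i] <- if (is.null(p$lag) || is.na(p$lag)) NA else -p$lag
    }
  }
  structure(list(values = values, lags = lags, method = method, signal = signal,
                 seed = NULL, mode = "whole",
                 subject_id = if (inherits(obj, "proc_record")) obj$raw$subject_id else NULL),
            class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  if (x$mode == "seed") {
    cat(sprintf("seed FC (%s, %s), seed channel %d: %d channels\n",
                x$method, x$signal, x$seed, length(x$values)))
  } else {
    cat(sprintf("whole-brain FC (%s, %s): %d x %d matrix\n",
                x$method, x$signal, nrow(x$values), ncol(x$values)))
  }
  invisible(x)
}

#' Fisher r-to-z transform and its inverse
#'
#' z = atanh(r), r = tanh(z); variance-stabilizing for averaging correlations
#' across subjects.
#'
#' @param r Correlation value(s), |r| < 1 (or exactly 1 with `clamp`).
#' @param clamp If TRUE, values with |r| >= 1 are clamped to 1 - 1e-7 in
#'   magnitude (with a message) instead of raising an error.
#' @return Transformed values.
#' @export
fisher_z <- function(r, clamp = FALSE) {
  bad <- is.finite(r) & abs(r) >= 1
  if (any(bad)) {
    if (!clamp) stop("|r| >= 1: Fisher z undefined (use clamp = TRUE to clip)")
    message(sum(bad), " value(s) clamped to |r| = 1 - 1e-7")
    r[bad] <- sign(r[bad]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
z_to_r <- function(z) tanh(z)

#' Group-level statistical maps from per-subject FC results
#'
#' Elementwise across subjects: the R map (mean r), the Z map (mean Fisher
#' z), the Z-to-R map (tanh of the Z map), and the T map (one-sample t of the
#' subject z values against 0, df = n - 1, with two-sided uncorrected p).
#' Undefined per-subject entries are skipped pairwise-complete; the count of
#' contributing subjects per entry is reported. Entries with zero
#' across-subject variance get an undefined t (NA).
#'
#' @param results List of `fc_result` objects with identical dimensions,
#'   mode, and method.
#' @param clamp Passed to [fisher_z()] for |r| = 1 entries (default TRUE:
#'   diagonal entries of whole-brain maps are 1 by construction).
#' @return A `group_maps` object: `r_map`, `z_map`, `z_to_r_map`, `t_map`,
#'   `p_map`, `df`, `n_subjects`, `n_used`.
#' @export
group_maps <- function(results, clamp = TRUE) {
  stopifnot(length(results) >= 2L)
  if (length(unique(vapply(results, `[[`, "", "method"))) != 1L)
    stop("subjects use different correlation methods")
  if (length(unique(vapply(results, `[[`, "", "mode"))) != 1L)
    stop("subjects mix seed and whole-brain results")
  dims <- lapply(results, function(r) dim(as.matrix(r$values)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("subjects have mismatched channel sets")
  mats <- lapply(results, function(r) as.matrix(r$values))
  n <- length(results)
  arr <- array(unlist(mats), dim = c(dim(mats[[1L]]), n))
  zarr <- suppressMessages(fisher_z(arr, clamp = clamp))
  n_used <- apply(!is.na(arr), c(1, 2), sum)
  r_map <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  z_map <- apply(zarr, c(1, 2), mean, na.rm = TRUE)
  z_sd <- apply(zarr, c(1, 2), stats::sd, na.rm = TRUE)
  z_to_r_map <- tanh(z_map)
  t_map <- ifelse(z_sd > 0, z_map / (z_sd / sqrt(n_used)), NA_real_)
  df <- n_used - 1L
  p_map <- ifelse(is.na(t_map), NA_real_, 2 * stats::pt(-abs(t_map), pmax(df, 1L)))
  drop1 <- function(m) if (nrow(m) == 1L || ncol(m) == 1L) as.numeric(m) else m
  structure(list(r_map = drop1(r_map), z_map = drop1(z_map),
                 z_to_r_map = drop1(z_to_r_map), t_map = drop1(t_map),
                 p_map = drop1(p_map), df = drop1(df), n_subjects = n,
                 n_used = drop1(n_used),
                 method = results[[1L]]$method, mode = results[[1L]]$mode),
            class = "group_maps")
}

#' @export
print.group_maps <- function(x, ...) {
  cat(sprintf("group FC maps (%s, %s mode), n = %d subjects\n",
              x$method, x$mode, x$n_subjects))
  cat(sprintf("  mean r: %.4f   mean z-to-r: %.4f\n",
              mean(x$r_map, na.rm = TRUE), mean(x$z_to_r_map, na.rm = TRUE)))
  invisible(x)
}
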