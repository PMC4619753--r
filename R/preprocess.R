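#' Hemoglobin concentration series
#'
#' Per-channel time series of oxy- (HbO), deoxy- (HbR) and total (HbT)
#' hemoglobin concentration changes in micromol/L, channels x time.
#' HbT is HbO + HbR by definition and is recomputed if not supplied.
#'
#' @param hbo,hbr Numeric matrices, channels x time, micromol/L.
#' @param time Time vector in seconds.
#' @param hbt Optional; defaults to `hbo + hbr`.
#' @return A `conc_series` object with derived `sampling_rate`.
#' @export
conc_series <- function(hbo, hbr, time, hbt = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)), ncol(hbo) == length(time))
  if (is.null(hbt)) hbt <- hbo + hbr
  hbt <- as.matrix(hbt)
  stopifnot(all(dim(hbt) == dim(hbo)))
  if (max(abs(hbt - (hbo + hbr))) > 1e-9 * max(1, max(abs(hbt))))
    stop("hbt must equal hbo + hbr (tolerance 1e-9)")
  dt <- diff(time)
  structure(list(hbo = hbo, hbr = hbr, hbt = hbt, time = as.numeric(time),
                 sampling_rate = 1 / mean(dt)),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("hemoglobin concentration series: %d channels x %d samples @ %.4g Hz\n",
              nrow(x$hbo), ncol(x$hbo), x$sampling_rate))
  invisible(x)
}

# Molar extinction coefficients for HbO2 and Hb in cm^-1 (mol/L)^-1 at
# wavelengths commonly used by CW fNIRS instruments (Gratzer/Prahl
# compilation values).
.EXTINCTION_TABLE <- matrix(c(
  #       HbO2      Hb
  690,     276,  2051.96,
  730,     390,  1102.20,
  760,     586,  1548.52,
  780,     710,  1075.44,
  808,     836,   761.72,
  830,     974,   693.04,
  850,    1058,   691.32), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("nm", "hbo", "hbr")))

#' Extinction coefficients for oxy- and deoxyhemoglobin
#'
#' Looks up molar extinction coefficients (cm^-1 per mol/L) from an embedded
#' published table; exact matches only, since interpolating extinction spectra
#' across tens of nm is not meaningful.
#'
#' @param wavelengths Wavelengths in nm.
#' @return Matrix, length(wavelengths) x 2 with columns `hbo`, `hbr`.
#' @export
extinction_coefficients <- function(wavelengths) {
  idx <- match(wavelengths, .EXTINCTION_TABLE[, "nm"])
  if (anyNA(idx))
    stop("no embedded extinction coefficients for wavelength(s) ",
         paste(wavelengths[is.na(idx)], collapse = ", "),
         " nm; supply an explicit extinction matrix")
  .EXTINCTION_TABLE[idx, c("hbo", "hbr"), drop = FALSE]
}

#' Modified Beer-Lambert law parameters
#'
#' @param wavelengths Two wavelengths in nm (per measurement channel).
#' @param separations Per-channel source-detector distance in cm.
#' @param dpf Differential pathlength factor per wavelength (dimensionless);
#'   default 6.0 at both wavelengths.
#' @param extinction Optional 2 x 2 matrix of extinction coefficients,
#'   rows = wavelengths, columns = (HbO, HbR), in cm^-1 (mol/L)^-1. Defaults
#'   to the embedded table via [extinction_coefficients()].
#' @return An `mbll_params` object.
#' @export
mbll_params <- function(wavelengths, separations, dpf = c(6, 6),
                        extinction = NULL) {
  stopifnot(length(wavelengths) == 2L)
  if (length(dpf) == 1L) dpf <- rep(dpf, 2L)
  stopifnot(length(dpf) == 2L, all(dpf > 0), all(separations > 0))
  if (is.null(extinction)) extinction <- extinction_coefficients(wavelengths)
  extinction <- as.matrix(extinction)
  stopifnot(all(dim(extinction) == c(2L, 2L)))
  cond <- kappa(extinction)
  if (!is.finite(cond) || abs(det(extinction)) < 1e-12)
    stop("extinction matrix is singular; cannot separate HbO from HbR")
  structure(list(wavelengths = wavelengths, separations = as.numeric(separations),
                 dpf = dpf, extinction = extinction, condition_number = cond),
            class = "mbll_params")
}

#' Convert raw intensity to optical density
#'
#' OD(c, t) = -ln( I(c, t) / mean_t I(c, .) ): intensity normalized by its
#' temporal mean per channel, then negative natural log. Channels whose
#' intensity equals its mean give OD exactly 0, and rescaling a channel by a
#' positive constant leaves its OD unchanged.
#'
#' @param rec A [raw_recording()], or a channels x time intensity matrix.
#' @return Optical-density matrix (dimensionless), channels x time.
#' @export
intensity_to_od <- function(rec) {
  intensity <- if (inherits(rec, "raw_recording")) rec$intensity else as.matrix(rec)
  bad <- which(apply(intensity, 1L, function(x) any(x <= 0)))
  if (length(bad) > 0L)
    stop("nonpositive intensity in channel(s): ", paste(bad, collapse = ", "))
  -log(intensity / rowMeans(intensity))
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert law. For each measurement channel (a
#' source-detector pair measured at two wavelengths) the 2 x 2 linear system
#' dOD(lambda_i) = (eps_HbO(lambda_i) dHbO + eps_HbR(lambda_i) dHbR) * L * DPF(lambda_i)
#' is solved per time point; HbT = HbO + HbR.
#'
#' @param od Optical-density matrix, measurement rows x time.
#' @param params An [mbll_params()] with one separation per measurement channel.
#' @param probe A [probe_geometry()] describing which rows pair up; if NULL,
#'   rows are assumed wavelength-major (first half wavelength 1, second half
#'   wavelength 2).
#' @param time Time vector in seconds.
#' @return A [conc_series()] in micromol/L, one row per measurement channel.
#' @export
od_to_concentration <- function(od, params, time, probe = NULL) {
  od <- as.matrix(od)
  stopifnot(inherits(params, "mbll_params"))
  if (is.null(probe)) {
    if (nrow(od) %% 2L != 0L) stop("odd number of OD rows: unpaired wavelength channel")
    nch <- nrow(od) %/% 2L
    pairs <- lapply(seq_len(nch), function(i) c(i, i + nch))
  } else {
    pairs <- measurement_channels(probe)
    if (any(lengths(pairs) != 2L))
      stop("each measurement channel must have exactly two wavelength rows")
  }
  nch <- length(pairs)
  sep <- params$separations
  if (length(sep) == 1L) sep <- rep(sep, nch)
  if (length(sep) != nch)
    stop("need one source-detector separation per measurement channel")
  hbo <- matrix(0, nch, ncol(od))
  hbr <- matrix(0, nch, ncol(od))
  for (i in seq_len(nch)) {
    rows <- pairs[[i]]
    m <- params$extinction * (sep[i] * params$dpf)   # row-wise L*DPF scaling
    sol <- solve(m, od[rows, , drop = FALSE])        # mol/L
    hbo[i, ] <- sol[1L, ] * 1e6                      # micromol/L
    hbr[i, ] <- sol[2L, ] * 1e6
  }
  conc_series(hbo, hbr, time)
}

# --- zero-phase Butterworth filtering via second-order sections ------------

# Digital Butterworth design as a cascade of biquads (bilinear transform of
# the analog prototype). The transfer-function form is numerically
# ill-conditioned at very low normalized cutoffs (e.g. 0.01 Hz on 25 Hz
# data), so sections are designed and applied individually.
butter_sos <- function(order, wn, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1L, wn > 0, wn < 1)
  W <- tan(pi * wn / 2)
  k <- seq_len(order)
  pproto <- complex(modulus = 1, argument = pi * (2 * k + order - 1) / (2 * order))
  pa <- if (type == "low") W * pproto else W / pproto
  z <- (1 + pa) / (1 - pa)
  zref <- if (type == "low") 1 + 0i else -1 + 0i
  zzero <- if (type == "low") -1 else 1
  sos <- list()
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(z[i])) < 1e-12) {
      a <- c(1, -Re(z[i])); b <- c(1, -zzero)
    } else {
      j <- which(!used & abs(z - Conj(z[i])) < 1e-9 & seq_len(order) != i)[1L]
      used[j] <- TRUE
      a <- c(1, -2 * Re(z[i]), Mod(z[i])^2); b <- c(1, -2 * zzero, zzero^2)
    }
    used[i] <- TRUE
    g <- Mod(sum(a * zref^-(seq_along(a) - 1)) / sum(b * zref^-(seq_along(b) - 1)))
    sos[[length(sos) + 1L]] <- list(b = b * g, a = a)
  }
  attr(sos, "H1") <- if (type == "low") 1 else 0   # DC gain of the cascade
  sos
}

.sosfilt <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# One zero-phase (forward-backward) pass of an SOS cascade over a vector.
# Odd-reflection padding plus exact steady-state handling of the DC offset:
# filtering x - x[1] with zero initial state and adding back x[1] * H(1) is
# the steady-state initial-condition trick, so a constant input maps exactly
# to its steady-state response.
.filtfilt_sos <- function(sos, x, pad) {
  one_pass <- function(x) {
    n <- length(x)
    p <- min(n - 1L, pad)
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    x0 <- xp[1]
    y <- .sosfilt(sos, xp - x0) + x0 * attr(sos, "H1")
    y[(p + 1):(p + n)]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Cascade of a fifth-order high-pass (cutoff `low_cut`) and a third-order
#' low-pass (cutoff `high_cut`), each applied forward and backward
#' (zero-phase, so the effective attenuation is the squared magnitude
#' response and the group delay is zero). Defaults follow the resting-state
#' hemodynamic band, 0.01-0.1 Hz.
#'
#' Each filter is applied as a cascade of second-order sections with
#' odd-reflection padding whose length scales with the filter's time constant
#' (about three time constants of the cutoff, capped at the series length),
#' keeping edge transients small even for very low cutoffs.
#'
#' @param x Numeric matrix (channels x time) or vector.
#' @param fs Sampling rate in Hz.
#' @param low_cut High-pass edge in Hz (default 0.01).
#' @param high_cut Low-pass edge in Hz (default 0.1).
#' @param lp_order,hp_order Butterworth orders (defaults 3 and 5).
#' @return Filtered series, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low_cut = 0.01, high_cut = 0.1,
                            lp_order = 3L, hp_order = 5L) {
  stopifnot(fs > 0, low_cut > 0, low_cut < high_cut)
  if (high_cut >= fs / 2)
    stop("high_cut (", high_cut, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  min_len <- 3L * (max(lp_order, hp_order) + 1L)
  if (ncol(m) < min_len)
    stop("series too short for filtering: need at least ", min_len, " samples")
  hp <- butter_sos(hp_order, low_cut / (fs / 2), "high")
  lp <- butter_sos(lp_order, high_cut / (fs / 2), "low")
  pad_hp <- max(3L * (hp_order + 1L), ceiling(3 * fs / (2 * pi * low_cut)))
  pad_lp <- max(3L * (lp_order + 1L), ceiling(3 * fs / (2 * pi * high_cut)))
  out <- t(apply(m, 1L, function(row)
    .filtfilt_sos(lp, .filtfilt_sos(hp, row, pad_hp), pad_lp)))
  if (vec) as.numeric(out) else out
}

#' Remove per-channel linear trends
#'
#' Ordinary least-squares fit of a straight line per channel, subtracted from
#' the signal; the residual has zero mean and zero least-squares slope.
#' Idempotent.
#'
#' @param x Numeric matrix (channels x time) or vector.
#' @param time Optional time vector (only affects the fitted line's
#'   parameterization, not the residual).
#' @return Detrended series, same shape as `x`.
#' @export
detrend_linear <- function(x, time = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 time points to detrend")
  tv <- if (is.null(time)) seq_len(ncol(m)) else as.numeric(time)
  X <- cbind(1, tv - mean(tv))
  beta <- solve(crossprod(X), crossprod(X, t(m)))
  out <- m - t(X %*% beta)
  if (vec) as.numeric(out) else out
}

#' Motion correction by spline subtraction
#'
#' Detects motion-contaminated segments with the moving-standard-deviation
#' rule (window `window_s`, threshold mean + `threshold_sd` standard
#' deviations of the MSD; defaults 2 s and 5), models each flagged segment
#' with a smoothing cubic spline, subtracts the spline, re-levels the
#' corrected segment to the clean baseline preceding it, and shifts the
#' remainder of the series so the signal level is continuous across the
#' segment (which repairs both spikes and baseline steps). Samples outside
#' flagged segments are left untouched except for the level continuation.
#'
#' @param x Numeric matrix (channels x time) or vector.
#' @param fs Sampling rate in Hz.
#' @param window_s MSD window length in seconds (default 2).
#' @param threshold_sd Threshold in MSD standard deviations (default 5).
#' @param smoothing Spline smoothing parameter in (0, 1]; 1 interpolates,
#'   smaller values smooth more (mapped to `stats::smooth.spline`'s `spar`
#'   as `1 - smoothing`). Default 0.99.
#' @return Corrected series, same shape as `x`, with attribute `segments`
#'   (per-channel list of flagged [start, end] sample index pairs).
#' @export
motion_correct_spline <- function(x, fs, window_s = 2, threshold_sd = 5,
                                  smoothing = 0.99) {
  stopifnot(smoothing > 0, smoothing <= 1)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  n <- ncol(m)
  win <- max(2L, round(window_s * fs))
  seg_list <- vector("list", nrow(m))
  for (ch in seq_len(nrow(m))) {
    sig <- m[ch, ]
    if (stats::sd(sig) == 0) { seg_list[[ch]] <- matrix(0L, 0L, 2L); next }
    msd <- moving_std(sig, window_s, fs)
    segs <- .flag_segments(msd, threshold_sd)
    # merge segments separated by less than one window
    segs <- .merge_segments(segs, gap = win)
    if (nrow(segs) > 0 && segs[1, 1] == 1L && segs[nrow(segs), 2] == n &&
        nrow(segs) == 1L)
      stop("signal unusable: entire series flagged as motion in channel ", ch)
    for (si in seq_len(nrow(segs))) {
      a <- segs[si, 1]; b <- segs[si, 2]
      idx <- a:b
      if (length(idx) >= 4L) {
        fit <- stats::smooth.spline(idx, sig[idx], spar = 1 - smoothing)
        resid <- sig[idx] - stats::predict(fit, idx)$y
      } else {
        resid <- sig[idx] - mean(sig[idx])
      }
      pre <- max(1L, a - win):(a - 1L)
      base_pre <- if (a > 1L) mean(sig[pre]) else 0
      sig[idx] <- resid + base_pre
      # continue the level across the segment: shift everything after it so
      # its immediate baseline matches the pre-segment baseline
      if (b < n) {
        post <- (b + 1L):min(n, b + win)
        shift <- base_pre - mean(sig[post])
        sig[(b + 1L):n] <- sig[(b + 1L):n] + shift
      }
    }
    m[ch, ] <- sig
    seg_list[[ch]] <- segs
  }
  out <- if (vec) as.numeric(m) else m
  attr(out, "segments") <- seg_list
  out
}

#' Motion correction by correlation-based signal improvement (CBSI)
#'
#' Exploits the physiological anticorrelation of HbO and HbR: with
#' alpha = sd(HbO)/sd(HbR) per channel, the corrected signals are
#' HbO' = (HbO - alpha HbR)/2 and HbR' = -HbO'/alpha, which removes the
#' shared (motion) component and enforces corr(HbO', HbR') = -1 exactly.
#' HbT is recomputed.
#'
#' @param conc A [conc_series()].
#' @return A corrected [conc_series()] with attribute `alpha` (per-channel).
#' @export
motion_correct_cbsi <- function(conc) {
  stopifnot(inherits(conc, "conc_series"))
  sd_hbo <- apply(conc$hbo, 1L, stats::sd)
  sd_hbr <- apply(conc$hbr, 1L, stats::sd)
  if (any(sd_hbr == 0))
    stop("sd(HbR) is zero in channel(s): ",
         paste(which(sd_hbr == 0), collapse = ", "))
  if (any(sd_hbo == 0))
    stop("sd(HbO) is zero in channel(s): ",
         paste(which(sd_hbo == 0), collapse = ", "))
  alpha <- sd_hbo / sd_hbr
  hbo2 <- (conc$hbo - alpha * conc$hbr) / 2
  hbr2 <- -hbo2 / alpha
  out <- conc_series(hbo2, hbr2, conc$time)
  attr(out, "alpha") <- alpha
  out
}

# Default preprocessing pipeline, mirroring the toolchain's standard order:
# OD conversion, MBLL, band-pass, detrend, CBSI.
default_steps <- function() {
  list(list(name = "od"),
       list(name = "mbll"),
       list(name = "bandpass", low_cut = 0.01, high_cut = 0.1),
       list(name = "detrend"),
       list(name = "cbsi"))
}

# Apply one named preprocessing step to a proc record.
.apply_step <- function(rec, step, dpf = c(6, 6)) {
  params <- step[setdiff(names(step), "name")]
  pstr <- if (length(params))
    paste(names(params), unlist(params), sep = "=", collapse = ", ") else ""
  fs <- rec$raw$sampling_rate
  switch(step$name,
    od = { rec$od <- intensity_to_od(rec$raw) },
    mbll = {
      if (is.null(rec$od)) stop("mbll step requires optical density (run 'od' first)")
      ml <- measurement_channels(rec$probe)
      sep_per_ch <- rec$probe$separations[vapply(ml, `[`, 0L, 1L)]
      p <- mbll_params(rec$probe$wavelengths, sep_per_ch,
                       dpf = if (!is.null(step$dpf)) step$dpf else dpf)
      rec$conc <- od_to_concentration(rec$od, p, rec$raw$time, rec$probe)
    },
    bandpass = {
      if (is.null(rec$conc)) stop("bandpass step requires concentrations")
      lc <- if (!is.null(step$low_cut)) step$low_cut else 0.01
      hc <- if (!is.null(step$high_cut)) step$high_cut else 0.1
      rec$conc <- conc_series(bandpass_filter(rec$conc$hbo, fs, lc, hc),
                              bandpass_filter(rec$conc$hbr, fs, lc, hc),
                              rec$conc$time)
    },
    detrend = {
      if (is.null(rec$conc)) stop("detrend step requires concentrations")
      rec$conc <- conc_series(detrend_linear(rec$conc$hbo, rec$conc$time),
                              detrend_linear(rec$conc$hbr, rec$conc$time),
                              rec$conc$time)
    },
    spline = {
      if (is.null(rec$conc)) stop("spline step requires concentrations")
      ws <- if (!is.null(step$window_s)) step$window_s else 2
      th <- if (!is.null(step$threshold_sd)) step$threshold_sd else 5
      sm <- if (!is.null(step$smoothing)) step$smoothing else 0.99
      hbo <- motion_correct_spline(rec$conc$hbo, fs, ws, th, sm)
      hbr <- motion_correct_spline(rec$conc$hbr, fs, ws, th, sm)
      attr(hbo, "segments") <- NULL; attr(hbr, "segments") <- NULL
      rec$conc <- conc_series(hbo, hbr, rec$conc$time)
    },
    cbsi = {
      if (is.null(rec$conc)) stop("cbsi step requires concentrations")
      rec$conc <- motion_correct_cbsi(rec$conc)
    },
    stop("unknown preprocessing step: ", step$name))
  add_history(rec, step$name, pstr)
}

#' Run the preprocessing pipeline over a directory of recordings
#'
#' Reads every `.nirs` (and `.csv`) recording in `input_dir`, applies the
#' given steps in order, and writes one `.proc` file per subject plus a run
#' log to `output_dir`. A failing subject is logged and skipped; the batch
#' continues.
#'
#' @param input_dir Directory of `.nirs` / `.csv` recordings.
#' @param output_dir Output directory (created if needed).
#' @param steps Ordered list of steps, each `list(name = ..., <params>)`;
#'   names from od, mbll, bandpass, detrend, spline, cbsi. Default:
#'   od, mbll, bandpass (0.01-0.1 Hz), detrend, cbsi.
#' @param dpf Differential pathlength factor used by the mbll step.
#' @return Invisibly, a data frame with one row per subject (`subject`,
#'   `status`, `message`, `proc_path`); attribute `log_path` points to the
#'   run log. All subjects failing raises an error; partial failure is
#'   reported in the return value.
#' @export
run_preprocessing <- function(input_dir, output_dir, steps = default_steps(),
                              dpf = c(6, 6)) {
  files <- list.files(input_dir, pattern = "\\.(nirs|csv)$", full.names = TRUE)
  if (length(files) == 0L) stop("no input data in ", input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "preprocess_log.txt")
  log_lines <- c(sprintf("[%s] preprocessing run: %d input file(s)",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), length(files)),
                 sprintf("steps: %s",
                         paste(vapply(steps, `[[`, "", "name"), collapse = " -> ")))
  results <- data.frame(subject = character(0), status = character(0),
                        message = character(0), proc_path = character(0))
  for (f in files) {
    subj <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      rec_raw <- if (grepl("\\.csv$", f)) read_hitachi_csv(f) else read_nirs(f)
      rec <- proc_record(rec_raw)
      for (s in steps) rec <- .apply_step(rec, s, dpf = dpf)
      out <- file.path(output_dir, paste0(subj, ".proc"))
      write_proc(rec, out)
      list(status = "ok", message = "", path = out)
    }, error = function(e) list(status = "failed", message = conditionMessage(e),
                                path = NA_character_))
    log_lines <- c(log_lines, sprintf("[%s] %s: %s %s",
                                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                      subj, res$status, res$message))
    results <- rbind(results, data.frame(subject = subj, status = res$status,
                                         message = res$message,
                                         proc_path = res$path))
  }
  writeLines(log_lines, log_path)
  if (all(results$status == "failed"))
    stop("all ", nrow(results), " subjects failed preprocessing; see ", log_path)
  attr(results, "log_path") <- log_path
  invisible(results)
}
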