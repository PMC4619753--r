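#' Specification for a synthetic resting-state fNIRS dataset
#'
#' Defines a group of simulated recordings with known ground truth: a block
#' partition of channels with target within/between-block correlations of the
#' hemodynamic (HbO) signals, band-limited latent sources in the
#' resting-state band, per-channel noise and linear drift, optional injected
#' motion artifacts and dead (low-SNR) channels, and the optical forward
#' model that turns concentrations into raw intensities. Defaults mirror a
#' whole-head CW acquisition: 46 measurement channels at 25 Hz, wavelengths
#' 690/830 nm, 3 cm separations.
#'
#' @param n_channels Number of measurement channels (default 46).
#' @param n_subjects Number of subjects (default 1).
#' @param duration_s Recording length in seconds (default 300).
#' @param sampling_rate Hz (default 25).
#' @param blocks Integer vector assigning each channel to a block (default:
#'   two equal blocks).
#' @param within_r Target Pearson correlation between HbO series within a
#'   block (default 0.8).
#' @param between_r Target correlation between blocks (default 0).
#' @param band Frequency band of the latent sources in Hz (default
#'   0.01-0.1, the resting-state hemodynamic band, so the default band-pass
#'   preserves the planted structure).
#' @param hbo_sd Standard deviation of each channel's HbO series in
#'   micromol/L (default 0.05).
#' @param hbr_ratio HbR amplitude as a fraction of HbO, with the
#'   physiological anticorrelation HbR ~ -hbr_ratio * HbO (default 1/3).
#' @param hbr_noise_sd Independent noise added to HbR, micromol/L
#'   (default 0.005).
#' @param drift_slope_max Per-channel linear drift slope drawn uniformly from
#'   +/- this value, micromol/L per second (default 1e-4, small enough that
#'   drift does not dilute the planted correlations beyond their tolerance
#'   before detrending).
#' @param artifacts Data frame describing motion artifacts to inject into
#'   the intensities (`time_s`, `amplitude`, `shape` in spike/step,
#'   `duration_s`), or NULL.
#' @param dead_channels Integer vector of channels replaced by white noise.
#' @param dead_snr Target SNR of dead channels (default 2).
#' @param baseline_intensity Baseline detector intensity I0 (default 1).
#' @param wavelengths Two wavelengths in nm (default c(690, 830)).
#' @param dpf Differential pathlength factor (default 6).
#' @param separation_cm Source-detector separation (default 3).
#' @param seed Base RNG seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_channels = 46, n_subjects = 1, duration_s = 300,
                           sampling_rate = 25,
                           blocks = rep(1:2, length.out = n_channels),
                           within_r = 0.8, between_r = 0,
                           band = c(0.01, 0.1), hbo_sd = 0.05,
                           hbr_ratio = 1 / 3, hbr_noise_sd = 0.005,
                           drift_slope_max = 1e-4, artifacts = NULL,
                           dead_channels = integer(0), dead_snr = 2,
                           baseline_intensity = 1, wavelengths = c(690, 830),
                           dpf = c(6, 6), separation_cm = 3, seed = 1L) {
  stopifnot(length(blocks) == n_channels,
            abs(within_r) <= 1, abs(between_r) <= 1,
            duration_s * sampling_rate >= 64)
  nb <- length(unique(blocks))
  rt <- matrix(between_r, nb, nb); diag(rt) <- 1
  if (nb > 1 && min(eigen(rt, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("block correlation targets are not positive semidefinite")
  structure(list(n_channels = n_channels, n_subjects = n_subjects,
                 duration_s = duration_s, sampling_rate = sampling_rate,
                 blocks = as.integer(blocks), within_r = within_r,
                 between_r = between_r, band = band, hbo_sd = hbo_sd,
                 hbr_ratio = hbr_ratio, hbr_noise_sd = hbr_noise_sd,
                 drift_slope_max = drift_slope_max, artifacts = artifacts,
                 dead_channels = as.integer(dead_channels), dead_snr = dead_snr,
                 baseline_intensity = baseline_intensity,
                 wavelengths = wavelengths, dpf = dpf,
                 separation_cm = separation_cm, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Band-limited unit-variance noise row(s): white noise band-passed to the
# spec band and standardized. The filter's edge transients at a 0.01 Hz
# high-pass extend over several hundred samples and would dominate the
# variance, so the noise is generated with burn-in margins (about five time
# constants of the low cutoff) that are trimmed before standardization.
.band_noise <- function(n, fs, band, ncols = 1L) {
  burn <- ceiling(5 * fs / (2 * pi * band[1L]))
  x <- matrix(stats::rnorm((n + 2L * burn) * ncols), ncols, n + 2L * burn)
  y <- bandpass_filter(x, fs, band[1L], band[2L])
  y <- y[, (burn + 1L):(burn + n), drop = FALSE]
  y <- y - rowMeans(y)
  y / apply(y, 1L, stats::sd)
}

#' Simulate hemoglobin concentration series with known block structure
#'
#' Each block has one latent band-limited source; the latent sources across
#' blocks are orthogonalized on the sample and then mixed to carry exactly
#' the target between-block correlation, so the planted structure is not at
#' the mercy of finite-sample latent correlations. A channel's HbO is
#' sqrt(within_r) x (its block's latent) + sqrt(1 - within_r) x independent
#' band-limited noise, scaled to `hbo_sd`, plus a linear drift. HbR is
#' -hbr_ratio x HbO plus independent noise (the physiological
#' anticorrelation). The expected channel-pair correlation is `within_r`
#' within a block and `within_r * between_r` across blocks.
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return List with `conc` (a [conc_series()]), `truth` (list with `blocks`,
#'   the target correlation matrix `r_target`, drift slopes).
#' @export
simulate_concentrations <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$duration_s * fs)
  tv <- (seq_len(n) - 1L) / fs
  blocks <- spec$blocks
  nb <- length(unique(blocks))
  block_ids <- sort(unique(blocks))
  withr::with_seed(seed, {
    lat <- .band_noise(n, fs, spec$band, ncols = nb)
    # orthonormalize the latents on the sample; a narrow band over a few
    # hundred seconds has few effective degrees of freedom, so chance latent
    # correlations would otherwise swamp the between-block target
    qr_ <- qr(scale(t(lat), center = TRUE, scale = FALSE))     # time x nb
    basis <- t(qr.Q(qr_))                                      # nb x time
    ortho <- basis / apply(basis, 1L, stats::sd)
    lat <- if (nb > 1L) {
      rt <- matrix(spec$between_r, nb, nb); diag(rt) <- 1
      t(chol(rt)) %*% ortho
    } else ortho
    # channel noise projected onto the latents' orthogonal complement, so
    # the planted correlations hold by construction, not by sampling luck
    noise <- .band_noise(n, fs, spec$band, ncols = spec$n_channels)
    noise <- noise - (noise %*% t(basis)) %*% basis
    noise <- (noise - rowMeans(noise)) / apply(noise, 1L, stats::sd)
    rho <- abs(spec$within_r)
    bi <- match(blocks, block_ids)
    hbo <- (sqrt(rho) * lat[bi, , drop = FALSE] +
            sqrt(1 - rho) * noise) * spec$hbo_sd
    slopes <- stats::runif(spec$n_channels, -spec$drift_slope_max,
                           spec$drift_slope_max)
    hbo <- hbo + outer(slopes, tv)
    hbr <- -spec$hbr_ratio * hbo +
      matrix(stats::rnorm(length(hbo), sd = spec$hbr_noise_sd),
             nrow(hbo), ncol(hbo))
    r_target <- matrix(spec$within_r * spec$between_r,
                       spec$n_channels, spec$n_channels)
    same <- outer(blocks, blocks, `==`)
    r_target[same] <- spec$within_r
    diag(r_target) <- 1
    list(conc = conc_series(hbo, hbr, tv),
         truth = list(blocks = blocks, r_target = r_target, drift = slopes))
  })
}

#' Optical forward model: concentrations to raw intensities
#'
#' The exact inverse of the preprocessing chain: dOD(lambda) =
#' (eps_HbO dHbO + eps_HbR dHbR) L DPF, intensity I = I0 exp(-dOD). Running
#' [intensity_to_od()] and [od_to_concentration()] on the output recovers a
#' zero-mean concentration input exactly (up to the per-channel constant
#' absorbed by the mean normalization).
#'
#' @param conc A [conc_series()] (micromol/L).
#' @param params An [mbll_params()].
#' @param baseline_intensity Baseline intensity I0 (scalar or per measurement
#'   row).
#' @param probe Optional [probe_geometry()]; a default linear layout is
#'   synthesized when omitted.
#' @param subject_id Label.
#' @return A [raw_recording()] with one row per channel and wavelength
#'   (wavelength-major).
#' @export
forward_model <- function(conc, params, baseline_intensity = 1, probe = NULL,
                          subject_id = "synthetic") {
  stopifnot(inherits(conc, "conc_series"), inherits(params, "mbll_params"))
  nch <- nrow(conc$hbo)
  if (is.null(probe))
    probe <- default_probe(nch, params$wavelengths, params$separations[1L])
  sep <- params$separations
  if (length(sep) == 1L) sep <- rep(sep, nch)
  od <- matrix(0, 2L * nch, ncol(conc$hbo))
  for (ch in seq_len(nch)) {
    cmol <- rbind(conc$hbo[ch, ], conc$hbr[ch, ]) * 1e-6   # mol/L
    m <- params$extinction * (sep[ch] * params$dpf)
    od[c(ch, ch + nch), ] <- m %*% cmol
  }
  intensity <- baseline_intensity * exp(-od)
  raw_recording(intensity, conc$time, probe, subject_id)
}

#' Inject motion artifacts into a recording
#'
#' Adds spike (one-sided triangular pulse) or step transients to all
#' intensity rows at the given times, scaled per row to `amplitude` times
#' the row's standard deviation. Returns the recording plus the ground-truth
#' sample mask.
#'
#' @param rec A [raw_recording()].
#' @param times_s Artifact onset times in seconds.
#' @param amplitude Artifact size in units of each row's SD.
#' @param shape "spike" or "step".
#' @param duration_s Spike duration in seconds (default 0.5); a step lasts
#'   until the end of the recording but only its onset transition is masked.
#' @return List with `rec` (modified recording) and `mask` (logical vector
#'   over samples, TRUE where the artifact acts).
#' @export
inject_motion <- function(rec, times_s, amplitude, shape = c("spike", "step"),
                          duration_s = 0.5) {
  shape <- match.arg(shape)
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  n <- ncol(rec$intensity)
  mask <- rep(FALSE, n)
  if (amplitude == 0) return(list(rec = rec, mask = mask))
  row_sd <- apply(rec$intensity, 1L, stats::sd)
  row_sd[row_sd == 0] <- mean(row_sd[row_sd > 0])
  for (t0 in times_s) {
    i0 <- round(t0 * fs) + 1L
    if (i0 < 1L || i0 > n) stop("artifact time ", t0, " s outside the recording")
    if (shape == "spike") {
      len <- max(2L, round(duration_s * fs))
      idx <- i0:min(n, i0 + len - 1L)
      pulse <- 1 - abs(seq_along(idx) - length(idx) / 2) / (length(idx) / 2)
      rec$intensity[, idx] <- rec$intensity[, idx] +
        amplitude * row_sd %o% pulse
      mask[idx] <- TRUE
    } else {
      rec$intensity[, i0:n] <- rec$intensity[, i0:n] + amplitude * row_sd
      mask[i0] <- TRUE
    }
  }
  list(rec = rec, mask = mask)
}

#' Replace a channel by instrument noise with a target SNR
#'
#' Emulates an optode with poor scalp contact: both wavelength rows of the
#' measurement channel are replaced by gamma-distributed instrument noise
#' (intensities must stay positive) whose mean/SD ratio is `target_snr`,
#' uncorrelated with everything else. Other channels are untouched.
#'
#' @param rec A [raw_recording()].
#' @param channel Measurement channel index (1-based).
#' @param target_snr Target mean/SD ratio (default 2).
#' @param seed RNG seed.
#' @return The modified [raw_recording()].
#' @export
inject_dead_channel <- function(rec, channel, target_snr = 2, seed = 1L) {
  stopifnot(inherits(rec, "raw_recording"), target_snr > 0)
  pairs <- measurement_channels(rec$probe)
  if (channel < 1L || channel > length(pairs))
    stop("channel ", channel, " out of range")
  rows <- pairs[[channel]]
  n <- ncol(rec$intensity)
  withr::with_seed(seed, {
    for (r in rows) {
      mu <- mean(rec$intensity[r, ])
      # gamma with shape snr^2 has mean/sd = snr and strictly positive support
      rec$intensity[r, ] <- stats::rgamma(n, shape = target_snr^2,
                                          scale = mu / target_snr^2)
    }
  })
  rec
}

#' Simulate a group of subjects and write them as .nirs files
#'
#' Runs [simulate_concentrations()] + [forward_model()] per subject (seed =
#' spec seed + subject index), applies any artifact schedule and dead
#' channels, writes `subject_XX.nirs` files, and a plain-text ground-truth
#' sidecar (`ground_truth.tsv`: channel block assignments, dead channels,
#' artifact schedule, per-subject seeds).
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `files`, `truth` (per subject), and
#'   `sidecar` path.
#' @export
simulate_group <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- mbll_params(spec$wavelengths, rep(spec$separation_cm, spec$n_channels),
                        dpf = spec$dpf)
  files <- character(spec$n_subjects)
  truths <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    subj_seed <- spec$seed + s
    sim <- simulate_concentrations(spec, seed = subj_seed)
    rec <- forward_model(sim$conc, params, spec$baseline_intensity,
                         subject_id = sprintf("subject_%02d", s))
    mask <- rep(FALSE, ncol(rec$intensity))
    if (!is.null(spec$artifacts) && nrow(spec$artifacts) > 0) {
      for (ai in seq_len(nrow(spec$artifacts))) {
        a <- spec$artifacts[ai, ]
        inj <- inject_motion(rec, a$time_s, a$amplitude, a$shape,
                             if (!is.null(a$duration_s)) a$duration_s else 0.5)
        rec <- inj$rec
        mask <- mask | inj$mask
      }
    }
    for (dc in spec$dead_channels)
      rec <- inject_dead_channel(rec, dc, spec$dead_snr, seed = subj_seed + 1000L)
    files[s] <- file.path(out_dir, sprintf("subject_%02d.nirs", s))
    write_nirs(rec, files[s])
    truths[[s]] <- list(seed = subj_seed, blocks = sim$truth$blocks,
                        r_target = sim$truth$r_target, artifact_mask = mask)
  }
  sidecar <- file.path(out_dir, "ground_truth.tsv")
  gt <- data.frame(channel = seq_len(spec$n_channels), block = spec$blocks,
                   dead = seq_len(spec$n_channels) %in% spec$dead_channels)
  header <- c(sprintf("# within_r=%g between_r=%g seed=%d n_subjects=%d",
                      spec$within_r, spec$between_r, spec$seed, spec$n_subjects),
              sprintf("# artifacts=%s",
                      if (is.null(spec$artifacts)) "none" else
                        paste(sprintf("%gs:%gx%s", spec$artifacts$time_s,
                                      spec$artifacts$amplitude,
                                      spec$artifacts$shape), collapse = ",")))
  writeLines(header, sidecar)
  suppressWarnings(utils::write.table(gt, sidecar, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(list(files = files, truth = truths, sidecar = sidecar))
}
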