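test_that("optical density conversion matches the closed form", {
  # hand-evaluated oracle: OD = -ln(I / mean(I))
  I <- c(1, exp(-0.1))
  expected <- -log(I / mean(I))
  expect_equal(as.numeric(intensity_to_od(matrix(I, 1))), expected,
               tolerance = 1e-12)
  # constant channel -> OD identically zero
  expect_equal(as.numeric(intensity_to_od(matrix(5, 1, 10))), rep(0, 10))
  # scale invariance
  withr::with_seed(1, x <- matrix(runif(50, 1, 2), 1))
  expect_equal(intensity_to_od(10 * x), intensity_to_od(x), tolerance = 1e-12)
  expect_error(intensity_to_od(matrix(c(1, -1, 2, 1), 2, 2)),
               "channel\\(s\\): 2")
})

test_that("MBLL inverts its forward model", {
  # identity extinction, L*DPF = 1 -> concentration equals OD (up to unit scale)
  p_id <- mbll_params(c(690, 830), separations = 1, dpf = c(1, 1),
                      extinction = diag(2))
  od <- rbind(sin(seq(0, 1, length.out = 20)), cos(seq(0, 1, length.out = 20)))
  conc <- od_to_concentration(od, p_id, time = seq(0, 1.9, 0.1))
  expect_equal(conc$hbo[1, ], od[1, ] * 1e6, tolerance = 1e-9)
  expect_equal(conc$hbr[1, ], od[2, ] * 1e6, tolerance = 1e-9)
  expect_equal(conc$hbt, conc$hbo + conc$hbr, tolerance = 1e-12)

  # zero OD -> zero concentrations with the real coefficient table
  p <- mbll_params(c(690, 830), separations = rep(3, 2))
  z <- od_to_concentration(matrix(0, 4, 10), p, time = (0:9) / 10)
  expect_equal(max(abs(z$hbo)), 0)

  # full round trip: forward model then OD + inversion recovers zero-mean input
  tv <- (0:499) / 25
  hbo <- rbind(0.05 * sin(2 * pi * 0.05 * tv), 0.03 * cos(2 * pi * 0.03 * tv))
  hbr <- rbind(-0.02 * sin(2 * pi * 0.05 * tv), -0.01 * cos(2 * pi * 0.03 * tv))
  hbo <- hbo - rowMeans(hbo); hbr <- hbr - rowMeans(hbr)
  conc0 <- conc_series(hbo, hbr, tv)
  p2 <- mbll_params(c(690, 830), separations = rep(3, 2))
  rec <- forward_model(conc0, p2)
  back <- od_to_concentration(intensity_to_od(rec), p2, tv, rec$probe)
  rec_hbo <- back$hbo - rowMeans(back$hbo)   # mean-normalization offset
  rec_hbr <- back$hbr - rowMeans(back$hbr)
  expect_lt(max(abs(rec_hbo - hbo)) / max(abs(hbo)), 1e-9)
  expect_lt(max(abs(rec_hbr - hbr)) / max(abs(hbr)), 1e-9)

  expect_error(mbll_params(c(690, 830), 3, extinction = matrix(1, 2, 2)),
               "singular")
  expect_error(od_to_concentration(matrix(0, 3, 5), p, time = (0:4) / 10),
               "unpaired")
})

test_that("band-pass filter matches the closed-form Butterworth response", {
  fs <- 25
  tv <- seq(0, 600 - 1 / fs, by = 1 / fs)
  # DC removed exactly
  dc <- bandpass_filter(rep(7, length(tv)), fs)
  expect_lt(max(abs(dc)), 7e-6)
  # passband: 0.05 Hz retained at the analytic squared-magnitude gain
  y <- bandpass_filter(sin(2 * pi * 0.05 * tv), fs)
  a <- fit_amplitude(y, 0.05, fs)
  expect_gt(a, 0.9)
  expect_lt(abs(a - analytic_bandpass_gain(0.05)), 0.01)
  # stopband: 1 Hz attenuated to ~1e-6 (3rd order, 10x cutoff, applied twice)
  y1 <- bandpass_filter(sin(2 * pi * 1 * tv), fs)
  expect_lt(fit_amplitude(y1, 1, fs), 0.01)
  # zero group delay: passband peak not shifted
  clean <- sin(2 * pi * 0.05 * tv)
  mid <- 4000:6000
  expect_lt(abs(which.max(y[mid]) - which.max(clean[mid])), 2)
  # contract errors
  expect_error(bandpass_filter(rnorm(100), fs = 0.15, high_cut = 0.1),
               "Nyquist")
  expect_error(bandpass_filter(rnorm(5), fs), "too short")
})

test_that("filtering is linear", {
  fs <- 10
  withr::with_seed(2, {
    x <- rnorm(2000); y <- rnorm(2000)
  })
  lhs <- bandpass_filter(2 * x + 3 * y, fs)
  rhs <- 2 * bandpass_filter(x, fs) + 3 * bandpass_filter(y, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("linear detrending removes exactly the least-squares line", {
  tv <- seq(0, 300, 0.2)
  # pure line -> zero
  expect_lt(max(abs(detrend_linear(2 + 3 * tv, tv))), 1e-9)
  # sinusoid + line -> sinusoid up to the line's projection onto the
  # sinusoid; the residual equals the explicit lm fit exactly
  s <- sin(2 * pi * 0.05 * tv)
  out <- detrend_linear(s + 1 + 0.01 * tv, tv)
  expect_lt(sqrt(mean((out - s)^2)), 0.05)
  oracle <- stats::residuals(stats::lm(y ~ tv, data = list(y = s + 1 + 0.01 * tv)))
  expect_lt(max(abs(out - oracle)), 1e-9)
  # zero mean and zero refit slope
  withr::with_seed(3, x <- cumsum(rnorm(500)))
  d <- detrend_linear(x)
  expect_lt(abs(mean(d)), 1e-9 * stats::sd(x))
  expect_lt(abs(stats::coef(stats::lm(d ~ seq_along(d)))[2]), 1e-9)
  # idempotent
  expect_equal(detrend_linear(d), d, tolerance = 1e-12)
})

test_that("spline motion correction repairs planted artifacts", {
  fs <- 25
  tv <- seq(0, 120 - 1 / fs, by = 1 / fs)
  withr::with_seed(11, {
    clean <- sin(2 * pi * 0.05 * tv)
    noisy <- clean + 0.03 * rnorm(length(tv))
  })
  # clean series: nothing flagged, output identical
  out0 <- motion_correct_spline(noisy, fs)
  expect_equal(nrow(attr(out0, "segments")[[1]]), 0)
  expect_equal(as.numeric(out0), noisy)

  # step artifact of 5 signal-SDs at t = 60 s
  step_at <- which(tv >= 60)[1]
  contaminated <- noisy
  contaminated[step_at:length(tv)] <-
    contaminated[step_at:length(tv)] + 5 * stats::sd(noisy)
  corrected <- motion_correct_spline(contaminated, fs)
  segs <- attr(corrected, "segments")[[1]]
  expect_gt(nrow(segs), 0)
  expect_true(any(segs[, "start"] <= step_at & segs[, "end"] >= step_at))
  rmse_before <- sqrt(mean((contaminated - clean)^2))
  rmse_after <- sqrt(mean((as.numeric(corrected) - clean)^2))
  expect_lt(rmse_after, 0.5 * rmse_before)

  # white noise at the default 5-SD threshold: < 1% flagged
  withr::with_seed(12, wn <- rnorm(5000))
  scan_frac <- detect_motion(wn, fs)$flagged_fraction
  expect_lt(scan_frac, 0.01)
  # zero-variance series: identity
  expect_equal(as.numeric(motion_correct_spline(rep(1, 100), fs)), rep(1, 100))
})

test_that("CBSI enforces the anticorrelation closed form", {
  conc <- make_conc(n_channels = 3, n_samples = 400)
  out <- motion_correct_cbsi(conc)
  alpha <- attr(out, "alpha")
  # corr(hbo', hbr') = -1 and hbr' = -hbo'/alpha exactly
  for (ch in 1:3) {
    expect_equal(stats::cor(out$hbo[ch, ], out$hbr[ch, ]), -1, tolerance = 1e-12)
    expect_equal(out$hbr[ch, ], -out$hbo[ch, ] / alpha[ch], tolerance = 1e-12)
  }
  # closed-form oracle on constructed input: hbo = s, hbr = -s/a0
  s <- sin(seq(0, 20, length.out = 500))
  a0 <- 2.5
  cc <- conc_series(matrix(s, 1), matrix(-s / a0, 1), seq(0, 49.9, 0.1))
  res <- motion_correct_cbsi(cc)
  # alpha = sd(s)/sd(s/a0) = a0; hbo' = (s - a0 * (-s/a0))/2 = s
  expect_equal(attr(res, "alpha")[1], a0, tolerance = 1e-12)
  expect_equal(res$hbo[1, ], s, tolerance = 1e-12)

  # shared artifact removal: corr(hbo', clean) >= 0.99
  withr::with_seed(13, {
    tv <- seq(0, 120, 1 / 25)
    clean <- sin(2 * pi * 0.05 * tv)
    m <- numeric(length(tv))
    m[1000:1500] <- 10                     # shared motion artifact, dominant
    hbo <- clean + m
    hbr <- -clean / 3 + m
  })
  cc2 <- conc_series(matrix(hbo, 1), matrix(hbr, 1), tv)
  res2 <- motion_correct_cbsi(cc2)
  expect_gte(stats::cor(res2$hbo[1, ], clean), 0.99)

  cc3 <- conc_series(matrix(rnorm(100), 1), matrix(0, 1, 100), (0:99) / 10)
  expect_error(motion_correct_cbsi(cc3), "sd\\(HbR\\)")
})

test_that("batch preprocessing applies steps in order and survives failures", {
  indir <- withr::local_tempdir()
  outdir <- withr::local_tempdir()
  spec <- synthetic_spec(n_channels = 4, n_subjects = 3, duration_s = 60,
                         blocks = rep(1:2, each = 2), seed = 21)
  simulate_group(spec, indir)
  res <- run_preprocessing(indir, outdir)
  expect_equal(sum(res$status == "ok"), 3)
  expect_true(file.exists(attr(res, "log_path")))
  log <- readLines(attr(res, "log_path"))
  expect_length(grep(": ok", log), 3)
  rec <- suppressMessages(read_proc(res$proc_path[1]))
  expect_equal(rec$history$step, c("od", "mbll", "bandpass", "detrend", "cbsi"))

  # reordered steps are recorded verbatim
  steps <- list(list(name = "od"), list(name = "mbll"),
                list(name = "detrend"), list(name = "bandpass"))
  res2 <- run_preprocessing(indir, withr::local_tempdir(), steps = steps)
  rec2 <- suppressMessages(read_proc(res2$proc_path[1]))
  expect_equal(rec2$history$step, c("od", "mbll", "detrend", "bandpass"))

  # empty input dir
  expect_error(run_preprocessing(withr::local_tempdir(), outdir), "no input data")

  # a corrupt file fails alone; the batch continues
  writeLines("not a mat file", file.path(indir, "broken.nirs"))
  res3 <- run_preprocessing(indir, withr::local_tempdir())
  expect_equal(sum(res3$status == "ok"), 3)
  expect_equal(sum(res3$status == "failed"), 1)
})
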