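test_that("moving_std matches a brute-force per-window computation", {
  # the documented window: centered, truncated at the edges, min 2 samples
  brute_msd <- function(x, win) {
    n <- length(x)
    half_lo <- (win - 1) %/% 2; half_hi <- win %/% 2
    vapply(seq_len(n), function(i) {
      lo <- max(1, i - half_lo); hi <- min(n, i + half_hi)
      if (hi - lo < 1) { lo <- max(1, hi - 1); if (hi - lo < 1) hi <- min(n, lo + 1) }
      stats::sd(x[lo:hi])
    }, 0)
  }
  withr::with_seed(5, {
    for (win_s in c(0.2, 0.5, 1)) {
      for (len in c(7, 50, 301)) {
        x <- rnorm(len)
        fs <- 10
        expect_equal(moving_std(x, win_s, fs), brute_msd(x, round(win_s * fs)),
                     tolerance = 1e-12)
      }
    }
  })
  # constant series -> identically zero; shift invariance
  expect_equal(moving_std(rep(3, 20), 0.5, 10), rep(0, 20))
  withr::with_seed(6, x <- rnorm(100))
  expect_equal(moving_std(x + 1e4, 0.5, 10), moving_std(x, 0.5, 10),
               tolerance = 1e-9)
  # spike localizes: [0,0,0,10,0,0,0] with a 3-sample window
  msd <- moving_std(c(0, 0, 0, 10, 0, 0, 0), 0.3, 10)
  expect_equal(which(abs(msd - max(msd)) < 1e-9), 3:5)
  expect_error(moving_std(1, 1, 1), "at least 2")
})

test_that("motion detection flags planted transients and respects the threshold", {
  fs <- 25
  withr::with_seed(7, x <- rnorm(3000))
  # clean noise: < 1% flagged at the default 5-SD rule
  expect_lt(detect_motion(x, fs)$flagged_fraction, 0.01)
  # planted transient: exactly one segment containing the spike
  y <- x
  y[1500:1520] <- y[1500:1520] + 30
  scan <- detect_motion(y, fs)
  expect_equal(nrow(scan$segments[[1]]), 1)
  expect_true(scan$segments[[1]][1, "start"] <= 1500 &&
              scan$segments[[1]][1, "end"] >= 1520)
  # infinite threshold: nothing flagged
  expect_equal(nrow(detect_motion(y, fs, threshold_sd = Inf)$segments[[1]]), 0)
  # flag count monotone nonincreasing in the threshold
  counts <- vapply(c(1, 2, 3, 5, 8), function(th)
    sum(detect_motion(y, fs, threshold_sd = th)$flagged_fraction), 0)
  expect_true(all(diff(counts) <= 0))
  # absolute-threshold mode
  expect_equal(nrow(detect_motion(y, fs, threshold_abs = 1e9)$segments[[1]]), 0)
})

test_that("channel SNR is mean over sample sd, with documented edge cases", {
  # hand arithmetic: mean 10, sample sd sqrt(16/3) = 2.3094 -> SNR 4.3301
  snr <- channel_snr(matrix(c(8, 12, 8, 12), 1))
  expect_equal(snr, 10 / sqrt(16 / 3), tolerance = 1e-9)
  expect_equal(round(snr, 4), 4.3301)
  # constant channel -> Inf marker with warning
  expect_warning(s2 <- channel_snr(rbind(c(1, 2, 3), c(5, 5, 5))), "zero-variance")
  expect_true(is.infinite(s2[2]))
  # invariant to positive rescaling
  withr::with_seed(8, x <- matrix(runif(200, 10, 12), 2))
  expect_equal(channel_snr(3.7 * x), channel_snr(x), tolerance = 1e-12)
})

test_that("correlation quality isolates uncorrelated channels", {
  n <- 500
  withr::with_seed(9, {
    shared <- sin(2 * pi * 0.05 * (1:n) / 10)
    m <- rbind(shared + 0.1 * rnorm(n), shared + 0.1 * rnorm(n),
               shared + 0.1 * rnorm(n), rnorm(n))
  })
  mac <- correlation_quality(m)
  expect_equal(which.min(mac), 4)
  expect_true(all(mac >= 0 & mac <= 1))
  # identical channels -> all mean |r| = 1
  same <- matrix(rep(shared, 3), 3, byrow = TRUE)
  expect_equal(correlation_quality(same), rep(1, 3), tolerance = 1e-12)
  expect_error(correlation_quality(m[1:2, ]), ">= 3 channels")
})

test_that("qc_report combines the three checks into a verdict", {
  spec <- synthetic_spec(n_channels = 6, duration_s = 60,
                         blocks = rep(1:2, each = 3), seed = 31)
  sim <- simulate_concentrations(spec)
  params <- mbll_params(c(690, 830), rep(3, 6))
  rec <- forward_model(sim$conc, params)
  # clean subject passes with no flagged channels
  rep0 <- qc_report(rec, sim$conc)
  expect_equal(rep0$subject_verdict, "pass")
  expect_length(rep0$flagged_channels, 0)

  # dead channel: flagged for low SNR (and low correlation), strict threshold
  rec_dead <- inject_dead_channel(rec, 3, target_snr = 2, seed = 32)
  conc_dead <- od_to_concentration(intensity_to_od(rec_dead), params,
                                   rec_dead$time, rec_dead$probe)
  rep1 <- suppressWarnings(qc_report(rec_dead, conc_dead, channel_frac_max = 0))
  expect_equal(rep1$subject_verdict, "fail")
  expect_true(3 %in% rep1$flagged_channels)
  expect_match(rep1$channels$reasons[3], "low-snr")

  # heavy motion: fail with reason motion when 30% of time is contaminated.
  # Contamination this extensive inflates the MSD's own mean and sd, so the
  # adaptive rule needs a low multiplier to separate the two regimes (with
  # the default 5 the threshold ends up above the artifact itself).
  conc_mot <- sim$conc
  n <- ncol(conc_mot$hbo)
  idx <- seq(round(0.6 * n), round(0.9 * n))
  bursts <- sin(2 * pi * 3 * seq_along(idx) / 25) * 50 * stats::sd(conc_mot$hbo)
  conc_mot$hbo[, idx] <- sweep(conc_mot$hbo[, idx], 2, bursts, `+`)
  conc_mot$hbt <- conc_mot$hbo + conc_mot$hbr
  rep2 <- qc_report(rec, conc_mot, time_frac_max = 0.1, threshold_sd = 1)
  expect_equal(rep2$subject_verdict, "fail")
  expect_true(any(grepl("motion", rep2$verdict_reasons)))

  # tabular export: one row per channel + one summary row per subject
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qc_table(list(rep0, rep1), path)
  tab <- utils::read.delim(path)
  expect_equal(sum(tab$row_type == "channel"), 12)
  expect_equal(sum(tab$row_type == "subject"), 2)
  expect_equal(tab$verdict[tab$row_type == "subject"], c("pass", "fail"))
})
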