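# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures are stored.

# Minimal two-wavelength probe with one source-detector pair per channel.
make_probe <- function(n_channels = 4, wavelengths = c(690, 830), sep = 3) {
  src <- cbind(sep * (seq_len(n_channels) - 1), 0, 0)
  det <- cbind(sep * (seq_len(n_channels) - 1) + sep, 0, 0)
  ml <- do.call(rbind, lapply(seq_along(wavelengths), function(w)
    cbind(seq_len(n_channels), seq_len(n_channels), w)))
  probe_geometry(src, det, ml, wavelengths)
}

# Raw recording with smooth positive intensities.
make_recording <- function(n_channels = 4, n_samples = 100, fs = 10, seed = 1) {
  probe <- make_probe(n_channels)
  withr::with_seed(seed, {
    tv <- (seq_len(n_samples) - 1) / fs
    intensity <- matrix(0, 2 * n_channels, n_samples)
    for (r in seq_len(2 * n_channels))
      intensity[r, ] <- 1 + 0.05 * sin(2 * pi * 0.05 * tv + r) +
        0.005 * rnorm(n_samples)
    raw_recording(intensity, tv, probe, "fixture")
  })
}

# Hitachi-dialect CSV fixture text for n channels x 2 wavelengths.
make_csv_lines <- function(values, sampling_period = 0.1,
                           wavelengths = c(695, 830)) {
  c("File Version,1.0",
    sprintf("Sampling Period[s],%g", sampling_period),
    sprintf("Wavelength[nm],%s", paste(wavelengths, collapse = ",")),
    "Data",
    apply(values, 1, paste, collapse = ","))
}

# Synthetic concentration series with planted band-limited sinusoids.
make_conc <- function(n_channels = 4, n_samples = 500, fs = 10, seed = 1) {
  withr::with_seed(seed, {
    tv <- (seq_len(n_samples) - 1) / fs
    hbo <- t(sapply(seq_len(n_channels), function(ch)
      0.05 * sin(2 * pi * 0.05 * tv + ch / 2) + 0.002 * rnorm(n_samples)))
    hbr <- -hbo / 3 + 0.002 * matrix(rnorm(n_channels * n_samples),
                                     n_channels, n_samples)
    conc_series(hbo, hbr, tv)
  })
}
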