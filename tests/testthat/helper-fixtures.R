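# shared fixture builders for the test suite

# a minimal scan object on an arbitrary grid
make_scan <- function(data, subject_id = "s1", group = "old", tr = 2.6,
                      motion = NULL, dims = NULL) {
  scan <- list(subject_id = subject_id, group = group, data = data,
               dims = dims, tr = tr, motion = motion)
  class(scan) <- "cohort_scan"
  scan
}

# slow-5 fALFF of a series through the standard measurement chain
measure_falff <- function(series, tr, numerator = "slow5",
                          denominator = "full", sigma_bins = 2) {
  sp <- smooth_spectrum(amplitude_spectrum(series, tr), sigma_bins)
  sch <- band_scheme(max(sp$freqs))
  band_falff(sp, get_band(sch, numerator), get_band(sch, denominator))
}

# constant (flat) amplitude spectrum on the Fourier grid of an n-point scan
flat_spectrum <- function(n = 2200, tr = 2.6, value = 1) {
  half <- floor(n / 2)
  sp <- list(freqs = (0:half) / (n * tr),
             amplitude = rep(value, half + 1L),
             smoothed = NULL, tr = tr, n = n)
  class(sp) <- "component_spectrum"
  sp
}

# small four-group cohort spec shared across tests (desk scale)
small_spec <- function(n_per_group = 3L, ...) {
  cohort_spec(n_per_group = n_per_group, ...)
}
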