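#' One-sided amplitude spectrum of a component time course
#'
#' Computes the single-sided magnitude spectrum of a detrended, zero-mean
#' series by FFT, without windowing. The amplitude convention is the square
#' root of power: a unit-amplitude cosine at an on-grid frequency yields an
#' amplitude of 1 at that frequency. Frequencies are
#' \code{f_k = k / (T * tr)} for \code{k = 0 .. floor(T/2)}.
#'
#' @param series Numeric time series (one component, one subject).
#' @param tr Repetition time in seconds (sampling interval).
#' @return Object of class \code{component_spectrum}: list with \code{freqs}
#'   (Hz), \code{amplitude}, \code{smoothed} (NULL until
#'   \code{\link{smooth_spectrum}} is applied), \code{tr} and \code{n}.
#' @examples
#' x <- cos(2 * pi * 0.02 * (0:219) * 2.6)
#' sp <- amplitude_spectrum(x, 2.6)
#' sp$freqs[which.max(sp$amplitude)]
#' @export
amplitude_spectrum <- function(series, tr) {
  if (anyNA(series) || any(!is.finite(series))) {
    stop("series contains missing or non-finite values")
  }
  if (!is.numeric(tr) || tr <= 0) stop("'tr' must be a positive duration (s)")
  n <- length(series)
  if (n < 8L) stop("series too short for spectral analysis")
  half <- floor(n / 2)
  x <- fft(series)[seq_len(half + 1L)]
  amp <- Mod(x) * 2 / n
  # DC (and Nyquist for even n) are not doubled in a one-sided spectrum
  amp[1L] <- amp[1L] / 2
  if (n %% 2L == 0L) amp[half + 1L] <- amp[half + 1L] / 2
  out <- list(
    freqs = (0:half) / (n * tr),
    amplitude = amp,
    smoothed = NULL,
    tr = tr,
    n = n
  )
  class(out) <- "component_spectrum"
  out
}

#' @export
print.component_spectrum <- function(x, ...) {
  cat("Component amplitude spectrum:", length(x$freqs), "frequencies,",
      "0 to", format(max(x$freqs), digits = 5), "Hz",
      if (!is.null(x$smoothed)) "(smoothed)" else "(raw)", "\n")
  invisible(x)
}

#' Gaussian smoothing of an amplitude spectrum
#'
#' Convolves the amplitude spectrum with a Gaussian kernel along the
#' frequency axis. The width \code{sigma_bins} is expressed in Fourier-bin
#' units. Boundaries are handled by reflection, so total amplitude mass in
#' the interior of the axis is conserved.
#'
#' @param spec A \code{component_spectrum}.
#' @param sigma_bins Gaussian standard deviation in Fourier bins (default 2).
#' @return The spectrum with its \code{smoothed} field filled in.
#' @export
smooth_spectrum <- function(spec, sigma_bins = 2) {
  stopifnot(inherits(spec, "component_spectrum"))
  if (!is.numeric(sigma_bins) || sigma_bins <= 0) {
    stop("'sigma_bins' must be a positive width")
  }
  spec$smoothed <- gauss_smooth(spec$amplitude, sigma_bins)
  spec$sigma_bins <- sigma_bins
  spec
}

# reflect-padded Gaussian convolution of a numeric vector
gauss_smooth <- function(y, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  r <- min(r, n - 1L)
  k <- k[(length(k) + 1L) / 2 + (-r:r)]
  k <- k / sum(k)
  padded <- c(y[(r + 1L):2L], y, y[(n - 1L):(n - r)])
  as.numeric(stats::filter(padded, k, sides = 2))[(r + 1L):(r + n)]
}

#' Resample a smoothed spectrum onto a discrete bin grid
#'
#' Linearly interpolates the smoothed amplitude spectrum at the centers of
#' the discrete frequency bins. The default bin width (0.0015 Hz) is finer
#' than the native Fourier resolution of a 10-minute scan (about 0.0017 Hz),
#' so interpolation rather than aggregation is the appropriate resampling.
#'
#' @param spec A smoothed \code{component_spectrum}.
#' @param grid A \code{\link{bin_grid}}.
#' @return Numeric vector of bin amplitudes, one per bin center.
#' @export
resample_to_bins <- function(spec, grid = bin_grid()) {
  stopifnot(inherits(spec, "component_spectrum"), inherits(grid, "bin_grid"))
  if (is.null(spec$smoothed)) stop("spectrum must be smoothed first")
  nyq <- max(spec$freqs)
  if (max(grid$edges) > nyq + 1e-12) {
    stop("bin grid extends beyond the Nyquist frequency (", nyq, " Hz)")
  }
  approx(spec$freqs, spec$smoothed, xout = grid$centers)$y
}

#' Band-limited fractional amplitude (fALFF)
#'
#' Fractional amplitude of low-frequency fluctuation for a numerator band
#' within a denominator band: the sum of (smoothed) amplitudes at Fourier
#' frequencies inside the numerator divided by the sum inside the
#' denominator. Slow-5 fALFF uses numerator \code{[0.01, 0.027)} over the
#' full acquired range \code{[0, Nyquist]}; resting-state fALFF uses
#' \code{[0.01, 0.073)} over the full range.
#'
#' @param spec A \code{component_spectrum} (smoothed unless
#'   \code{use_smoothed = FALSE}).
#' @param numerator,denominator Bands (one-row data frames from
#'   \code{\link{get_band}} or lists with \code{lo}, \code{hi},
#'   \code{closed_upper}).
#' @param use_smoothed Use the smoothed spectrum (default); set FALSE for a
#'   raw-spectrum sensitivity analysis.
#' @return fALFF value in [0, 1].
#' @export
band_falff <- function(spec, numerator, denominator,
                       use_smoothed = TRUE) {
  stopifnot(inherits(spec, "component_spectrum"))
  amp <- if (use_smoothed) {
    if (is.null(spec$smoothed)) stop("spectrum must be smoothed first")
    spec$smoothed
  } else {
    spec$amplitude
  }
  if (numerator$lo < denominator$lo - 1e-12 ||
      numerator$hi > denominator$hi + 1e-12) {
    stop("numerator band must lie inside the denominator band")
  }
  num <- sum(amp[band_mask(spec$freqs, numerator)])
  den <- sum(amp[band_mask(spec$freqs, denominator)])
  if (den <= 0) {
    stop("degenerate series: zero amplitude mass in the denominator band")
  }
  num / den
}

#' Share of slow-5 amplitude within the resting-state band
#'
#' Ratio of slow-5 oscillation amplitude to the combined resting-state
#' oscillation amplitude (slow-5 plus slow-4).
#'
#' @inheritParams band_falff
#' @param scheme A \code{\link{band_scheme}}.
#' @return Value in [0, 1].
#' @export
slow5_share <- function(spec, scheme, use_smoothed = TRUE) {
  band_falff(spec, get_band(scheme, "slow5"), get_band(scheme, "resting"),
             use_smoothed = use_smoothed)
}

#' Combine component spectra into a composite
#'
#' Unweighted per-frequency mean of several component spectra on an
#' identical frequency grid, used to form composite networks (the three
#' default-mode subcomponents into a representative DMN, visual plus
#' sensorimotor into a task-positive composite).
#'
#' @param specs List of \code{component_spectrum} objects.
#' @return A composite \code{component_spectrum}.
#' @export
combine_component_spectra <- function(specs) {
  stopifnot(length(specs) >= 1L)
  f0 <- specs[[1L]]$freqs
  for (s in specs) {
    if (length(s$freqs) != length(f0) || any(abs(s$freqs - f0) > 1e-12)) {
      stop("component spectra are on different frequency grids")
    }
  }
  out <- specs[[1L]]
  out$amplitude <- rowMeans(sapply(specs, `[[`, "amplitude"))
  sm <- lapply(specs, `[[`, "smoothed")
  out$smoothed <- if (any(vapply(sm, is.null, logical(1L)))) NULL
                  else rowMeans(do.call(cbind, sm))
  out
}

#' fALFF table for a cohort of component time courses
#'
#' Computes, for every subject and component, the band-limited fALFF values
#' feeding the statistics layer: slow-5 and slow-4 over the full acquired
#' range, the resting-state fALFF (0.01--0.073 Hz over full), and the
#' slow-5 share of the resting band.
#'
#' @param timecourses Named list (by subject id) of time-by-component
#'   matrices with component labels as column names.
#' @param groups Named character vector or list mapping subject id to group
#'   label.
#' @param tr Repetition time in seconds.
#' @param sigma_bins Spectral smoothing width in Fourier bins.
#' @param use_smoothed Compute fALFF from the smoothed spectrum (default).
#' @return Data frame of class \code{falff_table} with columns
#'   \code{subject_id}, \code{group}, \code{component}, \code{band},
#'   \code{falff}, \code{denominator}.
#' @export
falff_table <- function(timecourses, groups, tr, sigma_bins = 2,
                        use_smoothed = TRUE) {
  stopifnot(length(timecourses) >= 1L)
  n <- nrow(timecourses[[1L]])
  scheme <- band_scheme(nyquist_freq(n, tr))
  slow5 <- get_band(scheme, "slow5")
  slow4 <- get_band(scheme, "slow4")
  resting <- get_band(scheme, "resting")
  full <- get_band(scheme, "full")
  rows <- vector("list", length(timecourses))
  for (i in seq_along(timecourses)) {
    sid <- names(timecourses)[i]
    tc <- timecourses[[i]]
    comps <- colnames(tc)
    vals <- lapply(seq_len(ncol(tc)), function(j) {
      sp <- smooth_spectrum(amplitude_spectrum(tc[, j], tr), sigma_bins)
      c(slow5 = band_falff(sp, slow5, full, use_smoothed),
        slow4 = band_falff(sp, slow4, full, use_smoothed),
        resting = band_falff(sp, resting, full, use_smoothed),
        slow5_share = band_falff(sp, slow5, resting, use_smoothed))
    })
    rows[[i]] <- data.frame(
      subject_id = sid,
      group = unname(groups[[sid]]),
      component = rep(comps, each = 4L),
      band = rep(c("slow5", "slow4", "resting", "slow5_share"),
                 times = length(comps)),
      falff = unlist(vals),
      denominator = rep(c("full", "full", "full", "resting"),
                        times = length(comps)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("falff_table", "data.frame")
  out
}

# Nyquist frequency of a scan with n volumes at repetition time tr
nyquist_freq <- function(n, tr) floor(n / 2) / (n * tr)
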