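#' Synthesize a band-structured component time course
#'
#' Builds a component time course as the sum of (a) random-phase sinusoids at
#' every Fourier frequency inside the slow-5 band, scaled so the slow-5 part
#' has root-mean-square amplitude \code{slow5_amp}, (b) the same for slow-4,
#' and (c) white Gaussian noise with standard deviation \code{broadband_amp}.
#' Phases are drawn independently per sinusoid. The output is zero-mean and
#' reproducible under a fixed seed.
#'
#' @param slow5_amp,slow4_amp RMS amplitude allocated to the slow-5 and
#'   slow-4 bands (arbitrary BOLD units, non-negative).
#' @param broadband_amp Standard deviation of the white broadband component.
#' @param n_volumes Number of time points (>= 64).
#' @param tr Repetition time in seconds.
#' @param seed Optional integer seed; when given, the draw is deterministic.
#' @param grid_n Length of the Fourier grid on which the sinusoid
#'   frequencies are placed (default \code{n_volumes}). A cohort whose scans
#'   lose their first volumes to magnetization equilibration is generated
#'   with \code{grid_n} equal to the retained length, so the oscillations
#'   sit exactly on the analysis grid of the retained segment.
#' @return Numeric vector of length \code{n_volumes}.
#' @examples
#' x <- synth_component_timecourse(1, 0, 0, 230, 2.6, seed = 1)
#' @export
synth_component_timecourse <- function(slow5_amp, slow4_amp, broadband_amp,
                                       n_volumes, tr, seed = NULL,
                                       grid_n = n_volumes) {
  if (any(c(slow5_amp, slow4_amp, broadband_amp) < 0)) {
    stop("band amplitudes must be non-negative")
  }
  if (n_volumes < 64L) stop("'n_volumes' must be at least 64")
  if (!is.null(seed)) set.seed(seed)
  scheme <- band_scheme(nyquist_freq(grid_n, tr))
  tgrid <- (seq_len(n_volumes) - 1L) * tr
  x <- numeric(n_volumes)
  for (b in list(c("slow5", slow5_amp), c("slow4", slow4_amp))) {
    amp <- as.numeric(b[2L])
    if (amp == 0) next
    fs <- band_freqs(grid_n, tr, get_band(scheme, b[1L]))
    if (length(fs) == 0L) next
    c_bin <- amp * sqrt(2 / length(fs))
    phases <- runif(length(fs), 0, 2 * pi)
    x <- x + c_bin * colSums(cos(outer(fs, tgrid, function(f, t)
      2 * pi * f * t) + phases))
  }
  if (broadband_amp > 0) x <- x + rnorm(n_volumes, sd = broadband_amp)
  x - mean(x)
}

# Fourier frequencies (k = 1 .. floor(n/2)) of an n-point series at
# sampling interval tr that fall inside a band
band_freqs <- function(n, tr, band) {
  fs <- (1:floor(n / 2)) / (n * tr)
  fs[band_mask(fs, band)]
}

#' Expected amplitude spectrum of a synthetic component time course
#'
#' Analytic expectation of the one-sided amplitude spectrum produced by
#' \code{\link{synth_component_timecourse}}: per-bin sinusoid amplitudes
#' inside the slow bands combined (in quadrature) with the Rayleigh-mean
#' amplitude of the white broadband component. Used to compute generative
#' fALFF targets against which the measured pipeline values are checked.
#'
#' @inheritParams synth_component_timecourse
#' @return A \code{component_spectrum} holding the expected amplitudes.
#' @export
expected_amplitude_spectrum <- function(slow5_amp, slow4_amp, broadband_amp,
                                        n_volumes, tr) {
  scheme <- band_scheme(nyquist_freq(n_volumes, tr))
  half <- floor(n_volumes / 2)
  freqs <- (0:half) / (n_volumes * tr)
  amp <- numeric(half + 1L)
  for (b in list(c("slow5", slow5_amp), c("slow4", slow4_amp))) {
    a <- as.numeric(b[2L])
    if (a == 0) next
    mask <- band_mask(freqs, get_band(scheme, b[1L])) & freqs > 0
    if (any(mask)) amp[mask] <- a * sqrt(2 / sum(mask))
  }
  if (broadband_amp > 0) {
    noise <- rep(broadband_amp * sqrt(pi / n_volumes), half + 1L)
    # DC is removed by demeaning; Nyquist bin (even n) is real-valued
    noise[1L] <- 0
    if (n_volumes %% 2L == 0L) {
      noise[half + 1L] <- broadband_amp * sqrt(2 / (pi * n_volumes))
    }
    amp <- sqrt(amp^2 + noise^2)
  }
  amp[1L] <- 0
  out <- list(freqs = freqs, amplitude = amp, smoothed = NULL, tr = tr,
              n = n_volumes)
  class(out) <- "component_spectrum"
  out
}

#' Generative fALFF implied by planted band amplitudes
#'
#' @inheritParams synth_component_timecourse
#' @param numerator,denominator Band labels (see \code{\link{band_scheme}}).
#' @param sigma_bins Smoothing width applied to the expected spectrum, to
#'   mirror the measurement pipeline.
#' @return Expected fALFF value.
#' @export
generative_falff <- function(slow5_amp, slow4_amp, broadband_amp,
                             n_volumes, tr, numerator = "slow5",
                             denominator = "full", sigma_bins = 2) {
  sp <- expected_amplitude_spectrum(slow5_amp, slow4_amp, broadband_amp,
                                    n_volumes, tr)
  sp <- smooth_spectrum(sp, sigma_bins)
  scheme <- band_scheme(nyquist_freq(n_volumes, tr))
  band_falff(sp, get_band(scheme, numerator), get_band(scheme, denominator))
}

# Invert the generative model: find (slow5_amp, slow4_amp) such that the
# expected smoothed spectrum has slow-5 fALFF `falff5` (over the full band)
# and total resting-band amplitude mass `lf_mass`. Fixed-point iteration on
# the band masses; converges in a few steps because cross-band smoothing
# leakage is a small perturbation.
solve_band_amplitudes <- function(falff5, lf_mass, broadband_amp,
                                  n_volumes, tr, sigma_bins = 2) {
  scheme <- band_scheme(nyquist_freq(n_volumes, tr))
  masses <- function(a5, a4) {
    sp <- smooth_spectrum(
      expected_amplitude_spectrum(a5, a4, broadband_amp, n_volumes, tr),
      sigma_bins)
    c(m5 = sum(sp$smoothed[band_mask(sp$freqs, get_band(scheme, "slow5"))]),
      m4 = sum(sp$smoothed[band_mask(sp$freqs, get_band(scheme, "slow4"))]),
      full = sum(sp$smoothed[band_mask(sp$freqs, get_band(scheme, "full"))]))
  }
  # noise-only masses fix the target split
  m0 <- masses(0, 0)
  m5_target <- falff5 * (lf_mass + (m0["full"] - m0["m5"] - m0["m4"]))
  # refine: full mass depends weakly on the split; iterate
  a5 <- max(m5_target - m0["m5"], 1e-6) / sqrt(2 * n_slow_bins(n_volumes, tr, "slow5"))
  a4 <- max(lf_mass - m5_target - m0["m4"], 1e-6) /
    sqrt(2 * n_slow_bins(n_volumes, tr, "slow4"))
  for (i in 1:8) {
    m <- masses(a5, a4)
    m5_target <- falff5 * (m["full"] - m["m5"] - m["m4"] + lf_mass)
    m4_target <- lf_mass - m5_target
    a5 <- a5 * as.numeric(m5_target / m["m5"])
    a4 <- a4 * as.numeric(m4_target / m["m4"])
  }
  c(slow5_amp = a5, slow4_amp = a4)
}

n_slow_bins <- function(n, tr, label) {
  scheme <- band_scheme(nyquist_freq(n, tr))
  length(band_freqs(n, tr, get_band(scheme, label)))
}

#' Default spatial network templates
#'
#' Analytic non-negative spatial maps for the five planted intrinsic
#' connectivity networks (posterior, anterior and ventral default-mode
#' subcomponents, primary visual, primary sensorimotor), built as sums of
#' Gaussian blobs on a small voxel grid. Blob centers are placed so that
#' pairwise spatial correlations stay below 0.3.
#'
#' @param dims Grid dimensions (voxels), default \code{c(20, 24, 20)}.
#' @return Matrix voxels x 5 with component labels as column names; each
#'   column has peak value 1. The grid dimensions are kept in the
#'   \code{"dims"} attribute.
#' @export
network_templates <- function(dims = c(20, 24, 20)) {
  blobs <- list(
    pDMN   = list(c(10, 6, 12, 2.2), c(4, 8, 11, 1.8), c(16, 8, 11, 1.8)),
    aDMN   = list(c(10, 20, 11, 2.5)),
    vDMN   = list(c(10, 11, 4, 2.2)),
    visual = list(c(10, 2, 6, 2.0)),
    motor  = list(c(4, 15, 17, 2.0), c(16, 15, 17, 2.0))
  )
  grid <- as.matrix(expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                                z = seq_len(dims[3L])))
  maps <- sapply(blobs, function(bl) {
    m <- numeric(nrow(grid))
    for (b in bl) {
      d2 <- (grid[, 1L] - b[1L])^2 + (grid[, 2L] - b[2L])^2 +
        (grid[, 3L] - b[3L])^2
      m <- m + exp(-d2 / (2 * b[4L]^2))
    }
    m / max(m)
  })
  attr(maps, "dims") <- dims
  maps
}

#' Default slow-5 fALFF group targets
#'
#' Generative per-group, per-component slow-5 fALFF means. The old-healthy
#' and stroke-late columns follow the printed group means of the motivating
#' study; stroke-early equals old-healthy (no observed difference), and the
#' young-healthy column applies the aging pattern in reverse: higher DMN
#' slow-5 fALFF, lower task-positive slow-5 fALFF.
#'
#' @return Matrix components x groups of slow-5 fALFF targets.
#' @export
default_falff_targets <- function() {
  comps <- c("pDMN", "aDMN", "vDMN", "visual", "motor")
  old <- c(0.383, 0.401, 0.349, 0.429, 0.437)
  late <- c(0.329, 0.335, 0.305, 0.385, 0.376)
  young <- old + c(0.035, 0.035, 0.035, -0.045, -0.045)
  out <- cbind(young = young, old = old, stroke_early = old,
               stroke_late = late)
  rownames(out) <- comps
  out
}

#' Ground-truth specification for a synthetic cohort
#'
#' Describes a four-group resting-state cohort (young healthy, old healthy,
#' early-stage stroke, late-stage stroke) with five planted spatial networks
#' whose time courses allocate amplitude across the slow-5 and slow-4 bands
#' plus broadband noise. Per-band RMS amplitudes are derived from the
#' slow-5 fALFF targets under the constraint that total resting-band
#' amplitude mass equals \code{lf_mass[group]}; for the stroke-late group
#' this mass equals the old-healthy mass, so the slow-5 deficit is a pure
#' reallocation toward slow-4 with no net change in resting-state power.
#'
#' Band amplitudes are solved on the Fourier grid of the retained segment
#' (\code{n_volumes - n_discard} volumes), the grid on which the analysis
#' pipeline measures spectra, and the planted sinusoid frequencies are
#' placed on that same grid; the generative fALFF targets therefore refer to
#' the post-equilibration analysis spectra.
#'
#' @param n_per_group Subjects per group (default 12, desk scale).
#' @param n_volumes Time points per scan (default 230, a 10-minute scan at
#'   TR 2.6 s).
#' @param n_discard Leading volumes the preprocessing stage is expected to
#'   drop (default 10).
#' @param tr Repetition time in seconds (default 2.6).
#' @param noise_sd Voxel-level white noise SD added to the mixed data.
#' @param subject_sdlog Log-normal SD of the per-subject multiplicative
#'   jitter on band amplitudes (between-subject dispersion; the default 0.3
#'   yields a measured slow-5 fALFF SD of roughly 0.1).
#' @param broadband_amp White broadband RMS inside each component time
#'   course.
#' @param falff_targets Matrix of slow-5 fALFF targets
#'   (\code{\link{default_falff_targets}}).
#' @param lf_mass Total resting-band amplitude mass: a named vector (per
#'   group) or a components x groups matrix. The default gives every cell
#'   mass 1 except the young default-mode components (1.15), encoding the
#'   aging-related loss of total resting-state power that is specific to the
#'   default-mode network.
#' @param dims Voxel grid dimensions.
#' @param motion_rms_mm Target RMS framewise displacement of the synthetic
#'   motion tracks.
#' @param seed Default seed used by \code{\link{simulate_cohort}}.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 12L, n_volumes = 230L, n_discard = 10L,
                        tr = 2.6, noise_sd = 0.06, subject_sdlog = 0.3,
                        broadband_amp = 0.004,
                        falff_targets = default_falff_targets(),
                        lf_mass = NULL,
                        dims = c(20, 24, 20), motion_rms_mm = 0.1,
                        seed = 1L) {
  n_analysis <- as.integer(n_volumes - n_discard)
  if (n_analysis * tr <= 3 / 0.017) {
    stop("scan too short: the slow-5 band must contain at least 3 Fourier frequencies")
  }
  groups <- colnames(falff_targets)
  maps <- network_templates(dims)
  comps <- colnames(maps)
  stopifnot(all(rownames(falff_targets) == comps))
  if (is.null(lf_mass)) {
    lf_mass <- matrix(1, nrow = length(comps), ncol = length(groups),
                      dimnames = list(comps, groups))
    if ("young" %in% groups) {
      dmn <- intersect(comps, c("pDMN", "aDMN", "vDMN"))
      lf_mass[dmn, "young"] <- 1.15
    }
  } else if (is.null(dim(lf_mass))) {
    stopifnot(all(groups %in% names(lf_mass)))
    lf_mass <- matrix(rep(lf_mass[groups], each = length(comps)),
                      nrow = length(comps),
                      dimnames = list(comps, groups))
  }
  amps <- array(NA_real_, dim = c(length(comps), length(groups), 3L),
                dimnames = list(comps, groups,
                                c("slow5_amp", "slow4_amp", "broadband_amp")))
  for (g in groups) {
    for (cc in comps) {
      a <- solve_band_amplitudes(falff_targets[cc, g], lf_mass[cc, g],
                                 broadband_amp, n_analysis, tr)
      amps[cc, g, ] <- c(a, broadband_amp)
    }
  }
  out <- list(n_per_group = as.integer(n_per_group), groups = groups,
              n_volumes = as.integer(n_volumes),
              n_discard = as.integer(n_discard),
              n_analysis = n_analysis, tr = tr,
              noise_sd = noise_sd, subject_sdlog = subject_sdlog,
              maps = maps, components = comps, band_amps = amps,
              falff_targets = falff_targets, lf_mass = lf_mass,
              dims = dims, motion_rms_mm = motion_rms_mm,
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification:\n",
      " ", length(x$groups), "groups x", x$n_per_group, "subjects,",
      x$n_volumes, "volumes at TR", x$tr, "s\n",
      " ", length(x$components), "planted networks on a",
      paste(x$dims, collapse = "x"), "grid\n")
  invisible(x)
}

#' Simulate a multi-subject resting-state cohort
#'
#' Generates one scan per subject: the planted spatial maps mixed with
#' band-structured component time courses (per-subject amplitudes jittered
#' log-normally around the group values) plus white voxel noise, together
#' with a synthetic motion track. Ground truth (maps, time courses,
#' amplitudes, and per-subject generative fALFF targets) is returned
#' alongside.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param seed Integer seed; defaults to the seed recorded in the spec.
#'   Fixing it makes the output byte-identical across runs.
#' @return Object of class \code{cohort}: list with \code{scans} (each a
#'   \code{cohort_scan} with fields \code{subject_id}, \code{group},
#'   \code{data} voxels x time, \code{dims}, \code{tr}, \code{motion}) and
#'   \code{ground_truth}.
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  cmat <- cor(spec$maps)
  if (any(abs(cmat[upper.tri(cmat)]) >= 0.3)) {
    stop("planted spatial maps violate the pairwise correlation < 0.3 invariant")
  }
  set.seed(seed)
  scans <- list()
  truth_tc <- list()
  truth_amps <- list()
  comps <- spec$components
  n <- spec$n_volumes
  for (g in spec$groups) {
    for (j in seq_len(spec$n_per_group)) {
      sid <- sprintf("%s_%02d", g, j)
      amps <- spec$band_amps[, g, , drop = TRUE]
      jit <- matrix(exp(rnorm(length(comps) * 2L, 0, spec$subject_sdlog)),
                    ncol = 2L)
      amps[, 1L] <- amps[, 1L] * jit[, 1L]
      amps[, 2L] <- amps[, 2L] * jit[, 2L]
      tc <- sapply(comps, function(cc) {
        synth_component_timecourse(amps[cc, 1L], amps[cc, 2L], amps[cc, 3L],
                                   n, spec$tr, grid_n = spec$n_analysis)
      })
      data <- spec$maps %*% t(tc)
      if (spec$noise_sd > 0) {
        data <- data + matrix(rnorm(length(data), sd = spec$noise_sd),
                              nrow = nrow(data))
      }
      motion <- synth_motion_track(n, spec$motion_rms_mm)
      scan <- list(subject_id = sid, group = g, data = data,
                   dims = spec$dims, tr = spec$tr, motion = motion)
      class(scan) <- "cohort_scan"
      scans[[sid]] <- scan
      truth_tc[[sid]] <- tc
      truth_amps[[sid]] <- amps
    }
  }
  gt_falff <- if (length(truth_tc) > 0L) {
    groups <- vapply(scans, `[[`, character(1L), "group")
    # generative targets refer to the analysis segment the pipeline sees
    retained <- lapply(truth_tc, function(tc) {
      seg <- tc[(spec$n_discard + 1L):n, , drop = FALSE]
      sweep(seg, 2L, colMeans(seg))
    })
    falff_table(retained, groups, spec$tr)
  } else NULL
  out <- list(
    scans = scans,
    ground_truth = list(maps = spec$maps, timecourses = truth_tc,
                        band_amps = truth_amps, falff = gt_falff),
    spec = spec, seed = seed
  )
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$scans), "scans")
  if (length(x$scans) > 0L) {
    tab <- table(vapply(x$scans, `[[`, character(1L), "group"))
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Synthesize a six-parameter rigid-body motion track
#'
#' Smooth mean-reverting random track (three translations in mm, three
#' rotations in degrees): each parameter follows a first-order
#' autoregressive process (coefficient 0.95) whose increments are smoothed
#' with a short moving average, then the whole track is rescaled so the
#' realized root-mean-square framewise displacement (Euclidean norm of
#' backward differences, rotations converted to mm on a 50-mm radius) equals
#' \code{rms_mm}. Mean reversion keeps the peak-to-peak excursion of a
#' typical still subject well below motion-exclusion thresholds while the
#' framewise displacement matches the target.
#'
#' @param n_volumes Number of frames.
#' @param rms_mm Target RMS framewise displacement in mm (0 gives a constant
#'   track).
#' @param seed Optional integer seed.
#' @return Matrix n_volumes x 6 with columns x, y, z, roll, pitch, yaw.
#' @export
synth_motion_track <- function(n_volumes, rms_mm = 0.1, seed = NULL) {
  if (rms_mm < 0) stop("'rms_mm' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  track <- matrix(0, nrow = n_volumes, ncol = 6L,
                  dimnames = list(NULL, c("x", "y", "z",
                                          "roll", "pitch", "yaw")))
  if (rms_mm == 0 || n_volumes < 2L) return(track)
  rho <- 0.95
  k <- rep(1 / 3, 3)
  for (j in 1:6) {
    eps <- rnorm(n_volumes)
    eps <- as.numeric(stats::filter(c(eps[2:3], eps, eps[(n_volumes - 2):(n_volumes - 1)]),
                                    k, sides = 2))[3:(2 + n_volumes)]
    x <- numeric(n_volumes)
    for (t in 2:n_volumes) x[t] <- rho * x[t - 1L] + eps[t]
    track[, j] <- x - x[1L]
  }
  track[, 4:6] <- track[, 4:6] / (50 * pi / 180)  # degrees, 50-mm lever arm
  e <- motion_enorm(track)
  track * (rms_mm / sqrt(mean(e[-1L]^2)))
}
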