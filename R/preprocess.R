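#' Discard equilibration volumes and detrend voxel time series
#'
#' Removes the first \code{n_discard} volumes (magnetization equilibration)
#' from the data and the motion track, then removes a polynomial trend of
#' order \code{detrend_order} (0 = mean, 1 = mean + linear) from every voxel
#' series. Output series are zero-mean.
#'
#' @param scan A \code{cohort_scan} (fields \code{data} voxels x time,
#'   \code{motion}, \code{tr}).
#' @param n_discard Number of initial volumes to drop (default 10).
#' @param detrend_order 0 or 1 (default 1).
#' @return The scan with shortened, detrended data.
#' @export
discard_and_detrend <- function(scan, n_discard = 10L, detrend_order = 1L) {
  stopifnot(inherits(scan, "cohort_scan"))
  n <- ncol(scan$data)
  if (n <= n_discard + 20L) {
    stop("scan too short: ", n, " volumes with ", n_discard, " to discard")
  }
  if (!detrend_order %in% c(0L, 1L)) stop("'detrend_order' must be 0 or 1")
  keep <- (n_discard + 1L):n
  x <- scan$data[, keep, drop = FALSE]
  scan$data <- detrend_rows(x, detrend_order)
  if (!is.null(scan$motion)) scan$motion <- scan$motion[keep, , drop = FALSE]
  scan$n_discarded <- as.integer(n_discard)
  scan
}

# remove order-0 or order-1 trend from each row of a matrix
detrend_rows <- function(x, order) {
  if (order == 0L) return(x - rowMeans(x))
  tgrid <- seq_len(ncol(x))
  basis <- qr.Q(qr(cbind(1, tgrid)))
  x - (x %*% basis) %*% t(basis)
}

#' Clip data spikes against a running-median baseline
#'
#' Transparent despiking surrogate: samples whose deviation from a
#' running-median baseline (window 7) exceeds
#' \code{mad_threshold} times the MAD of the deviations are shrunk to the
#' threshold envelope; all other samples pass through unchanged.
#'
#' @param series Numeric time series (length >= 9).
#' @param mad_threshold Envelope half-width in MAD units (default 5).
#' @param window Running-median window (odd, default 7).
#' @return Despiked series of the same length.
#' @export
despike <- function(series, mad_threshold = 5, window = 7L) {
  if (length(series) < 9L) stop("series too short to despike")
  if (mad_threshold <= 0) stop("'mad_threshold' must be positive")
  base <- stats::runmed(series, window)
  r <- series - base
  m <- stats::mad(r)
  if (m == 0) return(series)
  out <- series
  flag <- abs(r) > mad_threshold * m
  out[flag] <- base[flag] + sign(r[flag]) * mad_threshold * m
  out
}

#' Framewise displacement by Euclidean norm (enorm)
#'
#' Per-frame head displacement: the Euclidean norm of the backward
#' differences of the six rigid-body parameters, with rotations converted to
#' millimetres of arc on a sphere of radius \code{radius_mm}. The first
#' frame has displacement 0.
#'
#' @param motion Matrix frames x 6 (x, y, z in mm; roll, pitch, yaw in
#'   degrees).
#' @param radius_mm Lever arm for the rotation-to-mm conversion (default 50).
#' @return Numeric vector of per-frame displacements (mm).
#' @export
motion_enorm <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L) {
    stop("'motion' must be a frames x 6 matrix with at least 2 frames")
  }
  if (anyNA(motion) || any(!is.finite(motion))) {
    stop("motion track contains missing or non-finite values")
  }
  d <- diff(motion)
  d[, 4:6] <- d[, 4:6] * radius_mm * pi / 180
  c(0, sqrt(rowSums(d^2)))
}

#' Motion-based subject exclusion
#'
#' A scan is dropped when any of the six rigid-body parameters shows a
#' peak-to-peak range strictly greater than \code{threshold_mm} (rotations on
#' the mm-equivalent scale, 50-mm radius). A range of exactly the threshold
#' keeps the scan.
#'
#' @param scan A \code{cohort_scan} with a motion track.
#' @param threshold_mm Exclusion threshold in mm (default 2).
#' @param radius_mm Rotation lever arm (default 50).
#' @return List with \code{keep} (logical) and \code{reason} (offending axis
#'   name, or NA when kept).
#' @export
motion_exclude <- function(scan, threshold_mm = 2, radius_mm = 50) {
  stopifnot(inherits(scan, "cohort_scan"))
  if (is.null(scan$motion)) stop("scan has no motion track")
  m <- as.matrix(scan$motion)
  m[, 4:6] <- m[, 4:6] * radius_mm * pi / 180
  ranges <- apply(m, 2L, function(v) diff(range(v)))
  axes <- c("x", "y", "z", "roll", "pitch", "yaw")
  bad <- which(ranges > threshold_mm)
  if (length(bad) == 0L) {
    list(keep = TRUE, reason = NA_character_)
  } else {
    list(keep = FALSE, reason = axes[bad[1L]])
  }
}

#' Apply the preprocessing stage to a whole cohort
#'
#' Motion screening followed by discard-and-detrend (and optional despiking)
#' for the retained scans.
#'
#' @param cohort A \code{cohort} (or plain list of \code{cohort_scan}s).
#' @param n_discard,detrend_order See \code{\link{discard_and_detrend}}.
#' @param despike_enabled Clip voxel spikes before detrending.
#' @param mad_threshold Despiking envelope in MAD units.
#' @param motion_exclude_mm Peak-to-peak motion exclusion threshold.
#' @return List with \code{scans} (preprocessed, retained) and
#'   \code{exclusions} (data frame subject_id, keep, reason).
#' @export
preprocess_cohort <- function(cohort, n_discard = 10L, detrend_order = 1L,
                              despike_enabled = FALSE, mad_threshold = 5,
                              motion_exclude_mm = 2) {
  scans <- if (inherits(cohort, "cohort")) cohort$scans else cohort
  decisions <- lapply(scans, motion_exclude, threshold_mm = motion_exclude_mm)
  keep <- vapply(decisions, `[[`, logical(1L), "keep")
  excl <- data.frame(
    subject_id = vapply(scans, `[[`, character(1L), "subject_id"),
    keep = keep,
    reason = vapply(decisions, `[[`, character(1L), "reason"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  kept <- lapply(scans[keep], function(s) {
    if (despike_enabled) {
      s$data <- t(apply(s$data, 1L, despike, mad_threshold = mad_threshold))
    }
    discard_and_detrend(s, n_discard, detrend_order)
  })
  list(scans = kept, exclusions = excl)
}
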