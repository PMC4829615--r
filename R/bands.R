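#' Frequency band scheme for slow-oscillation analysis
#'
#' Builds the set of named frequency intervals used throughout the package:
#' the infra-slow bands slow-5 (0.01--0.027 Hz) and slow-4 (0.027--0.073 Hz),
#' the combined resting-state band (0.01--0.073 Hz), the low- and
#' high-frequency bands used by the spectral robustness filter
#' (0.01--0.1 Hz and 0.1 Hz--Nyquist), and the full acquired range
#' (0--Nyquist).
#'
#' All bands are half-open intervals \code{[lo, hi)} except those whose upper
#' edge is the Nyquist frequency (\code{HF} and \code{full}), which are closed
#' above so that the Nyquist bin itself is counted. A frequency exactly at a
#' band edge (for instance 0.027 Hz) therefore belongs to the upper band
#' (slow-4, not slow-5).
#'
#' @param nyquist Nyquist frequency of the acquisition in Hz. Must exceed
#'   0.073 Hz so that the slow-4 band is fully contained in the acquired
#'   spectrum.
#' @return An object of class \code{band_scheme}: a data frame with columns
#'   \code{label}, \code{lo}, \code{hi} and \code{closed_upper}.
#' @examples
#' sch <- band_scheme(0.1923)
#' sch
#' @export
band_scheme <- function(nyquist) {
  if (!is.numeric(nyquist) || length(nyquist) != 1L || !is.finite(nyquist)) {
    stop("'nyquist' must be a single finite number (Hz)")
  }
  if (nyquist <= 0.073) {
    stop("unsupported sampling: Nyquist frequency ", nyquist,
         " Hz does not cover the slow-4 band (upper edge 0.073 Hz)")
  }
  sch <- data.frame(
    label = c("slow5", "slow4", "resting", "LF", "HF", "full"),
    lo = c(0.01, 0.027, 0.01, 0.01, 0.1, 0),
    hi = c(0.027, 0.073, 0.073, 0.1, nyquist, nyquist),
    closed_upper = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  # degenerate HF band when 0.073 < Nyquist <= 0.1: flag rather than error
  if (nyquist <= 0.1) sch$hi[sch$label == "HF"] <- NA_real_
  class(sch) <- c("band_scheme", "data.frame")
  attr(sch, "nyquist") <- nyquist
  sch
}

#' Retrieve a single band from a scheme
#'
#' @param scheme A \code{band_scheme}.
#' @param label Band label, e.g. \code{"slow5"}.
#' @return One-row data frame with the band's edges.
#' @export
get_band <- function(scheme, label) {
  stopifnot(inherits(scheme, "band_scheme"))
  row <- scheme[scheme$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("no band labelled '", label, "' in scheme")
  row
}

#' Membership of frequencies in a band
#'
#' Half-open convention: \code{lo <= f < hi}, with the upper edge included
#' when the band is closed above (Nyquist-terminated bands).
#'
#' @param freqs Numeric vector of frequencies in Hz.
#' @param band One-row band as returned by \code{\link{get_band}}, or any
#'   list with \code{lo}, \code{hi} and \code{closed_upper} fields.
#' @return Logical vector.
#' @export
band_mask <- function(freqs, band) {
  lo <- band$lo
  hi <- band$hi
  if (is.na(hi)) return(rep(FALSE, length(freqs)))
  inside <- freqs >= lo & freqs < hi
  if (isTRUE(band$closed_upper)) inside <- inside | freqs == hi
  inside
}

#' Discrete frequency-bin grid
#'
#' Uniform grid of half-open bins used by the discrete bin analysis of
#' oscillation amplitudes: by default from 0.009 to 0.060 Hz in increments
#' of 0.0015 Hz, giving 34 bins.
#'
#' @param lo Lower edge of the first bin (Hz).
#' @param hi Upper edge of the last bin (Hz).
#' @param width Bin width (Hz).
#' @return Object of class \code{bin_grid}: list with \code{edges} (length
#'   n_bins + 1) and \code{centers} (length n_bins).
#' @examples
#' g <- bin_grid()
#' length(g$centers)  # 34
#' @export
bin_grid <- function(lo = 0.009, hi = 0.060, width = 0.0015) {
  if (width <= 0 || hi <= lo) stop("invalid bin grid parameters")
  n <- round((hi - lo) / width)
  if (abs(n * width - (hi - lo)) > 1e-9) {
    stop("bin width does not evenly divide the grid range")
  }
  edges <- lo + width * 0:n
  grid <- list(edges = edges, centers = (edges[-1] + edges[-(n + 1)]) / 2)
  class(grid) <- "bin_grid"
  grid
}
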