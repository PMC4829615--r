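#' ICASSO-style stability resampling of the group ICA
#'
#' Reruns the group ICA under random weight initializations and subject-level
#' bootstrap resampling, clusters all runs' component maps by absolute
#' spatial correlation (average-linkage agglomerative clustering on
#' 1 - |r|), and scores each component of the reference fit by the mean
#' within-cluster similarity minus the mean between-cluster similarity of its
#' cluster, clipped to [0, 1].
#'
#' @param scans List of preprocessed \code{cohort_scan}s (or a \code{cohort}).
#' @param k Number of components.
#' @param n_runs Number of resampled runs (>= 2; default 20).
#' @param bootstrap Resample subjects with replacement in each run.
#' @param reference Optional existing \code{gica} fit to score; fitted here
#'   when missing.
#' @param seed Integer seed.
#' @param ... Further arguments passed to \code{\link{gica}}.
#' @return The reference \code{gica} fit with a \code{stability} vector (one
#'   value in [0, 1] per component) attached.
#' @export
stability_resample <- function(scans, k, n_runs = 20L, bootstrap = TRUE,
                               reference = NULL, seed = NULL, ...) {
  if (inherits(scans, "cohort")) scans <- scans$scans
  if (n_runs < 2L) stop("'n_runs' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- gica(scans, k = k, ...)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    idx <- if (bootstrap) sample(length(scans), replace = TRUE)
           else seq_along(scans)
    # bootstrap duplicates share data; subject PCA handles repeats
    runs[[r]] <- gica(scans[idx], k = k, ...)$group_maps
  }
  all_maps <- rbind(reference$group_maps, do.call(rbind, runs))
  sim <- abs(cor(t(all_maps)))
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim),
                                    method = "average"), k = k)
  stab <- vapply(seq_len(k), function(i) {
    members <- which(cl == cl[i])
    others <- which(cl != cl[i])
    intra <- if (length(members) > 1L) {
      s <- sim[members, members]
      mean(s[upper.tri(s)])
    } else 0
    extra <- if (length(others) > 0L) mean(sim[members, others, drop = FALSE])
             else 0
    min(max(intra - extra, 0), 1)
  }, numeric(1L))
  reference$stability <- stab
  reference$n_stability_runs <- as.integer(n_runs)
  reference
}

#' Match group components to network templates
#'
#' Greedy assignment of components to labelled template maps in descending
#' order of absolute spatial correlation; each component and each template is
#' used at most once, assignments below the threshold are dropped, and the
#' sign of each assigned map is flipped so its correlation with the template
#' is positive.
#'
#' @param fit A \code{gica} fit (or a k x voxels map matrix).
#' @param templates Matrix voxels x templates with labels as column names
#'   (e.g. \code{\link{network_templates}} output, or maps loaded from file).
#' @param threshold Minimum absolute correlation to accept a match
#'   (default 0.3).
#' @return When given a fit: the fit with an \code{assignment} data frame
#'   (label, component, match_correlation) and any flipped maps/time courses;
#'   otherwise the assignment data frame alone. Unmatched labels appear with
#'   component NA.
#' @export
match_templates <- function(fit, templates, threshold = 0.3) {
  maps <- if (inherits(fit, "gica")) fit$group_maps else fit
  if (ncol(maps) != nrow(templates)) {
    stop("templates are not on the component map grid")
  }
  r <- cor(t(maps), templates)  # components x templates
  labels <- colnames(templates)
  assign <- data.frame(label = labels, component = NA_integer_,
                       match_correlation = NA_real_,
                       stringsAsFactors = FALSE)
  work <- abs(r)
  repeat {
    best <- which(work == max(work), arr.ind = TRUE)[1L, , drop = FALSE]
    if (work[best] < threshold || all(!is.finite(work))) break
    comp <- best[1L, 1L]
    tpl <- best[1L, 2L]
    assign$component[tpl] <- comp
    assign$match_correlation[tpl] <- r[comp, tpl]
    work[comp, ] <- -Inf
    work[, tpl] <- -Inf
    if (all(work == -Inf)) break
  }
  if (!inherits(fit, "gica")) return(assign)
  for (i in seq_len(nrow(assign))) {
    comp <- assign$component[i]
    if (!is.na(comp) && assign$match_correlation[i] < 0) {
      fit$group_maps[comp, ] <- -fit$group_maps[comp, ]
      fit$mixing[, comp] <- -fit$mixing[, comp]
      fit$subject_timecourses <- lapply(fit$subject_timecourses, function(tc) {
        tc[, comp] <- -tc[, comp]; tc
      })
      fit$subject_maps <- lapply(fit$subject_maps, function(m) {
        m[comp, ] <- -m[comp, ]; m
      })
      assign$match_correlation[i] <- -assign$match_correlation[i]
    }
  }
  fit$assignment <- assign
  fit
}

#' Spectral robustness filter for components
#'
#' A component is robust when the mean over subjects of its low-frequency
#' (0.01--0.1 Hz) to high-frequency (0.1 Hz--Nyquist) power ratio strictly
#' exceeds the threshold (default 50). Zero high-frequency power yields an
#' infinite ratio (robust).
#'
#' @param subject_timecourses Named list of time x k matrices.
#' @param tr Repetition time in seconds.
#' @param threshold Power-ratio threshold (default 50).
#' @return List with \code{robust} (logical per component) and \code{ratio}
#'   (mean LF/HF power ratio per component).
#' @export
robustness_filter <- function(subject_timecourses, tr, threshold = 50) {
  stopifnot(length(subject_timecourses) >= 1L)
  n <- nrow(subject_timecourses[[1L]])
  scheme <- band_scheme(nyquist_freq(n, tr))
  lf <- get_band(scheme, "LF")
  hf <- get_band(scheme, "HF")
  k <- ncol(subject_timecourses[[1L]])
  ratios <- sapply(subject_timecourses, function(tc) {
    vapply(seq_len(k), function(j) {
      sp <- amplitude_spectrum(tc[, j], tr)
      p_lf <- sum(sp$amplitude[band_mask(sp$freqs, lf)]^2)
      p_hf <- sum(sp$amplitude[band_mask(sp$freqs, hf)]^2)
      if (p_hf == 0) Inf else p_lf / p_hf
    }, numeric(1L))
  })
  ratios <- matrix(ratios, nrow = k)
  mean_ratio <- rowMeans(ratios)
  list(robust = mean_ratio > threshold, ratio = mean_ratio)
}
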