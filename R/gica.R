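#' Group spatial ICA of a multi-subject cohort
#'
#' Fits the standard two-stage group spatial independent component analysis:
#' each subject's voxel-by-time data is reduced to \code{pca_dim} temporal
#' principal components, the reductions are concatenated across subjects
#' along time, a group PCA reduces the stack to \code{k} dimensions, and the
#' whitened group matrix is unmixed with natural-gradient Infomax (logistic
#' nonlinearity, spatial ICA: voxels are the samples). Subject-specific time
#' courses and spatial maps are recovered by GICA back-reconstruction through
#' the retained reduction matrices.
#'
#' Group maps are scaled to unit variance and oriented to positive skewness.
#'
#' @param scans List of preprocessed \code{cohort_scan}s (or a \code{cohort}).
#' @param k Number of independent components (default 28, a mid-order model).
#' @param pca_dim Subject-level PCA dimension; default 1.5 * k (capped at
#'   the scan length).
#' @param maxit Maximum Infomax iterations (default 512).
#' @param lrate Initial learning rate (default 0.1; annealed on divergence).
#' @param tol Convergence threshold on the squared weight change
#'   (default 1e-6).
#' @param seed Integer seed for the random weight initialization.
#' @return Object of class \code{gica} with fields \code{group_maps}
#'   (k x voxels, unit variance rows), \code{subject_timecourses} (list of
#'   time x k matrices), \code{subject_maps} (list of k x voxels matrices),
#'   \code{variance_explained}, \code{mixing}, \code{unmixing},
#'   \code{converged}, \code{iterations}, plus the reduction matrices needed
#'   to back-reconstruct further subjects.
#' @seealso \code{\link{stability_resample}}, \code{\link{match_templates}},
#'   \code{\link{robustness_filter}}
#' @export
gica <- function(scans, k = 28L, pca_dim = NULL, maxit = 512L, lrate = 0.1,
                 tol = 1e-6, seed = NULL) {
  if (inherits(scans, "cohort")) scans <- scans$scans
  stopifnot(length(scans) >= 1L)
  red <- temporal_concat_pca(scans, k = k, pca_dim = pca_dim)
  if (!is.null(seed)) set.seed(seed)
  um <- infomax_unmix(red$Z, maxit = maxit, lrate = lrate, tol = tol)
  S <- um$sources
  # orient to positive skewness, scale rows to unit variance
  sk <- apply(S, 1L, function(v) mean((v - mean(v))^3))
  flip <- ifelse(sk < 0, -1, 1)
  sds <- apply(S, 1L, sd)
  S <- S * (flip / sds)
  A_w <- solve(um$W) * rep(flip * sds, each = nrow(um$W))
  back <- gica_backreconstruct(scans, red, A_w, S)
  out <- list(
    group_maps = S,
    mixing = A_w,
    unmixing = um$W,
    subject_timecourses = back$timecourses,
    subject_maps = back$maps,
    variance_explained = red$variance_explained,
    reduction = red[c("F_list", "G", "lambda", "pca_dim")],
    converged = um$converged,
    iterations = um$iterations,
    k = as.integer(k),
    n_subjects = length(scans),
    tr = scans[[1L]]$tr,
    dims = scans[[1L]]$dims,
    subject_ids = vapply(scans, `[[`, character(1L), "subject_id"),
    groups = vapply(scans, `[[`, character(1L), "group"),
    call = match.call()
  )
  class(out) <- "gica"
  out
}

#' Two-stage subject-then-group PCA reduction
#'
#' @param scans List of preprocessed \code{cohort_scan}s on a common voxel
#'   grid.
#' @param k Group PCA dimension.
#' @param pca_dim Subject PCA dimension (default 1.5 * k, capped at the
#'   number of retained volumes).
#' @return List with the whitened group matrix \code{Z} (k x voxels), the
#'   per-subject reduction bases \code{F_list}, the group reduction \code{G}
#'   and eigenvalues \code{lambda}, the stacked reduced data \code{R}, and
#'   \code{variance_explained} (fraction of group-stage variance captured by
#'   the k components).
#' @export
temporal_concat_pca <- function(scans, k, pca_dim = NULL) {
  nvox <- nrow(scans[[1L]]$data)
  ntime <- ncol(scans[[1L]]$data)
  for (s in scans) {
    if (nrow(s$data) != nvox || ncol(s$data) != ntime) {
      stop("subject ", s$subject_id, " is not on the common voxel/time grid")
    }
  }
  if (is.null(pca_dim)) pca_dim <- min(ceiling(1.5 * k), ntime)
  if (k > pca_dim) stop("'k' must not exceed 'pca_dim'")
  if (pca_dim > min(ntime, nvox)) {
    stop("'pca_dim' exceeds the data rank bound min(time, voxels)")
  }
  F_list <- vector("list", length(scans))
  R <- matrix(0, nrow = length(scans) * pca_dim, ncol = nvox)
  for (i in seq_along(scans)) {
    X <- scans[[i]]$data  # voxels x time, already detrended/zero-mean
    C <- crossprod(X)  # time x time
    e <- eigen(C, symmetric = TRUE)
    if (e$values[pca_dim] <= max(e$values) * 1e-12) {
      stop("rank-deficient data for subject ", scans[[i]]$subject_id,
           ": cannot extract ", pca_dim, " temporal components")
    }
    Fi <- e$vectors[, seq_len(pca_dim), drop = FALSE]  # time x pca_dim
    F_list[[i]] <- Fi
    R[(i - 1L) * pca_dim + seq_len(pca_dim), ] <- t(X %*% Fi)
  }
  eg <- eigen(tcrossprod(R), symmetric = TRUE)
  G <- eg$vectors[, seq_len(k), drop = FALSE]
  lambda <- eg$values[seq_len(k)]
  Z <- (t(G) %*% R) / sqrt(lambda / nvox)
  list(Z = Z, F_list = F_list, G = G, lambda = lambda, R = R,
       pca_dim = pca_dim,
       variance_explained = sum(lambda) / sum(pmax(eg$values, 0)))
}

#' Natural-gradient Infomax unmixing
#'
#' Spatial ICA on a whitened k x voxels matrix using the Infomax rule with a
#' logistic nonlinearity and natural-gradient updates. The learning rate is
#' annealed (halved, weights reset) whenever the update diverges; an error is
#' raised only if annealing cannot restore stability.
#'
#' @param Z Whitened matrix, components x samples (voxels).
#' @param maxit Maximum number of full-data iterations.
#' @param lrate Initial learning rate.
#' @param tol Convergence threshold on the squared weight increment.
#' @return List with the unmixing matrix \code{W}, the source matrix
#'   \code{sources = W Z}, \code{converged} and \code{iterations}.
#' @export
infomax_unmix <- function(Z, maxit = 512L, lrate = 0.1, tol = 1e-6) {
  k <- nrow(Z)
  nv <- ncol(Z)
  if (qr(Z)$rank < k) stop("reduced matrix is not full rank")
  W <- random_orthonormal(k)
  I_k <- diag(k)
  converged <- FALSE
  it <- 0L
  anneals <- 0L
  W_good <- W
  while (it < maxit) {
    it <- it + 1L
    U <- W %*% Z
    g <- 1 / (1 + exp(-U))
    dW <- lrate * (I_k + ((1 - 2 * g) %*% t(U)) / nv) %*% W
    W_new <- W + dW
    if (any(!is.finite(W_new)) || max(abs(W_new)) > 1e8) {
      lrate <- lrate / 2
      anneals <- anneals + 1L
      if (anneals > 40L) stop("Infomax diverged despite learning-rate annealing")
      W <- W_good
      next
    }
    wchange <- sum(dW^2)
    W_good <- W_new
    W <- W_new
    if (wchange < tol) {
      converged <- TRUE
      break
    }
  }
  list(W = W, sources = W %*% Z, converged = converged, iterations = it)
}

random_orthonormal <- function(k) {
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}

#' GICA back-reconstruction of subject time courses and maps
#'
#' Projects each subject's data through the pseudo-inverse chain of its
#' PCA reduction and the group unmixing: the subject time course is
#' \code{F_i G_i A} (time x k) and the subject map is the least-squares
#' regression of the subject data onto that time course.
#'
#' @param scans List of preprocessed \code{cohort_scan}s.
#' @param red Reduction structure from \code{\link{temporal_concat_pca}}.
#' @param A_w Mixing matrix in the whitened group space (k x k).
#' @param S Group source maps (k x voxels) matching \code{A_w}.
#' @return List with \code{timecourses} and \code{maps}, both named by
#'   subject.
#' @export
gica_backreconstruct <- function(scans, red, A_w, S) {
  k <- ncol(A_w)
  p <- red$pca_dim
  scale_back <- sqrt(red$lambda / ncol(S))
  tcs <- vector("list", length(scans))
  maps <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    Gi <- red$G[(i - 1L) * p + seq_len(p), , drop = FALSE]
    TC <- red$F_list[[i]] %*% (Gi * rep(scale_back, each = p)) %*% A_w
    X <- scans[[i]]$data
    maps[[i]] <- t(qr.solve(TC, t(X)))  # voxels x k -> transpose below
    tcs[[i]] <- TC
  }
  ids <- vapply(scans, `[[`, character(1L), "subject_id")
  names(tcs) <- ids
  names(maps) <- ids
  maps <- lapply(maps, t)  # k x voxels
  list(timecourses = tcs, maps = maps)
}

#' @export
print.gica <- function(x, ...) {
  cat("Group spatial ICA fit\n")
  cat("  components:", x$k, " subjects:", x$n_subjects, "\n")
  cat("  variance explained at group reduction:",
      sprintf("%.1f%%", 100 * x$variance_explained), "\n")
  cat("  Infomax:", if (x$converged) "converged" else "max iterations",
      "after", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
summary.gica <- function(object, ...) {
  sk <- apply(object$group_maps, 1L, function(v) {
    m <- mean(v); s <- sd(v); mean((v - m)^3) / s^3
  })
  out <- list(
    k = object$k,
    n_subjects = object$n_subjects,
    variance_explained = object$variance_explained,
    converged = object$converged,
    iterations = object$iterations,
    map_skewness = sk,
    assignment = object$assignment,
    stability = object$stability
  )
  class(out) <- "summary.gica"
  out
}

#' @export
print.summary.gica <- function(x, ...) {
  cat("Group spatial ICA:", x$k, "components,", x$n_subjects, "subjects\n")
  cat("Variance explained:", sprintf("%.1f%%", 100 * x$variance_explained),
      "| Infomax", if (x$converged) "converged" else "not converged",
      "(", x$iterations, "iterations )\n")
  cat("Component map skewness:\n")
  print(round(x$map_skewness, 2))
  if (!is.null(x$stability)) {
    cat("Stability index:\n")
    print(round(x$stability, 2))
  }
  if (!is.null(x$assignment)) {
    cat("Template assignment:\n")
    print(x$assignment)
  }
  invisible(x)
}

#' Mixing matrix or group maps of a fitted group ICA
#'
#' @param object A \code{gica} fit.
#' @param type \code{"maps"} (group spatial maps, k x voxels) or
#'   \code{"mixing"} (whitened-space mixing matrix).
#' @param ... Unused.
#' @export
coef.gica <- function(object, type = c("maps", "mixing"), ...) {
  type <- match.arg(type)
  if (type == "maps") object$group_maps else object$mixing
}

#' Back-reconstruct component time courses for new scans
#'
#' For scans outside the fitted cohort the subject time course is obtained by
#' regressing the subject data onto the group maps (spatio-temporal dual
#' projection); for fitted subjects the stored GICA back-reconstruction is
#' returned.
#'
#' @param object A \code{gica} fit.
#' @param newscans Optional list of \code{cohort_scan}s.
#' @param ... Unused.
#' @return Named list of time x k matrices.
#' @export
predict.gica <- function(object, newscans = NULL, ...) {
  if (is.null(newscans)) return(object$subject_timecourses)
  if (inherits(newscans, "cohort")) newscans <- newscans$scans
  S <- object$group_maps
  out <- lapply(newscans, function(s) {
    X <- s$data - rowMeans(s$data)
    t(qr.solve(t(S), X))
  })
  names(out) <- vapply(newscans, `[[`, character(1L), "subject_id")
  out
}

#' Plot group component maps
#'
#' Displays the mid-axial slice of each group map.
#'
#' @param x A \code{gica} fit.
#' @param components Which components to draw (default all).
#' @param ... Passed to \code{graphics::image}.
#' @export
plot.gica <- function(x, components = seq_len(x$k), ...) {
  if (is.null(x$dims)) stop("fit carries no voxel grid dimensions")
  d <- x$dims
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(components)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (i in components) {
    vol <- array(x$group_maps[i, ], dim = d)
    graphics::image(vol[, , ceiling(d[3L] / 2)], axes = FALSE,
                    main = paste("IC", i), ...)
  }
  invisible(x)
}
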