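#' Write a cohort to disk
#'
#' Per subject, writes the data matrix (TSV voxels x time, or 4D NIfTI-1)
#' and the motion track (6-column TSV), plus a cohort manifest TSV with
#' columns \code{subject_id}, \code{group}, \code{data_path}, \code{tr},
#' \code{motion_path}. For simulated cohorts the ground truth (spatial maps
#' TSV, per-subject generative fALFF TSV, band amplitudes JSON) is written
#' alongside.
#'
#' @param cohort A \code{cohort} (or plain list of \code{cohort_scan}s).
#' @param dir Output directory (created if missing).
#' @param format \code{"tsv"} or \code{"nifti"}.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "nifti")) {
  format <- match.arg(format)
  scans <- if (inherits(cohort, "cohort")) cohort$scans else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    if (format == "tsv") {
      dp <- file.path(dir, paste0(s$subject_id, "_data.tsv"))
      write.table(s$data, dp, sep = "\t", row.names = FALSE,
                  col.names = FALSE)
    } else {
      dp <- file.path(dir, paste0(s$subject_id, "_data.nii.gz"))
      vol <- array(s$data, dim = c(s$dims, ncol(s$data)))
      RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(3.5, 3.5, 3.5, s$tr)),
                         dp)
    }
    mp <- file.path(dir, paste0(s$subject_id, "_motion.tsv"))
    write.table(s$motion, mp, sep = "\t", row.names = FALSE)
    rows[[i]] <- data.frame(subject_id = s$subject_id, group = s$group,
                            data_path = basename(dp), tr = s$tr,
                            motion_path = basename(mp),
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", row.names = FALSE)
  if (inherits(cohort, "cohort")) {
    gt <- cohort$ground_truth
    write.table(gt$maps, file.path(dir, "ground_truth_maps.tsv"),
                sep = "\t", row.names = FALSE)
    if (!is.null(gt$falff)) {
      write.table(gt$falff, file.path(dir, "ground_truth_falff.tsv"),
                  sep = "\t", row.names = FALSE)
    }
    jsonlite::write_json(gt$band_amps, file.path(dir, "ground_truth_amps.json"),
                         digits = NA)
  }
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' Loads the scans listed in a manifest TSV (columns \code{subject_id},
#' \code{group}, \code{data_path}, \code{tr}, optional \code{motion_path});
#' data files may be TSV matrices (voxels x time) or 4D NIfTI-1 volumes.
#' The cohort must share one voxel grid and one TR.
#'
#' @param manifest Path to the manifest TSV.
#' @return List of \code{cohort_scan}s.
#' @export
read_cohort <- function(manifest) {
  man <- read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "data_path", "tr")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(man$tr)) > 1L) {
    stop("mixed repetition times in manifest: ",
         paste(unique(man$tr), collapse = ", "))
  }
  root <- dirname(manifest)
  scans <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    dp <- file.path(root, man$data_path[i])
    if (!file.exists(dp)) {
      stop("manifest row ", i, " (", man$subject_id[i],
           "): data file not found: ", dp)
    }
    if (grepl("\\.nii(\\.gz)?$", dp)) {
      vol <- RNifti::readNifti(dp)
      d <- dim(vol)
      data <- matrix(vol, nrow = prod(d[1:3]), ncol = d[4L])
      dims <- d[1:3]
    } else {
      data <- as.matrix(read.delim(dp, header = FALSE))
      dimnames(data) <- NULL
      dims <- NULL
    }
    motion <- NULL
    if ("motion_path" %in% names(man) && nzchar(man$motion_path[i])) {
      motion <- as.matrix(read.delim(file.path(root, man$motion_path[i])))
    }
    scan <- list(subject_id = man$subject_id[i], group = man$group[i],
                 data = data, dims = dims, tr = man$tr[i], motion = motion)
    class(scan) <- "cohort_scan"
    scans[[i]] <- scan
  }
  grid <- vapply(scans, function(s) nrow(s$data), integer(1L))
  if (length(unique(grid)) > 1L) stop("scans are not on a uniform voxel grid")
  names(scans) <- man$subject_id
  scans
}

#' Run the full spectral analysis pipeline
#'
#' Orchestrates preprocessing, group spatial ICA, template matching, the
#' spectral robustness filter, fALFF computation and the group statistics,
#' writing every stage's outputs and the effective configuration (with
#' resolved defaults and seed) to the output directory. Identical
#' configuration and seed yield identical results.
#'
#' @param config Configuration list or path to a YAML file. Recognized
#'   fields (all optional except a data source): \code{manifest} (cohort
#'   manifest path) or \code{simulate} (arguments for
#'   \code{\link{cohort_spec}}), \code{templates} (path to a voxels x labels
#'   TSV; simulated cohorts default to their ground-truth maps),
#'   \code{preprocess} (\code{n_discard}, \code{detrend_order},
#'   \code{despike_enabled}, \code{mad_threshold}, \code{motion_exclude_mm}),
#'   \code{ica} (\code{k}, \code{pca_dim}, \code{maxit}, \code{tol},
#'   \code{stability_runs}), \code{sigma_bins}, \code{contrasts} (list of
#'   \code{a}, \code{b}, optional \code{direction}), \code{alpha},
#'   \code{out_dir}, \code{seed}.
#' @return List with the fitted \code{gica}, the fALFF table, the contrast
#'   report, robustness flags and exclusion report (also serialized under
#'   \code{out_dir} when given).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_config(config)
  set.seed(cfg$seed)
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    spec <- do.call(cohort_spec, cfg$simulate)
    cohort <- simulate_cohort(spec, seed = cfg$seed)
    scans <- cohort$scans
    truth <- cohort$ground_truth
  } else if (!is.null(cfg$manifest)) {
    scans <- read_cohort(cfg$manifest)
  } else {
    stop("config must provide either 'manifest' or 'simulate'")
  }
  pp <- do.call(preprocess_cohort, c(list(scans), cfg$preprocess))
  if (length(pp$scans) == 0L) stop("no scans survive motion exclusion")
  fit <- gica(pp$scans, k = cfg$ica$k, pca_dim = cfg$ica$pca_dim,
              maxit = cfg$ica$maxit, tol = cfg$ica$tol, seed = cfg$seed)
  if (cfg$ica$stability_runs >= 2L) {
    fit <- stability_resample(pp$scans, k = cfg$ica$k,
                              n_runs = cfg$ica$stability_runs,
                              reference = fit, seed = cfg$seed + 1L,
                              pca_dim = cfg$ica$pca_dim, maxit = cfg$ica$maxit,
                              tol = cfg$ica$tol)
  }
  templates <- if (!is.null(cfg$templates)) {
    as.matrix(read.delim(cfg$templates))
  } else if (!is.null(truth)) {
    truth$maps
  } else NULL
  if (!is.null(templates)) fit <- match_templates(fit, templates)
  robust <- robustness_filter(fit$subject_timecourses, fit$tr)
  # restrict the fALFF layer to assigned, robust components
  comps <- if (!is.null(fit$assignment)) {
    a <- fit$assignment[!is.na(fit$assignment$component), ]
    setNames(a$component, a$label)
  } else setNames(seq_len(fit$k), paste0("IC", seq_len(fit$k)))
  comps <- comps[robust$robust[comps]]
  groups <- setNames(fit$groups, fit$subject_ids)
  tcs <- lapply(fit$subject_timecourses, function(tc) {
    m <- tc[, comps, drop = FALSE]
    colnames(m) <- names(comps)
    m
  })
  falff <- falff_table(tcs, groups, fit$tr, sigma_bins = cfg$sigma_bins)
  falff <- add_composites(falff)
  report <- NULL
  note <- NULL
  if (length(unique(fit$groups)) >= 2L && length(cfg$contrasts) > 0L) {
    tf <- if (!is.null(truth)) add_composites(truth$falff) else NULL
    report <- contrast_report(falff, cfg$contrasts, truth = tf,
                              alpha = cfg$alpha)
  } else {
    note <- "group statistics skipped: fewer than 2 groups in the cohort"
  }
  results <- list(fit = fit, falff = falff, report = report,
                  robustness = robust, exclusions = pp$exclusions,
                  note = note, config = cfg)
  if (!is.null(cfg$out_dir)) write_results(results, cfg$out_dir)
  results
}

resolve_config <- function(config) {
  defaults <- list(
    manifest = NULL, simulate = NULL, templates = NULL,
    preprocess = list(n_discard = 10L, detrend_order = 1L,
                      despike_enabled = FALSE, mad_threshold = 5,
                      motion_exclude_mm = 2),
    ica = list(k = 28L, pca_dim = NULL, maxit = 512L, tol = 1e-6,
               stability_runs = 0L),
    sigma_bins = 2,
    contrasts = list(list(a = "stroke_late", b = "old"),
                     list(a = "old", b = "young")),
    alpha = 0.05, out_dir = NULL, seed = 1L
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(results$falff, file.path(out_dir, "falff.tsv"),
              sep = "\t", row.names = FALSE)
  write.table(results$exclusions, file.path(out_dir, "exclusions.tsv"),
              sep = "\t", row.names = FALSE)
  tc_dir <- file.path(out_dir, "timecourses")
  dir.create(tc_dir, showWarnings = FALSE)
  for (sid in names(results$fit$subject_timecourses)) {
    write.table(results$fit$subject_timecourses[[sid]],
                file.path(tc_dir, paste0(sid, "_tc.tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  write.table(t(results$fit$group_maps),
              file.path(out_dir, "group_maps.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  model <- list(
    k = results$fit$k,
    variance_explained = results$fit$variance_explained,
    converged = results$fit$converged,
    iterations = results$fit$iterations,
    stability = results$fit$stability,
    assignment = results$fit$assignment,
    robustness = results$robustness,
    note = results$note,
    config = results$config[setdiff(names(results$config), "simulate")]
  )
  jsonlite::write_json(model, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(results$report)) {
    jsonlite::write_json(results$report, file.path(out_dir, "contrasts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    write.table(results$report, file.path(out_dir, "contrasts.tsv"),
                sep = "\t", row.names = FALSE)
  }
  invisible(out_dir)
}
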