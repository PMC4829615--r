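#' Discrete frequency-bin two-sample t-tests
#'
#' Per-bin pooled-variance (Student) two-sample t-test between two groups of
#' binned amplitude spectra, with two-sided uncorrected p-values flagged at
#' \code{alpha}. Optionally appends Benjamini-Hochberg adjusted p-values.
#'
#' @param bins_a,bins_b Matrices subjects x bins of bin amplitudes (common
#'   grid; at least 2 subjects per group).
#' @param centers Bin center frequencies in Hz (default the standard
#'   0.009--0.060 Hz grid).
#' @param alpha Significance level for the uncorrected flags (default 0.05).
#' @param adjust Add a \code{p_bh} column of Benjamini-Hochberg adjusted
#'   p-values.
#' @return Data frame of class \code{bin_comparison} with one row per bin:
#'   \code{center}, \code{mean_a}, \code{mean_b}, \code{diff}, \code{t},
#'   \code{p}, \code{significant}.
#' @export
bin_ttest <- function(bins_a, bins_b, centers = bin_grid()$centers,
                      alpha = 0.05, adjust = FALSE) {
  bins_a <- as.matrix(bins_a)
  bins_b <- as.matrix(bins_b)
  if (nrow(bins_a) < 2L || nrow(bins_b) < 2L) {
    stop("each group needs at least 2 subjects")
  }
  if (ncol(bins_a) != ncol(bins_b) || ncol(bins_a) != length(centers)) {
    stop("groups are not on a common bin grid")
  }
  na <- nrow(bins_a)
  nb <- nrow(bins_b)
  ma <- colMeans(bins_a)
  mb <- colMeans(bins_b)
  va <- apply(bins_a, 2L, var)
  vb <- apply(bins_b, 2L, var)
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se == 0, 0, (ma - mb) / se)
  p <- ifelse(se == 0, 1, 2 * pt(-abs(tstat), df = na + nb - 2L))
  out <- data.frame(center = centers, mean_a = ma, mean_b = mb,
                    diff = ma - mb, t = tstat, p = p,
                    significant = p < alpha)
  if (adjust) out$p_bh <- p.adjust(p, method = "BH")
  class(out) <- c("bin_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Single-factor fixed-effects ANOVA of a fALFF measure with group as the
#' factor, followed by Tukey honest-significant-difference pairwise
#' comparisons (studentized range with the Tukey-Kramer unequal-n
#' correction, as provided by \code{stats::TukeyHSD}).
#'
#' @param values Numeric vector of per-subject fALFF values.
#' @param groups Factor or character vector of group labels (>= 2 levels,
#'   each with >= 2 subjects).
#' @return Object of class \code{omnibus}: list with \code{F}, \code{p},
#'   \code{df}, \code{group_means}, \code{group_n} and \code{tukey} (data
#'   frame pair, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 subjects")
  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  ss <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  out <- list(F = ss$`F value`[1L], p = ss$`Pr(>F)`[1L],
              df = ss$Df, group_means = tapply(values, groups, mean),
              group_n = as.integer(table(groups)), tukey = tukey)
  class(out) <- "omnibus"
  out
}

#' @export
print.omnibus <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Directional (one-tailed) two-sample t-test
#'
#' Pooled-variance two-sample t-test with a pre-registered direction: the
#' direction must be stated explicitly, never inferred from the data.
#'
#' @param a,b Numeric vectors of per-subject values.
#' @param direction \code{"greater"} tests mean(a) > mean(b); \code{"less"}
#'   tests mean(a) < mean(b). No default.
#' @param var_equal Pooled (Student) variance, the default; set FALSE for
#'   Welch.
#' @return List with \code{t}, \code{p} (one-tailed), \code{df},
#'   \code{mean_a}, \code{mean_b}, \code{direction}.
#' @export
directional_ttest <- function(a, b, direction, var_equal = TRUE) {
  if (missing(direction) || !direction %in% c("greater", "less")) {
    stop("'direction' must be declared a priori as \"greater\" or \"less\"")
  }
  ht <- t.test(a, b, alternative = direction, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b),
       direction = direction)
}

#' Component-by-band contrast report
#'
#' Renders every component x band x contrast cell: group means, mean
#' difference, pooled t statistic and p-value (two-sided, or one-tailed for
#' contrasts with a declared direction), plus the generative ground-truth
#' difference when a truth table is available (simulated data).
#'
#' @param falff A \code{\link{falff_table}} (possibly including composite
#'   components).
#' @param contrasts List of contrasts, each a list with fields \code{a} and
#'   \code{b} (group labels, reported as a - b) and optional
#'   \code{direction}.
#' @param truth Optional fALFF table of generative targets on the same
#'   components/bands; adds \code{true_diff} and \code{true_sign} columns.
#' @param alpha Significance level for the flags.
#' @return Data frame of class \code{contrast_report}, empty (zero rows)
#'   when \code{falff} has no rows.
#' @export
contrast_report <- function(falff, contrasts, truth = NULL, alpha = 0.05) {
  template <- data.frame(component = character(), band = character(),
                         contrast = character(), mean_a = numeric(),
                         mean_b = numeric(), diff = numeric(), t = numeric(),
                         p = numeric(), significant = logical(),
                         stringsAsFactors = FALSE)
  if (nrow(falff) == 0L || length(contrasts) == 0L) {
    class(template) <- c("contrast_report", "data.frame")
    return(template)
  }
  rows <- list()
  for (comp in unique(falff$component)) {
    for (band in unique(falff$band)) {
      slice <- falff[falff$component == comp & falff$band == band, ]
      for (ct in contrasts) {
        a <- slice$falff[slice$group == ct$a]
        b <- slice$falff[slice$group == ct$b]
        if (length(a) < 2L || length(b) < 2L) next
        if (!is.null(ct$direction)) {
          ht <- directional_ttest(a, b, ct$direction)
          tstat <- ht$t; p <- ht$p
        } else {
          ht <- t.test(a, b, var.equal = TRUE)
          tstat <- unname(ht$statistic); p <- ht$p.value
        }
        row <- data.frame(component = comp, band = band,
                          contrast = paste(ct$a, "-", ct$b),
                          mean_a = mean(a), mean_b = mean(b),
                          diff = mean(a) - mean(b), t = tstat, p = p,
                          significant = p < alpha, stringsAsFactors = FALSE)
        if (!is.null(truth)) {
          ts <- truth[truth$component == comp & truth$band == band, ]
          td <- mean(ts$falff[ts$group == ct$a]) -
            mean(ts$falff[ts$group == ct$b])
          row$true_diff <- td
          row$true_sign <- sign(td)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else template
  rownames(out) <- NULL
  class(out) <- c("contrast_report", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Append composite components to a fALFF table
#'
#' Adds composite rows formed by combining member components: by default the
#' three default-mode subcomponents into \code{DMN} and visual plus motor
#' into \code{vis_smn}. The composite fALFF is recomputed from the averaged
#' member spectra when time courses are supplied, or taken as the member mean
#' fALFF otherwise (exact when member denominators agree).
#'
#' @param falff A \code{\link{falff_table}}.
#' @param composites Named list mapping composite label to member component
#'   labels.
#' @return The table with composite rows appended.
#' @export
add_composites <- function(falff,
                           composites = list(
                             DMN = c("pDMN", "aDMN", "vDMN"),
                             vis_smn = c("visual", "motor"))) {
  extra <- list()
  for (lab in names(composites)) {
    members <- composites[[lab]]
    slice <- falff[falff$component %in% members, ]
    if (nrow(slice) == 0L) next
    agg <- aggregate(falff ~ subject_id + group + band + denominator,
                     data = slice, FUN = mean)
    agg$component <- lab
    extra[[lab]] <- agg[, c("subject_id", "group", "component", "band",
                            "falff", "denominator")]
  }
  out <- rbind(as.data.frame(falff), do.call(rbind, extra))
  rownames(out) <- NULL
  class(out) <- c("falff_table", "data.frame")
  out
}
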