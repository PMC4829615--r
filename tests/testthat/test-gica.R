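rlaplace <- function(n) sign(runif(n) - 0.5) * rexp(n)

# principal angles (degrees) between the row spaces of two matrices
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(t(A)))
  qb <- qr.Q(qr(t(B)))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

test_that("two-stage PCA preserves duplicated and full-rank structure", {
  set.seed(1)
  X <- matrix(rnorm(200 * 40), nrow = 200)  # voxels x time
  s1 <- make_scan(X, "a")
  dup <- temporal_concat_pca(list(s1, make_scan(X, "b")), k = 4, pca_dim = 10)
  single <- temporal_concat_pca(list(s1), k = 4, pca_dim = 10)
  cc <- abs(cor(t(dup$Z), t(single$Z)))
  expect_true(all(apply(cc, 1, max) > 1 - 1e-8))
  # complete temporal basis reconstructs the subject exactly
  full <- temporal_concat_pca(list(s1), k = 4, pca_dim = 40)
  recon <- X %*% full$F_list[[1]] %*% t(full$F_list[[1]])
  expect_equal(recon, X, tolerance = 1e-8)
})

test_that("group PCs span a planted orthogonal source subspace", {
  set.seed(2)
  V <- 300; T <- 60
  S <- qr.Q(qr(matrix(rnorm(V * 3), V, 3)))  # orthonormal spatial sources
  scans <- lapply(1:4, function(i) {
    make_scan(S %*% matrix(rnorm(3 * T), 3, T), paste0("s", i))
  })
  red <- temporal_concat_pca(scans, k = 3, pca_dim = 3)
  expect_lt(max(principal_angles(red$Z, t(S))), 5)
})

test_that("rank-deficient subject data is reported by name", {
  lowrank <- make_scan(outer(rnorm(100), rnorm(40)), "degenerate_subject")
  expect_error(temporal_concat_pca(list(lowrank), k = 2, pca_dim = 5),
               "degenerate_subject")
})

test_that("Infomax separates super-Gaussian spatial sources", {
  set.seed(3)
  S <- rbind(rlaplace(5000), rlaplace(5000))
  A <- matrix(c(1, 0.6, -0.4, 1), 2, 2)
  X <- A %*% S
  # whiten before unmixing
  e <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)
  Z <- diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% X
  um <- infomax_unmix(Z, maxit = 1024, tol = 1e-9)
  cc <- abs(cor(t(um$sources), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.99))
})

test_that("already-unmixed input yields a permuted signed identity", {
  set.seed(4)
  Z <- rbind(rlaplace(4000), rlaplace(4000), rlaplace(4000))
  Z <- Z / apply(Z, 1, sd)
  um <- infomax_unmix(Z)
  cc <- abs(cor(t(um$sources), t(Z)))
  # each recovered source matches exactly one input source
  expect_true(all(apply(cc, 1, max) > 0.99))
  expect_equal(sort(apply(cc, 1, which.max)), 1:3)
})

test_that("Infomax terminates on Gaussian-only sources", {
  set.seed(5)
  Z <- matrix(rnorm(3 * 3000), 3)
  um <- infomax_unmix(Z, maxit = 64)
  expect_true(is.matrix(um$W))
  expect_lte(um$iterations, 64L)
})

test_that("back-reconstruction collapses correctly for a single subject", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 20)
  pp <- preprocess_cohort(coh)
  one <- pp$scans[1L]
  fit <- gica(one, k = 5, seed = 20)
  direct <- predict(fit, newscans = one)[[1L]]
  back <- fit$subject_timecourses[[1L]]
  for (j in 1:5) expect_gt(abs(cor(direct[, j], back[, j])), 0.99)
})

test_that("back-reconstructed time courses recover the planted dynamics", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 21)
  pp <- preprocess_cohort(coh)
  fit <- match_templates(gica(pp$scans, k = 8, seed = 21),
                         coh$ground_truth$maps)
  expect_true(all(!is.na(fit$assignment$component)))
  for (i in seq_len(nrow(fit$assignment))) {
    comp <- fit$assignment$component[i]
    lab <- fit$assignment$label[i]
    rs <- vapply(names(fit$subject_timecourses), function(sid) {
      gt <- coh$ground_truth$timecourses[[sid]][11:230, lab]
      abs(cor(fit$subject_timecourses[[sid]][, comp], gt))
    }, numeric(1L))
    expect_gt(min(rs), 0.9)
  }
})

test_that("a zero-signal subject back-reconstructs near-zero time courses", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 22)
  set.seed(22)
  coh$scans[[4L]]$data <- matrix(rnorm(length(coh$scans[[4L]]$data),
                                       sd = coh$spec$noise_sd),
                                 nrow = nrow(coh$scans[[4L]]$data))
  pp <- preprocess_cohort(coh)
  fit <- match_templates(gica(pp$scans, k = 8, seed = 22),
                         coh$ground_truth$maps)
  comps <- fit$assignment$component[!is.na(fit$assignment$component)]
  amp <- vapply(fit$subject_timecourses, function(tc) {
    mean(apply(tc[, comps, drop = FALSE], 2, sd))
  }, numeric(1L))
  expect_lt(amp[4L], 0.3 * mean(amp[-4L]))
})

test_that("stability resampling separates planted structure from noise", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 23)
  pp <- preprocess_cohort(coh)
  fit <- stability_resample(pp$scans, k = 8, n_runs = 5, seed = 23)
  fit <- match_templates(fit, coh$ground_truth$maps)
  comps <- fit$assignment$component[!is.na(fit$assignment$component)]
  expect_true(all(fit$stability[comps] > 0.9))
  noise_scans <- lapply(pp$scans, function(s) {
    s$data <- matrix(rnorm(length(s$data)), nrow = nrow(s$data))
    s
  })
  nfit <- stability_resample(noise_scans, k = 8, n_runs = 5, seed = 23)
  expect_lt(max(nfit$stability), min(fit$stability[comps]))
  expect_error(stability_resample(pp$scans, k = 8, n_runs = 1), "at least 2")
})

test_that("template matching is greedy, sign-correcting and threshold-bounded", {
  set.seed(6)
  maps <- matrix(rlaplace(6 * 500), 6, 500)
  tpl <- t(maps[c(2, 5), ])
  colnames(tpl) <- c("netA", "netB")
  tpl[, 2] <- -tpl[, 2]  # anti-correlated template must still match
  asg <- match_templates(maps, tpl)
  expect_equal(asg$component, c(2L, 5L))
  expect_equal(abs(asg$match_correlation), c(1, 1), tolerance = 1e-10)
  # orthogonal templates stay unassigned at the 0.3 threshold
  ortho <- matrix(rnorm(500 * 2), 500, 2)
  colnames(ortho) <- c("u1", "u2")
  asg2 <- match_templates(maps, ortho)
  expect_true(all(is.na(asg2$component)))
  # duplicated template receives the next-best distinct component
  dup <- cbind(netA = tpl[, 1], netA2 = tpl[, 1])
  asg3 <- match_templates(maps, dup, threshold = 0)
  expect_equal(asg3$component[1L], 2L)
  expect_false(asg3$component[2L] == 2L)
})

test_that("the robustness filter passes narrow-band and rejects broadband components", {
  set.seed(7)
  tcs <- lapply(1:5, function(i) {
    cbind(tone = synth_component_timecourse(1, 0, 0.01, 220, 2.6),
          noise = rnorm(220))
  })
  rf <- robustness_filter(tcs, 2.6)
  expect_true(rf$robust[1L])
  expect_false(rf$robust[2L])
  expect_gt(rf$ratio[1L], 50)
  expect_lt(rf$ratio[2L], 5)
  # the threshold is strict: a ratio exactly at threshold is not robust
  rf_edge <- robustness_filter(tcs, 2.6, threshold = rf$ratio[1L])
  expect_false(rf_edge$robust[1L])
})

test_that("assignments and robustness are invariant to a global sign/scale change", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 24)
  pp <- preprocess_cohort(coh)
  fit1 <- match_templates(gica(pp$scans, k = 6, seed = 24),
                          coh$ground_truth$maps)
  flipped <- lapply(pp$scans, function(s) { s$data <- -3 * s$data; s })
  fit2 <- match_templates(gica(flipped, k = 6, seed = 24),
                          coh$ground_truth$maps)
  # component numbering is an arbitrary ICA permutation; the invariant is
  # label-level: the same networks are found and keep their robustness flags
  expect_true(all(!is.na(fit1$assignment$component)))
  expect_true(all(!is.na(fit2$assignment$component)))
  expect_true(all(fit2$assignment$match_correlation > 0.8))
  r1 <- robustness_filter(fit1$subject_timecourses, 2.6)
  r2 <- robustness_filter(fit2$subject_timecourses, 2.6)
  flags1 <- r1$robust[fit1$assignment$component]
  flags2 <- r2$robust[fit2$assignment$component]
  expect_equal(flags1, flags2)
})

test_that("subject order does not change the group maps", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 25)
  pp <- preprocess_cohort(coh)
  f1 <- gica(pp$scans, k = 5, seed = 25)
  f2 <- gica(rev(pp$scans), k = 5, seed = 25)
  cc <- abs(cor(t(f1$group_maps), t(f2$group_maps)))
  expect_true(all(apply(cc, 1, max) > 0.999))
})

test_that("variance explained grows with the model order", {
  coh <- simulate_cohort(small_spec(n_per_group = 1L), seed = 26)
  pp <- preprocess_cohort(coh)
  ve <- vapply(c(3L, 5L, 8L), function(k) {
    temporal_concat_pca(pp$scans, k = k, pca_dim = 10)$variance_explained
  }, numeric(1L))
  expect_true(all(diff(ve) >= 0))
  expect_true(all(ve > 0 & ve <= 1))
})
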