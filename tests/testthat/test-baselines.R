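test_that("correlation matrix detects duplicates and zero variance", {
  x <- generate_scores(p = 5, k = 2, n = 50, noise_sd = 0.3, seed = 1)
  X <- t(as.matrix(dplyr::select(x, -subject_id)))
  Xdup <- rbind(X, X[1, , drop = FALSE])
  R <- correlation_matrix(Xdup)
  expect_equal(R[1, 6], 1)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  Xz <- X; Xz[3, ] <- 2
  rownames(Xz) <- paste0("v", 1:5)
  expect_error(correlation_matrix(Xz), "v3")
})

test_that("PCA loadings obey closed forms and the spectral identity", {
  p <- 4
  I4 <- diag(p)
  L <- pca_loadings(I4, p)
  # any column order is fine for a degenerate spectrum: expect a permutation
  perm_abs <- round(abs(unname(L$loadings)), 10)
  expect_equal(rowSums(perm_abs), rep(1, p))
  expect_equal(colSums(perm_abs), rep(1, p))
  expect_true(all(perm_abs %in% c(0, 1)))
  expect_equal(L$eigenvalues, rep(1, p))
  # 2x2 closed form with r = 0.5: one-component loadings sqrt(1.5/2) each
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  L1 <- pca_loadings(R2, 1)
  expect_equal(unname(L1$loadings[, 1]), rep(sqrt(1.5 / 2), 2), tolerance = 1e-12)
  # full-rank reconstruction
  x <- generate_scores(p = 7, k = 2, n = 60, noise_sd = 0.4, seed = 2)
  R <- correlation_matrix(x)
  Lf <- pca_loadings(R, 7)
  expect_equal(unname(tcrossprod(Lf$loadings)), unname(R), tolerance = 1e-8)
  expect_error(pca_loadings(R, 8), "k <= p")
})

test_that("one-factor structures are recovered by minres with vanishing chi-square", {
  lam <- c(0.8, 0.7, 0.6, 0.5, 0.4)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  fit <- efa_fit(R, 1, n_subjects = 500)
  expect_equal(unname(abs(fit$loadings[, 1])), lam, tolerance = 1e-3)
  expect_lt(fit$fit_stats$chisq, 1e-6)  # population matrix fits exactly
  expect_equal(fit$communalities, lam^2, tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("minres matches a direct full-loading-matrix optimizer", {
  for (s in 1:3) {
    x <- generate_scores(p = 9, k = 2, n = 400, noise_sd = 0.4,
                         overlap = 0.2, seed = s)
    R <- correlation_matrix(x)
    fit <- efa_fit(R, 2, n_subjects = 400)
    oracle <- brute_minres_fit(R, 2, seed = s)
    off <- upper.tri(R)
    ours <- sum((R - tcrossprod(fit$loadings))[off]^2)
    # neither route should beat the other beyond numerical slack
    expect_equal(ours, oracle$value, tolerance = 1e-6)
    expect_equal(tcrossprod(fit$loadings)[off], oracle$fitted[off],
                 tolerance = 1e-3)
    expect_equal(fit$communalities, oracle$communalities,
                 tolerance = 1e-2, ignore_attr = TRUE)
  }
})

test_that("maximum-likelihood extraction agrees with factanal", {
  x <- generate_scores(p = 12, k = 3, n = 334, noise_sd = 0.4,
                       overlap = 0.2, seed = 4)
  R <- correlation_matrix(x)
  fit <- efa_fit(R, 3, n_subjects = 334, method = "ml")
  ref <- stats::factanal(covmat = R, factors = 3, n.obs = 334, rotation = "none")
  expect_lt(align_max_diff(fit$loadings, unclass(ref$loadings)[, , drop = FALSE]),
            1e-6)
})

test_that("EFA enforces the identifiability bound and subject count", {
  R <- diag(5)
  expect_error(efa_fit(R, 3, 100), "identifiable")
  expect_error(efa_fit(R, 1, 4), "more subjects")
})

test_that("promax is identity at k = 1 and near-varimax for simple structure", {
  L1 <- pca_loadings(matrix(c(1, .3, .3, 1), 2), 1)
  r1 <- promax_rotate(L1)
  expect_equal(r1$loadings, L1$loadings)
  expect_equal(r1$factor_correlations, matrix(1, 1, 1))
  # perfectly simple orthogonal structure: factors stay nearly uncorrelated
  B <- generate_basis(p = 12, k = 3, overlap = 0, seed = 5)
  rot <- promax_rotate(unname(unclass(B)))
  phi <- rot$factor_correlations
  expect_lt(max(abs(phi[upper.tri(phi)])), 0.02)
  expect_equal(diag(phi), rep(1, 3), tolerance = 1e-12)
})

test_that("promax agrees with the stats reference implementation", {
  for (s in 1:3) {
    x <- generate_scores(p = 17, k = 3, n = 334, noise_sd = 0.4,
                         overlap = 0.3, seed = 10 + s)
    L <- pca_loadings(correlation_matrix(x), 3)
    mine <- promax_rotate(L, kappa = 4)
    ref <- stats::promax(L$loadings, m = 4)
    expect_lt(align_max_diff(mine$loadings,
                             unclass(ref$loadings)[, , drop = FALSE]), 1e-3)
  }
})

test_that("unnormalized varimax satisfies the exact rotation identity", {
  x <- generate_scores(p = 10, k = 3, n = 200, noise_sd = 0.4, seed = 6)
  L <- pca_loadings(correlation_matrix(x), 3)$loadings
  vm <- opnmfcv:::varimax_rotation(L, normalize = FALSE)
  expect_equal(vm$loadings, L %*% vm$rotmat, tolerance = 1e-12)
  expect_equal(crossprod(vm$rotmat), diag(3), tolerance = 1e-12)
})

test_that("parallel analysis thresholds are ordered and seed-stable", {
  x <- generate_scores(p = 10, k = 2, n = 150, noise_sd = 0.3, seed = 7)
  pa <- parallel_analysis(x, n_sim = 30, seed = 1)
  expect_true(all(diff(pa$pa_thresholds) <= 0))
  expect_identical(pa$pa_thresholds,
                   parallel_analysis(x, n_sim = 30, seed = 1)$pa_thresholds)
  expect_error(parallel_analysis(x, n_sim = 0), "n_sim")
})

test_that("parallel analysis separates structured from null data", {
  pa2 <- parallel_analysis(generate_scores(p = 17, k = 2, n = 334,
                                           noise_sd = 0.3, seed = 8),
                           n_sim = 50, seed = 2)
  expect_equal(pa2$k_parallel, 2L)
  pa0 <- parallel_analysis(generate_null(17, 334, seed = 9), n_sim = 50, seed = 3)
  expect_lte(pa0$k_parallel, 1L)  # almost always 0; never structure-like
})

test_that("scree diagnostics report the spectrum and an advisory elbow", {
  s <- scree_eigenvalues(diag(6))
  expect_equal(s$eigenvalues, rep(1, 6))
  expect_true(is.na(s$k_scree))
  # rank-2-dominant spectrum: sharpest bend right after position 2
  V <- qr.Q(qr(matrix(rnorm(64), 8)))
  R <- V %*% diag(c(3.2, 2.8, 0.5, 0.45, 0.4, 0.3, 0.2, 0.15)) %*% t(V)
  s2 <- scree_eigenvalues(R)
  expect_equal(s2$k_scree, 2L)
  expect_equal(sum(s2$eigenvalues), 8, tolerance = 1e-8)
})

test_that("Tucker-Lewis index matches its closed form", {
  expect_equal(tucker_lewis_index(100, 100, 1000, 100), 1)
  expect_equal(tucker_lewis_index(50, 10, 500, 100), 0)
  expect_equal(tucker_lewis_index(120, 100, 1000, 136), 523 / 540,
               tolerance = 1e-12)
  expect_error(tucker_lewis_index(10, 0, 100, 10), "degrees of freedom")
})

test_that("loading-based assignment uses absolute values and low-index ties", {
  L <- rbind(c(0.9, 0.1), c(0.2, -0.8), c(0.3, 0.3), c(-0.7, 0.1))
  expect_equal(unname(assign_items_from_loadings(L)), c(1L, 2L, 1L, 1L))
  expect_equal(assign_items_from_loadings(L), assign_items_from_loadings(-L))
  expect_warning(out <- assign_items_from_loadings(rbind(c(0, 0), c(1, 0))),
                 "all-zero")
  expect_equal(unname(out), c(1L, 1L))
})

test_that("baseline accessors return tidy structures", {
  x <- generate_scores(p = 8, k = 2, n = 100, noise_sd = 0.3, seed = 11)
  R <- correlation_matrix(x)
  fit <- promax_rotate(efa_fit(R, 2, 100))
  td <- tidy(fit)
  expect_equal(nrow(td), 16)
  gl <- glance(fit)
  expect_equal(gl$rotation, "promax")
  expect_s3_class(autoplot(parallel_analysis(x, n_sim = 25, seed = 1)), "ggplot")
})
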