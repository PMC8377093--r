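#' Pearson correlation matrix of the items
#'
#' @param data Score table (subjects x items data frame, `score_matrix`, or
#'   items x subjects matrix).
#' @return p x p correlation matrix with item labels as dimnames.
#' @export
correlation_matrix <- function(data) {
  X <- as_score_values(data)
  vars <- apply(X, 1, var)
  if (any(vars == 0)) {
    bad <- rownames(X)[vars == 0] %||% as.character(which(vars == 0))
    abort(paste0("zero-variance item(s): ", paste(bad, collapse = ", ")))
  }
  R <- cor(t(X))
  dimnames(R) <- list(rownames(X), rownames(X))
  R
}

new_loading_matrix <- function(loadings, method, rotation = "none",
                               rotation_matrix = NULL,
                               factor_correlations = NULL,
                               communalities = NULL, fit_stats = NULL,
                               eigenvalues = NULL, heywood = FALSE,
                               n_subjects = NULL) {
  structure(
    list(loadings = loadings, method = method, rotation = rotation,
         rotation_matrix = rotation_matrix,
         factor_correlations = factor_correlations,
         communalities = communalities, fit_stats = fit_stats,
         eigenvalues = eigenvalues, heywood = heywood,
         n_subjects = n_subjects),
    class = "loading_matrix")
}

# Flip column signs so the largest-magnitude entry of each column is positive.
canonical_signs <- function(L) {
  signs <- apply(L, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  sweep(L, 2, signs, "*")
}

#' Principal component loadings of a correlation matrix
#'
#' Unrotated loadings are the leading eigenvectors scaled by the square root
#' of their eigenvalues, so `L L'` reproduces `R` exactly at `k = p`.
#' Column signs are fixed so each column's largest-magnitude entry is
#' positive.
#'
#' @param R Correlation matrix (as from [correlation_matrix()]).
#' @param k Number of components.
#' @return A `loading_matrix` with `method = "pca"`; `eigenvalues` holds the
#'   full descending spectrum.
#' @export
pca_loadings <- function(R, k) {
  p <- nrow(R)
  if (k < 1 || k > p) abort("need 1 <= k <= p")
  eig <- eigen(R, symmetric = TRUE)
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k, k)
  L <- canonical_signs(L)
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("PC", seq_len(k))
  new_loading_matrix(L, method = "pca", eigenvalues = eig$values,
                     communalities = rowSums(L^2))
}

efa_df <- function(p, k) ((p - k)^2 - (p + k)) / 2

ml_discrepancy <- function(R, L, psi) {
  sigma <- tcrossprod(L) + diag(psi, nrow(L))
  # F_ML = log|Sigma| - log|R| + tr(R Sigma^-1) - p
  ld_s <- determinant(sigma, logarithm = TRUE)$modulus
  ld_r <- determinant(R, logarithm = TRUE)$modulus
  as.numeric(ld_s - ld_r + sum(diag(solve(sigma, R))) - nrow(R))
}

efa_fit_stats <- function(R, L, psi, k, n_subjects) {
  p <- nrow(R)
  f <- max(ml_discrepancy(R, L, psi), 0)
  chisq <- (n_subjects - 1 - (2 * p + 5) / 6 - 2 * k / 3) * f
  df <- efa_df(p, k)
  f0 <- max(-as.numeric(determinant(R, logarithm = TRUE)$modulus), 0)
  null_chisq <- (n_subjects - 1 - (2 * p + 5) / 6) * f0
  null_df <- p * (p - 1) / 2
  tli <- if (df > 0 && null_df > 0 && null_chisq / null_df != 1) {
    tucker_lewis_index(chisq, df, null_chisq, null_df)
  } else NA_real_
  list(chisq = chisq, df = df, null_chisq = null_chisq, null_df = null_df,
       tli = tli)
}

#' Exploratory factor analysis of a correlation matrix
#'
#' Common-factor model `R ~ L L' + Psi`. The default extraction is minimum
#' residual (minres / unweighted least squares): uniquenesses are chosen to
#' minimize the sum of squared discarded eigenvalues of `R - Psi` (the
#' residual not representable by `k` factors), with analytic gradients and
#' squared-multiple-correlation starting values; loadings follow from the
#' eigendecomposition of `R - Psi`. `method = "ml"` delegates to
#' [stats::factanal()] (Gaussian maximum likelihood). Model and null-model
#' chi-squares use the ML discrepancy with Bartlett's correction; the
#' Tucker-Lewis index compares the two.
#'
#' @param R Correlation matrix.
#' @param k Number of factors; must respect the identifiability bound
#'   `df = ((p-k)^2 - (p+k))/2 >= 0`.
#' @param n_subjects Number of subjects behind `R` (for chi-square scaling).
#' @param method `"minres"` (default) or `"ml"`.
#' @return A `loading_matrix` with `method = "efa-minres"` or `"efa-ml"`,
#'   communalities, and `fit_stats` (model/null chi-square, dfs, TLI).
#'   Heywood cases (communalities pinned at the upper bound) set
#'   `heywood = TRUE` with a warning.
#' @export
efa_fit <- function(R, k, n_subjects, method = c("minres", "ml")) {
  method <- match.arg(method)
  p <- nrow(R)
  if (k < 1) abort("need k >= 1")
  if (efa_df(p, k) < 0) {
    abort(sprintf("k = %d is not identifiable for p = %d items (negative df)", k, p))
  }
  if (n_subjects <= p) abort("need more subjects than items")

  if (method == "ml") {
    fa <- stats::factanal(covmat = R, factors = k, n.obs = n_subjects,
                          rotation = "none")
    L <- canonical_signs(unclass(fa$loadings)[, , drop = FALSE])
    psi <- fa$uniquenesses
  } else {
    smc <- 1 - 1 / diag(solve(R))
    start <- pmin(pmax(1 - smc, 0.05), 0.95)
    lower <- 0.001
    objective <- function(psi) {
      e <- eigen(R - diag(psi, p), symmetric = TRUE, only.values = TRUE)$values
      sum(e[(k + 1):p]^2)
    }
    gradient <- function(psi) {
      e <- eigen(R - diag(psi, p), symmetric = TRUE)
      tailed <- (k + 1):p
      # d lambda_j / d psi_i = -v_ij^2, so df/dpsi_i = -2 sum_j lambda_j v_ij^2
      -2 * as.vector(e$vectors[, tailed, drop = FALSE]^2 %*% e$values[tailed])
    }
    opt <- optim(start, objective, gradient, method = "L-BFGS-B",
                 lower = lower, upper = 1,
                 control = list(maxit = 1000, factr = 1e7))
    if (opt$convergence != 0) {
      abort(sprintf("minres did not converge (optim code %d: %s)",
                    opt$convergence, opt$message %||% ""))
    }
    psi <- opt$par
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k, k)
    L <- canonical_signs(L)
  }
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(k))
  comm <- rowSums(L^2)
  heywood <- any(comm > 1 + 1e-6) || any(psi <= 0.001 + 1e-8)
  if (heywood) warn("Heywood case: communality at or above 1 for some item(s)")
  new_loading_matrix(L, method = paste0("efa-", method),
                     communalities = comm,
                     fit_stats = efa_fit_stats(R, L, psi, k, n_subjects),
                     heywood = heywood, n_subjects = n_subjects)
}

# Kaiser-normalized varimax by SVD iteration (standard algorithm).
varimax_rotation <- function(L, normalize = TRUE, eps = 1e-6, max_iter = 1000) {
  p <- nrow(L); k <- ncol(L)
  if (k < 2) return(list(loadings = L, rotmat = diag(1)))
  sc <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  sc[sc == 0] <- 1
  x <- L / sc
  TT <- diag(k)
  d <- 0
  for (i in seq_len(max_iter)) {
    z <- x %*% TT
    B <- t(x) %*% (z^3 - z %*% diag(drop(rep(1, p) %*% z^2)) / p)
    sv <- svd(B)
    TT <- sv$u %*% t(sv$v)
    d_old <- d
    d <- sum(sv$d)
    if (d < d_old * (1 + eps)) break
  }
  list(loadings = (x %*% TT) * sc, rotmat = TT)
}

#' Promax oblique rotation
#'
#' The classic two-stage oblique rotation: a Kaiser-normalized varimax
#' pre-rotation, an element-wise power-`kappa` target with signs preserved,
#' and a least-squares fit of the varimax loadings to that target, with
#' columns rescaled so the implied factor-correlation matrix `Phi` has unit
#' diagonal. Sharpening the target (`kappa` > 1) drives small loadings
#' toward zero at the price of correlated factors. `k = 1` is returned
#' unchanged with `Phi = 1`.
#'
#' @param L A `loading_matrix` (from [pca_loadings()] or [efa_fit()]) or a
#'   bare p x k loadings matrix.
#' @param kappa Power of the target (default 4, the conventional choice).
#' @return A `loading_matrix` with `rotation = "promax"`, pattern loadings,
#'   the total rotation matrix, and `factor_correlations` `Phi`.
#' @export
promax_rotate <- function(L, kappa = 4) {
  if (kappa < 1) abort("kappa must be >= 1")
  obj <- if (inherits(L, "loading_matrix")) L else
    new_loading_matrix(as.matrix(L), method = "custom")
  L0 <- obj$loadings
  k <- ncol(L0)
  if (k == 1) {
    obj$rotation <- "promax"
    obj$rotation_matrix <- matrix(1, 1, 1)
    obj$factor_correlations <- matrix(1, 1, 1)
    return(obj)
  }
  vm <- varimax_rotation(L0, normalize = TRUE)
  x <- vm$loadings
  Q <- x * abs(x)^(kappa - 1)           # power target, signs preserved
  U <- solve(crossprod(x), crossprod(x, Q))
  d <- diag(solve(t(U) %*% U))
  U <- U %*% diag(sqrt(d))
  z <- x %*% U
  rot_total <- vm$rotmat %*% U
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  sv <- svd(U)$d
  condU <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(condU) || condU > 1e12) {
    abort(sprintf("promax target fit is numerically singular (condition number %.2e)", condU))
  }
  dimnames(z) <- dimnames(L0)
  obj$loadings <- z
  obj$rotation <- "promax"
  obj$rotation_matrix <- rot_total
  obj$factor_correlations <- phi
  obj
}

#' Horn's parallel analysis
#'
#' Simulates `n_sim` standard-normal datasets with the same number of
#' subjects and items as the data, computes each simulated correlation
#' spectrum, and retains the leading observed eigenvalues that strictly
#' exceed the per-position simulated threshold (the `percentile` quantile by
#' default, the mean if `threshold = "mean"`), stopping at the first
#' failure. `basis = "efa"` uses reduced correlation matrices (squared
#' multiple correlations on the diagonal) for both observed and simulated
#' spectra.
#'
#' @param data Score table.
#' @param n_sim Number of simulated datasets (default 100).
#' @param percentile Quantile of the simulated eigenvalue distribution used
#'   as threshold (default 0.95).
#' @param basis `"pca"` (raw correlation eigenvalues, default) or `"efa"`.
#' @param threshold `"percentile"` or `"mean"`.
#' @param seed Seed for the simulations.
#' @return A `rank_diagnostics` object: observed `eigenvalues`,
#'   `pa_thresholds`, retained count `k_parallel`, and settings.
#' @export
parallel_analysis <- function(data, n_sim = 100, percentile = 0.95,
                              basis = c("pca", "efa"),
                              threshold = c("percentile", "mean"),
                              seed = NULL) {
  if (n_sim < 1) abort("n_sim must be >= 1")
  if (n_sim < 20) warn("n_sim < 20 gives unstable thresholds")
  basis <- match.arg(basis)
  threshold <- match.arg(threshold)
  X <- as_score_values(data)
  p <- nrow(X); n <- ncol(X)

  spectrum <- function(M) {  # M: n x p data
    R <- cor(M)
    if (basis == "efa") diag(R) <- 1 - 1 / diag(solve(R))
    eigen(R, symmetric = TRUE, only.values = TRUE)$values
  }
  obs <- spectrum(t(X))
  draw <- function() {
    vapply(seq_len(n_sim),
           function(i) spectrum(matrix(rnorm(n * p), n, p)),
           numeric(p))
  }
  sims <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  thr <- if (threshold == "mean") rowMeans(sims) else
    apply(sims, 1, quantile, probs = percentile, names = FALSE)

  exceeds <- obs > thr
  k_parallel <- if (!exceeds[1]) 0L else {
    runs <- rle(exceeds)
    as.integer(runs$lengths[1])
  }
  structure(
    list(eigenvalues = obs, pa_thresholds = thr, k_parallel = k_parallel,
         k_scree = NULL, n_sim = n_sim, percentile = percentile,
         basis = basis, threshold = threshold, seed = seed,
         n_subjects = n, p = p),
    class = "rank_diagnostics")
}

#' Scree eigenvalues and an advisory elbow estimate
#'
#' Returns the descending eigenvalues of a correlation matrix for scree
#' plotting, plus an automated elbow estimate via the acceleration factor
#' (largest second difference of the spectrum): the advised factor count is
#' the position just before the sharpest bend. Scree reading is inherently
#' judgment-based; the automated value is advisory only.
#'
#' @param R Correlation matrix.
#' @return A `rank_diagnostics` object with `eigenvalues` and `k_scree`
#'   (`NA` when the spectrum is flat).
#' @export
scree_eigenvalues <- function(R) {
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  p <- length(ev)
  k_scree <- NA_integer_
  if (p >= 3) {
    accel <- vapply(2:(p - 1), function(i) ev[i - 1] - 2 * ev[i] + ev[i + 1],
                    numeric(1))
    if (max(accel) > 1e-8) {
      elbow <- which.max(accel) + 1L  # position of sharpest bend
      k_scree <- elbow - 1L
    }
  }
  structure(
    list(eigenvalues = ev, pa_thresholds = NULL, k_parallel = NULL,
         k_scree = k_scree, p = p),
    class = "rank_diagnostics")
}

#' Tucker-Lewis incremental fit index
#'
#' `TLI = ((chi_null/df_null) - (chi_model/df_model)) / ((chi_null/df_null) - 1)`.
#' Values usually fall in `[0, 1]` (not clipped here): > 0.95 is
#' conventionally a good fit, > 0.90 acceptable.
#'
#' @param chi_model,df_model Model chi-square and degrees of freedom.
#' @param chi_null,df_null Independence-model chi-square and degrees of
#'   freedom.
#' @return Scalar.
#' @export
#' @examples
#' tucker_lewis_index(100, 100, 1000, 100)  # 1
tucker_lewis_index <- function(chi_model, df_model, chi_null, df_null) {
  if (df_model <= 0 || df_null <= 0) abort("degrees of freedom must be > 0")
  if (chi_model < 0 || chi_null < 0) abort("chi-square values must be >= 0")
  r_null <- chi_null / df_null
  r_model <- chi_model / df_model
  if (r_null == 1) abort("null model chi-square/df equals 1; TLI undefined")
  (r_null - r_model) / (r_null - 1)
}

#' Assign items to factors by largest absolute loading
#'
#' The linear-model counterpart of [assign_items()]: each item goes to the
#' factor carrying its largest absolute (pattern) loading, enabling
#' cross-method partition comparisons with OPNMF. Ties break toward the
#' lowest factor index; an all-zero row is assigned to factor 1 with a
#' warning.
#'
#' @param L A `loading_matrix` or bare loadings matrix.
#' @return Named integer vector of factor indices.
#' @export
assign_items_from_loadings <- function(L) {
  if (inherits(L, "loading_matrix")) L <- L$loadings
  A <- abs(L)
  zero_rows <- rowSums(A) == 0
  if (any(zero_rows)) {
    warn(sprintf("%d all-zero loading row(s) assigned to factor 1", sum(zero_rows)))
  }
  setNames(as.integer(apply(A, 1, which.max)), rownames(L))
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf("<loading_matrix> %s, rotation = %s, %d items x %d factors\n",
              x$method, x$rotation, nrow(x$loadings), ncol(x$loadings)))
  if (!is.null(x$fit_stats) && !is.null(x$fit_stats$tli)) {
    cat(sprintf("  TLI = %.3f (model chisq %.1f on %d df)\n",
                x$fit_stats$tli, x$fit_stats$chisq, x$fit_stats$df))
  }
  invisible(x)
}

#' @describeIn efa_fit Loadings in long form (item, factor, loading,
#'   communality).
#' @param x A `loading_matrix`.
#' @param ... Unused.
#' @export
tidy.loading_matrix <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    item = rep(rownames(L) %||% as.character(seq_len(nrow(L))), times = ncol(L)),
    factor = rep(colnames(L) %||% as.character(seq_len(ncol(L))),
                 each = nrow(L)),
    loading = as.vector(L),
    communality = rep(x$communalities %||% rep(NA_real_, nrow(L)),
                      times = ncol(L)))
}

#' @describeIn efa_fit One-row summary (method, k, fit statistics).
#' @export
glance.loading_matrix <- function(x, ...) {
  fs <- x$fit_stats
  tibble::tibble(
    method = x$method, rotation = x$rotation, k = ncol(x$loadings),
    chisq = fs$chisq %||% NA_real_, df = fs$df %||% NA_real_,
    null_chisq = fs$null_chisq %||% NA_real_,
    null_df = fs$null_df %||% NA_real_,
    tli = fs$tli %||% NA_real_, heywood = x$heywood)
}

#' @describeIn parallel_analysis Scree plot with the parallel-analysis
#'   threshold curve when available.
#' @param object A `rank_diagnostics` object.
#' @param ... Unused.
#' @export
autoplot.rank_diagnostics <- function(object, ...) {
  d <- tibble::tibble(position = seq_along(object$eigenvalues),
                      observed = object$eigenvalues)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$observed)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "component", y = "eigenvalue", title = "Scree") +
    ggplot2::theme_minimal()
  if (!is.null(object$pa_thresholds)) {
    d2 <- tibble::tibble(position = seq_along(object$pa_thresholds),
                         threshold = object$pa_thresholds)
    g <- g +
      ggplot2::geom_line(data = d2,
                         ggplot2::aes(y = .data$threshold),
                         linetype = "dashed", color = "firebrick") +
      ggplot2::labs(title = sprintf("Parallel analysis (retain %d)",
                                    object$k_parallel))
  }
  g
}
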