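#' Initialize a non-negative basis for OPNMF
#'
#' `"nndsvda"` computes the non-negative double SVD start (per singular
#' triplet, keep whichever sign-consistent part pair carries more mass) and
#' replaces zeros by the data mean, which makes the start strictly positive
#' and deterministic. `"random"` draws uniform entries scaled to the data
#' magnitude and needs a `seed` for reproducibility.
#'
#' @param data Score table (subjects x items data frame, `score_matrix`, or
#'   items x subjects matrix).
#' @param k Number of factors.
#' @param method `"nndsvda"` or `"random"`.
#' @param seed Seed for `"random"` initialization.
#' @return p x k non-negative matrix.
#' @export
initialize_basis <- function(data, k, method = c("nndsvda", "random"),
                             seed = NULL) {
  X <- as_score_values(data)
  p <- nrow(X)
  if (k < 1 || k > p) abort("need 1 <= k <= number of items")
  method <- match.arg(method)
  if (method == "random") {
    draw <- function() matrix(runif(p * k), p, k) * mean(X)
    W0 <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    return(W0)
  }
  sv <- svd(X, nu = k, nv = k)
  W0 <- matrix(0, p, k)
  W0[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  if (k > 1) {
    for (j in 2:k) {
      x <- sv$u[, j]; y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      xpn <- sqrt(sum(xp^2)); xnn <- sqrt(sum(xn^2))
      ypn <- sqrt(sum(yp^2)); ynn <- sqrt(sum(yn^2))
      mp <- xpn * ypn; mn <- xnn * ynn
      if (mp >= mn) {
        if (xpn > 0) W0[, j] <- sqrt(sv$d[j] * mp) * xp / xpn
      } else {
        if (xnn > 0) W0[, j] <- sqrt(sv$d[j] * mn) * xn / xnn
      }
    }
  }
  W0[W0 == 0] <- mean(X)
  W0
}

#' Fit orthonormal projective NMF
#'
#' Approximates a non-negative items x subjects score matrix X by the
#' projection `W W' X`, minimizing `||X - W W' X||_F^2` over element-wise
#' non-negative `W` (p x k) with the multiplicative update
#' `W <- W * (A W) / (W (W' A W))`, `A = X X'`. The update keeps `W`
#' non-negative and drives it toward near-orthonormal columns, so each item
#' ends up dominated by one factor — a sparse, clustering-like loading
#' pattern. After convergence the columns of `W` are normalized to unit
#' norm, deterministically ordered by loading mass, and each item is
#' assigned to the factor holding its largest basis coefficient.
#'
#' @param data Score table: subjects x items data frame (as returned by the
#'   generators), a [score_matrix()], or an items x subjects matrix.
#' @param k Number of factors, `1 <= k <= p`.
#' @param init `"nndsvda"` (deterministic, the default) or `"random"`.
#' @param max_iter Iteration cap (default 50000).
#' @param tol Relative objective-change convergence tolerance (default 1e-5).
#' @param seed Seed used by `"random"` initialization.
#' @param eps Epsilon guard added to update denominators.
#' @return An `opnmf_fit` object: `basis` (p x k, unit-norm columns),
#'   `loadings` (`W' X`, k x n), `partition` (named item -> factor vector),
#'   `objective_trace`, `recon_error` (relative Frobenius), `converged`,
#'   `n_iter`, plus labels and call metadata.
#' @export
#' @examples
#' x <- generate_scores(p = 17, k = 2, n = 100, noise_sd = 0.1, seed = 1)
#' fit <- opnmf(x, k = 2)
#' fit$partition
opnmf <- function(data, k, init = c("nndsvda", "random"),
                  max_iter = 50000, tol = 1e-5, seed = NULL, eps = 1e-16) {
  sm <- if (inherits(data, "score_matrix")) data else
    if (is.data.frame(data)) score_matrix(data) else NULL
  X <- if (is.null(sm)) as_score_values(data) else sm$values
  init <- match.arg(init)
  p <- nrow(X); n <- ncol(X)
  if (k < 1 || k > p) abort("need 1 <= k <= number of items")
  if (all(X == 0)) abort("degenerate input: score matrix is all zero")

  W0 <- initialize_basis(X, k, method = init, seed = seed)
  A <- X %*% t(X)
  res <- .opnmf_update_cpp(A, W0, as.integer(max_iter), tol, eps)

  W <- res$W
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  W <- order_basis_columns(W)
  rownames(W) <- rownames(X) %||%
    (if (!is.null(sm)) sm$item_labels else default_item_labels(p))

  H <- t(W) %*% X
  part <- assign_items(W)

  structure(
    list(basis = W,
         loadings = H,
         k = k,
         partition = part,
         objective_trace = res$objective_trace,
         recon_error = reconstruction_error(X, W),
         converged = res$converged,
         n_iter = res$n_iter,
         init = init,
         seed = seed,
         tol = tol,
         item_labels = rownames(W),
         subject_ids = if (!is.null(sm)) sm$subject_ids else as.character(seq_len(n))),
    class = "opnmf_fit")
}

#' Relative reconstruction error of a projective basis
#'
#' Computes `||X - W W' X||_F / ||X||_F`: the fraction of the data's
#' Frobenius norm not captured by projecting onto the basis `W`. Zero when
#' the columns of `W` are orthonormal and span the column space of `X`.
#'
#' @param data Score table (any representation accepted by [opnmf()]).
#' @param W p x k non-negative basis, or an `opnmf_fit`.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(data, W) {
  X <- as_score_values(data)
  if (inherits(W, "opnmf_fit")) W <- W$basis
  if (!is.matrix(W) || nrow(W) != nrow(X)) {
    abort("basis shape does not match the score matrix (items mismatch)")
  }
  if (any(W < 0)) abort("basis must be non-negative")
  R <- X - W %*% (t(W) %*% X)
  sqrt(sum(R^2)) / sqrt(sum(X^2))
}

#' Project new subjects onto a fitted basis
#'
#' Computes loadings `W' X_new` and the out-of-sample relative
#' reconstruction error of the held-out data through the training basis.
#' Item labels must match the training items in the same order; a permuted
#' or mismatched item set raises an alignment error rather than silently
#' projecting misaligned rows.
#'
#' @param data Held-out score table with the same items as the training data.
#' @param fit An `opnmf_fit`, or a bare p x k basis matrix.
#' @return List with `loadings` (k x n_new) and `error` (scalar).
#' @export
project <- function(data, fit) {
  W <- if (inherits(fit, "opnmf_fit")) fit$basis else fit
  sm <- if (inherits(data, "score_matrix")) data else
    if (is.data.frame(data)) score_matrix(data) else NULL
  X <- if (is.null(sm)) as_score_values(data) else sm$values
  if (nrow(X) != nrow(W)) abort("alignment error: item count differs from training basis")
  new_labels <- rownames(X) %||% (if (!is.null(sm)) sm$item_labels else NULL)
  train_labels <- rownames(W)
  if (!is.null(new_labels) && !is.null(train_labels) &&
      !identical(unname(new_labels), unname(train_labels))) {
    abort("alignment error: item labels differ from training basis (same order required)")
  }
  list(loadings = t(W) %*% X, error = reconstruction_error(X, W))
}

#' Assign items to factors by largest basis coefficient
#'
#' Each item goes to the factor (column) holding its largest coefficient;
#' ties break toward the lowest column index. An all-zero row is assigned to
#' factor 1 with a warning. Factors that receive no items are permitted.
#'
#' @param W p x k non-negative basis, or an `opnmf_fit`.
#' @return Integer vector of factor indices (1-based), named by item when
#'   `W` has row names.
#' @export
assign_items <- function(W) {
  if (inherits(W, "opnmf_fit")) W <- W$basis
  if (any(W < 0)) abort("basis must be non-negative")
  zero_rows <- rowSums(W) == 0
  if (any(zero_rows)) {
    warn(sprintf("%d all-zero item row(s) assigned to factor 1", sum(zero_rows)))
  }
  part <- apply(W, 1, which.max)  # which.max ties -> lowest index
  setNames(as.integer(part), rownames(W))
}

#' Canonically order basis columns
#'
#' Sorts columns by descending loading mass (sum of squared entries); ties
#' break by the smallest row index of each column's maximal entry. Applied
#' to every fitted basis so repeated runs report factors in a stable order.
#'
#' @param W p x k matrix.
#' @param ties_tol Relative tolerance under which two masses count as tied.
#' @return `W` with reordered columns; attribute `order` gives the
#'   permutation applied.
#' @export
order_basis_columns <- function(W, ties_tol = 1e-10) {
  mass <- colSums(W^2)
  scale <- max(mass, 1e-300)
  key <- round(mass / scale / ties_tol) * ties_tol  # quantize to merge float ties
  max_row <- apply(W, 2, which.max)
  ord <- order(-key, max_row)
  out <- W[, ord, drop = FALSE]
  attr(out, "order") <- ord
  out
}

#' @export
print.opnmf_fit <- function(x, ...) {
  cat(sprintf("<opnmf_fit> k = %d, %d items, %d subjects\n",
              x$k, nrow(x$basis), ncol(x$loadings)))
  cat(sprintf("  relative reconstruction error: %.4f\n", x$recon_error))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "iteration cap reached", x$n_iter))
  invisible(x)
}

#' @describeIn opnmf Basis loadings in long form: one row per (item, factor)
#'   with the item's assigned factor flagged.
#' @param x An `opnmf_fit`.
#' @param ... Unused.
#' @export
tidy.opnmf_fit <- function(x, ...) {
  tibble::tibble(
    item = rep(x$item_labels, times = x$k),
    factor = rep(seq_len(x$k), each = length(x$item_labels)),
    loading = as.vector(x$basis),
    assigned = rep(unname(x$partition), times = x$k) ==
      rep(seq_len(x$k), each = length(x$item_labels)))
}

#' @describeIn opnmf One-row model summary (rank, fit, convergence).
#' @export
glance.opnmf_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    recon_error = x$recon_error,
    objective = x$objective_trace[length(x$objective_trace)],
    n_iter = x$n_iter,
    converged = x$converged,
    n_items = nrow(x$basis),
    n_subjects = ncol(x$loadings))
}

#' @describeIn opnmf Heatmap of the basis matrix with items grouped by
#'   their assigned factor.
#' @param object An `opnmf_fit`.
#' @export
autoplot.opnmf_fit <- function(object, ...) {
  d <- tidy(object)
  item_order <- names(sort(object$partition))
  d$item <- factor(d$item, levels = rev(item_order))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$factor), y = .data$item,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "factor", y = NULL, fill = "basis\nloading",
                  title = sprintf("OPNMF basis (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}
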