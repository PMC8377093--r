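#' Synthetic score data with planted non-negative factor structure
#'
#' The generators in this file emulate the statistical regime of a
#' D-KEFS-like battery: a small number of items (default 17) scored
#' non-negatively for a few hundred subjects, with items organized into
#' factor blocks. They exist so that every downstream stage (OPNMF,
#' split-half stability, PCA/EFA baselines) can be exercised against a known
#' ground truth.
#'
#' @name synthetic-data
#' @keywords internal
NULL

new_ground_truth <- function(basis_true, scores_true, noise_sd, seed,
                             k_fine = ncol(basis_true), k_coarse = NULL,
                             nesting = NULL, meta = list()) {
  partition_true <- apply(basis_true, 1, which.max)
  partition_coarse <- if (!is.null(nesting)) unname(nesting[partition_true]) else NULL
  structure(
    list(basis_true = basis_true,
         scores_true = scores_true,
         partition_true = partition_true,
         partition_coarse = partition_coarse,
         noise_sd = noise_sd,
         k_fine = k_fine,
         k_coarse = k_coarse %||% k_fine,
         nesting = nesting,
         seed = seed,
         meta = meta),
    class = "ground_truth")
}

#' Retrieve the planted ground truth of a synthetic score table
#'
#' @param x A tibble returned by [generate_scores()], [generate_hierarchical()]
#'   or [generate_subgroups()].
#' @return A `ground_truth` object (planted basis, subject factor scores,
#'   item partition(s), noise level, seed), or `NULL` if absent.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

# Evenly allocate p items to k factors; the remainder goes to the
# lowest-index factors so allocation is deterministic.
even_allocation <- function(p, k) {
  sizes <- rep(p %/% k, k)
  r <- p %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Generate a planted non-negative basis matrix
#'
#' Builds an items x factors basis with disjoint block support: items are
#' allocated as evenly as possible across factors and each item carries one
#' primary loading on its home factor (magnitude drawn from U(0.8, 1.2)).
#' With `overlap > 0`, a random half of the items additionally receive a
#' secondary loading of relative magnitude `overlap` on one other factor.
#' Columns are normalized to unit Euclidean norm.
#'
#' @param p Number of items.
#' @param k Number of factors, `1 <= k <= p`.
#' @param overlap Relative magnitude of secondary loadings, in `[0, 1)`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return p x k non-negative matrix with unit-norm columns; row names are
#'   item labels, attribute `partition` gives the home factor of each item.
#' @export
#' @examples
#' W <- generate_basis(p = 17, k = 2, seed = 1)
#' colSums(W^2)  # both 1
generate_basis <- function(p, k, overlap = 0, seed = NULL) {
  if (k < 1 || k > p) abort("need 1 <= k <= p")
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  home <- even_allocation(p, k)
  draw <- function() {
    B <- matrix(0, p, k)
    primary <- runif(p, 0.8, 1.2)
    B[cbind(seq_len(p), home)] <- primary
    if (overlap > 0 && k > 1) {
      chosen <- sample.int(p, size = max(1L, floor(p / 2)))
      for (i in chosen) {
        other <- sample(setdiff(seq_len(k), home[i]), 1L)
        B[i, other] <- overlap * primary[i]
      }
    }
    B
  }
  B <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  rownames(B) <- default_item_labels(p)
  attr(B, "partition") <- home
  B
}

draw_subject_scores <- function(k, n, skew) {
  if (skew) {
    matrix(rlnorm(k * n, meanlog = 0, sdlog = 0.5), k, n)
  } else {
    matrix(abs(rnorm(k * n)), k, n)
  }
}

assemble_scores <- function(basis, scores_true, noise_sd) {
  X <- basis %*% scores_true
  if (noise_sd > 0) {
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), ncol(X))
    X <- pmax(X, 0)  # additive Gaussian noise clipped at zero
  }
  X
}

scores_to_tibble <- function(X, truth, group = NULL) {
  out <- tibble::as_tibble(t(X))
  names(out) <- rownames(X) %||% default_item_labels(nrow(X))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(ncol(X)))),
    if (!is.null(group)) tibble::tibble(group = group),
    out)
  attr(out, "ground_truth") <- truth
  out
}

#' Generate a synthetic score table with planted factor structure
#'
#' Draws subject factor scores (half-normal by default, log-normal(0, 0.5)
#' when `skew = TRUE`), multiplies by a planted basis, adds Gaussian noise
#' clipped at zero, and returns a subjects x items tibble whose planted
#' structure is available through [ground_truth()]. When `p = 17` the items
#' are labeled with the D-KEFS variable names of [dkefs_variables()].
#'
#' @inheritParams generate_basis
#' @param n Number of subjects (`n >= 2`).
#' @param noise_sd Standard deviation of additive noise, in score units.
#' @param skew Draw log-normal subject scores to mimic skewed marginals.
#' @param basis Optional pre-built basis (as from [generate_basis()]);
#'   by default one is generated from `(p, k, overlap, seed)`.
#' @return Tibble with `subject_id` and one column per item; attribute
#'   `ground_truth` carries the planted structure.
#' @export
#' @examples
#' x <- generate_scores(p = 17, k = 2, n = 50, noise_sd = 0.25, seed = 42)
#' ground_truth(x)$partition_true
generate_scores <- function(p = 17, k = 2, n = 334, noise_sd = 0.25,
                            overlap = 0, skew = FALSE, seed = NULL,
                            basis = NULL) {
  if (n < 2) abort("need n >= 2")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  B <- basis %||% generate_basis(p, k, overlap = overlap, seed = seed)
  draw <- function() {
    S <- draw_subject_scores(ncol(B), n, skew)
    list(S = S, X = assemble_scores(B, S, noise_sd))
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed + 1L, draw())
  truth <- new_ground_truth(B, res$S, noise_sd, seed,
                            meta = list(skew = skew,
                                        score_model = if (skew) "lognormal(0,0.5)" else "half-normal",
                                        noise_model = "additive Gaussian clipped at 0"))
  scores_to_tibble(res$X, truth)
}

#' Generate hierarchically structured scores (fine factors nested in coarse)
#'
#' Emulates a battery whose items form `k_fine` fine-grained blocks that
#' group into `k_coarse` coarse domains: fine-factor subject scores are
#' correlated at `within_corr` when their factors share a coarse parent and
#' at `within_corr / 4` across parents, so the coarse division dominates
#' shared variance while the fine division governs item blocks. Fine scores
#' are shifted Gaussians (mean 3, unit variance, clipped at 0) so the target
#' correlations survive the non-negativity constraint.
#'
#' @inheritParams generate_scores
#' @param k_fine,k_coarse Numbers of fine and coarse factors,
#'   `k_coarse <= k_fine <= p`; fine factors are allocated evenly to coarse
#'   parents.
#' @param within_corr Correlation between fine-factor scores sharing a
#'   coarse parent, in `(0, 1)`.
#' @return Tibble as in [generate_scores()]; `ground_truth()` additionally
#'   carries `partition_coarse` and the fine-to-coarse `nesting` map.
#' @export
generate_hierarchical <- function(p = 17, k_fine = 5, k_coarse = 2,
                                  within_corr = 0.7, n = 334,
                                  noise_sd = 0.25, seed = NULL) {
  if (!(k_coarse <= k_fine && k_fine <= p)) abort("need k_coarse <= k_fine <= p")
  if (within_corr <= 0 || within_corr >= 1) abort("within_corr must be in (0, 1)")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  B <- generate_basis(p, k_fine, overlap = 0, seed = seed)
  nesting <- even_allocation(k_fine, k_coarse)
  a <- within_corr / 4        # across-parent correlation
  draw <- function() {
    g0 <- rnorm(n)                           # weak global component
    gc <- matrix(rnorm(k_coarse * n), k_coarse, n)
    Z <- matrix(0, k_fine, n)
    for (f in seq_len(k_fine)) {
      Z[f, ] <- sqrt(a) * g0 +
        sqrt(within_corr - a) * gc[nesting[f], ] +
        sqrt(1 - within_corr) * rnorm(n)
    }
    S <- pmax(Z + 3, 0)
    list(S = S, X = assemble_scores(B, S, noise_sd))
  }
  res <- if (is.null(seed)) draw() else withr::with_seed(seed + 1L, draw())
  truth <- new_ground_truth(B, res$S, noise_sd, seed,
                            k_fine = k_fine, k_coarse = k_coarse,
                            nesting = nesting,
                            meta = list(within_corr = within_corr,
                                        across_corr = a,
                                        score_model = "shifted Gaussian (mean 3, clipped at 0)",
                                        noise_model = "additive Gaussian clipped at 0"))
  scores_to_tibble(res$X, truth)
}

#' Generate subject subgroups sharing one planted basis
#'
#' All subgroups are drawn from the same ground-truth basis; each group may
#' receive its own non-negative loading perturbation of magnitude
#' `perturbation_sd` (0 means the groups are generatively identical, as when
#' emulating gender or age splits of one population).
#'
#' @inheritParams generate_scores
#' @param groups Data frame (or list coercible to one) with columns
#'   `label`, `size`, and optionally `perturbation_sd` (default 0).
#' @return Tibble as in [generate_scores()] with an extra `group` column.
#' @export
#' @examples
#' x <- generate_subgroups(p = 17, k = 2,
#'                         groups = data.frame(label = c("M", "F"),
#'                                             size = c(101, 233)),
#'                         seed = 7)
#' table(x$group)
generate_subgroups <- function(p = 17, k = 2, groups, noise_sd = 0.25,
                               skew = FALSE, seed = NULL) {
  groups <- tibble::as_tibble(groups)
  if (!all(c("label", "size") %in% names(groups))) {
    abort("groups needs columns 'label' and 'size'")
  }
  if (anyDuplicated(groups$label)) abort("duplicate group labels")
  if (any(groups$size < 2)) abort("every group size must be >= 2")
  if (!"perturbation_sd" %in% names(groups)) groups$perturbation_sd <- 0
  if (any(groups$perturbation_sd < 0)) abort("perturbation_sd must be >= 0")

  B <- generate_basis(p, k, overlap = 0, seed = seed)
  draw_group <- function(size, perturbation_sd) {
    Bg <- B
    if (perturbation_sd > 0) {
      Bg <- pmax(B + matrix(rnorm(length(B), sd = perturbation_sd), p, k), 0)
      Bg <- sweep(Bg, 2, sqrt(colSums(Bg^2)), "/")
    }
    S <- draw_subject_scores(k, size, skew)
    assemble_scores(Bg, S, noise_sd)
  }
  draw_all <- function() {
    purrr::map2(groups$size, groups$perturbation_sd, draw_group)
  }
  blocks <- if (is.null(seed)) draw_all() else withr::with_seed(seed + 1L, draw_all())
  X <- do.call(cbind, blocks)
  rownames(X) <- rownames(B)
  truth <- new_ground_truth(B, scores_true = NULL, noise_sd, seed,
                            meta = list(groups = groups, skew = skew))
  scores_to_tibble(X, truth, group = rep(groups$label, groups$size))
}

#' Generate structureless (null) score data
#'
#' Entries are i.i.d. standard normal shifted by +5 and clipped at zero, so
#' the table is non-negative but carries no factor structure. Used to
#' calibrate rank diagnostics (parallel analysis should retain ~0 factors).
#'
#' @inheritParams generate_scores
#' @return Tibble with `subject_id` and `p` item columns.
#' @export
generate_null <- function(p = 17, n = 334, seed = NULL) {
  if (p < 2) abort("need p >= 2")
  if (n < 3) abort("need n >= 3")
  draw <- function() matrix(pmax(rnorm(p * n) + 5, 0), p, n)
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  rownames(X) <- default_item_labels(p)
  scores_to_tibble(X, truth = NULL)
}

#' Write a score table with its ground-truth sidecar
#'
#' Writes the subjects x items table as TSV and, when the table carries a
#' planted ground truth, a companion JSON sidecar (`<path>.truth.json`)
#' recording basis, partitions, seed and generator parameters.
#'
#' @param data Tibble from a generator, or any subjects x items table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(data, path) {
  out <- dplyr::mutate(tibble::as_tibble(data),
                       dplyr::across(dplyr::where(is.double),
                                     ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path)
  truth <- ground_truth(data)
  if (!is.null(truth)) {
    side <- list(
      basis_true = unclass(truth$basis_true),
      partition_true = truth$partition_true,
      partition_coarse = truth$partition_coarse,
      nesting = truth$nesting,
      noise_sd = truth$noise_sd,
      k_fine = truth$k_fine,
      k_coarse = truth$k_coarse,
      seed = truth$seed,
      meta = truth$meta[setdiff(names(truth$meta), "groups")])
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
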