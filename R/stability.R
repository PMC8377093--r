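#' Plan repeated split-half partitions of the subjects
#'
#' Draws `n_splits` independent random half-splits of the subjects (sizes
#' differing by at most one; the first half takes the extra subject when n
#' is odd). With `stratify_by`, each half balances every group's count to
#' within one subject while keeping the overall half sizes within one of
#' each other. Splits are expressed in subject ids so they are invariant to
#' the column order of the score table.
#'
#' @param subjects Either the number of subjects or a character vector of
#'   subject ids.
#' @param n_splits Number of independent split-half replicates.
#' @param seed Integer seed; the plan is deterministic given
#'   `(subjects, n_splits, seed, stratify_by)`.
#' @param stratify_by Optional vector of group labels, one per subject.
#' @return A `split_plan`: list with `pairs` (each a list of id vectors `A`,
#'   `B`), `n`, `n_splits`, `seed`, `stratify_by`.
#' @export
#' @examples
#' plan <- make_splits(10, n_splits = 3, seed = 1)
#' lengths(plan$pairs[[1]])
make_splits <- function(subjects, n_splits, seed = NULL, stratify_by = NULL) {
  if (n_splits < 1) abort("n_splits must be >= 1")
  ids <- if (is.numeric(subjects) && length(subjects) == 1) {
    as.character(seq_len(subjects))
  } else {
    as.character(subjects)
  }
  n <- length(ids)
  if (n < 6) abort("need at least 6 subjects to split in half")
  if (!is.null(stratify_by) && length(stratify_by) != n) {
    abort("stratify_by must have one label per subject")
  }

  one_split <- function() {
    if (is.null(stratify_by)) {
      perm <- sample.int(n)
      nA <- ceiling(n / 2)
      list(A = ids[perm[seq_len(nA)]], B = ids[perm[-seq_len(nA)]])
    } else {
      A <- character(0); B <- character(0)
      extra_to_A <- TRUE  # alternate odd-group remainders between halves
      for (g in unique(stratify_by)) {
        gi <- which(stratify_by == g)
        gi <- gi[sample.int(length(gi))]
        half <- length(gi) %/% 2
        odd <- length(gi) %% 2 == 1
        nA <- half + as.integer(odd && extra_to_A)
        if (odd) extra_to_A <- !extra_to_A
        A <- c(A, ids[gi[seq_len(nA)]])
        B <- c(B, ids[gi[-seq_len(nA)]])
      }
      list(A = A, B = B)
    }
  }
  draw <- function() purrr::map(seq_len(n_splits), function(i) one_split())
  pairs <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(pairs = pairs, n = n, n_splits = n_splits, seed = seed,
         stratify_by = stratify_by),
    class = "split_plan")
}

safe_cor <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(if (isTRUE(all.equal(a, b))) 1 else 0)
  cor(a, b)
}

#' Match factor columns of two bases
#'
#' Finds the one-to-one column matching between two bases maximizing the sum
#' of matched-column Pearson correlations, solved exactly as a linear
#' assignment problem. Needed before entry-wise comparison because factor
#' order is arbitrary across fits.
#'
#' @param W_A,W_B p x k matrices (or `opnmf_fit` objects) with equal `k`.
#' @return Integer permutation `perm` such that `W_B[, perm]` is aligned
#'   with `W_A` column by column.
#' @export
match_factors <- function(W_A, W_B) {
  if (inherits(W_A, "opnmf_fit")) W_A <- W_A$basis
  if (inherits(W_B, "opnmf_fit")) W_B <- W_B$basis
  if (!all(dim(W_A) == dim(W_B))) abort("bases must have identical dimensions")
  k <- ncol(W_A)
  if (k == 1) return(1L)
  corr <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    corr[i, j] <- safe_cor(W_A[, i], W_B[, j])
  }
  solve_assignment(-corr)
}

lin_ccc <- function(a, b) {
  # Lin's concordance correlation with population (1/n) moments
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  cab <- mean((a - ma) * (b - mb))
  denom <- va + vb + (ma - mb)^2
  if (denom == 0) {
    warn("zero-variance, equal-mean column pair in concordance_index")
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  }
  if (va == 0 || vb == 0) {
    warn("zero-variance column in concordance_index")
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  }
  2 * cab / denom
}

#' Concordance between two basis matrices
#'
#' After optimally matching columns ([match_factors()]), computes an
#' agreement coefficient between each matched column pair and returns the
#' mean. The default coefficient is Lin's concordance correlation
#' `2 cov(a, b) / (var(a) + var(b) + (mean(a) - mean(b))^2)`, which is 1
#' only when matched columns are entry-wise identical; `"pearson"` uses the
#' plain correlation instead.
#'
#' @inheritParams match_factors
#' @param method `"ccc"` (Lin's concordance, default) or `"pearson"`.
#' @return Scalar in `[-1, 1]`.
#' @export
concordance_index <- function(W_A, W_B, method = c("ccc", "pearson")) {
  if (inherits(W_A, "opnmf_fit")) W_A <- W_A$basis
  if (inherits(W_B, "opnmf_fit")) W_B <- W_B$basis
  method <- match.arg(method)
  perm <- match_factors(W_A, W_B)
  W_B <- W_B[, perm, drop = FALSE]
  coefs <- vapply(seq_len(ncol(W_A)), function(j) {
    if (method == "ccc") lin_ccc(W_A[, j], W_B[, j]) else safe_cor(W_A[, j], W_B[, j])
  }, numeric(1))
  mean(coefs)
}

#' Within- vs out-of-sample reconstruction error of a split pair
#'
#' Projects each half's data through the basis fitted on the other half.
#' The increase of the transfer error over the within-half error measures
#' how poorly a basis generalizes: a basis that merely memorized its half
#' reconstructs the other half badly.
#'
#' @param X_A,X_B Items x subjects matrices for the two halves (same items,
#'   same order).
#' @param W_A,W_B Bases fitted on `X_A` and `X_B` respectively.
#' @return List with `err_within`, `err_transfer` (each the mean of the two
#'   directions) and `increase = err_transfer - err_within`.
#' @export
out_of_sample_error_increase <- function(X_A, X_B, W_A, W_B) {
  if (inherits(W_A, "opnmf_fit")) W_A <- W_A$basis
  if (inherits(W_B, "opnmf_fit")) W_B <- W_B$basis
  if (nrow(X_A) != nrow(X_B) || nrow(X_A) != nrow(W_A) || nrow(W_A) != nrow(W_B)) {
    abort("halves and bases must share the item set")
  }
  err_within <- mean(c(reconstruction_error(X_A, W_A),
                       reconstruction_error(X_B, W_B)))
  err_transfer <- mean(c(reconstruction_error(X_B, W_A),
                         reconstruction_error(X_A, W_B)))
  list(err_within = err_within, err_transfer = err_transfer,
       increase = err_transfer - err_within)
}

#' Split-half stability analysis over a range of ranks
#'
#' For every split-half replicate and every candidate rank `k`, fits OPNMF
#' independently on both halves and records: adjusted Rand index and
#' variation of information between the halves' item partitions, the matched
#' concordance of the two bases, and within-/out-of-sample reconstruction
#' errors. These are the four criterion families used to pick the most
#' stable and generalizable rank.
#'
#' @param data Score table (subjects x items data frame, `score_matrix`, or
#'   items x subjects matrix).
#' @param ranks Candidate factor numbers (default `2:9`).
#' @param n_splits Number of split-half replicates (default 10000 as in a
#'   full analysis; use ~50-200 for interactive or test-scale runs).
#' @param seed Seed for the split plan (and nothing else: the default
#'   deterministic initialization makes each fit reproducible).
#' @param plan Optional pre-built [make_splits()] plan overriding
#'   `n_splits`/`seed`.
#' @param stratify_by Optional per-subject group labels to balance within
#'   halves.
#' @param ... Passed to [opnmf()] (e.g. `tol`, `max_iter`, `init`).
#' @return An `opnmf_stability` object: `replicates` (tibble: replicate,
#'   k, ari, vi, concordance, err_within, err_transfer, err_increase),
#'   `summary` (per-rank mean, sd, 5th/95th percentiles of each metric),
#'   `ranks`, `plan`.
#' @export
run_stability <- function(data, ranks = 2:9, n_splits = 10000, seed = NULL,
                          plan = NULL, stratify_by = NULL, ...) {
  sm <- if (inherits(data, "score_matrix")) data else
    if (is.data.frame(data)) score_matrix(data) else NULL
  X <- if (is.null(sm)) as_score_values(data) else sm$values
  ids <- if (!is.null(sm)) sm$subject_ids else as.character(seq_len(ncol(X)))
  colnames(X) <- ids
  p <- nrow(X)
  if (any(ranks < 1) || any(ranks > p)) abort("ranks must lie in [1, number of items]")
  if (is.null(plan)) {
    plan <- make_splits(ids, n_splits = n_splits, seed = seed,
                        stratify_by = stratify_by)
  }

  rows <- purrr::imap(plan$pairs, function(pair, r) {
    if (length(pair$A) < 3 || length(pair$B) < 3) {
      abort("each half must contain at least 3 subjects")
    }
    X_A <- X[, pair$A, drop = FALSE]
    X_B <- X[, pair$B, drop = FALSE]
    purrr::map(ranks, function(k) {
      fit_A <- opnmf(X_A, k = k, ...)
      fit_B <- opnmf(X_B, k = k, ...)
      errs <- out_of_sample_error_increase(X_A, X_B, fit_A$basis, fit_B$basis)
      tibble::tibble(
        replicate = r,
        k = k,
        ari = adjusted_rand_index(fit_A$partition, fit_B$partition),
        vi = variation_of_information(fit_A$partition, fit_B$partition),
        concordance = concordance_index(fit_A$basis, fit_B$basis),
        err_within = errs$err_within,
        err_transfer = errs$err_transfer,
        err_increase = errs$increase)
    })
  })
  replicates <- dplyr::bind_rows(purrr::flatten(rows))

  summary <- replicates |>
    tidyr::pivot_longer(-c("replicate", "k"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$k, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = sd(.data$value),
                     q05 = quantile(.data$value, 0.05, names = FALSE),
                     q95 = quantile(.data$value, 0.95, names = FALSE),
                     .groups = "drop")

  structure(
    list(replicates = replicates, summary = summary,
         ranks = sort(unique(ranks)), plan = plan),
    class = "opnmf_stability")
}

#' Select the most stable and generalizable rank
#'
#' Ranks every candidate `k` on four criteria — maximize mean adjusted Rand
#' index, minimize mean variation of information, maximize mean concordance,
#' minimize mean out-of-sample error increase — and returns the `k` with the
#' best (lowest) average criterion rank. Exact average-rank ties break
#' toward the smaller `k` (parsimony).
#'
#' @param result An `opnmf_stability` object from [run_stability()].
#' @return List with `k_star` (selected rank) and `criteria`, a tibble of
#'   per-rank criterion means, per-criterion ranks, and the average rank.
#' @export
select_rank <- function(result) {
  stopifnot(inherits(result, "opnmf_stability"))
  if (length(result$ranks) < 2) abort("need at least 2 evaluated ranks")
  means <- result$replicates |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(ari = mean(.data$ari),
                     vi = mean(.data$vi),
                     concordance = mean(.data$concordance),
                     err_increase = mean(.data$err_increase),
                     .groups = "drop")
  criteria <- means |>
    dplyr::mutate(rank_ari = rank(-.data$ari),
                  rank_vi = rank(.data$vi),
                  rank_concordance = rank(-.data$concordance),
                  rank_err = rank(.data$err_increase),
                  avg_rank = (.data$rank_ari + .data$rank_vi +
                                .data$rank_concordance + .data$rank_err) / 4) |>
    dplyr::arrange(.data$k)
  best <- min(criteria$avg_rank)
  k_star <- min(criteria$k[criteria$avg_rank == best])
  list(k_star = k_star, criteria = criteria)
}

#' @export
print.opnmf_stability <- function(x, ...) {
  cat(sprintf("<opnmf_stability> ranks %s, %d split-half replicates\n",
              paste(range(x$ranks), collapse = "-"),
              x$plan$n_splits))
  sel <- select_rank(x)
  cat(sprintf("  selected rank: k = %d\n", sel$k_star))
  invisible(x)
}

#' @describeIn run_stability Per-replicate metrics in long form.
#' @param x An `opnmf_stability` object.
#' @export
tidy.opnmf_stability <- function(x, ...) {
  tidyr::pivot_longer(x$replicates, -c("replicate", "k"),
                      names_to = "metric", values_to = "value")
}

#' @describeIn run_stability One-row summary: selected rank and its
#'   criterion means.
#' @export
glance.opnmf_stability <- function(x, ...) {
  sel <- select_rank(x)
  at <- sel$criteria[sel$criteria$k == sel$k_star, ]
  tibble::tibble(k_star = sel$k_star,
                 ari = at$ari, vi = at$vi,
                 concordance = at$concordance,
                 err_increase = at$err_increase,
                 n_splits = x$plan$n_splits)
}

#' @describeIn run_stability Stability curves: per-rank mean and 5th-95th
#'   percentile band for each metric, one panel per metric.
#' @param object An `opnmf_stability` object.
#' @export
autoplot.opnmf_stability <- function(object, ...) {
  d <- object$summary |>
    dplyr::filter(.data$metric %in% c("ari", "vi", "concordance", "err_increase"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = object$ranks) +
    ggplot2::labs(x = "number of factors k", y = NULL,
                  title = "Split-half stability and generalizability") +
    ggplot2::theme_minimal()
}
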