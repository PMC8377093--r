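test_that("split plans are disjoint, balanced, and deterministic", {
  plan <- make_splits(10, n_splits = 3, seed = 1)
  expect_length(plan$pairs, 3)
  for (pair in plan$pairs) {
    expect_length(intersect(pair$A, pair$B), 0)
    expect_setequal(c(pair$A, pair$B), as.character(1:10))
    expect_equal(lengths(pair), c(A = 5L, B = 5L))
  }
  odd <- make_splits(11, n_splits = 2, seed = 2)
  expect_equal(unname(lengths(odd$pairs[[1]])), c(6L, 5L))
  expect_identical(make_splits(20, 5, seed = 3), make_splits(20, 5, seed = 3))
  expect_error(make_splits(10, 0), "n_splits")
  expect_error(make_splits(4, 1), "at least 6")
})

test_that("stratified splits balance every group to within one subject", {
  groups <- rep(c("M", "F"), times = c(101, 233))
  plan <- make_splits(334, n_splits = 5, seed = 4, stratify_by = groups)
  names(groups) <- as.character(1:334)
  for (pair in plan$pairs) {
    expect_equal(abs(length(pair$A) - length(pair$B)) <= 1, TRUE)
    for (g in c("M", "F")) {
      nA <- sum(groups[pair$A] == g)
      nB <- sum(groups[pair$B] == g)
      expect_lte(abs(nA - nB), 1)
    }
  }
})

test_that("factor matching recovers permutations and matches brute force", {
  W <- generate_basis(p = 17, k = 3, overlap = 0.2, seed = 5)
  perm <- c(3, 1, 2)
  expect_equal(match_factors(W, W[, perm]), order(perm))
  expect_equal(match_factors(W[, 1, drop = FALSE], W[, 2, drop = FALSE]), 1L)
  set.seed(6)
  for (rep in 1:10) {
    A <- matrix(runif(17 * 3), 17, 3)
    B <- matrix(runif(17 * 3), 17, 3)
    got <- match_factors(A, B)
    best <- -Inf; best_perm <- NULL
    for (p in all_perms(3)) {
      v <- sum(vapply(1:3, function(j) cor(A[, j], B[, p[j]]), numeric(1)))
      if (v > best) { best <- v; best_perm <- p }
    }
    expect_equal(sum(vapply(1:3, function(j) cor(A[, j], B[, got[j]]), numeric(1))),
                 best, tolerance = 1e-12)
  }
  expect_error(match_factors(matrix(1, 4, 2), matrix(1, 4, 3)), "dimensions")
})

test_that("concordance index is 1 for permuted copies and < 1 under noise", {
  W <- generate_basis(p = 17, k = 4, overlap = 0.1, seed = 8)
  expect_equal(concordance_index(W, W[, c(2, 4, 1, 3)]), 1, tolerance = 1e-12)
  Wn <- W
  set.seed(9); Wn[, 2] <- runif(17)
  expect_lt(concordance_index(W, Wn), 1)
  # permutation invariance of either argument
  expect_equal(concordance_index(W[, c(3, 1, 2, 4)], Wn),
               concordance_index(W, Wn), tolerance = 1e-12)
})

test_that("concordance equals the direct CCC formula on a small case", {
  A <- matrix(c(1, 2, 3, 4, 2, 1, 0, 1), 4, 2)
  B <- matrix(c(1.1, 2.2, 2.9, 3.8, 2, 1.2, 0.1, 0.9), 4, 2)
  expect_equal(concordance_index(A, B),
               mean(c(brute_ccc(A[, 1], B[, 1]), brute_ccc(A[, 2], B[, 2]))),
               tolerance = 1e-12)
  # matched-after-permutation case against the exhaustive oracle
  set.seed(10)
  for (k in 2:4) {
    WA <- matrix(runif(17 * k), 17, k)
    WB <- matrix(runif(17 * k), 17, k)
    expect_equal(concordance_index(WA, WB), brute_concordance(WA, WB),
                 tolerance = 1e-10)
  }
})

test_that("transfer error equals within error for identical halves", {
  x <- generate_scores(p = 8, k = 2, n = 30, noise_sd = 0.3, seed = 11)
  X <- t(as.matrix(dplyr::select(x, -subject_id)))
  fit <- opnmf(X, k = 2)
  res <- out_of_sample_error_increase(X, X, fit$basis, fit$basis)
  expect_equal(res$increase, 0)
  expect_equal(res$err_within, res$err_transfer)
})

test_that("noiseless halves generalize with negligible error increase", {
  x <- generate_scores(p = 17, k = 2, n = 100, noise_sd = 0, seed = 12)
  X <- t(as.matrix(dplyr::select(x, -subject_id)))
  XA <- X[, 1:50]; XB <- X[, 51:100]
  fA <- opnmf(XA, k = 2, tol = 1e-10, max_iter = 2e5)
  fB <- opnmf(XB, k = 2, tol = 1e-10, max_iter = 2e5)
  res <- out_of_sample_error_increase(XA, XB, fA$basis, fB$basis)
  expect_lt(abs(res$increase), 1e-6)
})

test_that("overfit bases transfer worse than they fit", {
  # ranks far above the planted k = 2 chase half-specific noise; at k = p the
  # projector can reproduce anything, so near-full rank is the telling regime
  incs <- vapply(1:15, function(i) {
    x <- generate_scores(p = 8, k = 2, n = 24, noise_sd = 0.6, seed = 100 + i)
    X <- t(as.matrix(dplyr::select(x, -subject_id)))
    XA <- X[, 1:12]; XB <- X[, 13:24]
    fA <- opnmf(XA, k = 6)
    fB <- opnmf(XB, k = 6)
    out_of_sample_error_increase(XA, XB, fA$basis, fB$basis)$increase
  }, numeric(1))
  expect_gt(mean(incs), 0)
})

test_that("run_stability produces one row per replicate and rank", {
  x <- generate_scores(p = 8, k = 2, n = 40, noise_sd = 0.3, seed = 13)
  st <- run_stability(x, ranks = 2, n_splits = 1, seed = 1)
  expect_equal(nrow(st$replicates), 1)
  expect_named(st$replicates,
               c("replicate", "k", "ari", "vi", "concordance",
                 "err_within", "err_transfer", "err_increase"))
  st3 <- run_stability(x, ranks = 2:4, n_splits = 3, seed = 1)
  expect_equal(nrow(st3$replicates), 9)
  expect_true(all(st3$replicates$ari <= 1))
  expect_true(all(st3$replicates$vi >= 0))
  expect_true(all(abs(st3$replicates$concordance) <= 1))
})

test_that("noiseless planted structure yields perfect split-half agreement", {
  x <- generate_scores(p = 17, k = 2, n = 120, noise_sd = 0, seed = 14)
  st <- run_stability(x, ranks = 2:4, n_splits = 10, seed = 2)
  at2 <- dplyr::filter(st$replicates, k == 2)
  expect_equal(mean(at2$ari), 1)
  expect_equal(mean(at2$vi), 0, tolerance = 1e-12)
})

test_that("metrics are invariant to subject order under an id-based plan", {
  x <- generate_scores(p = 8, k = 2, n = 30, noise_sd = 0.4, seed = 15)
  sm <- score_matrix(x)
  plan <- make_splits(sm$subject_ids, n_splits = 2, seed = 3)
  st1 <- run_stability(sm, ranks = 2:3, plan = plan)
  perm <- sample(seq_len(30))
  sm2 <- sm
  sm2$values <- sm$values[, perm]
  sm2$subject_ids <- sm$subject_ids[perm]
  sm2$groups <- sm$groups[perm, , drop = FALSE]
  st2 <- run_stability(sm2, ranks = 2:3, plan = plan)
  expect_equal(st1$replicates, st2$replicates, tolerance = 1e-12)
})

test_that("rank selection follows dominance and breaks ties toward smaller k", {
  fake <- function(reps) {
    structure(list(replicates = reps, summary = NULL,
                   ranks = sort(unique(reps$k)),
                   plan = list(n_splits = max(reps$replicate))),
              class = "opnmf_stability")
  }
  # k = 3 dominates every criterion
  reps <- tibble::tibble(
    replicate = rep(1:2, each = 3),
    k = rep(2:4, 2),
    ari = c(0.5, 0.9, 0.4, 0.5, 0.9, 0.4),
    vi = c(0.8, 0.1, 0.9, 0.8, 0.1, 0.9),
    concordance = c(0.6, 0.95, 0.5, 0.6, 0.95, 0.5),
    err_within = 0.1, err_transfer = 0.2,
    err_increase = c(0.10, 0.01, 0.12, 0.10, 0.01, 0.12))
  expect_equal(select_rank(fake(reps))$k_star, 3)
  # exact tie between k = 2 and k = 3 -> parsimony
  reps2 <- tibble::tibble(
    replicate = 1, k = 2:3,
    ari = c(0.8, 0.8), vi = c(0.2, 0.2),
    concordance = c(0.9, 0.9), err_within = 0.1,
    err_transfer = 0.15, err_increase = c(0.05, 0.05))
  expect_equal(select_rank(fake(reps2))$k_star, 2)
  expect_error(select_rank(fake(reps2[1, ])), "at least 2")
})

test_that("stability accessors return tidy structures", {
  x <- generate_scores(p = 8, k = 2, n = 40, noise_sd = 0.3, seed = 16)
  st <- run_stability(x, ranks = 2:3, n_splits = 2, seed = 4)
  td <- tidy(st)
  expect_named(td, c("replicate", "k", "metric", "value"))
  expect_equal(nrow(td), 2 * 2 * 6)
  gl <- glance(st)
  expect_true(all(c("k_star", "ari", "vi", "concordance") %in% names(gl)))
  expect_s3_class(autoplot(st), "ggplot")
})
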