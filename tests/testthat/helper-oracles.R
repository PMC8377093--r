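# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: pair counting instead of contingency
# algebra, exhaustive permutation search instead of the assignment solver,
# element loops instead of matrix identities.

# Rand-type indices by explicit iteration over all item pairs.
brute_ari <- function(p1, p2) {
  n <- length(p1)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same1 <- p1[i] == p1[j]
    same2 <- p2[i] == p2[j]
    if (same1 && same2) a <- a + 1
    else if (same1 && !same2) b <- b + 1
    else if (!same1 && same2) c <- c + 1
    else d <- d + 1
  }
  total <- a + b + c + d
  expected <- (a + b) * (a + c) / total
  maxi <- ((a + b) + (a + c)) / 2
  if (abs(maxi - expected) < 1e-12) return(if (a == maxi) 1 else 0)
  (a - expected) / (maxi - expected)
}

# Variation of information from explicit joint counts.
brute_vi <- function(p1, p2) {
  n <- length(p1)
  u1 <- unique(p1); u2 <- unique(p2)
  h1 <- h2 <- mi <- 0
  for (x in u1) {
    px <- sum(p1 == x) / n
    h1 <- h1 - px * log(px)
  }
  for (y in u2) {
    py <- sum(p2 == y) / n
    h2 <- h2 - py * log(py)
  }
  for (x in u1) for (y in u2) {
    pxy <- sum(p1 == x & p2 == y) / n
    if (pxy > 0) {
      px <- sum(p1 == x) / n; py <- sum(p2 == y) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  h1 + h2 - 2 * mi
}

# Lin's concordance correlation, population moments, straight formula.
brute_ccc <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  va <- sum((a - ma)^2) / n; vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  2 * cab / (va + vb + (ma - mb)^2)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(n - 1)) {
      out[[length(out) + 1]] <- c(i, setdiff(seq_len(n), i)[rest])
    }
  }
  out
}

# Exhaustive-permutation concordance: best mean CCC over all column matchings.
brute_concordance <- function(W_A, W_B) {
  k <- ncol(W_A)
  # replicate the implementation's matching objective (sum of Pearson r),
  # searched exhaustively, then average CCC over the matched pairs
  best_perm <- NULL; best_sum <- -Inf
  for (perm in all_perms(k)) {
    s <- sum(vapply(seq_len(k),
                    function(j) stats::cor(W_A[, j], W_B[, perm[j]]),
                    numeric(1)))
    if (s > best_sum + 1e-12) { best_sum <- s; best_perm <- perm }
  }
  mean(vapply(seq_len(k),
              function(j) brute_ccc(W_A[, j], W_B[, best_perm[j]]),
              numeric(1)))
}

# All set partitions of n items as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    m <- length(labels)
    if (m == n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (lab in seq_len(max(labels) + 1L)) grow(c(labels, lab))
  }
  grow(1L)
  out
}

# Element-wise double-loop reconstruction error (no matrix identities).
brute_recon_error <- function(X, W) {
  p <- nrow(X); n <- ncol(X); k <- ncol(W)
  H <- matrix(0, k, n)
  for (f in seq_len(k)) for (j in seq_len(n)) {
    H[f, j] <- sum(W[, f] * X[, j])
  }
  num <- den <- 0
  for (i in seq_len(p)) for (j in seq_len(n)) {
    xhat <- sum(W[i, ] * H[, j])
    num <- num + (X[i, j] - xhat)^2
    den <- den + X[i, j]^2
  }
  sqrt(num) / sqrt(den)
}

# Minres oracle: direct minimization of the off-diagonal residual sum of
# squares over the full loading matrix (independent of the uniqueness
# profile / eigen route used by efa_fit). Returns fitted common covariance.
brute_minres_fit <- function(R, k, n_starts = 5, seed = 1) {
  p <- nrow(R)
  off <- upper.tri(R)
  objective <- function(par) {
    L <- matrix(par, p, k)
    resid <- R - tcrossprod(L)
    sum(resid[off]^2)
  }
  best <- NULL
  set.seed(seed)
  starts <- c(list(as.vector(pca_loadings(R, k)$loadings)),
              replicate(n_starts - 1, rnorm(p * k, sd = 0.3), simplify = FALSE))
  for (s in starts) {
    o <- optim(s, objective, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  L <- matrix(best$par, p, k)
  list(fitted = tcrossprod(L), communalities = rowSums(L^2),
       value = best$value)
}

# Align columns of B to A up to permutation and sign; max abs difference.
align_max_diff <- function(A, B) {
  k <- ncol(A)
  best <- Inf
  for (perm in all_perms(k)) {
    Bp <- B[, perm, drop = FALSE]
    for (j in seq_len(k)) {
      if (sum(A[, j] * Bp[, j]) < 0) Bp[, j] <- -Bp[, j]
    }
    best <- min(best, max(abs(A - Bp)))
  }
  best
}
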