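#' Adjusted Rand index between two item partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert-Arabie form): `(Index - E[Index]) / (Max - E[Index])` computed
#' from the pair-count contingency table. Equals 1 iff the partitions are
#' identical up to relabeling; 0 expected under independent random
#' labelings. Degenerate pairs for which Max equals E[Index] (e.g. both
#' partitions all-singleton) return 1 when the partitions agree and 0
#' otherwise.
#'
#' @param p1,p2 Vectors of cluster labels over the same items (any atomic
#'   type); names, if present on both, must address the same item set.
#' @return Scalar, at most 1.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
adjusted_rand_index <- function(p1, p2) {
  check_same_items(p1, p2)
  tab <- table(p1, p2)
  n <- length(p1)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps * max(1, maxi)) {
    return(if (sum_ij == maxi) 1 else 0)
  }
  (sum_ij - expected) / (maxi - expected)
}

#' Variation of information between two item partitions
#'
#' Information-theoretic partition distance
#' `VI = H(p1) + H(p2) - 2 I(p1; p2)` with natural-log entropies. Zero iff
#' the partitions are identical up to relabeling; symmetric; bounded above
#' by `log(n)` for n items.
#'
#' @inheritParams adjusted_rand_index
#' @return Non-negative scalar.
#' @export
variation_of_information <- function(p1, p2) {
  check_same_items(p1, p2)
  n <- length(p1)
  joint <- table(p1, p2) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- ent(rowSums(joint))
  h2 <- ent(colSums(joint))
  h12 <- ent(as.vector(joint))
  mi <- h1 + h2 - h12
  max(h1 + h2 - 2 * mi, 0)
}

check_same_items <- function(p1, p2) {
  if (length(p1) != length(p2)) abort("partitions cover different numbers of items")
  n1 <- names(p1); n2 <- names(p2)
  if (!is.null(n1) && !is.null(n2) && !identical(n1, n2)) {
    if (setequal(n1, n2)) {
      abort("partitions address the same items in different orders; align them first")
    }
    abort("partitions address different item sets")
  }
  invisible(TRUE)
}

# Exact solution of the linear assignment problem (Hungarian algorithm with
# potentials, O(n^3)); cost is a square matrix, minimization. Returns for
# each row the assigned column. Sizes here are the factor count k <= ~10.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 1) return(1L)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)          # row potentials, 1..n
  v <- numeric(n + 1)      # col potentials, index j+1 for j = 0..n
  p <- integer(n + 1)      # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}
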