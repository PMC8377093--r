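#' Load a subjects-by-items score table from CSV/TSV
#'
#' Reads a delimited score table (header row of item names, optional
#' `subject_id` and metadata columns), applies complete-case filtering
#' (subjects missing any item score are dropped, with the exclusion count
#' reported), and rejects negative scores. Mirrors the inclusion rule of
#' score batteries where only subjects with all items observed enter the
#' factorization.
#'
#' @param path CSV or TSV file path (delimiter inferred from the extension,
#'   `.tsv`/`.txt` read as tab-separated).
#' @param id_col,group_cols,items Passed to [score_matrix()].
#' @return A `score_matrix`; attribute `n_excluded` records how many
#'   subjects were dropped as incomplete.
#' @export
load_scores <- function(path, id_col = NULL, group_cols = NULL, items = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  reader <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  # read everything as character, then convert score columns with base R's
  # correctly-rounded numeric parser so written tables round-trip bit-exactly
  tab <- reader(path, col_types = readr::cols(.default = "c"))
  tab <- dplyr::mutate(
    tab,
    dplyr::across(dplyr::where(~ all(!is.na(suppressWarnings(as.numeric(.x[!is.na(.x)]))) )
                               & !all(is.na(.x))),
                  ~ suppressWarnings(as.numeric(.x))))
  if (ncol(tab) < 2) abort("table must have a header row and at least 2 columns")

  if (is.null(id_col) && "subject_id" %in% names(tab)) id_col <- "subject_id"
  numeric_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  item_cols <- items %||% setdiff(numeric_cols, c(id_col, group_cols))
  if (length(item_cols) < 2) abort("fewer than 2 numeric item columns found")

  complete <- stats::complete.cases(tab[item_cols])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    inform(sprintf("excluded %d incomplete subject(s); %d remain",
                   n_excluded, sum(complete)))
  }
  tab <- tab[complete, ]
  if (nrow(tab) < 3) abort("fewer than 3 complete subjects")

  neg <- which(as.matrix(tab[item_cols]) < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative score at row %d, column '%s': scores must be non-negative",
                  neg[1, 1], item_cols[neg[1, 2]]))
  }
  sm <- score_matrix(tab, id_col = id_col, group_cols = group_cols,
                     items = item_cols)
  attr(sm, "n_excluded") <- n_excluded
  sm
}

#' Pairwise agreement between labeled partitions
#'
#' Computes symmetric cross-tables of adjusted Rand index and variation of
#' information over a named set of item partitions (e.g. one per method or
#' per subgroup), for quantifying statements like "all subsamples show the
#' same items on each factor".
#'
#' @param partitions Named list of partition vectors over the same items.
#' @return List with matrices `ari` (unit diagonal) and `vi` (zero
#'   diagonal), plus `tidy`, a long tibble of the upper triangle.
#' @export
compare_partitions <- function(partitions) {
  stopifnot(is.list(partitions), length(partitions) >= 2)
  if (is.null(names(partitions)) || any(names(partitions) == "")) {
    names(partitions) <- paste0("partition", seq_along(partitions))
  }
  m <- length(partitions)
  ari <- matrix(1, m, m, dimnames = list(names(partitions), names(partitions)))
  vi <- matrix(0, m, m, dimnames = dimnames(ari))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ari[i, j] <- ari[j, i] <- adjusted_rand_index(partitions[[i]], partitions[[j]])
    vi[i, j] <- vi[j, i] <- variation_of_information(partitions[[i]], partitions[[j]])
  }
  idx <- which(upper.tri(ari), arr.ind = TRUE)
  tidy_tab <- tibble::tibble(
    a = rownames(ari)[idx[, 1]], b = colnames(ari)[idx[, 2]],
    ari = ari[idx], vi = vi[idx])
  list(ari = ari, vi = vi, tidy = tidy_tab)
}

analyse_sample <- function(sm, label, ranks, n_splits, seed, methods,
                           n_sim, percentile, tol, max_iter) {
  out <- list(label = label, n_subjects = ncol(sm$values))
  partitions <- list()

  if ("opnmf" %in% methods) {
    stab <- run_stability(sm, ranks = ranks, n_splits = n_splits, seed = seed,
                          tol = tol, max_iter = max_iter)
    sel <- select_rank(stab)
    fit <- opnmf(sm, k = sel$k_star, tol = tol, max_iter = max_iter)
    out$opnmf <- list(stability = stab, k_star = sel$k_star,
                      criteria = sel$criteria, fit = fit)
    partitions$opnmf <- fit$partition
  }

  R <- correlation_matrix(sm)
  pa <- parallel_analysis(sm, n_sim = n_sim, percentile = percentile,
                          seed = seed)
  pa_efa <- parallel_analysis(sm, n_sim = n_sim, percentile = percentile,
                              basis = "efa", seed = seed)
  scree <- scree_eigenvalues(R)

  if ("pca" %in% methods) {
    k_pca <- max(pa$k_parallel, 1L)
    pca <- promax_rotate(pca_loadings(R, k_pca))
    out$pca <- list(k_parallel = pa$k_parallel, k_scree = scree$k_scree,
                    loadings = pca)
    partitions$pca <- assign_items_from_loadings(pca)
  }
  if ("efa" %in% methods) {
    # EFA rank retention uses reduced-correlation (common-factor) eigenvalues
    k_efa <- max(pa_efa$k_parallel, 1L)
    k_max <- floor((2 * nrow(R) + 1 - sqrt(8 * nrow(R) + 1)) / 2)
    k_efa <- min(k_efa, k_max)
    efa <- efa_fit(R, k_efa, n_subjects = ncol(sm$values))
    efa_rot <- promax_rotate(efa)
    out$efa <- list(k_parallel = pa_efa$k_parallel, k_retained = k_efa,
                    k_scree = scree$k_scree, loadings = efa_rot,
                    fit_stats = efa$fit_stats)
    partitions$efa <- assign_items_from_loadings(efa_rot)
  }
  out$diagnostics <- list(parallel = pa, parallel_efa = pa_efa, scree = scree)
  out$partitions <- partitions
  if (length(partitions) >= 2) out$method_agreement <- compare_partitions(partitions)
  out
}

#' Run the full factorization-comparison analysis
#'
#' Orchestrates the whole pipeline on the full sample and any declared
#' subgroups: OPNMF split-half stability over the rank range and a final
#' full-(sub)sample fit at the selected rank; PCA and minres EFA at the rank
#' retained by parallel analysis, promax-rotated; strongest-loading item
#' partitions per method; and cross-method / cross-subgroup agreement
#' tables. Fully deterministic given `(data, arguments, seed)`.
#'
#' @param data Subjects x items data frame, `score_matrix`, or a CSV/TSV
#'   path (loaded through [load_scores()]).
#' @param ranks Candidate OPNMF ranks (default `2:9`).
#' @param n_splits Split-half replicates per rank (default 10000; use
#'   ~50-200 for interactive runs).
#' @param seed Mandatory integer seed covering every stochastic step.
#' @param subgroup_cols Character vector of metadata columns; every distinct
#'   value of each named column defines a subsample (those with fewer than 6
#'   subjects are skipped with a warning).
#' @param methods Subset of `c("opnmf", "pca", "efa")`.
#' @param n_sim,percentile Parallel-analysis settings.
#' @param tol,max_iter OPNMF convergence settings.
#' @param out_dir Optional directory; when given, TSV/JSON artifacts and a
#'   manifest are written via [write_analysis()].
#' @return An `opnmf_analysis` object: named list of per-sample results
#'   (`full` first), `subgroup_agreement` (cross-subsample OPNMF partition
#'   agreement, when applicable), and the `config`.
#' @export
run_full_analysis <- function(data, ranks = 2:9, n_splits = 10000, seed,
                              subgroup_cols = NULL,
                              methods = c("opnmf", "pca", "efa"),
                              n_sim = 100, percentile = 0.95,
                              tol = 1e-5, max_iter = 50000,
                              out_dir = NULL) {
  if (missing(seed)) abort("seed is mandatory")
  methods <- match.arg(methods, several.ok = TRUE)
  sm <- if (is.character(data)) load_scores(data) else score_matrix(data)

  config <- list(ranks = ranks, n_splits = n_splits, seed = seed,
                 subgroup_cols = subgroup_cols, methods = methods,
                 n_sim = n_sim, percentile = percentile, tol = tol,
                 max_iter = max_iter,
                 package_version = as.character(utils::packageVersion("opnmfcv")))

  samples <- list(full = sm)
  for (colname in subgroup_cols %||% character()) {
    if (!colname %in% names(sm$groups)) {
      abort(sprintf("subgroup column '%s' not found in metadata", colname))
    }
    for (val in unique(sm$groups[[colname]])) {
      keep <- sm$groups[[colname]] == val
      if (sum(keep) < 6) {
        warn(sprintf("subgroup %s=%s has %d (< 6) subjects; skipped",
                     colname, val, sum(keep)))
        next
      }
      sub <- sm
      sub$values <- sm$values[, keep, drop = FALSE]
      sub$subject_ids <- sm$subject_ids[keep]
      sub$groups <- sm$groups[keep, , drop = FALSE]
      samples[[paste0(colname, "=", val)]] <- sub
    }
  }

  results <- purrr::imap(samples, function(s, label) {
    analyse_sample(s, label, ranks = ranks, n_splits = n_splits, seed = seed,
                   methods = methods, n_sim = n_sim, percentile = percentile,
                   tol = tol, max_iter = max_iter)
  })

  subgroup_agreement <- NULL
  opnmf_parts <- purrr::compact(purrr::map(results, ~ .x$partitions$opnmf))
  if (length(opnmf_parts) >= 2) {
    subgroup_agreement <- compare_partitions(opnmf_parts)
  }

  report <- structure(
    list(samples = results, subgroup_agreement = subgroup_agreement,
         config = config),
    class = "opnmf_analysis")
  if (!is.null(out_dir)) write_analysis(report, out_dir)
  report
}

#' @export
print.opnmf_analysis <- function(x, ...) {
  cat(sprintf("<opnmf_analysis> %d sample(s), methods: %s\n",
              length(x$samples), paste(x$config$methods, collapse = ", ")))
  for (s in x$samples) {
    cat(sprintf("  %-12s n = %3d", s$label, s$n_subjects))
    if (!is.null(s$opnmf)) cat(sprintf("  OPNMF k* = %d", s$opnmf$k_star))
    if (!is.null(s$efa)) {
      cat(sprintf("  PA retains %d (EFA TLI %.3f)",
                  s$efa$k_parallel, s$efa$fit_stats$tli))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write analysis artifacts and a reproducibility manifest
#'
#' Emits, per analysed (sub)sample: the stability replicates and per-rank
#' summary (tidy TSV), the selected-rank criterion table, the final OPNMF
#' basis with item labels (TSV) and its partition, baseline loadings, and
#' rank diagnostics (JSON). A `manifest.json` captures the full
#' configuration so a run can be reproduced bit-identically.
#'
#' @param report An `opnmf_analysis` from [run_full_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(report, out_dir) {
  stopifnot(inherits(report, "opnmf_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  wj(report$config, "manifest.json")

  for (s in report$samples) {
    slug <- gsub("[^A-Za-z0-9]+", "_", s$label)
    if (!is.null(s$opnmf)) {
      readr::write_tsv(tidy(s$opnmf$stability),
                       file.path(out_dir, paste0(slug, "_stability.tsv")))
      readr::write_tsv(s$opnmf$criteria,
                       file.path(out_dir, paste0(slug, "_rank_criteria.tsv")))
      basis <- tibble::as_tibble(s$opnmf$fit$basis, .name_repair = "minimal")
      names(basis) <- paste0("factor", seq_len(ncol(basis)))
      readr::write_tsv(dplyr::bind_cols(tibble::tibble(item = s$opnmf$fit$item_labels), basis),
                       file.path(out_dir, paste0(slug, "_opnmf_basis.tsv")))
    }
    diag_json <- list(
      k_star = s$opnmf$k_star %||% NULL,
      partitions = s$partitions,
      parallel = list(k_parallel = s$diagnostics$parallel$k_parallel,
                      eigenvalues = s$diagnostics$parallel$eigenvalues,
                      thresholds = s$diagnostics$parallel$pa_thresholds),
      k_scree = s$diagnostics$scree$k_scree,
      efa_fit_stats = s$efa$fit_stats %||% NULL)
    wj(diag_json, paste0(slug, "_diagnostics.json"))
  }
  if (!is.null(report$subgroup_agreement)) {
    readr::write_tsv(report$subgroup_agreement$tidy,
                     file.path(out_dir, "subgroup_agreement.tsv"))
  }
  invisible(out_dir)
}
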