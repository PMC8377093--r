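#' The 17 D-KEFS total achievement score variables
#'
#' Variable labels for the 17 Total Achievement Scores of the
#' Delis-Kaplan Executive Function System (D-KEFS) battery: one score from
#' the Trail Making Test, three Verbal Fluency scores, three Design Fluency
#' scores, two Color-Word Interference (CWI) scores, three Sorting Test
#' scores, two Twenty Questions scores, and one score each from the Word
#' Context, Tower and Proverb tests. These are the default item labels used
#' by the synthetic generators when `p = 17`.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' dkefs_variables()
dkefs_variables <- function() {
  c("Number_Letter_Switching",
    "Letter_Fluency",
    "Category_Fluency",
    "Category_Switching",
    "Design_Fluency_Filled_Dots",
    "Design_Fluency_Empty_Dots",
    "Design_Fluency_Switching",
    "CWI_Inhibition",
    "CWI_Switching",
    "Confirmed_Sorts",
    "Free_Sorting_Description",
    "Sort_Recognition",
    "Initial_Abstraction",
    "Twenty_Questions_Total",
    "Word_Context_Total",
    "Tower_Total",
    "Proverb_Total")
}

default_item_labels <- function(p) {
  if (p == 17L) dkefs_variables() else sprintf("item%02d", seq_len(p))
}

#' Build a score matrix from a subjects-by-items table
#'
#' Converts a data frame with one row per subject into the internal
#' items-by-subjects matrix representation used by [opnmf()] and the
#' stability pipeline. Numeric columns are treated as item scores; a subject
#' identifier column and grouping columns (e.g. gender, age band) are kept as
#' metadata. Scores must be complete (no `NA`) and non-negative: the intended
#' input is age-corrected scaled scores, which live on a non-negative scale.
#'
#' @param data Data frame or tibble, one row per subject.
#' @param id_col Name of the subject-identifier column, if present.
#'   Defaults to `"subject_id"` when that column exists; otherwise row
#'   numbers are used.
#' @param group_cols Character vector of metadata column names to retain as
#'   subject group labels (non-numeric columns other than `id_col` are
#'   retained automatically).
#' @param items Optional character vector naming the item columns; default is
#'   every numeric column not named in `id_col`/`group_cols`.
#'
#' @return An object of class `score_matrix`: a list with elements
#'   `values` (p x n numeric matrix, items in rows), `item_labels`,
#'   `subject_ids`, and `groups` (tibble of per-subject metadata, possibly
#'   zero-column).
#' @export
#' @examples
#' x <- generate_scores(p = 6, k = 2, n = 20, noise_sd = 0.1, seed = 1)
#' sm <- score_matrix(x)
#' dim(sm$values)  # 6 items x 20 subjects
score_matrix <- function(data, id_col = NULL, group_cols = NULL, items = NULL) {
  if (inherits(data, "score_matrix")) return(data)
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)

  if (is.null(id_col) && "subject_id" %in% names(data)) id_col <- "subject_id"
  numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  auto_groups <- setdiff(names(data), c(numeric_cols, id_col))
  group_cols <- union(group_cols %||% character(), auto_groups)
  if (is.null(items)) {
    items <- setdiff(numeric_cols, c(id_col, group_cols))
  }
  missing_items <- setdiff(items, names(data))
  if (length(missing_items) > 0) {
    abort(paste0("item columns not found: ",
                 paste(missing_items, collapse = ", ")))
  }

  values <- t(as.matrix(data[items]))
  subject_ids <- if (!is.null(id_col)) as.character(data[[id_col]]) else
    as.character(seq_len(ncol(values)))
  groups <- data[intersect(group_cols, names(data))]

  validate_score_values(values)
  structure(
    list(values = values,
         item_labels = items,
         subject_ids = subject_ids,
         groups = tibble::as_tibble(groups)),
    class = "score_matrix")
}

validate_score_values <- function(values) {
  p <- nrow(values); n <- ncol(values)
  if (p < 2) abort("need at least 2 items")
  if (n < 3) abort("need at least 3 subjects")
  if (anyNA(values)) abort("score matrix contains missing values; complete cases only")
  if (!all(is.finite(values))) abort("score matrix contains non-finite values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative score at item '%s', subject index %d: scores must be non-negative",
      rownames(values)[bad[1]] %||% as.character(bad[1]), bad[2]))
  }
  invisible(values)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d items x %d subjects\n",
              nrow(x$values), ncol(x$values)))
  cat("items: ", paste(head(x$item_labels, 5), collapse = ", "),
      if (length(x$item_labels) > 5) ", ..." else "", "\n", sep = "")
  if (ncol(x$groups) > 0) {
    cat("group columns: ", paste(names(x$groups), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.matrix.score_matrix <- function(x, ...) x$values

# Accept either a score_matrix, a subjects x items data frame, or a plain
# items x subjects numeric matrix (used internally by split-half fits).
as_score_values <- function(x) {
  if (inherits(x, "score_matrix")) return(x$values)
  if (is.data.frame(x)) return(score_matrix(x)$values)
  if (is.matrix(x)) {
    validate_score_values(x)
    return(x)
  }
  abort("expected a score_matrix, data frame, or numeric matrix")
}

#' Convert a score matrix back to a subjects-by-items tibble
#'
#' @param x A `score_matrix`.
#' @return Tibble with `subject_id`, group columns, and one column per item.
#' @export
as_subject_table <- function(x) {
  stopifnot(inherits(x, "score_matrix"))
  out <- tibble::as_tibble(t(x$values))
  names(out) <- x$item_labels
  dplyr::bind_cols(tibble::tibble(subject_id = x$subject_ids), x$groups, out)
}
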