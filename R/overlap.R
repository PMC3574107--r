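#' Overlap ratio between two category membership sets
#'
#' The percentage of common compounds relative to the union of the two
#' categories: `100 * n_ab / (n_a + n_b - n_ab)` (the Jaccard index times
#' 100), reported to one decimal (half-up). It is 100 exactly when the two
#' sets are identical and 0 exactly when they are disjoint.
#'
#' @param n_a,n_b Category sizes.
#' @param n_ab Intersection count; must satisfy `n_ab <= min(n_a, n_b)` and
#'   `n_a + n_b - n_ab > 0`. All three arguments are vectorized.
#' @return Percentages rounded to one decimal.
#' @examples
#' overlap_ratio(2501, 4198, 1409) # 26.6
#' @export
overlap_ratio <- function(n_a, n_b, n_ab) {
  if (any(n_ab > pmin(n_a, n_b))) {
    abort("intersection count exceeds a category size")
  }
  union_n <- n_a + n_b - n_ab
  if (any(union_n <= 0)) {
    abort("union of the two categories must be non-empty")
  }
  round_half_up(100 * n_ab / union_n, 1)
}

#' Pairwise category co-occurrence counts and overlap ratios
#'
#' For every ordered category pair computes the category sizes, the number
#' of compounds carrying both categories, and the common/union overlap
#' ratio (see [overlap_ratio()]). By default the analysis covers the 15
#' pairs over the six toxicity endpoints `T1`..`T6`; set
#' `include_nontoxic = TRUE` to add `T7` (21 pairs).
#'
#' @param labels A `tox_labels` table.
#' @param include_nontoxic Include the non-toxicity class `T7`.
#' @return A tibble of class `tox_overlap` with columns `category_a`,
#'   `category_b` (`a < b`), `n_a`, `n_b`, `n_both`, `ratio` (percent).
#' @export
cooccurrence_counts <- function(labels, include_nontoxic = FALSE) {
  tags <- if (include_nontoxic) .tox_tags else .tox_tags[1:6]
  sets <- lapply(tags, function(tg) {
    unique(labels$compound_id[labels$category == tg])
  })
  names(sets) <- tags
  pairs <- utils::combn(tags, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    n_a <- length(sets[[a]])
    n_b <- length(sets[[b]])
    n_both <- length(intersect(sets[[a]], sets[[b]]))
    tibble(
      category_a = a, category_b = b,
      n_a = n_a, n_b = n_b, n_both = n_both,
      ratio = if (n_a + n_b - n_both > 0) {
        overlap_ratio(n_a, n_b, n_both)
      } else {
        NA_real_
      }
    )
  })
  out <- mutate(out,
    category_a = as_category(.data$category_a),
    category_b = as_category(.data$category_b)
  )
  class(out) <- c("tox_overlap", class(out))
  out
}

#' Write a co-occurrence matrix as an upper-triangular table
#'
#' One row and one column per category; the diagonal carries the category
#' size and each upper-triangular cell the `"count(ratio%)"` pair.
#'
#' @param overlap A `tox_overlap` tibble from [cooccurrence_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(overlap, path) {
  tags <- sort(unique(c(as.character(overlap$category_a),
                        as.character(overlap$category_b))))
  k <- length(tags)
  cells <- matrix("", nrow = k, ncol = k, dimnames = list(tags, tags))
  for (i in seq_len(nrow(overlap))) {
    a <- as.character(overlap$category_a[i])
    b <- as.character(overlap$category_b[i])
    cells[a, a] <- format(overlap$n_a[i])
    cells[b, b] <- format(overlap$n_b[i])
    cells[a, b] <- if (is.na(overlap$ratio[i])) {
      format(overlap$n_both[i])
    } else {
      sprintf("%d(%.1f%%)", overlap$n_both[i], overlap$ratio[i])
    }
  }
  tab <- as_tibble(cells)
  tab <- dplyr::bind_cols(tibble(category = tags), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
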