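#' Tidy an evaluation report
#'
#' @param x A `tox_eval` from [evaluate()].
#' @param ... Unused.
#' @return A tibble with one row per prediction order: `order`, `correct`,
#'   `accuracy`.
#' @method tidy tox_eval
#' @export
tidy.tox_eval <- function(x, ...) {
  x$orders
}

#' One-row summary of an evaluation report
#'
#' @param x A `tox_eval` from [evaluate()].
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `n`, `acc_1`, `M`, `m`, `coverage`,
#'   `baseline`.
#' @method glance tox_eval
#' @export
glance.tox_eval <- function(x, ...) {
  tibble(
    mode = x$mode, n = x$n,
    acc_1 = x$orders$accuracy[1],
    M = x$M, m = x$m,
    coverage = x$coverage, baseline = x$baseline
  )
}

#' Tidy a set of train/test groups
#'
#' @param x A `tox_groups` from [make_test_groups()].
#' @param ... Unused.
#' @return A tibble with columns `group`, `compound_id`, `split`
#'   (`"training"` or `"test"`).
#' @method tidy tox_groups
#' @export
tidy.tox_groups <- function(x, ...) {
  purrr::map_dfr(x, function(g) {
    bind_rows(
      tibble(group = g$group, compound_id = g$training, split = "training"),
      tibble(group = g$group, compound_id = g$test, split = "test")
    )
  })
}

#' One-row summary of a benchmark dataset
#'
#' @param x A `tox_benchmark`.
#' @param ... Unused.
#' @return A one-row tibble: compound and interaction counts, excluded
#'   compounds, mean label count and mean degree.
#' @method glance tox_benchmark
#' @export
glance.tox_benchmark <- function(x, ...) {
  tibble(
    n_compounds = length(x$roster),
    n_interactions = nrow(x$network),
    n_excluded = x$n_excluded,
    mean_labels = mean_label_count(x$labels),
    mean_degree = 2 * nrow(x$network) / length(x$roster)
  )
}
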