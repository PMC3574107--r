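# Predictions are a tibble (compound_id, rank, category, score) plus a
# "compounds" attribute recording every query, including those whose
# prediction is empty (no interactive training compound).
new_predictions <- function(tbl, compounds) {
  structure(tbl, compounds = unique(as.character(compounds)),
            class = c("tox_predictions", class(tibble())))
}

prediction_compounds <- function(predictions) {
  attr(predictions, "compounds") %||% unique(predictions$compound_id)
}

#' Binary label vector of a compound
#'
#' The 7-component 0/1 membership vector over the fixed category order
#' `T1`..`T7`; component j is 1 exactly when the compound carries category
#' `Tj`.
#'
#' @param dataset A `tox_benchmark`.
#' @param compound A single compound identifier in the dataset roster.
#' @return A named integer vector of length 7.
#' @examples
#' bench <- generate_benchmark(n_compounds = 20, mean_degree = 4, seed = 1)
#' label_vector(bench, bench$roster[1])
#' @export
label_vector <- function(dataset, compound) {
  stopifnot(length(compound) == 1)
  if (!compound %in% dataset$roster) {
    abort(sprintf("unknown compound: %s", compound))
  }
  tags <- as.character(
    dataset$labels$category[dataset$labels$compound_id == compound]
  )
  setNames(as.integer(.tox_tags %in% tags), .tox_tags)
}

# Weighted-vote scores for many queries at once. For each query q and
# category j: S_j(q) = sum over training neighbours c of Q(q, c) * t_j(c).
# Self-contributions are impossible (the network has no self-edges), so
# scoring a compound against a training set containing it is identical to
# leave-one-out.
neighbor_vote_scores <- function(queries, training, dataset) {
  directed <- both_directions(dataset$network)
  directed <- directed[directed$compound_id %in% queries &
                         directed$neighbor %in% training &
                         directed$neighbor != directed$compound_id, ]
  scored <- inner_join(directed, dataset$labels,
                       by = c(neighbor = "compound_id"),
                       relationship = "many-to-many") |>
    group_by(.data$compound_id, .data$category) |>
    summarise(score = sum(.data$score), .groups = "drop")
  scored
}

#' Category scores for a query compound
#'
#' The score that a query compound has toxicity `Tj` is the sum, over all
#' its interactive compounds in the training set, of the interaction
#' confidence score times the neighbour's 0/1 membership in `Tj`
#' (guilt-by-association weighted voting). A category no training neighbour
#' carries scores exactly 0.
#'
#' @param query A single compound identifier; must not be in `training`
#'   (leave-one-out is the caller's responsibility).
#' @param training Character vector of training compound identifiers
#'   (subset of the dataset roster).
#' @param dataset A `tox_benchmark`.
#'
#' @return A tibble with 7 rows: `category` (factor `T1`..`T7`) and
#'   `score` (non-negative; exact integer sums when scores are integers).
#' @examples
#' bench <- generate_benchmark(n_compounds = 30, mean_degree = 4, seed = 1)
#' q <- bench$roster[1]
#' category_scores(q, setdiff(bench$roster, q), bench)
#' @export
category_scores <- function(query, training, dataset) {
  stopifnot(length(query) == 1)
  if (query %in% training) {
    abort(sprintf("query compound %s must not be in the training set", query))
  }
  extra <- setdiff(training, dataset$roster)
  if (length(extra) > 0) {
    abort(sprintf("training compound(s) not in roster: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  scored <- neighbor_vote_scores(query, training, dataset)
  tibble(category = factor(.tox_tags, levels = .tox_tags)) |>
    left_join(scored[c("category", "score")], by = "category") |>
    mutate(score = ifelse(is.na(.data$score), 0, .data$score))
}

#' Ordered candidate-toxicity prediction from category scores
#'
#' Categories with positive score, sorted by descending score; ties broken
#' by ascending category index (T1 first). Zero-score categories are
#' excluded: a category carried by no interactive training compound is not
#' a candidate, so a prediction has anywhere from 0 to 7 entries. The
#' rank-1 entry is the 1st order prediction, and so forth.
#'
#' @param scores A 7-row tibble from [category_scores()] (columns
#'   `category`, `score`).
#' @return A tibble with columns `rank`, `category`, `score`.
#' @export
ordered_prediction <- function(scores) {
  out <- scores |>
    filter(.data$score > 0) |>
    arrange(dplyr::desc(.data$score), .data$category) |>
    mutate(rank = row_number()) |>
    select("rank", "category", "score")
  out
}

#' Ordered predictions for a batch of query compounds
#'
#' Element-wise [category_scores()] + [ordered_prediction()] over `queries`,
#' computed with vectorized joins. Queries that happen to be members of
#' `training` are scored leave-one-out (a compound never votes for itself).
#'
#' @param queries Character vector of query compound identifiers.
#' @param training Character vector of training compound identifiers.
#' @param dataset A `tox_benchmark`.
#'
#' @return A `tox_predictions` tibble (`compound_id`, `rank`, `category`,
#'   `score`), rows ordered by compound then rank; queries with empty
#'   predictions contribute no rows but are recorded in the `compounds`
#'   attribute.
#' @export
predict_batch <- function(queries, training, dataset) {
  queries <- as.character(queries)
  unknown <- setdiff(queries, dataset$roster)
  if (length(unknown) > 0) {
    abort(sprintf("query compound(s) not in roster: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (length(queries) == 0) {
    return(new_predictions(
      tibble(compound_id = character(), rank = integer(),
             category = as_category(character()), score = numeric()),
      character()
    ))
  }
  scored <- neighbor_vote_scores(queries, training, dataset)
  out <- scored |>
    filter(.data$score > 0) |>
    arrange(.data$compound_id, dplyr::desc(.data$score), .data$category) |>
    group_by(.data$compound_id) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("compound_id", "rank", "category", "score")
  new_predictions(out, queries)
}

#' @export
print.tox_predictions <- function(x, ...) {
  n_all <- length(prediction_compounds(x))
  n_nonempty <- length(unique(x$compound_id))
  cat(sprintf("<tox_predictions> %d compound(s), %d with non-empty predictions\n",
              n_all, n_nonempty))
  NextMethod()
}
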