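# Restrict a label table to a set of compounds, keeping the tox_labels class.
labels_for <- function(dataset, ids) {
  out <- dataset$labels[dataset$labels$compound_id %in% ids, ]
  class(out) <- class(dataset$labels)
  out
}

#' Leave-one-out (jackknife) predictions
#'
#' Each compound of the pool is singled out in turn and predicted by the
#' classifier trained on all remaining pool compounds, so every compound is
#' tested exactly once. Because a compound never interacts with itself,
#' this is computed in one vectorized pass over the edge list.
#'
#' @param dataset A `tox_benchmark`.
#' @param pool Compounds to jackknife over (default: the whole roster).
#'   Must contain at least 2 compounds.
#' @return A `tox_predictions` tibble; compounds without any interactive
#'   pool compound get an empty prediction.
#' @export
jackknife <- function(dataset, pool = NULL) {
  pool <- pool %||% dataset$roster
  if (length(pool) < 2) {
    abort("jackknife needs at least 2 compounds")
  }
  predict_batch(pool, pool, dataset)
}

#' Per-order prediction accuracies
#'
#' The j-th order accuracy is `Acc_j = CT_j / N`, where `CT_j` counts the
#' compounds whose j-th ranked predicted category is one of their true
#' categories and `N` is the number of evaluated compounds. A compound with
#' fewer than j predicted categories cannot score a hit at order j.
#'
#' @param predictions A `tox_predictions` tibble.
#' @param truths A `tox_labels` table covering exactly the predicted
#'   compounds.
#' @param L Number of orders to report (default 7, the category count).
#' @return A tibble with columns `order`, `correct` (`CT_j`) and
#'   `accuracy`.
#' @export
order_accuracies <- function(predictions, truths, L = 7) {
  ids_pred <- prediction_compounds(predictions)
  ids_true <- unique(truths$compound_id)
  check_same_compounds(ids_pred, ids_true)
  N <- length(ids_true)
  hits <- dplyr::semi_join(
    as_tibble(predictions), as_tibble(truths),
    by = c("compound_id", "category")
  )
  ct <- vapply(seq_len(L), function(j) sum(hits$rank == j), integer(1))
  tibble(order = seq_len(L), correct = ct, accuracy = ct / N)
}

check_same_compounds <- function(ids_pred, ids_true) {
  extra <- setdiff(ids_pred, ids_true)
  missing <- setdiff(ids_true, ids_pred)
  if (length(extra) > 0 || length(missing) > 0) {
    abort(sprintf(
      "predictions and truths cover different compounds (only in predictions: %s; only in truths: %s)",
      paste(head(extra, 5), collapse = ", ") %||% "",
      paste(head(missing, 5), collapse = ", ") %||% ""
    ))
  }
  invisible(TRUE)
}

#' First-m coverage of true toxicities
#'
#' For compound i let `S_im` be the number of its true categories appearing
#' among its first `m` predictions and `N_i` its number of true categories;
#' coverage is the mean of `S_im / N_i` over compounds. A compound with
#' fewer than `m` predicted categories is scored over all it has.
#'
#' @inheritParams order_accuracies
#' @param m Prediction depth (positive integer); conventionally
#'   [choose_m()] of the dataset's mean label count.
#' @return A single proportion in `[0, 1]`.
#' @export
coverage <- function(predictions, truths, m) {
  stopifnot(length(m) == 1, m >= 1)
  ids_true <- unique(truths$compound_id)
  check_same_compounds(prediction_compounds(predictions), ids_true)
  hits <- dplyr::semi_join(
    as_tibble(predictions[predictions$rank <= m, ]), as_tibble(truths),
    by = c("compound_id", "category")
  )
  s <- table(factor(hits$compound_id, levels = ids_true))
  n_i <- table(factor(truths$compound_id, levels = ids_true))
  mean(as.numeric(s) / as.numeric(n_i))
}

#' Mean number of true categories per compound
#'
#' @param truths A non-empty `tox_labels` table.
#' @return The mean label count `M`.
#' @export
mean_label_count <- function(truths) {
  n <- length(unique(truths$compound_id))
  if (n == 0) {
    abort("empty label table")
  }
  nrow(truths) / n
}

#' Coverage depth from the mean label count
#'
#' The smallest integer no less than `M`.
#'
#' @param M Mean label count.
#' @return An integer depth `m`.
#' @examples
#' choose_m(1.78) # 2
#' @export
choose_m <- function(M) {
  as.integer(ceiling(M))
}

#' Expected first-order accuracy of random guessing
#'
#' A uniformly random guess of one category is a true category of a random
#' compound with probability `M / L`, the mean label count over the number
#' of categories.
#'
#' @param M Mean label count, `0 <= M <= L`.
#' @param L Number of categories (default 7).
#' @return The expected first-order accuracy as a proportion.
#' @examples
#' random_baseline(1.78, 7) # 0.2543 (25.43%)
#' @export
random_baseline <- function(M, L = 7) {
  if (L == 0) {
    abort("L must be positive")
  }
  stopifnot(M >= 0, M <= L)
  M / L
}

# One greedy iterative-stratification split (rarest label first): repeatedly
# take the category with fewest unassigned compounds and deal its compounds
# to the side (test/train) with the larger unmet demand for that category,
# ties going to the side with more remaining capacity, then at random.
stratified_split <- function(roster, labels, test_n) {
  n <- length(roster)
  idx <- match(labels$compound_id, roster)
  cat_idx <- as.integer(labels$category)
  labs_by_compound <- split(cat_idx, idx)
  labs_by_compound <- labs_by_compound[as.character(seq_len(n))]
  n_j <- tabulate(cat_idx, nbins = 7)
  frac <- test_n / n
  d_test <- n_j * frac           # fractional unmet demand per category
  d_train <- n_j * (1 - frac)
  r_test <- test_n
  r_train <- n - test_n
  cnt <- n_j                     # unassigned compounds per category
  unassigned <- rep(TRUE, n)
  members <- lapply(seq_len(7), function(j) unique(idx[cat_idx == j]))
  in_test <- logical(n)

  while (any(unassigned)) {
    active <- which(cnt > 0)
    if (length(active) == 0) break
    l <- active[which.min(cnt[active])]
    todo <- members[[l]][unassigned[members[[l]]]]
    todo <- todo[sample.int(length(todo))]
    for (c in todo) {
      if (r_test == 0) {
        to_test <- FALSE
      } else if (r_train == 0) {
        to_test <- TRUE
      } else if (d_test[l] > d_train[l]) {
        to_test <- TRUE
      } else if (d_test[l] < d_train[l]) {
        to_test <- FALSE
      } else if (r_test != r_train) {
        to_test <- r_test > r_train
      } else {
        to_test <- runif(1) < 0.5
      }
      labs <- labs_by_compound[[c]]
      if (to_test) {
        in_test[c] <- TRUE
        d_test[labs] <- d_test[labs] - 1
        r_test <- r_test - 1
      } else {
        d_train[labs] <- d_train[labs] - 1
        r_train <- r_train - 1
      }
      unassigned[c] <- FALSE
      cnt[labs] <- cnt[labs] - 1
    }
  }
  list(test = roster[in_test], training = roster[!in_test])
}

#' Random stratified train/test groups
#'
#' Constructs `k` independent random splits of the dataset roster (each a
#' fresh draw from the full roster, not a k-fold partition). Splits are
#' multi-label stratified by greedy iterative assignment, rarest category
#' first, so each category's share of the test set roughly matches its
#' share of the training set.
#'
#' @param dataset A `tox_benchmark` with at least 10 roster compounds.
#' @param k Number of groups (default 10).
#' @param test_fraction Fraction of the roster per test set, in (0, 1)
#'   (default 0.1; the test size is `round(n * test_fraction)`).
#' @param seed Integer seed; the same seed reproduces identical groups.
#' @param tolerance Maximum relative difference between a category's test
#'   and training proportions before a best-effort warning (default 0.2).
#' @return A list of class `tox_groups`; each element has `training` and
#'   `test` character vectors.
#' @export
make_test_groups <- function(dataset, k = 10, test_fraction = 0.1, seed = 1,
                             tolerance = 0.2) {
  stopifnot(test_fraction > 0, test_fraction < 1, k >= 1)
  roster <- dataset$roster
  if (length(roster) < 10) {
    abort("need at least 10 compounds to build test groups")
  }
  test_n <- round(length(roster) * test_fraction)
  groups <- withr::with_seed(seed, {
    lapply(seq_len(k), function(g) {
      sp <- stratified_split(roster, dataset$labels, test_n)
      check_stratification(sp, dataset$labels, tolerance, g)
      structure(c(sp, list(group = g)), class = "tox_group")
    })
  })
  structure(groups, class = "tox_groups")
}

check_stratification <- function(split, labels, tolerance, group) {
  test_counts <- tabulate(
    as.integer(labels$category[labels$compound_id %in% split$test]), 7)
  train_counts <- tabulate(
    as.integer(labels$category[labels$compound_id %in% split$training]), 7)
  test_share <- test_counts / length(split$test)
  train_share <- train_counts / length(split$training)
  present <- train_counts + test_counts > 0
  rel <- abs(test_share - train_share) / pmax(train_share, 1e-12)
  off <- present & train_counts >= 20 & rel > tolerance
  if (any(off)) {
    warn(sprintf(
      "group %d: best-effort stratification; categories out of tolerance: %s",
      group, paste(.tox_tags[off], collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Evaluate the order classifier on a dataset or test group
#'
#' Composes the prediction and metric machinery into a single evaluation
#' report. In `"jackknife"` mode every pool compound (the group's training
#' set, or the whole roster when no group is given) is predicted
#' leave-one-out; in `"holdout"` mode the group's test compounds are
#' predicted from its training compounds.
#'
#' @param dataset A `tox_benchmark`.
#' @param mode `"jackknife"` or `"holdout"`.
#' @param group A `tox_group` from [make_test_groups()] (required for
#'   holdout; optional for jackknife).
#' @param m Coverage depth override; defaults to [choose_m()] of the
#'   evaluated compounds' mean label count.
#' @return An object of class `tox_eval` with per-order correct counts and
#'   accuracies, mean label count `M`, depth `m`, first-m coverage and the
#'   `M/L` random baseline. See [tidy.tox_eval()] and [glance.tox_eval()].
#' @export
evaluate <- function(dataset, mode = c("jackknife", "holdout"), group = NULL,
                     m = NULL) {
  mode <- match.arg(mode)
  if (mode == "jackknife") {
    pool <- if (is.null(group)) dataset$roster else group$training
    predictions <- jackknife(dataset, pool)
    truths <- labels_for(dataset, pool)
  } else {
    if (is.null(group)) {
      abort("holdout evaluation requires a test group")
    }
    if (length(group$test) == 0) {
      abort("empty test set")
    }
    predictions <- predict_batch(group$test, group$training, dataset)
    truths <- labels_for(dataset, group$test)
  }
  acc <- order_accuracies(predictions, truths, L = 7)
  M <- mean_label_count(truths)
  m <- m %||% choose_m(M)
  structure(
    list(
      mode = mode,
      n = length(unique(truths$compound_id)),
      orders = acc,
      M = M,
      m = as.integer(m),
      coverage = coverage(predictions, truths, m),
      baseline = random_baseline(M, 7)
    ),
    class = "tox_eval"
  )
}

#' @export
print.tox_eval <- function(x, ...) {
  cat(sprintf("<tox_eval> %s evaluation of %d compound(s)\n", x$mode, x$n))
  cat(sprintf("  Acc: %s\n",
              paste(sprintf("%d:%.4f", x$orders$order, x$orders$accuracy),
                    collapse = " ")))
  cat(sprintf("  M = %.4f, m = %d, coverage@%d = %.4f, baseline M/L = %.4f\n",
              x$M, x$m, x$m, x$coverage, x$baseline))
  invisible(x)
}

#' Summarise per-order accuracies across evaluation reports
#'
#' @param reports A list of `tox_eval` objects (e.g. one per test group).
#' @return A tibble with per-order `min`, `mean` and `max` accuracy across
#'   the reports.
#' @export
summarize_reports <- function(reports) {
  stopifnot(length(reports) > 0)
  purrr::map_dfr(reports, function(r) r$orders, .id = "report") |>
    group_by(.data$order) |>
    summarise(
      min = min(.data$accuracy),
      mean = mean(.data$accuracy),
      max = max(.data$accuracy),
      .groups = "drop"
    )
}

#' Serialize an evaluation report
#'
#' JSON (all fields) or TSV (the per-order table, with the scalar summary
#' fields as a comment-style header line).
#'
#' @param report A `tox_eval`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(
        mode = report$mode, n = report$n,
        correct = report$orders$correct, accuracy = report$orders$accuracy,
        M = report$M, m = report$m, coverage = report$coverage,
        baseline = report$baseline
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    header <- sprintf("# mode=%s n=%d M=%.6f m=%d coverage=%.6f baseline=%.6f",
                      report$mode, report$n, report$M, report$m,
                      report$coverage, report$baseline)
    writeLines(header, path)
    readr::write_tsv(report$orders, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}
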