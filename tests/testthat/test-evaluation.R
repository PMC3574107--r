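test_that("jackknife predicts each compound from the others exactly once", {
  labels <- as_label_table(list(A = "T1", B = "T1"))
  net <- as_interaction_network(
    tibble::tibble(compound_a = "A", compound_b = "B", score = 500))
  ds <- restrict_to_networked(labels, net)
  jk <- jackknife(ds)
  expect_equal(unique(jk$compound_id), c("A", "B"))
  expect_equal(as.character(jk$category), c("T1", "T1"))
  expect_equal(jk$rank, c(1L, 1L))

  expect_error(jackknife(ds, pool = "A"), "at least 2")
})

test_that("compounds without interactive pool members get empty predictions", {
  labels <- as_label_table(list(A = "T1", B = "T1", C = "T2"))
  # C's only edge goes to an unlabeled outsider, so it stays networked but
  # has no interactive compound inside the pool
  net <- as_interaction_network(tibble::tibble(
    compound_a = c("A", "C"), compound_b = c("B", "Z"),
    score = c(500, 300)))
  ds <- restrict_to_networked(labels, net)
  jk <- jackknife(ds)
  expect_false("C" %in% jk$compound_id)
  expect_true("C" %in% attr(jk, "compounds"))
  acc <- order_accuracies(jk, ds$labels)
  expect_equal(acc$accuracy[1], 2 / 3)
})

test_that("perfect homophily gives perfect first-order predictions", {
  ds <- perfect_homophily_fixture()
  ev <- evaluate(ds, "jackknife")
  expect_equal(ev$orders$accuracy[1], 1)
  expect_equal(coverage(jackknife(ds), ds$labels, 1), 1)
  expect_equal(ev$coverage, 1)
})

test_that("per-order accuracies count rank-j hits over all compounds", {
  labels <- as_label_table(list(A = "T1"))
  preds <- structure(
    tibble::tibble(compound_id = "A", rank = 1L,
                   category = factor("T1", levels = paste0("T", 1:7)),
                   score = 10),
    compounds = "A",
    class = c("tox_predictions", class(tibble::tibble())))
  acc <- order_accuracies(preds, labels)
  expect_equal(acc$accuracy, c(1, rep(0, 6)))

  # two compounds: one fully right at orders 1-2, one fully wrong
  labels2 <- as_label_table(list(A = c("T1", "T3"), B = "T5"))
  preds2 <- structure(
    tibble::tibble(
      compound_id = c("A", "A", "B"), rank = c(1L, 2L, 1L),
      category = factor(c("T1", "T3", "T2"), levels = paste0("T", 1:7)),
      score = c(30, 20, 10)),
    compounds = c("A", "B"),
    class = c("tox_predictions", class(tibble::tibble())))
  acc2 <- order_accuracies(preds2, labels2)
  expect_equal(acc2$accuracy[1:2], c(0.5, 0.5))
  expect_equal(sum(acc2$accuracy[3:7]), 0)

  expect_error(order_accuracies(preds, labels2), "different compounds")
})

test_that("random guessing attains the M/L first-order rate", {
  # uniform random permutations of all 7 categories as predictions, truths
  # drawn to mean label count ~1.78
  withr::with_seed(101, {
    N <- 4000
    p <- prevalence_for_mean_labels(1.78, 7)
    ids <- sprintf("R%04d", seq_len(N))
    sets <- lapply(ids, function(i) {
      repeat {
        draw <- which(stats::runif(7) < p)
        if (length(draw) > 0) return(paste0("T", draw))
      }
    })
    truths <- as_label_table(stats::setNames(sets, ids))
    rows <- lapply(ids, function(i) {
      tibble::tibble(compound_id = i, rank = 1:7,
                     category = factor(paste0("T", sample(7)),
                                       levels = paste0("T", 1:7)),
                     score = 7:1)
    })
    preds <- structure(dplyr::bind_rows(rows), compounds = ids,
                       class = c("tox_predictions", class(tibble::tibble())))
    acc <- order_accuracies(preds, truths)
    M <- mean_label_count(truths)
    se <- sqrt(acc$accuracy[1] * (1 - acc$accuracy[1]) / N)
    expect_lt(abs(acc$accuracy[1] - random_baseline(M, 7)), 3 * se)
  })
})

test_that("coverage averages per-compound hit fractions", {
  labels <- as_label_table(list(A = c("T1", "T2")))
  preds <- structure(
    tibble::tibble(compound_id = "A", rank = 1:2,
                   category = factor(c("T1", "T3"),
                                     levels = paste0("T", 1:7)),
                   score = c(20, 10)),
    compounds = "A",
    class = c("tox_predictions", class(tibble::tibble())))
  expect_equal(coverage(preds, labels, 2), 0.5)

  # upper bound attained when the first m predictions contain every truth
  ds <- perfect_homophily_fixture()
  expect_equal(coverage(jackknife(ds), ds$labels, 1), 1)

  # with full-depth predictions, coverage equals the mean fraction of
  # truths that received a positive score anywhere in the prediction
  ds2 <- random_dataset(40, seed = 23)
  jk <- jackknife(ds2)
  hits <- dplyr::semi_join(tibble::as_tibble(jk),
                           tibble::as_tibble(ds2$labels),
                           by = c("compound_id", "category"))
  ids <- unique(ds2$labels$compound_id)
  s <- table(factor(hits$compound_id, levels = ids))
  n_i <- table(factor(ds2$labels$compound_id, levels = ids))
  expect_equal(coverage(jk, ds2$labels, 7),
               mean(as.numeric(s) / as.numeric(n_i)))
})

test_that("coverage is non-decreasing in m and flat beyond 7", {
  ds <- random_dataset(50, seed = 29)
  jk <- jackknife(ds)
  cov <- vapply(1:9, function(m) coverage(jk, ds$labels, m), numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_equal(cov[8], cov[7])
  expect_equal(cov[9], cov[7])
})

test_that("mean label count and coverage depth follow their definitions", {
  labels <- as_label_table(list(A = "T1", B = c("T1", "T2", "T3")))
  expect_equal(mean_label_count(labels), 2)
  expect_equal(choose_m(1.78), 2L)
  expect_equal(choose_m(2), 2L)
  expect_error(mean_label_count(labels[0, ]), "empty")
})

test_that("random baseline is M/L with guarded inputs", {
  expect_equal(random_baseline(1.78, 7), 1.78 / 7)
  expect_equal(round(100 * random_baseline(1.78, 7), 2), 25.43)
  expect_equal(random_baseline(7, 7), 1)
  expect_equal(random_baseline(0, 7), 0)
  expect_error(random_baseline(1, 0), "positive")
})

test_that("hit-count identity bounds the summed per-order counts", {
  ds <- random_dataset(60, seed = 31)
  jk <- jackknife(ds)
  acc <- order_accuracies(jk, ds$labels)
  hits <- dplyr::semi_join(tibble::as_tibble(jk),
                           tibble::as_tibble(ds$labels),
                           by = c("compound_id", "category"))
  expect_equal(sum(acc$correct), nrow(hits))
  expect_lte(sum(acc$correct), nrow(ds$labels))
})

test_that("accuracies are invariant to compound iteration order", {
  ds <- random_dataset(40, seed = 37)
  jk <- jackknife(ds)
  acc <- order_accuracies(jk, ds$labels)
  perm <- withr::with_seed(1, sample(nrow(jk)))
  jk_perm <- structure(tibble::as_tibble(jk)[perm, ],
                       compounds = rev(attr(jk, "compounds")),
                       class = class(jk))
  labs_perm <- ds$labels[withr::with_seed(2, sample(nrow(ds$labels))), ]
  class(labs_perm) <- class(ds$labels)
  expect_equal(order_accuracies(jk_perm, labs_perm), acc)
})

test_that("stratified groups match the requested split sizes and shares", {
  ds <- random_dataset(1000, seed = 41, mean_degree = 8)
  groups <- make_test_groups(ds, k = 10, test_fraction = 0.1, seed = 43)
  n <- length(ds$roster)
  test_n <- round(n * 0.1)
  for (g in groups) {
    expect_equal(length(g$test), test_n)
    expect_equal(length(g$training), n - test_n)
    expect_length(intersect(g$test, g$training), 0)
    expect_setequal(c(g$test, g$training), ds$roster)
    test_counts <- table(ds$labels$category[
      ds$labels$compound_id %in% g$test])
    train_counts <- table(ds$labels$category[
      ds$labels$compound_id %in% g$training])
    share_test <- as.numeric(test_counts) / length(g$test)
    share_train <- as.numeric(train_counts) / length(g$training)
    big <- as.numeric(train_counts) >= 50
    expect_true(all(
      abs(share_test - share_train)[big] / share_train[big] <= 0.2))
  }
  # independent draws, not a partition: test sets differ across groups
  expect_gt(length(unique(lapply(groups, function(g) sort(g$test)))), 1)

  groups2 <- make_test_groups(ds, k = 10, test_fraction = 0.1, seed = 43)
  expect_identical(groups, groups2)
})

test_that("evaluate composes jackknife and holdout reports", {
  ds <- random_dataset(300, seed = 47, mean_degree = 8, homophily = 0.95)
  groups <- make_test_groups(ds, k = 1, test_fraction = 0.2, seed = 49)
  jk <- evaluate(ds, "jackknife", group = groups[[1]])
  expect_equal(jk$n, length(groups[[1]]$training))
  ho <- evaluate(ds, "holdout", group = groups[[1]])
  expect_equal(ho$n, length(groups[[1]]$test))
  expect_gt(ho$orders$accuracy[1], ho$baseline)
  expect_equal(ho$m, choose_m(ho$M))

  expect_error(evaluate(ds, "holdout"), "requires a test group")
  empty_group <- structure(list(training = ds$roster, test = character()),
                           class = "tox_group")
  expect_error(evaluate(ds, "holdout", group = empty_group), "empty test set")

  tdy <- tidy(jk)
  expect_equal(nrow(tdy), 7)
  expect_equal(glance(jk)$acc_1, jk$orders$accuracy[1])
  sm <- summarize_reports(list(jk, ho))
  expect_equal(nrow(sm), 7)
  expect_true(all(sm$min <= sm$mean & sm$mean <= sm$max))
})

test_that("evaluation reports serialize to JSON and TSV", {
  ds <- random_dataset(60, seed = 53)
  ev <- evaluate(ds, "jackknife")
  jpath <- tempfile(fileext = ".json")
  write_evaluation_report(ev, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$accuracy, ev$orders$accuracy)
  expect_equal(back$M, ev$M)

  tpath <- tempfile(fileext = ".tsv")
  write_evaluation_report(ev, tpath, format = "tsv")
  lines <- readLines(tpath)
  expect_match(lines[1], "^# mode=jackknife")
  tab <- readr::read_tsv(tpath, comment = "#", show_col_types = FALSE)
  expect_equal(tab$correct, ev$orders$correct)
})
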