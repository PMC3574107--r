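# Shared fixtures and independent oracles for the test suite.

# The tasosartan neighbourhood: a "non-toxic" query whose seven interactive
# compounds are five high-confidence non-toxic drugs plus two toxic ones.
tasosartan_fixture <- function() {
  labels <- as_label_table(list(
    CID000060919 = "T7",
    CID000003749 = "T7",
    CID000002541 = "T7",
    CID000060921 = "T7",
    CID000003961 = "T7",
    CID000060846 = "T7",
    CID000065999 = c("T1", "T6"),
    CID000054738 = c("T1", "T2")
  ))
  network <- as_interaction_network(tibble::tibble(
    compound_a = "CID000060919",
    compound_b = c("CID000003749", "CID000002541", "CID000060921",
                   "CID000003961", "CID000060846", "CID000065999",
                   "CID000054738"),
    score = c(679, 670, 669, 667, 658, 643, 172)
  ))
  suppressMessages(restrict_to_networked(labels, network))
}

# A perfectly homophilous toy: three single-label communities, edges only
# within a community, so all weighted votes land on the true category.
perfect_homophily_fixture <- function(per_class = 10) {
  tags <- c("T1", "T3", "T7")
  ids <- unlist(lapply(seq_along(tags), function(k) {
    sprintf("C%s%02d", tags[k], seq_len(per_class))
  }))
  labels <- as_label_table(tibble::tibble(
    compound_id = ids,
    category = rep(tags, each = per_class)
  ))
  edges <- do.call(rbind, lapply(seq_along(tags), function(k) {
    block <- ids[seq_len(per_class) + (k - 1) * per_class]
    data.frame(compound_a = block,
               compound_b = c(block[-1], block[1]),
               score = 500)
  }))
  suppressMessages(
    restrict_to_networked(labels, as_interaction_network(edges))
  )
}

random_dataset <- function(n, seed, mean_degree = 4, homophily = 0.5) {
  suppressWarnings(generate_benchmark(
    n_compounds = n, mean_degree = mean_degree, homophily = homophily,
    seed = seed
  ))
}

# Independent double-loop oracle for the weighted-vote score: iterates all
# training compounds x all 7 categories using nothing but raw edge rows.
brute_force_scores <- function(dataset, query, training) {
  edges <- dataset$network
  S <- stats::setNames(numeric(7), paste0("T", 1:7))
  for (ci in setdiff(training, query)) {
    hit <- (edges$compound_a == query & edges$compound_b == ci) |
      (edges$compound_b == query & edges$compound_a == ci)
    Q <- if (any(hit)) edges$score[hit][1] else 0
    if (Q > 0) {
      tags <- as.character(
        dataset$labels$category[dataset$labels$compound_id == ci]
      )
      for (j in 1:7) {
        if (paste0("T", j) %in% tags) S[j] <- S[j] + Q
      }
    }
  }
  S
}

# Brute-force set-intersection oracle for the co-occurrence matrix.
brute_force_overlap <- function(labels, tags = paste0("T", 1:6)) {
  out <- list()
  for (i in seq_along(tags)) {
    for (k in seq_along(tags)) {
      if (i < k) {
        A <- unique(labels$compound_id[labels$category == tags[i]])
        B <- unique(labels$compound_id[labels$category == tags[k]])
        out[[length(out) + 1]] <- data.frame(
          category_a = tags[i], category_b = tags[k],
          n_a = length(A), n_b = length(B),
          n_both = length(intersect(A, B))
        )
      }
    }
  }
  do.call(rbind, out)
}

# Run the installed CLI in a child Rscript with the test library visible.
run_cli <- function(args, wd = tempdir()) {
  script <- system.file("cli", "toxorder.R", package = "toxorder")
  stopifnot(nzchar(script))
  out <- withr::with_dir(wd, suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  )))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
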