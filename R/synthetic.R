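# Per-category prevalence of the 17,233-compound curated toxicity benchmark
# (category sizes 12633, 6110, 2293, 2353, 2501, 4198, 646): the default
# label marginals for generated datasets.
.benchmark_prevalence <- c(12633, 6110, 2293, 2353, 2501, 4198, 646) / 17233

#' Category prevalence that yields a target mean label count
#'
#' Labels are drawn per category as independent Bernoulli trials and empty
#' label sets are redrawn, so the realized mean label count conditional on
#' non-emptiness exceeds `L * p`. This solves for the equal per-category
#' probability `p` such that `L * p / (1 - (1 - p)^L)` equals the target
#' mean `M`.
#'
#' @param M Target mean label count, in `(1, L]`.
#' @param L Number of categories (default 7).
#' @return A single probability `p` to use for all `L` categories.
#' @export
prevalence_for_mean_labels <- function(M, L = 7) {
  stopifnot(M > 1, M <= L)
  f <- function(p) L * p / (1 - (1 - p)^L) - M
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Generate a benchmark-shaped homophilous labelled network
#'
#' Simulates a dataset with the structure the order classifier consumes: a
#' compound-to-category label table and a weighted undirected interaction
#' network in which linked compounds share categories more often than
#' chance. Labels are independent Bernoulli draws per category (empty sets
#' redrawn); each edge is drawn, with probability `homophily`, uniformly
#' from the label-sharing compound pairs (by rejection sampling) and
#' otherwise uniformly from all pairs; duplicate pairs are merged keeping
#' the larger weight; weights are uniform integers on `weight_range`
#' (STITCH-like confidence scores).
#'
#' Defaults mirror a large curated toxicity benchmark: category prevalences
#' proportional to sizes 12,633 / 6,110 / 2,293 / 2,353 / 2,501 / 4,198 /
#' 646 over 17,233 compounds, mean degree 37.5 (323,432 interactions over
#' 17,233 compounds) and confidence scores in 150..999.
#'
#' @param n_compounds Number of compounds to simulate.
#' @param n_categories Number of active categories (first `n_categories`
#'   of `T1`..`T7`; default 7).
#' @param prevalence Per-category Bernoulli probabilities (length
#'   `n_categories`); default: the benchmark marginals above (uniform over
#'   active categories when `n_categories < 7`).
#' @param mean_degree Expected number of interactions per compound.
#' @param homophily Probability in `[0, 1]` that an edge is drawn from
#'   label-sharing pairs rather than uniformly.
#' @param weight_range Integer confidence-score range, low/high.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `tox_benchmark` (compounds left without any interaction are
#'   excluded from the roster, as in real benchmark assembly). The
#'   generating settings are attached as attribute `"config"`.
#' @export
generate_benchmark <- function(n_compounds, n_categories = 7,
                               prevalence = NULL, mean_degree = 37.5,
                               homophily = 0.8,
                               weight_range = c(150L, 999L), seed = 1) {
  stopifnot(
    n_compounds >= 2, n_categories >= 1, n_categories <= 7,
    mean_degree >= 0, homophily >= 0, homophily <= 1,
    length(weight_range) == 2, weight_range[1] <= weight_range[2],
    weight_range[1] >= 1
  )
  if (is.null(prevalence)) {
    prevalence <- if (n_categories == 7) {
      .benchmark_prevalence
    } else {
      rep(1.78 / n_categories, n_categories)
    }
  }
  stopifnot(length(prevalence) == n_categories,
            all(prevalence >= 0), all(prevalence <= 1),
            sum(prevalence) > 0)

  out <- withr::with_seed(seed, {
    lab <- draw_labels(n_compounds, prevalence)
    ids <- sprintf("SYN%05d", seq_len(n_compounds))
    edges <- draw_edges(lab, round(n_compounds * mean_degree / 2), homophily)
    wts <- seq.int(weight_range[1], weight_range[2])
    weight <- wts[sample.int(length(wts), nrow(edges), replace = TRUE)]
    network <- as_interaction_network(tibble(
      compound_a = ids[edges$a], compound_b = ids[edges$b], score = weight
    ))
    labels <- as_label_table(tibble(
      compound_id = rep(ids, times = rowSums(lab)),
      category = .tox_tags[which(t(lab), arr.ind = TRUE)[, 1]]
    ))
    restrict_to_networked(labels, network)
  })
  attr(out, "config") <- list(
    n_compounds = n_compounds, n_categories = n_categories,
    prevalence = prevalence, mean_degree = mean_degree,
    homophily = homophily, weight_range = weight_range, seed = seed
  )
  out
}

# n x 7 logical label matrix; empty rows are redrawn until non-empty.
draw_labels <- function(n, prevalence) {
  L <- length(prevalence)
  draw <- function(k) {
    matrix(rbinom(k * L, 1, rep(prevalence, each = k)), nrow = k) > 0
  }
  lab <- draw(n)
  empty <- which(rowSums(lab) == 0)
  while (length(empty) > 0) {
    lab[empty, ] <- draw(length(empty))
    empty <- empty[rowSums(lab[empty, , drop = FALSE]) == 0]
  }
  if (L < 7) {
    lab <- cbind(lab, matrix(FALSE, nrow = n, ncol = 7 - L))
  }
  lab
}

# Draw m undirected edges over compounds 1..n: homophilous edges by
# rejection sampling of label-sharing pairs, the rest uniform.
draw_edges <- function(lab, m, homophily) {
  n <- nrow(lab)
  if (m == 0) {
    return(tibble(a = integer(), b = integer()))
  }
  n_h <- rbinom(1, m, homophily)
  sharable <- any(colSums(lab) >= 2)
  if (n_h > 0 && !sharable) {
    warn("no label-sharing pairs exist; falling back to uniform edges")
    n_h <- 0
  }
  uniform_pairs <- function(k) {
    a <- sample.int(n, k, replace = TRUE)
    b <- sample.int(n, k, replace = TRUE)
    while (any(a == b)) {
      eq <- a == b
      b[eq] <- sample.int(n, sum(eq), replace = TRUE)
    }
    tibble(a = a, b = b)
  }
  hom <- tibble(a = integer(), b = integer())
  tries <- 0
  while (nrow(hom) < n_h && tries < 200) {
    cand <- uniform_pairs(max(2 * (n_h - nrow(hom)), 200))
    share <- rowSums(lab[cand$a, , drop = FALSE] &
                       lab[cand$b, , drop = FALSE]) > 0
    hom <- bind_rows(hom, cand[share, ])
    tries <- tries + 1
  }
  if (nrow(hom) < n_h) {
    warn("could not draw enough label-sharing pairs; filling uniformly")
    n_h <- nrow(hom)
  }
  bind_rows(hom[seq_len(n_h), ], uniform_pairs(m - n_h))
}

#' Permute label sets across compounds (null model)
#'
#' Reassigns whole label sets to compounds by a random permutation of the
#' roster, leaving the network untouched. The label multiset — and hence
#' the mean label count — is preserved, but any association between
#' network structure and labels is destroyed, which makes this the null
#' model against which the guilt-by-association signal is measured.
#'
#' @param dataset A `tox_benchmark`.
#' @param seed Integer seed.
#' @return A new `tox_benchmark` with permuted labels.
#' @export
shuffle_labels <- function(dataset, seed = 1) {
  roster <- dataset$roster
  perm <- withr::with_seed(seed, sample(roster))
  map <- setNames(perm, roster)
  labels <- dataset$labels
  labels$compound_id <- unname(map[labels$compound_id])
  restrict_to_networked(as_label_table(labels), dataset$network)
}
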