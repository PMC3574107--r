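#' Build an interaction network from an edge table
#'
#' Canonicalizes a weighted chemical-chemical edge list into the undirected
#' network representation used by the scorer: endpoints sorted within each
#' row, self-interactions dropped with a warning, duplicate (or reversed)
#' records for the same pair merged by keeping the maximum confidence score,
#' and all stored scores strictly positive. A pair absent from the network
#' has, by convention, confidence score 0.
#'
#' @param edges A data frame with two compound-identifier columns and one
#'   numeric score column (by default `compound_a`, `compound_b`, `score`;
#'   the first three columns are used if those names are absent).
#'
#' @return A tibble of class `tox_network` with columns `compound_a`,
#'   `compound_b`, `score`, one row per undirected pair.
#' @seealso [read_stitch_interactions()], [interaction_score()]
#' @export
as_interaction_network <- function(edges) {
  edges <- as_tibble(edges)
  if (!all(c("compound_a", "compound_b", "score") %in% names(edges))) {
    if (ncol(edges) < 3) {
      abort("`edges` needs two compound columns and a score column")
    }
    edges <- setNames(edges[1:3], c("compound_a", "compound_b", "score"))
  }
  edges <- mutate(edges,
    compound_a = as.character(.data$compound_a),
    compound_b = as.character(.data$compound_b)
  )
  if (!is.numeric(edges$score)) {
    abort("interaction scores must be numeric")
  }
  if (any(!is.finite(edges$score)) || any(edges$score <= 0)) {
    abort("all stored interaction scores must be finite and > 0")
  }
  out <- canonicalize_edges(edges)
  class(out) <- c("tox_network", class(out))
  out
}

#' Look up confidence scores for compound pairs
#'
#' Vectorized lookup of the confidence score `Q(a, b)`. Pairs without a
#' recorded interaction return 0, and the lookup is symmetric:
#' `Q(a, b) == Q(b, a)`.
#'
#' @param network A `tox_network` (see [as_interaction_network()]).
#' @param a,b Character vectors of compound identifiers (recycled).
#'
#' @return A numeric vector of confidence scores.
#' @export
interaction_score <- function(network, a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  net_key <- paste(network$compound_a, network$compound_b, sep = "\r")
  out <- network$score[match(key, net_key)]
  out[is.na(out)] <- 0
  out
}

#' Read a STITCH-dialect chemical-chemical interaction file
#'
#' Reads the tab-separated `chemical_chemical.links.detailed` format
#' (columns `chemical1`, `chemical2`, `similarity`, `experimental`,
#' `database`, `textmining`, `combined_score`). Pairs whose chosen score
#' channel is strictly greater than `threshold` are deemed interactive and
#' retained; everything else is treated as non-interacting (score 0).
#'
#' @param path Path to the TSV file (a header row is required).
#' @param score_field Name of the score column to use as the confidence
#'   score (default `"combined_score"`, the integrated evidence channel).
#' @param threshold Minimum score, strict comparison (`score > threshold`);
#'   default 0, i.e. any recorded interaction counts.
#' @param normalize_ids If `TRUE`, collapse STITCH stereo/merged prefixes
#'   (`CIDm...`/`CIDs...`) to plain `CID...` codes so both code spaces
#'   coincide. Off by default.
#'
#' @return A `tox_network` tibble (see [as_interaction_network()]).
#' @export
read_stitch_interactions <- function(path, score_field = "combined_score",
                                     threshold = 0, normalize_ids = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("interaction file not found: %s", path))
  }
  stopifnot(is.numeric(threshold), threshold >= 0)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (col in c("chemical1", "chemical2", score_field)) {
    if (!col %in% names(raw)) {
      abort(sprintf("column '%s' not found in %s", col, path))
    }
  }
  score <- suppressWarnings(as.numeric(raw[[score_field]]))
  bad <- which(is.na(score) & !is.na(raw[[score_field]]))
  if (length(bad) > 0) {
    abort(sprintf(
      "non-numeric %s value at line %d of %s: '%s'",
      score_field, bad[1] + 1L, path, raw[[score_field]][bad[1]]
    ))
  }
  ids1 <- raw$chemical1
  ids2 <- raw$chemical2
  if (normalize_ids) {
    ids1 <- sub("^CID[ms]", "CID", ids1)
    ids2 <- sub("^CID[ms]", "CID", ids2)
  }
  keep <- !is.na(score) & score > threshold
  inform(sprintf(
    "Read %d interaction record(s) from %s; %d above %s threshold %s",
    nrow(raw), path, sum(keep), score_field, format(threshold)
  ))
  edges <- tibble(compound_a = ids1[keep], compound_b = ids2[keep],
                  score = score[keep])
  as_interaction_network(edges)
}

#' Write an interaction network in the STITCH detailed-links dialect
#'
#' The confidence score is written to `combined_score`; the four individual
#' evidence channels are written as 0 (they are not modelled here).
#'
#' @param network A `tox_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_stitch_interactions <- function(network, path) {
  out <- tibble(
    chemical1 = network$compound_a,
    chemical2 = network$compound_b,
    similarity = 0L, experimental = 0L, database = 0L, textmining = 0L,
    combined_score = network$score
  )
  readr::write_tsv(out, path, progress = FALSE)
  inform(sprintf("Wrote %d interaction record(s) to %s", nrow(out), path))
  invisible(path)
}

#' Build a label table from compound/category pairs
#'
#' The label table is the long-format compound-to-category membership map:
#' one row per (compound, category) pair, every compound carrying at least
#' one of the seven categories.
#'
#' @param x A data frame with columns `compound_id` and `category` (tags
#'   `T1`..`T7`), or a named list of character tag vectors.
#'
#' @return A tibble of class `tox_labels` with columns `compound_id`
#'   (character) and `category` (factor with levels `T1`..`T7`).
#' @export
as_label_table <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- tibble(
      compound_id = rep(names(x), lengths(x)),
      category = unlist(x, use.names = FALSE)
    )
  }
  x <- as_tibble(x)
  stopifnot(all(c("compound_id", "category") %in% names(x)))
  out <- tibble(
    compound_id = as.character(x$compound_id),
    category = as_category(x$category)
  ) |>
    distinct() |>
    arrange(.data$compound_id, .data$category)
  if (any(is.na(out$compound_id)) || any(out$compound_id == "") ||
      grepl("\\s", paste(out$compound_id, collapse = ""))) {
    abort("compound identifiers must be non-empty tokens without whitespace")
  }
  class(out) <- c("tox_labels", class(out))
  out
}

#' Read a compound-to-toxicity-category label table
#'
#' Accepts either of two TSV layouts: a wide table with a `compound_id`
#' column plus one 0/1 column per category tag (`T1`..`T7`), or a two-column
#' table `compound_id` / `categories` where the second column is a
#' `;`-delimited (or `,`-delimited) list of tags. A compound with an empty
#' category set, or appearing twice with conflicting sets, is an error.
#'
#' @param path Path to the TSV file.
#' @return A `tox_labels` tibble (see [as_label_table()]).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("label file not found: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"compound_id" %in% names(raw)) {
    abort(sprintf("column 'compound_id' not found in %s", path))
  }
  tag_cols <- intersect(.tox_tags, names(raw))
  if (length(tag_cols) > 0) {
    long <- tidyr::pivot_longer(raw, cols = dplyr::all_of(tag_cols),
                                names_to = "category", values_to = "member")
    long <- filter(long, !is.na(.data$member) & .data$member != "0")
    long <- select(long, "compound_id", "category")
  } else if ("categories" %in% names(raw)) {
    long <- raw |>
      mutate(category = strsplit(.data$categories, "[;,]\\s*")) |>
      tidyr::unnest_longer("category") |>
      select("compound_id", "category")
  } else {
    abort(sprintf(
      "%s must have either per-category columns (%s) or a 'categories' column",
      path, paste(.tox_tags, collapse = "/")
    ))
  }
  empty <- setdiff(unique(raw$compound_id), unique(long$compound_id))
  if (length(empty) > 0) {
    abort(sprintf(
      "compound(s) with empty category set: %s",
      paste(head(empty, 5), collapse = ", ")
    ))
  }
  # Conflicting duplicate records: same ID listed twice with different sets.
  dup <- raw$compound_id[duplicated(raw$compound_id)]
  if (length(dup) > 0) {
    conflicted <- unique(dup[vapply(dup, function(id) {
      rows <- which(raw$compound_id == id)
      if (length(tag_cols) > 0) {
        n_distinct_rows <- nrow(distinct(raw[rows, c("compound_id", tag_cols)]))
      } else {
        n_distinct_rows <- length(unique(raw$categories[rows]))
      }
      n_distinct_rows > 1
    }, logical(1))])
    if (length(conflicted) > 0) {
      abort(sprintf(
        "conflicting duplicate label records for: %s",
        paste(conflicted, collapse = ", ")
      ))
    }
  }
  inform(sprintf("Read labels for %d compound(s) from %s",
                 length(unique(long$compound_id)), path))
  as_label_table(long)
}

#' Write a label table
#'
#' Writes the two-column `compound_id` / `categories` layout with
#' `;`-delimited tags; [read_labels()] round-trips it.
#'
#' @param labels A `tox_labels` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- labels |>
    group_by(.data$compound_id) |>
    summarise(
      categories = paste(sort(as.character(.data$category)), collapse = ";"),
      .groups = "drop"
    ) |>
    arrange(.data$compound_id)
  readr::write_tsv(out, path, progress = FALSE)
  inform(sprintf("Wrote labels for %d compound(s) to %s", nrow(out), path))
  invisible(path)
}

#' Assemble a benchmark dataset of networked, labelled compounds
#'
#' Compounds without any recorded chemical-chemical interaction cannot be
#' scored by neighbour voting, so the benchmark roster is restricted to
#' labelled compounds that are an endpoint of at least one network edge.
#'
#' @param labels A `tox_labels` table.
#' @param network A `tox_network`.
#'
#' @return A list of class `tox_benchmark` with elements `labels` (restricted
#'   to the roster), `network`, `roster` (character vector of compound IDs)
#'   and `n_excluded` (labelled compounds dropped for lack of interactions).
#' @export
restrict_to_networked <- function(labels, network) {
  labelled <- unique(labels$compound_id)
  endpoints <- unique(c(network$compound_a, network$compound_b))
  roster <- sort(intersect(labelled, endpoints))
  if (length(roster) == 0) {
    abort("no networked compounds: no labelled compound has any interaction")
  }
  n_excluded <- length(labelled) - length(roster)
  kept <- labels[labels$compound_id %in% roster, ]
  class(kept) <- class(labels)
  structure(
    list(labels = kept, network = network, roster = roster,
         n_excluded = n_excluded),
    class = "tox_benchmark"
  )
}

#' @export
print.tox_benchmark <- function(x, ...) {
  cat(sprintf(
    "<tox_benchmark> %d compounds, %d interactions (%d labelled compound(s) excluded for lacking interactions)\n",
    length(x$roster), nrow(x$network), x$n_excluded
  ))
  counts <- table(x$labels$category)
  cat("category counts:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  invisible(x)
}

#' Write ordered predictions
#'
#' One row per predicted category: `compound_id`, `rank` (1 = most likely),
#' `category`, `score`. Compounds with empty predictions contribute no rows
#' but are preserved in the `compounds` attribute on reading back only if
#' present in the table; row order is deterministic (by compound, then rank).
#'
#' @param predictions A predictions tibble as returned by [predict_batch()]
#'   or [jackknife()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions |>
    mutate(category = as.character(.data$category)) |>
    arrange(.data$compound_id, .data$rank)
  readr::write_tsv(out, path, progress = FALSE)
  inform(sprintf("Wrote %d prediction row(s) for %d compound(s) to %s",
                 nrow(out), length(unique(out$compound_id)), path))
  invisible(path)
}

#' Read ordered predictions written by [write_predictions()]
#'
#' @param path TSV path.
#' @return A predictions tibble (`compound_id`, `rank`, `category`, `score`).
#' @export
read_predictions <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cicd", progress = FALSE)
  out <- mutate(raw, category = as_category(.data$category))
  new_predictions(out, unique(out$compound_id))
}
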