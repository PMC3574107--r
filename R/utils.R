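# Round half away from zero to `digits` decimals, matching the usual
# table-formatting convention (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonicalize an edge list: order endpoints lexicographically within each
# row, drop self-edges (with a warning), and merge duplicate pairs keeping
# the maximum score.
canonicalize_edges <- function(edges, warn_self = TRUE) {
  stopifnot(all(c("compound_a", "compound_b", "score") %in% names(edges)))
  self <- edges$compound_a == edges$compound_b
  if (any(self)) {
    if (warn_self) {
      warn(sprintf("Dropping %d self-interaction(s)", sum(self)))
    }
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    return(tibble(compound_a = character(), compound_b = character(),
                  score = numeric()))
  }
  a <- pmin(edges$compound_a, edges$compound_b)
  b <- pmax(edges$compound_a, edges$compound_b)
  tibble(compound_a = a, compound_b = b, score = edges$score) |>
    group_by(.data$compound_a, .data$compound_b) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$compound_a, .data$compound_b)
}

# Stack an undirected edge list into both directions for per-endpoint joins.
both_directions <- function(network) {
  bind_rows(
    tibble(
      compound_id = network$compound_a,
      neighbor = network$compound_b,
      score = network$score
    ),
    tibble(
      compound_id = network$compound_b,
      neighbor = network$compound_a,
      score = network$score
    )
  )
}
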