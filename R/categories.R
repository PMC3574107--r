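# The fixed seven-category toxicity system. The non-toxic class is treated
# as an ordinary seventh category so that "safe" is a predictable label.
.tox_tags <- paste0("T", 1:7)
.tox_names <- c(
  "Acute Toxicity",
  "Mutagenicity",
  "Tumorigenicity",
  "Skin and Eye Irritation",
  "Reproductive Effects",
  "Multiple Dose Effects",
  "Non-toxicity"
)

#' The seven toxicity categories
#'
#' The category system used throughout the package: six toxicity endpoints
#' plus non-toxicity as a seventh class. The tag order T1 < T2 < ... < T7 is
#' fixed and is used for deterministic tie-breaking in ordered predictions.
#'
#' @param include_nontoxic Keep the non-toxicity class T7 (default `TRUE`).
#'
#' @return A tibble with columns `tag` (ordered factor, levels `T1`..`T7`)
#'   and `name`.
#' @examples
#' toxicity_categories()
#' @export
toxicity_categories <- function(include_nontoxic = TRUE) {
  out <- tibble(
    tag = factor(.tox_tags, levels = .tox_tags),
    name = .tox_names
  )
  if (!include_nontoxic) {
    out <- out[out$tag != "T7", ]
  }
  out
}

# Coerce a vector of tags to the canonical category factor, erroring on
# anything outside T1..T7.
as_category <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), .tox_tags)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown toxicity category tag(s): %s (expected %s)",
      paste(bad, collapse = ", "), paste(range(.tox_tags), collapse = "..")
    ))
  }
  factor(x, levels = .tox_tags)
}
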