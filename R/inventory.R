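#' Phoneme inventories with manner-of-articulation categories
#'
#' A phoneme inventory is a tibble with one row per phoneme carrying its
#' manner of articulation (vowel, nasal, plosive or fricative) and its
#' utterance count across the stimulus set. The bundled inventories hold
#' the per-phoneme utterance counts of the Korean and English sentence
#' sets used throughout the package examples; [phoneme_inventory()] builds
#' a validated inventory from scratch.
#'
#' @param phoneme Character vector of unique phoneme labels.
#' @param manner Character vector, one of `"vowel"`, `"nasal"`,
#'   `"plosive"`, `"fricative"` per phoneme.
#' @param count Positive integer utterance count per phoneme.
#'
#' @return A tibble of class `phoneme_inventory` with columns `phoneme`,
#'   `manner`, `count`.
#' @examples
#' inv <- phoneme_inventory(c("A", "B", "S"),
#'                          c("vowel", "plosive", "fricative"),
#'                          c(10, 5, 5))
#' inventory_totals(inv)
#' @export
phoneme_inventory <- function(phoneme, manner, count) {
  phoneme <- as.character(phoneme)
  manner <- as.character(manner)
  count <- as.numeric(count)
  if (length(phoneme) == 0) abort("inventory must contain at least one phoneme")
  if (anyDuplicated(phoneme)) {
    abort(sprintf("duplicated phoneme labels: %s",
                  paste(unique(phoneme[duplicated(phoneme)]), collapse = ", ")))
  }
  ok <- manner %in% manner_levels()
  if (!all(ok)) {
    abort(sprintf("unknown manner category: %s",
                  paste(unique(manner[!ok]), collapse = ", ")))
  }
  if (any(!is.finite(count) | count <= 0 | count != round(count))) {
    abort("counts must be positive integers")
  }
  out <- tibble(phoneme = phoneme, manner = manner, count = as.integer(count))
  class(out) <- c("phoneme_inventory", class(out))
  out
}

manner_levels <- function() c("vowel", "nasal", "plosive", "fricative")

#' @rdname phoneme_inventory
#' @param language `"korean"` or `"english"`: which bundled sentence-set
#'   inventory to load.
#' @param path Optional path to a tab-separated file with columns
#'   `language`, `phoneme`, `manner`, `count` (defaults to the bundled one).
#' @export
default_inventory <- function(language = c("english", "korean"), path = NULL) {
  language <- match.arg(language)
  path <- path %||% system.file("extdata", "phoneme_counts.tsv",
                                package = "speechtrack", mustWork = TRUE)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("language", "phoneme", "manner", "count")
  if (!all(need %in% names(raw))) {
    abort(sprintf("inventory file %s lacks columns: %s", path,
                  paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  raw <- raw[raw$language == language, , drop = FALSE]
  phoneme_inventory(raw$phoneme, raw$manner, raw$count)
}

#' Utterance-count totals per manner category
#'
#' Sums the per-phoneme utterance counts of an inventory by manner of
#' articulation and overall, the bookkeeping used to check a stimulus set
#' against its published per-category totals.
#'
#' @param inventory A [phoneme_inventory()].
#' @return A tibble with one row per manner category plus a `total` row,
#'   columns `manner`, `n_phonemes`, `count`.
#' @export
inventory_totals <- function(inventory) {
  stopifnot(inherits(inventory, "phoneme_inventory"))
  per <- inventory |>
    group_by(manner = factor(.data$manner, levels = manner_levels())) |>
    summarise(n_phonemes = dplyr::n(), count = sum(.data$count), .groups = "drop") |>
    mutate(manner = as.character(.data$manner))
  bind_rows(per, tibble(manner = "total",
                        n_phonemes = nrow(inventory),
                        count = sum(inventory$count)))
}
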