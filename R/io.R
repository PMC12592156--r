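# Readers and writers for the plain-text interchange formats: Praat
# TextGrid annotations, pronunciation lexica, word-vector tables, and a
# simple on-disk container for trial sets.

#' Write and read Praat TextGrid annotations
#'
#' `write_textgrid()` serializes a phoneme annotation (one row per phoneme
#' with its onset, word index and word label) as a long-format TextGrid
#' with a `phones` and a `words` interval tier. `read_textgrid()` parses
#' such a file back into per-tier interval tables, rejecting overlapping
#' or ill-ordered intervals.
#'
#' @param annotation Tibble with columns `phoneme`, `onset_s`,
#'   `word_index`, `word` (as produced by [gen_sentence()]).
#' @param path File path.
#' @param duration_s Total annotated duration in seconds.
#' @return `write_textgrid()` returns `path` invisibly; `read_textgrid()`
#'   returns a named list of tibbles (`xmin`, `xmax`, `text`), one per tier.
#' @export
write_textgrid <- function(annotation, path, duration_s) {
  stopifnot(all(c("phoneme", "onset_s", "word_index", "word") %in% names(annotation)))
  ann <- arrange(annotation, .data$onset_s)
  phone_int <- tibble(
    xmin = ann$onset_s,
    xmax = c(ann$onset_s[-1], duration_s),
    text = ann$phoneme
  )
  words <- ann |>
    group_by(.data$word_index) |>
    summarise(xmin = min(.data$onset_s), text = .data$word[1], .groups = "drop") |>
    arrange(.data$xmin)
  word_int <- tibble(xmin = words$xmin,
                     xmax = c(words$xmin[-1], duration_s),
                     text = words$text)
  tiers <- list(phones = phone_int, words = word_int)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("File type = \"ooTextFile\"")
  w("Object class = \"TextGrid\"")
  w("")
  w("xmin = 0")
  w("xmax = %.10g", duration_s)
  w("tiers? <exists>")
  w("size = %d", length(tiers))
  w("item []:")
  for (k in seq_along(tiers)) {
    tier <- tiers[[k]]
    w("    item [%d]:", k)
    w("        class = \"IntervalTier\"")
    w("        name = \"%s\"", names(tiers)[k])
    w("        xmin = 0")
    w("        xmax = %.10g", duration_s)
    w("        intervals: size = %d", nrow(tier))
    for (i in seq_len(nrow(tier))) {
      w("        intervals [%d]:", i)
      w("            xmin = %.10g", tier$xmin[i])
      w("            xmax = %.10g", tier$xmax[i])
      w("            text = \"%s\"", tier$text[i])
    }
  }
  invisible(path)
}

#' @rdname write_textgrid
#' @export
read_textgrid <- function(path) {
  if (!file.exists(path)) abort(sprintf("TextGrid not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  get_val <- function(line) sub("^[^=]*=\\s*", "", line)
  tier_starts <- grep("^\\s*item \\[[0-9]+\\]:", lines)
  if (!length(tier_starts)) abort(sprintf("%s: no tiers found", path))
  tiers <- list()
  bounds <- c(tier_starts, length(lines) + 1L)
  for (k in seq_along(tier_starts)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    name_line <- grep("^\\s*name =", block, value = TRUE)[1]
    if (is.na(name_line)) abort(sprintf("%s: tier %d has no name", path, k))
    tier_name <- gsub("\"", "", get_val(name_line))
    idx <- grep("^\\s*intervals \\[[0-9]+\\]:", block)
    xmin <- xmax <- numeric(0)
    text <- character(0)
    for (i in idx) {
      xmin <- c(xmin, as.numeric(get_val(block[i + 1L])))
      xmax <- c(xmax, as.numeric(get_val(block[i + 2L])))
      text <- c(text, gsub("\"", "", get_val(block[i + 3L])))
    }
    if (any(is.na(xmin)) || any(is.na(xmax))) {
      abort(sprintf("%s: malformed interval in tier '%s'", path, tier_name))
    }
    if (any(xmax <= xmin)) {
      abort(sprintf("%s: empty or inverted interval in tier '%s'", path, tier_name))
    }
    if (length(xmin) > 1 && any(xmin[-1] < xmax[-length(xmax)] - 1e-9)) {
      abort(sprintf("%s: overlapping intervals in tier '%s'", path, tier_name))
    }
    tiers[[tier_name]] <- tibble(xmin = xmin, xmax = xmax, text = text)
  }
  tiers
}

#' Read and write frequency-weighted pronunciation lexica
#'
#' A lexicon is a tibble mapping each word form to a phoneme-sequence
#' pronunciation and a corpus frequency count, the ingredients of
#' phonemic surprisal. The file format is tab-separated with columns
#' `word`, `pronunciation` (space-separated phoneme labels), `frequency`.
#'
#' @param path File path.
#' @param inventory Optional [phoneme_inventory()]; when given, every
#'   pronunciation symbol must belong to it.
#' @return A validated lexicon tibble.
#' @export
read_lexicon <- function(path, inventory = NULL) {
  if (!file.exists(path)) abort(sprintf("lexicon not found: %s", path))
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("word", "pronunciation", "frequency")
  if (!all(need %in% names(raw))) {
    abort(sprintf("%s: lexicon needs columns %s", path, paste(need, collapse = ", ")))
  }
  as_lexicon(as_tibble(raw), inventory = inventory, source = path)
}

#' @rdname read_lexicon
#' @param lexicon A tibble with columns `word`, `pronunciation`, `frequency`.
#' @param source Label used in error messages.
#' @export
as_lexicon <- function(lexicon, inventory = NULL, source = "lexicon") {
  lexicon <- as_tibble(lexicon)
  bad <- which(!is.finite(lexicon$frequency) | lexicon$frequency < 1 |
                 lexicon$frequency != round(lexicon$frequency))
  if (length(bad)) {
    abort(sprintf("%s: row %d ('%s') has invalid frequency %s (must be a positive integer)",
                  source, bad[1], lexicon$word[bad[1]], lexicon$frequency[bad[1]]))
  }
  if (anyDuplicated(lexicon$word)) {
    abort(sprintf("%s: duplicated word '%s'", source,
                  lexicon$word[duplicated(lexicon$word)][1]))
  }
  if (!is.null(inventory)) {
    symbols <- unique(unlist(strsplit(lexicon$pronunciation, " ", fixed = TRUE)))
    unknown <- setdiff(symbols, inventory$phoneme)
    if (length(unknown)) {
      abort(sprintf("%s: pronunciation symbols outside the inventory: %s",
                    source, paste(unknown, collapse = ", ")))
    }
  }
  lexicon$frequency <- as.integer(lexicon$frequency)
  lexicon
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write word-vector tables
#'
#' Word embeddings in the usual whitespace-delimited text layout: one
#' word per line followed by its vector entries. All vectors must share
#' one dimensionality and have nonzero variance across entries (so that
#' Pearson correlation between vectors is defined).
#'
#' @param path File path.
#' @return A numeric matrix with one row per word, words as rownames.
#' @export
read_vectors <- function(path) {
  if (!file.exists(path)) abort(sprintf("vector file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    abort(sprintf("%s: inconsistent vector dimensions (line %d)",
                  path, which(dims != dims[1])[1]))
  }
  words <- vapply(parts, `[[`, character(1), 1)
  vals <- vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[1]))
  m <- t(matrix(vals, nrow = dims[1]))
  rownames(m) <- words
  validate_vectors(m, source = path)
}

validate_vectors <- function(m, source = "vectors") {
  if (any(!is.finite(m))) abort(sprintf("%s: non-finite vector entries", source))
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    abort(sprintf("%s: word '%s' has a constant vector (correlation undefined)",
                  source, rownames(m)[which(v == 0)[1]]))
  }
  m
}

#' @rdname read_vectors
#' @param vectors Numeric matrix with words as rownames.
#' @export
write_vectors <- function(vectors, path) {
  lines <- vapply(seq_len(nrow(vectors)), function(i) {
    paste(c(rownames(vectors)[i], format(vectors[i, ], digits = 17)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Trial-set container round trip
#'
#' Serializes a [trial_set()] (or a named list of them) to an on-disk
#' container: one binary array store plus a JSON sidecar carrying the
#' sampling rate, window, channel labels, units, and the rejection log.
#' The round trip is bit-exact for the data arrays.
#'
#' @param x A `trial_set` or named list of `trial_set`s.
#' @param path Base path; `<path>.rds` and `<path>.json` are written.
#' @return `write_trialset()` returns `path` invisibly; `read_trialset()`
#'   the restored object.
#' @export
write_trialset <- function(x, path) {
  meta_of <- function(ts) list(
    sentence = ts$sentence, fs = ts$fs, pre_s = ts$pre_s, units = ts$units,
    dim = dim(ts$data), channels = ts$channels, log = ts$log
  )
  meta <- if (inherits(x, "trial_set")) meta_of(x) else lapply(x, meta_of)
  saveRDS(x, paste0(path, ".rds"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  rds <- paste0(path, ".rds")
  if (!file.exists(rds)) abort(sprintf("container not found: %s", rds))
  readRDS(rds)
}
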