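#' Read a source term bank
#'
#' The term bank is a delimited text file with a header naming at least a
#' `term` column; an optional `term_id` column supplies identifiers,
#' otherwise the 1-based row ordinal is used. Term text is trimmed of
#' surrounding whitespace; accents and case are preserved on disk and only
#' normalized in memory. Duplicate term texts are kept as distinct rows.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default comma.
#' @return A tibble with columns `term_id` (character) and `term`, one row
#'   per source term in file order.
#' @export
read_term_bank <- function(path, delim = ",") {
  df <- read_delim_strict(path, delim)
  if (!"term" %in% names(df)) {
    abort(sprintf("term bank '%s' has no 'term' column", path))
  }
  out <- tibble(
    term_id = if ("term_id" %in% names(df)) as.character(df$term_id)
              else as.character(seq_len(nrow(df))),
    term = stringr::str_trim(df$term)
  )
  if (any(!nzchar(out$term))) abort("term bank contains empty terms")
  if (anyDuplicated(out$term_id)) abort("duplicate term_id in term bank")
  out
}

#' Read a target terminology
#'
#' The terminology is a delimited file with header columns `code`, `term`,
#' `axis`, `version` and optional `definition` and `synonyms` (the latter
#' pipe-separated). Codes must be unique; the axis must be one of the seven
#' closed-set labels (see [terminology_axes()]).
#'
#' @inheritParams read_term_bank
#' @param name Optional terminology name stored as an attribute.
#' @return A tibble of class `terminology` with columns `code`, `term`,
#'   `axis`, `version`, `definition`, `synonyms` (list-column).
#' @export
read_terminology <- function(path, delim = ",", name = basename(path)) {
  df <- read_delim_strict(path, delim)
  required <- c("code", "term", "axis", "version")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("terminology '%s' lacks column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  as_terminology(df, name = name)
}

#' Build a terminology from a data frame
#'
#' Validates codes and axes and attaches the `terminology` class. Used by
#' [read_terminology()] and by the synthetic-fixture generator.
#'
#' @param df Data frame with columns `code`, `term`, `axis`, `version` and
#'   optionally `definition` and `synonyms` (list or pipe-separated string).
#' @param name Terminology name attribute.
#' @return A `terminology` tibble.
#' @export
as_terminology <- function(df, name = "terminology") {
  code <- as.character(df$code)
  if (anyDuplicated(code)) {
    abort(sprintf("duplicate concept code(s): %s",
                  paste(unique(code[duplicated(code)]), collapse = ", ")))
  }
  bad <- setdiff(unique(df$axis), terminology_axes())
  if (length(bad)) {
    abort(sprintf("unknown axis label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(!nzchar(stringr::str_trim(df$term)))) abort("empty concept label")
  syn <- if (!"synonyms" %in% names(df)) {
    rep(list(character(0)), nrow(df))
  } else if (is.list(df$synonyms)) {
    df$synonyms
  } else {
    lapply(strsplit(ifelse(is.na(df$synonyms), "", df$synonyms), "|",
                    fixed = TRUE),
           function(x) x[nzchar(x)])
  }
  out <- tibble(
    code = code,
    term = stringr::str_trim(df$term),
    axis = as.character(df$axis),
    version = as.character(df$version),
    definition = if (!"definition" %in% names(df)) NA_character_
                 else as.character(df$definition),
    synonyms = syn
  )
  structure(out, class = c("terminology", class(tibble())), name = name)
}

#' Look up a concept by code
#'
#' @param terminology A `terminology` tibble.
#' @param code Character vector of concept codes; unknown codes are an error.
#' @return The matching rows, in `code` order.
#' @export
lookup_code <- function(terminology, code) {
  idx <- match(as.character(code), terminology$code)
  if (anyNA(idx)) {
    abort(sprintf("unknown concept code(s): %s",
                  paste(code[is.na(idx)], collapse = ", ")))
  }
  terminology[idx, ]
}

#' Write a terminology to CSV
#'
#' Inverse of [read_terminology()]; the `synonyms` list-column is
#' pipe-joined.
#'
#' @param terminology A `terminology` tibble.
#' @param path Output path.
#' @export
write_terminology <- function(terminology, path) {
  out <- as_tibble(terminology)
  out$synonyms <- vapply(out$synonyms, paste, character(1), collapse = "|")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a synonym lexicon
#'
#' The lexicon stands in for the online synonym dictionary of the synonym
#' rule: a JSON object mapping a headword to an array of synonyms. Headwords
#' and synonyms are passed through normalization (without stopword removal)
#' before storage, so lookups happen in normalized space. The mapping is
#' directional as loaded; no symmetric closure is taken.
#'
#' @param path Path to a JSON file.
#' @return A named list of character vectors (possibly empty).
#' @export
read_lexicon <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(sprintf(
                    "malformed lexicon '%s': %s", path, conditionMessage(e))))
  as_lexicon(obj)
}

#' @rdname read_lexicon
#' @param entries Named list (headword -> character vector of synonyms).
#' @export
as_lexicon <- function(entries) {
  if (length(entries) == 0) return(structure(list(), names = character(0)))
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    abort("lexicon must be a named headword -> synonyms mapping")
  }
  vals <- lapply(entries, function(v) {
    if (!is.character(v) && !is.null(v)) v <- as.character(v)
    unique(norm_join(v, character(0)))
  })
  keys <- norm_join(names(entries), character(0))
  # merge entries whose headwords normalize to the same key
  out <- tapply(vals, keys, function(vs) unique(unlist(vs)), simplify = FALSE)
  out <- lapply(out, as.character)
  out[order(names(out))]
}

#' Write a synonym lexicon as JSON
#'
#' @param lexicon Named list of character vectors.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  jsonlite::write_json(lapply(lexicon, as.list), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stopword list
#'
#' One token per line; tokens are normalized and empty lines dropped.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of stopword tokens.
#' @export
read_stopwords <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- norm_join(stringr::str_trim(x), character(0))
  unique(x[nzchar(x)])
}

mapping_table_cols <- c("source_term", "rule", "similarity", "icnp_code",
                        "icnp_term", "icnp_mod", "icnp_axis", "icnp_version")

#' Write and read the mapping output table
#'
#' The 8-column output schema of the automated mapping: the source term, the
#' rule that mapped it, the percent similarity, the target concept code,
#' label and axis, the modified form actually compared by the rule, and the
#' terminology version tag. Column order is fixed; a write followed by a
#' read reproduces the records field by field.
#'
#' @param records A tibble of mapping records (columns as above).
#' @param path File path.
#' @return `read_mapping_table()` returns the records tibble.
#' @export
write_mapping_table <- function(records, path) {
  records <- as_tibble(records)[, mapping_table_cols]
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_mapping_table
#' @export
read_mapping_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    source_term = "c", rule = "i", similarity = "i", icnp_code = "c",
    icnp_term = "c", icnp_mod = "c", icnp_axis = "c", icnp_version = "c"
  ), progress = FALSE)
  if (!identical(names(df), mapping_table_cols)) {
    abort(sprintf("'%s' is not an 8-column mapping table", path))
  }
  df
}

manual_categories <- c("identical", "similar", "in_definition", "new")

#' Read manual mapping labels
#'
#' Manual (human) mapping verdicts: CSV `term_id,category` where category is
#' one of `identical`, `similar`, `in_definition`, `new`. Anything outside
#' this closed set is rejected rather than coerced.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `term_id`, `category`.
#' @export
read_manual_labels <- function(path) {
  df <- read_delim_strict(path, ",")
  if (!all(c("term_id", "category") %in% names(df))) {
    abort("manual labels need columns 'term_id' and 'category'")
  }
  bad <- setdiff(unique(df$category), manual_categories)
  if (length(bad)) {
    abort(sprintf("unknown manual category: %s", paste(bad, collapse = ", ")))
  }
  tibble(term_id = as.character(df$term_id), category = df$category)
}

equivalence_degrees <- c("1", "2", "3", "4", "not_attributed")

#' Read expert equivalence judgments
#'
#' Equivalence degrees are imported human judgments on the ISO/TR 12300
#' 4-value scale (1 lexical+conceptual equivalence, 2 synonymy, 3 source
#' broader, 4 source narrower) plus `not_attributed` for relationships whose
#' degree could not be assigned. They are validated and aggregated, never
#' computed.
#'
#' @param path CSV with columns `source_term`, `target_code`, `degree`.
#' @return Tibble with those columns, `degree` as character.
#' @export
read_judgments <- function(path) {
  df <- read_delim_strict(path, ",")
  if (!all(c("source_term", "target_code", "degree") %in% names(df))) {
    abort("judgments need columns 'source_term', 'target_code', 'degree'")
  }
  degree <- as.character(df$degree)
  bad <- setdiff(unique(degree), equivalence_degrees)
  if (length(bad)) {
    abort(sprintf("unknown equivalence degree: %s",
                  paste(bad, collapse = ", ")))
  }
  tibble(source_term = as.character(df$source_term),
         target_code = as.character(df$target_code),
         degree = degree)
}

read_delim_strict <- function(path, delim) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tryCatch(
    readr::read_delim(path, delim = delim, trim_ws = TRUE,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path,
                                      conditionMessage(e))))
  if (nrow(df) == 0 && ncol(df) == 0) abort(sprintf("empty file: %s", path))
  df
}
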