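#' Portuguese suffix-stripping stemmer
#'
#' A reduced RSLP-style stemmer for normalized (lowercase, unaccented)
#' Portuguese tokens. Steps, applied in order: plural reduction, adverb
#' reduction (`-mente`), a table of common noun/adjective suffixes, verb
#' infinitive endings, and a final-vowel strip. Each suffix is removed only
#' when the remaining stem keeps a minimum length, so short clinical roots
#' ("dor", "pele") survive unchanged. Gender variants meet at a common
#' radical: `"clinico"` and `"clinica"` both stem to `"clin"`, and a plural
#' such as `"dores"` stems to the same radical as `"dor"`.
#'
#' @param tokens Character vector of normalized tokens.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' stem_rslp(c("clinico", "clinica", "medicar", "dores", "dor"))
stem_rslp <- function(tokens) {
  vapply(tokens, stem_one, character(1), USE.NAMES = FALSE)
}

strip_suffix <- function(w, suffix, replacement = "", min_stem = 3L) {
  nw <- nchar(w)
  ns <- nchar(suffix)
  if (nw > ns && endsWith(w, suffix) && (nw - ns) >= min_stem) {
    paste0(substr(w, 1L, nw - ns), replacement)
  } else {
    w
  }
}

stem_one <- function(w) {
  # plural reduction
  for (rule in list(c("oes", "ao"), c("aes", "ao"), c("ais", "al"),
                    c("eis", "el"), c("ns", "m"))) {
    w2 <- strip_suffix(w, rule[1], rule[2], min_stem = 2L)
    if (!identical(w2, w)) { w <- w2; break }
  }
  if (endsWith(w, "s")) w <- strip_suffix(w, "s", min_stem = 3L)
  # adverb reduction
  w <- strip_suffix(w, "mente", min_stem = 4L)
  # noun / adjective suffixes, longest first
  for (suf in c("amento", "imento", "adora", "idade", "mento", "agem",
                "ador", "acao", "ismo", "ista", "ico", "ica", "ivo",
                "iva", "oso", "osa")) {
    w2 <- strip_suffix(w, suf, min_stem = 3L)
    if (!identical(w2, w)) { w <- w2; break }
  }
  # verb infinitive endings
  for (suf in c("ar", "er", "ir")) {
    w2 <- strip_suffix(w, suf, min_stem = 3L)
    if (!identical(w2, w)) { w <- w2; break }
  }
  # final vowel removal
  if (nchar(w) > 3L && grepl("[aeo]$", w)) w <- substr(w, 1L, nchar(w) - 1L)
  w
}

#' Lexicon-backed lemmatizer
#'
#' The lemma ("motto") rule needs a map from inflected forms to their
#' canonical dictionary form. `read_lemma_table()` loads a two-column CSV
#' (`form,lemma`); `make_lemmatizer()` turns such a table into a vectorized
#' token -> lemma function (identity on unknown tokens);
#' `default_lemmatizer()` uses the small Portuguese table bundled with the
#' package. Forms and lemmas are normalized on load so lookup happens in the
#' same space as the matching rules.
#'
#' @param path Path to a CSV file with columns `form` and `lemma`.
#' @param table A data frame with columns `form` and `lemma`.
#' @return `read_lemma_table()` a tibble; the others a `function(tokens)`.
#' @export
read_lemma_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("form", "lemma") %in% names(df))) {
    abort("lemma table must have columns 'form' and 'lemma'")
  }
  tibble(form = norm_join(df$form, character(0)),
         lemma = norm_join(df$lemma, character(0)))
}

#' @rdname read_lemma_table
#' @export
make_lemmatizer <- function(table) {
  map <- setNames(as.character(table$lemma), table$form)
  function(tokens) {
    out <- unname(map[tokens])
    ifelse(is.na(out), tokens, out)
  }
}

#' @rdname read_lemma_table
#' @export
default_lemmatizer <- function() {
  path <- system.file("extdata", "lemma_table_pt.csv", package = "termmapr")
  make_lemmatizer(read_lemma_table(path))
}
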