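#' Strip accents and other combining marks from text
#'
#' Applies Unicode canonical decomposition and removes the combining marks,
#' leaving base letters untouched: `"Evolução"` becomes `"Evolucao"`. ASCII
#' input passes through unchanged.
#'
#' @param text Character vector.
#' @return Character vector of the same length, accents removed.
#' @export
#' @examples
#' strip_accents(c("Evolução", "côco", "abc"))
strip_accents <- function(text) {
  stringi::stri_trans_general(text, "NFD; [:Nonspacing Mark:] Remove; NFC")
}

#' Replace special characters by spaces
#'
#' Everything outside ASCII letters, digits and spaces is replaced by a
#' single space; runs of spaces are then collapsed and the ends trimmed.
#' Hyphens and slashes in clinical phrases (`"pos-operatorio"`,
#' `"woman/man"`) therefore become token separators. Intended to run after
#' [strip_accents()] (as [normalize_terms()] does): accented letters are
#' rescued by the accent strip, while characters with no ASCII decomposition
#' (ligatures, other scripts) count as specials, keeping the normalized
#' alphabet to `[a-z0-9 ]`.
#'
#' @param text Character vector.
#' @return Character vector with only ASCII letters, digits and single
#'   spaces.
#' @export
#' @examples
#' remove_special(c("pos-operatorio", "woman/man"))
remove_special <- function(text) {
  out <- stringi::stri_replace_all_regex(text, "[^A-Za-z0-9 ]", " ")
  stringi::stri_trim_both(stringi::stri_replace_all_regex(out, " +", " "))
}

#' Default Portuguese stopword list
#'
#' A small function-word list (articles, prepositions, conjunction) used when
#' no stopword file is supplied. Portuguese clinical phrases such as
#' "dor de cabeça" drop the connective and normalize to `"dor cabeca"`.
#'
#' @return Character vector of lowercase, unaccented stopword tokens.
#' @export
default_stopwords <- function() {
  c("de", "da", "do", "das", "dos", "e", "a", "o", "em", "para", "com", "por")
}

#' Normalize a term for lexical comparison
#'
#' Phase-1 normalization: accent stripping, special-character removal,
#' lowercasing, whitespace tokenization and stopword removal, in that order.
#' The operation is idempotent: normalizing the joined output again changes
#' nothing. A term made entirely of stopwords or specials normalizes to the
#' empty string; such terms cannot be mapped and are reported as new.
#'
#' @param text Character vector of raw terms.
#' @param stopwords Character vector of stopword tokens, themselves already
#'   lowercase and unaccented. Defaults to [default_stopwords()].
#' @return For `norm_join()`, a character vector of space-joined normalized
#'   tokens. For `normalize_terms()`, a tibble with columns `original`,
#'   `joined` and a `tokens` list-column.
#' @export
#' @examples
#' norm_join("Dor de Cabeça")
#' normalize_terms(c("Clínica", "pós-operatório"))
norm_join <- function(text, stopwords = default_stopwords()) {
  joined <- stringi::stri_trans_tolower(remove_special(strip_accents(text)))
  if (length(stopwords)) {
    toks <- stringi::stri_split_fixed(joined, " ")
    joined <- vapply(toks, function(tk) {
      paste(tk[!(tk %in% stopwords) & nzchar(tk)], collapse = " ")
    }, character(1))
  }
  joined
}

#' @rdname norm_join
#' @export
normalize_terms <- function(text, stopwords = default_stopwords()) {
  joined <- norm_join(text, stopwords)
  tokens <- stringi::stri_split_fixed(joined, " ")
  tokens <- lapply(tokens, function(tk) tk[nzchar(tk)])
  tibble(original = text, joined = joined, tokens = tokens)
}
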