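#' Cascade configuration
#'
#' Settings for the two-phase mapping pipeline. The candidate floor and match
#' threshold define the two similarity bands: a comparison scoring at or
#' above `match_threshold` (default 100) produces a mapping record, while a
#' score in `[candidate_floor, match_threshold - 1]` (default 90–99) adds the
#' concept to the candidate list offered for expert review. The lemmatizer
#' and stemmer used by rules 2 and 3 are pluggable functions over token
#' vectors.
#'
#' @param candidate_floor Lower edge of the candidate band, percent.
#' @param match_threshold Score required for a full match, percent.
#' @param rules Integer vector of enabled rules, subset of `1:6`.
#' @param stopwords Stopword tokens for normalization.
#' @param lemmatizer `function(tokens) -> lemmas` used by rule 2.
#' @param stemmer `function(tokens) -> stems` used by rule 3.
#' @param max_variants Cap on the per-term orthographic variant expansion;
#'   above it only single-token and all-token substitutions are generated.
#' @param seed Reserved; the cascade itself is deterministic.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(candidate_floor = 90L, match_threshold = 100L,
                           rules = 1:6, stopwords = default_stopwords(),
                           lemmatizer = default_lemmatizer(),
                           stemmer = stem_rslp, max_variants = 64L,
                           seed = NULL) {
  candidate_floor <- as.integer(candidate_floor)
  match_threshold <- as.integer(match_threshold)
  if (is.na(candidate_floor) || is.na(match_threshold) ||
      candidate_floor < 0L || candidate_floor > match_threshold ||
      match_threshold > 100L) {
    abort("need 0 <= candidate_floor <= match_threshold <= 100")
  }
  rules <- sort(unique(as.integer(rules)))
  if (length(setdiff(rules, 1:6))) abort("rules must be a subset of 1:6")
  structure(list(candidate_floor = candidate_floor,
                 match_threshold = match_threshold, rules = rules,
                 stopwords = stopwords, lemmatizer = lemmatizer,
                 stemmer = stemmer, max_variants = as.integer(max_variants),
                 seed = seed),
            class = "cascade_config")
}

# all combinations of per-token options, joined by spaces, original excluded
variant_combos <- function(options, joined, cap) {
  sizes <- lengths(options)
  total <- prod(sizes)
  if (total <= 1) return(character(0))
  if (total <= cap) {
    grid <- expand.grid(options, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    variants <- do.call(paste, grid)
  } else {
    k <- length(options)
    singles <- unlist(lapply(seq_len(k), function(i) {
      vapply(options[[i]][-1], function(alt) {
        toks <- vapply(options, `[[`, character(1), 1L)
        toks[i] <- alt
        paste(toks, collapse = " ")
      }, character(1))
    }), use.names = FALSE)
    all_sub <- paste(vapply(options, function(op) {
      if (length(op) > 1L) op[[2L]] else op[[1L]]
    }, character(1)), collapse = " ")
    variants <- c(singles, all_sub)
  }
  setdiff(unique(variants), joined)
}

term_tokens <- function(term) {
  tk <- strsplit(term, " ", fixed = TRUE)[[1]]
  tk[nzchar(tk)]
}

#' Orthographic variants of a normalized term
#'
#' Rules 2–4 modify both the input term and the target labels to cover all
#' orthographic variant possibilities before scoring. `lemma_variants()`
#' substitutes each token's lemma ("motto", the canonical dictionary form),
#' `stem_variants()` each token's stem (suffix-stripped radical), and
#' `synonym_variants()` every lexicon synonym, both per token and for the
#' whole term as a headword. All combinations of substituted and original
#' tokens are produced (capped, see [cascade_config()]); the unmodified term
#' is excluded from the result.
#'
#' @param term A normalized term string (space-joined tokens).
#' @param lemmatizer,stemmer Token-vector functions, see [cascade_config()].
#' @param lexicon Named list, normalized headword -> synonyms
#'   (see [read_lexicon()]).
#' @param max_variants Expansion cap.
#' @return Character vector of distinct variant strings (possibly empty).
#' @export
#' @examples
#' stem_variants("medicar ferida")
#' synonym_variants("pessoa", lexicon = list(pessoa = "individuo"))
lemma_variants <- function(term, lemmatizer = default_lemmatizer(),
                           max_variants = 64L) {
  toks <- term_tokens(term)
  if (!length(toks)) return(character(0))
  options <- lapply(toks, function(tk) unique(c(tk, lemmatizer(tk))))
  variant_combos(options, term, max_variants)
}

#' @rdname lemma_variants
#' @export
stem_variants <- function(term, stemmer = stem_rslp, max_variants = 64L) {
  toks <- term_tokens(term)
  if (!length(toks)) return(character(0))
  options <- lapply(toks, function(tk) unique(c(tk, stemmer(tk))))
  variant_combos(options, term, max_variants)
}

#' @rdname lemma_variants
#' @export
synonym_variants <- function(term, lexicon, max_variants = 64L) {
  toks <- term_tokens(term)
  if (!length(toks)) return(character(0))
  options <- lapply(toks, function(tk) unique(c(tk, lexicon[[tk]])))
  token_vars <- variant_combos(options, term, max_variants)
  whole <- setdiff(unique(unlist(lexicon[names(lexicon) == term])), term)
  unique(c(whole, token_vars))
}

rule_variant_fn <- function(rule, lexicon, config) {
  switch(as.character(rule),
    "2" = function(term) lemma_variants(term, config$lemmatizer,
                                        config$max_variants),
    "3" = function(term) stem_variants(term, config$stemmer,
                                       config$max_variants),
    "4" = function(term) synonym_variants(term, lexicon,
                                          config$max_variants),
    abort("variant rules are 2, 3 and 4"))
}

#' Precompute normalized labels and per-rule variants of a terminology
#'
#' Normalizing and variant-expanding the target side once, rather than per
#' source term, makes bank-scale mapping practical. The result is consumed
#' by [map_term()] and [map_bank()]; recompute it whenever the terminology,
#' lexicon or configuration changes.
#'
#' @param terminology A `terminology` tibble.
#' @param lexicon Synonym lexicon (named list).
#' @param config A [cascade_config()].
#' @return An opaque list used via the `prep` argument of [map_term()].
#' @export
prepare_terminology <- function(terminology, lexicon = list(),
                                config = cascade_config()) {
  norm <- norm_join(terminology$term, config$stopwords)
  tokens <- lapply(strsplit(norm, " ", fixed = TRUE),
                   function(tk) unique(tk[nzchar(tk)]))
  n <- nrow(terminology)
  targets <- list()
  for (r in intersect(config$rules, 2:4)) {
    vf <- rule_variant_fn(r, lexicon, config)
    vars <- lapply(norm, vf)
    if (r == 4L && "synonyms" %in% names(terminology)) {
      decl <- lapply(terminology$synonyms,
                     function(s) norm_join(s, config$stopwords))
      vars <- Map(function(v, d, nm) setdiff(unique(c(v, d)), nm),
                  vars, decl, norm)
    }
    idx <- c(seq_len(n), rep(seq_len(n), lengths(vars)))
    str <- c(norm, unlist(vars, use.names = FALSE))
    targets[[as.character(r)]] <- list(idx = idx, str = str)
  }
  list(terminology = terminology, norm = norm, tokens = tokens,
       targets = targets)
}

# similarity matrix between two string vectors
sim_cross <- function(a, b) {
  d <- lev_cross_cpp(lapply(a, utf8ToInt), lapply(b, utf8ToInt))
  len <- outer(nchar(a, type = "chars"), nchar(b, type = "chars"), pmax)
  s <- matrix(100L, nrow(d), ncol(d))
  nz <- len > 0L
  s[nz] <- as.integer(((len[nz] - d[nz]) * 100L) %/% len[nz])
  s
}

empty_records <- function() {
  tibble(source_term = character(0), rule = integer(0),
         similarity = integer(0), icnp_code = character(0),
         icnp_term = character(0), icnp_mod = character(0),
         icnp_axis = character(0), icnp_version = character(0))
}

make_records <- function(source_text, rule, sim, idx, mod, terminology) {
  tibble(source_term = source_text, rule = as.integer(rule),
         similarity = as.integer(sim),
         icnp_code = terminology$code[idx],
         icnp_term = terminology$term[idx],
         icnp_mod = mod,
         icnp_axis = terminology$axis[idx],
         icnp_version = terminology$version[idx])
}

# score src_strs (first element = unmodified term) against one rule's target
# strings; returns records (>= threshold) and candidates (in the band),
# one row per concept, best pair kept, deterministic order
score_rule <- function(rule, source_text, src_strs, tgt_idx, tgt_str,
                       terminology, config) {
  if (!length(src_strs) || !length(tgt_str)) {
    return(list(records = empty_records(), candidates = empty_records()))
  }
  s <- sim_cross(src_strs, tgt_str)
  best <- s[1, ]                            # best source string per target
  for (i in seq_len(nrow(s))[-1]) best <- pmax(best, s[i, ])
  pick <- function(mask) {
    if (!any(mask)) return(empty_records())
    cols <- which(mask)
    # per concept, keep the highest-scoring target string (first on ties)
    o <- order(tgt_idx[cols], -best[cols], cols)
    cols <- cols[o]
    keep <- cols[!duplicated(tgt_idx[cols])]
    make_records(source_text, rule, best[keep], tgt_idx[keep],
                 tgt_str[keep], terminology)
  }
  rec_mask <- best >= config$match_threshold
  cand_mask <- best >= config$candidate_floor & !rec_mask
  recs <- pick(rec_mask)
  cands <- pick(cand_mask)
  if (nrow(recs)) cands <- cands[!cands$icnp_code %in% recs$icnp_code, ]
  list(records = recs, candidates = cands)
}

# strict token-set containment rules; similarity is the score of the shorter
# side against its own tokens inside the longer one, i.e. 100 on containment
score_containment <- function(rule, source_text, src_tokens, prep, config) {
  s <- unique(src_tokens)
  if (!length(s)) {
    return(list(records = empty_records(), candidates = empty_records()))
  }
  hit <- vapply(prep$tokens, function(tt) {
    if (rule == 5L) all(s %in% tt) && length(tt) > length(s)
    else            all(tt %in% s) && length(s) > length(tt)
  }, logical(1))
  idx <- which(hit)
  list(records = make_records(source_text, rule, 100L, idx, prep$norm[idx],
                              prep$terminology),
       candidates = empty_records())
}

order_records <- function(recs) {
  recs[order(recs$rule, -recs$similarity, recs$icnp_code), ]
}

#' Apply a single mapping rule to one source term
#'
#' Rule 1 compares the normalized source term against every normalized
#' target label. Rules 2–4 additionally expand orthographic variants
#' (lemmas, stems, synonyms) on both sides and score every pair. Rules 5 and
#' 6 match by strict token-set containment: a target whose tokens strictly
#' contain the source's tokens has a more restricted meaning (rule 5); a
#' target whose tokens are strictly contained has a broader meaning
#' (rule 6).
#'
#' @param rule Integer rule id in `1:6`.
#' @param source A raw source term string.
#' @param terminology A `terminology` tibble.
#' @param lexicon Synonym lexicon.
#' @param config A [cascade_config()].
#' @param prep Optional [prepare_terminology()] result for `terminology`.
#' @return List with `records` and `candidates` tibbles (8-column schema).
#' @export
#' @examples
#' trm <- as_terminology(data.frame(
#'   code = "10004459", term = "Clinica", axis = "Location", version = "1"))
#' apply_rule(1, "Clínica", trm)
apply_rule <- function(rule, source, terminology, lexicon = list(),
                       config = cascade_config(), prep = NULL) {
  rule <- as.integer(rule)
  if (!rule %in% 1:6) abort("rule must be in 1:6")
  if (is.null(prep)) prep <- prepare_terminology(terminology, lexicon, config)
  nt <- normalize_terms(source, config$stopwords)
  out <- apply_rule_prepped(rule, source, nt$joined, nt$tokens[[1]],
                            prep, lexicon, config)
  out$records <- order_records(out$records)
  out$candidates <- order_records(out$candidates)
  out
}

apply_rule_prepped <- function(rule, source_text, joined, tokens, prep,
                               lexicon, config) {
  if (rule == 1L) {
    score_rule(1L, source_text, joined, seq_along(prep$norm), prep$norm,
               prep$terminology, config)
  } else if (rule %in% 2:4) {
    vf <- rule_variant_fn(rule, lexicon, config)
    src_strs <- c(joined, vf(joined))
    tgt <- prep$targets[[as.character(rule)]]
    score_rule(rule, source_text, src_strs, tgt$idx, tgt$str,
               prep$terminology, config)
  } else {
    score_containment(rule, source_text, tokens, prep, config)
  }
}

#' Map one source term through the rule cascade
#'
#' Phase 2 of the pipeline. Rule 1 (exact coincidence) runs first; if it
#' reaches a full match the remaining rules are not executed and the verdict
#' is `matched` with rule-1 records only. Otherwise rules 2–6 all run and
#' their records and candidates accumulate — one source term can legitimately
#' match under several rules. A term no rule could map is `new`; its
#' candidate list (concepts scoring 90–99) is still reported for expert
#' review. A term that normalizes to nothing (all stopwords or special
#' characters) is unmappable and is reported as `new` with a warning.
#'
#' @inheritParams apply_rule
#' @return A list of class `mapping_outcome`: `term_id`, `term`, `joined`,
#'   `status` (`"matched"` or `"new"`), `records`, `candidates`.
#' @export
map_term <- function(source, terminology, lexicon = list(),
                     config = cascade_config(), prep = NULL) {
  if (is.null(prep)) prep <- prepare_terminology(terminology, lexicon, config)
  src <- if (is.list(source)) source else list(term_id = NA_character_,
                                               term = source)
  nt <- normalize_terms(src$term, config$stopwords)
  joined <- nt$joined
  tokens <- nt$tokens[[1]]
  records <- empty_records()
  candidates <- empty_records()
  if (!nzchar(joined)) {
    warn(sprintf("term '%s' normalizes to nothing; reported as new",
                 src$term))
  } else {
    if (1L %in% config$rules) {
      r1 <- apply_rule_prepped(1L, src$term, joined, tokens, prep, lexicon,
                               config)
      records <- r1$records
      candidates <- r1$candidates
    }
    if (!nrow(records)) {
      for (r in setdiff(config$rules, 1L)) {
        res <- apply_rule_prepped(r, src$term, joined, tokens, prep,
                                  lexicon, config)
        records <- bind_rows(records, res$records)
        candidates <- bind_rows(candidates, res$candidates)
      }
    }
  }
  # one candidate row per (code, rule), highest similarity kept
  if (nrow(candidates)) {
    o <- order(candidates$icnp_code, candidates$rule,
               -candidates$similarity)
    candidates <- candidates[o, ]
    dup <- duplicated(candidates[, c("icnp_code", "rule")])
    candidates <- candidates[!dup, ]
  }
  structure(list(term_id = src$term_id, term = src$term, joined = joined,
                 status = if (nrow(records)) "matched" else "new",
                 records = order_records(records),
                 candidates = order_records(candidates)),
            class = "mapping_outcome")
}

#' Map a whole term bank against a terminology
#'
#' Runs [map_term()] over every row of the bank, in order, against a single
#' precomputed terminology preparation. Because one term can match under
#' several rules, the total number of rule assignments plus new terms can
#' exceed the bank size.
#'
#' @param bank Term-bank tibble (`term_id`, `term`), or a character vector.
#' @inheritParams apply_rule
#' @return An object of class `term_mapping` with elements `outcomes` (a
#'   tibble, one row per source term, `records`/`candidates` list-columns),
#'   `records` and `candidates` (flat 8-column tibbles), and `summary`
#'   (per-rule term counts, new/identical totals). Use [tidy()] for the
#'   record table and [glance()] for the count summary.
#' @export
map_bank <- function(bank, terminology, lexicon = list(),
                     config = cascade_config()) {
  if (is.character(bank)) {
    bank <- tibble(term_id = as.character(seq_along(bank)), term = bank)
  }
  if (!all(c("term_id", "term") %in% names(bank))) {
    abort("bank needs columns 'term_id' and 'term'")
  }
  prep <- prepare_terminology(terminology, lexicon, config)
  outs <- purrr::map(seq_len(nrow(bank)), function(i) {
    map_term(list(term_id = bank$term_id[i], term = bank$term[i]),
             terminology, lexicon, config, prep = prep)
  })
  outcomes <- tibble(
    term_id = bank$term_id,
    term = bank$term,
    joined = vapply(outs, `[[`, character(1), "joined"),
    status = vapply(outs, `[[`, character(1), "status"),
    n_records = vapply(outs, function(o) nrow(o$records), integer(1)),
    n_candidates = vapply(outs, function(o) nrow(o$candidates), integer(1)),
    records = lapply(outs, `[[`, "records"),
    candidates = lapply(outs, `[[`, "candidates")
  )
  flat <- function(col) {
    dplyr::bind_rows(Map(function(id, df) {
      if (nrow(df)) cbind(term_id = id, df) else NULL
    }, outcomes$term_id, outcomes[[col]]))
  }
  records <- as_tibble(flat("records"))
  candidates <- as_tibble(flat("candidates"))
  if (!nrow(records)) records <- cbind_empty_records()
  if (!nrow(candidates)) candidates <- cbind_empty_records()
  rule_terms <- vapply(1:6, function(r) {
    length(unique(records$term_id[records$rule == r]))
  }, integer(1))
  names(rule_terms) <- paste0("rule", 1:6)
  n_new <- sum(outcomes$status == "new")
  summary <- list(
    n_terms = nrow(bank),
    n_concepts = nrow(terminology),
    rule_counts = rule_terms,
    n_new = n_new,
    n_identical = length(unique(records$term_id[records$rule == 1L])),
    total_assignments = sum(rule_terms) + n_new
  )
  structure(list(outcomes = outcomes, records = records,
                 candidates = candidates, summary = summary,
                 config = config),
            class = "term_mapping")
}

cbind_empty_records <- function() {
  tibble(term_id = character(0), !!!empty_records())
}

#' @export
print.term_mapping <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<term_mapping> %d source terms vs %d concepts\n",
              s$n_terms, s$n_concepts))
  cat(sprintf("  matched: %d (identical via rule 1: %d), new: %d\n",
              s$n_terms - s$n_new, s$n_identical, s$n_new))
  cat("  terms per rule: ",
      paste(sprintf("%s=%d", names(s$rule_counts), s$rule_counts),
            collapse = " "), "\n", sep = "")
  cat(sprintf("  total rule assignments + new: %d\n", s$total_assignments))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
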