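#' Synthetic fixtures: terminology, source bank and planted ground truth
#'
#' The real inputs — a licensed nursing terminology and an unpublished
#' hospital term bank — cannot ship with the package, so tests run on
#' synthetic stand-ins. `generate_terminology()` builds `n` concepts with
#' unique 8-digit codes, pronounceable 1–3-token Portuguese-plausible
#' labels, axes drawn from the seven-axis set and a fixed version tag.
#' `generate_bank()` then plants source terms in seven relationship
#' categories, each constructed so that exactly one mapping rule (or none,
#' for `novel`) is the expected recovery path:
#'
#' * `exact` — verbatim copy of a label (rule 1);
#' * `accent_variant` — a label with accents, case changes and hyphens
#'   injected, normalizing back to the label (rule 1);
#' * `inflected` — a label with one token pluralized, which the default
#'   stemmer reduces back to the label's radical (rule 3);
#' * `synonym` — a label with one token replaced by a fresh word, the
#'   replacement being registered in the emitted lexicon (rule 4);
#' * `restricted` — a strict token subset of a multi-token label, so the
#'   target has the more restricted meaning (rule 5);
#' * `comprehensive` — a label plus extra tokens, so the target is broader
#'   (rule 6);
#' * `novel` — fresh tokens kept below the 90-percent candidate floor
#'   against every label and label variant (no rule; verdict `new`).
#'
#' Category separation is enforced at generation (a planted term is rejected
#' and redrawn if it collides with another category's signature), so the
#' expected rule is well defined. Everything is reproducible from `seed`.
#'
#' @param n Number of concepts / source terms.
#' @param seed Integer seed; identical seeds give identical output.
#' @param version Version tag stored on every concept.
#' @param name Terminology name attribute.
#' @return `generate_terminology()`: a `terminology` tibble.
#'   `generate_bank()`: a list with `bank` (term bank tibble), `truths`
#'   (tibble `term_id`, `planted_category`, `expected_rule`, `target_code`)
#'   and `lexicon` (named list for [map_bank()]).
#' @export
#' @examples
#' trm <- generate_terminology(20, seed = 7)
#' fix <- generate_bank(trm, n = 10, seed = 7)
#' fix$truths
generate_terminology <- function(n, seed = 1L, version = "1",
                                 name = "synthetic") {
  if (!is.numeric(n) || n < 1) abort("n must be a positive integer")
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    labels <- character(0)
    tries <- 0L
    while (length(labels) < n) {
      k <- sample(1:3, 1L, prob = c(0.5, 0.35, 0.15))
      lab <- paste(replicate(k, random_token()), collapse = " ")
      if (!lab %in% labels) labels <- c(labels, lab)
      tries <- tries + 1L
      if (tries > 50L * n) abort("could not generate enough unique labels")
    }
    codes <- sprintf("%08d", sample(10000000:10999999, n))
    axes <- sample(terminology_axes(), n, replace = TRUE)
    as_terminology(tibble(code = codes, term = labels, axis = axes,
                          version = version), name = name)
  })
}

planted_categories <- c("exact", "accent_variant", "inflected", "synonym",
                        "restricted", "comprehensive", "novel")

#' Default category mix for synthetic banks
#'
#' Roughly mirrors the observed shape of a real mapping run: about a fifth
#' of terms exactly present in the terminology, a third absent, and the rest
#' reachable only through orthographic-variant or containment rules.
#'
#' @return Named numeric vector over the seven planted categories, summing
#'   to 1.
#' @export
default_proportions <- function() {
  c(exact = 0.20, accent_variant = 0.10, inflected = 0.10, synonym = 0.15,
    restricted = 0.10, comprehensive = 0.05, novel = 0.30)
}

#' @rdname generate_terminology
#' @param terminology A `terminology` to plant against.
#' @param proportions Named fractions over the planted categories, summing
#'   to 1; missing categories count as 0.
#' @export
generate_bank <- function(terminology, n, seed = 1L,
                          proportions = default_proportions()) {
  if (!is.numeric(n) || n < 1) abort("n must be a positive integer")
  n <- as.integer(n)
  bad <- setdiff(names(proportions), planted_categories)
  if (length(bad)) {
    abort(sprintf("unknown planted category: %s", paste(bad, collapse = ", ")))
  }
  p <- setNames(numeric(length(planted_categories)), planted_categories)
  p[names(proportions)] <- proportions
  if (abs(sum(p) - 1) > 1e-9) abort("proportions must sum to 1")
  counts <- largest_remainder(p, n)

  norm <- norm_join(terminology$term)
  tok_list <- lapply(strsplit(norm, " ", fixed = TRUE),
                     function(tk) tk[nzchar(tk)])
  stemmed <- vapply(tok_list, function(tk) paste(stem_rslp(tk), collapse = " "),
                    character(1))
  label_tokens <- unique(unlist(tok_list))
  multi <- which(lengths(tok_list) >= 2L)
  if (counts[["restricted"]] > 0L && !length(multi)) {
    abort("terminology has no multi-token labels to plant restricted terms")
  }

  withr::with_seed(as.integer(seed), {
    used_tokens <- label_tokens
    lexicon <- list()
    rows <- vector("list", n)
    i <- 0L
    for (cat in planted_categories) {
      for (k in seq_len(counts[[cat]])) {
        i <- i + 1L
        tgt <- NA_integer_
        text <- NULL
        for (try in seq_len(200L)) {
          if (cat == "restricted") {
            tgt <- resample(multi)
          } else if (cat != "novel") {
            tgt <- sample.int(nrow(terminology), 1L)
          }
          plant <- plant_term(cat, tgt, terminology, norm, tok_list,
                              stemmed, used_tokens)
          if (!is.null(plant)) break
          plant <- NULL
        }
          if (is.null(plant)) {
            abort(sprintf("could not plant a '%s' term after bounded retries",
                          cat))
          }
        text <- plant$text
        used_tokens <- unique(c(used_tokens, plant$new_tokens))
        if (!is.null(plant$lexicon_entry)) {
          lexicon[[plant$lexicon_entry$head]] <-
            unique(c(lexicon[[plant$lexicon_entry$head]],
                     plant$lexicon_entry$syn))
        }
        rows[[i]] <- tibble(
          term = text, planted_category = cat,
          expected_rule = expected_rule_for(cat),
          target_code = if (is.na(tgt)) NA_character_
                        else terminology$code[tgt])
      }
    }
    out <- bind_rows(rows)
    perm <- sample(n)
    out <- out[perm, ]
    out$term_id <- as.character(seq_len(n))
    list(bank = out[, c("term_id", "term")],
         truths = out[, c("term_id", "planted_category", "expected_rule",
                          "target_code")],
         lexicon = as_lexicon(lexicon))
  })
}

expected_rule_for <- function(cat) {
  switch(cat, exact = 1L, accent_variant = 1L, inflected = 3L,
         synonym = 4L, restricted = 5L, comprehensive = 6L, NA_integer_)
}

largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(-(raw - counts), seq_along(raw))
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  as.integer(counts) |> setNames(names(p))
}

# sample k elements of x, safe for length-1 numeric vectors
resample <- function(x, k = 1L) x[sample.int(length(x), k)]

syllables <- function() {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  paste0(rep(cons, each = length(vow)), vow)
}

random_token <- function(min_syl = 2L, max_syl = 4L) {
  repeat {
    k <- sample(min_syl:max_syl, 1L)
    tok <- paste(sample(syllables(), k, replace = TRUE), collapse = "")
    if (!tok %in% default_stopwords()) return(tok)
  }
}

fresh_token <- function(used, min_syl = 3L) {
  for (try in seq_len(500L)) {
    tok <- random_token(min_syl = min_syl)
    if (!tok %in% used) return(tok)
  }
  abort("could not generate a fresh token")
}

accent_map <- list(a = c("á", "â", "ã"),
                   e = c("é", "ê"), i = "í",
                   o = c("ó", "ô", "õ"), u = "ú",
                   c = "ç")

inject_accents <- function(label) {
  chars <- strsplit(label, "")[[1]]
  eligible <- which(chars %in% names(accent_map))
  if (length(eligible)) {
    k <- resample(seq_len(min(3L, length(eligible))))
    for (j in resample(eligible, k)) {
      chars[j] <- resample(accent_map[[chars[j]]])
    }
  }
  out <- paste(chars, collapse = "")
  # uppercase first letter; occasionally hyphenate a token boundary
  out <- paste0(toupper(substr(out, 1, 1)), substring(out, 2))
  if (grepl(" ", out) && stats::runif(1) < 0.5) {
    out <- sub(" ", "-", out)
  }
  out
}

# build one planted source term; NULL signals "retry"
plant_term <- function(cat, tgt, terminology, norm, tok_list, stemmed,
                       used_tokens) {
  if (cat == "exact") {
    return(list(text = norm[tgt], new_tokens = character(0)))
  }
  if (cat == "accent_variant") {
    text <- inject_accents(norm[tgt])
    if (identical(text, norm[tgt])) return(NULL)
    stopifnot(identical(norm_join(text), norm[tgt]))
    return(list(text = text, new_tokens = character(0)))
  }
  if (cat == "inflected") {
    toks <- tok_list[[tgt]]
    j <- sample(length(toks), 1L)
    if (endsWith(toks[j], "s")) return(NULL)
    toks[j] <- paste0(toks[j], "s")
    text <- paste(toks, collapse = " ")
    if (text %in% norm) return(NULL)
    return(list(text = text, new_tokens = character(0)))
  }
  if (cat == "synonym") {
    toks <- tok_list[[tgt]]
    j <- sample(length(toks), 1L)
    syn <- fresh_token(used_tokens)
    replaced <- toks[j]
    toks[j] <- syn
    text <- paste(toks, collapse = " ")
    if (text %in% norm) return(NULL)
    return(list(text = text, new_tokens = syn,
                lexicon_entry = list(head = syn, syn = replaced)))
  }
  if (cat == "restricted") {
    toks <- tok_list[[tgt]]
    k <- sample.int(length(toks) - 1L, 1L)
    sub <- sort(resample(seq_along(toks), k))
    text <- paste(toks[sub], collapse = " ")
    if (text %in% norm) return(NULL)
    # strict containment must hold on unique token sets
    if (!length(setdiff(unique(toks), unique(toks[sub])))) return(NULL)
    return(list(text = text, new_tokens = character(0)))
  }
  if (cat == "comprehensive") {
    extra <- replicate(sample(1:2, 1L), fresh_token(used_tokens))
    text <- paste(c(tok_list[[tgt]], extra), collapse = " ")
    return(list(text = text, new_tokens = extra))
  }
  # novel: stay strictly below the candidate floor against every label and
  # every stem variant, with no containment relation possible
  toks <- replicate(sample(2:3, 1L), fresh_token(used_tokens))
  text <- paste(toks, collapse = " ")
  stext <- paste(stem_rslp(toks), collapse = " ")
  refs <- c(norm, stemmed)
  s <- sim_cross(c(text, stext), refs)
  if (max(s) >= 90L) return(NULL)
  list(text = text, new_tokens = toks)
}

#' Write a synthetic fixture set to disk
#'
#' Emits the four files consumed by the mapping pipeline: `terminology.csv`,
#' `bank.csv`, `lexicon.json` and `truths.csv`.
#'
#' @param terminology A `terminology`.
#' @param fixtures Result of [generate_bank()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(terminology, fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_terminology(terminology, file.path(dir, "terminology.csv"))
  readr::write_csv(fixtures$bank, file.path(dir, "bank.csv"),
                   progress = FALSE)
  write_lexicon(fixtures$lexicon, file.path(dir, "lexicon.json"))
  readr::write_csv(fixtures$truths, file.path(dir, "truths.csv"),
                   progress = FALSE)
  invisible(dir)
}
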