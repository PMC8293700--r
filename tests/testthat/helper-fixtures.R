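# Shared fixtures and independent oracles.

tiny_terminology <- function(df) {
  as_terminology(df, name = "fixture")
}

# A terminology mirroring the worked output example for the source term
# "clinico" (clinical): a location concept "clinica" reachable via lemma and
# stem variants, and a means concept "medico" reachable via a shared synonym.
worked_example <- function() {
  trm <- tiny_terminology(data.frame(
    code = c("10004459", "10014522"),
    term = c("Clinica", "Medico"),
    axis = c("Location", "Means"),
    version = c("1", "1")
  ))
  lexicon <- as_lexicon(list(clinico = "doutor", medico = "doutor"))
  lemma <- make_lemmatizer(data.frame(form = "clinico", lemma = "clinica"))
  list(terminology = trm, lexicon = lexicon,
       config = cascade_config(lemmatizer = lemma))
}

# Breadth-first search over single-character edit scripts: an oracle for the
# Levenshtein distance that never runs the DP. Explores strings reachable
# from `a` by k edits until `b` appears.
bfs_lev <- function(a, b, alphabet, max_depth = 8L) {
  if (identical(a, b)) return(0L)
  seen <- a
  frontier <- a
  for (depth in seq_len(max_depth)) {
    nxt <- unique(unlist(lapply(frontier, edits1, alphabet = alphabet)))
    if (b %in% nxt) return(depth)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
    if (!length(frontier)) break
  }
  stop("bfs_lev: max_depth exceeded")
}

edits1 <- function(s, alphabet) {
  ch <- if (nchar(s)) strsplit(s, "")[[1]] else character(0)
  n <- length(ch)
  out <- character(0)
  for (i in seq_len(n)) {                    # deletions
    out <- c(out, paste(ch[-i], collapse = ""))
  }
  for (i in seq_len(n)) {                    # substitutions
    for (x in alphabet) {
      tmp <- ch; tmp[i] <- x
      out <- c(out, paste(tmp, collapse = ""))
    }
  }
  for (i in 0:n) {                           # insertions
    for (x in alphabet) {
      out <- c(out, paste(c(ch[seq_len(i)], x, ch[seq_len(n - i) + i]),
                          collapse = ""))
    }
  }
  unique(out)
}

# All strings over `alphabet` of length 0..max_len.
all_strings <- function(alphabet, max_len) {
  out <- ""
  cur <- ""
  for (l in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

random_unicode_strings <- function(n, seed = 1L) {
  pool <- c(letters, LETTERS, 0:9, " ", "-", "/", ".", ",", "(", ")",
            strsplit("áâãàäéêèëíîìïóôõòöúûùüçÁÉÍÓÚÂÊÔÃÕÇñÑœ", "")[[1]])
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(pool, sample(0:20, 1), replace = TRUE), collapse = "")
    }, character(1))
  })
}
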