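test_that("rule 1 finds exact coincidences and banks 90-99 near misses", {
  trm <- tiny_terminology(data.frame(
    code = c("11111111", "22222222"),
    term = c("Veia", "Hipercalcemia"),
    axis = c("Location", "Focus"), version = "1"))

  r <- apply_rule(1, "veia", trm)
  expect_equal(nrow(r$records), 1)
  expect_equal(r$records$rule, 1L)
  expect_equal(r$records$similarity, 100L)
  expect_equal(r$records$icnp_code, "11111111")
  expect_equal(nrow(r$candidates), 0)

  # the documented erroneous near-miss: candidate at 92, no record
  r <- apply_rule(1, "hipercalemia", trm)
  expect_equal(nrow(r$records), 0)
  expect_equal(nrow(r$candidates), 1)
  expect_equal(r$candidates$similarity, 92L)
  expect_equal(r$candidates$icnp_code, "22222222")

  empty <- tiny_terminology(data.frame(code = character(0),
                                       term = character(0),
                                       axis = character(0),
                                       version = character(0)))
  r <- apply_rule(1, "xyz", empty)
  expect_equal(nrow(r$records), 0)
  expect_equal(nrow(r$candidates), 0)
})

test_that("variant generators substitute lemmas, stems and synonyms", {
  lem <- make_lemmatizer(data.frame(form = "aborto", lemma = "abortar"))
  expect_equal(lemma_variants("aborto", lem), "abortar")
  expect_equal(lemma_variants("abortar", lem), character(0))
  # two tokens, one lemmatizable: the substituted combination appears
  expect_equal(lemma_variants("aborto previo", lem), "abortar previo")

  expect_equal(stem_variants("medicar"), "medic")
  expect_equal(stem_variants("medic"), character(0))

  lex <- as_lexicon(list(pessoa = "individuo"))
  expect_equal(synonym_variants("pessoa", lex), "individuo")
  expect_equal(synonym_variants("ausente", lex), character(0))
  # whole-term headword substitution
  lex2 <- as_lexicon(list("mascara oxigenio" = "oxigenoterapia"))
  expect_true("oxigenoterapia" %in% synonym_variants("mascara oxigenio", lex2))
})

test_that("rules 2-4 match through modified forms on either side", {
  fx <- worked_example()
  # rule 2: source lemma variant reaches the target label
  r2 <- apply_rule(2, "clinico", fx$terminology, fx$lexicon, fx$config)
  expect_equal(r2$records$icnp_code, "10004459")
  expect_equal(r2$records$similarity, 100L)
  # rule 3: both sides stem to a common radical
  r3 <- apply_rule(3, "clinico", fx$terminology, fx$lexicon, fx$config)
  expect_true("10004459" %in% r3$records$icnp_code)
  # rule 4: source and target meet at the shared synonym "doutor"
  r4 <- apply_rule(4, "clinico", fx$terminology, fx$lexicon, fx$config)
  expect_equal(r4$records$icnp_code, "10014522")
  expect_equal(r4$records$icnp_term, "Medico")
  expect_equal(r4$records$icnp_mod, "doutor")
})

test_that("restricted and comprehensive rules use strict token containment", {
  trm <- tiny_terminology(data.frame(
    code = c("1", "2", "3", "4"),
    term = c("Sala", "Sala Cirurgica", "Sala Parto", "Cateterizar"),
    axis = c("Location", "Location", "Location", "Action"), version = "1"))

  r5 <- apply_rule(5, "sala", trm)
  expect_setequal(r5$records$icnp_code, c("2", "3"))
  expect_true(all(r5$records$rule == 5L))
  expect_true(all(r5$records$similarity == 100L))
  # equality is excluded: concept "Sala" itself is not a rule-5 match
  expect_false("1" %in% r5$records$icnp_code)

  r6 <- apply_rule(6, "cateterizar bexiga", trm)
  expect_equal(r6$records$icnp_code, "4")
  expect_equal(r6$records$rule, 6L)

  # a single-token source has no strict superset of its tokens to contain
  expect_equal(nrow(apply_rule(6, "sala", trm)$records), 0)

  trm2 <- tiny_terminology(data.frame(
    code = "9", term = "Trocar Curativo", axis = "Action", version = "1"))
  expect_equal(apply_rule(6, "trocar curativo ferida", trm2)$records$rule, 6L)
})

test_that("rule 1 short-circuits the cascade; multi-rule terms accumulate", {
  fx <- worked_example()
  trm <- fx$terminology
  # exact source: only rule-1 records even though rule 3 would also match
  out <- map_term("clinica", trm, fx$lexicon, fx$config)
  expect_equal(out$status, "matched")
  expect_true(all(out$records$rule == 1L))

  # no exact hit: rules 2, 3 and 4 all contribute records for one source
  out <- map_term("clinico", trm, fx$lexicon, fx$config)
  expect_equal(out$status, "matched")
  expect_setequal(out$records$rule, c(2L, 3L, 4L))
  expect_true(all(out$records$similarity == 100L))
  # records ordered by rule, similarity, code
  expect_equal(out$records$rule, sort(out$records$rule))

  # nothing shared: new, no records
  out <- map_term("zzzz qqqq", trm, fx$lexicon, fx$config)
  expect_equal(out$status, "new")
  expect_equal(nrow(out$records), 0)
})

test_that("unmappable all-stopword terms are flagged new with a warning", {
  fx <- worked_example()
  expect_warning(out <- map_term("de da", fx$terminology, fx$lexicon,
                                 fx$config),
                 "normalizes to nothing")
  expect_equal(out$status, "new")
  expect_equal(nrow(out$records), 0)
})

test_that("map_bank preserves order, counts per rule, and flattens records", {
  trm <- tiny_terminology(data.frame(
    code = c("1", "2"), term = c("Veia", "Pessoa Idosa"),
    axis = c("Location", "Client"), version = "1"))
  lex <- as_lexicon(list(individuo = "pessoa"))
  bank <- tibble::tibble(term_id = c("a", "b", "c"),
                         term = c("Veia", "Individuo Idosa", "Zumthor"))
  m <- map_bank(bank, trm, lex)
  expect_equal(m$outcomes$term_id, c("a", "b", "c"))
  expect_equal(unname(m$summary$rule_counts[c("rule1", "rule4")]), c(1L, 1L))
  expect_equal(m$summary$n_new, 1L)
  expect_equal(m$summary$n_identical, 1L)
  expect_equal(sort(unique(m$records$term_id)), c("a", "b"))

  empty <- map_bank(bank[0, ], trm, lex)
  expect_equal(nrow(empty$outcomes), 0)
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$summary$total_assignments, 0L)
})

test_that("one term matching under two rules yields two assignments", {
  trm <- tiny_terminology(data.frame(
    code = c("1", "2"), term = c("Sala Cirurgica Grande", "Sala"),
    axis = c("Location", "Location"), version = "1"))
  m <- map_bank(c("sala cirurgica"), trm)
  # restricted against concept 1, comprehensive against concept 2
  expect_setequal(m$records$rule, c(5L, 6L))
  expect_gt(m$summary$total_assignments, m$summary$n_terms)
})

test_that("identical inputs give identical outcomes and record order", {
  trm <- generate_terminology(40, seed = 3)
  fix <- generate_bank(trm, n = 25, seed = 3)
  m1 <- map_bank(fix$bank, trm, fix$lexicon)
  m2 <- map_bank(fix$bank, trm, fix$lexicon)
  expect_identical(m1$records, m2$records)
  expect_identical(m1$candidates, m2$candidates)
  expect_identical(m1$summary, m2$summary)
})

test_that("tidy, glance and autoplot expose the mapping result", {
  trm <- generate_terminology(30, seed = 5)
  fix <- generate_bank(trm, n = 15, seed = 5)
  m <- map_bank(fix$bank, trm, fix$lexicon)
  expect_identical(tidy(m), m$records)
  expect_identical(tidy(m, type = "candidates"), m$candidates)
  g <- glance(m)
  expect_equal(g$n_terms, 15L)
  expect_equal(g$total_assignments, m$summary$total_assignments)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("cascade thresholds are validated and candidates stay in band", {
  expect_error(cascade_config(candidate_floor = 101), "candidate_floor")
  expect_error(cascade_config(candidate_floor = 95, match_threshold = 90),
               "candidate_floor")
  expect_error(cascade_config(rules = c(1, 7)), "subset")

  trm <- generate_terminology(60, seed = 13)
  fix <- generate_bank(trm, n = 40, seed = 13)
  m <- map_bank(fix$bank, trm, fix$lexicon)
  if (nrow(m$candidates)) {
    expect_true(all(m$candidates$similarity >= 90L &
                      m$candidates$similarity <= 99L))
  }
  expect_true(all(m$records$similarity == 100L))
})
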