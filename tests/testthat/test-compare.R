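test_that("verdicts collapse outcomes to identical / other / new", {
  trm <- tiny_terminology(data.frame(
    code = c("1", "2"), term = c("Veia", "Pessoa"),
    axis = c("Location", "Client"), version = "1"))
  lex <- as_lexicon(list(individuo = "pessoa"))
  bank <- tibble::tibble(term_id = c("a", "b", "c"),
                         term = c("Veia", "Individuo", "Zumthor"))
  v <- verdicts_from_outcomes(map_bank(bank, trm, lex))
  expect_equal(v$category, c("identical", "other", "new"))
})

test_that("equality and exclusivity partition the category sets", {
  manual <- tibble::tibble(term_id = c("a", "b", "c", "d"),
                           category = c("identical", "identical",
                                        "identical", "new"))
  auto <- tibble::tibble(term_id = c("a", "b", "c", "d"),
                         category = c("new", "identical", "identical",
                                      "identical"))
  cmp <- compare_category(manual, auto, "identical")
  expect_equal(cmp$manual_count, 3L)
  expect_equal(cmp$auto_count, 3L)
  expect_equal(cmp$shared_count, 2L)
  expect_equal(cmp$exclusive_manual, 1L)
  expect_equal(cmp$exclusive_auto, 1L)
  expect_equal(cmp$agreement_pct, 66.66)

  # equal label sets: full agreement, no exclusives
  cmp <- compare_category(manual, manual, "identical")
  expect_equal(cmp$agreement_pct, 100)
  expect_equal(cmp$exclusive_manual, 0L)
  expect_equal(cmp$exclusive_auto, 0L)

  bad <- tibble::tibble(term_id = c("a", "x"), category = c("new", "new"))
  expect_error(compare_category(manual, bad), "same term_id set")
})

test_that("count-level comparison reproduces the published agreement", {
  id <- category_comparison("identical", manual_count = 650,
                            auto_count = 569, shared_count = 549)
  expect_equal(id$agreement_pct, 84.46)
  expect_equal(id$exclusive_manual, 101L)
  expect_equal(id$exclusive_auto, 20L)

  nw <- category_comparison("new", manual_count = 1251,
                            auto_count = 1031, shared_count = 822)
  expect_equal(nw$agreement_pct, 65.70)
  expect_equal(nw$exclusive_manual, 429L)
  expect_equal(nw$exclusive_auto, 209L)

  expect_error(category_comparison("new", 5, 5, 6), "shared_count")
})

test_that("partition invariant holds across random label assignments", {
  withr::with_seed(17, {
    for (i in 1:20) {
      ids <- as.character(1:50)
      manual <- tibble::tibble(
        term_id = ids,
        category = sample(c("identical", "new", "similar"), 50, TRUE))
      auto <- tibble::tibble(
        term_id = sample(ids),
        category = sample(c("identical", "new", "other"), 50, TRUE))
      for (cat in c("identical", "new")) {
        cmp <- compare_category(manual, auto, cat)
        expect_equal(cmp$exclusive_manual + cmp$shared_count,
                     cmp$manual_count)
        expect_equal(cmp$exclusive_auto + cmp$shared_count, cmp$auto_count)
        expect_true(is.na(cmp$agreement_pct) ||
                      (cmp$agreement_pct >= 0 && cmp$agreement_pct <= 100))
        m <- manual$term_id[manual$category == cat]
        a <- auto$term_id[auto$category == cat]
        expect_equal(isTRUE(cmp$agreement_pct == 100) &&
                       cmp$exclusive_auto == 0L, setequal(m, a) && length(m) > 0)
      }
    }
  })
})

test_that("percentages are truncated, never rounded", {
  expect_equal(truncate_pct(65.7074, 2), 65.70)
  expect_equal(truncate_pct(84.4615, 2), 84.46)
  expect_equal(truncate_pct(23.31, 1), 23.3)
  expect_equal(truncate_pct(22.966, 1), 22.9)
  # exact ratios are not dragged below the boundary by floating point
  expect_equal(truncate_pct(549 / 650 * 100, 2), 84.46)
  expect_equal(truncate_pct(100, 2), 100)
  expect_equal(truncate_pct(29 / 29 * 100, 2), 100)
})

test_that("judgment summaries aggregate the ISO equivalence degrees", {
  j <- tibble::tibble(
    source_term = c("alcoholism", "apron", "bedridden", "palpation"),
    target_code = c("10002137", "10011222", "10050397", "10013997"),
    degree = c("2", "3", "2", "not_attributed"))
  s <- summarize_judgments(j, universe_size = 10)
  expect_equal(unname(s$histogram[c("2", "3", "not_attributed")]),
               c(2L, 1L, 1L))
  expect_equal(s$n_equivalent, 4L)
  expect_equal(s$equivalence_pct, 40)

  # 48 equivalences over a universe of 209 reviewed terms: 22.9 truncated
  j48 <- tibble::tibble(source_term = as.character(1:48),
                        target_code = as.character(1:48),
                        degree = rep(c("1", "2", "3", "4"), 12))
  expect_equal(summarize_judgments(j48, 209)$equivalence_pct, 22.9)

  # 100 over 429: the published 23.3
  j100 <- tibble::tibble(source_term = as.character(1:100),
                         target_code = as.character(1:100),
                         degree = rep("2", 100))
  expect_equal(summarize_judgments(j100, 429)$equivalence_pct, 23.3)

  empty <- summarize_judgments(j[0, ], 5)
  expect_true(all(empty$histogram == 0L))
  expect_equal(empty$equivalence_pct, 0)

  expect_error(summarize_judgments(j, 2), "universe_size")
  j$degree[1] <- "7"
  expect_error(summarize_judgments(j, 10), "unknown equivalence degree")
})

test_that("compare_mappings tidiers and report round-trip", {
  manual <- tibble::tibble(term_id = as.character(1:6),
                           category = c("identical", "identical", "new",
                                        "new", "similar", "in_definition"))
  auto <- tibble::tibble(term_id = as.character(1:6),
                         category = c("identical", "other", "new", "new",
                                      "other", "new"))
  cmp <- compare_mappings(manual, auto)
  td <- tidy(cmp)
  expect_equal(td$category, c("identical", "new"))
  expect_equal(td$shared_count, c(1L, 2L))
  g <- glance(cmp)
  expect_equal(g$agreement_identical, 50)
  expect_equal(g$agreement_new, 100)
  expect_s3_class(autoplot(cmp), "ggplot")

  path <- withr::local_tempfile(fileext = ".json")
  write_comparison_report(cmp, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$categories$agreement_pct, c(50, 100))
})
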