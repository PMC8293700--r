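#' Truncate (not round) a percentage
#'
#' Agreement and equivalence percentages are truncated to a fixed number of
#' decimals. Truncation, fixed once, is the convention used throughout this
#' package: with manual counts 650 shared 549 the agreement is 84.4615...,
#' reported as 84.46, and 822/1251 = 65.7074... is reported as 65.70 (where
#' rounding would give 65.71). Values are pre-rounded at 1e-9 so that exact
#' ratios are not pushed below the truncation boundary by floating point.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimals kept.
#' @return Numeric vector truncated to `digits` decimals.
#' @export
#' @examples
#' truncate_pct(c(84.4615, 65.7074), 2)
truncate_pct <- function(x, digits = 2L) {
  f <- 10^digits
  floor(round(x * f, 9)) / f
}

#' Per-term verdicts from mapping outcomes
#'
#' Collapses each source term's outcome to the three-way verdict used in the
#' manual-vs-automated comparison: `identical` when a rule-1 full match
#' exists, `new` when no rule produced a match, `other` for matches under
#' rules 2–6 only.
#'
#' @param mapping A `term_mapping` from [map_bank()], or its `outcomes`
#'   tibble.
#' @return Tibble with columns `term_id`, `category`.
#' @export
verdicts_from_outcomes <- function(mapping) {
  outcomes <- if (inherits(mapping, "term_mapping")) mapping$outcomes
              else mapping
  category <- vapply(seq_len(nrow(outcomes)), function(i) {
    if (outcomes$status[i] == "new") return("new")
    if (any(outcomes$records[[i]]$rule == 1L)) "identical" else "other"
  }, character(1))
  tibble(term_id = outcomes$term_id, category = category)
}

#' Equality and exclusivity of one verdict category
#'
#' Stage 1 of the manual-vs-automated comparison. For a category
#' (`identical` or `new`), the terms carrying that category in the manual
#' and automated label sets are intersected: terms labelled by both
#' processes are shared ("equality"), terms labelled by only one are
#' exclusive to that process ("exclusivity"). Agreement is the shared count
#' over the manual count (manual mapping is the standard), truncated to two
#' decimals.
#'
#' `compare_category()` works from per-term label tables;
#' `category_comparison()` builds the same summary directly from counts.
#'
#' @param manual,auto Tibbles with columns `term_id`, `category`, covering
#'   the same set of terms.
#' @param category `"identical"` or `"new"`.
#' @return One-row tibble: `category`, `manual_count`, `auto_count`,
#'   `shared_count`, `exclusive_manual`, `exclusive_auto`, `agreement_pct`.
#' @export
#' @examples
#' category_comparison("identical", manual_count = 650, auto_count = 569,
#'                     shared_count = 549)
compare_category <- function(manual, auto, category = c("identical", "new")) {
  category <- match.arg(category)
  if (!setequal(manual$term_id, auto$term_id) ||
      anyDuplicated(manual$term_id) || anyDuplicated(auto$term_id)) {
    abort("manual and automated labels must cover the same term_id set")
  }
  m <- manual$term_id[manual$category == category]
  a <- auto$term_id[auto$category == category]
  category_comparison(category, manual_count = length(m),
                      auto_count = length(a),
                      shared_count = length(intersect(m, a)))
}

#' @rdname compare_category
#' @param manual_count,auto_count,shared_count Category counts.
#' @export
category_comparison <- function(category, manual_count, auto_count,
                                shared_count) {
  if (shared_count > manual_count || shared_count > auto_count) {
    abort("shared_count cannot exceed either process count")
  }
  agreement <- if (manual_count > 0) {
    truncate_pct(shared_count / manual_count * 100, 2L)
  } else {
    NA_real_
  }
  tibble(category = category,
         manual_count = as.integer(manual_count),
         auto_count = as.integer(auto_count),
         shared_count = as.integer(shared_count),
         exclusive_manual = as.integer(manual_count - shared_count),
         exclusive_auto = as.integer(auto_count - shared_count),
         agreement_pct = agreement)
}

#' Compare manual and automated mappings
#'
#' Runs [compare_category()] for the two categories the comparison framework
#' analyses — `identical` and `new`. Matches under rules 2–6 are not compared
#' against the manual `similar` / `in_definition` categories, which do not
#' partition terms the same way.
#'
#' @inheritParams compare_category
#' @return An object of class `mapping_comparison`; its `categories` element
#'   is the two-row comparison tibble. [tidy()] returns that tibble,
#'   [glance()] a one-row summary.
#' @export
compare_mappings <- function(manual, auto) {
  cats <- bind_rows(compare_category(manual, auto, "identical"),
                    compare_category(manual, auto, "new"))
  structure(list(categories = cats, n_terms = length(manual$term_id)),
            class = "mapping_comparison")
}

#' @export
print.mapping_comparison <- function(x, ...) {
  cat(sprintf("<mapping_comparison> over %d terms\n", x$n_terms))
  print(x$categories)
  invisible(x)
}

#' Aggregate expert equivalence judgments
#'
#' Stages 2 and 3 of the comparison are expert work: for terms one process
#' mapped as new, reviewers look for an equivalent concept and grade it on
#' the ISO/TR 12300 scale (1–4, or `not_attributed` when a relationship
#' exists but no degree could be assigned). This function only aggregates
#' those imported judgments: a histogram over degrees and the fraction of
#' the reviewed universe for which an equivalence was established, truncated
#' to one decimal.
#'
#' @param judgments Tibble from [read_judgments()] (one row per term with an
#'   established equivalence).
#' @param universe_size Number of terms reviewed (at least
#'   `nrow(judgments)`).
#' @return List with `histogram` (named counts over the five degree values),
#'   `n_equivalent`, `universe_size`, `equivalence_pct`.
#' @export
#' @examples
#' j <- tibble::tibble(source_term = letters[1:3],
#'                     target_code = c("1", "2", "3"),
#'                     degree = c("1", "2", "not_attributed"))
#' summarize_judgments(j, universe_size = 10)
summarize_judgments <- function(judgments, universe_size) {
  if (universe_size < nrow(judgments)) {
    abort("universe_size must be at least the number of judged terms")
  }
  degree <- as.character(judgments$degree)
  bad <- setdiff(unique(degree), equivalence_degrees)
  if (length(bad)) {
    abort(sprintf("unknown equivalence degree: %s",
                  paste(bad, collapse = ", ")))
  }
  hist <- vapply(equivalence_degrees,
                 function(d) sum(degree == d), integer(1))
  n_eq <- nrow(judgments)
  pct <- if (universe_size > 0) {
    truncate_pct(n_eq / universe_size * 100, 1L)
  } else {
    NA_real_
  }
  list(histogram = hist, n_equivalent = n_eq,
       universe_size = as.integer(universe_size), equivalence_pct = pct)
}

#' Write a comparison report as JSON
#'
#' Serializes a `mapping_comparison` (and optionally a judgment summary) to
#' a machine-readable JSON report.
#'
#' @param comparison A `mapping_comparison`.
#' @param path Output path.
#' @param judgments Optional result of [summarize_judgments()].
#' @export
write_comparison_report <- function(comparison, path, judgments = NULL) {
  payload <- list(
    n_terms = comparison$n_terms,
    categories = comparison$categories
  )
  if (!is.null(judgments)) payload$judgments <- judgments
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
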