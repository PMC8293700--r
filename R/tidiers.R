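#' Tidy a term mapping
#'
#' `tidy()` returns the flat record table (one row per source term, rule and
#' matched concept; `type = "candidates"` returns the 90–99 candidate rows
#' instead). `glance()` returns a one-row summary: per-rule term counts,
#' new-term count and the total number of rule assignments plus new terms,
#' which can exceed the bank size because one term may match under several
#' rules.
#'
#' @param x A `term_mapping` from [map_bank()].
#' @param type `"records"` or `"candidates"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.term_mapping <- function(x, type = c("records", "candidates"), ...) {
  type <- match.arg(type)
  if (type == "records") x$records else x$candidates
}

#' @rdname tidy.term_mapping
#' @export
glance.term_mapping <- function(x, ...) {
  s <- x$summary
  tibble(n_terms = s$n_terms, n_concepts = s$n_concepts,
         !!!as.list(s$rule_counts), n_new = s$n_new,
         n_identical = s$n_identical,
         total_assignments = s$total_assignments)
}

#' @rdname tidy.term_mapping
#' @param object A `term_mapping`.
#' @export
autoplot.term_mapping <- function(object, ...) {
  s <- object$summary
  df <- tibble(
    outcome = factor(c(paste("Rule", 1:6), "New"),
                     levels = c(paste("Rule", 1:6), "New")),
    terms = c(unname(s$rule_counts), s$n_new)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$terms)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Source terms",
                  title = "Terms mapped per rule",
                  subtitle = sprintf(
                    "%d source terms; %d rule assignments + new",
                    s$n_terms, s$total_assignments)) +
    ggplot2::theme_minimal()
}

#' Tidy a manual-vs-automated comparison
#'
#' `tidy()` returns the per-category equality/exclusivity table; `glance()`
#' a one-row summary with both agreement percentages.
#'
#' @param x A `mapping_comparison` from [compare_mappings()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mapping_comparison <- function(x, ...) {
  x$categories
}

#' @rdname tidy.mapping_comparison
#' @export
glance.mapping_comparison <- function(x, ...) {
  cats <- x$categories
  tibble(
    n_terms = x$n_terms,
    agreement_identical = cats$agreement_pct[cats$category == "identical"],
    agreement_new = cats$agreement_pct[cats$category == "new"]
  )
}

#' @rdname tidy.mapping_comparison
#' @param object A `mapping_comparison`.
#' @export
autoplot.mapping_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$categories,
    c("shared_count", "exclusive_manual", "exclusive_auto"),
    names_to = "portion", values_to = "terms")
  df$portion <- factor(df$portion,
                       levels = c("exclusive_manual", "shared_count",
                                  "exclusive_auto"),
                       labels = c("Manual only", "Both processes",
                                  "Automated only"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$terms,
                                   fill = .data$portion)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Terms", fill = NULL,
                  title = "Equality and exclusivity by category") +
    ggplot2::theme_minimal()
}
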