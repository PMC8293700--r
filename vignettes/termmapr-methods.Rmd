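---
title: "Cross-mapping clinical term banks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-mapping clinical term banks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termmapr)
```

## The model

`termmapr` maps each term of a free-text source bank onto the primitive
concepts of a coded, seven-axis target terminology in two phases: lexical
normalization, then a cascade of six matching rules scored with Levenshtein
percent similarity. The underlying assumptions are worth stating plainly:

* matching is **lexical**, not semantic — two terms map because their
  normalized strings (or rule-modified variants of them) coincide, not
  because a human judged them equivalent;
* the source language is Portuguese, which drives the default stopword
  list, the accent handling and the stemmer;
* target concepts are **primitive** (single-axis atoms), so a source term
  is compared against labels, never against composed diagnosis or
  intervention statements, and never against concept definitions.

## Normalization

Three steps, in a fixed order: accent stripping (Unicode canonical
decomposition, combining marks removed), special-character removal
(everything outside ASCII letters, digits and spaces becomes a token
boundary), lowercasing with whitespace tokenization and stopword removal.
The operation is idempotent and maps the output alphabet into `[a-z0-9 ]`.

Two boundary decisions the pipeline depends on:

* **Characters with no ASCII decomposition** (ligatures such as `œ`, other
  scripts) are treated as specials and become separators. Accented Latin
  letters are rescued beforehand by the decomposition step, so Portuguese
  text loses nothing; this is what keeps the output-alphabet invariant
  property-testable on arbitrary Unicode input.
* **A term consisting entirely of stopwords or specials** normalizes to the
  empty string. Such a term cannot be compared against anything; it is
  reported as `new` with a warning rather than silently dropped, so bank
  counts stay complete.

Digits are retained: clinical terms may embed numerals and nothing mandates
their removal.

## The similarity score

All rules score pairs with

$$\mathrm{sim}(a,b) = \left\lfloor \left(1 -
  \frac{d(a,b)}{\max(|a|,|b|)}\right) \times 100 \right\rfloor$$

where $d$ is the Levenshtein distance over Unicode code points, computed in
C++ on the joined normalized string, spaces included, so multi-token terms
compare as wholes. Two conventions are deliberate:

* the denominator is the **longer** string and the percent is
  **truncated**, not rounded — the only simple convention consistent with
  both documented near misses (1 edit over lengths 12/13 gives 92; 1 edit
  over 10/11 gives 90, where rounding would print 91);
* the score is 100 exactly when the strings are equal, which makes the
  match test on normalized strings equivalent to string equality and keeps
  the 90–99 candidate band free of false "perfect" matches.

One caveat: a plausible-sounding monotonicity ("appending a differing
character never raises the score") is false for this score. Appending `ß`
to `ab` against `ba` leaves the distance at 2 while lengthening the
denominator, raising the score from 0 to 33. The distance itself never
decreases under such padding, and the score cannot rise while the padded
side is still the shorter one; the test suite asserts exactly those
provable forms.

## The cascade

Rule 1 compares the normalized source against every normalized label; a
full match stops the cascade (this is the only inter-rule short-circuit).
Rules 2–4 expand orthographic variants on **both** sides — per-token lemmas
from a pluggable lemma table, per-token stems from the bundled reduced
RSLP-style stemmer, and per-token plus whole-term synonyms from a lexicon —
and score every pair of (source variant or source) × (target variant or
label). Rules 5 and 6 are decided by strict token-set containment: target
tokens strictly containing the source's means the target is more
restricted; strictly contained means broader. Their recorded similarity is
100, the score of the shorter side against its own tokens inside the
longer one — the containment is exact by construction.

Parameters that matter, with defaults and why:

| parameter | default | rationale |
|---|---|---|
| match threshold | 100 % | a full match is string equality after normalization |
| candidate floor | 90 % | catches one-edit clinical near misses on 10–13-letter words without flooding review lists |
| enabled rules | 1–6 | the full cascade; any subset can be run |
| variant-expansion cap | 64 | combinatorial substitution over tokens is exponential; above the cap only single-token and all-token substitutions are kept |
| stopwords | 12 Portuguese function words | the step is named by the design, the list is not; bundled and overridable |

Further conventions: the candidate band applies to every rule, uniformly;
candidates are deduplicated per (concept, rule) keeping the highest score;
records are ordered by rule, then similarity, then code, making every run
deterministic; all 100 %-scoring concepts are kept for rule 1 rather than
the first found (codes are unique, labels may repeat; keeping all is
lossless). The recorded "modified form" is the target-side string the
winning comparison actually used (the label itself when the match came
through a source-side variant).

Since no Portuguese stemmer package is available to build on, the default
rule-3 stemmer is a reduced RSLP-style suffix stripper written here:
plural, adverb (`-mente`), a table of common noun/adjective suffixes,
infinitive endings, and a final-vowel strip, each guarded by a minimum stem
length. It is intentionally conservative; it is pluggable precisely because
it is reduced. The default rule-2 lemmatizer is a small bundled
inflected-form → lemma table; real deployments should supply their own.

## The comparison framework

Per-term verdicts collapse to `identical` (a rule-1 match), `new` (no
match) or `other` (rules 2–6 only). Only `identical` and `new` are compared
with manual labels — the manual categories `similar` and
`in_definition` do not partition terms the way rules 2–6 do, so comparing
them would be category error. Agreement uses the manual count as
denominator (the manual process is the reference standard) and is
**truncated** to two decimals; truncation rather than rounding is fixed
once, because published figures of this kind mix both conventions and a
single documented choice beats chasing each printed decimal. The same
truncation (one decimal) applies to the equivalence fraction of the
expert-judgment summary, where degrees on the ISO/TR 12300 scale
(1 lexical+conceptual, 2 synonymy, 3 source broader, 4 source narrower,
plus `not_attributed`) are imported human decisions the package only
validates and aggregates.

## What the synthetic generator emulates — and what it does not

`generate_terminology()` produces unique 8-digit codes, syllable-built
Portuguese-plausible labels of 1–3 tokens and axes drawn uniformly from the
seven-axis set. `generate_bank()` plants seven categories, each engineered
so its expected recovery path is unambiguous: exact copies; accent/case/
hyphen variants that normalize back to their label; pluralized tokens the
default stemmer provably inverts; token substitutions registered in the
emitted lexicon; strict token subsets and supersets of labels; and novel
terms verified at generation time to stay below the 90 % floor against
every label and stem variant, with no containment relation possible. The
default mix (20 % exact, 10 % accent variants, 10 % inflected, 15 %
synonyms, 10 % restricted, 5 % comprehensive, 30 % novel) roughly mirrors
the observed shape of a real mapping run — about a fifth of terms directly
present and a third absent.

Category separation is enforced so the planted truth is well defined; real
banks are messier — terms match under several rules at once, inflections
escape any fixed suffix table, and synonym coverage is far thinner than a
purpose-built lexicon. A green recovery test therefore establishes that the
cascade's machinery routes each relationship type to the right rule, not
that any particular recall would be achieved on hospital data. Label
distributions and clinical frequency statistics are explicitly not
imitated.

## Degenerate inputs and numerical corners

* Empty vs empty string scores 100 (both sides empty only arises for
  unmappable terms, which never reach scoring).
* Percent truncation pre-rounds at 1e-9 so exact ratios like 549/650 are
  not dragged below the boundary by floating point.
* An empty terminology yields no records and no candidates; an empty bank
  yields empty outputs with zeroed summaries.
* Duplicate codes, unknown axes, categories or degrees outside their
  closed sets are rejected on read, never coerced.

## Known limitations

Matching is strictly lexical: hierarchical relationships (`mascara
oxigenio` vs `oxigenoterapia`), meaning equivalences without surface
overlap, and grammatical-class shifts (`traqueostomizado` vs
`traqueostomia`) are invisible to the cascade and surface, at best, as
candidates. The bundled lemma table and stemmer cover a sliver of
Portuguese morphology. The comparison stage reproduces bookkeeping
faithfully but cannot validate expert judgments it merely aggregates.
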