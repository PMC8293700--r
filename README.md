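# termmapr

Automated cross-mapping between a free-text bank of clinical terms and a
coded, axis-tagged nursing terminology, plus the bookkeeping needed to
compare an automated run against a manual (expert) mapping.

## The problem

Health institutions accumulate banks of terms from nurses' records —
thousands of short Portuguese phrases such as *"dor de cabeça"* or
*"pós-operatório"*. Reusing those records, building terminological subsets,
or achieving interoperability requires mapping each term onto a reference
terminology whose primitive concepts carry a numeric code and sit on a
seven-axis model (Focus, Judgment, Means, Action, Time, Location, Client),
as the ICNP does. Doing this by hand over a few thousand terms is slow and
error-prone; `termmapr` implements the automated side and the framework for
comparing it with the manual one.

## The method

**Phase 1 — normalization.** Every source term and every concept label goes
through accent stripping (Unicode decomposition, marks removed),
special-character removal, lowercasing and stopword removal, so that
*"Dor de Cabeça"* becomes `dor cabeca`.

**Phase 2 — a cascade of six matching rules.** Comparisons are scored with
Levenshtein percent similarity

```
sim(a, b) = floor( (1 - d(a, b) / max(|a|, |b|)) * 100 )
```

where `d` is the edit distance. A pair scoring 100 is a match; a pair
scoring 90–99 becomes a *candidate* offered for expert review (this band
deliberately catches clinically dangerous near misses such as
`hipercalemia` / `hipercalcemia` at 92 and `referencia` / `preferencia`
at 90).

1. **Identical** — exact coincidence of normalized strings. A rule-1 match
   stops the cascade.
2. **Lemmatizer** — tokens replaced by their lemma (dictionary form) on both
   sides before scoring.
3. **Stemmer** — tokens reduced to suffix-stripped radicals (a reduced
   RSLP-style Portuguese stemmer is bundled).
4. **Synonym** — tokens or whole terms replaced by synonyms from a lexicon.
5. **Restricted term** — the target's token set strictly contains the
   source's (target more specific: `sala` → `sala cirurgica`).
6. **Comprehensive term** — the target's token set is strictly contained in
   the source's (target broader: `cateterizar bexiga` → `cateterizar`).

A term no rule can map is **new**. One term may match under several rules,
so the number of rule assignments plus new terms can exceed the bank size.

**Comparison framework.** Per-term verdicts (`identical` / `new` / `other`)
are compared against manual labels by set intersection: shared terms are
*equality*, one-sided terms are *exclusivity*, and agreement is the shared
count over the manual count, truncated (never rounded) to two decimals.
Expert equivalence judgments on the ISO/TR 12300 four-value scale are
validated and aggregated, never computed.

Because the real inputs (a licensed terminology release and an unpublished
hospital term bank) cannot ship, the package includes a seeded synthetic
generator that plants each relationship category with ground truth, so the
whole cascade is testable end to end.

## Worked example

```r
library(termmapr)

trm <- generate_terminology(500, seed = 42)   # 500 coded concepts
fix <- generate_bank(trm, n = 200, seed = 42) # bank + ground truth + lexicon
m   <- map_bank(fix$bank, trm, fix$lexicon)
m
#> <term_mapping> 200 source terms vs 500 concepts
#>   matched: 140 (identical via rule 1: 60), new: 60
#>   terms per rule: rule1=60 rule2=0 rule3=20 rule4=30 rule5=20 rule6=10
#>   total rule assignments + new: 200
```

The flat record table uses the fixed 8-column output schema (source term,
rule, similarity, target code/label, the modified form the rule actually
compared, axis, version):

```r
head(tidy(m)[, 1:6], 3)
#>   source_term     rule similarity icnp_code icnp_term       icnp_mod
#> 1 dotes              3        100 10170034  dote            dot
#> 2 vavavuri bufepi    1        100 10232566  vavavuri bufepi vavavuri bufepi
#> 3 pudito silite      4        100 10554644  pudito nedele   pudito nedele
```

Here `dotes` (a planted plural) reached its concept through the stemmer
(rule 3, shared radical `dot`), and `pudito silite` reached `pudito nedele`
through a lexicon synonym (rule 4). The documented near-miss pair scores

```r
similarity_percent(norm_join("hipercalemia"), norm_join("hipercalcemia"))
#> [1] 92
```

— close enough to be offered as a candidate, not equal enough to be
asserted as a match. Verdicts feed the comparison stage:

```r
auto <- verdicts_from_outcomes(m)
cmp  <- compare_mappings(manual_labels, auto)   # manual labels from experts
tidy(cmp)    # equality / exclusivity counts and truncated agreement %
```

A command-line wrapper with subcommands `map`, `compare` and `simulate`
lives at `inst/scripts/termmap.R` (`Rscript termmap.R map --bank B.csv
--terminology T.csv --lexicon L.json --out M.csv --summary M.json`).

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end
(synthetic fixture generation, bank mapping, count invariants) and then
recomputes, from raw strings, the percent similarity of the two documented
near-miss pairs. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
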