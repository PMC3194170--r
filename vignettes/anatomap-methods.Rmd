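---
title: "Lexical mapping of anatomical annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical mapping of anatomical annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatomap)
```

## The problem

Biologists annotate experimental samples with free-text anatomy terms
("mouse liver", "Liver/Kidney", "both ventricles", "colon pinch biopsy").
Anatomy ontologies name the same structures as curated classes with
singular, noun-form, American-spelled primary labels and controlled
synonyms. The gap between the two vocabularies is wide enough that even
very large ontologies directly cover only a minority of real annotation
terms. `anatomap` implements, as reusable and testable components, the
pipeline needed to measure that gap: clean the annotations, index the
ontology's lexical surface, match exactly and phonetically, decompose
composite terms, and score everything against a curated gold standard.

Two matching philosophies are modelled because they expose different
failure modes:

* **Exact mode** accepts only string-identical matches after shared
  normalization. It produces no false positives by construction, at the
  price of many false negatives.
* **Phonetic mode** additionally proposes sound-alike candidates via
  Double Metaphone codes. Proposals are *never* auto-accepted: they model
  a curator-driven workflow, and when evaluation counts unreviewed
  proposals as positives, false positives explode to many times the term
  count -- the cost a curator actually faces.

## Normalization

`normalize_text()` applies, in a fixed order: control/non-printing
character removal, whitespace collapse and trim, case folding,
punctuation and hyphen unification, and British-to-American respelling
from an editable ~40-pair table. The order is fixed so the recorded
provenance (`steps`) is deterministic; each rule tags itself only when it
changed the string. Non-printing characters get their own rule because
they are invisible to a curator but not to a matcher -- a documented
source of irreproducible match counts.

Species handling precedes the rest: `strip_species()` removes whole-word
occurrences of the paired species name and of a vernacular lexicon
("mouse", "Bos taurus", ...), because anatomy matching is
species-agnostic and terms distinct only in species must collapse.
`deduplicate()` then keeps the first occurrence of every normalized
string and logs the collapsed groups.

Both sides of every comparison -- the annotation and the ontology labels
and synonyms -- go through the *same* `normalizer_config()`. Indexes
record a fingerprint of their configuration and refuse comparisons
across configurations.

Misspelling repair (`spellfix()`) exists but is **off by default**:
it replaces a term by an index string at edit distance exactly 1 only
when that neighbour is unique. Automated respelling (like stemming and
lemmatisation generally) is a false-positive amplifier, so it must be
opted into deliberately.

## The matching cascade

`run_matcher()` tries, per term:

1. exact match against indexed labels and (by default EXACT-scoped)
   synonyms;
2. if nothing matched, the enabled *variant stages*, each a query rewrite
   re-entering the exact matcher so every hit is auditable:
   singular/plural rules (`-ies -> -y`, sibilant `-es`, plain `-s`, with
   a Latin-singular exception list: "pancreas" is not a plural),
   adjective-to-noun substitution ("abdominal" -> "abdomen"), and
   shorthand expansion ("both ventricles" -> the two ventricle classes);
3. composite decomposition (below), components matched exactly;
4. in phonetic mode, Double Metaphone proposals.

All variant stages default to off. Each models one documented class of
annotation/ontology mismatch, and keeping them individually switchable is
what lets the synthetic harness attribute recovered terms to stages.

Ranking is deterministic: exact-label before exact-synonym before
variant/composite kinds before phonetic proposals; phonetic proposals
order by (code tier: primary agreement before alternate, word-count
difference, indexed string, class id). The tie-break scheme is this
package's own choice -- any fixed order would do, but a fixed order is
required for testability.

### Double Metaphone

The phonetic encoder is an R implementation of Lawrence Philips' Double
Metaphone algorithm, producing a primary and an alternate code of up to
four symbols per word. Multi-word terms are encoded word by word and the
codes joined in order: encoding whole strings without word boundaries
makes arbitrary multi-word terms collide and inflates false positives.
The implementation is validated in the test suite against hand-traced
canonical vectors (the classic Smith/Schmidt pairs among them) and
against algebraic properties (doubled consonants and interior vowel
changes never alter a code), and the phonetic matcher as a whole is
checked against an exhaustive encode-every-pair oracle.

## Composite terms

Composite annotations pack several entities into one string. Nothing in
"liver/kidney" matches as a whole, yet both components match trivially.
`split_composite()` splits on punctuation delimiters (`/`, `,`, `;`),
conjunctions ("and", "&"), and locative connector phrases ("flushed
from", "derived from", "from") which mark a sample/source boundary.
Plain "of" is deliberately **not** a separator: "left ventricle of
heart" is one entity. A configurable stop-phrase table strips procedure
words ("pinch biopsy", "lavage") that imply a location without naming a
second entity.

`cross_product_match()` matches components independently. Policy `any`
(default) emits every component hit -- composites are treated as
recoverable information, not errors; policy `all` demands every
component hit. When components share tokens ("adrenal cortex, adrenal
gland") the result carries a redundancy flag and is left for a curator:
the annotator may have meant two entities or one, and no heuristic can
decide. Terms that no curator could interpret out of context ("11
different tissues") are routed to `unmatched` with reason
`uninterpretable`; no recovery is attempted.

## Evaluation

`compare_to_gold()` builds a confusion matrix with deliberately
asymmetric units: `tp`, `tn` and `fn` count query **terms**, while `fp`
counts candidate **pairs** -- every wrongly accepted (term, class) pair
plus, when `count_proposals = TRUE`, every unreviewed proposed pair. A
proposal-generating matcher can emit dozens of candidates per term, so
pair-counted false positives legitimately dwarf the corpus size; this
accounting is the only one under which proposal-scale confusion matrices
are arithmetically coherent, and it is what `run_config()` defaults to
in phonetic mode.

Precision and recall are reported at three decimals, coverage at two,
all half-up at report time only; internal values stay full-precision.
Empty denominators yield `NA` ("undefined"), never a silent 0 or 1.
`lexical_overlap()` between two indexes is the Jaccard percentage of
their normalized string sets -- chosen because overlap figures without a
stated denominator are otherwise unreproducible; Jaccard is symmetric
and self-documenting.

## The synthetic corpus generator

No public corpus pairs raw multi-species annotation terms with curated
gold mappings at useful size, so `generate_ontology()` and `corrupt()`
build closed-world benchmarks:

* **Toy ontologies** use a template grammar (anatomical modifier + organ
  noun, e.g. "left kidney", "fetal esophagus") rather than text scraped
  from real ontologies -- the labels are plausible, unencumbered, and
  their morphology (pluralizable heads, adjective-bearing nouns,
  British-respellable words) is known by construction. A configurable
  number of duplicate-label collisions exercises duplicate detection,
  and a configurable fraction of classes carry one EXACT synonym.
* **Corruption classes** mirror the documented mismatch taxonomy:
  `identity`, `synonym_use`, `plural`, `adjectival`, `anglicism`,
  `species_suffix`, `whitespace_punct`, `misspelling_ed1`,
  `composite_delimiter`, `composite_locative`, `shorthand`,
  `process_phrase`, `uninterpretable`. Each annotation records which
  rule produced it and carries a gold set naming every class that the
  source string resolves to (all twins of a duplicated label; both
  components of a composite; empty for noise). Published work orders
  composites as the largest mismatch class but gives no per-class
  frequencies, so the default proportions (composites 17% across the
  three composite-like classes, the rest spread over the remaining
  classes) are this package's own documented choice.
* The species mixture defaults to roughly half human, a quarter mouse,
  a tenth rat and a tail of other vertebrates -- cosmetic realism for the
  species-stripping stage; any mixture is accepted.
* `duplicate_fraction` appends cross-species duplicate rows (same term,
  different species) so that deduplication has real work to do; a
  1097-term corpus with fraction 440/1097 yields a 1537-row raw file
  that collapses back to 1097.

Two generator design points are deliberate. First, the generator and the
matcher share the adjective, shorthand and stop-phrase tables (via
`corpus_match_config()`), making recovery experiments closed-world;
passing different tables to the matcher emulates the real-world table
gap. Second, corruptions are kept *separable*: a misspelling instance is
rejected if a morphological stage could also repair it (e.g. an edit
that just appends "s"), so that toggling one stage changes recovery for
exactly one corruption class. Without this, the stages' contributions
could not be measured independently.

What passing these closed-world tests does **not** show: recovery on
real corpora, where the adjective and shorthand tables are incomplete,
misspellings are not uniformly distance-1, composites nest, and many
terms are simply absent from the ontology. The synthetic results are a
correctness check of the machinery, not a coverage forecast.

## Reproducibility and numerical choices

* All generation is seeded; regenerating with the same spec and seed is
  bit-identical, and the generator restores the caller's RNG state.
* Study outputs carry a UTC timestamp in the *filename* only
  (`matches_<UTC>.tsv`); file contents are timestamp-free so repeat runs
  diff cleanly.
* Rounding is half-up (not banker's) at the printed precision, because
  reported three-decimal figures like 277/286 = 0.9685... must round the
  way the domain's literature prints them (0.969).
* The test suite and the acceptance script use corpora of 1000 terms
  over ~620-class toy ontologies -- large enough that every corruption
  class appears tens of times, small enough to run in seconds on one
  core.

## Known limitations

* OBO flat files only (id/name/synonym/is_obsolete); no OWL, no graph
  structure, no reasoning, no remote ontology services.
* English morphology only, with rule-based singularization; no
  lemmatisation or stemming (deliberately -- both amplify false
  positives).
* The optional Levenshtein stage (off by default) proposes only; true
  fuzzy-matching evaluation is future work.
* Quantitative annotations ("75% kidney, 25% liver") are out of scope;
  they surface as unmatched terms.
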