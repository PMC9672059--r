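---
title: "Interpreting verbatim scientific names against a curated checklist backbone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting verbatim scientific names against a curated checklist backbone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxacade)
library(dplyr)
```

## The problem

Occurrence aggregators receive every specimen or observation record with a
*verbatim* scientific name — the string the data publisher supplied. Before
the record becomes searchable it must be *interpreted*: matched to a taxon
in the aggregator's taxonomic backbone, with synonyms resolved to their
accepted names. When the backbone lacks a name (or holds conflicting
near-duplicates), the record can only be indexed at a coarser rank —
a species-level determination degrades to the genus, an infraspecific
determination to the species, an unknown genus to the family. The quality
of the backbone therefore directly bounds the precision of every
downstream biodiversity analysis.

`taxacade` implements this machinery end to end for expert-curated family
checklists such as the legume (Fabaceae) checklist: Darwin Core Archive
and working-spreadsheet I/O, a verbatim-name parser, an indexed backbone
with synonym resolution and hierarchical fallback, the interpretation
cascade, checklist version diffs and backbone overlap accounting, and an
impact evaluation that quantifies how many occurrences gain a finer
interpretation when a curated checklist replaces an older backbone. A
synthetic-data generator with analytic ground truth makes the entire
pipeline testable without multi-gigabyte aggregator snapshots.

## The data model

A checklist is a tibble with fifteen columns in the Darwin Core taxon
dialect (`checklist_columns()`), one row per name record. Two fields carry
the taxonomy's structure:

* `taxonomic_status` — one of nine values: `accepted`,
  `artificial_hybrid`, `illegitimate`, `incomplete`, `invalid`,
  `misapplied`, `orthographic_variant`, `synonym`, `unplaced`. Every
  status other than `accepted` and `unplaced` points to an accepted record
  through `acceptedNameUsageID`; `unplaced` marks names an expert could
  not confirm or link.
* `taxonRank` — `family`, `genus`, `species`, `subspecies`, `variety`,
  `form` (plus `other` for anything else). For the impact accounting the
  three infraspecific ranks are pooled, giving the four-level ladder
  family < genus < species < infraspecific.

`scientificName` is stored *without* authorship — authorship lives only in
`scientificNameAuthorship`. Many Darwin Core publishers embed authorship in
the name; keeping the two separate makes canonical-name matching and
name-key comparisons unambiguous.

The 19-field working-table format used during collaborative curation
(`read_working_table()`) is consumed as CSV/TSV export rather than native
`.xlsx`: the spreadsheet is an exchange convenience and delimited text
keeps the package dependency-light. `working_to_dwca()` converts it to the
archive dialect, splitting `taxon_name` (which carries authorship) with
the name parser.

### Validation

`validate_checklist()` and `build_backbone()` report — rather than crash
on — the defects real aggregated checklists contain: dangling accepted or
parent pointers, accepted-pointer chains longer than the one-hop contract,
parent cycles, and rank inversions. Only record-level invariants (empty or
duplicate identifiers, unknown status tokens, pointed statuses without a
pointer) abort a write. Chains longer than one hop are still followed to
their accepted terminus during resolution, but flagged.

## The name parser

`parse_name()` uses a deliberately small grammar mirroring how aggregators
tokenize incoming names: first alphabetic token = genus; following
lower-case tokens = epithets; `subsp.`, `ssp.`, `var.`, `f.` (dot
optional) are rank markers; the hybrid sign `×` is stripped and flagged;
everything from the first capitalized or parenthesised token after the
epithets is authorship. Three choices are worth calling out:

* `f.` is a forma marker only *after* an epithet, so `F. Muell.` and the
  filius abbreviation inside authorships are never eaten.
* Only the three infraspecific markers above are recognized; other rank
  designations stay inside the epithet and the name parses at species
  rank.
* Authorship detection is heuristic by necessity — the published archive
  dialect separates authorship anyway, so the heuristic only serves
  verbatim occurrence names, whose tokenization by aggregators is not
  publicly specified.

## The interpretation cascade

`match_name()` implements the cascade, in order:

1. **Exact** canonical + authorship match.
2. **Exact canonical** match when unique; among canonical homonyms,
   authorship acts as a tie-break when enabled.
3. **Fuzzy**: candidates within an edit-distance threshold of the
   canonical, ranked by distance then authorship agreement.
4. The single best candidate's accepted form (synonym resolution via
   `resolve_accepted()`) becomes the interpretation.
5. A best candidate that is *unplaced* cannot supply an accepted name: the
   query falls back one rank (`higher_rank_unplaced`).
6. No candidate at all: the terminal epithet is stripped and the coarser
   query re-matched, recursively down to the family root
   (`higher_rank_no_match`). An infraspecific query falls back to its
   binomial first, not straight to the genus.
7. Two or more equally best candidates surviving all tie-breaks fall back
   to the finest rank they share — their common genus, else the family
   (`higher_rank_ambiguous`).

A family-level root is synthesized at build time when the checklist has no
family-rank record, so the cascade is total: every parseable query
receives an interpretation. When recursion coarsens a query more than
once, the reported `match_type` is the *first* fallback trigger — the
reason the query could not be interpreted at its own rank.

### Distance and thresholds

Edit distance is the optimal-string-alignment (restricted
Damerau–Levenshtein) distance on the lower-cased canonical, computed in
C++: insertions, deletions, substitutions and adjacent transpositions all
cost one. Transpositions matter for names (`daelbata` is one slip away
from `dealbata`, not two). The thresholds in `match_config()` are
length-scaled, the conventional choice for fuzzy name matching:

| parameter | default | role |
|---|---|---|
| `max_edit_distance_short` | 1 | canonicals of ≤ 8 characters |
| `max_edit_distance_long`  | 2 | longer canonicals |
| `genus_max_distance`      | 1 | genus token of a fuzzy candidate; its initial letter must agree |
| `use_authorship_tiebreak` | on | authorship participates in tie-breaking |

The genus constraint guards against cross-genus epithet collisions.
Authorship is a tie-break, never a hard filter: names with diverging
recorded authorities should still match, but authority agreement may
disambiguate otherwise equal candidates. Whether an aggregator's
production tie-breaking includes authorship is not publicly specified, so
the behaviour is a switch rather than a guess. The hybrid flag is ignored
for matching.

## Checklist metrics and comparisons

Three accountings mirror how a curated checklist's impact is measured:

* **Version diff** (`summarize_checklist()`, `diff_summaries()`): accepted
  counts per rank plus a single *synonyms* bucket pooling all seven
  pointed statuses; unplaced records are reported separately and excluded
  from the headline categories. Differences are *absolute* per category
  (a release table reports magnitude of change; a category can shrink),
  with signed deltas exposed alongside.
* **Backbone overlap** (`name_overlap()`): set arithmetic over name keys —
  lower-cased canonical plus normalized authorship — because the two
  systems are independently keyed and only the name strings are
  comparable. Two conservation identities are asserted on every call.
  `per_genus_new_names()` filters the per-genus contributions of newly
  added names above a threshold.
* **Occurrence impact** (`evaluate_impact()`): every occurrence is matched
  against the old and the new backbone; the 4×4 rank-transition matrix,
  the strictly-finer (*improved*) total, per-genus improved counts and the
  residual still-above-species count summarize the change. *Improved*
  means strictly finer interpreted rank; same-rank identity changes are
  counted separately as *reassigned*. `classify_residual()` partitions the
  residual coarse interpretations by cause: infraspecific names landing at
  species level, species-level names landing coarser, and genus-only
  source determinations that no backbone improvement can refine.

## The synthetic-data generator

`generate_checklist()` builds a family-shaped taxonomy from a seeded
pseudo-Latin syllable sampler: one family root, `n_genera` accepted
genera, a long-tailed negative-binomial number of species per genus
(so per-genus threshold accountings have non-degenerate output),
infraspecific taxa, synonym groups (with a sprinkling of the other
pointed statuses), unplaced records and — for the ambiguity corruption
class — engineered pairs of accepted names exactly one edit either side
of an unused probe string.

Two separation rules make corruption semantics provable: epithets within a
genus are pairwise ≥ 5 edits apart (ambiguity pairs excepted), and genus
names sharing an initial letter are ≥ 2 edits apart. A typo of ≤ 2 edits
therefore stays strictly closest to its source name, and the analytic
ground truth can state the matcher's outcome without running the matcher.

`degrade_backbone()` deletes a configurable fraction of species-group
names (never the genus/family scaffold), closed over pointers so the
degraded checklist stays referentially valid; the deletion manifest is the
construction oracle for the overlap and impact accountings.
`generate_occurrences()` draws a true accepted name and a corruption class
per occurrence — `exact`, `synonym_use`, `typo1`/`typo2`,
`unknown_epithet`, `genus_only`, `ambiguous` — and records the expected
interpreted rank under both backbones. Running the full pipeline on a
generated triple must reproduce the implied transition matrix cell for
cell; that equality is the package's end-to-end acceptance test.

The reference study conditions (the `sim_config()` defaults) are a
checklist of roughly 5,000 names, a degrade fraction of 10%, and the
corruption mix 40% exact / 20% synonym use / 15% one-edit typo /
10% unknown epithet / 10% genus-only / 5% ambiguous — a stream dominated
by clean and synonym-using names with realistic minorities of misspellings
and provider-level genus determinations.

What the generator does *not* emulate: real epithet distributions (real
epithets cluster much closer than 5 edits, so real fuzzy matching faces
harder ambiguity than the synthetic stream), authorship variants and
misspellings, nothotaxa beyond the hybrid sign, cultivated and fossil
names, and the multi-source layering of production backbones. Passing
tests demonstrate that the accounting procedures and the cascade contract
are implemented correctly — not that the package reproduces any
aggregator's production match rates on real data.

## Numerical and design notes

* **Determinism**: all generator randomness flows from one seed
  (sub-seeded per stage); matching is deterministic, so identical inputs
  give identical reports. The seeded syllable sampler retries are part of
  the deterministic stream.
* **Monotonicity and its exception**: deleting a matched record never
  yields a *finer* interpretation, and enriching a backbone never coarsens
  one — except through ambiguity: restoring a second equally-close name
  legitimately demotes a previously unique fuzzy match to the shared
  genus. The property tests assert monotonicity on all non-ambiguous
  occurrences and the transition-matrix equality covers the ambiguous
  ones exactly.
* **Unplaced fallback**: whether an aggregator interprets a match to an
  unplaced name at the genus or drops the record is unspecified; the
  package falls back to the next higher rank, keeping the cascade total.
* **Misapplied names** resolve through their pointer like synonyms but the
  resolution carries `terminal_status = "misapplied"` so downstream
  consumers can exclude misapplications.
* **Dual-route verification**: the compiled distance kernel is tested
  against an independent pure-R dynamic-programming implementation; the
  fuzzy stage's candidate choice is tested against a brute-force
  all-names scan that applies the documented candidate rules directly,
  with no indexing or blocking.
* **Problem sizes**: the default test run uses checklists of a few hundred
  names for property sweeps, an ~5,000-name checklist with 5,000
  occurrences for the end-to-end recovery check, and 100 random backbones
  × 50 queries for the matcher-oracle sweep; the acceptance script runs
  the reference study conditions plus a 25-backbone oracle sweep. These
  sizes keep a full verification run in minutes on one CPU while
  exercising every cascade branch thousands of times.

## Limitations

Full nomenclatural parsing (named hybrids, cultivars, autonyms) is out of
scope, as is epithet gender-ending normalization (`-us`/`-a`/`-um`
variants currently count as edits), merging more than two source
checklists with priority ordering, and any claim of bit-compatibility
with a production aggregator matcher, whose complete algorithm is not
public. The published-release metric checks require the deposited
checklist files, which are too large to ship with the package; the test
suite states the expected values and runs them when the files are placed
locally.

## A worked example

```{r example}
cfg <- sim_config(seed = 42)
checklist <- generate_checklist(cfg)
pair <- degrade_backbone(checklist, cfg)
occ <- generate_occurrences(checklist, 1000, cfg,
                            deleted_ids = pair$manifest$taxon_id)

bb_new <- build_backbone(checklist)
bb_old <- build_backbone(pair$old_checklist)

name_overlap(bb_old, checklist)

impact <- evaluate_impact(occ$occurrences, bb_old, bb_new)
impact
glance(impact)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(impact)
```
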