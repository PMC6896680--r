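---
title: "Screening peptidomes for bioactive peptides and cryptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening peptidomes for bioactive peptides and cryptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptides)
```

## The problem

A peptidomic experiment on a protein-rich food ingredient yields a list of
unique peptide sequences per sample and fraction: free peptides below an
ultrafiltration cutoff, tryptic fragments of retained intact proteins, and
fragments from milder buffer extracts. The biological question is which of
these sequences are, contain, or are contained in peptides with documented
bioactivities — ACE inhibition, DPP4 inhibition, opioid, antimicrobial,
antithrombotic, antioxidative and related categories — and whether those
bioactive sequences would plausibly survive, or be produced by, gastric
proteolysis after oral consumption. `cryptides` implements this screen as a
deterministic, fully testable pipeline: peptidome and database containers,
a three-mode substring matcher, summaries by sample/scope/category, a
rule-based pepsin digestion model, and a synthetic-data generator for
validation.

The pipeline starts from peptide lists. Search-engine output handling
(score thresholds, FDR control, raw spectra) is upstream and out of scope;
the only concession to identification exports is that modified-residue
annotations are stripped to bare sequence on load, because all matching is
sequence-level.

## Matching model

For a sample peptide $s$ and a database entry $d$ exactly one of three
relations can hold: $s = d$ (**exact**), $s \subset d$ as a proper substring
(**partial**), or $d \subset s$ (**cryptide**). Exclusivity is defined *per
pair*: a peptide identical to one entry can still be a proper substring of a
second entry and contain a third. The alternative convention — removing a
peptide from the partial search once it has any exact match — changes the
partial-pair count whenever a database holds nested variants of one family
(as the hemorphin family in the bundled database does); we chose the
pair-level convention because it keeps each count a property of the pair
alone and makes the three record sets a partition of all matching pairs.
`partial_match_counts()` reports both a pair count and a unique-peptide
count, because published summaries use both phrasings.

Coordinates are 0-based, half-open, so every reported offset verifies by
`substr(containing, offset + 1, offset + nchar(contained)) == contained`
— an invariant the tests apply to every record. Cryptide records list
*every* start position, overlapping ones included: for multiplicity
statements like "GP occurred on average twice within a containing
sequence" to be well-defined, the within-peptide count must include
overlaps, and the convention has to be fixed somewhere, so it is fixed here
and stated prominently. Output ordering is lexicographic by (sample,
fraction, sample sequence, database sequence), making all reports
byte-stable; two runs on identical inputs produce identical files.

The search itself uses vectorized fixed-string matching (stringi, with
overlap enabled) — at the package's working scale (thousands of peptides,
tens to thousands of patterns) this is the practical choice, and a naive
all-pairs sliding-window scan is retained in the test suite as an
independent oracle; the two are compared field-for-field on a thousand
randomized instances.

## Database semantics

Curated bioactive collections list one peptide under several activity
categories. The container folds such rows into one entry per unique
sequence holding the *union* of its activity labels; category-level
counting later re-expands them, so a sequence with $k$ activities
contributes its full hit count to each of the $k$ categories and column
sums over categories can exceed total hits. Labels are trimmed and compared
case-insensitively, with the first spelling kept; a controlled vocabulary
(`activity_categories()`) is provided but deliberately not enforced, since
category schemes differ between sources. Sequences are case-folded before
validation; rows with non-standard residues (B, J, O, U, X, Z) are rejected
individually rather than failing the file, so one bad row cannot poison a
large load. Both the unique-sequence count and the sequence-by-activity row
count are exposed (`db_counts()`), because published database sizes rarely
say which is meant.

The bundled `bioactive_fixture_db()` holds the 29 literature-reported
bioactive peptides of a deer velvet antler study: five long matched
sequences (haemoglobin fragment, buforin II, an ACE-inhibitor nonapeptide,
a wound-healing peptide, LVV-hemorphin-6), the three free bioactives found
in the fermented sample, and 21 short cryptide motifs with their reported
categories. Hemorphin-4 and hemorphin-5 are included under their
field-standard sequences YPWT and YPWTQ, as the study names but does not
spell them. The companion `velvet_free_peptides()` carries the
ultrafiltrate peptides of both samples (22 FDVA, 9 DVA). One transcription
choice deserves note: the DVA list is published as nine sequences of 5–17
residues, and the recoverable table rows span only 10–17, so the missing
5-residue entry was restored as TYFPH — the only pentapeptide consistent
with the table's own structure (it appears identically, with the same
flanking context, in the FDVA rows).

## Summary statistics

`cryptide_summary()` reports, per group, the number of distinct matched
database sequences, the mean ± SD of their residue lengths, and the total
hit count. The length statistics are **unweighted over distinct sequences**
by default: they pair naturally with the distinct-sequence count. Whether
such averages should instead weight each sequence by its hit count is a
genuine open choice; the hit-weighted variant is available via
`weight = "hits"`. With no hits the counts are zero and the statistics
reported as missing; a single distinct sequence has SD 0 by convention
(there is no dispersion to estimate, not an undefined one). Two scopes are
reported by `run_match()`: *free peptides* (the ultrafiltrate fraction) and
*all peptides* (each sample's fractions pooled to unique sequences before
matching, so a sequence seen in two fractions counts once).

## Digestion model

Cleavage specificity is data, not code: a TSV of positional constraints per
rule, in P4..P1/P1′..P4′ nomenclature (offsets −4..−1 and +1..+4 around the
scissile bond), each constraint either an allowed-set or a forbidden-set of
residues. A bond is a predicted site when at least one rule is fully
satisfied. The packaged `pepsin_pH_gt2` table encodes the published
specificity model for pepsin above pH 2 — cleavage next to the bulky
hydrophobic residues F/L/W/Y, blocked by proline at P1/P1′/P2′ (as the rule
side requires) and by H/K/R at P2. Because the table is data, a lab can
audit the encoding, or add pepsin at pH 1.3 or another protease, without
touching the engine.

Two conventions had to be fixed where the model is silent:

* **Terminal windows.** Positions falling outside the sequence pass
  forbidden-set constraints and fail allowed-set constraints. The practical
  effect is that a cleavable residue adjacent to a terminus still produces
  a site (there is nothing there to forbid), while a rule that requires a
  specific residue in an out-of-range position cannot fire.
* **Bond indexing.** Site $i$ is the bond after residue $i$, for
  $i \in 1..n-1$; terminal "bonds" are never sites.

Fragment enumeration takes all boundary pairs from {0, sites, length},
keeps those spanning at most `max_missed` internal sites, then applies the
length window. For $k$ sites and limit $m$ the pre-filter count is
$\sum_{j=0}^{\min(m,k)} (k+1-j)$, a closed form the tests check against
random sequences; zero-missed fragments concatenate to the parent, and
relaxing either limit never removes a fragment. The defaults —
`max_missed = 3`, fragment length 2–13 — are the gastric-screening settings
used throughout: three missed cleavages reflect incomplete digestion in
vivo, 2 residues is the shortest database entry worth tracking, and 13
bounds the fragment size a single pepsin exposure is credited with
producing. *Survival* of a peptide is equivalent to (site count ≤
`max_missed`) and (length in window); *release* of a target from a parent
requires an exact fragment, i.e. cleavage boundaries (or termini) flanking
the target — mere containment is not enough. A corollary worth knowing:
no rule can cleave immediately after proline, so a motif ending in P (GP,
PGP) is only released when it reaches a parent's C-terminus.

The model is deliberately all-or-none: no kinetics, no cleavage
probabilities, no pancreatin/trypsin stage. It answers "could this fragment
be produced under the stated settings", not "how much of it".

Validation uses a 12-probe panel of expected cleavage sites (hemorphins,
a haemoglobin fragment, and constructed edge cases for each exception:
proline blocking, P2 basic residues, terminal windows). The expected sites
were derived by hand from the rule table before the engine ran on them, so
the panel validates the engine's transcription of the rules; it cannot
validate the rule table against the live reference web tool, and any user
needing certified agreement with that tool should spot-check their own
sequences against it.

## Synthetic data

`generate_peptidome()` emulates the structure of a single-sample LC-MS/MS
peptide list: by default 1500 unique peptides (the scale of the real lists
the pipeline targets), lengths uniform on 5–30 (identification pipelines
rarely report shorter; free peptides are rarely longer), residues i.i.d.
from either a uniform composition or an average vertebrate protein
composition (the `"vertebrate"` preset, which gives realistic chance-hit
rates for G/P-rich motifs). Planted motifs are written over random
stretches of random peptides until the requested insertion count is met.
Ground truth is then **re-derived by scanning the final, deduplicated
peptidome** with an independent sliding-window comparison — never taken
from insertion bookkeeping, because insertions can create or destroy chance
occurrences, and deduplication can merge carriers. Recovery by the matcher
is therefore *exact*, not approximate, and the tests assert equality of
per-motif hit counts, distinct-motif counts and per-category frequencies at
the 1200-peptide scale.

What the generator does not emulate: mass-spectrometric detectability,
ionization bias, the ≥5-residue identification floor (a length option can
mimic it), shared-protein structure between samples, or realistic
inter-residue correlation. Passing recovery tests therefore demonstrates
the correctness of the counting machinery on lists of this shape, not the
biological completeness of any real peptide list.

## Degenerate inputs and errors

Empty files load as empty containers with a warning; empty peptidomes or
databases yield zero-row match tables and zero summaries rather than
errors. Invalid residues reject the record (readers) or raise an error
naming the offending position (digestion, where a silent skip would shift
bond indices). Summary functions refuse records referring to sequences
absent from the database they are summarized against.

## Known limitations

* Matching is exact substring matching only — no mismatches and no I/L
  equivalence, which conservatively undercounts against databases that
  treat isobaric residues as interchangeable.
* The digestion model is a single pepsin stage under one published
  specificity encoding; agreement with any specific simulator depends on
  that simulator's own terminal-window and exception conventions.
* The bundled database is a transcription of one study's reported
  sequences, orders of magnitude smaller than the multi-thousand-entry
  compilations such studies use; counts obtained against it are worked
  examples, not re-estimates of the study's totals.
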