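# cryptides

In silico discovery of bioactive peptides and cryptides in peptidomic data.

Protein-rich foods and traditional ingredients — milk, meat, plant proteins,
deer velvet antler — carry short peptides with documented physiological
activities: inhibitors of angiotensin-converting enzyme (ACE) and of
dipeptidyl-aminopeptidase IV (DPP4), opioid hemorphins, antimicrobial and
antioxidative fragments. Some are present as free peptides; many more are
*cryptides*, bioactive sequences encrypted inside longer peptides and
proteins, waiting to be released by fermentation, processing, or gastric
proteolysis. Given an LC-MS/MS-derived peptide list, `cryptides` answers two
questions a peptidomics lab asks before any wet-lab assay: **which known
bioactive sequences are present or encrypted in my sample**, and **would
they survive (or be released by) gastric digestion after oral consumption?**

## The method

Sample peptides are screened against a database of known bioactive sequences
under three mutually exclusive relations per (peptide *s*, entry *d*) pair:

* **exact** — *s* = *d*;
* **partial** — *s* is a proper substring of *d* (the sample peptide is a
  fragment of a longer known bioactive sequence);
* **cryptide** — *d* is a proper substring of *s*, counting **every** start
  position, overlapping occurrences included.

Cryptide content is summarized per sample and scope (free peptides =
ultrafiltrate fraction; all peptides = fractions pooled to unique sequences)
as the number of distinct matched bioactives, the mean ± SD of their lengths,
and the total hit count; hits are also tallied per bioactivity category,
with multi-activity sequences counting once per category.

Gastric digestion is simulated with positional cleavage rules in
P4..P1/P1′..P4′ protease nomenclature. The packaged table encodes pepsin at
pH > 2: a bond is cut when P1 ∈ {F, L, W, Y} with P1′ ≠ P and P2 ∉ {H, K, R},
or when P1′ ∈ {F, L, W, Y} with P1 ≠ P, P2 ∉ {H, K, R} and P2′ ≠ P.
Fragments are all substrings bounded by cleavage sites or termini with at
most `max_missed = 3` internal sites and 2–13 residues. A peptide *survives*
digestion when it is itself such a fragment; a bioactive is *released* from
a parent when some fragment equals it exactly.

A seeded generator plants motifs into random peptidomes and re-derives
ground truth by an independent scan, so the whole pipeline is validated by
exact recovery, plus brute-force oracles for matching and digestion.

## Worked example

The package bundles the free-peptide (ultrafiltrate) lists of a fermented
(FDVA) and unfermented (DVA) deer velvet antler sample and a database of 29
literature-reported bioactive peptides (see `?velvet_free_peptides` and
`?bioactive_fixture_db`).

```r
library(cryptides)
p  <- velvet_free_peptides()
db <- bioactive_fixture_db()
res <- run_match(p, db)
res$partial_counts
#> # A tibble: 2 × 5
#>   sample n_pairs n_peptides min_peptide_length max_peptide_length
#> 1 DVA          9          9                  5                 17
#> 2 FDVA        24         22                  5                 22
```

Fermentation makes the difference: FDVA's free peptides give 24 partial
matches to known bioactives from 22 peptides of 5–22 residues (mostly
fragments of haemoglobin-derived opioid/antimicrobial/ACE-inhibitor
peptides), while DVA yields 9 matching peptides of 5–17 residues and, unlike
FDVA, no exact match to any free bioactive peptide:

```r
screen <- run_digest_screen(classify_matches(p, db))
screen[screen$mode == "exact", ]
#>   sample fraction      mode  target   parent   flag
#> 1 FDVA   ultrafiltrate exact LVVYPW   LVVYPW   TRUE
#> 2 FDVA   ultrafiltrate exact LVVYPWTQ LVVYPWTQ TRUE
#> 3 FDVA   ultrafiltrate exact VVYPWTQ  VVYPWTQ  TRUE
```

The three free bioactives unique to the fermented sample — myelopeptide MP-2
and two extended hemorphin-5 peptides, the latter known ACE inhibitors — are
all predicted to survive pepsin digestion intact (`flag = TRUE`), i.e. they
would remain bioavailable after oral consumption.

## Documentation

The methods vignette (`vignettes/cryptide-discovery.Rmd`) describes the
matching semantics, the cleavage-rule model and its terminal-window
conventions, the synthetic-data generator, and the package's numerical and
design choices in detail.
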