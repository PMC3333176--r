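---
title: "Methods: accession mapping and LCA binning of 16S rRNA reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accession mapping and LCA binning of 16S rRNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnabin)
```

## The problem

Amplicon sequencing of the 16S rRNA gene is the standard way to profile the
bacterial composition of an environmental sample. Reads are typically
aligned with BLASTN against the SILVA ribosomal RNA database, but SILVA
records identify sequences by accession and by a curated taxonomic path —
not by NCBI taxon IDs. Any analysis that wants to place 16S reads on the
NCBI taxonomy (for instance, to compare them with shotgun data analyzed the
same way) first needs a bridge from SILVA accessions to NCBI taxa.

`rrnabin` builds that bridge as a plain two-column mapping file, then uses
it to bin reads, so the SILVA database itself never needs modification and
the mapping can be regenerated cheaply whenever either source updates.

## The mapping algorithm

The inputs are (a) an NCBI `names.dmp` file, providing taxon IDs for every
name class — scientific names, synonyms, equivalent names and misspellings;
indexing *all* classes raises the chance of a successful match — and (b) a
SILVA "NDS field export": one record per sequence with accession,
semicolon-separated taxonomic path, and organism full name.

For each SILVA record:

1. **Full-name match.** If the full name does not contain a blocked
   keyword (`uncultured`, `unidentified`, `metagenome`; case-insensitive
   substring test) it is looked up in the name hash map, exact case first.
   A hit writes `(accession, taxon_id)` to the mapping file.
2. **Capitalization retry.** On a miss, deterministic case variants are
   tried in a fixed order: all-lowercase, first-letter-capitalized,
   each-word-capitalized (the original form excluded, duplicates dropped).
   The first variant that resolves wins.
3. **Path climb.** Blocked names — and names that still miss after the
   retry — fall through to the taxonomic path, walked from its lowest
   (most specific) element towards the root. Elements containing
   `environmental samples` are skipped; every element gets the same
   exact-then-variants lookup. The first element that resolves supplies
   the taxon. The retry applies to path elements as well as the full name
   because the two lookups are the same operation; restricting it to one
   side would be an arbitrary asymmetry.
4. **Unmapped.** If the climb exhausts the path, the accession is left out
   of the mapping file and counted in the run summary. In practice the top
   of a SILVA path (a domain name) nearly always resolves, but emitting
   nothing is safer than guessing.

Homonyms (one name borne by several taxa) are resolved deterministically:
scientific-name entries outrank other classes, and remaining ties go to
the numerically smallest taxon ID with a warning. Identical inputs
therefore always produce byte-identical mapping files.

## Read assignment

BLAST tabular output (the ubiquitous 12-column dialect) is grouped by
query. Multiple HSPs between one read and one accession are collapsed to
the best bit score so a single reference sequence cannot vote twice. Then,
per read:

* hits with bit score below **Min Score** are dropped;
* of the survivors, only hits within **Top Percent** of the best surviving
  bit score — the band `[best × (1 − p/100), best]` — are retained;
* retained accessions are resolved through the mapping file and the read
  is assigned to the lowest common ancestor of the resolved taxa.

Reads with no rows in the BLAST file are `no-hits` (they can only be
counted when the caller supplies the full read list, since tabular output
omits hitless queries); reads whose hits all fail Min Score are
`unassigned-low-score`; reads whose retained accessions all miss the
mapping are `unmapped-accession`. Every read lands in exactly one bin, so
assigned + special bins always equals the number of reads processed — an
invariant the test suite asserts at every stage.

After tallying, **Min Support** is applied as a push-up, not a discard:
nodes are processed deepest-first in a single sweep, and any non-root taxon
whose count (including reads already pushed into it) is positive but below
the threshold passes its reads to its parent. Because parents are strictly
shallower, one deepest-first pass reaches the same fixpoint as repeated
sweeping; the suite checks this equivalence against a naive iterative
oracle on random profiles. Push-up, rather than discarding, reflects what
the thresholds are for: reads supported by too few neighbors are not wrong,
just not resolvable at that depth, so they surface at a higher rank.

### Parameters

| Parameter   | Default | Units                 | Why this default |
|-------------|---------|-----------------------|------------------|
| Min Score   | 120     | bit score             | conservative floor; chance alignments rarely reach it for ~16S-length reads |
| Top Percent | 10      | % of best bit score   | wide enough to catch equally good references, narrow enough that the LCA stays informative |
| Min Support | 5       | reads                 | suppresses one-off assignments; taxa need corroboration before being reported |

Min Score is applied to the bit score (not the raw score); both are
monotone transforms of each other for a fixed scoring system, and the bit
score is what the tabular format carries.

Raising Min Score can only shrink the assigned set, and widening Top
Percent can only move an assignment to an ancestor-or-self (the LCA over a
superset of taxa is an ancestor-or-self of the LCA over the subset); both
monotonicity properties are tested.

## Profile comparison

External genus-level classifiers export flat tables. The importer reads a
headerless two-column CSV (genus, abundance), resolves genus names through
the same name index and homonym rule, and accumulates unresolvable rows in
a *No hits* bin. Flat profiles place all mass at genus nodes; no hierarchy
is inferred for them. The comparison table takes the union of taxa across
profiles, zero-fills absences, and reports per-sample raw counts alongside
subtree-summarized values `summarized(t) = count(t) + Σ summarized(children(t))`,
whose root value equals the column total — the form in which profiles from
different methods are most comparable.

Raw counts are emitted without cross-method normalization; methods differ
in what they leave unassigned, and any rescaling belongs to the downstream
analysis, not the table.

## The synthetic fixtures

`generate_fixtures()` produces a taxonomy (rooted tree over the canonical
rank ladder superkingdom…genus, species, written in genuine taxdump
dialect, with a share of extra synonym/equivalent-name/misspelling records,
optional homonyms, and one `environmental samples` node under a genus), a
SILVA export whose paths are the true name lineages, and a BLAST table in
which each read's best hit is its true source accession. Stated fractions
of accessions get blocked full names (`uncultured <parent>`), case-mangled
names, or names resolvable nowhere; stated fractions of reads score below
Min Score or receive lower-scoring decoy hits. The manifest records every
intended outcome, so tests can compare pipeline output against ground truth
rather than against re-implementations. Each generator draws from its own
stream derived from `(seed, generator name)`, and equal seeds give
byte-identical files.

Default fixture conditions are 200 taxa, 500 accessions and 2,000 reads,
with perturbation fractions of 0.2 blocked, 0.1 case-mangled, 0.05
unmappable, 0.1 low-score and 0.3 decoy — chosen once as a realistic mix
for a SILVA export and a relaxed-threshold BLAST run, and kept fixed. The
clean parameter-recovery check zeroes *all* perturbation fractions and sets
Min Support to 1: blocked entries legitimately map to a path ancestor of
their source organism, and Min Support deliberately moves reads upward, so
exact source-taxon recovery is only a meaningful expectation when neither
mechanism is in play. Under those conditions the pipeline recovers 100% of
source taxa; under the default mix, per-status read counts equal the
manifest's intended counts.

What the fixtures do **not** emulate: real BLAST score distributions (bit
scores are drawn uniformly within bounds — only threshold behavior
matters), sequence content (no reads or FASTA are generated), chimeras,
multi-copy 16S operons, or the actual size and name messiness of SILVA and
the NCBI taxonomy. Passing tests demonstrate the algorithms are correct on
their contracts, not that any particular biological dataset will map at a
particular rate.

## Numerical and degenerate-input choices

* Dump dialect: fields split on `\t|\t`, trailing `\t|` stripped, CRLF
  tolerated; malformed lines fail with their line number.
* Tree validity is enforced at construction: exactly one self-parenting
  root, no orphan parents, no cycles.
* Duplicate SILVA accessions: last occurrence wins, with a warning (the
  mapping file needs unique keys).
* Empty inputs are values, not errors: empty files parse to empty
  collections, an empty mapping round-trips, `min_support = 1` is the
  identity.
* Score comparisons use `>=` on both thresholds, so a single hit at
  exactly Min Score survives and the best hit always survives its own
  band.
* All ties anywhere (homonyms, equal scores) break deterministically, so
  the same inputs always give the same outputs.

## Scope and limitations

The toolkit consumes BLAST output; it does not run BLAST. Merged/deleted
taxon dumps are not consulted, and RDP/SILVA-website log formats are not
parsed. The test suite exercises the pipeline at desk scale (tens to a few
hundred taxa, up to 2,000 reads; the sizes above are the package's chosen
test conditions) — the algorithms are linear or near-linear in reads and
accessions, but the hash-map build is the memory bottleneck for a
full-size `names.dmp`.
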