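---
title: "Methods: alignment-based taxonomic profiling of de novo peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-based taxonomic profiling of de novo peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metaproteomics normally annotates fragmentation spectra by searching a
sample-specific protein database, usually built from a parallel metagenome.
Building that database is slow, expensive, and biased by extraction,
assembly, and storage differences; when it misses community members the
loss is silent. De novo sequencing reads peptide sequences directly off the
spectra, so it needs no database — but short peptides carry sequencing
errors (isobaric substitutions, fragment inversions, and worse), and exact
string matching throws away most of that evidence.

`denovotax` takes the alignment route: de novo peptides (plus scrambled
decoys) are aligned against a large protein reference with
short-peptide-tuned parameters, per-peptide consensus taxonomies are formed
by one of three lowest-common-ancestor (LCA) rules, and the community
composition is aggregated with decoy-based false-positive control. The same
machinery evaluates how completely a database-search experiment covered the
community, and can extract reference sequences of the identified taxa to
complement an incomplete database.

## De novo input, filtering, decoys

Input is any delimited table with a `Peptide` column; the PEAKS de novo CSV
and DeepNovo TSV dialects are recognized automatically. Peptides are
normalized on read: in-line modification annotations (`(...)`, `[...]`)
stripped, then isoleucine folded onto leucine — I/L are isobaric and
indistinguishable in standard fragmentation spectra, so the whole package
(queries, references, simulators) works on the 19-letter alphabet.

Default quality filters: minimum ALC 70% (PEAKS) or score −0.1 (DeepNovo);
optional maximum |ppm| error, minimum length, and minimum intensity.
Decoys are built one-per-target by uniformly permuting the residues in
front of the C-terminal cleavage site (K/R), keeping length, composition,
and the tryptic signature; non-tryptic endings are permuted over the full
length rather than discarded, which preserves the same null model without
losing data. Duplicate peptides stay separate records (spectral-counting
semantics).

## The sequencing-error simulator

The simulator generates the three error families that dominate de novo
output:

* **Equal-mass substitutions.** All residue multisets up to length 6 are
  enumerated (roughly 177k multisets — orderings are counted analytically,
  never expanded) and grouped into mass classes by quantizing the
  monoisotopic mass at a configurable tolerance (default 1e−4 Da, i.e.
  effectively equal elemental composition; N↔GG and Q↔AG are the canonical
  classes). A sliding window scans each peptide left to right; windows with
  an equal-mass alternative of the configured target length are replaced
  with probability 0.25 by a replacement drawn uniformly over all
  alternative strings of the class (all orderings of a multiset count as
  distinct; the original string itself is excluded). After a substitution
  the scan resumes past the replaced span, so edits never overlap, and the
  peptide mass is conserved within tolerance.
* **Fragment inversions.** The peptide is partitioned left to right into
  fragments of length 2 or 3 (length drawn uniformly per fragment; a
  trailing single residue stays untouched); each fragment is shuffled with
  probability 0.05.
* **Codon-level mutations ("other").** Each residue is reverse-translated
  to a uniformly chosen synonymous codon of the standard genetic code, each
  nucleotide flips to one of the three other bases with probability 0.01,
  and the codons are translated back. A codon that would become a stop has
  its mutated positions re-drawn (mask fixed) until a residue results, so
  peptide length is preserved; translated I is folded onto L like
  everything else.

Levenshtein distances between original and altered peptides calibrate the
rates: inversions at 5% per fragment and substitutions at 25% per window
produce edit-distance distributions comparable to a 5% mutation rate, which
is why those are the per-type defaults.

The **combined dataset** draws one error type per peptide at the observed
per-type occurrence rates (1↔1/2 substitution 6.3%, 2↔2 13.7%, 3↔3 6.3%,
2↔3 3.7%, 4↔4 9.7%, 5↔5 7.6%, 6↔6 6.8%, inversion 16.1%, other 29.7%) and
applies the matching generator at its configured rate. The drawn type is
recorded whenever it is *applicable* to the peptide (at least one
substitutable window; length ≥ 2 for inversions) even if the per-window
dice produced no edit — exactly what one gets by sampling records from the
per-type dataset files. Inapplicable draws are redrawn up to ten times and
then fall back to the always-applicable mutation type, so output
cardinality equals input cardinality. Because short peptides without N/Q or
glycine-pair windows cannot take the 1↔1/2 and 2↔3 types, redraws shift a
few tenths of a percentage point onto the remaining types; this is a
property of the redraw rule, not a tuning choice.

The dataset panel (`make_error_datasets()`) contains 13 members: the seven
substitution length-pairs at the 25% window chance, pooled any-length
substitution at 25/50/100%, inversion at 5%, mutation at the 5% calibration
rate, and the combined dataset. The exact panel composition is this
package's choice; only its cardinality and the per-type constructions are
externally fixed.

## Alignment of short, erroneous peptides

Default alignment parameters are those that work for error-bearing short
peptides: PAM70 (PAM matrices beat BLOSUM62 at short lengths), gap opening
2 / gap extension 4 (low opening cost matters because de novo errors often
insert or delete short mass-equivalent blocks), percent identity ≥ 85,
query coverage ≥ 80 (the useful range is 75–85), contiguous-seed mode for
the external aligner, and at most 25 hits per query. `run_diamond()`
composes the corresponding DIAMOND invocation and additionally disables
low-complexity masking and composition-based statistics, both of which
silently drop short-peptide hits; it requires the external binary on the
PATH.

The **internal engine** used throughout the tests computes exact local
affine-gap alignments with `Biostrings::pairwiseAlignment` under the same
matrix and penalties. Candidate subjects are prefiltered by shared exact
4-mers — the package's own analogue of seed-and-extend, chosen because an
all-vs-all scan of every query against every subject does not pay its way
even at fixture scale; `exhaustive = TRUE` disables the prefilter and is
what the oracle tests use. Setting `min_pident = 0` / `min_qcov = 0`
disables the reporting filters (best local alignments of unrelated pairs
can contain zero identities).

Bitscores for internal alignments come from ungapped Karlin–Altschul
statistics: λ is the positive root of Σ pᵢpⱼ·exp(λ·sᵢⱼ) = 1 and K is
computed by the truncated Karlin–Altschul series over convolutions of the
integer score distribution (validated against the published ungapped
BLOSUM62 values under Robinson–Robinson background frequencies). Applying
ungapped statistics to gapped scores is an approximation, flagged as such;
when an external aligner reports its own bitscores those are authoritative.
E-values are the corresponding K·m·n·e^(−λS). Hits are filtered at a
minimum bitscore of 25 (inclusive: exactly 25 is kept, the boundary
semantics being this package's choice).

## Consensus taxonomy (LCA)

TaxIDs are projected onto the fixed seven-rank ladder
superkingdom→species; intermediate ranks are skipped. Taxonomies load from
NCBI-taxdump-dialect `nodes.dmp`/`names.dmp` or from an 8-column lineage
TSV (from which a tree is rebuilt with synthetic internal ids); tree
invariants (single self-parented root, no cycles) are verified on load.

* **CON** — conventional: the deepest rank at which all hit lineages agree;
  the most stringent rule.
* **W** — frequency-weighted: every taxon's weight is its frequency over
  *all* target (never decoy) hits of the run; a peptide's hit taxa are
  sorted by descending weight (ties broken by ascending taxid), the
  weights are cumulatively summed and normalized over the peptide's taxa,
  and the minimal prefix reaching the cutoff (default 0.6; the crossing
  taxon is included) is reduced by CON. Taxa without global evidence
  receive an infinitesimal weight, so they are retained only in the
  cutoff→1 limit — which makes W at cutoff 1 exactly CON. A 0.8 cutoff
  variant is a documented configuration, not the default.
* **BIT** — bitscore: walking the ladder top-down, hit bitscores are summed
  per taxon at each rank among the hits compatible with the taxa already
  assigned at shallower ranks; a taxon is assigned when its share exceeds
  the cutoff (default 0.6), otherwise the walk stops. Restricting to
  compatible hits guarantees the assigned path is a proper lineage even
  when some hit lineages have gaps at intermediate ranks; with any cutoff
  above 0.5 at most one taxon can qualify per rank.

Decoy queries run through the identical machinery, flagged, and never touch
the global weights.

## Composition and false-positive control

Classified target peptides are counted per taxon at the chosen rank
(peptide counts are the abundance unit). Taxa under the reporting threshold
`freq_cut` (default 5 peptides) are pooled into `"other"` rather than
dropped, so fractions always sum to 1; fractions are over classified
peptides only (the classified-vs-all-queries denominator being this
package's documented choice). The decoy retained-alignment rate — decoy
queries with at least one retained hit over all decoys submitted — is
reported alongside every composition and never influences the fractions.
`spearman_compare()` rank-correlates two compositions over the union of
their taxa (absent taxa count 0, the `"other"` pool is excluded).

`extract_taxon_sequences()` collects all reference sequences projecting to
the identified taxa at a chosen rank (with exclusion lists, optional decoy
proteins, optional query entries) and `complement_db()` merges them into an
existing database with exact-duplicate removal after L-normalization
(clustering-based redundancy removal is out of scope), keeping provenance
tags. The resulting FASTA is also the intended input for external
functional-annotation services.

## Spectral and database-coverage QC

Each query's best retained hit (bitscore, ties by identity, coverage, then
accession) puts it into exactly one of: `exact` (100% identity and
coverage), `exact_tag` (full identity, partial coverage), `aligned`,
`aligned_tag`, or `unmatched`; comparisons against 100 use a 1e−6 tolerance
to absorb tabular rounding. If database-search PSMs are supplied, records
are joined by scan reference when both sides have one, else by normalized
peptide string, and `high_quality_matched_fraction()` reports the share of
ALC ≥ 90 spectra the search matched — a sensitive indicator of database
completeness, since a high-quality de novo spectrum should also produce a
strong peptide-spectrum match whenever its sequence is in the database. The coverage report compares taxon distributions of the
DN_only / DN_all / DB_only / DB_all peptide sets at order/family/genus,
with membership decided on normalized peptide strings (so
DN_only = DN_all ∖ DB_all holds exactly); PSM peptides hitting several
proteins are reduced by CON over the proteins' lineages.

## Synthetic data: what it does and does not emulate

The generators build a full seven-rank taxonomy (deterministic shape,
seeded names), uniform-composition proteomes over the 19-letter alphabet
with `OX=` headers, tryptic digests (cleave after K/R except before P),
and de novo experiments: peptides sampled by a Dirichlet abundance profile,
perturbed by the combined error model, with ALC scores drawn lower for
error-bearing peptides (normal(88,5) vs normal(78,8), clamped to [40,99])
and ground truth recorded per scan.

They emulate the *structure* of real data — header dialects, taxonomy
files, error statistics, score/quality correlation — not its content:
residue composition is uniform rather than biological, proteins share no
homology across species (so cross-species alignment is rarer than in real
communities and species-level assignment is easier), and there is no
spectrum-level noise, retention time, or intensity structure. Passing tests
therefore demonstrate the pipeline's correctness and its directional
behaviour (decoy suppression, recovery of abundant families, the effect of
database complementation), not field performance on real instruments or on
databases at UniRef scale.

## Numerical choices and problem sizes

* Isobaric classes: mass keys are `round(mass / tolerance)`; classes are
  quantization bins, so members agree within the tolerance by construction.
* Weight/share cutoffs compare with a 1e−12 slack to absorb cumulative
  floating-point error; qcov/pident against 100 with 1e−6.
* Tie-breaks are always deterministic: taxid ascending in W sorting,
  subject accession lexicographic for best hits, first occurrence wins at
  database deduplication.
* Degenerate inputs: peptides shorter than 2 are returned unscrambled and
  uninverted with warnings; empty hit sets yield empty lineages; an
  all-decoy run yields a zero-row composition with a defined decoy rate.
* Every stochastic component takes an explicit seed and is bit-reproducible
  under it.

The test suite runs the simulator targets at 20,000 peptides, the property
suites at 10,000 peptides (mass conservation, decoy invariants), 500
random pairs (alignment DP oracle), 1,000 random hit sets (LCA oracles),
and the end-to-end recovery on a 10-family / 30-species community with
2,000 simulated peptides under the internal engine — sizes chosen so the
whole suite completes on a single CPU in minutes while keeping binomial
noise well under the tolerances tested.

## Known limitations

* The internal aligner is exact but not fast: it is a validation engine
  and a small-study fallback, not a UniRef-scale substitute for the
  external aligner.
* Internal bitscores use ungapped statistics for gapped alignments; absolute
  parity with external aligners is approximate (the bitscore-25 filter is
  consistent within one engine, comparisons across engines are not exact).
* Custom seed shapes for the external aligner are passed through verbatim;
  no defaults are shipped beyond contiguous-seed mode.
* GTDB or other taxonomies are supported only when supplied in taxdump
  dialect; no cross-release name reconciliation is attempted.
* The PEAKS dialect is recognized by its `ALC (%)`/`ALC` header; other
  export variants may need the generic dialect with a `Peptide` column.
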