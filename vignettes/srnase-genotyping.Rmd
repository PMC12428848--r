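---
title: "S-RNase genotyping of apricot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{S-RNase genotyping of apricot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SRNaseTyper)
```

## The biological model

Apricot carries a gametophytic self-incompatibility (GSI) system: the
haploid pollen grain expresses one S-haplotype, and the pistil arrests
any pollen tube whose haplotype matches either of its own two S-alleles.
The pistil determinant is the *S-RNase* gene. Its second intron sits
inside the RHV, the hypervariable protein region between the conserved
C2 and C3 domains, and varies enormously in length between alleles
(90–1749 bp across the packaged reference). That length polymorphism is
the genotyping handle: PCR with universal *Prunus* primers anchored in
the conserved regions yields fragment sizes that shortlist alleles, and
product sequencing confirms or refutes the shortlist.

Two things the fragment assay cannot do shape the rest of the design.
First, the S_C haplotype — the self-compatible allele found in some
European cultivars — has an *S-RNase* coding region identical to S_8's;
the haplotypes differ by a 358 bp insertion in the pollen-side *SFB*
gene, so a separate fragment assay on SFB (roughly 500 bp for SFB_C
versus roughly 150 bp for SFB_8, after a shared RNase-positive screen)
is the only way to separate them. `resolve_sc()` encodes exactly that
decision tree. Second, some cultivars yield only one amplifiable allele
on every primer pair. Whether that reflects a large unamplifiable
intron, a complex genetic background, or true homozygosity cannot be
decided from the data, so the package reports "one allele detected" and
never imputes a homozygous genotype.

## The packaged tables

The reference ships as three CSV fixtures transcribed from the published
tables: `alleles.csv` (46 alleles in long format, one row per
allele × primer pair, with fragment and intron sizes and GenBank
accession labels), `primers.csv` (the five universal pairs with their
IUPAC-degenerate sequences), and `genotypes.csv` (168 cultivars with
origin, area and 1–2 allele labels). Known transcription quirks are
deliberately preserved and surfaced by `lint_reference()` rather than
silently fixed: two alleles (S15, S16) share one accession label; three
alleles print slightly different intron sizes on different primer pairs
(e.g. 409/410/411 bp); and the printed row numbering contains duplicated
indices, so rows are renumbered sequentially — counts, not indices, are
the contract. The printed table also contains five known alleles with
introns shorter than the 180 bp that the source text quotes as the
known-allele minimum; the package reports what the table contains.

`"SC"` is a reserved label: legal in genotypes, never in the reference
(it has no fragment profile of its own).

## Allele calling

`call_alleles()` works per observation (cultivar, primer pair, size,
optional product sequence):

- **size_tol = 5 bp.** Gel-derived sizes are integers and the smallest
  same-pair gaps between reference alleles are a few base pairs (700 vs
  704, 884 vs 885), so 5 bp absorbs measurement noise while keeping the
  table separable through the sequence step.
- **Nearest-size rule.** Among alleles within tolerance, the unique
  nearest size wins; *equally* near candidates are a genuine tie, and a
  tie is never broken silently — without sequence evidence the cultivar
  is flagged ambiguous. This is what the 884/885 and 700/704 near-pairs
  demand.
- **id_threshold = 99%.** Same-allele products align at 99–100%
  identity in practice; the threshold admits sequencing noise without
  admitting the next-closest allele.
- **Sequence primacy.** When a product sequence rejects every
  size-shortlisted allele but matches another reference allele at or
  above threshold, the sequence prevails and the call is recorded with
  `sequence_only` evidence; if a size shortlist existed it is flagged as
  a fragment/sequence conflict. This mirrors how such discrepancies are
  actually resolved at the bench — by trusting the clone sequence — and
  it is what makes perfect recovery possible when gel noise occasionally
  drifts a size beyond tolerance.
- **Never truncate.** A cultivar with more than two surviving labels is
  flagged ambiguous in full rather than trimmed to two.

`classify_novel()` requires the complete S-RNase architecture (all four
conserved domains) before it will call anything novel; a sequence
missing domains is "unclassifiable", never novel. Novelty then means an
intron length matching no reference allele within tolerance *and* an
RHV string unseen in the reference. `name_novel()` continues the
numeric series (suffixed labels like S14a and split labels like S18-1
collapse to their base numbers), so a reference ending at S107 mints
S108.

## Annotation

`find_intron()` assumes the single-intron model: genomic =
exon1 + intron + exon2 with the intron length fixed by
`nchar(genomic) - nchar(coding_ref)`. Every GT..AG-consistent split is
scored by exact identity of the concatenated exons to the coding
reference; the best split wins and ties go to the leftmost placement —
a stated convention of this package, since equally good placements have
no principled winner. The identity floor defaults to 0.95: loose enough
to tolerate simulated noise, far below the 0.99 practical same-allele
identity, so real mismatches still surface as "no valid splice".

Translation (`deduce_protein()`) drops trailing partial codons and
trims a terminal stop. With an explicit frame, internal stops are
*flagged* (kept as `*`, offsets in an attribute), never silently
truncated; automatic frame selection picks the unique stop-free frame
and errors, listing offsets, when none exists.

Domain models are an editable fixture (`domain_motifs.csv`) of
position-specific allowed-set patterns with a default allowance of one
mismatch. The published figures mark where C2/C3/RC4/C5 fall but do not
print motif content, so the packaged blocks are this package's own
consensus choice; they echo the translations of the universal primer
annealing regions (the C2 block contains HGLWPSN, the C3 block
WNKHGT), which keeps synthetic sequences structurally faithful to how
the real primers sit inside the conserved regions. Scanning takes the
best-scoring placement per domain, leftmost on ties, and enforces the
canonical C2 < C3 < RC4 < C5 order, dropping and reporting violators.
The RHV is then simply the protein segment between C2's end and C3's
start. All coordinates are 0-based half-open.

## Diversity statistics

The one substantive convention is the **frequency denominator**: the
total number of *detected* allele occurrences in a stratum, not twice
the accession count. A mono-allelic accession contributes one
occurrence. East China pins this down: 5 occurrences of S11 among 16
detected occurrences gives the published 31%, whereas 5/20 would give
25%. Percentages round half-up to integers (regional profiles) or one
decimal (the heterozygosity summary), matching the printed convention.
An allele counts once per accession. National Chinese statistics include
the `UnclearChina` rows; the regional profiles cover the five named
regions plus Xinjiang and exclude them.

## Compatibility

GSI semantics: pollen is rejected iff its single haplotype matches
either pistil allele. Two complete genotypes sharing 0/1/2 alleles are
fully compatible / semi-compatible / incompatible. S_C is modeled as
universally accepted pollen — S_C in the *pollen* parent makes a cross
fully compatible regardless of sharing — and its pistil-side behaviour
is not modeled further. Mono-allelic genotypes make relations
undetermined (except a two-allele overlap, which is already
incompatible), and undetermined cells are exported distinctly, never
promoted. Cross-incompatibility groups collect cultivars with identical
complete genotypes; mono-allelic cultivars form provisional singletons.

## Phylogeny

The tree pipeline mirrors the field's desktop practice: p-distances on
aligned C2–C5 amino-acid segments, Poisson correction
d = −ln(1−p) (monotone, ≥ p, saturating at p = 1 where the package
errors rather than extrapolates), Saitou–Nei neighbor joining, and
column-resampling bootstrap.

Design choices made where the source is silent:

- **Pairwise deletion** of gap sites is the default (complete deletion
  is a switch). Pairwise deletion preserves the signal of short RHV
  indels — the very feature that distinguishes close allele pairs.
- **Tie-breaking.** Q-criterion ties are broken by the
  lexicographically smallest pair of cluster labels (a cluster is
  labeled by its smallest leaf). A creation-order index rule would be
  equally deterministic but not invariant under reordering of the input
  taxa, and support values should not depend on row order; for taxa
  supplied in label order the two rules coincide.
- **Negative branch lengths** are clamped to zero with the total
  deficit recorded in the `clamped` attribute.
- **Bootstrap** resamples alignment columns with replacement under a
  caller-supplied seed (recorded in the result's attributes); supports
  are the percentage of replicates containing each original internal
  bipartition. The same seed yields byte-identical output.

The multiple alignment itself is an input, as in the original analysis
chain; the package reads aligned FASTA and the analysis driver shows a
trivial gap-padded block alignment for synthetic sequences. The
published clade structure is only checkable with the real GenBank
sequences, which are not shipped; the packaged tree demonstrates the
reproducible pipeline, not those clades.

## The synthetic-data generator

`make_allele_sequence()` builds, per allele, a genomic record with the
full designed architecture: a GT..AG intron of exactly the designed
length inside the RHV-coding region, the four domain blocks in order,
and a primer-pair site whose amplicon size equals intron length plus
exonic footprint, exactly as the reference table relates fragment to
intron sizes. Three layouts cover the footprint range: primers flanking
the whole C2–C5 core (large footprints), primers flanking only C2–C3
with RC4/C5 downstream of the reverse site (intermediate), and primers
embedded inside the RHV-coding DNA itself (small footprints, e.g. the
86 bp exonic footprint of S10's 266/180 profile) — the last mirroring
how the real universal primers anneal within the conserved regions. The
generator chooses primer expansions and reading phases so the translated
record is stop-free, verifies its own output by running the annotation
module, and retries with fresh filler on the rare pathological draw
(e.g. an accidental equally-good splice placement). Everything is a
pure function of (spec, seed).

`make_panel()` draws two alleles per accession independently from a
frequency vector (Hardy–Weinberg-like); identical draws collapse to a
single listed allele, mimicking mono-allelic rows, because no published
genotype was ever homozygous-called — the generator stays honest about
what the assay cannot distinguish. A `force_het` switch reproduces
all-heterozygous panels. Fragment sizes are the designed reference sizes
plus integer-rounded Gaussian noise (gels report whole base pairs),
default `noise_sd = 0`.

What the generator does *not* emulate: chromatograms and base-calling
error, cloning artifacts and PCR chimeras, primer annealing
thermodynamics (degeneracy is matched set-wise, mismatch 0 by default),
amplification failure of large introns, and real sequence homology
between alleles (RHVs are random, so synthetic trees have no
phylogenetic signal). Passing the end-to-end tests therefore shows the
pipeline's logic is sound under controlled truth, not that wet-lab
error modes are handled.

## Problem sizes and numerical notes

The shipped checks run at desk scale, chosen to exercise every code
path while staying quick: the full 168-cultivar table for all
diversity/compatibility statistics; a 200-accession synthetic panel at
`noise_sd = 2` for end-to-end recovery (about 0.6% of sizes drift
beyond the 5 bp tolerance, exercising the sequence-primacy path); 100
random additive trees (n ≤ 8) for NJ recovery; 50 synthetic genes for
splice placement; 100 random templates for the in-silico PCR oracle;
and n = 1000 panels for frequency recovery, where the observed
frequency is compared within three binomial standard errors plus a
small allowance for the known collapse bias (collapsing homozygous
draws to one listed allele shifts detected-occurrence frequencies by
about 1–2% at these allele frequencies; the bias vanishes as allele
frequencies shrink).

Numerical conventions: percentages round half-up (the printed tables'
convention, not R's round-half-even); NJ branch lengths are written
with 12 significant digits, ample for the 1e-9 additive-recovery
tolerance; distance saturation (p = 1) is an error, not a cap.

## Known limitations

- The SFB assay is modeled at fragment-size level only; no SFB
  sequences are shipped or simulated.
- S_C pistil-side behaviour is not modeled.
- The annotation module assumes the single-intron model; multi-intron
  genes are out of scope.
- Real GenBank sequences are optional external data; nothing in the
  package downloads them.
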