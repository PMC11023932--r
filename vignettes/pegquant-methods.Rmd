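---
title: "Models and methods behind pegquant"
author: "pegquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pegquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegquant)
```

# Scope

`pegquant` quantifies the read-level outcomes of prime editing and the
screen- and RNA-level measurements that surround it: on-target outcome
frequencies in amplicon sequencing, off-target conversion at diagnostic
nucleotides derived from the pegRNA 3' flap, CRISPRi reporter-screen
enrichment statistics with pseudogene nulls, and integrity binning of
pegRNA-derived small-RNA fragments. A set of seeded synthetic-data
generators emulates the statistical structure each stage assumes, so the
whole pipeline is testable end to end without sequencing data. This
vignette records the models, the parameters that matter, and the design
choices made where the design was genuinely open.

# On-target outcome quantification

## Coordinates, nick and window

All coordinates are 0-based, half-open, on the + strand of the stored
amplicon. The protospacer is located by exact spacer match plus an IUPAC
PAM check on both strands; zero or multiple matches are errors, because an
amplicon that cannot anchor a unique nick cannot be quantified. The Cas9
nickase cleaves the protospacer-containing strand 3 nt 5' of the PAM; the
cut coordinate `c` means cleavage between positions `c - 1` and `c`, and
edit positions +1, +2, ... count 3' of the nick on the nicked strand.
For minus-strand protospacers every operation is computed on the nicked
strand by mirroring, so results are strand-coherent (verified by
reverse-complement tests).

The quantification window is the half-open interval
`[c - w, c + w)` with half-width `w = 10` by default. Published analyses
choose per-edit window sizes; when one is known it can be passed
explicitly, and in all cases the window is auto-expanded to contain the
intended-edit footprint and clipped to the amplicon. Because insertion or
deletion edits shift coordinates 3' of the nick, the window is derived
separately on the reference and the expected-edit allele, each containing
its own footprint.

## Alignment model

Reads are aligned globally (Needleman-Wunsch with affine gaps, Gotoh
three-state recursion, implemented in C++) against both alleles with
match +5, mismatch −4, gap open −20, gap extension −2 — a gap of length
L costs `−20 − 2L`. `N` never matches. These are deliberately
indel-averse amplicon-scoring parameters: a single mismatch costs 9
relative to a match, the cheapest possible gapped detour costs 44, so
substitution-only discrepancies are never explained away with gaps.
The scores are integers, which makes score ties exact, and the traceback
tie-breaks are fixed (diagonal preferred, then gap-in-read, then
gap-in-reference; within a gap state, extension preferred over opening),
so every read has one canonical alignment. The test suite exploits this:
an independently written plain-R aligner with the same documented
conventions acts as a brute-force oracle, and classification must agree
with it on 100% of randomised cases.

A read is assigned to the allele with the higher alignment score. Score
ties go to the reference by default — the conservative choice, since it
can only understate the intended-edit frequency — and the tie-break is
configurable. If the identity of the winning alignment (matching columns
over alignment length) is below 0.6, the read is `UNALIGNED` and excluded
from the denominator; 0.6 is the conventional identity floor of amplicon
quantifiers. The quality filter interprets "q30" as a minimum mean read
Phred score of 30, with no per-base masking.

## Indel scoring and the five frequencies

A read is *indel-containing* iff any insertion or deletion of its
canonical alignment touches the window on its assigned allele: deletions
by half-open interval overlap, insertions when their left anchor (the
reference base immediately 5' of the inserted run) lies in the window.
The half-open anchor convention makes boundary cases unambiguous. The
four aligned classes (`HDR_CLEAN`, `HDR_INDEL`, `REF_INDEL`, `REF_CLEAN`)
plus `DISCARDED_QUALITY` and `UNALIGNED` partition every input read.
Frequencies are all reported over `n_aligned`, the four aligned classes;
the two total frequencies are computed as sums of their component
frequencies so the accounting identities hold bitwise.

# Off-target quantification

The 3' DNA flap is the reverse complement of the RT template (U pairing
as A), written 5'→3' along the nicked strand from the nick. Walking the
flap along an off-target amplicon, the first position at which the
amplicon differs is the diagnostic nucleotide; if the flap is exhausted
without a mismatch the site is not quantifiable by this method and an
error is raised rather than a guess returned. Reads are aligned to the
off-target reference only; reads with window indels (half-width 10
around the off-target nick) are counted as indel reads and excluded from
base calling, and remaining aligned reads carrying the flap base at the
diagnostic coordinate are converted. Reads that are both converted and
indel-containing are counted once, as indel reads — the nucleotide-level
frequency tables that this mirrors exclude indel reads — and
`f_offtarget = (n_converted + n_indel) / n_aligned`. An amplicon `N` at
a compared position counts as a mismatch (hence a candidate diagnostic
site) but never as converted.

# Reporter-screen statistics

Counts below 50 are raised to 50 in each sorted population independently.
"Imposing a minimum" could also mean dropping rows; flooring preserves
the library and stabilises log-ratios of barely-detected sgRNAs, and a
`filter` mode is provided for sensitivity analysis. After flooring, zero
counts are impossible and no further pseudocount is added.

The sgRNA phenotype is
`log2((count_pos/total_pos) / (count_neg/total_neg))` minus the median
raw enrichment of the non-targeting sgRNAs, making phenotypes invariant
to per-sample sequencing depth and exactly centred (the centring is
applied twice if a floating-point residual survives the first pass).
Gene scores per transcription start site average the 3 strongest sgRNA
phenotypes by absolute value, keeping the sign; with fewer than 3 sgRNAs
all are used. Multi-TSS genes collapse to the TSS score of largest
magnitude — the collapse rule is a package convention, since per-TSS
scoring does not itself dictate one.

Hit calling in the original analyses uses an external hierarchical
mixture model over sgRNA phenotypes; this package exports its input
table verbatim and implements its own testable significance stage: an
empirical null from pseudogenes of 5 non-targeting sgRNAs scored exactly
like genes, `empirical_p = (1 + #{|pseudo| ≥ |gene|}) / (1 + B)`,
Benjamini-Hochberg FDR, hits at FDR ≤ 0.01. Hit sets from the two
methods are not expected to coincide exactly. Pseudogene membership is
sampled without replacement within each pseudogene; the default builds
disjoint groups (`floor(n_nt / 5)` of them), and a with-replacement mode
resamples any number `B` of pseudogenes when the empirical-p resolution
`1/(B + 1)` needs to be finer than the non-targeting pool allows — with
a few hundred disjoint pseudogenes the smallest attainable p-value
(~1/201) cannot reach FDR 0.01 after multiplicity correction over
thousands of genes, which is a property of the statistic, not of any
particular dataset.

# Small-RNA fragment integrity

Only properly paired, sense-strand fragments enter the analysis; a
BAM/SAM reader (via Rsamtools) reduces each concordant pair to the
interval its fragment spans. Fragments are assigned to the annotation
minimising the sum of endpoint distances
`|Δstart| + |Δend|` among overlapping annotations (ties: shorter
annotation, then name); the sum-of-endpoints metric is a documented
choice where "closest match" admits several readings. The three bins
encode the functional reading of pegRNA anatomy: *cis-active* fragments
retain both the spacer 5' end (start ≤ 5' tolerance, default 3 nt) and
the 3' extension (end ≥ L − 3' tolerance, default 3 nt); *trans-active*
fragments retain only the extension; everything else — any fragment
whose 3' extension is truncated — is *inactive*. The published bin
definitions live in supplementary material not reproduced here, so the
tolerances and the rule are explicit, configurable parameters rather
than a claimed transcription of that source. Coverage uses half-open
intervals, so the profile sums exactly to the total fragment length.

# Synthetic-data generators

All generators take an explicit seed, use R's default Mersenne-Twister
locally, and restore the caller's RNG state; identical seeds give
byte-identical outputs, and every dataset ships a truth table.

**Amplicon reads** are drawn from a programmed mixture over the four
aligned outcome classes (default 25/5/10/60%), written as full-length
copies of the reference or edited allele. Indel classes receive one
indel, length uniform on 1-5 nt with deletions twice as likely as
insertions, placed uniformly inside the quantification window — where
nick-associated indels concentrate — but never overlapping the
intended-edit footprint: an indel that erased the edited bases would
make "edited with indel" and "indel without edit" biologically and
alignment-wise indistinguishable, so the generator keeps the programmed
classes observable. Substitution errors are i.i.d. per base (default
0.1%, bounded at 5%); qualities are constant Phred 37 by default with an
option to vary them so the quality filter is exercised. The generator
does not model quality-dependent or homopolymer errors, PCR duplicates,
chimeras or unmerged pairs, so passing recovery tests demonstrates
correctness of the accounting, not robustness to every real-world
artefact.

**Screen tables** emulate a pooled CRISPRi library: 5 sgRNAs per gene,
log-normal baseline abundances (sdlog 0.5, a realistic library skew),
negative-binomial counts with variance `mu + dispersion * mu^2`
(dispersion 0.01 by default, 0 giving Poisson sampling) around a mean
depth of 500 reads per sgRNA, and planted regulator genes whose first
`active_per_gene` (default 3 of 5, since CRISPRi sgRNAs vary in potency)
sgRNAs have their marker-positive expectation multiplied by
`2^effect`. The default non-targeting pool is 1,001 sgRNAs — odd, so
the non-targeting median is an order statistic and centring is exact in
floating point.

**Fragments** are generated either from programmed bin proportions
(endpoints drawn uniformly within each bin's admissible region) or from
a geometric 5'/3' truncation model whose closed-form expectation the
tests check against simulation.

# Validation problem sizes

The test suite validates, among other properties: exact frequency
identities over 1,000 random tallies; oracle agreement on 500 random
read/allele pairs (amplicons ≤ 60 nt, ≤ 2 mutation events); recovery of
the programmed outcome mixture within 3 binomial standard deviations in
≥ 95 of 100 seeds at 10,000 reads per seed; off-target recovery of a
programmed 3% conversion + 1% indel rate at 5,000 reads; null screen
calibration at 20,000 genes (non-targeting median exactly 0,
Kolmogorov-Smirnov statistic of the empirical p-values against uniform
< 0.05, 5% exceedance within 3 standard deviations — including the
Beta order-statistic term from estimating the threshold on a finite
pseudogene sample); recovery of 20 planted regulators (|effect| = 2,
3 of 5 sgRNAs active, depth 500) in a 2,000-gene screen with 20,000
resampled pseudogenes, requiring ≥ 18 of 20 in the top 40 by |score|
and the top planted gene at FDR ≤ 0.01 in ≥ 90% of 20 seeds; and exact
coverage conservation plus multinomial recovery of programmed fragment
bins at 10,000 fragments. `scripts/acceptance.R` re-runs the same
computations from scratch for a given seed and writes the resulting
numbers as JSON.

# Known limitations

- Reads must be single-end or pre-merged full-length amplicon reads in
  the amplicon's + orientation; no paired-end merging and no orientation
  detection.
- No genome-scale alignment: references are desk-scale amplicons or
  pegRNA sequences supplied directly.
- The off-target method requires a diagnostic nucleotide; loci whose
  downstream sequence matches the whole flap cannot be quantified this
  way and are reported as errors.
- The empirical FDR stage is a pseudogene permutation test, not a
  mixture model; its hit set is calibrated but can differ from
  mixture-model hit sets near the threshold.
- The three-bin fragment rule is a configurable functional reading of
  pegRNA anatomy, not a transcription of any published supplementary
  definition.
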