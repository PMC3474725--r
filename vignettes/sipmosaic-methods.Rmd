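---
title: "Methods: mosaic operon attribution and SIP metagenomics with sipmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic operon attribution and SIP metagenomics with sipmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipmosaic)
```

## The scientific problem

Aerobic naphthalene degradation genes travel in operons (*nah* in
*Pseudomonas*-type hosts, *nag* in *Burkholderiales* such as *Ralstonia*
sp. U2 and *Polaromonas naphthalenivorans* CJ2). In a contaminated aquifer,
stable isotope probing (SIP) with ^13^C-naphthalene lets the DNA of active
degraders grow dense enough to separate on a CsCl gradient; sequencing the
heavy fraction then reveals *who* consumed the label and *which* catabolic
gene variants they carry. A recurring observation in such communities is a
**mosaic operon**: a gene cluster whose segments derive from two distinct
parental operons, evidencing homologous recombination after horizontal
transfer.

`sipmosaic` implements the computational chain for this kind of study:

1. **Mosaic attribution** — classify every position of a query operon by
   parent of origin against two references, summarize per gene, and call
   donor segments with recombination breakpoints.
2. **Variant quantification** — recruit metagenomic reads to a panel of
   operon variants and report per-variant read fractions, plus detection of
   reads physically linking two genes.
3. **SIP taxon analysis** — nearest-reference 16S classification per
   fraction and heavy-versus-light enrichment calling.
4. **In-silico PCR** — IUPAC-degenerate primer matching and virtual
   amplification, for primer screens and amplicon sizing.
5. **Biosensor kinetics** — normalization of whole-cell reporter
   bioluminescence by culture density and induction-onset calling.
6. **Synthetic community generation** — every input above, with ground
   truth, so the whole chain is testable offline.

## Pairwise alignment substrate

All sequence comparison is built on an affine-gap Needleman–Wunsch
implemented in C++ (global, and semi-global with free end gaps on the
reference only). Homology assessment in studies of this kind is usually
done with BLAST or alignment editors; an in-package aligner keeps
attribution self-contained and bit-reproducible. Three choices matter:

* **Scoring.** Default `match = +5`, `mismatch = -4`, `gap_open = -10`,
  `gap_extend = -1` (EDNAFULL-like). A gap of length $L$ costs
  $\mathrm{open} + (L-1)\,\mathrm{extend}$. Gaps are penalized strongly
  because operon variants are collinear: their differences are almost
  entirely substitutions.
* **Identity.** matches / alignment columns, counting every column in the
  aligned span (gap columns are non-matches). This makes identity monotone
  under added gaps. For semi-global alignments the span excludes the free
  reference overhangs.
* **Determinism.** The traceback tie-break is fixed (diagonal > up > left),
  and the semi-global end column prefers the leftmost best column, so
  alignments are identical across runs and platforms.

The test suite checks the scores against two independent oracles (full
enumeration of alignment paths, and a memoized recursion that charges gap
runs straight from the definition) on every two-letter sequence pair up to
length 4 and on a large seeded sample of longer pairs, plus
`Biostrings::pairwiseAlignment` under the mapped gap convention. A full
sweep of all pairs up to length 8 with a path-enumeration oracle is not
computationally reasonable in pure R (hundreds of thousands of pairs with
up to $2.6\times10^5$ paths each), so longer pairs are covered by the
sampled sweep; the sample size (400 pairs per run) makes a surviving score
defect implausible.

## Mosaic attribution

The query is aligned **globally and independently** to each parent, and
both alignments are projected onto query coordinates. A simultaneous
three-sequence alignment would be quadratically more expensive and is not
what "homologous bases between X and Y" means operationally; two pairwise
comparisons are faithful to that reading and deterministic.

For each query position with base $q$: the position *matches* a parent iff
the parent symbol aligned to it equals $q$; a gap never matches, and `N`
matches nothing. Labels: `A_SPECIFIC` (A only), `B_SPECIFIC` (B only),
`SHARED` (both), `NOVEL` (neither). A query base absent from a parent is
thereby counted as non-homologous to it.

**Informative sites** are the `A_SPECIFIC`/`B_SPECIFIC` positions — the
only positions carrying donor signal. `detect_segments()` takes maximal
same-donor runs of at least `min_run` informative sites as segments;
shorter runs are absorbed into the flanking segment with more informative
sites (ties to the preceding one). Because the true recombination switch
between two informative sites is unidentifiable, a breakpoint is reported
as the **interval** between the last informative site of one segment and
the first of the next, never as a point.

Per gene, `summarize_gene()` reports the four label percentages (summing
to 100), the two per-gene identities
($\mathrm{id}_X = \%X\text{-specific} + \%\text{shared}$), and a call:

* `A_LIKE` / `B_LIKE` when one identity leads by `call_margin`
  (default 2 percentage points);
* otherwise `MOSAIC` when both donors contribute informative runs of at
  least `min_run` (default 3) sites within the gene;
* otherwise `NOVEL` when the novel percentage exceeds `novel_threshold`
  (default 5% — point mutations in a real mosaic are sparse);
* otherwise `UNINFORMATIVE`.

Margin-first ordering means a gene dominated by one donor is called for
that donor even if a short opposing run exists; `MOSAIC` is reserved for
genes where the two identities are genuinely close. Published per-gene
"percent similarity to each parent / neither" figures are ambiguous about
whether shared sites count toward both parents, so the package reports
**both** the four-way partition and the two pairwise identities and makes
no attempt to reproduce any figure-only arithmetic.

## Read recruitment and variant fractions

Each read is compared to every variant on both strands. Aligning every
read in full against every ~10 kb operon would cost ~$5\times10^6$ DP
cells per pair; instead exact 13-mers sampled every 7 bases along the read
vote for a reference diagonal, only the voted strand is aligned, and the
alignment is banded (±40) around the seeded diagonal inside a padded
window. Wherever a seed exists this reproduces the unrestricted
semi-global alignment (verified in tests); a read with no seed against a
long reference scores identity 0 there, which is harmless because its own
variant seeds essentially always (at 0.5% read error the chance that all
~40 sampled 13-mers are damaged is negligible). Short references
(≤ `max_full_len`, e.g. 16S genes) instead fall back to a full-length
alignment, so no related read is dropped.

A read is `unrecruited` below `recruit_min_identity` (default 0.80 — a
conservative homology floor; "related reads" has no standard operational
definition), `assigned` to the top variant when its identity lead over the
runner-up reaches `assign_margin` (default 0.005), else `ambiguous`.
**Fractions are computed over confidently assigned reads only**, with
ambiguous and unrecruited counts reported alongside — published read
fractions rarely state their denominator, so this package states its own
prominently.

Reads drawn from a *mosaic* operon are intrinsically ambiguous against the
donor parent of the segment they come from (the sequences are locally
identical up to sparse novel sites). Mixture-recovery experiments therefore
use a panel of mutually diverged variants (pairwise ≥ 5%), where every
position is variant-specific; the ambiguous tally is the honest output for
the mosaic-plus-parents case.

`find_linking_reads()` returns assigned reads whose aligned span covers at
least `min_overlap` (default 20) bases inside each of two gene intervals —
the in-silico form of "a single read links gene X and gene Y", evidence
that a complete operon exists on one molecule.

## 16S classification and enrichment

The taxonomic stage is a deliberate **nearest-reference stand-in** for a
database pipeline (the original analyses of such data use dedicated
taxonomic software against curated 16S databases, which a self-contained
package should not re-implement): each read is aligned to a small
user-supplied panel and takes the taxon of its best reference if identity
reaches `min_identity` (default 0.97, the conventional species-level 16S
threshold); identity ties between taxa are `UNCLASSIFIED` rather than
guessed. Abundances are percentages of classified reads per fraction, with
the unclassified count carried in the result.

Enrichment of taxon $t$:
$\mathrm{ratio}_t = (H_t + c)/(L_t + c)$ with pseudocount $c = 0.5$
percentage points; $t$ is called enriched when
$\mathrm{ratio}_t \ge 5$ and $H_t \ge 1\%$. These are declared heuristics:
in gel-based SIP studies enrichment is read qualitatively off band
intensities, so the package states a numeric rule rather than pretending
to reconstruct one.

## In-silico PCR

Primer sites are matched with IUPAC degeneracy (a code matches any base of
its set) and up to `max_mismatch` mismatches (default 0), on both template
orientations; the reverse primer is matched as its reverse complement
downstream of the forward site, products longer than `max_product_len`
(default 10 kb) are discarded, and footprints may not overlap. A read-set
screen calls a primer pair `POSITIVE` when at least `min_hit_reads`
(default 5) reads contain a site for either primer — single-primer
evidence suffices because short fragmented reads rarely span a product;
the threshold is a declared proxy for a "strong band". 3′-anchored
mismatch weighting (real polymerase chemistry) is deliberately not
modelled.

The shipped primer table carries the study's real primer sequences: the
cluster pair whose product is the 4973 bp *nagFCQED* cluster, and the
*Comamonas*-type/*Pseudomonas*-type naphthalene dioxygenase screening
pairs. Because the deposited accession for the cluster cannot be assumed
present offline, `synthetic_nag_region()` generates a clearly-labelled
synthetic template embedding those primers with the documented 4973 bp
geometry (and an internal *Comamonas*-type NDO site, no
*Pseudomonas*-type site); it exercises amplicon sizing and screening
logic, and is not the deposited sequence.

## Biosensor kinetics

The reporter readout is **relative bioluminescence**: luminescence divided
by OD~600~ per well and time point, exactly and elementwise; a well with
non-positive OD is rejected as unusable. Replicate wells (typically 4) are
averaged per time point before calling. Induction onset is the earliest
time at which the induced series reaches `fold_threshold` (default 2)
times the vehicle control **at two consecutive points** — the two-point
rule guards against single-point spikes; the fold default is a declared
choice, as reporter induction is usually described qualitatively. No
background subtraction is applied (none is defined for this readout).

## The synthetic community generator

The generator is the package's experimental design, not a test fixture:

* **Parent operons.** Twelve genes in the canonical *nag* order
  (*nagAa–G–H–Ab–Ac–Ad–B–F–C–Q–E–D*), with round stand-in lengths summing
  to 10,200 bp (the artifact does not claim these equal the real gene
  lengths). Parent B substitutes bases independently per gene (default
  10%); parents are equal length so donor truth maps one-to-one onto
  mosaic coordinates. Indel divergence between parents is a documented
  extension point.
* **Mosaic.** Segments copied from their planned donor, then sparse novel
  point mutations (default 0.5% per base) forced to differ from **both**
  parents, so truth labels are exact by construction under a diagonal
  alignment. One caveat is inherent to optimal alignment rather than to
  the generator: in a dense mismatch run the affine aligner occasionally
  prefers a compensating gap pair over three or more mismatches
  ("shift pockets"), which can re-label a handful of informative sites as
  `SHARED` (never as the wrong donor — inside an A segment the query
  equals parent A, so a B-specific label is impossible except at a novel
  site). In practice well under 1% of informative sites are affected at
  10% parent divergence; segment and breakpoint calls are insensitive to
  this because they rest on informative-site runs.
* **Reads.** Lengths uniform in 30–530 bp (pyrosequencing-like), uniform
  start and strand, substitution rate 0.5% and single-base indel rate 0.1%
  (no homopolymer model in v1); mixture weights default to the three
  variant proportions reported for this kind of community
  (64.3% / 17.7% / 18.0%).
* **SIP pools.** The light pool is the community at its stated abundances;
  the heavy pool draws from labelled taxa re-normalized, except each read
  is background with probability `leakage` (default 5%), modelling
  carry-over of unlabelled DNA into heavy gradient fractions. The default
  community makes the labelled degraders **rare in the bulk community**
  (1.4%, 0.4%, 0.2%) against an unlabelled 98% background, so the heavy
  fraction shows one dominant and two minor labelled taxa — the defining
  SIP signature. Published heavy-fraction percentages (e.g. 55%/1%/0.1%)
  describe the heavy pool of a community whose bulk composition is
  unknown, and a 0.1%-of-heavy taxon is statistically undetectable by any
  threshold rule at simulated pool sizes; the generator therefore emulates
  the qualitative dominance structure, not those exact percentages. The
  classification stage is separately verified to recover a
  55% / 1% / 0.1% / remainder community within three binomial standard
  errors.
* **16S panel.** One random ancestor mutated per taxon (10% each), giving
  pairwise divergences (~18%) comfortably outside the species threshold —
  synthetic stand-ins, not real 16S genes.
* **Determinism.** Every generator is a pure function of one integer seed;
  derived child seeds give each output file its own stream, so
  regenerating one file does not perturb the others.

What passing tests on these synthetics does **not** show: robustness to
homopolymer indel error (the dominant 454 error mode), chimeric reads,
amplification bias, real 16S phylogenetic structure, or reference panels
with shared conserved blocks. The generator's divergences are uniform per
gene, which makes informative sites denser and more evenly spaced than in
real operon pairs; breakpoint intervals on real data will be wider.

## Numerical and size choices

Problem sizes used by the shipped tests and the acceptance script — 50
simulated mosaics on the 10.2 kb layout, one 10,000-read mixture, 20
seeded SIP pool pairs of 500 reads each, 20 kinetic series — were chosen
as the smallest sizes at which the binomial error bands around the study
conditions are tight enough to be meaningful. Fraction recovery is judged
within three binomial standard errors of the planned weights; enrichment
and onset calls are judged exact. Degenerate inputs are defined, not
special-cased: zero informative sites give an empty segment list, an
all-ambiguous read set gives flagged `NA` fractions, an empty read file
gives a zero-count report, and an empty read set screens every primer pair
negative (unless `min_hit_reads = 0`, which is trivially positive and
documented as such).

Coordinates are 1-based inclusive everywhere inside the package — the
native R and GenBank convention, and what the annotation dialects already
use — with the single exception of BED export, converted at the format
boundary. All user-facing reports print 1-based inclusive coordinates.

## Known limitations

* Two parents only; no phylogenetic recombination statistics (those are a
  different tool's job).
* Equal-length, substitution-only parent pairs in the generator.
* The 16S classifier is a stand-in; its absolute abundances depend on the
  supplied panel.
* Read recruitment identity thresholds stand in for an unstated
  "related reads" definition in the source analyses; results should be
  read relative to the stated denominator.
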