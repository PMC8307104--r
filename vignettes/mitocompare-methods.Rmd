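---
title: "Methods and design notes for mitocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompare)
```

`mitocompare` implements the standard analysis battery of comparative insect
mitogenomics — annotation accounting, composition and skew statistics, RSCU,
NG86 Ka/Ks, tRNA cloverleaf structure, and PCG+rRNA supermatrix assembly —
over annotated circular mitogenomes. This vignette records the models, the
tunable parameters, the numerical conventions, and the design choices made
where the method left genuine freedom, together with what the synthetic-data
tests do and do not demonstrate.

## Data model and coordinate conventions

A genome is its major-strand (J) sequence; features are 1-based inclusive
`[start, end]` intervals with strand `J` or `N`. A feature of strand `N` is
analysed in reading direction, i.e. as the reverse complement of its slice.
The intergenic value attached to a gene is the gap to the *next* gene in
genomic order (negative = overlap), and the last feature wraps circularly to
the first, which gives the conservation identity used as a self-check on
every input: sum of feature sizes plus sum of (signed) spacers equals the
genome length.

Ambiguity characters (`N`) are tolerated in sequences; they are excluded
from both numerator and denominator of composition percentages but still
counted in region sizes, and any codon containing one is skipped (codon
usage) or deleted pairwise (Ka/Ks).

The five packaged annotation fixtures were expanded coordinate-first from
their published table; where the printed derived columns disagree internally
with the printed coordinates (three intergenic/size cells across the five
species), the fixtures follow the coordinates. Two further source
inconsistencies (a stated tRNA maximum of 72 bp where no table row exceeds
71; a small-rRNA maximum of 854 bp against a table size of 853) are
annotation-source discrepancies that the package records but does not
resolve.

## Composition and skews

Skew is `(x − y)/(x + y)` with the convention 0 when `x + y = 0` (degenerate
all-A/T or all-G/C regions). Regional statistics concatenate member-feature
sense-strand sequences in genomic order; the "all genes" row is the whole
circular genome on the J strand, control region included, which is why its
size equals the genome length. Codon-position statistics pool PCG
sense-strand sequences by strand class with the frame anchored at the
initiation codon; bases of incomplete stop codons ("T", "TA") keep their
frame positions, so the three position totals may differ by a few bases.
Whether published codon-position blocks include stop codons is generally
unstated; the inclusive convention is used here because it reproduces the
characteristic unequal position totals (e.g. 3729/3727/3726 for a genome
whose PCGs carry remainders of 1, 1 and 2 bases). Report output rounds
percentages to 1 decimal and skews to 2; all internal computation is at full
precision.

## Codon usage and RSCU

The genetic code is fixed to translation table 5 (invertebrate
mitochondrial: TGA=Trp, ATA=Met, AGA/AGG=Ser), giving family sizes k = 2 to
8 (Leu 6, Ser 8). RSCU(c) = n_c·k/Σ_fam n; families with zero usage score 0
throughout. Initiation codons are counted as ordinary sense codons
(including nonstandard ones such as CCG or GTG, which the start/stop survey
flags verbatim rather than correcting); complete stop codons are tallied
separately; incomplete stops never enter codon counts.

## NG86 Ka/Ks

The estimator is the classical Nei–Gojobori (1986) counting method with
Jukes–Cantor correction — the conventional choice for this genre of
analysis. Variants differ in stop-codon handling, so the convention is
stated explicitly: in site counting, mutations that create stops are
excluded and the position's 1/3 weights are renormalised over the non-stop
mutants (hence S + N = 3 exactly for every sense codon); in difference
counting, all orderings of the differing positions are enumerated, pathways
through stops are discarded, and synonymous/nonsynonymous step counts are
averaged with equal weights. In the degenerate case where every pathway
passes through a stop, the average is taken over all pathways and the result
flagged. Proportions at or beyond the Jukes–Cantor pole (p ≥ 3/4) raise a
saturation error rather than returning NaN.

Aggregation across a taxon set is the unweighted mean of defined pairwise
ratios (pairs with Ks = 0 are flagged undefined and excluded); the
alternative mean(Ka)/mean(Ks) is available via
`gene_mean_kaks(method = "ratio_of_means")` because published analyses
rarely state which rule they used. Exact numerical agreement with any
particular legacy implementation is a goal, not a guarantee.

Both kernels are backed by 64×64 lookup tables built once per session, so
clade-level computation is vectorised.

## tRNA cloverleaf folding

`fold_trna()` is a template-constrained search, not free-energy
minimisation: no thermodynamic parameters enter. The template fixes the
acceptor stem at 7 pairs and bounds the other elements (DHU stem 0 or 2–4
with a 3–10 nt loop; anticodon stem 3–6 around a 7-nt loop whose centre is
anchored at the annotated anticodon; TψC stem 3–6 with a 3–9 nt loop;
variable loop 3–9 nt; connectors 1–3 and 0–2 nt; 3' tail 0–2 nt). All bounds
are user-overridable (`bounds =`) since they describe observed structures,
not physical limits. Candidate decompositions are scored 2 per Watson–Crick
pair, 1 per G·U wobble and −1 per retained mismatch — weights chosen to
favour canonical pairing while tolerating the scattered mismatches (U·U,
U·C, A·A, A·G, A·C) real mitochondrial tRNA stems show. Ties are broken
deterministically: higher acceptor-stem score, then DHU stem of the
canonical length 4, then a 4–5 nt variable loop, then the longer anticodon
stem, then enumeration order. A 9-nt anticodon loop (a rare natural variant)
is admitted only behind `relax_ac_loop = TRUE`.

`design_trna()` builds template-consistent sequences with perfectly paired
stems for testing and simulation. By default its unpaired regions (loops,
connectors, tail) are drawn from the non-self-pairing alphabet {A, C}: with
fully random loops, a one-pair stem extension into a loop is frequently a
strictly better fold, so "the generating arm lengths" would not be
identifiable even in principle. Sealed designs make every extension a scored
mismatch; the residual non-recoveries (≈0.1–0.6% of cases) are exact score
ties that the canonical-DHU tie-break resolves toward an equally good
alternative decomposition. Cross-species structure comparison aligns
positions by structural role (arm-relative), not raw index, so species with
different loop lengths remain comparable.

## Supermatrix and smoke tree

`build_supermatrix()` concatenates the 13 PCGs and 2 rRNAs in genomic order
and emits an exact partition table; blocks must be equal length across taxa
(externally aligned real data, or simulator output, which is comparable by
construction). Missing genes abort — no silent gap-filling. Writers produce
FASTA, relaxed PHYLIP, NEXUS with a charset sets block, and RAxML-style
partition text, byte-stably. Maximum-likelihood and Bayesian inference are
deliberately out of scope: the package guarantees bit-exact input files for
external tools. The internal p-distance + neighbor-joining tree
(`p_distance_matrix()`, `nj_tree()`, via `ape`) exists to smoke-test the
pipeline (e.g. simulated-ingroup monophyly via `check_monophyly()`, an
edge-bipartition test); it reproduces no support values.

## The synthetic-data generator

The simulator emulates the statistical structure the analyses assume: the
canonical 38-feature layout (order, strands, lengths, anticodons, start/stop
codons — incomplete stops included) copied from a packaged fixture; regional
A+T fractions defaulting to the compositional profile typical of the study
system (PCGs 0.73, tRNAs 0.70, rRNAs 0.73, control region 0.83); foldable
tRNAs; and clade-structured divergence. Two deliberate idealisations:

- **Overlaps are clipped to abutting genes.** Real mitogenomes overlap some
  genes (e.g. ATP8/ATP6 by 7 bp); generating literal overlaps would let one
  gene overwrite another's codons. Gene lengths are preserved, so the
  simulated genome is ~30 bp longer than its template. Overlap accounting is
  still exercised by the packaged fixtures.
- **The dN/dS control is an acceptance filter, not a codon model.**
  Substitutions are proposed per site at the branch-length rate; synonymous
  proposals are always accepted, nonsynonymous ones with probability omega,
  stop-creating proposals (and changes to the start codon, terminal stop, or
  anticodon triplet) are rejected. This gives monotone, approximately
  unbiased control of dN/dS — sufficient for recovery tests — but no
  transition/transversion structure, no rate heterogeneity, no indels, no
  rearrangements. omega must be positive (a zero rate is outside the
  configuration contract); the limit behaviour is tested at small omega.

Determinism: `make_reference_genome()` seeds the RNG with `seed` and
`evolve_clade()` with `seed + 1`, so a `sim_config` reproduces byte-identical
clades.

Because the generator draws bases i.i.d. within regions, passing tests show
that the *estimators and accounting* behave correctly under the assumed
structure; they do not validate behaviour under real-data features such as
compositional heterogeneity along a gene, context-dependent mutation,
alignment error, or annotation error beyond what the fixtures encode.

## Problem sizes and test design

The dN/dS recovery setting is a 10-taxon clade (8 ingroup, 2 outgroup,
pectinate, uniform branch length 0.05 substitutions/site — intrageneric-scale
divergence) at omega = 0.05/0.3/0.8; replicated runs at omega = 0.3 across
20 seeds estimate a mean ratio of ≈0.33. Mean-of-ratio estimates carry a
small upward Jensen bias that shrinks with divergence; the branch length was
chosen as a realistic value at which short genes (ATP8, 162 bp) still
accumulate enough substitutions for stable ratios. Fold-recovery checks run
1,000 sealed designs drawn uniformly over the template bounds. The
monophyly check uses the 16-taxon setting (12 ingroup, 4 outgroup) that
mirrors the study design.

## Known limitations

- `read_genbank()` is a minimal single-record flat-file reader (simple and
  `complement()` locations only; no `join()`, no multi-record files).
- Wrap-around features (origin-spanning) are modelled conceptually but the
  packaged fixtures and simulator never produce them.
- NG86 only; no ML codon models (GY94), no transition/transversion-weighted
  counting (LWL/YN00), no site-specific omega.
- The cloverleaf search assumes the annotated anticodon is correct; it
  anchors the fold rather than discovering it.
- No multiple sequence alignment: cross-taxon gene comparisons require
  equal-length (pre-aligned or simulator) input.
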