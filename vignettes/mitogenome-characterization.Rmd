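---
title: "Comparative mitogenome characterization: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome characterization: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## What the package computes

`mitocomp` characterizes annotated vertebrate (here: teleost) mitochondrial
genomes the way comparative mitogenomics papers do, and adds the
distance/likelihood/dating machinery used downstream of such
characterizations. The working object is a `mito_genome`: a circular
sequence (optional) plus an ordered table of the canonical 38 features —
13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and the control region
(CR). Every stage consumes this object and returns tibbles, so results
compose with the usual tidyverse verbs.

The package ships the printed annotation table of the *Psettodes belcheri*
mitogenome (GenBank OR231239) as a plain-text fixture
(`extdata/psettodes_belcheri_features.tsv`), together with the published
per-partition composition percentages of that genome and its two
*P. erumei* relatives. These are inputs, not test constants: the
architecture stage recomputes every derived number from the coordinates.

## Gene-architecture accounting

Junction gaps are signed: `start(downstream) - end(upstream) - 1`, so
positive values are intergenic spacers and negative values overlaps.
Published tables attach the intergenic value to the upstream gene row and
count junctions linearly in table order, *without* the closing CR-to-trnF
junction; `architecture_summary()` therefore defaults to the linear chain
and offers the circular closure as an opt-in flag. On the shipped table the
linear chain reproduces the published accounting exactly: 5 overlaps
totalling 14 bp (longest 7 bp at ATP8–ATP6) and 15 spacers totalling 106 bp
(longest 38 bp at trnN–trnC), with 28 of the 37 genes on the heavy strand.
Ties for the longest spacer/overlap break by first occurrence so reports
are deterministic.

Gene orders are compared strand-aware on the circle: each adjacency
`(+a, +b)` is identified with its mirror `(-b, -a)`, and the breakpoint
distance is the number of adjacencies of one order absent from the other.
The built-in reference order is the ancestral teleost arrangement, which
the shipped table matches with breakpoint distance zero.

## Composition and codons

Skews follow the standard definitions `AT-skew = (A - T)/(A + T)` and
`GC-skew = (G - C)/(G + C)`; they are scale-invariant, so counts and
percentages give identical values. Reporting rounds half-up, percentages to
2 decimals and skews to 3, only at the output boundary. Partition
statistics (whole, PCGs, rRNAs, tRNAs, CR) are computed on the deposited
heavy-strand sequence — light-strand genes contribute their plus-strand
substring — matching how whole-sequence partition tables are produced by
genome-wide tools; only the codon stage works on sense strands.

Start codons are reported verbatim (first triplet, no alternative-start
remapping); the stop is classified from the sense length mod 3: remainder 0
yields the final triplet (complete), remainder 1 a single base plus `--`,
remainder 2 two bases plus `-` (incomplete; in vivo these are completed to
TAA by polyadenylation). The vertebrate mitochondrial code is the fixed
translation context.

### Known inconsistencies in the source table

The published record contradicts itself in places, and the package reports
its own arithmetic rather than patching either side:

* the genome length appears both as 16,747 bp (abstract and tables) and
  16,739 bp (text); the shipped table ends at 16,747;
* the printed PCG total (11,427 bp) exceeds the sum of the printed PCG
  sizes (11,413), the rRNA total (2,689) exceeds 961 + 1,702 = 2,663, and
  the CR is printed both as 1,015 bp and as coordinates spanning 1,023 bp;
* three PCGs (ATP6, COIII, ND3) print incomplete stops although their
  printed lengths are divisible by three, which admits only a complete
  triplet.

`partition_lengths()` returns the coordinate sums (11,413 / 2,663 / 1,023),
and the synthetic default plants complete TAA stops for those three genes so
that its codon plan is internally consistent with the planted lengths.

## tRNA cloverleaf folding

Folding is a constrained template search, not free-energy minimization: the
biological claims at stake are arm-level (cloverleaf present, DHU arm
missing, wobble pairs used), so a deterministic, exhaustively enumerable
layout is preferable to thermodynamic folding. The template places an
acceptor stem of 6–7 bp at the termini, a DHU stem of 3–4 bp, an anticodon
stem of 4–5 bp around a 5–9 nt loop with the anticodon at its center, and a
T stem of 4–5 bp, with short linkers and a 3–23 nt variable loop absorbing
the residual length (55–95 nt inputs). Stem positions count only when they
pair as A:T, G:C (Watson–Crick, score 2) or G:T (wobble, score 1); the
maximum-score template wins, with ties resolved in a fixed order (longer
acceptor stem, more Watson–Crick pairs, 5'-most DHU arm, longer anticodon
then T stems). An arm whose realized stem keeps fewer than two legal pairs
is reported missing — this is how the DHU-less mitochondrial serine tRNA
(trnS1, the AGY isoacceptor) is flagged. When the annotation supplies an
anticodon triplet it is used as a hint restricting the search; the scan is
the fallback.

The printed "anti-codon" column of the source table actually contains
codon triplets (e.g. TTC for tRNA-Phe); the package carries them verbatim
as loop-center hints, since folding does not depend on which triplet sits
in the loop. The two leucine and serine isoacceptors are disambiguated by
those triplets (TTA→trnL2, CTA→trnL1, TCA→trnS2, AGC→trnS1), consistent
with the light-strand gene list and the DHU-less serine of the source
genome.

## Control-region analytics

The tandem-repeat scanner is a deterministic period scan: for each
candidate period the sequence is compared with itself at that lag, maximal
runs above the identity threshold are merged greedily, a period-length
consensus is built by column majority, and overlapping reports collapse to
the highest-identity, smallest-period record. Defaults (`min_copies = 2`,
`min_identity = 0.9`) reflect what repeat finders report at control-region
scale (~1 kb); the design trades the probabilistic alignment of classic
repeat finders for exact reproducibility, which is the property the tests
exercise (a planted 72-bp, 2.5-copy repeat is recovered with its exact
span, and 100 i.i.d. null sequences of 1 kb produce no spurious
period-≥20 report).

Conserved sequence blocks (CSB-D, CSB-I, CSB-II, CSB-III) are found by
best ungapped local alignment of a motif library (match +1, mismatch −1,
report threshold 0.6 of the maximum score, i.e. 80% identity). The source
paper gives block lengths (27/36/51/35 bp) but no consensus sequences, so
the shipped library (`extdata/csb_motifs_synthetic.fa`) is a
package-invented, clearly-labelled synthetic stand-in with those lengths:
results on real control regions depend entirely on the motif library the
user supplies, and the synthetic tests plant the shipped defaults.
Variable sites across genomes use the standard definitions: a column with
at least two distinct bases is variable; with at least two bases each seen
twice it is parsimony-informative.

## Distances, likelihoods, model ranking, dating

`k2p_distance()` implements the Kimura two-parameter estimator with
pairwise deletion of ambiguous sites (the common distance-tool default),
separating transition and transversion proportions and flagging saturated
pairs instead of returning spurious numbers; the reported standard error is
the usual delta-method form. `neighbor_joining()` wraps the standard NJ
agglomeration (exact on additive matrices) and clamps negative branch
lengths to zero with a warning.

`loglikelihood()` is a Felsenstein pruning implementation over compressed
site patterns for the nested JC/K2P/HKY/GTR family, with among-site rate
variation as a k-category discrete gamma (mean-per-category, k = 4 by
default). Proportion-invariant is deliberately not modelled: with +G it is
weakly identifiable and model ranking keeps +G only. `bic_rank()` fits each
candidate by coordinate ascent (Brent per branch, bounded 1-D or
Nelder–Mead for model parameters, empirical base frequencies) and ranks by
`BIC = p ln(n) − 2 lnL`, counting branch lengths in `p`; non-converged fits
are flagged but still ranked. The tests verify the likelihood against
brute-force enumeration over internal states (to 1e−9 on 4-taxon, 6-site
instances, with transition matrices from an independent series matrix
exponential) and against an established ML implementation, and verify the
ranking by simulation (the generating model wins in the majority of 20
seeded replicates in both a JC-vs-GTR and a GTR+G-vs-JC design at 10 kb
sites).

Divergence dating is a simplified relative-rate scheme on a fixed rooted
topology, in the spirit of relative-time methods but not a reimplementation
of any published variance machinery: after rooting on the named outgroup
(used for rooting only) relative node heights are computed tips-to-root,
each node taking the mean of its two child path depths — which equalizes
sister-lineage rates — clamped so ages never increase towards the tips.
Calibrations rescale relative heights to absolute ages: one point
calibration fixes the scale exactly; several are combined by least squares
and each must hold within 10% or a constraint conflict is raised; interval
calibrations intersect feasible scale ranges. On strict-clock trees the
scheme recovers node depths exactly; under lognormal branch-rate noise
(sdlog 0.2, 12 taxa) inferred heights correlate with truth at Pearson
≈ 0.99 over 20 seeds. Uncertainty comes from a seeded nonparametric
bootstrap over sites (default 100 replicates) with least-squares branch
lengths on the fixed topology per replicate.

## The synthetic-data generator

`simulate_mitogenome()` produces the inputs every stage needs, with the
ground truth recorded for assertion. Its defaults *are* the study
conditions of the source genome: the printed coordinates, strands, codon
plan (mod-3 reconciled as above), per-partition base frequencies from the
published composition table, a 72-bp × 2.5-copy CR repeat, the four CSB
motifs planted in order, 15 tRNAs with one planted G:T wobble pair and 7
pure Watson–Crick, and a DHU-deleted trnS1. Sampling choices worth knowing:

* PCG interiors are codon-structured — interior codons are drawn from the
  61-codon non-stop set weighted by the partition's base frequencies — so
  the codon stage sees realistic input with no in-frame stops;
* tRNA loops and linkers are drawn from A/C so the planted stems are the
  pairing optimum; the generator additionally rejection-samples (up to 50
  draws per tRNA) until the folder returns exactly the planted arms, making
  "exact arm recovery" a property of the generator, not luck;
* features are written in annotation order, so where the real architecture
  overlaps features (e.g. ATP8/ATP6 by 7 bp, ND4L/ND4, ND5/ND6 on opposite
  strands) the later feature's bases stand; a repair pass restores planted
  tRNA pairs where one partner position is owned by that tRNA alone, and
  the ground truth records the *realized* codons and pair labels read back
  from the final sequence — printed start/stop codons of mutually
  overlapping genes cannot all be co-realized in any single sequence;
* one seed drives everything; the same spec and seed give byte-identical
  FASTA/TSV/GenBank/JSON bundles.

What the generator does not emulate: sequencing error, heteroplasmy,
annotation error, compositional heterogeneity along a gene, secondary
structure of rRNAs, and selection on codon usage. Tests passing on
synthetic genomes therefore demonstrate that the pipeline recovers what its
own model of a mitogenome plants — they do not validate annotation quality
on real records, and CSB results on real data are motif-library-dependent.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single CPU:
likelihood oracles use 4 taxa × 6 sites (exhaustive enumeration), model
ranking uses 4 taxa × 10 kb × 20 seeds per design, NJ recovery 8 taxa ×
5 kb, dating 12 taxa × 20 seeds, and the repeat-scanner null 100 × 1 kb.
Skews are undefined (reported `NA`, never 0) when a base-pair class is
absent; K2P saturation is reported as `valid = FALSE`; NJ rejects
asymmetric or negative matrices; pruning rescales partials per node to
avoid underflow; the gamma discretization uses category means, so its
α → ∞ limit reproduces the rate-homogeneous likelihood to numerical
tolerance.
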