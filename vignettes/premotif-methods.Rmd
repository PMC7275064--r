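---
title: "Methods: mutation-selection simulation and motif statistics"
author: "premotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-selection simulation and motif statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the model

Exonic splicing enhancers (ESEs) are short exon-enriched motifs bound by
splicing activators; intronic splicing enhancers (ISEs) are their
intron-enriched counterparts. `premotif` implements a mechanistic account
of how such skewed motif distributions can arise *before* any splicing
function exists: single-nucleotide mutation rates vary by orders of
magnitude with local sequence context, so highly mutable motifs decay
quickly wherever evolution is free, while purifying selection on the
protein code prevents part of that decay in coding sequence. The joint
effect leaves mutable motifs relatively enriched in exons (pre-ESEs) and
depleted, mutability-coupled motifs enriched in introns (pre-ISEs).

The mutation model conditions on the heptamer (+/-3 nt) context: each of
the 16384 heptamers carries three dimensionless relative rates, one per
alternate middle base. Hexamer-level mutability is the mean over all 18
single-nucleotide changes, averaged uniformly over the unknown flanking
bases needed to complete each heptamer (each flank base counts 1/4;
`NNN[hexamer]NNN`). Arithmetic means are used wherever a "mean rate"
appears.

## The simulator

Sequences are circular (a fixed frame-0 anchor and a length divisible by
3 keep codons consistent across the origin), and evolve one substitution
at a time:

1. each position is assigned the mean rate of its three possible changes
   given its current heptamer;
2. a position is drawn proportional to that weight;
3. an allele is drawn proportional to the three rates;
4. under `constraint = "protein"` the proposal is rejected if it changes
   the amino acid or the mutated codon is a stop; rejected proposals are
   redrawn (position *and* allele) and only accepted substitutions
   advance time. Without constraint every proposal is applied.

This two-stage draw makes the joint proposal probability of (position,
allele) proportional to the substitution's rate, which is also how the
exact oracle below defines the chain. Time is tau = accepted
substitutions / total bases; states are recorded on the grid
`0, record_interval, ..., t_max` (defaults 0.2 and 10 — long enough for
the motif statistics to approach their dynamic equilibrium). Recorded
quantities: the 4096-vector of overlapping circular hexamer frequencies
pooled over sequences (length-weighted), the mean per-site rate, and the
mean activity score of all hexamer windows.

Mutational bias is rescaled by `rescale_bias(erm, beta)`: rates are
log-transformed, multiplied by beta, and exponentiated back, i.e.
`r -> r^beta`. This preserves positivity and rank order, returns the
original table at beta = 1 and uniform rates at beta = 0, and satisfies
the composition law `(r^a)^b = r^(ab)` exactly, which the tests assert.

Design choices worth stating explicitly:

* **Rejection handling.** Rejections are redrawn rather than advancing a
  "proposal clock", because time is defined as mutations *introduced*;
  constrained and unconstrained runs are then comparable at equal
  accepted counts. (The alternative would shrink tau per wall-clock
  proposal in constrained runs without changing the visited states.)
* **Frozen stops.** A random initial genome contains in-frame stop
  codons. Under the literal acceptance rule (no amino-acid change, no
  stop creation) every mutation touching a stop codon is rejected, so
  reference stops are immortal. The enforced invariant is translation
  identity, stop positions included; user-supplied coding sequence
  (`init = "from_fasta"`) is additionally required to be stop-free up
  front. Deadlock (a genome admitting no acceptable change, e.g. all
  Met/Trp) is detected after a bounded number of rejections and raised
  as an error rather than looping forever.
* **Incremental cache.** Only positions within +/-3 nt of a substitution
  change their site rate; the Fenwick tree is updated locally
  (O(log n)), and a full-recompute reference path exists and is compared
  against the cache in the tests.

## The exact oracle

`exact_stationary()` builds, for a single circular sequence of length
L <= 6, the embedded jump chain over all 4^L states whose transition
probabilities are proportional to per-substitution rates (restricted to
accepted moves under constraint, where the reachable synonymous class is
found by breadth-first search and stranded states are reported as
errors). The stationary law is found by damped power iteration
(`pi <- pi/2 + (pi P)/2`, which removes any periodicity concern) to a
sup-norm tolerance of 1e-12. `sim_occupancy()` runs the *same compiled
simulator* used everywhere else on that toy state space and tallies the
state after every accepted substitution. The two are compared by total
variation distance; the acceptance suite requires TV <= 0.02 with and
without constraint. Occupancy is tallied over 5e6 post-burn-in
substitutions: an occupancy estimate over ~4096 states from autocorrelated
draws has a Monte Carlo noise floor near the tolerance at 1e6 steps, and
5e6 (a few seconds of compute) makes the comparison a test of chain
correctness rather than of counting noise.

## Genome-layer statistics

Splice windows reach 300 nt into the intron and 150 nt into the exon on
both sides of every internal splice site, in transcript orientation, with
3 nt of genuine neighbouring sequence kept on each end so that heptamer
contexts within 3 nt of the junction extend into the adjacent feature.
Windows truncated by short exons or introns are kept (with spans
recorded) rather than dropped — dropping would bias the profile toward
long exons — and duplicated splice sites shared across isoforms are
deduplicated by genomic coordinate. Profile aggregation is per-site
(every window position contributes equally); exon/intron summary means
average over all profiled exonic/intronic positions.

Hexamer frequencies use overlapping windows, step 1, never spanning
record boundaries; k-mers containing ambiguous bases are skipped, not
imputed. Enrichment is reported as
`log2((f_exon + pi) / (f_intron + pi))` with pseudo-frequency
`pi = 1/n_windows` of the respective collection (one pseudo-window), a
transform choice that leaves sign and ordering conclusions unchanged;
swapping the two collections flips the sign exactly. Correlations with
activity-score tables are Pearson over the hexamers present in both
tables; `exclude_cpg = TRUE` removes the 1185 hexamers containing the CG
dinucleotide (the count follows the avoid-a-word recurrence
a_n = 4a_{n-1} - a_{n-2}: 4096 - a_6 = 4096 - 2911), mirroring
CpG-free reanalyses.

The simulated analogue of the splice-site profile concatenates, for each
triple, 300 nt of an unconstrained sequence, 300 nt of a constrained
sequence and 300 nt of a second unconstrained sequence (round-robin by
sequence index — the assignment is arbitrary and determinism wins), and
averages site rates per pseudo-position; the first and last 3 positions
of the linear 900-mer have no full context and are NA.

## Protein-layer statistics

Mutation classification uses the standard genetic code: a substitution
reaching TAA/TAG/TGA is a stop gain, one preserving the amino acid is
synonymous, anything else missense; input stop codons are rejected
(stop-loss is out of scope). A hexamer occurrence is associated with the
two codons that overlap it most (overlap patterns 3+3, 2+3+1, 1+3+2 —
the top two are always unique), and pair-level mean activity is the
occurrence-weighted mean over all in-frame hexamer windows. Pair
enrichment is observed adjacent-pair frequency (within proteins only)
over the product of single-residue frequencies; pairs are ordered (400
cells), and the two-proteome contrast is the difference of ratios with
residues pooled across each proteome. Per-mutation activity change
(delta-EI) averages, with equal weight, the score change of the two
hexamers in which the mutated base sits at positions 3 and 4; the
mutation's own mutability is its heptamer-context rate, and aggregation
is the equal-weighted mean over genomic occurrences per (pair, class).
Stop-gain fractions are exact enumerations under uniform weighting
(verified against an independent brute-force oracle for all 400 pairs)
and rate-weighted per occurrence, then averaged over occurrences, under
ERM-context weighting.

## Variant-layer statistics

The M/W splice ratio is `log2((mt_o/mt_i)/(wt_o/wt_i))` on counts summed
over replicates; the default pseudocount is 0 with a hard error on zero
terms (replicate sums make zeros rare), and 0.5 is available. The ratio
is invariant to common count scaling and antisymmetric under swapping
mutant and wild type. Splice-region variants are the first/final 3
exonic nt and are excluded from the synonymous/missense/stop-gain
comparison, which reports medians, quartiles and pairwise two-sided
Mann-Whitney tests. Variant filtering for the frequency analysis removes
missing-DAF records, extremely rare variants (DAF < 5e-5, where
recurrent mutation dominates the frequency spectrum) and out-of-scope
effects, reporting every removal count; bin edges default to the
log-decade grid {5e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1} (unstated in the
source analysis; the grid spans the observable DAF range and is
configurable).

## Synthetic-data generators

Every generator is a pure function of its `synth_spec` (the seed is part
of the spec), and each output passes the corresponding reader without
warnings. The rate table is heptamer-native (completeness is structural,
not lifted from a smaller context): log-normal base rates with
sigma = 0.5 (natural-log scale), transitions boosted 2x over
transversions, CpG-deamination-like changes (C>T before G, G>A after C)
boosted 8x, and G>T with purine neighbours on both sides boosted 4x —
the purine-context hotspot that makes GARGAR stop gains mutable. These
values are standard orders of magnitude for the human point-mutation
spectrum, and together with the log-normal spread they give the table a
several-hundred-fold dynamic range, matching the reported >400-fold
context spread; they were fixed once and are not tuned per analysis.
Score tables hit a target correlation rho (default 0.7) with log hexamer
mutability by additive Gaussian mixing on the log-rate scale
(`rho*z + sqrt(1-rho^2)*eps`, rescaled to sd 0.3), which is analytically
controllable. Gene models take exons from a protein-constrained run and
introns from an unconstrained run at matched tau (default 5, where the
exon/intron mutability gap is well developed); three 240-nt exons
alternate with 300-nt introns per gene. Variant DAFs follow
`10^(-5.5 * Phi(latent))` with `latent` coupling the site's log rate for
coding variants only, so high-mutability constrained sites skew rare and
~a fifth of draws fall below the 5e-5 filter, exercising it. Assay
counts are negative-binomial around class-dependent true odds
(synonymous 0, missense -0.5, stop gain -2 in log2 units, between-variant
sd 0.5, depths ~1000 per replicate, 2 input and 4 output replicates);
with noise sd 0 the generator emits exact expected counts — non-integer,
a deliberate degenerate mode used to verify noiseless recovery of the
planted effects.

What the generators do *not* emulate: GC isochores, repeat structure,
real codon usage, linked selection, finite-population drift, or the
specific rate spectrum of the published human heptamer table. Passing
tests therefore demonstrate that the estimators recover planted structure
of the kind the mechanism predicts, not that any particular quantitative
value from human data is reproduced; analyses whose magnitudes depend on
the real rate table (e.g. the several-fold enrichment of the single most
mutable hexamer, or its ~6-fold depletion counterpart) keep their
real-table character only directionally here.

## Problem sizes

The full-study configuration is 5000 sequences x 999 nt to tau = 10.
The package's analyses and tests run reduced configurations chosen to
keep every qualitative feature while staying desk-sized: the default
pipeline uses 500 x 300 nt to tau = 3; the acceptance computations use
1000 x 999 to tau = 10 for the enrichment endpoints, ten replicates of
the gene-model construction, 5e6-step occupancy runs at L = 6, and
4e6-residue proteomes for the iid pair-enrichment null. All are stated
in the scripts that run them.

## Known limitations

* Reference stop codons in random-initialization constrained runs are
  frozen rather than purged; their frequency (~1/21 of codons at t = 0)
  slightly dilutes coding-like structure relative to real exons.
* The jump-chain oracle covers L <= 6; longer circular sequences are
  validated only through invariants and convergence diagnostics.
* Pair enrichment pools residues across a proteome; no per-genome
  normalization is applied for multi-genome aggregates.
* The strand-specific rate table is applied in transcript orientation;
  analyses mixing strands assume the table's strand asymmetry is part of
  the signal, as in the source data.
* `classify_splice_region` requires exonic positions; intronic variants
  must be flagged upstream.
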