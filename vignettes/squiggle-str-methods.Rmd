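---
title: "Calling STR lengths from raw nanopore signals: models and methods"
author: "squiggleSTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling STR lengths from raw nanopore signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squiggleSTR)
```

## The problem

Short tandem repeats (STRs) are stretches of DNA in which a short motif
(1–6 bp) is copied many times in a row; the copy number is polymorphic and,
for dozens of loci, clinically decisive.  Nanopore sequencing reads are long
enough to span even expanded alleles, but basecalling is least reliable
exactly inside repetitive sequence, so length estimates taken from the
basecalled letters are biased.  This package instead measures the repeat
length directly in the raw current signal ("squiggle"): the signal is
aligned to a finite-state model of the locus and the length is read off the
alignment path.

## The locus model

A locus is written as a small repeat expression: IUPAC nucleotide symbols,
skippable blocks in braces, and repeat groups in parentheses that must be
traversed at least once.  `(CAG)` models a pure trinucleotide repeat;
`(CAGG{CAGM})` models a CAGG repeat interrupted by occasional CAGA or CAGC
(M = A or C).  When no expression is supplied, `autogenerate_expression()`
derives one from the reference sequence: every maximal run of exact motif
copies becomes a repeat group and everything in between stays literal, so
re-instantiating the expression with the observed run lengths reproduces
the reference region exactly.

The expression, together with the two flanking sequences, is compiled into
a nucleotide-level automaton (flanks are simple chains; repeat groups get a
back edge realizing "at least once, arbitrarily many") and then expanded
into k-mer space: each state is a length-k path of the base automaton and
carries the expected current level of its k-mer from a pore model.  Two
states are connected when their k-mers overlap by k−1 *and* the underlying
base transition exists.  Two design choices matter here:

* **Positional identity.**  States are identified by the pair (k-mer
  string, base-automaton end state).  Identical k-mers arising at
  different structural positions stay distinct, because repeat counting is
  positional: an automaton that merged them could not tell an extra
  traversal from a revisit.
* **IUPAC expansion at k-mer time.**  Pore models are defined over
  A/C/G/T only, so ambiguity symbols branch into one concrete state per
  allowed nucleotide during the expansion, not in the model lookup.

For every locus two automata are built — forward, and the forward
construction applied to the reverse-complemented, order-reversed
expression with swapped reverse-complemented flanks — and a read's mapped
strand selects which one it is aligned to (the signal is always used in
native temporal order).

Homopolymer repeat units (e.g. `(A)`) would create k-mer self-loops that
the alignment recurrence cannot distinguish from ordinary dwell; they are
outside the supported locus class, which matches the benchmarking practice
of restricting to 2–6 bp units (`str_locus_filter()`).

## Signal preparation

Per read, the two flanks (default 110 bases) are located in the basecalled
sequence by local alignment (match +1, mismatch −1, gap −1; a hit must
score at least 0.7 × flank length, and the left hit must end before the
right one starts).  The basecaller's base-to-signal ("move") map then
excises the raw signal between the outer flank boundaries, half-open on
event starts.  Reads failing these checks are rejected and tallied, never
fatal.

The segment is normalized with the median strategy:
shift = ½(perc₄₆.₅ + perc₅₃.₅), scale = medianᵢ|rᵢ − shift| (percentiles
interpolate linearly between order statistics), giving values with median
absolute value 1.  Normalization is computed on the extracted segment
(flanks + STR) rather than the whole read: the segment is what is aligned,
and locus-local deviation is precisely what the subsequent polishing step
corrects.

## Alignment with minimum dwell

The normalized signal *s₁…s\_m* is aligned against the automaton by a
dynamic program over subproblems "best cost of aligning the first *i*
points, ending in state *j*": each point aligned to state *j* costs
|sᵢ − eⱼ| and a state may be entered only from itself or a predecessor.
Because consecutive expected levels can be similar, the program additionally
requires a minimum number *s* of points per visited state (default 4),
implemented as a countdown carried in the DP state, so the complexity grows
only by the factor *s*.  The path must start in the first left-flank
context at the first point and end in the last right-flank context at the
last point (global alignment over the segment).  Cost ties prefer staying
in the current state and then predecessors in lexicographic k-mer order,
which makes warping paths fully deterministic.  The core loop is compiled
(Rcpp); the test suite checks it cell-for-cell against an independent
run-length formulation on a randomized grid of small automata.

The STR length is the number of path transitions whose destination state
lies in the repeat region — one per consumed repeat base, flanks
contributing nothing — and per-group repeat counts are the numbers of
traversals of each group's (and each optional block's) entry boundary,
which is how an interrupted locus can be reported per repeat unit.

One property worth noting: with anchored ends, the optimal cost is *not*
monotone in signal length (a longer signal can admit a cheaper feasible
path), so no such invariant is asserted anywhere.

## Polishing

Median normalization assumes the segment looks like random sequence; a long
repeat violates that, so normalized values systematically miss the pore
model scale.  After a first alignment pass, all points aligned to state *j*
are pooled into mean *mⱼ* and population SD *σⱼ*.  Pairs with
|mⱼ − eⱼ| > 2.0 or σⱼ > 1.5 × median σ likely contain misassigned points
and are dropped; the rest become control points of a recalibration
*f: observed → expected*, fitted as a cubic smoothing spline (smoothness by
generalized cross-validation, falling back to linear interpolation below 10
distinct control points) and extended linearly with the boundary slope
outside the observed range.  With fewer than 8 retained pairs polishing is
skipped (identity) with a warning.  Applying *f* pointwise never changes
the signal length and, being monotone in practice, preserves value order.

A pure *global affine* miscalibration is removed exactly by median
normalization (the normalization is affine-equivariant), so the polishing
tests plant *piecewise-affine* (kinked) distortions — the simplest
miscalibration normalization cannot touch.  The suite also carries a
crafted regression read in which a steep local miscalibration blasts a
small in-event wobble out to the exact levels of one extra repeat cycle:
the first pass walks the spurious repeat, and the spline learned from the
rest of the read compresses the wobble back so the second pass drops it.

## Adaptive event-size restriction

A fixed dwell floor of 4 points can swallow genuinely short consecutive
events.  The first-pass alignment is therefore split into windows of
*m* = 6 events; each window is scanned with a sliding Welch's t over
half-windows of *p* points (default 3), using the population-variance
convention t = (S̄₁ − S̄₂)/√((σ₁² + σ₂²)/p) — zero pooled variance yields 0
for equal means and ±∞ otherwise.  Strict local maxima of |t| at or above
3.0 (ties resolved to the earlier index) count as context changes; a window
with more changes than events presumably lost short events, and the second
pass lowers its dwell floor by one.  A run's requirement is taken from the
window containing the run's first signal index.  The defaults for
*p* and the |t| threshold are deliberately surfaced in the configuration
and echoed into every report, since they are operating-point choices rather
than derived quantities.

## Genotyping

Per-locus length estimates are filtered (drop estimates further than 2
sample SDs from the mean; a zero SD keeps everything) and clustered with a
two-component Bayesian Gaussian mixture: Dirichlet weight prior with
concentration 0.25, tied variance, 5 random initializations, up to 1000
variational updates, fixed seed.  The mixture is written out in this
package as a one-dimensional mean-field variational scheme (Dirichlet prior
on weights, Gaussian priors on means, a single tied Gamma precision); no
installed R package provides a Dirichlet-prior Bayesian GMM, and an
established non-Bayesian mixture implementation (mclust) serves as an
independent cross-check in the tests, not as the implementation.  Among the
5 initializations the solution with the highest point-estimate mixture
likelihood is kept, which is cheap, deterministic under the seed, and — on
one-dimensional allele data — agrees with full ELBO ranking in every case
we examined.

If the smaller cluster does not exceed 20% of the reads, the locus is
homozygous and the median retained length is reported; otherwise the two
cluster medians are reported sorted.  Two literal readings were possible
for the 20% denominator; the default is the reads *entering* the genotyper
(before outlier removal), with the post-filter denominator available in the
configuration.  Medians of even-sized integer sets take the lower central
value so allele lengths stay integral.

## Truth derivation and metrics

For benchmarking against high-confidence VCFs, per-haplotype allele lengths
start from the reference length and add insertion / subtract deletion
lengths of the genotyped records (the two genotype fields act as the two
haplotypes in the order given; overlapping records discard the locus).
Multiple callers are combined by consensus: one caller — discard; two
agreeing callers — accept; k ≥ 3 callers with at least k − 1 identical —
accept; anything else — discard.  Accuracy is summarized by per-read MAE
and MedAE (minimum distance to either truth allele) and by the genotype
distance D = |ŷ₁ − m₁| + |ŷ₂ − m₂| (homozygous sides contribute their
allele twice; both-homozygous pairs compare once).

## The simulator and what it does (not) show

Every stochastic quantity the tests rely on comes from the bundled
simulator, so no sequencing data is needed:

* **Pore models** are seeded random permutations of an equally spaced grid
  on [−2, 2]: any two k-mers are separated by at least 4/(4ᵏ−1), and the
  symmetric span puts the median absolute level at 1, the scale median
  normalization produces.  Tests use k = 3 (gap ≈ 0.063); the tool default
  for real ONT tables is k = 6.
* **Dwell times** are shifted negative binomial, minimum 1, mean 8.5
  (nanopore contexts are read ≈8–9 times on average).  The dispersion
  parameter matters: the maximally dispersed (geometric) choice puts ~12%
  of events at a single point and ~31% below the dwell floor of 4, which
  no dwell-constrained aligner can represent — whole units then vanish
  even from noise-free reads.  The default dispersion (size 6) puts
  roughly 8% of events below the floor, closer to real squiggle left
  tails, and is what makes exact recovery attainable; it is a generator
  property, not a tuning knob, and is fixed across all tests.
* **Noise** defaults to 0.25 × the model's guaranteed level gap; "zero
  noise" runs set it to 0.
* **Reads** get a uniform raw shift/scale, an optional monotone distortion,
  an exact move map recorded as truth, and idealized basecalls (optionally
  with uniform substitutions) — enough to exercise flank localization and
  the basecall-space baseline, but no realistic basecaller error model and
  no event skips beyond what dwell dispersion produces.  Conclusions about
  real flowcell data are therefore limited to the mechanisms tested:
  alignment optimality, normalization/polishing behavior, counting, and
  genotyping rules.

## Problem sizes used by the checks

The automated checks run at desk scale, chosen once: 30–40 base flanks,
k = 3 models, repeat counts 5–50 with 50 reads per count for per-read
recovery (median absolute error must be 0), 100 seeded diploid replicates
at 5 reads per allele and alleles (10, 20) for genotype recovery (D = 0
required at zero noise; D ≤ 2 in ≥95% at default noise), and a 100-read
kinked-distortion set for polishing (pass-2 error ≤ pass-1 error in ≥90%).
At the hardest corner of the genotyper separation regime (allele gap
exactly 10, read SD exactly 2) about 6% of replicates contain a read that
genuinely lies nearer the opposite allele, so exact cluster-median recovery
plateaus near 94% there; heterozygosity and within-one-base recovery stay
above 99%.

## Known limitations

* Matching states only: no insertion/deletion states and no probabilistic
  emission model; scoring is the absolute level difference.
* Homopolymer units and full regular-expression features (alternation,
  bounded counts) are unsupported.
* FAST5/POD5/BAM adapters are out of scope; the canonical input is the
  documented per-read JSON container that the simulator writes.
* The basecall-distance baseline and the locus suitability filter are
  provided for comparison and documentation, not as calibrated tools.
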