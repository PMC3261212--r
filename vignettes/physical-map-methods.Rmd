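---
title: "Models and methods behind physmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind physmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

physmapr builds clone-based physical maps from restriction-fragment
fingerprints and studies how genome heterozygosity distorts them. This
vignette explains the models, the tunable parameters, what the synthetic
data generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## 1. The overlap model

A fingerprint is a sorted vector of integer band mobilities: 0.1-bp units
for AFLP capillary fingerprints (capillary sizes are decimal; a factor-10
scaling preserves the decimal within a 16-bit integer contract), or
pseudo-mobility tag IDs for WGP fingerprints. Two fingerprints are
compared by a greedy one-to-one sweep over the sorted lists: bands match
when they differ by at most the tolerance *t*; otherwise the pointer at
the lower mobility advances. For *t* = 0 this is exact multiset
intersection, which is the WGP mode.

The match count *m* is scored against a chance model: with *GL* distinct
mobility values, a single band pair collides with probability
*p = (2t+1)/GL*; a band of the smaller fingerprint (*n_L* bands) hits the
larger (*n_H* bands) anywhere with *q = 1 − (1−p)^{n_H}*; and

$$S \;=\; \sum_{j=m}^{n_L} \binom{n_L}{j} q^j (1-q)^{\,n_L-j}$$

implemented as the binomial upper tail `pbinom(m - 1, nL, q,
lower.tail = FALSE)`. The test suite checks this against the literal sum
and against Monte-Carlo frequencies. The Monte-Carlo check shows the
known property that the binomial model is *conservative*: greedy
one-to-one matching produces slightly fewer chance matches than the
independence assumption predicts (about 5–25% relative, growing with
*m*), so true chance-match probabilities sit a little below *S*. Scores
are used as thresholds on a log scale, where this bias is immaterial.

Parameters (AFLP / WGP): tolerance 5 / 0 mobility units; gel length 5501
(window 100.0–650.0 bp) / 53706 (ID range 1000–54705); build cut-off
1e−09 / 1e−21; DQ resplit cut-offs 1e−10..1e−12 / 1e−24..1e−30; end-merge
cut-offs 1e−08, 1e−07 / 1e−21, 1e−18; 3477 bp of genome per consensus
band. These are the published build schedules and are taken as given, not
tuned.

## 2. Contig building

Clones join when *S* is at or below the build cut-off; contigs are the
connected components (single linkage). Within a contig:

* **Order**: greedy seriation. Seed at the best-scoring pair; repeatedly
  place the unplaced clone with the strongest edge to a placed clone at
  `offset(anchor) + (nL − m)` band units. This is a deliberate
  simplification of full consensus-map layout; order-recovery against
  simulation truth is what justifies it.
* **Consensus bands (CB)**: matched band pairs across significant edges
  are united (union–find), under two constraints that keep co-migrating
  but distinct loci apart: a consensus band may contain at most one band
  per clone, and its feasible position interval — the intersection of its
  member clones' spans, with 5 band units of slack for seriation error —
  must stay non-empty. Edges are processed strongest-first. `cb_length`,
  the number of consensus bands, times 3477 bp is the contig length.
* **Q clones**: a clone is questionable when under half of its bands lie
  in consensus bands supported by another clone (configurable threshold).
  Q-rich contigs (> 5 Qs) are dissolved and rebuilt at the stricter DQ
  cut-offs; still-failing contigs are kept as they are.
* **End merging**: contigs merge when at least 2 clone pairs between
  their end regions (within 45 band units of an end) score below the
  relaxed cut-off; merging is transitive within a round.

**Known limitation — length at realistic noise.** With 0.3 bp sizing
noise, about 23% of same-locus band pairs fall outside the ±0.5 bp match
tolerance, so consensus bands over-split and absolute synthetic map
lengths run ~1.5–1.6× the genome even for a homozygous genome. A
consolidation pass that re-merges mobility-compatible clusters was tried
and rejected: it collapses genuinely co-migrating loci and breaks the
noise-free calibration (homozygous map length ≈ 0.97–0.99× genome, which
is the regime where the length model is asserted). Heterozygosity effects
are therefore always evaluated as *paired contrasts* at matched noise,
never as absolute lengths.

## 3. The pooling design and deconvolution

Each 384-well plate contributes four quarter-plate pools (QPPs) through a
96-pin replicator interleave: quarter = 1 + 2·(row mod 2) + (col mod 2)
with 0-based indices, so well F12 of plate 42 belongs to pool 042Q4. A
random k-sets design assigns each QPP a distinct set of k = 4 of v = 90
superpools; balanced drawing (least-loaded pools first, random
tie-breaks) keeps loads within one, e.g. 33 or 34 QPPs per superpool at
the default n = 764.

Deconvolution of a marker's positive superpools: candidates are QPPs
whose entire k-set is positive; a candidate is a **resolved positive**
when it owns a positive superpool covered by no other candidate — the
formalisation of "needed to explain the scores", verified against a
brute-force enumeration oracle on small designs. Monte-Carlo simulation
(1000 draws per copy number) reproduces the published behaviour: up to
six positive QPPs are fully resolved; by thirteen, resolution declines
and false positives appear.

## 4. Marker anchoring

Marker sizes from radioactive mapping gels shift on capillary gels. The
shift is fitted as piecewise-linear in radioactive size with a knot at
450 bp (constant below, rising to about +20 bp at 600 bp); the residual
sd sets the scoring-interval width, clamped to 0.2–0.4 bp. Scoring is a
closed-interval band search per superpool; markers whose interval catches
two or more distinct bands in most positive lanes are flagged unusable.

Anchoring requires ≥ 2 *mutually overlapping* positive clones — members
of candidate QPPs carrying a band within 0.4 bp of the marker — in one
contig; mutual overlap is enforced by requiring their offsets to fall
within one clone length, since true carriers share the marker fragment.
If several contigs qualify the record is `ambiguous` (never
auto-resolved); one candidate QPP only → `omitted_single_qpp`. Markers
below 100 bp are matched against unclipped fingerprints retained by
`preprocess()`. Conflict screening flags anchors disagreeing with their
contig's majority chromosome or lying > 10 bins (configurable; no
published value) from the contig median.

**Scale caveat.** In a genome-wide screen the candidate QPPs cover < 1%
of the library, so chance band matches rarely let a second contig reach
the two-clone rule. At desk scale (tens of QPPs) candidates cover ~30% of
the clones and most markers return a short list — exactly the situation
the original procedure resolved by eye. Synthetic screens therefore
report the best-supported contig of the short list; the uniqueness rule
itself is unchanged.

## 5. Heterozygosity models

*Marker mixing.* If marker haplotypes combined freely, a contig with n
dominant markers would show a single haplotype with probability
0.5^(n−1), i.e. 50% two-haplotype contigs at n = 2, 87.5% at n = 4,
93.8% at n = 5. Observed mixing far below this indicates
haplotype-specific contigs; the synthetic heterozygous world reproduces
the effect strongly (observed near 0%).

*Tag copy numbers.* With G genome equivalents of template, a homozygous
tag appears in Poisson(G) clones and a heterozygous tag (one haplotype)
in Poisson(G/2). Observed spectra exclude singleton tags, so the mixture
w·Pois(G/2) + (1−w)·Pois(G) is renormalised over k ≥ 2 (maximum
likelihood on the truncated support is the statistically coherent choice;
the support is capped at k = 200 and heavy tails beyond it would indicate
duplicated loci, which the generator does not emulate). At G = 8.2 and a
het:hom ratio of 1.2 : 1 (w = 1.2/2.2 ≈ 0.545) the mode is 4 copies.
Parameter recovery on 50 000 simulated tags is within ±0.3 (G) and ±0.05
(w).

## 6. The synthetic diploid world

The generator's defaults are the stated world of the analysis: mean
restriction-fragment length 3477 bp with a geometric (right-skewed)
length law; a partial-digest library of 127 kb clones at 9.6 g.e. plus a
sheared library of 96 kb clones at 3.3 g.e. on 384-well plates; capillary
sizing noise 0.3 bp (the stated sizing accuracy); band scoring window
100–650 bp with a 10–100 band-count filter; contamination rates 3.8%
(chloroplast, fingerprint replaced by a fixed profile), 4.7% (artefact
bands added) and 4.4% (neighbour-well mixing, union of adjacent wells);
and 5% repetitive fragments whose WGP tags fail to resolve.

Three modelling choices deserve emphasis:

* **Allelic, block-structured heterozygosity.** A heterozygous locus
  carries two allelic fragments, one per haplotype, with independent
  mobilities and tags — dominant markers are single alleles scored as
  presence/absence. Modelling heterozygosity as pure fragment *absence*
  cannot work: the union of distinct fragments per locus would be one
  regardless of heterozygosity, so map inflation and haplotype-specific
  contigs could never arise. Divergence is organised in blocks (default
  mean 500 kb, a few clone lengths) rather than i.i.d. per fragment,
  because with i.i.d. heterozygosity at the stated level every
  cross-haplotype clone pair still shares ~60% of its bands — far inside
  the Sulston cut-offs — and haplotypes always co-assemble. Block
  divergence is also the biologically realistic picture
  (structural-variant and indel blocks). `het_fraction` is defined as the
  fraction of distinct fragments (equivalently tags) that are
  haplotype-specific; the diverged length fraction is then
  `het_fraction/(2 − het_fraction)`. At 10 Mb the per-seed realisation of
  this fraction is noisy (sd ≈ 0.15 with 500 kb blocks) — tests
  account for block-level, not fragment-level, sampling variance.
* **Band mobilities** are drawn per locus from a truncated geometric over
  the 100–650 bp window with mean 350 bp, giving a low-end band density
  of ~0.1 bands/bp — skewed toward low mobilities as in real gels, but
  not so concentrated that interval scoring becomes uninformative.
  Mobility is independent of the fragment's genomic length (an AFLP band
  is the amplified subfragment, not the full inter-site distance).
* **Selective marker screening.** Marker screening gels amplify one of
  135 selective primer combinations at a time, so each locus is assigned
  a primer combination and superpool scoring sees only same-combination
  fragments. Without this, interval scoring against non-selective
  fingerprints saturates every superpool.

What a green end-to-end test establishes: the assembly separates
haplotype blocks, inflates heterozygous maps relative to homozygous ones,
anchors markers at copy numbers near coverage/2, and recovers mixture
parameters. What it does not establish: absolute contig-length accuracy
at realistic noise (Section 2), behaviour on repeat-rich genomes,
chimeric clone rates of real libraries, or the exact ambiguity rate of
a genome-wide screen.

## 7. Numerical and degenerate-input conventions

Empty fingerprints score S = 1 (no evidence). Window boundaries are
inclusive at both ends. Ties in edge processing and seriation are broken
by score, then lexicographic clone id, making every build deterministic.
The 16-bit mobility contract (integers ≤ 65535) is enforced at
construction. Pseudo-ID assignment shares IDs between tags only when the
range forces it (six per ID at the published scale, where the stated tag
count slightly exceeds capacity and the excess receives reported overflow
IDs above the range). The mixture fit optimises (log G, logit w) by
Nelder–Mead with a multinomial likelihood, which makes it invariant to
histogram scaling.
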