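---
title: "Consistency-based variant filtering for long-read phasing: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency-based variant filtering for long-read phasing: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefilt)
```

## The model

A diploid genome carries heterozygous variants on two haplotypes. A long
read originates from one haplotype, so its alleles at the het sites it
covers are a noisy copy of that haplotype's allele vector. Writing a read's
allele at a site as 0 (REF) or 1 (ALT), two *true* het sites co-covered by
$N$ reads produce allele pairs that concentrate on two of the four patterns:
either $\{00, 11\}$ (the ALT alleles are in cis) or $\{01, 10\}$ (trans).
With $x$ = discordant reads (01/10) and $y$ = concordant (00/11),
$x + y = N$, the pair's consistency is

$$\mathrm{score} = \frac{\max(x, y)}{x + y} \in [0.5,\, 1],$$

reaching 1 exactly when one pattern class is empty. A per-read allele error
rate $\varepsilon$ (wrong base call, mistagged INDEL) flips each call
independently, making a read discordant with probability
$2\varepsilon(1-\varepsilon)$; the expected score of a true pair is
therefore about $1 - 2\varepsilon(1-\varepsilon)$. A *false-positive* site,
by contrast, has alleles unrelated to haplotype: each co-covering read is
discordant with any true neighbor with probability near $1/2$, and the pair
score behaves as $\mathbb{E}[\max(X, N-X)]/N$, $X \sim \mathrm{Bin}(N, 1/2)$
— about $0.5 + 0.4/\sqrt{N}$. The gap between those two regimes is the
signal the filter uses.

Assumptions worth making explicit:

* **Diploid, biallelic, het-only.** Only 0/1 (or 0|1) biallelic records are
  scored; hom-alt and multi-allelic records carry no phase information for a
  two-haplotype model and pass through unscored (flagged in the report).
* **Tags, not signal.** The method consumes a read-by-site allele matrix.
  It cannot repair alignment artifacts that bias the tags themselves.
* **Independent errors.** Systematic, haplotype-correlated errors (e.g.
  homopolymer slippage affecting every read the same way) look like
  consistent signal; see Limitations.

## The filtering procedure

Each scorable site is summarized against its neighbors: pairs are formed
with up to `neighbor_window` (default 20) *active* scored sites on each side
in VCF order, and a pair counts only if at least `min_pair_support`
(default 3) reads call both sites. A site's summary is the max and the
unweighted mean of its qualifying pair scores. Three steps follow, with
thresholds $(p_1, p_2, p_3) = (0.7, 0.8, 0.9)$ by default:

1. **Step 1** removes filterable sites with *no* pair score strictly above
   $p_1$ (comparator `max <= p1`).
2. **Step 2** recomputes summaries on the survivors and removes sites with
   `mean < p2`.
3. **Step 3** recomputes again and removes sites whose *best* pair is still
   weak: `max < p3`.

Recomputing between steps matters: a false site drags down the mean of its
true neighbors, and its removal lets them recover — on clean data the
surviving set converges to all-ones summaries.

**Quality fallback.** A filterable site with zero qualifying pairs at the
step where it would be judged cannot be assessed by consistency at all (low
coverage, dead zone, or all partners already removed). It is judged by the
VCF QUAL field instead: kept iff `QUAL >= min_qual` (default 15; a missing
QUAL counts as 0, the conservative reading for unverifiable sites). A
quality-rescued site stays in the active set as a pairing partner but is not
re-judged at later steps.

**Modes.** `indels_only` (default) may remove only INDELs — the variant
class with poor calling precision on nanopore data — while SNVs still serve
as pairing partners; `all_variants` subjects both classes to filtering.

### Why step 3 compares the max, not the mean

The third step is described here as "the best link must clear $p_3$", with
`step3_stat = "mean"` available as a config flag. The mean comparator is
degenerate at realistic nanopore error rates: at $\varepsilon = 0.05$ the
expected true-pair score is $1 - 2\varepsilon(1-\varepsilon) \approx 0.905$,
so a `mean < 0.9` rule sits on a knife edge and removes true variants
essentially at the rate at which a site's own calls happen to carry two or
more errors — a large, threshold-discontinuous loss of recall that
contradicts the intended precision-for-a-little-recall trade. The max
comparator keeps the step's purpose (a stricter pass over "any remaining
low-consistency sites") while remaining specific: a true site almost always
retains at least one strong link, whereas a site with *no* pair reaching 0.9
has given no reliable phase evidence at all. False sites are in any case
overwhelmingly caught by steps 1–2 (their mean hovers near 0.6).

### Other numerical choices

* **Comparator literals.** Step 1 is `max <= p1` ("no score above p1");
  steps 2–3 use strict `<` ("below p"). Boundary cases are covered by tests
  (e.g. QUAL exactly 15 is kept).
* **Neighborhood.** "Neighboring" is bounded by pair count (window 20 per
  side) rather than genomic distance: read length already caps co-coverage,
  the window only caps cost. Pairs are re-formed against the *active* set
  after each step.
* **Unweighted mean.** Each qualifying pair contributes equally;
  `weight_by_support = TRUE` switches to support-weighted means for
  sensitivity analyses.
* **Degenerate inputs.** Empty pair sets yield `NA` summaries and route to
  the fallback; empty VCF bodies, single-site matrices and windowless grids
  return empty, well-typed results; `x + y = 0` pairs are never
  materialized.
* **Determinism.** No randomness anywhere in the filter; identical inputs
  and config give identical decisions.

## Tagging (fragment extraction)

The extraction stage turns BAM + VCF into the allele matrix, equivalent in
role to HapCUT2's extractHAIRS (whose fragment-file output can be supplied
directly instead). Per alignment and het site:

* **SNV:** the base aligned at the site position; REF base → 0, ALT base →
  1, anything else (third allele, deletion, base quality < `min_baseq`) →
  no call.
* **INDEL:** the read must align at least `require_full_span_bp` (default
  5) past both ends of the REF-allele span; the CIGAR-implied read sequence
  over the locus (aligned bases plus insertions anchored inside it) must
  equal the REF or ALT allele string exactly; anything ambiguous → no call.

Defaults `min_mapq = 20`, `min_baseq = 7`, skipping
secondary/supplementary/duplicate/QC-fail alignments, mirror common
extractHAIRS-style practice. Raising either threshold can only remove calls
(a tested monotonicity). Reads are treated as single-end (long-read scope);
fragments with fewer than two calls carry no pairwise information and are
dropped.

## The simulator

`simulate_phasing()` generates the study conditions every test runs under:
one chromosome, sites placed uniformly with a minimum spacing of 50 bp
(keeps INDEL loci disjoint), read windows of Normal(25 kb, 2.5 kb) length at
30× coverage, read haplotype Bernoulli(1/2), and three site classes:

* **true** het sites — read allele determined by haplotype, flipped with
  probability `allele_error_rate` (default 0.05, the lower end of nanopore
  raw error as seen after base-quality screening);
* **fp** sites — each read ALT with probability `fp_alt_prob = 0.5`
  independent of haplotype, the worst case for co-segregation and the model
  of a genotyping artifact;
* **fp_hom** sites — every read ALT (plus noise): a hom-alt call mislabeled
  het. These are *perfectly self-consistent* and deliberately included as
  the class the method cannot remove (see Limitations).

Default scale is 200 true + 40 fp sites over 1 Mb; VCF QUALs are drawn
Normal(30, 8) for true and Normal(10, 6) for false sites, so the fallback
rule faces a realistic overlap. `emit_fixtures()` materializes a reference
FASTA, a VCF, a fragment file, a truth table and a sorted indexed BAM whose
CIGARs encode each read's alleles; at error rate 0 extraction from that BAM
reproduces the simulated matrix exactly (a tested identity).

What the simulator does *not* emulate: alignment ambiguity and mapping
error, homopolymer/systematic error profiles, clustered variants closer
than the minimum spacing, coverage biases, and reference bias. Passing
tests therefore demonstrate the method's behavior under its own model
assumptions — clean co-segregation signal disturbed by independent noise —
not its performance on any real genome.

## Evaluation harness

`precision_recall()` scores decisions against simulation truth over the
filterable sites (tp = kept true, fp = kept false, fn = removed true).
`greedy_phase()` is a deliberately simple reference phaser — consecutive
sites are chain-linked when ≥ 3 reads cover both, oriented by majority
pattern, ties toward "same phase" — sufficient to expose how false sites
corrupt phase chains, and explicitly not a reimplementation of production
phasers. `switch_errors()` counts consecutive-site relative-orientation
disagreements with truth inside each block (invariant under global block
flips); `block_n50()` uses block genomic spans. `grid_search()` evaluates
all admissible $(p_1 < p_2 < p_3)$ triples over the default grids
$p_1 \in \{0.6, 0.65, 0.7, 0.75\}$, $p_2 \in \{0.7, ..., 0.85\}$,
$p_3 \in \{0.8, ..., 0.95\}$ on synthetic data.

## Problem sizes

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the full suite completes in about a minute: the main study uses
the simulator defaults (240 sites, 1,200 reads, 10 replicate seeds);
property tests use matrices of ≤ 10 sites × ≤ 50 reads against a
brute-force enumeration oracle; BAM round-trip tests use 150–200 kb regions
at 10–15×. All randomness is seed-derived and reproducible.

## Limitations

* **Hom-as-het artifacts are invisible.** A site where every read shows ALT
  is perfectly consistent with all neighbors; no co-segregation criterion
  can flag it. Such sites sail through the filter by design and would need
  allele-balance or genotype-likelihood evidence instead.
* **Sparse regions degrade to QUAL filtering.** Where no pairs exist the
  method *is* a quality filter, inheriting its weaknesses.
* **Systematic errors mimic haplotype signal.** Errors correlated across
  reads (strand- or motif-specific miscalls) can co-segregate and survive.
* **The toy phaser is a probe, not a benchmark.** Downstream numbers
  computed here characterize relative behavior (raw vs filtered variant
  sets) under the simulator's assumptions; real-data phasing performance
  must be assessed with production phasers and truth sets.
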