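---
title: "Window-based SNV similarity strain tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based SNV similarity strain tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsstrack)
```

## The problem

After a fecal microbiota transplant (FMT), the dominant strain of a given gut
species in the recipient can be donor-derived (engraftment), a persisting
strain the recipient already carried before the transplant, or a strain
related to neither. Species-level profiles cannot make this distinction —
donor and recipient typically share most species — so the comparison has to
happen at strain resolution, via the single-nucleotide variants (SNVs) each
sample's dominant strain carries against a species reference genome.

wsstrack implements that comparison as a complete, testable pipeline:

1. **read QC** — sliding-window quality trimming, a minimum-length filter and
   a k-mer host screen;
2. **SNV profiling** — placing reads on the species reference and calling a
   majority-consensus allele at every sufficiently covered position;
3. **pair scoring** — a window-based SNV similarity (WSS) score for a pair of
   samples, gated on per-sample genome coverage and depth;
4. **calibration** — a per-species relatedness cut-off fitted on labeled
   related/unrelated pairs;
5. **tracking** — donor-vs-recipient and pre-vs-post comparisons combined
   into a four-way attribution per species and post-FMT sample, and an
   engraftment-by-response summary.

A seeded synthetic-data generator produces reference genomes, SNV-diverged
strains, reads and whole FMT timelines with known strain origin, so every
stage — and the pipeline end to end — is validated against ground truth
without any external sequencing data.

## The score

Each sample's profile is the vector of consensus alleles at reference
positions with depth at least `site_min_depth` (default 4; a majority call on
fewer than four reads is unstable, and the value sits naturally with the
pair-level depth gate of 3.5). For samples $a, b$ the genome is partitioned
into consecutive non-overlapping windows of $W = 1000$ bp. In window $i$,
let $c_i$ be the number of *co-covered* sites (consensus present in both
samples) and $m_i$ the number of those where the alleles agree. Windows with
$c_i < 10$ are discarded; the score is

$$\mathrm{WSS}(a,b) = 100 \times \frac{1}{|I|}\sum_{i \in I} \frac{m_i}{c_i},$$

the unweighted mean over emitted windows $I$. Windows — not sites — are the
averaging unit, which is what "window-based" implies: a deeply covered region
cannot dominate the score. A site-weighted variant
($100\sum m_i / \sum c_i$) is available behind the `site_weighted` flag for
sensitivity checks. The published score's internal formula lives in prior
work and is not restated in the study this package accompanies; the
definition above is this package's own concrete re-specification, chosen to
preserve the score's semantics (a percent similarity with per-species
cut-offs in the high nineties) while being exactly testable. Window length
and the per-window site minimum are exposed as parameters.

Two identities pin the implementation down: a self-comparison of any
evaluable profile is exactly 100, and the score is symmetric. The test suite
additionally checks the windowed score against an independent brute-force
double loop over windows and positions, to $10^{-9}$.

### Gating

A pair is *evaluable* only when **both** samples have coverage fraction
strictly above 0.30 and mean depth strictly above 3.5 — the criteria printed
with the study's figures, with strict inequality taken literally. Pairs
failing the gate, and species without an established cut-off, produce
*indeterminate* cells (the figures' white boxes). The gate is deterministic:
a cell simulated at or below either criterion is indeterminate every time.

### Classification

A scored pair is *related* when the score strictly exceeds the species
cut-off and *unrelated* when strictly below. A score exactly at the cut-off
is undefined under the study's strict inequalities; we resolve it as
*unrelated*, the conservative side that avoids a false relatedness claim.

## Calibration

The cut-off for each species is fit on labeled scores — same-subject
longitudinal pairs as *related*, cross-subject pairs as *unrelated* — by a
one-dimensional minimum-error threshold under the rule "related iff score >
cut-off", placed at the midpoint between the two adjacent observed scores
spanning the optimal split. This is the simplest classifier consistent with
one published number per species; a Youden-index variant is available via
`method = "youden"`. Among error-tied splits we take the one with the widest
score gap (then the lower cut-off): the widest gap gives the largest margin
to both classes, and the lower cut-off again errs against claiming
relatedness. When classes interleave, the global error minimum is returned
with a warning and a nonzero training error. `fit_cutoff` is tested against
an exhaustive threshold sweep on every input.

## The synthetic generator

The generator emulates exactly the quantities the pipeline's decisions
depend on:

* **References** — i.i.d. bases at a target GC fraction (default 0.5,
  100 kb for scenario work).
* **Strains** — exactly `n_snvs` substitutions at distinct positions.
  Unrelated strains differ at 1 SNV per kb by default; a related sample is
  the same strain re-sequenced, so it differs by sequencing error only.
  These two settings define the calibration classes.
* **Reads** — fixed-length (default 100 bp) single-end reads from the
  forward strand, uniform within the covered region, substitution errors at
  `error_rate` (default 1 %), constant Phred quality (default Q35) or a
  two-segment high-to-low profile for exercising the trimmer. Read starts
  are confined to 1 kb blocks comprising `ceiling(covered_fraction * L)`
  bases, which makes the 30 % coverage gate sharply controllable.
* **Scenarios** — one donor and a recipient sampled at days 0 (pre-FMT,
  mirroring a colonoscopy-day baseline) and 7, 31, 65 post-FMT, the
  timeline of the melanoma-FMT cohort the pipeline is modeled on. Five
  templates fix the true origin of every post-FMT cell: full donor
  engraftment, recipient persistence, a temporal mosaic alternating donor
  and recipient strains across timepoints, a novel strain unrelated to
  both, and designated cells simulated at covered fraction 0.25 so they
  must fail the gate. The manifest records the true strain per
  (sample, species) cell; tracking output is scored against it.

Defaults (20x depth, 1 % error, 1 SNV/kb, 3 species, 100 kb genomes) are the
conditions under which all end-to-end recovery results in the tests are
computed.

What the generator does **not** model: multi-species communities with
abundance structure, GC or strand bias, indels and structural variants,
paired-end reads, within-sample strain mixtures. Reads are simulated from
and mapped to the forward strand only. Passing tests therefore demonstrate
the correctness of the scoring/gating/attribution machinery under a clean
dominant-strain model — not robustness to mixed strains, mapping artifacts
or real error profiles. On real data the profiling step is expected to be
fed from standard aligner output via `import_pileup()` rather than the
internal mapper.

## Numerical and design choices

* **Internal mapper** — exact-seed (31-mer) placement with ungapped
  verification at up to 5 % mismatches, seeds tried every k bases along the
  read. Sufficient for synthetic error rates up to ~1 %; it exists so the
  pipeline runs end to end with no external aligner, not as a bowtie2
  replacement.
* **Host filter** — a read is dropped when at least 50 % of its 31-mers
  occur exactly in the host reference on either strand. Exact k-mer
  membership is deterministic and testable at the drop/retain boundary,
  unlike alignment scores. At k = 31 chance collisions are negligible.
* **Trimming semantics** — windows advance one base at a time 5' to 3'; the
  read is truncated at the start of the first window whose mean quality
  falls below the threshold; reads shorter than one window are judged
  whole. Only the printed window (50), QScore (20) and length (50) rules
  are implemented; leading/trailing or adapter trimming are out of scope
  (no adapter list is given).
* **Consensus ties** — broken in fixed A<C<G<T order, so profiles are
  deterministic.
* **Both-related cells** — a post-FMT cell related to donor *and* pre-FMT
  strains (possible when those two are near-identical) is recorded as
  donor-related with a `both_related` flag, preserving the four-way color
  scheme of the study's figures without inventing a fifth category.
* **Donor pooling** — donors sequenced as several samples are merged before
  profiling (`pool_read_sets()` / `pool_pileups()`), matching the study's
  convention of analyzing one merged donor sample.
* **2x2 response summary** — recipient-level "donor strain detected" means
  at least one species donor-related at at least one post-FMT timepoint; the
  two-sided Fisher exact test is an added convenience for small cohorts,
  not a claim from the study, which reads concordance qualitatively.
* **Cut-off reuse across seeds** — in simulation studies the cut-off is a
  property of the divergence model (related = error-only resequencing,
  unrelated = 1 SNV/kb), not of a particular random genome, so cut-offs
  calibrated once per settings are applied across scenario replicates, as a
  fixed HMP-derived table is applied across cohorts in practice.
* **Re-dosed FMT** — repeated-transfer designs are not modeled; scenario
  timepoints are free parameters, but no template asserts a re-dose effect.

## Problem sizes

End-to-end recovery runs five templates at 3 species x 100 kb x 20x across
20 seeded replicates each; calibration recovery uses 20 related + 20
unrelated pairs per replicate on 20 kb genomes (pairs-per-class and
divergence as stated above; the genome length is a package choice for the
replicated setting). Score identities and oracle equivalence run on hundreds
of randomly generated profile pairs at 5-50 kb. These sizes make every
distributional claim in the tests reproducible on a single CPU.

## Worked example

```{r example, eval = FALSE}
scen <- compose_scenario("temporal_mosaic", n_species = 2,
                         genome_length = 2e4, mean_depth = 15,
                         error_rate = 0.01, seed = 1)
cutoffs <- calibrate_scenario_cutoffs(scen, seed = 2)
ev <- evaluate_scenario(scen, cutoffs = cutoffs)
ev$accuracy          # fraction of evaluable cells matching ground truth
table(ev$cells$truth_attribution, ev$cells$attribution)
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow — simulate, QC, profile, calibrate, track, summarize — writing
their tables under `results/`.

## Known limitations

The score reflects the *dominant* consensus only; a sample carrying a
donor/recipient strain mixture will be attributed to whichever strain
dominates the consensus, with no deconvolution. Cut-offs calibrated on the
synthetic divergence model are not substitutes for cut-offs established on
real paired samples; users with an established per-species table should load
it with `read_cutoff_table()` and pass it directly. Attribution requires
both a donor and a pre-FMT comparison; recipients lacking a pre-FMT sample
yield donor-relatedness calls but no four-way attribution.
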