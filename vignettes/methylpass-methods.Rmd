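---
title: "Methods: threshold DMR calling and passage-wise convergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold DMR calling and passage-wise convergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

methylpass analyses Infinium-style DNA methylation beta values — per-CpG
scores in [0, 1], 0 meaning completely unmethylated and 1 completely
methylated — across three kinds of cell lines: embryonic stem cell (ESC)
lines, induced pluripotent stem cell (iPSC) lines, and the somatic "parent"
lines the iPSCs were reprogrammed from. Its primitive is the threshold DMR
call: a CpG probe is differentially methylated between two profiles when the
beta difference is at least θ (default 0.3), with no statistical test — the
definition is a pure threshold on the group difference, inclusive at the
boundary. Everything else is set algebra and bookkeeping over such calls:
the seven-way overlap partition of probes among the ESC-vs-parent,
iPSC-vs-parent and ESC-vs-iPSC call sets of each parent-cell set; stem
cell-specific DMRs (the overlap pattern where ESCs and iPSCs jointly differ
from the parent, intersected across all parent-cell sets) and stem
cell-required DMRs (the union counterpart); per-iPSC-line differences from
the ESC average decomposed into parent-inherited versus aberrant sites; and
the passage-wise tracking of when such sites appear, whether they persist,
and whether their number converges toward zero.

## Group profiles and the intra-group exclusion

Group references (the ESC average, per-set iPSC averages) are per-probe
means over member samples. Before averaging, any probe at which two members
of the group differ by ≥ θ is set to missing *for that group*: a group that
disagrees internally at a probe cannot serve as a reference there. The
exclusion is pairwise (the span of the members) at the same θ as the main
analysis; an alternative criterion — deviation from the group mean — would
be less strict, and the pairwise form is the one that makes a group average
meaningful as a two-sided reference. Excluded probes stay in the global
probe universe; they are only invisible to comparisons involving that group.
By default a probe masked (missing) in any member is likewise excluded from
that group's profile (`require_complete = TRUE`), so comparisons never
silently mix member subsets.

Detection filtering happens before any analysis: a probe whose detection
p-value is ≥ α (default 0.05) in *any* sample is dropped from the shared
probe universe entirely, so every comparison runs on a single common set of
probes. The boundary is inclusive, and the filter is idempotent.

## The seven-category partition

For one parent-cell set, three call sets are computed on the shared
universe: D~EP~ (ESC average vs parent), D~IP~ (iPSC set average vs parent)
and D~EI~ (ESC vs iPSC averages). Each probe falls into exactly one of the
2³ membership patterns, labelled:

| label | pattern | meaning |
|---|---|---|
| none | in no set | not differential |
| aa | EP only | ESC-only difference |
| bb | IP ∧ EI | iPSC-specific DMR |
| cc | IP only | iPSC-vs-parent only |
| dd | EI only | ESC-vs-iPSC only |
| ee | EP ∧ IP, not EI | stem-cell state differs from parent |
| ff | EP ∧ EI, not IP | iPSC retains the parent state |
| gg | all three | all pairwise different |

Only `ee`, `bb` and `ff` carry analytical weight (stem-cell signature,
iPSC-specific aberration, inheritance); the remaining letters are a fixed
documented convention so that tables are stable across runs. Stem
cell-specific DMRs are the probes that are `ee` in **every** parent-cell
set; stem cell-required DMRs are `ee` in **at least one** set, with the
contributing sets recorded. The direction of a stem cell-specific DMR
(hyper- or hypo-methylated in stem cells) is taken from the iPSC-vs-parent
comparison and checked for consistency across sets.

## ES-iPS-DMRs, inheritance and aberrance

Each iPSC line (one array per sampled passage) is compared against the ESC
*group average* — not a single ESC line — at θ. A called site is
*inherited* when the line additionally matches its parent line within θ
(epigenetic memory), and *aberrant* when it differs from the parent by ≥ θ
as well. A site exactly θ from the parent counts as aberrant, consistent
with inclusive calling; a site can never be both. Without a parent profile
the class is *unresolved* and reported separately. The class of a site is
recomputed at every passage, because empirically inherited sites behave
like aberrant ones over time — they appear and disappear rather than
persisting deterministically.

Cross-line snapshots (the overlap spectrum, the chromosome/sex
stratification) use one passage per line: the earliest analysed, since
per-line DMR sets in the snapshot analyses are single-passage objects.
Y-chromosome probes are tallied separately and excluded from X-chromosome
comparisons. The recurrent-DMR list is parameterised by the minimum number
of lines k (default 15), since "more than 15 of 22" is ambiguous between
k ≥ 15 and k > 15; both are one parameter away.

## Passage cohorts and convergence

For a line sampled at passages p₁ < p₂ < … , every probe ever called is
assigned to the cohort of its **first** appearance; appearance is
observational at the sampled passages, with no interpolation between them.
The de novo count at a later passage is the size of its cohort. Survival of
a cohort is recorded per observation passage as "called there or not", so a
site that disappears and reappears stays in its original cohort — a
reappearance does not open a new one. Convergence is summarised by
per-passage totals and de novo counts plus two boolean flags: totals lower
at the last passage than the first, and de novo counts never increasing.
The headline per-site convergence metric is the mean **absolute**
difference value |β(sample) − β(ESC average)| per passage — a signed mean
would let hyper- and hypo-methylated deviations cancel — together with the
fraction of positive differences, which measures the hyper-methylation bias
of transient deviations.

Parent lines get the same cohort machinery against the ESC average (with no
grandparent, there is no inherited/aberrant split); the point of the
contrast is that parental de novo sites do **not** decay, so the summary
carries a non-decreasing-total flag.

The imprinted-locus screen compares each line's beta at supplied loci
against the hemi-methylated expectation (default 0.5, overridable per
locus, as one methylated parental allele implies); deviations of ≥ θ flag
the line/locus as hyper- or hypo-aberrant.

## The synthetic-data generator

The generator exists so the whole pipeline is testable without array data.
It draws a complete dataset — beta matrix, sample sheet, probe annotation,
expression table — from an explicit stochastic model of reprogramming, and
emits the full ground truth (probe labels, inherited-site lists, a complete
event log, the noiseless base matrix and the noise draws), so that recovery
tests can demand exactness rather than approximation.

The default configuration is the study design the analysis targets:
25,000 probes; 5 ESC lines; 5 parent-cell sets (named after fibroblast,
amnion, endometrium, placental-artery and menstrual-blood origins; two XY,
three XX) contributing 22 iPSC lines; iPSC passages 13, 18, 31, 39; parent
passages 5, 11, 16. Key parameters, all overridable:

* **Beta levels and noise.** Unmethylated/methylated levels μ₀ = 0.1,
  μ₁ = 0.9; truncated Gaussian noise, SD 0.05 per entry — small enough
  that planted Δβ ≈ 0.8 effects are always super-threshold at θ = 0.3.
  30% of background probes are methylated in the ESC reference, giving the
  bimodal beta distribution typical of promoter arrays.
* **Planted signature.** 220 stem cell-specific sites — 174 hyper- and 46
  hypo-methylated in stem cells relative to parents. (The source counts for
  this signature are internally inconsistent by one — 174 + 45 against a
  total of 220 — so the generator keeps the total and the hyper count.)
  Hypo sites are island-biased (85% CpG island) and hyper sites
  non-island-biased (30%), reproducing the observed island asymmetry.
* **Parent-specific sites and memory.** 800 sites per parent set differ
  between that parent and ESCs; a memory-prone subset of 200 per set is
  where each iPSC line draws its 120 inherited sites. Concentrating
  inheritance in a subset reflects loci prone to incomplete erasure and
  keeps the union of `ee` sites across sets (the stem cell-required count)
  in the low thousands, as observed.
* **De novo dynamics.** At sampled passage k, every eligible probe
  (background-labelled, unmethylated in the ESC reference, currently at its
  reference state) gains hyper-methylation with probability r·γ^(k−1),
  defaults r = 0.009, γ = 0.5; every deviating site reverts to the ESC
  level with probability ρ = 0.5 per passage. De novo events are hyper-only
  by default (a hypo rate would be a one-line extension) because transient
  deviations are overwhelmingly hyper-methylated. No event rates are
  printed in any source; these defaults were chosen once, from the
  closed-form expectations, so that de novo appearance counts fall from
  ~130 to ~15 across the four passages and totals from ~280 to ~80 — the
  observed order of magnitude — and they are not data-derived constants.
  Planted stem-cell-specific sites are excluded from the eligible pool:
  the methylation state at the pluripotency-defining signature is modelled
  as under selection in the stem-cell state, so stochastic drift targets
  background loci.
* **X chromosome.** 4% of probes are on chrX. In XX lines the chrX gain
  rate is multiplied by 8, gains on chrX occur only during the first 2
  sampled passages (the reprogramming-associated instability window of the
  inactive X), and chrX deviations revert with probability 1. This makes
  the transient chrX burden of XX lines — high early, exactly zero late,
  with XY lines low throughout — a structural property of the model rather
  than an accident of one seed.
* **Parent drift.** Parents gain (never lose) deviations at rate 0.002 per
  eligible probe per sampled passage: drift away from the ESC profile
  without convergence.
* **Imprinting.** 87 autosomal imprint loci sit at beta 0.5. One
  (MEG3-like) is fixed at 0.9 in 6 of the iPSC lines and never reverts;
  one (H19-like) is at 0.9 in every sample of every role, so it perturbs
  no between-group comparison while still failing the hemi-methylation
  screen everywhere.
* **Expression.** Genes behind hypo-methylated signature sites are 10-fold
  up in stem samples, genes behind hyper-methylated ones 10-fold down,
  with log-normal noise — just enough structure to exercise the 5-fold
  expression integration.

All randomness flows from a single seed (default 20110526); identical
configurations give bit-identical output, and the event log replays to the
emitted base matrix exactly (`replay_events()`).

### What the generator does not emulate

Probe-level chemistry (type I/II bias, SNP-affected probes), spatial
correlation along the genome, cell-population heterogeneity (betas are
bimodal point masses plus noise rather than continuous mixtures),
culture-adaptation copy-number artefacts, and any mechanistic model of the
de novo methyltransferases. Passing recovery tests therefore demonstrates
the correctness of the calling, partition and cohort logic under the
model's assumptions — not that real arrays are this clean. On real data the
threshold calls inherit all the usual caveats of beta thresholds
(heteroscedasticity near 0 and 1, no error control).

## Numerical choices

* Threshold comparisons are inclusive (≥ θ) everywhere, including the
  intra-group exclusion and ties at exactly θ (which go to "called", and to
  "aberrant" in the inherited/aberrant split).
* Histogram bins are half-open [lo, hi) with a closed last bin; bin edges
  are computed as integer ratios k/bins and assignment uses
  `findInterval()`, so values lying exactly on an edge bin correctly
  despite floating-point representation.
* Beta values outside [0, 1] in input files are an error, never clamped;
  the simulator truncates noisy values to [0, 1] at emission.
* Probe order from input files is preserved in memory; all written outputs
  are sorted by probe id, making reruns byte-identical.
* Expression ratios use group means of linear intensities; a zero group
  mean is replaced by a pseudocount of 1 intensity unit. Multi-probe genes
  are represented by their largest-|Δβ| probe.
* Group averages refuse silently partial data: with the default
  `require_complete`, a probe missing in any member is missing in the
  group.

## Problem sizes in the test suite

Unit tests run on matrices of tens of probes against brute-force oracles
(all-pairs scans, explicit truth tables, per-probe timeline walks) and on a
2,000-probe simulation; the study-scale checks use the full default
configuration (25,000 probes, 108 samples) once and complete in a few
seconds. Equivalence checks against the oracles cover 20 random seeds of
50 × 12 matrices. Determinism is asserted by simulating and analysing twice
and comparing output files byte for byte.

## Known limitations

* The threshold definition of a DMR carries no error model; counts near
  the threshold are sensitive to noise of the same order as the margin
  (visible in the simulator at imprint loci, whose planted offset of 0.4
  sits 2σ from the 0.3 threshold at the default noise level).
* "Stem cell-required" depends on the per-set iPSC group averages, so a
  site inherited by *every* line of a set is removed from that set's
  comparisons by the intra-group exclusion and cannot be recovered there —
  a property of the definition, not a bug.
* The overlap spectrum compares one snapshot per line; lines sampled at
  very different passages are comparable only to the extent their
  convergence states are.
* With only sampled passages, cohort assignment is right-censored:
  a site first observed at p₂ may have appeared anywhere in (p₁, p₂].
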