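---
title: "Detecting APOBEC-mediated mitochondrial DNA hypermutation"
author: "mitoHyperMut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting APOBEC-mediated mitochondrial DNA hypermutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoHyperMut)
```

## The problem

APOBEC3 cytidine deaminases attack single-stranded DNA and convert C to U,
which is read as T at the next replication. A single deamination episode
leaves many C->T changes clustered *on the same DNA molecule* — a
hypermutated molecule — with a characteristic preference for cytosines whose
5' neighbour is T or C (TpC > CpC >> ApC/GpC). When the deaminated strand is
the complement of the strand written in the reference, the same events are
seen as G->A. In deep amplicon sequencing of the mitochondrial genome, such
molecules appear as rare reads carrying several C->T/G->A calls each, hiding
among millions of reads whose mismatches come from PCR and sequencing error.

`mitoHyperMut` turns this into a calibrated detection problem:

1. align amplicon reads to a circular reference (rCRS-style 1-based
   coordinates; amplicons may wrap the replication origin, e.g.
   nt16331–nt3729 of a 16,569 nt genome);
2. build a per-library consensus after downsampling, masking any column
   without a single clear base as N;
3. call per-read substitutions against that consensus and histogram reads by
   their number of C->T/G->A calls (their *load*);
4. calibrate the hypermutation threshold *k* on a no-mutation control
   library, flag reads with load >= *k*, optionally discard flagged reads
   better explained by a known haplotype, and report hypermutated reads per
   million (ppm);
5. summarize the flagged reads as a 12-class substitution matrix, a strand
   bias, and a TpC/CpC dinucleotide-context enrichment test.

A synthetic-data module generates libraries from exactly the generative
model the analysis assumes, with truth labels, so every stage can be
validated by parameter recovery.

## The statistical model

**Error null.** Sequencing/PCR noise is modelled as independent uniform
substitutions at per-base rate $\varepsilon$. A read of length $L$ covering
$n_{CG}$ C/G positions then acquires C->T/G->A calls with mean
$\lambda = n_{CG}\,\varepsilon/3$, and the per-read load is approximately
Poisson($\lambda$): control histograms decay close to exponentially, and the
chance of reaching 4 calls by error alone is $O(\lambda^4)$ — negligible at
realistic $\varepsilon$. The threshold is nevertheless *not* taken from the
Poisson fit: `calibrateThreshold()` picks the smallest integer $k$ such that
at most `alpha` (default 0) control reads carry $\ge k$ calls, so the
calibration is purely empirical; the fitted $\hat\lambda$ is reported as a
diagnostic only. On histograms read back from published-style tables whose
lowest bin lumps loads 0–3, the lumped mass is treated as lying at or below
load 3, which keeps the tail count conservative for every candidate
$k \le 3$ and leaves $k$ exact for `alpha = 0`.

**Deamination signal.** A hypermutated read is modelled as a read whose
molecule was exposed to deamination on one strand: each eligible site
(C on the deaminated strand) mutates independently with the probability
assigned to its 5'-dinucleotide context. With context weights of the order
of tenths, an exposed 250 nt read acquires on the order of 8 or more calls,
so loads of exposed and unexposed reads separate cleanly around $k = 4$.

**Context enrichment.** Observed contexts of C->T/G->A calls are compared
with the *deamination-opportunity null*: every eligible C in the analyzed
region, on both strands pooled (reference-strand Cs classified by their 5'
base; reference Gs — complement-strand Cs — by the complement of their 3'
base), classified into ApC/CpC/GpC/TpC. Two 1-degree-of-freedom chi-square
goodness-of-fit tests collapse the four contexts to TpC vs rest and CpC vs
rest; the Yates correction is off by default but configurable. The
alternative null sometimes used in the field — the contexts of exactly the
mutated sites — is available as `expectedFrom = "mutated"`.

**3D-PCR selection.** Differential-denaturation PCR amplifies AT-enriched
templates at lower denaturation temperatures. `fitTmModel()` fits the
least-squares line $T_m(m) = t_{m0} - \delta m$ to (mutation count, lowest
amplification temperature) calibration pairs; a linear form is the simplest
model consistent with the few printed calibration points, and nothing
downstream depends on more than monotonicity. `simulate3dpcr()` then keeps a
read iff $T_m(\text{load}) \le T_d$, a deterministic selection that
reproduces the qualitative behaviour of the assay (lower $T_d$, higher
surviving loads):

```{r tm}
tm <- fitTmModel(c(0, 4, 17), c(84.9, 84.1, 82.6))
tm
# smallest load amplified when denaturing at 84.5 degC
min(which(simulate3dpcr(0:20, tm, 84.5))) - 1
```

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `minFraction` | `buildConsensus` | 0.8 | a column is called only if the modal base holds >= 80% of non-N coverage; a 10% hypermutated subpopulation cannot flip or mask a base, while genuinely mixed columns become N |
| `minDepth` | `buildConsensus` | 10 | below 10 reads a "single" base cannot be established; column becomes N |
| downsample `n` | `downsampleReads` | 100,000 | caps consensus cost per library; far above the depth needed for a stable consensus |
| `alpha` | `calibrateThreshold` | 0 | no control read may reach the threshold |
| `maxMismatchFraction` | `alignReads` | 0.1 | reads further than 10% from the region are tallied as unmapped (random DNA sits near 75%) |
| `contextWeights` | `simulationConfig` | TpC .7, CpC .25, ApC/GpC .025 | the APOBEC3 preference ordering at an effect size giving ~8 deaminations per exposed 250 nt read |
| `errorRate` | `simulationConfig` | 1e-4 | typical per-base substitution noise of a PCR + short-read workflow |
| `pHyper` | `simulationConfig` | 0.01 | exposed-read fraction large enough to measure sensitivity, small enough not to perturb the consensus |

Coordinates are 1-based inclusive everywhere, matching rCRS nt numbering;
`genomeRegion(16331, 3729)` denotes the origin-wrapping D-loop amplicon and
has length $16569 - 16331 + 1 + 3729 = 3968$.

## What the simulator does and does not emulate

`simulateLibrary()` draws read start positions uniformly over the region
(single orientation, indel-free), applies deamination *before* sequencing
error (biology precedes measurement), and derives one deterministic child
RNG stream per read index, so identical configs are byte-identical and
enlarging a library never perturbs earlier reads. Truth labels record each
read's deaminated positions.

It does **not** emulate PCR amplification bias or chimeras, quality-score
profiles, indels, or strand-of-origin mixtures within one library. Passing
the recovery tests therefore shows that the *statistical machinery* is
correct under its stated assumptions — not that real libraries satisfy
those assumptions. In particular, real amplicon data contain PCR duplicates
(which the package deliberately does not collapse) and alignment artefacts
that a Hamming-only mapper cannot express.

## Numerical and design choices

* **Calling reference.** Mutations are called against the per-library
  consensus, not the genome reference, so germline/haplogroup differences do
  not inflate loads. Contexts of C->T/G->A calls are likewise taken from
  the consensus (with the genome reference supplying the neighbour at window
  edges); expected context fractions enumerate the genome reference over the
  region. The two sequences agree wherever the consensus is callable, except
  at consensus variants, a per-mille effect.
* **N discipline.** N in a read, in the consensus, or as a context
  neighbour never produces a call, a context, or a consensus vote; dropped
  contexts are counted (`nDroppedContext`) rather than silently ignored.
* **Ties.** Modal-base ties cannot reach `minFraction > 0.5` and so become
  N; equal read-vs-consensus and read-vs-haplotype distances keep the read
  (exclusion requires a *strictly* closer haplotype); equal Hamming
  distances at several alignment offsets take the smallest offset.
* **Degenerate inputs.** Empty libraries give all-N consensuses, empty
  histograms refuse calibration, an empty flag set reports `NA` ppm
  explicitly, and a region shorter than the read length is an error.
* **Duplication and depth.** The modal-fraction mask is invariant under
  duplicating a library; the `minDepth` gate intentionally is not (depth
  doubles), which is why the invariance test pins `minDepth = 1`.
* **Type-I calibration of the context test.** The pooled-both-strands null
  matches single-strand deamination only when the context law is the same
  on both strands. On a base-asymmetric genome
  ($P(\text{5'T}\,|\,\text{C site}) = P(\text{prev}=T)$ but
  $P(\text{5'T}\,|\,\text{G site}) = P(\text{next}=A)$), a strand-exclusive
  mutator is *expected* to deviate from the pooled null. The calibration
  experiment in the test suite therefore deaminates both strands at equal
  rates, the condition under which the nominal level applies; for real
  strand-biased data the test measures enrichment relative to the pooled
  opportunity model, which is the convention the reported p-values follow.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at the following
scales, chosen to exercise every code path at mitochondrial-genome scale
while completing in minutes: a 16,569 nt synthetic circular reference with
mtDNA-like composition; a 100,000-read error-only control and a 50,000-read
hypermutated library (250 nt reads, D-loop-style wrapping region) for
threshold purity, strand bias and flagging sensitivity/specificity; 50
replicate libraries of 5,000 reads for the TpC-rejection rate; 300
replicates of 120 whole-region reads for the type-I level of the chi-square;
and printed-table histograms for the exact ppm and threshold arithmetic.

## Known limitations

* Substitution-only: indels are neither simulated nor aligned.
* The haplotype filter is a window-wise Hamming comparison against records
  sharing the reference coordinate system; it is not a database search, and
  it cannot recognize haplotypes that are rearranged or partially covered.
* Amplicon-overlap deduplication between adjacent primer pairs is out of
  scope; each region is analyzed independently.
* `lambdaHat` assumes site-homogeneous errors; error hotspots would show up
  as lack of fit in the control histogram, not in `k` (which is empirical).

## A compact worked example

```{r example}
ref <- simulateReference(16569, seed = 7)      # synthetic rCRS-scale genome
reg <- genomeRegion(16331, 3729)               # wraps the origin

cfg  <- simulationConfig(reg, nReads = 5000, pHyper = 0.01, seed = 5)
lib  <- simulateLibrary(cfg, ref)
al   <- alignReads(lib, ref)
cons <- buildConsensus(al, ref)
calls <- callMutations(al, cons, ref)
loads <- readLoads(al, calls)

ctrl <- simulationConfig(reg, nReads = 5000, pHyper = 0, seed = 6)
ctrlLoads <- with(
    list(a = alignReads(simulateLibrary(ctrl, ref), ref)),
    readLoads(a, callMutations(a, buildConsensus(a, ref), ref)))
cal <- calibrateThreshold(buildHistogram(ctrlLoads, "control"))
cal

cs <- flagHypermutated(loads, threshold(cal))
cs

hyperCalls <- calls[calls$read_id %in% hyperReadIds(cs), ]
strandBias(mutationMatrix(hyperCalls))
dinucleotideSpectrum(hyperCalls, ref, reg)
```
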