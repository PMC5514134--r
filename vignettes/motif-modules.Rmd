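---
title: "Position-bias motif target discovery in co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-bias motif target discovery in co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifnet)
```

## The problem

A short cis-regulatory motif — the CCAAT box bound by NF-Y, the GC box bound
by Sp1 — occurs by chance in a large fraction of all promoters. Asking
whether a gene group is *enriched* for such a motif is then almost
uninformative: the background rate is already 50–90%. What chance occurrences
cannot mimic is *position*: functional proximal elements concentrate within
a couple of hundred bases of the transcription start site (TSS), while
chance matches spread uniformly over whatever sequence is available.
`motifnet` combines that positional signal with a gene co-expression network
to call motif target genes and group them into regulated modules.

## Model and assumptions

### Uniform-placement background

Promoters are represented on the promoter sense strand over TSS-relative
positions $-M..+N$ (position 0 = the TSS base), with repeat and transposon
stretches masked out. For a group of promoters, let $k_i$ be the number of
promoters free (unmasked) at position $i$ and $K=\sum_i k_i$. A motif with
no positional preference is modelled as landing uniformly on any of the $K$
free bases, giving

$$E(d)=\sum_{i=-M}^{N}\frac{k_i}{K}\,|i|,\qquad
  V(d)=\sum_{i=-M}^{N}\frac{k_i}{K}\,i^{2}-E(d)^2 .$$

With no masking this reduces to $E(d)=\frac{M(M+1)+N(N+1)}{2(M+N+1)}$,
which the tests assert for random geometries. For $n$ observed occurrences
with mean absolute anchor distance $\overline{|x|}$,

$$Z=\frac{E(d)-\overline{|x|}}{\sqrt{V(d)/n}}$$

is asymptotically standard normal under uniform placement (central limit
theorem on the mean of $n$ i.i.d. distances). The assumptions worth naming:

* occurrences are treated as independent draws — tandem duplications of a
  site violate this and inflate $n$;
* $n$ counts *occurrences*, not promoters, pooling both strands, so one
  promoter with three sites contributes three distances;
* the anchor is the leftmost base of the matched window in promoter
  orientation. No convention is canonical here; for motifs a few bp wide
  any fixed anchor shifts $\overline{|x|}$ by less than the motif width,
  which is negligible against promoter-scale $E(d)$.

`bias_z()` refuses $n=0$ and $V(d)=0$, and warns below `min_occurrences`
(default 5), where the normal approximation for the mean is poor. Groups
failing that minimum are still tested for enrichment — the calling rule is a
disjunction, so a seed is never silently dropped.

One deliberate mismatch is documented rather than hidden: $k_i$ counts
single-position freeness exactly as defined above, while a scan hit needs
its whole $w$-length window free. Near mask-block edges the background
therefore slightly overstates the eligible anchors; for $w \ll M+N$ the
effect on $E(d)$ is second order.

### Co-expression network

Partial correlations are estimated by shrinking the sample correlation
matrix toward the identity with the analytic intensity
$\lambda^{*}=\sum_{i\neq j}\widehat{\mathrm{Var}}(r_{ij})/\sum_{i\neq j}r_{ij}^{2}$
(clipped to $[0,1]$), inverting, and standardising. This is the standard
small-$n$, large-$p$ estimator for graphical Gaussian models; it is
deterministic, and equals the sample partial correlation as $n/p \to
\infty$ (asserted at $p=3$, $n=10^5$ against the closed form
$(r-r^2)/(1-r^2)=1/3$ for three equicorrelated variables at $r=0.5$).

Edges keep *signed* `pcor >= cutoff` (default 0.04): a negative partial
correlation is not co-expression. An `absolute` flag exists for users who
want both tails. One behaviour of the analytic shrinkage deserves a note:
on data with no correlation structure at all, $\lambda^*$ clips to 1 and
every pcor is exactly zero, so a pure-noise matrix yields an *empty*
network (and `edge_fdr()` reports 0/0 as FDR 0) rather than a trickle of
false edges. The permutation machinery in `edge_fdr()` is therefore most
informative in the presence of some signal, where $\lambda^* < 1$.

For gene sets too large to invert at once, `estimate_pcor_subsampled()`
repeats the estimate on random gene subsets and averages each pair over its
co-occurrences — the classical strategy for genome-scale GGM networks. It
is an option, not the default, because at the problem sizes this package
targets the direct estimate is both exact and fast.

### Target calling and FDR

Each network gene seeds a group — itself plus its distance-1 neighbours
(wider neighbourhoods would blur module boundaries and are out of scope).
The group is tested for motif enrichment against all network genes with
promoters (exact hypergeometric upper tail) and for position bias (Z over
the pooled occurrences). If the *seed itself* carries the motif and either
test passes (both cutoffs inclusive: $p \le$ `p_cutoff` *or* $Z \ge$
`z_cutoff`), every motif-containing group member is called a target. The
target set is a union over seeds, hence invariant to iteration order.

The FDR rerolls the sequence dice while keeping everything else fixed: free
bases are shuffled *within* each promoter (masked blocks stay put, so every
group's $k_i$ background is unchanged), the scan and calling rerun, and

$$\mathrm{FDR}=\frac{\text{mean null target count}}{\text{observed target count}}.$$

A mononucleotide shuffle is the default; a first-order (dinucleotide)
shuffle is available behind `dinucleotide = TRUE` for motifs whose matches
are strongly CpG- or composition-driven.

### Scanning

PWMs come from JASPAR-format count files, with a pseudocount (default 1)
and a background (default uniform; promoter composition can be passed
instead — for human promoters' GC skew that choice matters more than the
pseudocount). Scores are summed log-odds in bits, both strands, whole
window unmasked, overlapping hits all kept. The score threshold for a
per-window p-value is computed by exact dynamic programming over the
discretised score distribution (bin 0.01 bits, configurable): the threshold
returned is the smallest *achievable* word score whose exact upper tail is
within the requested p-value, minus $w \cdot \mathrm{bin}/2$ of
discretisation slack so windows that round onto the chosen bin still pass.
The default p-value $4^{-8}$ matches an 8-bp exact word; a width-$w$ motif
cannot beat $4^{-w}$, so for, e.g., a bare 5-bp CCAAT consensus the
meaningful setting is $4^{-5}$ (the exact-match threshold) — the pipeline
configuration exposes this as `pwm_pvalue`.

### Modules

The target sub-network is clustered with Markov clustering: column-
stochastic flow matrix with self-loops (loop weight = maximum incident edge
weight), alternating expansion (power 2) and inflation (entrywise power,
default 2.0 — the conventional default; the published analyses do not
report their value, so module *counts* are not treated as reproducible
targets), pruning entries below $10^{-5}$. Determinism and label-invariance
come from canonical (sorted) node ordering; a node attracted to several
clusters goes to the larger one, ties to the lower id; modules are numbered
by descending size so module 1 is always the largest. Non-convergence at
`max_iter` returns the current interpretation with a warning rather than
failing a whole pipeline run.

Module statistics (term over-representation, binding fold enrichment) share
one exact hypergeometric kernel; both tails include the observed count, so
`p_enrich + p_deplete >= 1` always. Fold change is
$(k/m)/(K_{pop}/N_{pop})$. No multiple-testing correction is applied by
default — the published tables this mirrors report raw p-values against
fixed thresholds — but `module_enrichment(adjust = TRUE)` emits a
Benjamini–Hochberg column.

## Parameters at a glance

| parameter | default | units | rationale |
|---|---|---|---|
| `upstream`, `downstream` | 2500, 200 | bp | genome-wide scan geometry; the NF-Y preset uses 1000, 0 because CCAAT is too frequent for the wide window |
| `pwm_pvalue` | $4^{-8}$ | per-window tail | 8-bp-exact-word stringency; cap at $4^{-w}$ for narrow motifs |
| `pcor_cutoff` | 0.04 | pcor | the published edge rule |
| `z_cutoff` | 3.5 | sd | NF-Y setting; Sp1 preset uses 4 |
| `p_cutoff` | $10^{-5}$ | probability | NF-Y setting; Sp1 preset uses $10^{-4}$ |
| `min_occurrences` | 5 | count | floor for the normal approximation in Z |
| `inflation` | 2.0 | — | conventional MCL default |
| `n_perm` | 10 | count | FDR resolution of ~1/(10 × observed) |
| `bin` | 0.01 | bits | score-distribution discretisation |

## What the synthetic data does and does not emulate

The generators produce: i.i.d. uniform promoter sequence with masked blocks
of geometric length (mean 150 bp, the scale of common repeats — block
masking, not salt-and-pepper, because mask *geometry* is what the
background must absorb); motif words planted uniformly or with a truncated
geometric decay toward the TSS (any monotone decay would do; geometric
gives a one-parameter knob, `scale`, in bp); expression drawn exactly from
a block-diagonal precision matrix whose within-module partial correlation
is set directly (a module of size $s$ requires `within_pcor` $< 1/(s-1)$
for positive definiteness — checked before sampling); and Bernoulli
binding flags per group.

Deliberately absent: microarray/RNA-seq noise models, normalisation
artefacts, batch structure, probe effects, promoter GC/CpG composition,
correlated masking, motif degeneracy beyond the PWM itself, and enhancer
(distal) regulation. Passing tests therefore demonstrate that the
*estimators and the calling procedure* behave as designed under their own
model; they do not certify performance on real arrays, where preprocessing
and composition effects dominate. The study conditions used throughout the
tests and the acceptance script are: 200 genes, four planted 10-gene
modules, within-module pcor 0.09, 5000 samples, 1 kb promoters with 20%
masking, two TSS-biased CCAAT copies per module gene (decay scale 50 bp),
10 permutations.

## Numerical choices and degenerate inputs

* Coordinates: TSS base is position 0 and belongs to the background sum
  ($i$ runs $-M..N$ inclusive); genomic intervals are 0-based half-open;
  minus-strand promoters are reverse-complemented at extraction.
* Constant genes, missing values, and $n<3$ samples are refused by the
  estimator rather than imputed — silent imputation upstream of an
  inverse-covariance estimate is how artefactual edges are born.
* An all-masked promoter group ($K=0$) is an error; a fully masked single
  promoter simply contributes nothing to $k_i$.
* `pwm_score_threshold` warns and returns just above the maximum score when
  the requested p-value is below the most extreme achievable mass.
* Windows overlapping a promoter end or any masked base are ineligible on
  both strands; a PWM wider than the promoter yields an empty, warned scan.
* All generators and permutation procedures take explicit seeds, log them,
  and are bit-reproducible; pipeline outputs are pure functions of
  (inputs, config, seed).

## Limitations

Only promoter-proximal regulation is modelled — elements beyond the
configured window (distal enhancers) are invisible by design. The Z
statistic detects *bias toward the TSS*; a motif biased away from the TSS
gets a negative Z and is never called. Very small groups fall back to
enrichment only. The hypergeometric module statistics treat genes as
exchangeable units and know nothing of gene length or expression-level
confounding. And the published genome-scale counts (tens of thousands of
genes, hundreds of arrays) are outside what the bundled synthetic studies
emulate; the acceptance script instead verifies the arithmetic identities
those counts imply and the method's behaviour under planted truth.
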