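---
title: "Methods: Z-DNA-forming site discovery and characterization with zfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-DNA-forming site discovery and characterization with zfscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`zfscan` implements a complete computational route from replicated ChIP-Seq
read sets, obtained with a Z-DNA-binding protein probe, to a catalogue of
Z-DNA-forming sites (ZFSs) and their sequence, genomic and transcriptional
characterization. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic validation does and does not establish.

## The B-to-Z transition model

Z-DNA is the left-handed double-helical form of DNA, favoured by
alternating purine-pyrimidine sequence and by negative supercoiling. The
package scores the Z-forming potential of a DNA segment with a zipper
model. A candidate segment of even length $n$ is treated as $n/2$
dinucleotide units, each adopting one of the two anti/syn registers; the
transition free energy at zero superhelicity is

$$\Delta G_{BZ} = \sum_{i=1}^{n/2} \Delta g(d_i, r) + 2\,\Delta g_J ,$$

the sum of per-dinucleotide terms for the chosen register $r$ plus two B-Z
junction penalties. The per-dinucleotide defaults are 0.66 kcal/mol for
d(CG)/d(GC), 1.33 for d(CA)/d(TG) (and AC/GT), 2.40 for d(TA)/d(AT), and a
flat `dg_nonalt` for any dinucleotide that breaks the alternation or sits
in its unfavourable register. Out-of-alternation dinucleotides are
*allowed* at this high cost rather than forbidden, because enriched sites
are observed in vivo whose sequences are not alternating-repeat at all;
forbidding them would make such sites unscorable. The table is symmetric
under reverse complement, so a segment and its reverse complement always
receive the same score.

Supercoiling pays for the transition. For a topological domain of
$N$ bp at superhelical density $\sigma$ the residual-linking free energy is
quadratic, $G(\Delta Lk) = K \cdot RT \cdot \Delta Lk^2 / N$ with
$\Delta Lk_0 = \sigma N / h_B$. Converting an $n$-bp segment from B
($+n/h_B$ turns) to Z ($-n/h_Z$ turns) relaxes
$r = n(1/h_B + 1/h_Z)$ turns, releasing
$G(\Delta Lk_0) - G(\Delta Lk_0 + r)$. Setting the release equal to
$\Delta G_{BZ}$ and solving for $\sigma$ is *linear* (the quadratic terms
cancel in the difference), giving the closed form

$$\sigma_{\mathrm{req}} = -\frac{h_B}{2 r N}\left(
  \frac{\Delta G_{BZ}}{K\,RT/N} + r^2\right) .$$

`sigma_required()` evaluates this exactly; the test suite nevertheless
verifies it against bracketed root finding of the energy balance, to below
$10^{-6}$ in $\sigma$, because the closed form is the one piece of algebra
everything else rests on. Sequences requiring less negative $\sigma$
(closer to zero) are more Z-prone; a segment is called a Z-DNA-forming
region (ZDR) at cutoff $\sigma_c$ when
$\sigma_{\mathrm{req}} \ge \sigma_c$.

### Parameter defaults and the calibration choice

| parameter | default | meaning |
|---|---|---|
| `h_B`, `h_Z` | 10.5, 12.0 bp/turn | helical repeats of B and Z DNA |
| `K_sc` | 1100 (RT·bp) | supercoiling energy constant |
| `RT` | 0.616 kcal/mol | thermal energy at 37 °C |
| `N_domain` | 5000 bp | topological domain length |
| `dg_junction` | 7.0 kcal/mol | per B-Z junction (two per segment) |
| `dg_nonalt` | 4.5 kcal/mol | out-of-alternation / wrong register |
| `L_min`, `L_max` | 12, 50 bp | candidate segment lengths |

The published lineage of Z-DNA scanners does not fix a single energy
table, and the conventional cutoffs $\sigma = -0.08$ and $-0.07$ only
discriminate if the energy scale is right: with a junction penalty of
5 kcal/mol, long windows amortize the junctions so cheaply that random
45%-GC sequence qualifies at $-0.08$ almost everywhere, and the cutoffs
stop meaning anything. The defaults above were calibrated once, as a model
choice: random 500-bp background then contains a ZDR at $-0.08$ in roughly
a third of windows and almost never at $-0.07$, alternating repeats
qualify long before background, and the propensity ordering
d(GC) > d(CA) > d(AT) (most to least Z-prone, i.e.
$\sigma_{\mathrm{req}}$ closest to zero for GC) holds together with
monotonicity of $\sigma_{\mathrm{req}}$ in repeat count for (CG)$_n$ over
12-50 bp. `N_domain` rescales every $\sigma_{\mathrm{req}}$ and is echoed
into every output header, since cutoff values are only meaningful relative
to it.

`scan_zdrs()` slides all even window lengths in `[L_min, L_max]` over the
sequence, minimizes over the two registers per window, merges overlapping
and adjacent qualifying windows into maximal calls, and reports each
merged call with the best (closest to zero) constituent
$\sigma_{\mathrm{req}}$, its register and its $\Delta G_{BZ}$. Windows
containing N are skipped. Ties between registers break toward register 0.
The implementation uses stride-2 running sums; it is tested for exact
agreement with an exhaustive per-window enumeration. `sigma_profile()`
computes the Fig-3B-style landscape: 20-bp windows overlapping by 18 bp
across a center ± 2 kb, one $\sigma_{\mathrm{req}}$ per window, `NA` where
a window contains N or falls off the chromosome (flagged `truncated`).

## Peak calling and reproducibility

Reads (5'-anchored, strand-aware) are extended to
`fragment_extension_bp` (150) fragments and counted in `bin_bp` (50)
genome bins. Each bin's treatment count is tested against a depth-scaled
control expectation under a Poisson model; the control rate is a running
mean over `control_local_bp` (1000) floored at the genome-wide rate, plus
one pseudocount. Estimating the expectation from single control bins
would let control sampling noise masquerade as enrichment — this local
floor is the standard remedy. Bins with $p <$ `alpha_call` ($10^{-5}$)
are merged when adjacent; the peak score is $-\log_{10}$ of the best bin
p-value (computed in log space, so it never underflows), and peaks are
ranked by score with coordinate tie-breaks.

Reproducibility follows the irreproducible discovery rate (IDR)
framework. Peaks from two lists are paired by any-overlap, greedily by
combined rank, each peak matching at most once; unmatched peaks are
excluded. The matched score pairs are rank-transformed to
$u = \mathrm{rank}/(n+1)$ and modelled as a two-component Gaussian copula
mixture: a reproducible component (bivariate normal, mean $\mu$, scale
$\sigma_z$, correlation $\rho$) and an independent standard-normal noise
component. The fit is a pseudo-EM: pseudo-data are obtained by inverting
the model's marginal mixture CDF at $u$ and are recomputed after every
M-step; convergence at $10^{-6}$ in log-likelihood or 1000 iterations.
Three numerical safeguards matter in practice and are part of the method:
the reproducible component is constrained to $\mu \ge 0$, $\rho \ge 0$
(otherwise labels switch when the noise component is nearly empty), its
scale is floored to avoid variance collapse, and the EM is restarted from
three starting points keeping the best likelihood. Finally the fitted
mixture is compared with the independence copula (log-likelihood 0): if
it does not win by its AIC margin, the data carry no separable
reproducible component and every pair is assigned local idr 1 — without
this guard, fully independent rank lists are unidentifiable and the EM
can drift to "everything reproducible". The local idr of a pair is the
posterior probability of the noise component; the global IDR is the
running mean of sorted local idr values.

The site-selection recipe is: self-consistency of the two random
half-read pseudoreplicates of each replicate (IDR ≤ 0.01, QC),
consistency of pooled pseudoreplicates (IDR ≤ 0.001, QC), and consistency
of the three true replicate pairs (IDR ≤ 0.05). The maximum of the three
pairwise counts becomes the cutoff: that many top-ranked peaks are taken
from the pooled-replicate peak list, peaks overlapping a blacklist region
by ≥ 1 bp are removed, and the survivors are the final ZFSs. Per-sample
read counts within ZFSs give the Pearson correlation QC matrix.

At the toy scale of the synthetic validation, the pseudoreplicate
self-consistency counts at the strict 0.01 threshold are conservative and
can legitimately be zero: the planted sites span only a 2.5-fold strength
range, so the *rank order* of ~60 matched half-read peaks is
noise-dominated even though every peak is real. Real data, with peak
strengths spanning orders of magnitude, does not sit in this regime. The
pipeline's cutoff never uses the self counts; they are reported as QC.

## Annotation and null models

Promoters are strand-aware TSS ± 2 kb windows (boundary inclusive);
classification of an interval is by its midpoint with precedence
promoter > gene body > intergenic — a deterministic rule matching the
mutually exclusive categories of a pie-chart summary; the assignment rule
for straddling peaks is otherwise arbitrary. The random-peak null draws
lengths with replacement from the observed ZFS length distribution and
places peaks uniformly (chromosome ∝ size, start uniform, redrawn at
chromosome ends). Random peaks are not excluded from blacklist or gap
regions by default. The ZDR-content comparison between ZFSs and random
peaks uses the Pearson chi-square test on the 2×2 table with a 99%
confidence interval on the difference of proportions; Pol II overlap uses
two-sided Fisher's exact; location-stratified expression uses two-sided
Mann-Whitney. A gene belongs to the promoter stratum if any ZFS midpoint
falls in its promoter, else to the gene-body stratum if one falls in its
span (exclusive, promoter precedence).

## Expression and profiles

RPKM is `reads × 1e9 / (exon_length × total_mapped)`. Expression groups:
`top` = the `n_top` highest-RPKM genes, `bottom` = every gene with
RPKM = 0, `mid` = `n_mid` genes at evenly spaced ranks across the
expressed genes strictly between the two — chosen for representativeness,
as "between" does not pin down a selection. TSS metaprofiles count read
5' ends in 50-bp bins over TSS ± 5 kb, strand-flipped for minus-strand
genes, normalized per million mapped reads; the per-bin significance mask
is a two-sided Mann-Whitney between top and bottom groups at α = 0.05,
unadjusted (a display convention, not an inferential claim). Enrichment
matrices over ZFSs use the ZFS midpoint ± 3 kb in 50-bp bins — a fixed
frame, since variable peak widths do not define a common coordinate
system — with rows ordered by probe enrichment (per-million counts in the
same window, pooled replicates). All per-million quantities are invariant
to library-size rescaling. Reporter fold change is
`(zfs/baseline)/(negative/baseline)`; the baseline cancels.

## The synthetic study and what it shows

`synth_genome()` builds 2 chromosomes × 8 Mb of i.i.d. 45%-GC sequence
carrying 200 non-overlapping genes on an 80-kb grid with jittered spans of
4-7 kb (one gene per 80 kb, comparable to mammalian gene density — with a
denser toy genome, promoter enrichment over a random null cannot
arithmetically manifest). Half the genes are active; 60% of active genes
(60 sites) receive a planted insert drawn from (CG)₁₂, (CA)₁₄, (CGGG)₆ or
a non-alternating (GGAA)₆ control at proportions 0.4/0.3/0.2/0.1. 75% of
sites are placed within TSS ± 500 bp and 25% deep inside gene bodies
(> 2 kb from the TSS); without gene-body sites the location-stratified
expression comparison would have an empty stratum. Each site gets an
enrichment fold drawn uniformly in 8 × (1 ± 0.25). Expression means are
stratified by placement (promoter-site genes log-mean 3.8, other active
3.0, gene-body-site genes 2.2, silent 0), Pol II peaks cover active TSSs
± 300 bp with 10% dropout. `synth_chip_experiment()` emits exactly 400k
reads per sample: background uniform, treatment replicates adding mass at
sites ∝ (fold − 1) × width, IgG and input background-only; read 5' ends
sit at fragment boundaries so the caller's extension re-centers coverage.
All draws flow through per-stage seeds derived from one master seed.

Under the defaults the (CG)₁₂ and (CA)₁₄ inserts are ZDRs at both cutoffs,
(CGGG)₆ falls just below $-0.08$, and (GGAA)₆ never qualifies — so the
recovered ZFS population mixes strong-ZDR, weak-ZDR and non-ZDR enriched
sites, and the ZDR-content contrast against random peaks emerges from the
model rather than by construction (roughly 80% of ZFSs vs a third of
random peaks at $-0.08$).

What the synthetic validation shows: the pipeline recovers planted truth
(precision and recall ≥ 0.9 at the defaults), the statistics discriminate
in the planted directions, and every stage is deterministic given the
seed. What it does not show: robustness to chromatin-driven background
structure, mappability artefacts, GC bias, duplicated reads, or peak
strengths and widths with realistic long-tailed distributions — i.i.d.
background and uniform site placement are far kinder than real data.
Absolute genome-scale counts from real experiments are likewise outside
its reach; published worked examples are instead checked directly as
arithmetic (the max-cutoff rule on printed pairwise counts; ZDR frequency
ratios from printed percentages).

## Problem sizes and determinism

The shipped validation runs the full synthetic study once per seed
(2 × 8 Mb genome, 5 × 400k reads, 10,000 random peaks) in a few minutes
on one CPU, and exercises everything else on small fixtures against
brute-force oracles: exhaustive window enumeration for the scanner,
per-interval classification, hypergeometric enumeration for Fisher's
test, explicit pair counting for Mann-Whitney, root finding for the
energy balance. Degenerate inputs are defined errors, not silent
answers: odd-length or N-containing segments for energies, fewer than 50
matched pairs or all-tied scores for IDR, empty strata for rank tests
(skipped with a flag), zero-variance count vectors for correlation
(flagged `NA`). Coordinates are 0-based half-open everywhere inside the
package; 1-based conventions appear only in external display formats.
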