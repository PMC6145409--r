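---
title: "Scanning a crater-lake radiation for introgression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a crater-lake radiation for introgression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

Young adaptive radiations inside isolated crater lakes are candidate cases
of sympatric speciation, but genome-wide summary statistics often reveal
gene flow with populations outside the lake. The question that matters is
not *whether* any gene flow occurred but *where in the genome*, *into which
species*, and *when relative to diversification*: material that arrived
after species began diverging ("secondary gene flow") points away from
strict sympatry, whereas riverine variation carried in by multiple founding
colonizations and later sorted among species (an "ancestral hybrid swarm")
is still compatible with in-situ divergence. `introscan` implements the
statistical machinery for this dissection and a coalescent simulator that
generates datasets with known truth under each hypothesis, so that every
stage of the pipeline is testable end to end.

## Statistics

**Genome-wide f4.** For populations (A, B; C, D) we compute
$f_4 = \mathrm{mean}_s\,(p_A - p_B)(p_C - p_D)$ over all sites where the
four populations each have at least one called genotype. Under a strictly
bifurcating history ((A,B),(C,D)) the expectation is zero; differential
gene flow between one member of the pair and one of (C, D) shifts it away
from zero. The standard error comes from a delete-one-block jackknife over
blocks of 1,000 consecutive SNPs (never spanning chromosomes) so that
linkage disequilibrium does not deflate it. A trailing block of at least
half the block size stands on its own, otherwise it merges into its
neighbour; the jackknife is unweighted because blocks are near-equal in
size. Significance is the two-sided normal tail, $p = 2\Phi(-|f_4/SE|)$.

**Window D and fd.** Within sliding windows (default 50 kb advanced in
5-kb steps) we compute from derived-allele frequencies the ABBA/BABA
pattern terms, their normalized imbalance D, and the admixture-fraction
estimator fd, which divides the ABBA−BABA excess by its value under
complete donor sharing with a dynamic per-site donor
$p_D = \max(p_2, p_3)$. fd is only interpretable for sharing in the tested
direction, so windows whose numerator sum is non-positive are reported
undefined and can never become candidates; the mirrored test (P1 and P2
swapped) covers the other direction, and the antisymmetry of the numerator
guarantees a window is never a positive candidate in both orientations.

**Polarization.** The derived allele at each site is the allele that is
minor in the distant outgroup; an exact 0.5 tie resolves to the alternate
allele. This makes results deterministic; the tie rule is a documented
choice, not an inference about how any particular study polarized
half-frequency sites.

**Site usability.** A window site enters a test only when every member of
every focal population is called — the strictest reading of "no missing
data within a population" — and the site is still variant across the focal
populations. Windows need at least 100 usable variant sites (configurable)
to be scored.

**π and Dxy.** Per-window nucleotide diversity uses the unbiased per-site
form $\frac{n}{n-1} 2p(1-p)$ and divergence uses
$p_X(1-p_Y) + p_Y(1-p_X)$, both summed and divided by the full window
length in bp. Because invariant sites are not in a VCF, this denominator
makes both statistics lower bounds proportional to the callable fraction;
a per-variant-site mode (`denom = "sites"`) is provided, and the default
is stated in every output. Whether a published analysis normalized by
window length or by genotyped sites is generally unstated; we default to
window length and expose both.

## Null calibration by coalescent simulation

Significance of window fd values cannot be judged against a parametric
null, so thresholds come from simulating windows under the same
demographic model with no migration. The simulator is an event-driven
backwards-time Hudson coalescent on labelled demes: within a deme, `k`
lineages coalesce at rate $k(k-1)/2\,/\,2N_e(t)$ with piecewise-constant
sizes handled by bounding each exponential draw at the next model event;
splits move all lineages of the derived deme into the ancestral deme;
admixture pulses move each lineage of the recipient independently with the
pulse probability. Mutations fall on branches as a Poisson process under
infinite sites.

Recombination inside a window is approximated by concatenating independent
non-recombining sub-blocks (default ten 5-kb blocks per 50-kb window)
rather than an ancestral-recombination graph. What the thresholding needs
from recombination is the intra-window averaging over genealogies, which
the block approximation supplies at a small fraction of the cost; an exact
ARG backend could be slotted behind the same interface.

The default threshold rule is the maximum of the simulated window fd
values — a candidate must exceed every no-migration window. Because the
maximum of a finite simulation grows with the number of windows simulated,
a quantile rule is also provided and is what the calibration checks use:
fresh null windows exceed a `quantile(q)` threshold at rate `1 - q` within
binomial error (both the fresh exceedance count and the
threshold's own order-statistic noise contribute variance to this
comparison, and the checks use the two-sample band accordingly).

## The synthetic radiation

`lake_demography()` encodes the study conditions used throughout the test
suite: five lake species in two subclades — a three-species subclade
(an earlier-diverging species plus a close pair, mirroring radiations like
*Stomatepia*) and a species pair — plus a nearby riverine source
population (MM-like), a more distant one (CR-like), and a distant outgroup.
Defaults: lake $N_e = 2\times10^4$, riverine $5\times10^4$ diploids,
$\mu = 3.5\times10^{-9}$/bp/generation; close pairs split 2,000 generations
ago, subclade A at 4,000, the lake root at 10,000, colonization from the
MM-like lineage at 20,000, the riverine split ten times deeper than the
radiation (100,000) and the outgroup fifty times deeper (500,000). These
are order-of-magnitude choices for a young crater-lake radiation, made
once; the real system's demographic estimates are not printed numerically
anywhere we could adopt them.

Two structural choices deserve comment.

*The founding bottleneck.* Colonization of an isolated crater lake is a
founder event, so the lake ancestor spends its first 1,000 generations at
$N_e = 500$ before expanding. Backwards in time this coalesces most lake
lineages on the lake stem, which is what makes the radiation predominantly
monophyletic across the genome — the dominant signal in real crater-lake
systems. Without it, lake lineage pairs mostly reach the large riverine
ancestral deme uncoalesced and per-window trees shatter into incomplete
lineage sorting noise.

*The three-species subclade.* Sharing of swarm-derived material between
two sister species is a BBBA pattern — both carry the donor allele — and
is invisible to the quartet that contrasts them. A subclade-shared region
is therefore only observable when ancestry sorted on the branch ancestral
to a pair can be contrasted against a third subclade member. With only
two-species subclades the subclade-shared category would be structurally
empty.

**Scenarios.** `scenario_spec()` defines three study conditions with known
truth windows (each simulated window is its own contig, so truth is a set
of window ids):

- `none`: no pulses anywhere; the truth set is empty.
- `secondary_pulse`: one post-divergence pulse (default fraction 0.8 at
  generation 500) from the MM-like deme into one close-pair species,
  applied only in truth windows — introgression after diversification
  began.
- `hybrid_swarm`: the founding population is entirely a two-source
  riverine mixture. Backwards in time, lake-ancestor lineages move to the
  MM-like donor with probability 0.5 just above the lake root, and every
  remaining lineage moves to the CR-like donor immediately after; no
  residual third ancestry remains, which is what "founded as a hybrid
  swarm" means. Truth windows carry the swarm; other windows follow the
  base (single-colonization) history.

The per-lineage independence of pulse inheritance is what produces
differential sorting among descendants: in one window a species' surviving
ancestral lineages may all be CR-derived while its sister's are MM-derived,
and the scan sees exactly the dual-donor, multi-species sharing signature
expected of a swarm.

## Candidate regions and their classification

Windows above threshold are merged (overlapping or abutting spans) into
candidate regions with their peak fd. Regions are then compared across
focal species: a region overlapping (by at least 1 bp) a candidate of
another species in a different subclade is clade-shared; otherwise overlap
within the subclade makes it subclade-shared; otherwise it is private.
Clade-wide sharing takes precedence since it subsumes subclade sharing.
The 1-bp rule reflects that merged regions differ in length across
species; whether a published analysis additionally required significance
against the same donor in both species is unstated, so plain overlap is
the documented choice. Regions from the nearby-donor scans that overlap
any distant-donor candidate (and vice versa) receive a hybrid-swarm flag.
Finally, a region whose focal-species diversity is an order of magnitude
below its chromosome average (strictly below 0.1× the mean over usable
windows of that linkage group) is flagged as a possible selective sweep.

## Topology painting

As a deterministic per-window stand-in for machine-learning genome
segmentation, each window yields an allele-sharing distance matrix
($d_{ij} = \mathrm{mean}\,|g_i - g_j|/2$ over co-called sites, samples
ordered lexicographically so results are input-order invariant), a
neighbor-joining tree, and a rule-based classification after rooting on
the distant outgroup: lake-monophyletic; a configured group (species or
subclade, largest first) clustering with riverine samples to the exclusion
of other lake samples; other polyphyly; or uninformative (fewer than 20
variant sites, a sample pair with no co-called site, or a non-monophyletic
outgroup). Adjacent same-class windows merge into runs and per-class
genomic proportions are reported over the informative span. The HMM/EM
segmentation this replaces proposes its own local topologies; what the
downstream analysis consumes is only the class of relationship per region
and its genomic proportion, which this reproduces deterministically.

## Numerical and degenerate-input choices

- Windows are half-open `[start, end)` in 0-based bp internally and
  reported 1-based inclusive in tables; trailing spans shorter than the
  window size emit no window.
- fd is undefined (never a candidate) when the numerator or denominator
  sum is non-positive; D is undefined when ABBA + BABA = 0.
- A zero jackknife SE reports p = 0 with a degeneracy warning.
- Sites saturating a block under infinite sites (more mutations than
  positions) are capped at one mutation per position; with realistic
  parameters this is unreachable.
- Quantile thresholds use R's default (type 7) estimator.
- The sweep rule uses a strict inequality, so diversity exactly at 0.1×
  the linkage-group mean is not flagged.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, chosen to make
sampling error small relative to the margins being asserted: 1,000-window
null calibrations (about half of null windows have defined fd), 200-window
scenario recoveries with 10% truth windows, 2,000 replicates for the
analytic simulator checks (TMRCA of a pair and mean pairwise diversity,
both within 5%), and 100-window topology paintings.

## Limitations

The simulator emulates drift, splits, pulses and mutation under infinite
sites with free recombination between sub-blocks and none within; it does
not model gene conversion, selection (so simulated sweeps cannot calibrate
the sweep flag — that flag is a screen, not a test), sequencing error,
missing data, or fine-scale recombination-rate variation. Passing the
recovery suites therefore demonstrates that the statistics and
classification logic behave correctly under the stated demographies, not
that any particular empirical dataset meets those assumptions. Real-data
percentages from the original study system additionally depend on its
unreleased whole-genome data and unpublished demographic estimates and are
deliberately out of scope.
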