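---
title: "Dating population splits from mtDNA and microsatellites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating population splits from mtDNA and microsatellites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergekit)
```

divergekit estimates when two populations separated, from two classical
sources of signal: a non-recombining mitochondrial fragment and a panel of
microsatellite loci. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
built-in simulator does and does not emulate.

## The dating models

**Net nucleotide divergence.** For populations X and Y, the mean pairwise
difference count between groups, minus the average of the within-group
means, is the net number of nucleotide differences

$$D_A = \bar d_{XY} - \tfrac12(\bar d_X + \bar d_Y),$$

which removes polymorphism already present in the common ancestor. Under
neutrality its expectation grows linearly with time, $D_A = 2\mu T L$ for
a fragment of $L$ sites evolving at $\mu$ substitutions/site/year, so
$T = (D_A/L)/(2\mu)$ (`net_divergence_counts()`, `time_from_da()`).
Within-group means use distinct sample pairs (the unbiased estimator);
this is what makes $E[D_A] = 2\mu T L$ exact — the simulator confirms the
identity to about 1% over 150 replicates — at the price that a single
finite sample of two identically composed groups can have $D_A < 0$.
Negative estimates are clamped to zero with a warning.

**Rate calibration.** The rate itself comes from an outgroup with a
fossil-calibrated split: $\mu = d_{net}/(2T_{split})$
(`calibrate_rate()`). The worked example throughout the package uses the
net TN93+Γ distance 0.567 (SD 0.175) between cheetah and puma mtDNA over
a 4.92 Ma split (95% CI 3.86–6.92 Ma), which gives
$\mu = 5.76\times10^{-8}$/site/year. The rate CI combines $d \pm 2\,SD$
with the calibration extremes (smallest distance over oldest split, and
vice versa); this reproduces the published interval
$1.57\times10^{-8}$–$1.19\times10^{-7}$, which a $\pm1.96\,SD$ normal
interval does not. Time CIs invert the rate CI (high rate → low time).

**Microsatellite clocks.** Two distances are inverted to times, both in
repeat units and both with mutation rate $\beta$ per locus per
generation:

* $(\delta\mu)^2$, the squared difference in mean allele size averaged
  over loci, with $E[(\delta\mu)^2] = 2\beta G$ generations
  (`delta_mu_squared()`, `time_from_dmu2()`);
* $D_{SW}$, the between-population mean absolute allele-size difference
  minus the within-population average (`dsw()`), inverted through its
  drift-plus-mutation expectation
  $$f(\tau) = \sqrt{2/\pi}\left[\sqrt{2\beta\tau + 4\beta N_e} -
  \frac{4\beta N_e}{\sqrt{8\beta N_e + 1}}\right]$$
  by bisection on $\tau \ge 0$ (`time_from_dsw()`). $N_e$ is obtained
  from the stepwise-mutation equilibrium
  $H_E = 1 - 1/\sqrt{1 + 8 N_e \beta}$ (`ne_from_he()`), using the mean
  of the two populations' $H_E$ by default (the source of $H_E$ is not
  uniquely determined by the method; the choice is overridable).

As printed in the literature the $D_{SW}$ equation's parenthesization is
ambiguous: the $\sqrt{2/\pi}$ factor could scale the whole bracket or the
first term only. The default applies it to the bracket: the factor is
the half-normal mean-to-sd ratio converting a size variance into an
expected absolute difference, and both terms of the bracket are on that
same variance scale, so scaling one but not the other would mix units.
The literal reading is available via
`literal_sqrt_first_term_only = TRUE`; it makes the forward value
strictly smaller and hence the inverted dates older at the same
distance, and the package's forward–inverse identity tests cover both.

Three literature point rates are bundled (`rate_catalogue()`): human
"fast" $2.05\times10^{-3}$, human "slow" $5.6\times10^{-4}$ and an
average mammalian $2.05\times10^{-4}$ per locus per generation. Because
$\beta N_e$ is pinned by $H_E$ alone, $\hat\tau \propto 1/\beta$ exactly
for both clocks; dates obtained under different rates differ by the
inverse rate ratio and nothing else. Generation time defaults to 6 years
(configurable), matching the worked example.

## Sequence statistics

Distances use the Tamura–Nei (TN93) model, optionally with
gamma-distributed site rates: each $-\log w$ term becomes
$\alpha(w^{-1/\alpha} - 1)$, with $\alpha = 0.118$ in the worked
mitochondrial analyses. Base frequencies are estimated from the two
sequences being compared (as in pairwise-distance practice); sites with
gap or N in either sequence are excluded pairwise; a non-positive
logarithm argument raises a saturation error naming the pair — with
extreme base compositions this is reachable at a single difference, and
the p-distance mode is the appropriate fallback for such degenerate
inputs. The implementation is checked against an independent computation
(ape's `dist.dna`) to $10^{-10}$, with and without Γ.

Multi-base deletions are recoded to a single presence/absence column
(`recode_indel()`) so that difference counts score one event, not one per
column; the worked 915-bp concatenation (five blocks in mitochondrial
reference coordinates, tRNA-Leu through control region) carries a 3-bp
deletion treated this way. After collapsing, per-site quantities use the
collapsed length (913 + 1 indel column for that fragment), a 0.2% effect
on π. A block in which no sequence carries the deletion is left unchanged.

Haplotype diversity uses the small-sample estimator
$H_d = n(1-\sum p_i^2)/(n-1)$ and nucleotide diversity the mean pairwise
difference per site, with the Nei (1987) variance estimators (eqs. 8.12
and 10.7); published tables label these inconsistently as SD or SE, and
the package reports the Nei estimator and calls it SD.

Differentiation is measured by an AMOVA-style $\Phi_{ST}$ on squared
model distances with a label-permutation p-value, and by a Monte-Carlo
exact test on the haplotype-by-population table: the statistic is the
multivariate hypergeometric probability of the table given its margins,
the null tables are sampled with fixed margins (`r2dtable`), and both
tests use the +1/+1 correction. The Markov-chain exact test that desktop
population-genetics suites implement is asymptotically equivalent; the
Monte-Carlo version is exactly reproducible from a seed. Under simulated
panmixia both p-values are uniform (KS test over 200 replicates) provided
the data are polymorphic enough for the statistic to have rich support;
with near-monomorphic fragments the discrete tie mass at p = 1 makes any
permutation test conservative, which is a property of the data, not of
the implementation.

The diagnostic-site classifier (`classify_haplogroup()`) encodes the
fixed, exclusive states of the screened 139-bp fragment: the 3-bp
deletion at 12665–12667, A at 12698 or C at 16473 call the Northern-East
African haplogroup; T at 16448 the Asiatic one; G at 12707 the North
African population; otherwise readable fragments default to the
sub-Saharan group, which carries no exclusive state of its own. Conflicts
raise an error listing the offending sites rather than guessing.

## Microsatellite statistics

Expected heterozygosity is the unbiased $n(1-\sum p_i^2)/(n-1)$ over
observed allele copies. $F_{ST}$ is Weir–Cockerham θ; since the
published analyses do not name their estimator, θ was chosen as the field
standard and is recorded in output metadata. θ and the allele-size-based
$R_{ST}$ share one nested method-of-moments engine
(populations / individuals / gene copies), applied to allele indicators
or to allele sizes respectively; on a biallelic single-step locus the two
agree identically, a useful cross-check that is part of the test suite.
$D_{PS}$, one minus the proportion of shared alleles between two
individuals, feeds a PHYLIP-format matrix exporter for external
neighbor-joining; individuals missing more than half their loci are
excluded with a warning. Missing data are handled by per-locus pairwise
deletion throughout.

## The bottleneck test

After a recent decline, rare alleles are lost faster than heterozygosity
decays, so loci transiently show more $H_E$ than expected for their
allele count. For each polymorphic locus the package simulates
equilibrium coalescent samples of the observed number of gene copies
under SMM or TPM mutation (the simulation kernel is in C++ for speed),
tunes θ by bisection on log θ until the mean simulated allele count
matches the observed count within 2%, and keeps replicates with exactly
that count. The TPM is parameterized by the single-step probability
(default 0.95) and the variance of the geometric multi-step jump
(default 12).

The conditional $H_E\,|\,k$ distribution is markedly left-skewed: its
median exceeds its mean. A one-tailed Wilcoxon signed-rank on
mean-centred differences therefore rejects far too often under the null
(about 0.15–0.18 at nominal 0.05 in the package's calibration
simulations, even though the per-locus exceedance probability
$P(H_{eq} < H_{obs})$ is 0.506, i.e. the simulation itself is
calibrated). The package computes the Wilcoxon on **median-centred**
standardized differences, which restores the nominal level (observed
type-I 0.04 over 100 equilibrium datasets); the classical mean-based
standardized difference is still reported per locus. Power against a
very recent, severe crash is intrinsically limited under the SMM: a
100-fold crash only 10 generations old is 0.1 coalescent units of the
crashed size, so little allele loss has occurred and the test detects it
in only ~10% of replicates at the default population sizes; detection
rises steeply as the crash ages (the test suite checks the directional
shift). This mirrors the known weakness of the SMM variant of the
heterozygosity-excess test.

## The simulator

`simulate_dataset()` draws a standard two-deme coalescent with an
instantaneous split `tau_gens` ago into an ancestral deme, no migration,
an optional outgroup lineage joining at its divergence time, and optional
piecewise population-size crashes. mtDNA is one non-recombining locus
with gene-copy number $N/4$ relative to the diploid size (haploid,
maternally inherited; configurable), sampled once per individual;
microsatellites get independent trees over $2N$ copies, two per
individual. Sequence mutation places events at rate
$\mu \cdot r_s$ per site-year (site factors $r_s$ gamma-distributed when
a shape is given) and jumps to a different base with HKY-proportional
probabilities, so the realized per-site substitution rate is exactly μ
regardless of composition — the property the dating identity needs.
Microsatellites mutate per generation under SMM/TPM with a reflecting
floor at one repeat. Time is continuous (the Kingman approximation); a
discrete-generation mode is not implemented, as no supported analysis
requires it.

Defaults emulate the central study scenario: 11 + 29 sampled individuals,
diploid sizes 5000 (chosen so that equilibrium $H_E \approx 0.67$ at
$\beta = 2.05\times10^{-4}$ and mtDNA within-population diversity land in
the observed range), split 7000 generations (42 000 years) ago, a 915-bp
fragment at $5.76\times10^{-8}$/site/year with Γ shape 0.118 and ts/tv
10, an outgroup at 4.92 Ma, and 18 SMM loci. What the generator does not
emulate: recombination, migration and admixture, selection, sequencing or
genotyping error, and allele-size constraints beyond the floor — so
passing recovery tests demonstrate estimator correctness under the
neutral isolation model, not robustness to those violations.

A note on recovery precision: with a single mitochondrial locus and
$E[D_A] \approx 4.4$ net differences, the mutational noise (a handful of
effectively independent deep branches) plus ancestral lineage sorting put
the relative standard deviation of $\hat T_{DA}$ near 0.35–0.4 under the
default scenario; the estimator is unbiased (median $\hat T \approx$
truth over replicates), but the median absolute relative error sits
around 0.25–0.32. Tighter recovery requires either more loci or deeper
splits, not a different estimator.

## Problem sizes and reproducibility

The test and acceptance suites use deliberately scaled simulation sizes
chosen as a sensible validation budget: 150 replicates for the
$E[D_A] = 2\mu TL$ identity, 200 for p-value uniformity, 100 equilibrium
and 50 crash datasets for the bottleneck operating characteristics (with
400 retained null replicates per locus; the analysis default is 10 000),
and 50 replicates for split-time recovery. Every stochastic function
takes an explicit seed and restores the caller's RNG state;
`simulate_dataset()` is bit-reproducible from its config and seed, and
`pipeline()` re-runs byte-identically from the same YAML config. Config
files are YAML; every report records the seed and the parameter values
actually used.
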