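# divergekit

Population-genetic divergence dating from mitochondrial sequences and
microsatellite genotypes, in one reproducible R package. It is aimed at
conservation and population geneticists who have (a) an alignment of a
non-recombining mtDNA fragment, (b) a diploid microsatellite genotype
table, and (c) a population map, and who want diversity and
differentiation statistics, a calibrated substitution rate, and dated
population splits with honest confidence intervals — plus a built-in
coalescent simulator to validate the whole pipeline against known truth.

## What it computes

**Sequence side.** Haplotype collapse and diversity
(*H*<sub>d</sub> with the Nei small-sample variance), nucleotide
diversity (π), Tamura–Nei (TN93) distances with optional Γ rate
heterogeneity, AMOVA-based pairwise Φ<sub>ST</sub> with permutation
tests, a Monte-Carlo exact test of differentiation, multi-base indel
recoding (one deletion = one event), and a diagnostic-site haplogroup
classifier for short (139-bp) fragments typical of degraded samples.

**Microsatellite side.** Unbiased expected heterozygosity,
Weir–Cockerham θ, allele-size R<sub>ST</sub>, Goldstein's
(δμ)², Shriver's stepwise-weighted distance D<sub>SW</sub>, the
proportion-of-shared-alleles distance D<sub>PS</sub> (exported in PHYLIP
format for neighbor-joining), and a coalescent heterozygosity-excess
bottleneck test under the stepwise (SMM) and two-phase (TPM) mutation
models.

**Dating.** Three estimators tied together by an outgroup-calibrated
rate:

* *D*<sub>A</sub> = 2μT — net nucleotide differences against a rate
  calibrated via d = 2μT on a fossil-dated outgroup split;
* (δμ)² = 2βG — mean-size distance over a per-generation microsatellite
  rate;
* D<sub>SW</sub> = √(2/π)·[√(2βτ + 4βN<sub>e</sub>) −
  4βN<sub>e</sub>/√(8βN<sub>e</sub> + 1)] — inverted numerically, with
  N<sub>e</sub> from the SMM equilibrium
  H<sub>E</sub> = 1 − 1/√(1 + 8N<sub>e</sub>β).

CI propagation runs the distance spread and the calibration CI through
every inversion (high rate → low time).

**Simulator.** A two-deme split coalescent with an outgroup lineage,
optional population crashes, HKY sequence mutation with Γ site rates,
and SMM/TPM microsatellite mutation — every dataset bit-reproducible
from a config and seed. See the vignette
(`vignettes/divergence-dating.Rmd`) for models, defaults and
limitations.

## Worked example

```r
library(divergekit)

# calibrate the mtDNA substitution rate on a 4.92 Ma outgroup split
cal <- calibrate_rate(d_net = 0.567, d_sd = 0.175,
                      T_split = 4.92e6, T_ci = c(3.86e6, 6.92e6))
cal
#> Substitution rate: 5.76e-08 subs/site/year
#>   95% CI: 1.57e-08 - 1.19e-07

# date a split from a net difference count of 4.412 over 915 sites
time_from_da(4.412, 915, cal)
#> DA divergence estimate: 41 800 years  (CI 20 300 - 154 000 )

# simulate a 42 000-year split and run the same estimator on it
cfg <- sim_config(seed = 42)        # 11 + 29 samples, 915 bp, 18 loci
sim <- simulate_dataset(cfg)
da  <- net_divergence_counts(sim$aln, sim$popmap, c("X", "Y"))
da
#> [1] 1.08867
time_from_da(da, 915, known_rate_calibration(5.76e-8))
#> DA divergence estimate: 10 300 years
expected_heterozygosity(sim$gm, sim$popmap, "X")$mean
#> [1] 0.6243386
```

The first two results reproduce the published worked arithmetic (the
rate 5.76×10⁻⁸/site/year, a split at ~41 900 years with the printed CI).
The simulated replicate illustrates the real sampling spread of a
single-locus estimator: this draw lands at 10 300 years against a true
42 000 — unbiased across replicates (`recovery_experiment()` shows the
median estimate at the truth) but with a relative standard deviation
near 0.4, which is exactly why the published intervals are wide.
`run_paper_arithmetic()` reruns all five published checks and reports
each computed value, reference and relative error.

A thin command-line front-end over the same functions is installed at
`inst/cli/divergekit.R`:

```sh
Rscript inst/cli/divergekit.R paper-check
Rscript inst/cli/divergekit.R simulate --out-prefix run1 --seed 5
Rscript inst/cli/divergekit.R pipeline --config analysis.yaml --out results.json
```

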