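# cas9enrich

Simulation and quantification toolkit for **Cas9-targeted,
amplification-free metabarcoding** — estimating the composition of mixed
communities (nematodes, bacteria, yeasts) by enriching a shared
marker-gene (rDNA/ITS) region with CRISPR-Cas9 cleavage instead of PCR,
and sequencing it with long nanopore-style reads. It is written for
people designing or analysing such assays: it lets you scan references
for probe sites and off-targets, rehearse the whole experiment in
silico, and quantify enrichment and community recovery with the field's
standard statistics.

## What it computes

**Enrichment score.** For reads mapped to a genome with a target region
of length *L*<sub>target</sub> present in *N*<sub>target</sub> copies,

> *E* = (*R*<sub>target</sub> · *G*) / (*R*<sub>total</sub> ·
> *L*<sub>target</sub> · *N*<sub>target</sub>)

is the fold increase in target-covering reads over the uniform-coverage
expectation (*G* = genome size; uniformly scattered reads give *E* ≈ 1).

**Copy-number-corrected composition.** A community member with gDNA mass
fraction *m*, genome size *G* and marker copies *c* per genome is
expected to contribute marker reads ∝ (*m*/*G*)·*c*; observed
proportions (read counts or mean depth) are compared against this with
**Lin's concordance correlation coefficient**
ρ<sub>c</sub> = 2 cov(*x*,*y*) / (var *x* + var *y* + (x̄ − ȳ)²)
(population moments).

**Kinetic models.** PCR: *C*(*n*) = *C*(*n*−1)(1+α) — a 10% efficiency
deficit turns a 1:1 ratio into 0.29 by cycle 25. Cas9 enrichment:
*P*(*t*) = *S* − e<sup>−β*t*</sup> — even a two-fold cleavage-rate gap
converges to the true 1:1 ratio as the reaction runs to completion.

**Simulation.** Protospacer/PAM scanning with bounded mismatches (blunt
cut 3 bp upstream of the NGG PAM), in-silico digestion with
dephosphorylation and Cas9 end-blocking bookkeeping, library sampling
with an off-target background component, nanopore-like error-bearing
reads with a truth table, and read assignment back to marker references.

## Worked example

The bundled demo configuration simulates a three-species nematode mock
community with one probe pair flanking a 1.2 kb marker unit:

```r
library(cas9enrich)
cfg <- load_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "cas9enrich"))
report <- run_all(cfg)
print(report)
#> pipeline run (seed 20260927): 3000 reads, 2945 assigned
#>   mean enrichment E = 12.3 across 3 members
#>   observed-vs-expected CCC rho_c = 0.9975 (species rank)
cbind(observed = round(as.numeric(report$observed), 3),
      expected = round(as.numeric(report$expected), 3))
#>      observed expected
#> [1,]    0.525    0.522
#> [2,]    0.292    0.306
#> [3,]    0.183    0.172
```

Reads concentrate 12-fold over the uniform expectation on the target
region, and the recovered species proportions track the
copy-number-corrected expectation (ρ<sub>c</sub> = 0.998). The numbered
drivers under `analysis/` run the full narrative — kinetic-model
contrast, expected composition of the ten-member microbial standard,
single-species enrichment with coverage and read-length profiles, and
mock-community quantification — writing tables under `results/`:

```sh
Rscript analysis/01_kinetic_models.R
#> PCR: with efficiencies 1.0 vs 0.9 the B/A ratio falls from 1 to 0.29 by cycle 25
#> Cas9: with cleavage rates 0.1 vs 0.05 the B/A ratio rises from 0.512 at t = 1 to 1.000 at t = 500
```

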