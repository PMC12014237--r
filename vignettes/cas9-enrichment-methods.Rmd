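---
title: "Models and methods behind cas9enrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cas9enrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

PCR-based metabarcoding estimates community composition by amplifying a
shared marker gene and counting reads per taxon. Amplification is
exponential, so any difference in per-cycle efficiency between templates
compounds: after $n$ cycles a product with efficiency $\alpha$ has grown by
$(1+\alpha)^{\,n-1}$, and two templates that started 1:1 end at
$\bigl((1+\alpha_B)/(1+\alpha_A)\bigr)^{\,n-1}$. With $\alpha_A = 1$ and
$\alpha_B = 0.9$ — a 10% efficiency deficit — the ratio is 0.29 after 25
cycles. Cas9-guided enrichment avoids amplification altogether: genomic DNA
is dephosphorylated (so sequencing adapters cannot ligate to pre-existing
ends), then Cas9 loaded with custom 20-mer crRNA probes cleaves at
user-chosen sites flanking the marker region. Cleavage exposes a ligatable
5' phosphate on one side of each cut, while the Cas9 ribonucleoprotein
stays bound to the other side and blocks it, so adapters attach
predominantly to the excised target fragments.

`cas9enrich` implements the computational side of such a study as a
reusable toolkit: probe-site scanning and off-target reporting, in-silico
digestion and library simulation, read simulation with a truth table,
read assignment, enrichment scoring, copy-number-corrected quantification,
and the two kinetic models. The `analysis/` scripts run these pieces as a
narrative workflow; every computation lives in the package and is covered
by the test suite.

# Kinetic models

Two idealized models, evaluated exactly:

* **PCR**: $C(n) = C(n-1) + C(n-1)\alpha$, $\alpha \in [0,1]$, starting
  from $C(1) = 1$. "After $n$ cycles" means evaluating the recurrence
  through index $n$, i.e. $n - 1$ multiplicative steps — the only
  convention that reproduces the 0.29 endpoint above.
  `pcr_trajectory()` iterates the recurrence and is tested against the
  closed form to $10^{-12}$ relative.
* **Cas9**: $P(t) = S - e^{-\beta t}$, with starting concentration $S$ and
  cleavage rate $\beta$. The formula is implemented verbatim; it is only
  dimensionally sensible at $S = 1$ (where $P(0) = 0$ and
  $P(t) \uparrow 1$), so other values of $S$ trigger a warning, and a
  `normalized = TRUE` variant $S\,(1-e^{-\beta t})$ is available but off
  by default. The bias ratio $P_B(t)/P_A(t)$ rises monotonically toward 1
  whenever $\beta_B < \beta_A$: run the reaction long enough and rate
  differences stop mattering — the central quantitative argument for
  enrichment over amplification.

# Probe-site scanning

A cleavage site is a 20-mer protospacer match followed immediately by an
NGG PAM on the same strand; Cas9 cuts bluntly 3 bp upstream (5') of the
PAM, i.e. between protospacer positions 17 and 18 counted from the
PAM-distal end. Conventions:

* Mismatches are Hamming substitutions only — no bulges — and the PAM
  itself must match exactly (its N position accepts any of A/C/G/T but
  never an ambiguous subject base; subject `N` never matches anything).
* Coordinates are 0-based half-open internally on the forward strand;
  `cut_position` is a between-base index; TSV reports render 1-based
  inclusive coordinates. Mismatch offsets are counted 1–20 from the
  PAM-proximal end, and `probe_conservation()` classifies offsets 1–10 as
  PAM-proximal (strong effect on cleavage) and 11–20 as PAM-distal (weak
  effect), following the usual SpCas9 seed-region picture.
* Overlapping candidate sites are all reported; no suppression rule is
  applied. The scanner gives no cleavage-rate prediction: the
  literature's mismatch-to-rate maps are assay-dependent, so the engine
  reports mismatch profiles and leaves rates to the user.

The implementation is a vectorized position-wise comparison; the test
suite holds it against an independently written naive sliding-window
oracle on 200 randomized instances (with and without planted sites) and
checks strand symmetry, mismatch-budget monotonicity and cut placement as
properties.

# Digestion, end protection and the library

`digest()` cuts each supplied site independently with probability
`cleavage_prob` and tracks, per fragment end: origin (`native` or
`cas9_cut`), ligatability and the blocking probe. Native genome termini
are dephosphorylated, hence never ligatable. At each realized cut exactly
one new end is ligatable and one is blocked. Which side the bound Cas9
blocks is not universally agreed; we adopt the convention that Cas9 stays
on the **PAM side** of the cut, so the PAM-distal side is ligatable. With
probes oriented so their PAMs face away from the region of interest
(ROI), the excised target fragment then carries two ligatable ends — the
geometry that makes the assay enrich. The convention is a single switch
(`pam_side_blocked = FALSE` flips it).

`sample_library()` draws molecules with replacement: with probability
$1-b$ from fragments with at least one ligatable end (weight =
`copy_weight` × ligatable ends), and with probability $b$ a uniform
random genome slice — a stand-in for DNA that escaped dephosphorylation
or fragmented after the phosphatase step. Background lengths follow a
log-normal; the `(mean, sd)` parameters are the mean and standard
deviation of the length itself and are converted to log-scale parameters
internally. Defaults (3000 ± 2000 bp) are typical of sheared high
molecular weight extracts; $b$ defaults to 0.05 in the pipeline and is a
free parameter everywhere.

One subtlety: a single digestion realization of one genome copy is the
wrong model when `cleavage_prob < 1`, because a missed cut then removes a
whole ROI copy from the library, which no real multi-template extract
shows. `run_all()` therefore digests `n_genome_copies` (default 20)
independent template copies per member and pools the fragments; with the
defaults this keeps per-species ligatable-end weights within a few
percent of their expectations. The default `cleavage_prob = 0.9` is an
assumption, not a measured value — per-site efficiencies are rarely
published — and is exposed in the configuration.

# Read simulation

One read per molecule, started from a uniformly chosen ligatable end
(background molecules: either end); starting from the left end yields a
forward read, from the right end the reverse complement, which is what
produces the approximately equal forward/reverse coverage of the target
region. Errors are i.i.d. per base; the default rates (2.5% substitution,
0.5% insertion, 0.5% deletion — 96.5% accuracy) emulate older-generation
nanopore flow cells. Quality strings are a constant placeholder
character: per-base quality modelling, homopolymer-specific errors and
chimeras are out of scope, so passing tests say nothing about those
failure modes of real data. Every read is recorded in a truth table
(source molecule, interval, strand, error counts), and
`assignments_from_truth()` converts it into idealized alignments for
enrichment accounting on simulations.

# Assignment and quantification

`assign_reads()` gives each read at most one reference: candidates are
pre-screened by shared 13-mer counts on both strands, then scored by
global unit-cost alignment (`utils::adist`), with identity defined as
matches / alignment columns **including indel columns** — the right
denominator for indel-rich long reads. Ties break by identity, then
aligned span, then lexicographic reference name, making results
deterministic across backends; externally produced PAF alignments
(`read_paf()`) go through the same best-hit and threshold policy with
identity = residue matches / block length. Two shortcuts keep the
backend honest but fast: reads identical to a reference (or its reverse
complement) skip alignment, and a candidate is skipped when
$\min(\ell_r,\ell_q)/\max(\ell_r,\ell_q)$ — an upper bound on global
identity — falls below `min_identity`. A consequence of global alignment
is that reads from partially digested, over-long fragments usually fall
below the identity floor and are counted unassigned rather than being
force-fitted; this mirrors a stringent mapping filter.

On-target accounting: a read is on-target when at least 50% of its
aligned span overlaps any ROI copy (the boundary case counts as
on-target). The fold enrichment is
$$E = \frac{R_\mathrm{target}\, G}{R_\mathrm{total}\, L_\mathrm{target}\,
N_\mathrm{target}},$$
the fold increase in target-covering reads over the uniform-coverage
expectation, normalized by genome size $G$, target length
$L_\mathrm{target}$ and target copies per genome $N_\mathrm{target}$.
Uniformly placed reads give $E \approx 1$ (checked as a property), and
the formula is exact arithmetic with double precision (integer inputs are
promoted before multiplying — $R\cdot G$ overflows 32-bit integers
already at desk scale).

Expected composition applies the copy-number correction: member $i$ with
mass fraction $m_i$, genome size $G_i$ and marker copies $c_i$ is
expected to contribute marker reads in proportion to $w_i \propto (m_i /
G_i)\, c_i$. The result is invariant to uniform rescaling of masses and
to the genome-size unit, provided it is uniform. Observed proportions
come in two modes — `read_count` (share of assigned reads) and
`mean_depth` (aligned bases over reference length, normalized) — because
"coverage" is ambiguous in pipeline descriptions; with full-length marker
reads the two nearly coincide, and `read_count` is the default.
`aggregate_rank()` collapses species to genus for the common situation
where single-read accuracy cannot support species-level calls.

Agreement between observed and expected proportions uses Lin's
concordance correlation coefficient with population (divisor-$n$)
moments,
$$\rho_c = \frac{2\,\mathrm{cov}(x,y)}{\mathrm{var}(x) + \mathrm{var}(y)
+ (\bar x - \bar y)^2},$$
which penalizes location and scale shifts that Pearson's $r$ ignores.
Significance testing is deliberately omitted: the appropriate degrees of
freedom for combined-replicate proportion data are not well defined, so
the package reports the coefficient and its moment components only.

# Synthetic genomes and what they do not emulate

`synthesize_genome()` builds an i.i.d. random background at a requested
GC content with `copy_number` exact tandem copies of a marker unit
inserted at a chosen locus; `plant_probe_site()` writes protospacer+PAM
sites (optionally with a controlled number of seeded mismatches) into the
unit. Tandem copies are exact duplicates — no intra-genomic repeat
heterogeneity, rDNA secondary structure or ploidy — and the background
has no repeat structure of its own, so read assignment is easier here
than on real genomes. Passing the recovery tests therefore demonstrates
the correctness of the bookkeeping and estimators under the stated model,
not robustness to repeat-rich genomes or database incompleteness.

# Reproducibility and numerical choices

Every stochastic function takes an explicit seed; `run_all()` fans a
single global seed out to per-stage child seeds through a stable integer
derivation (`derive_seed()`, kept below $2^{31}$), so any stage can be
rerun in isolation and full runs are byte-identical — the test suite
asserts hash-level equality of FASTQ/TSV/JSON artifacts across repeated
runs. RNG state of the caller is always restored. Degenerate inputs have
defined behaviour: empty sequences scan to empty site lists, zero-length
molecules are skipped with a warning, an all-background run warns and
skips quantification, zero assigned reads is an explicit "no signal"
error, and a library with no ligatable fragments and no background is an
explicit "empty library" error.

Problem sizes in the test suite are chosen to keep statistical checks
sharp at desk scale: scanner–oracle equivalence on 200 instances of
0.2–0.8 kb, digestion invariants over dozens of randomized site sets,
enrichment recovery on a 66 kb genome with 5 target copies at 50,000
library molecules (measured $E$ within 5% of the analytic prediction),
uniform-null calibration at 100,000 placements ($E \in [0.8, 1.2]$), and
composition recovery for a five-species community at 50,000 error-free
reads (±1% absolute per species) plus ~4%-error reads at a 0.90 identity
floor ($\rho_c \ge 0.95$ against truth).

# Known limitations

* No cleavage-efficiency prediction from mismatch profiles; the scanner
  reports, the user decides.
* The background model is a deliberate simplification (uniform slices,
  log-normal lengths); real off-target reads cluster at nicked or
  fragile sites.
* Constant-character base qualities; no basecaller or signal-level
  simulation; no adaptive sampling.
* Identity from global alignment penalizes length mismatch by design;
  users wanting local mapping semantics should supply external PAF
  alignments.
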