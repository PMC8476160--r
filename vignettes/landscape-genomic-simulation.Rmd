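---
title: "Simulating landscape genomics with landgen: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating landscape genomics with landgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(landgen)
```

## The model

`landgen` simulates a species of diploid, diallelic individuals evolving
forward in time in continuous space on a stack of raster layers. Each
individual carries a position $(x, y)$ in cell units, a sex, an age, a genome
of $L$ binary loci on two homologous chromatids, and one phenotype per trait.
Layers can serve as movement or dispersal resistance surfaces, as the
carrying-capacity field $K_{x,y}$ of the logistic mortality model, and as the
selection surfaces $e_{p;x,y}$ that traits track. Nothing at the population
level is imposed: spatial genetic structure, local adaptation, and density
regulation are emergent.

A run has two phases. The **burn-in** iterates movement, mating, and
density-dependent mortality *without genomes or selection* until a battery of
stationarity tests passes, leaving the species in a stationary spatial
distribution. Genomes are then assigned independently from the architecture's
starting allele frequencies, so the **main phase** begins with no pedigree and
no spatial genetic structure. Each main timestep applies, in order:

1. **movement** (optional),
2. **mating** — mate search within a radius, Bernoulli mating decisions,
   gamete formation with recombination and mutation, offspring dispersal
   from the parental midpoint,
3. **mortality** — density dependence composed with selection on all traits,
4. **change events** — environmental and demographic changes that take
   effect at the ends of their scheduled timesteps.

### Mortality

An individual dies with probability

$$P_{d;i} = 1 - (1 - P_{d;x,y}) \prod_{p=1}^{m} \omega_{i,p}
  \prod_{l} (1 - s_l g_{i,l}),$$

the product of a local density-dependent term, one fitness factor per trait,
and one factor per registered deleterious locus. The density term derives
from logistic growth $dN/dt = rN(1 - N/K)$ with expected births
$E[N_b] = \beta N$:

$$P_{d;x,y} = \mathrm{clamp}\left(\beta - r\left(1 -
  \hat N_{x,y}/K_{x,y}\right),\ p_{\min},\ p_{\max}\right),$$

so that births balance deaths exactly at $\hat N = K$. The logistic balance
alone does not pin down $E[N_b]$; `landgen` uses the per-capita expectation
$\beta = b\lambda/2$ (each individual joins at most one pair per timestep; a
pair mates with probability $b$ and yields $\lambda$ expected offspring).
$\hat N_{x,y}$ is a windowed count estimate (below). Cells with $K = 0$ take
$p_{\max}$; the clamp bounds default to $[0.001, 0.999]$ and avoid
certain-death or immortality artifacts at extreme densities.

Note that realized per-capita births fall below $\beta$ — some individuals
find no mate, and newborns face mortality in their birth timestep — so a
stationary population settles below $\sum K_{x,y}$ by a factor that grows
with turnover ($b\lambda$) and with spatial clumping (short dispersal
relative to the mating radius concentrates individuals, raising the density
they experience). The canned scenarios therefore state their *stationary
population size* as the design quantity and scale total $K$ accordingly
(factors measured once from pilot runs: 1/0.68 for the barrier scenario,
1/0.43 for the high-turnover drift emulation).

### Selection and phenotypes

Fitness of individual $i$ for trait $p$ penalises the mismatch between its
phenotype $z_{i;p}$ and the local selection-layer value:

$$\omega_{i,p} = 1 - \phi_{p;x,y}\,|e_{p;x,y} - z_{i;p}|^{\gamma_p},$$

with selection coefficient $\phi \in [0,1]$ (scalar or itself a raster, for
selection heterogeneous in space and time) and curvature $\gamma > 0$
(default 1). Phenotypes are additive in the per-locus genotype scores
$g_{i,l}$ (codominant: the allele mean, in $\{0, 0.5, 1\}$; dominant: 1 if
either allele is 1). The uncentered textbook form $z = \sum_l \alpha_l g_l +
g_0$ with $g_0 = 0.5$ for polygenic traits cannot span $[0,1]$ with
nonnegative effect sizes, so the default is the centered equivalent

$$z_{i;p} = g_0 + \sum_l \alpha_{p,l}\,(g_{i,l} - g_0),$$

which with the default equal effects $\alpha_l = 1/n$ maps an all-reference
genotype to 0, an all-alternate genotype to 1, and full heterozygosity to the
baseline 0.5. The literal uncentered form remains available per trait via
`centered = FALSE`. Monogenic traits use $g_0 = 0$ and a default effect size
of 1.

### Movement and dispersal

Each movement vector combines a Wald (inverse-Gaussian) step length — mean
$\mu_w$ and shape $\lambda_w$, in cell widths — with a direction drawn either
uniformly or from a **movement surface**: per raster cell, a unimodal or
mixture von Mises distribution. The unimodal mode points at the
highest-valued 8-neighbour (ties broken by the fixed N, NE, E, SE, S, SW, W,
NW order, so runs are reproducible); the mixture mode (the default — real
resistance surfaces are multimodal) weights eight components, one per
neighbour, by the neighbours' cell values, with component modes at the
centre-to-centre directions (diagonals at odd multiples of $\pi/4$). Missing
neighbours at edges get weight zero; a cell whose neighbourhood is all zero
falls back to uniform directions with a warning.

Each cell's distribution is materialised as an **approximation column** of
`approx_len` ($M$) pre-sampled directions; a runtime draw resamples one
stored value, so movement costs O(1) random draws per individual per step.
$M$ (default 1000) bounds the angular resolution; the test suite checks
convergence of the $M = 10^4$ empirical distribution against an $M = 10^6$
reference. If the source layer undergoes a change event, one surface per
scheduled step is precomputed at model build; the builder warns when paths
plus surfaces exceed a configurable element budget.

Candidate positions falling outside the landscape have the whole vector
redrawn (up to 50 attempts, then the step is truncated at the boundary minus
$10^{-6}$): redrawing preserves the surface-driven anisotropy where
reflection would distort it. Resistance affects direction only, not step
length. Offspring dispersal uses the same machinery, originating at the
parents' midpoint.

### Mating

Eligibility requires age $\ge$ `repro_age` and, in dioecious mode, opposite
sexes (the default is hermaphroditic, matching the demonstration scenarios).
Every eligible individual draws at most one partner from the eligible
individuals within `mating_radius`, uniformly, inverse-distance weighted, or
strict nearest-neighbour; duplicate pairs are merged and a random-order pass
enforces at most one mating per individual per timestep. Pairs mate with
probability $b$; offspring counts are Poisson($\lambda$) or fixed. Newborns
do not move in their birth timestep and become eligible once their age
reaches `repro_age` (with the default 1, the following step).

### Recombination and mutation

Gametes are formed by **recombination paths**: genome-length binary arrays
that switch chromatid at inter-locus gap $j$ with probability equal to the
gap's recombination rate (each in $[0, 0.5]$; 0.5 = free recombination). A
deck of $R$ paths (`n_recomb_paths`) is generated once at model build and
repeatedly shuffled and drawn through without replacement, so any window of
$R$ consecutive gametes uses each path exactly once; $1/R$ is the smallest
recombination-rate difference the deck can represent. For homogeneous maps an
on-the-fly mode generates a fresh path per gamete instead, trading runtime
for memory; the two mechanisms are distributionally identical and the test
suite verifies this by a chi-square comparison of per-gap switch counts.

Mutations are finite-sites allele flips in three classes with per-locus,
per-gamete rates: neutral (flip only), deleterious (flip plus a selection
coefficient $s \sim \mathrm{Exp}(0.01)$ capped at 1, registered once per
locus and entering the mortality product as $1 - s g$), and trait-affecting
(flip at a not-yet-active trait locus, activating an effect size drawn
Normal(0, $1/n$) unless preset; an exhausted pool skips the mutation with a
warning). The exponential and normal effect distributions are standard
modelling choices; only the three mutation classes themselves are part of
the model definition, so both distributions are isolated behind
configuration.

### Burn-in termination

Three series are tracked per burn-in timestep: total population size and the
mean and standard deviation of timestep-differenced cell-wise counts. Each
must pass two tests at level $\alpha$ (default 0.05): a Welch $t$-test
comparing the most recent `lag`-length window (default 50) against the
window one lag earlier, and an augmented Dickey-Fuller test (constant, no
trend, AIC-selected lag order, MacKinnon finite-sample critical values)
rejecting a unit root. The ADF test runs on the last $2\cdot$`lag` points:
the initial transient is not evidence about the current state. The battery
is evaluated every `cadence` (10) steps past `min_length` (100); a
configurable `max_length` cap aborts with a warning, mainly to keep
degenerate parameterisations testable. The window construction for the
time-lagged test (adjacent non-overlapping windows of one lag each) is the
simplest one consistent with its purpose of detecting residual drift in the
series level.

### Change events

Environmental events are either a terminal raster reached by cell-wise
linear interpolation at scheduled timesteps or an explicit raster series.
With unevenly spaced steps the interpolation advances by equal fractions
$i/K$ of the total change per scheduled step (the step list, not elapsed
time, drives the fractions — the simpler reading of a bare step list).
Demographic events multiply the carrying capacity raster by scheduled
factors: repeated (exponential), alternating $f, 1/f$ (cyclical), log-uniform
in a band (random; the band $[0.5, 2]$ is a package default), or explicit
(custom). All changes take effect at the ends of their scheduled timesteps:
a change at step $s$ governs steps $s+1$ onward.

### Determinism

A master seed expands into named substreams (landscape, genome, movement,
mating, mutation, mortality, burn-in), so toggling one subsystem does not
shift the draws another sees, and identical parameters plus seed give
byte-identical VCF, CSV, and log outputs. The acceptance and test suites
assert this by hashing outputs of repeated runs.

## Canned scenarios and what they (do not) show

`scenario_*()` builders encode the package's reference study conditions;
`scripts/acceptance.R` recomputes their headline statistics. Sizes were
chosen to run on a laptop-class single core: the barrier scenario takes
roughly two minutes per run, the others seconds.

* **`scenario_ibd_ibe()`** — 50×50 landscape; a central 7-column
  high-resistance barrier (layer value 0) acting as movement, dispersal, and
  carrying-capacity layer; a selection layer of two opposed gradients
  driving a 10-locus trait ($\phi = 0.05$) in a genome of 80 unlinked loci;
  stationary size ≈ 2,450; 1,000 main timesteps. Read with
  `analyse_ibd_ibe()`: PCA-based genetic distances on a 600-individual
  subsample, paired partial Mantel tests (IBD and IBE), the full MMRR model,
  and the per-timestep rate at which individuals cross the barrier's column
  range (side-change semantics: an individual lingering inside the zone
  keeps its last side until it emerges). Landscape size, barrier width,
  total locus count, movement scale, and total K are free design parameters
  here; they were fixed once, from short pilot runs, to land the scenario in
  its reference regime (a stationary ~2,450
  individuals and a barrier that suppresses crossings by well over
  fivefold), and are not revisited.
* **`scenario_divergent_selection()`** / **`scenario_cline()`** — 26×26
  landscapes; two habitat blocks (0/1) driving a 10-locus trait, or a linear
  gradient driving a monogenic trait; 500 timesteps to migration-selection
  balance; read with `analyse_phenotype_env()` (quasibinomial logistic
  regression of phenotype on environment, McFadden-style pseudo-$R^2$) and
  `gea_scan()` (locus-wise genotype-environment logistic associations,
  Bonferroni-corrected). Mean movement distance (0.6 and 1.0 cell widths
  respectively) sets the migration side of the balance and was calibrated
  once the same way.
* **`scenario_wright_fisher()`** — selection off, movement off, mate search
  and density regulation spanning the landscape, 250 unlinked loci at
  frequency 0.5: a drift emulation whose mean fixation time grows linearly
  with population size (run lengths $25N$; unfixed loci censored at the end,
  which biases all sizes equally).
* **`scenario_sweep()`** — a 101-locus block with inter-locus recombination
  0.01 and a monogenic trait at locus 51, absent at start; copies introduced
  with `introduce_mutation()` after burn-in sweep to fixation on a uniform
  selection layer at value 1, lifting mean fitness from $1-\phi$ toward 1
  and carving a nucleotide-diversity trough around the locus. The birth rate
  is set above $\phi$ so the pre-sweep selection load cannot extinguish the
  population.
* **`scenario_stepping_stone()`** — six islands separated by uninhabitable
  gaps; pairwise $F_{ST}$ (both the heterozygosity- and variance-based
  estimators) increases with inter-island distance.
* **`scenario_bottleneck()`** — a 70% carrying-capacity reduction for 50 of
  300 timesteps; the mean absolute per-step allele-frequency change rises
  during the bottleneck and recovers after.

These synthetic landscapes are deliberately minimal: binary barriers, exact
linear gradients, uniform K. Passing them shows the simulator's emergent
behaviour matches population-genetic expectations — drift scaling,
migration-selection balance, linkage signatures, isolation patterns — not
that any particular empirical system is captured; real rasters bring
autocorrelation structure, anisotropy, and measurement noise these fixtures
do not represent, and real phenotypes are rarely purely additive.

## Density estimation

$\hat N_{x,y}$ counts individuals in a square window (side `density_window`,
default 5 cells in the scenarios; windows are clipped at borders and
normalised by their actual area). A 1-cell window makes regulation extremely
local and noisy at $K$ of order 1 per cell; wider windows smooth regulation
over the mating neighbourhood. The estimator is the simplest consistent one;
kernel alternatives would change only the smoothing.

## Input and output formats

Models are parameterised by an annotated YAML file (`make_params_file()`
emits a commented template; unknown keys are rejected with their location;
omitted keys take documented defaults; `inst/cli/landgen` wraps
`make-params`, `validate-params`, and `run`). Outputs: VCF 4.2 (one record
per segregating locus, CHROM 1, POS = 1-based locus index, REF/ALT A/T,
phased genotypes since chromatids are explicit; monomorphic loci behind a
flag), FASTA (two sequences per individual, 0→A, 1→T), CSV / GeoJSON /
point-Shapefile individual tables (id, location, per-layer environmental
values, phenotypes, age, sex), and single-band float32 TIFF rasters with a
JSON sidecar carrying the affine transform, CRS tag, and value scale/offset
(round-trips are lossless at float32 precision). The spatial pedigree —
births, deaths, parentage, and each gamete's recombination switch positions
— is recorded on request (`record_pedigree`) from the moment genomes are
assigned, and `replay_chromatid()` reconstructs any descendant haplotype
exactly from founder genomes (exact in the absence of mutation, which is
recorded but not replayed).

## Known limitations

One species per model (the data model is multi-species-ready but
interaction-free); no epistasis or pleiotropy; back mutation is an allele
flip with no bookkeeping; the pedigree is plain tables rather than a
succinct tree sequence, so very long runs with pedigree recording grow
memory linearly; no least-cost-path movement, home ranges, or
frequency-dependent selection; rasters must share dimensions (no
reprojection or resampling).
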