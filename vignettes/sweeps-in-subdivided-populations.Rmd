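---
title: "Selective sweeps in subdivided populations: models, statistics and the classification protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective sweeps in subdivided populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`subsweep` is a simulation-and-detection toolkit for studying how
population subdivision distorts the genetic footprint of positive
selection. It contains two forward-in-time Wright–Fisher simulators (a
fast single-locus trajectory simulator and an infinite-sites simulator of
a recombining 600-kb region), the standard panel of site-frequency-spectrum
and haplotype statistics used in genome scans for sweeps, a
neutral-background threshold-calibration framework, and a two-stage
boosted-tree protocol that first detects sweeps and then labels them hard
or soft. The package exists to quantify two failure modes of sweep
classification: *temporal misclassification* (a hard sweep read as soft,
or vice versa, because the classifier's training stage does not match the
data's time stage) and *spatial softening* (a hard sweep imported into a
neighbouring deme by migration and read there as soft).

## The single-site model

A haploid Wright–Fisher population is split into 1–3 demes of sizes
$N_i$ (10,000 chromosomes each by default). Each generation applies, in
order:

1. **Migration** — deterministic mixing of allele frequencies along the
   topology's edges, $p_i' = p_i + \sum_{j \sim i} \frac{Nm}{N_i}(p_j - p_i)$,
   where $Nm$ is the expected number of migrant chromosomes per
   generation per direction per edge.
2. **Selection** — the haploid genic update
   $p'' = p'(1+s_i)\,/\,(1 + p'
   s_i)$, with a per-deme coefficient $s_i$ (0.02 by default; this equals
   the marginal update of a co-dominant diploid scheme with fitnesses
   $1 : 1+s : (1+s)^2$).
3. **Drift** — one binomial draw of the allele count per deme.

The adaptive allele arises as a single copy in its origin deme (d1 for
two demes, d0 for three). Runs in which the allele is lost everywhere
are discarded, so completed trajectories are conditioned on global
fixation.

**Clock convention.** By default (`clock = "origin"`) the generation
counter keeps running across discarded attempts: after a loss the
mutation recurs and time accumulates. Reported times are therefore
totals from the beginning of the simulation and include the *waiting
period* before the ultimately successful lineage arises; the waiting
period itself is defined as the last generation in which the watched
demes carry no copy of the allele, which is only meaningful under this
convention. Because the single-site state after a loss equals the
initial state, this is equivalent in distribution to discarding and
re-running with the elapsed time added. The alternative
(`clock = "lineage"`) measures time from the origin of the successful
lineage only; the two differ by roughly the expected number of failed
establishment attempts ($\approx 1/(2s)$) times the mean lifetime of a
failed excursion. Totals are the headline quantity; the timing tables
carry the waiting period separately so either accounting can be
recovered.

Timing summaries record the first passage of the 5% and 99.5%
frequencies per deme; "completion" of adaptation is the 99.5% crossing,
because the last half-percent is drift-dominated and extremely variable.
The *selection phase* is the 5%→99.5% interval; under the deterministic
logistic approximation it lasts
$\big(\mathrm{logit}(0.995)-\mathrm{logit}(0.05)\big)/s \approx 412$
generations at $s = 0.02$, independent of $N_e$, while the total sweep
duration scales as $\log(N_e)/s$.

```{r}
library(subsweep)
spec <- deme_spec(Ne = c(10000, 10000), s = c(0.02, 0.02), Nm = 2)
tm <- run_timing_batch(spec, reps = 1000, seed = 1)
median(tm$t995_d2)
```

The grid of the full experiment (11 two-deme rows, 8 three-deme rows
crossed with three migration topologies and five rates, 55 + 120
combinations) is exposed by `grid_rows()`, `grid_combinations()` and
`run_grid()`; `trajectory_stats()` computes the pooled Pearson
correlation of a timing column with $\log_{10} Nm$.

## The genomic model

The region simulator implements an infinite-sites model of a 600-kb
segment in one or two demes of $N_e = 10{,}000$ haploid chromosomes
each. Chromosomes are paired into transient diploids every generation
(monoecious random mating); an offspring chromosome chooses its parent
individual proportionally to diploid fitness at the selected site
($1 : 1+s : (1+s)^2$, co-dominant), is transmitted with at most one
recombination breakpoint (probability $c = 0.006$ per transmission,
breakpoint uniform), and acquires Poisson($\mu = 0.006$) new mutations
at uniform continuous positions. Migration swaps whole diploid
individuals between demes with a single balanced binomial draw, giving
an expected flux of $Nm$ chromosomes per generation per direction.

Rates are *per transmitted chromosome per region per generation*: with
$\mu = 10^{-8}$ per bp this corresponds to 600 kb of human-like
sequence, and the population-scaled diversity of the panmictic model is
$\theta_\pi = 2 N \mu = 240$ per region ($N$ = 20,000 chromosomes). The
initial equilibrium population comes from a structured coalescent with
recombination (the bundled msprime backend, exchanged as ms-format
text), from any user-supplied ms-format file, or from a forward neutral
burn-in.

The adaptive mutation is placed at 100 kb from the left end: a brand-new
mutation on one chromosome of d1 (hard sweep) or an existing standing
variant with pooled frequency closest to 10% (within 10 ± 2%) near the
focal position (soft sweep). If the allele is lost the population is
reset to the initial state; if no eligible standing variant exists the
neutral population is re-drawn.

**Snapshots.** The standard schedule records the population when the
allele first reaches 20/40/60/80/99.5% within each deme, 1,000–5,000
generations (in steps of 1,000) after each deme's 99.5% crossing, and at
global fixation — 21 snapshots for two demes, 11 for the panmictic
model; the pre-selection neutral state is kept as time point zero. The
low-migration local-adaptation scenario instead snapshots every 100
generations for 20,000 generations. Samples of 50 chromosomes per deme
(or 50 pooled chromosomes for "mixed" cryptic-structure samples) are
drawn without replacement from each snapshot; sample columns
monomorphic in the pooled sample are dropped, except the selected site.

**Rescaling.** `rescale_config(config, lambda)` divides deme sizes and
multiplies $s, m, \mu, c$ by $\lambda$, preserving $N_e s$, $Nm$,
$\theta$ and $\rho$; time contracts by $\lambda$. Rescaling is refused
when $s\lambda \ge 0.5$, where the weak-selection equivalence breaks.
The package's test and example scale is $\lambda = 10$ (demes of 1,000
chromosomes, $s = 0.2$); full scale is $\lambda = 1$. Neutral-background
samples are generated at face-value parameters, since the neutral
equilibrium is invariant under this rescaling.

## Scan statistics

Thirteen statistics are computed per sample, on sliding windows of
100 kb advancing by 10 kb (51 windows over 600 kb) or on a 10-kb bp
grid:

* **SFS estimators** — $\theta_\pi$ (mean pairwise differences),
  Watterson's $\theta_w = S/a_{n-1}$ with $a_{n-1} = \sum_{i<n} 1/i$,
  Fay & Wu's $\theta_h = \sum_i 2 i^2 S_i / (n(n-1))$, Tajima's $D$
  (1989 normalisation; reported only for windows with $S \ge 3$), and
  Fay & Wu's $H = \theta_\pi - \theta_h$, used unnormalised.
* **Haplotype spectrum** — number of distinct haplotypes $n_H$,
  $H_1 = \sum p_i^2$, $H_{12} = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2$,
  $H_2/H_1$ with $H_2 = H_1 - p_1^2$.
* **EHH integrals** — unstandardised iHS and nSL: for each pivot SNP
  with derived frequency in [0.06, 0.94], extended haplotype
  homozygosity is computed outward for derived and ancestral carriers,
  integrated by the trapezoid rule until it drops below 0.05 (the
  crossing trapezoid is included) or the data edge; the score is
  $\log(\mathrm{iHH}_A/\mathrm{iHH}_D)$. iHS measures distance in bp,
  nSL in segregating sites. Scores are standardised per derived-count
  bin against neutral-background tables, and the *window statistic* is
  the proportion of scored SNPs in the window with $|z| > 2$.
* **Composite likelihoods** — deliberately simplified re-implementations
  whose contract is neutral calibration and directional behaviour, not
  numeric parity with the released binaries. The SweepFinder-style CLR
  contrasts the sample's own SFS with a sweep spectrum (all mass on
  derived counts 1 and $n-1$) under an escape probability
  $1-e^{-\alpha d}$ per SNP, maximised over $\alpha$ on a log grid. The
  XP-CLR-style score models the focal-deme frequency as Gaussian around
  the control deme's with variance $\omega p(1-p)$ inflated by
  $1 + s\,e^{-d/50\mathrm{kb}}$ near the putative sweep, maximised over
  $s \ge 0$; each deme serves as the other's control.
* **Differentiation** — per-site Hudson FST,
  $1 - (p_1q_1 + p_2q_2)/(p_1q_2 + p_2q_1)$, averaged over polymorphic
  sites in the first 200 kb and over the 50 samples of a replicate.

$\theta_h$, $H_1$, $H_{12}$, CLR, XP-CLR and the iHS/nSL significance
proportions rise under sweeps; the others fall. All statistics are
invariant to haplotype and SNP order.

## Threshold calibration and power

Detection thresholds come from neutral background (NB) data of the
*same demography*: each 600-kb NB region is split into three 200-kb
blocks, each block contributes its extreme window value in the sweep
direction (windows lying entirely inside the block), and the pooled
block extremes (3 per region; 15,000 values for 5,000 regions) are cut
at nominal false positive rates 5%, 1% and 0.1% by the plain
order-statistic convention (the $k$-th most extreme value,
$k = \mathrm{round}(f M)$, no interpolation). "Beyond" a cutoff includes
equality, so re-applying a cutoff to its calibration set detects exactly
the nominal fraction. A sample is *detected* when at least one window of
the first 200 kb (centred on the adaptive locus) scores beyond the
cutoff — mimicking a scan of a much larger genome — with a whole-region
variant calibrated on the extreme of all 51 windows. Samples whose
entire span is missing are excluded from both numerator and denominator.
Power is the detected fraction of samples per scenario, deme, stage and
FPR. Calibrating against a mismatched demography (e.g. panmictic
thresholds for subdivided data) is possible and is exactly the
false-positive mechanism the package demonstrates.

## The two-stage classifier

Feature vectors concatenate the 11 in-house window statistics over the
first 11 windows (200-kb mode) or all 51 (600-kb mode); missing entries
are imputed by the NB mean of the same statistic and window, and samples
with more than half their entries missing are excluded. XP-CLR and CLR
are not features (single-population context; cost), which is a
documented, configurable narrowing.

For each training stage — ongoing sweeps at 60%, 80% and 99.5%
completion, fixation, 1,000 generations post fixation, and a pooled
mixture of a fifth from each — a *predictor pair* is trained: predictor
1 is a gradient-boosted tree classifier (xgboost; fixed
hyper-parameters: `max_depth` 3, `eta` 0.3, 60 rounds, single thread,
seeded) of neutral (2,000 samples) versus sweep (1,000 hard + 1,000
soft, the soft set grown from 10% standing frequency); predictor 2
separates soft (0) from hard (1). Predictor-1 thresholds are set on an
independent NB set at 5/1/0.1% FPR; predictor 2 always uses the fixed
0.5 cutoff to avoid biasing the hard/soft call. A sample below the
threshold is *neutral*; otherwise *soft* or *hard* by predictor 2.
`cross_test()` applies every pair to hard and soft test sets of every
stage, the matrix in which temporal softening (hard sweeps called soft
under stage mismatch), temporal hardening (soft called hard, mostly by
the early-stage pair) and the soft shoulder (the 100–300-kb flank of a
hard sweep called soft) appear.

The boosted-tree backend reproduces the *protocol*, not any particular
published predictor: the original study's boosting feature set and
hyper-parameters are not public, so only the directional phenomena and
the calibration properties are contracted, never per-figure numbers.

## What the generator does and does not emulate

The simulators reproduce: human-scale per-bp mutation and recombination
rates over 600 kb, equilibrium island-model structure with $Nm$ from 0.2
to 20, co-dominant selection of strength $2N_e s = 400$, hard and soft
(10% standing) origins, and the full snapshot/sampling design described
above. They deliberately omit: demographic change, background and
purifying selection, gene conversion, variable recombination maps,
ancestral-state misidentification (the derived allele is simulation
truth), unphased or missing data, and more than two demes at the genomic
level. Passing tests therefore demonstrate the internal consistency of
the study design, not robustness of the statistics on real data with
those complications.

## Numerical choices and degenerate inputs

* ms-format positions are scaled to continuous bp (no rounding); exact
  ties are separated by a minimal increment with a warning.
* Windows with no SNPs give $\theta = 0$ and missing $D$/$H$; $D$ also
  requires $S \ge 3$. Empty iHS/nSL windows are missing, excluded from
  block extremes and window maxima.
* Normalisation bins with zero or undefined standard deviation abort
  table construction; scores in bins absent from the table are dropped
  with a warning.
* Empirical quantiles are order statistics (conservative, no
  interpolation); "beyond" includes equality.
* The engine prunes fixed and lost sites lazily (every 25 generations
  and before every snapshot); lost sites have no carriers and fixed
  sites are monomorphic, so the postponement is statistically
  invisible while avoiding a full rebuild per generation.
* Every stochastic routine takes an explicit seed; per-replicate seeds
  derive from a master seed through a counter-based LCG and are recorded
  in output tables.

## Problem sizes used by the test and acceptance suites

The package's own checks run at desk scale, chosen once: single-site
grids at 1,000 conditioned replicates per migration rate; genomic
scenarios at $\lambda = 10$ with 20 panmictic replicates × 10 samples
per stage (power surface and training data), 10 replicates per class for
independent test sets, 5 replicates per two-deme scenario, 600 + 200
neutral background regions for calibration and holdout, and 200/100
training/test samples per class per stage. The acceptance script
re-simulates only the single-site grid (5 rates × 1,000 replicates).

## Known limitations

* The printed single-site medians are sensitive at the few-percent level
  to how the original scripts accounted time across discarded
  establishment attempts; the origin clock adopted here is the reading
  consistent with a defined waiting period, and the correlation
  structure over the migration-rate grid is insensitive to the choice.
* The simplified CLR/XP-CLR scores are calibrated and directionally
  correct but are not drop-in replacements for SweepFinder2/XP-CLR
  output values.
* Three-deme models exist only at the single-site level; genomic
  simulations support one or two demes.
* EHH kernels support samples of up to 128 chromosomes.
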