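---
title: "Methods: the demethylation cycle, its estimator, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the demethylation cycle, its estimator, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcycle)
```

This vignette records the scientific and numerical decisions behind
`methcycle`: the turnover model and what it assumes, the statistics the
pipeline computes, what the synthetic cohort generator does and does
not emulate, and the choices made where the design was genuinely open.

## The three-state demethylation cycle

Each CpG site is modelled as cycling through unmethylated cytosine (C),
5-methylcytosine (5-mC) and 5-hydroxymethylcytosine (5-hmC):
methylation C → 5-mC at a fixed unit rate, first TET oxidation
5-mC → 5-hmC at rate $\tau$, and the completion of demethylation —
further oxidation to 5-fC/5-caC, glycosylase excision and base-excision
repair — lumped into one step 5-hmC → C at rate $\rho$.  The dynamics
are linear,

$$\dot C = \rho H - C,\qquad \dot M = C - \tau M,\qquad
  \dot H = \tau M - \rho H,$$

conserve total mass, and have a unique attracting equilibrium with
proportions proportional to $(1, 1/\tau, 1/\rho)$.  Inverting the
equilibrium gives the point estimator used throughout:
$\tau = \%C/\%5\text{-mC}$ and $\rho = \%C/\%5\text{-hmC}$ with
$\%C = 100 - \%5\text{-mC} - \%5\text{-hmC}$, the percentages being
unweighted means of per-site modified fractions over a region class
(PBMC enhancers by default).

Assumptions worth keeping in mind:

* **Steady state.** Only equilibrium proportions are observed; the
  estimator is a fixed-point inversion, not a kinetic fit.  Transient
  behaviour after an intervention is invisible.
* **Lumped repair.** 5-fC/5-caC are not explicit states; their
  production and excision are folded into $\rho$.  A three-state model
  is the most that two observed proportions can identify.
* **No cell cycle.** Passive, replication-driven dilution of marks is
  not modelled; the rates are effective rates in a mixed, slowly
  renewing cell population.
* **Relative rates.** Fixing the methylation step at rate 1 makes
  $\tau$ and $\rho$ dimensionless; only percent *changes* between
  timepoints are compared across samples, which also cancels any
  sample-level scaling of all three rates.

`turnover_equilibrium()` is the closed form; `simulate_to_equilibrium()`
integrates the same right-hand side with `deSolve::lsodar` until the
largest derivative falls below a tolerance (default $10^{-9}$, root
finding on $\sum_i |\dot x_i| - \mathrm{tol}$).  The integrator is kept
as an independent check of the closed form — the central correctness
property, tested over the rate plane $[0.1, 100]^2$, is that
`estimate_rates(turnover_equilibrium(tau, rho))` returns the rates to
within $10^{-6}$ relative error — and as a hook for future
non-equilibrium extensions.

## The statistics

**Annotation screen.**  Per cell type and chromatin-state label, an
ordinary least-squares fit of per-sample average methylation on a
carrier indicator, a lymphoma-status indicator, and the sample's
genome-wide average methylation.  Covariates without variation (a
cohort with no lymphoma-affected member) are dropped with a warning and
the model refitted; covariates are not standardised, so estimates stay
on the fraction scale and read directly as %-point effects after
multiplying by 100.  Benjamini–Hochberg correction is applied over the
whole family of fits in one screen run — all (cell type, label) pairs —
matching a volcano-plot colouring at an FDR threshold.

**Change over time.**  Per-sample differences of regional means between
two timepoints, compared between unaffected carriers and controls with
Welch's unequal-variance t-test (Welch–Satterthwaite degrees of
freedom).  The FDR family for these tests is the set of chromatin-state
labels for one mark (15 by default); the genome-wide summary is not a
label and is excluded from the family.  Lymphoma-affected carriers are
excluded from all group comparisons (they did not respond to the
intervention and would dilute both groups), but are retained in the
annotation screen, where lymphoma status is a covariate.

**Hyper/hypomethylated partition.**  Within a region class, a site is
*hypermethylated* when its modified fraction strictly exceeds the
sample's own mean over the same site set; ties count as hypomethylated.
Strictness is the deterministic, conservative convention; because the
reference is the sample's own mean, the statistic is invariant under a
constant shift of all fractions and therefore insensitive to per-sample
global offsets.  Group comparison of per-sample proportions uses the
Student pooled-variance t-test, reported in percentage points; the
change-over-time tests use Welch.  The two variants are deliberately
different because they answer differently structured questions (paired
regional changes vs a cross-sectional proportion), and both are exposed
through `ttest_change(variant =)`.

**TF binding sites.**  A TF's score for a sample is the unweighted mean
modified fraction over qualifying CpG sites: inside a binding interval
of that TF, and (for the 5-mC analysis) inside an enhancer interval;
the `hyper_only` restriction additionally keeps only positions strictly
above the sample's enhancer mean, isolating binding sites carrying
sample-specific hypermethylation.  The 5-hmC variant uses the
genome-wide universe.  The per-TF model regresses the score on the
carrier indicator with the sample's enhancer mean as covariate; BH runs
over the TF family, one family per restriction × universe × timepoint.
The response averages over *positions*, not over binding intervals; the
alternative (per-interval means averaged per TF) would weight sparse
intervals more heavily and is not implemented.

Degenerate t-test inputs follow explicit conventions: zero variance in
both groups with equal means gives $p = 1$; with unequal means the
result is flagged `degenerate` with $p = 0$.

## Coordinates and formats

All internal coordinates are 0-based, half-open; a site at position $p$
belongs to $[s, e)$ iff $s \le p < e$, implemented with
GenomicRanges/IRanges and cross-checked against a quadratic brute-force
scan in the tests.  The tab-delimited call-table dialect declares its
position column 0-based; the bedMethyl dialect follows the community
layout (column 10 valid coverage, column 11 percent modified, converted
to a fraction).  CpG calls are strand-collapsed — one record per site —
and sites with zero calls are retained by the readers but excluded from
every downstream average.  Whether 5-mC and 5-hmC call sets should be
intersected to a shared site universe before comparison is left to the
caller; the synthetic generator emits both marks over the same site
universe, so the default pipeline implicitly uses the intersection.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the study the
pipeline targets: three unaffected mutation carriers and three controls
(optionally plus lymphoma-affected carriers) sampled at 0, 6 and
12 months; a genome segmented into 15 chromatin-state labels × 200
intervals × 50 CpGs; enhancer 5-mC near 60% and 5-hmC near 3%, with
genome-wide hydroxymethylation below 5% everywhere; a carrier enhancer
hypermethylation overload of +2 %-points at baseline; and an
intervention that multiplies the responding carriers' $\rho$ by 1.3 at
6 and 12 months.  Group-level regional proportions are the turnover
equilibrium for the per-sample rates; observations then follow a
beta-binomial model with Poisson coverage (mean 20).

The observation model is deliberately **bimodal** for 5-mC: each site
is either an unmethylated-type locus (mode 0.08) or a methylated-type
locus (mode 0.88), the regional mixing proportion chosen to reproduce
the regional mean, and per-site true fractions beta-distributed
(precision 30) around the site's mode.  This matters for the partition
statistic: a *unimodal* site model makes the proportion of sites above
the sample's own mean almost invariant to any mean change (the
statistic's shift invariance), so no mean effect could ever reproduce a
hypermethylated-proportion difference between groups.  With a bimodal
distribution the sample mean sits in the low-density valley, and a
carrier overload realised as *upgrading* low-mode sites to a
near-saturated level (0.98, above the normal methylated-locus mode)
raises both the regional mean and the hypermethylated proportion — the
structure the real data display.  The upgrades are concentrated in a
subset of enhancer intervals (10% by default), which is also what gives
TF tracks bound to those intervals their hypermethylation signal in the
`hyper_only` screen.

Individual variability has two deliberately separated components:

* **count-type** — a persistent per-sample excess or deficit in the
  proportion of methylated-type loci (SD 0.004, shared across labels,
  plus a smaller per-label term, SD 0.0015): the dominant term, which
  the genome-wide covariate of the screen absorbs and the partition
  statistic registers;
* **shift-type** — small lognormal dispersion of the per-sample rates
  (SD 0.004–0.003 on the log scale), realised as a location shift of
  the modes, which the partition statistic ignores by construction.

Both are drawn once per sample and reused at every timepoint: an
individual's methylome is a stable set-point, and rate changes over
time should reflect the intervention, not re-drawn noise.

The intervention is emulated by (i) the $\rho$ multiplier for
responding carriers and (ii) a retention schedule for the overload
(1, 0.5, 0 at 0, 6, 12 months): the upgraded loci are progressively
demethylated, so the hypermethylated-proportion difference and the TF
binding-site hypermethylation present at baseline disappear by
12 months.  Lymphoma-affected carriers keep the overload and receive no
$\rho$ response.  A consequence worth noting: because the resolving
overload returns its share of cytosine, the default cohort's carriers
show an estimated $\Delta\tau$ of a few percent and a $\Delta\rho$
somewhat above the configured +30%; a configuration with the overload
held fixed (retention 1 at all timepoints) isolates the $\rho$ effect
and recovers $\Delta\rho \approx 30\%$ with $\Delta\tau \approx 0$,
which is what the parameter-recovery validation uses.

What the generator does **not** emulate: read-level data (no FASTQ,
alignments or caller error models beyond binomial sampling), realistic
genome sequence or interval geometry (labels are laid out round-robin
in equal blocks), correlation between neighbouring CpGs, 5-hmC
concentration at methylated loci (the 5-hmC channel is unimodal and
independent of site type), cell-composition shifts, and age or sex
structure.  Tests passing on this generator therefore demonstrate that
the pipeline's statistics behave correctly under the assumed data
model at the study's effect sizes — not that the biological findings
would replicate in new human data.

`simulate_null()` regenerates the identical cohort with all carrier
effects switched off while consuming the same random streams, so
effect and null outputs differ only where the effects apply — used to
verify false-positive behaviour.  `simulate_hyper_proportions()` is a
focused generator that draws per-sample hypermethylated proportions
directly (normal on the percent scale) for power and type-I-error
studies of the proportion comparison at stated effect sizes
(+2 %-points, between-sample SD 0.3 %-points, 3 vs 3), where the full
genome-scale generator would only add layers between the stated
parameters and the test.

## Numerical choices

* ODE integration: `lsodar` with relative/absolute tolerances three
  orders below the convergence tolerance; non-convergence within the
  horizon raises an error carrying the final state and derivative.
* Rate estimation preconditions: both observed percentages must be
  positive and sum below 100; violations raise errors rather than
  returning infinities.
* KDE of rate changes: Silverman's rule-of-thumb bandwidth per axis
  (`bw.nrd0`) with a floor of $10^{-3}$ for degenerate inputs; grid
  101 × 101 spanning the data range padded by 3 bandwidths (the
  Gaussian-kernel SD is the Silverman bandwidth; `MASS::kde2d`'s `h`
  is four times the kernel SD).  Total mass is checked to integrate to
  1 within quadrature error.
* Site-call writers re-derive the modified fraction from the integer
  call counts, making write→read round-trips exact and repeated writes
  byte-identical.
* The generator derives one RNG substream per
  (sample, timepoint, mark, label) block from the configured seed, so
  cohorts are reproducible and matched effect/null cohorts stay
  aligned outside the blocks an effect touches.

## Problem sizes in the tests

The unit suite runs on reduced genomes (tens of intervals, tens of
CpGs) chosen to finish in seconds while preserving the structure under
test; the validation suite uses the full default cohort (15 labels ×
200 intervals × 50 CpGs × 6 samples × 3 timepoints × 2 marks,
5.4 million site records), a 10,000-CpG enhancer-only cohort at
coverage 20 for parameter recovery, 1,000 random rate pairs for the
duality check, and 200 replicates for the proportion test's power and
size.  These sizes were chosen as the smallest at which the stochastic
checks are stable across seeds.

## Known limitations

Six samples support no more than the models fitted here; age- and
sex-adjusted or mixed-effects models are out of scope by design.  The
per-TF model conditions on the sample's enhancer mean while the
carrier effect itself raises that mean, so the carrier coefficient is
estimated under near-collinearity and per-TF significance at n = 6 is
fragile — the TF screen is best read as a ranking, which is how the
tests treat it.  The turnover model ignores the cell cycle and yields
steady-state, relative rates only; and the hypermethylated-proportion
statistic depends on the bimodality of methylation levels, so its power
on data without that structure (e.g. heavily smoothed array data) would
differ.
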