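# methcycle

DNA methylation turnover analysis from per-CpG 5-mC and 5-hmC call
tables.

## The problem

TET2 drives active DNA demethylation in blood cells: it oxidises
5-methylcytosine (5-mC) to 5-hydroxymethylcytosine (5-hmC) and on to
5-formyl-/5-carboxylcytosine, which glycosylase excision and base
repair convert back to unmodified cytosine.  People carrying a
heterozygous loss-of-function *TET2* mutation accumulate a
hypermethylation overload, most visibly at enhancers, and an
intervention that boosts TET activity (such as vitamin C
supplementation) should be detectable as a change in the *turnover*
of the cycle — not necessarily in bulk methylation levels.

`methcycle` implements the full analysis path for a small longitudinal
cohort profiled for both marks at CpG resolution (e.g. from nanopore
sequencing with separate 5-mC and 5-hmC callers):

* readers/writers for per-site call tables (tab-delimited or
  bedMethyl-style), BED annotation and TF-binding tracks, and sample
  sheets;
* aggregation of site calls over chromatin-state annotations
  (unweighted means over CpG sites, per sample / cell type / state);
* an annotation-level screen,
  `lm(average methylation ~ mutation status + lymphoma status +
  genome-wide average methylation)`, fitted per cell type and state
  with Benjamini–Hochberg correction over the family;
* Welch/Student t-tests of per-sample change over time;
* partition of CpGs into hyper-/hypomethylated loci relative to the
  *sample's own* regional average, and a group comparison of the
  hypermethylated proportions;
* TF binding-site methylation scores, including the restricted variant
  that keeps only positions above the sample's enhancer average, with a
  per-TF linear model of the mutation-status effect;
* the demethylation-cycle model and its rate estimator (below);
* a synthetic-cohort generator so everything runs and is testable
  without access to controlled human data.

## The turnover model

A CpG site cycles through three states,

```
      1           tau           rho
  C -----> 5-mC -----> 5-hmC -----> C
```

with the methylation step fixed at unit rate, the first TET oxidation
at rate τ, and the further oxidation plus excision/repair lumped into a
single return step at rate ρ (both dimensionless, relative to the
methylation rate — only ratios are identifiable from state
proportions).  The cycle has a unique attracting equilibrium with
proportions ∝ (1, 1/τ, 1/ρ), so the rates follow from observed
percentages:

```
tau = %C / %5-mC        rho = %C / %5-hmC,      %C = 100 − %5-mC − %5-hmC
```

with %5-mC and %5-hmC measured as mean modified fractions over the CpG
sites of a region class (PBMC enhancers for the headline analysis).
Changes between timepoints are reported as percent change of each rate
per sample, drawn as arrows in the (Δτ, Δρ) plane and summarised by a
bivariate kernel density.

## Worked example

```r
library(methcycle)

## point estimate of the cycle rates from observed proportions
r <- estimate_rates(60.2, 3.1, sample_id = "M1", timepoint_months = 0)
print(r)
#> Demethylation-cycle turnover rates (M1, 0 months)
#>   observed: %C = 36.700, %5-mC = 60.200, %5-hmC = 3.100
#>   tau (first oxidation)        = 0.6096
#>   rho (further oxidation+repair) = 11.8387

## a synthetic cohort with the study's structure: 3 carriers vs 3
## controls at 0/6/12 months, enhancer overload +2 %-points, rho x 1.3
## under the intervention
co  <- simulate_cohort(sim_config(seed = 7))
res <- run_pipeline(co)

subset(res$screen, label == "Enh")
#>   cell_type label mark    term   estimate      p_value     q_value ...
#> 2      PBMC   Enh   mc carrier 0.02146671 0.0003554284 0.005331427

res$hyper$baseline[, c("mean_diff", "t", "p_value", "ci_low", "ci_high")]
#>   mean_diff        t     p_value   ci_low  ci_high
#> 1      2.31 5.772796 0.004470569 1.198998 3.421002

res$rates$changes
#>   sample_id  d_tau_pct  d_rho_pct
#> 1        C1 -0.2019791 -0.9306726
#> 2        C2 -0.4873751 -0.5166142
#> 3        C3 -0.7290489 -4.7962588
#> 4        M1  9.6876103 37.2436540
#> 5        M2  9.1415109 38.4674853
#> 6        M3  9.1415928 43.3740027
```

Reading the output: the screen recovers the carriers' +2 %-point
enhancer methylation excess (estimate 0.021 on the fraction scale,
q < 0.05 over the 15-state family); at baseline the carriers hold a
significantly higher proportion of hypermethylated enhancer CpGs
(+2.3 %-points, Student t, p = 0.004); and over the 12-month
intervention every carrier's repair rate ρ rises by roughly the
configured 30% (plus the share released by the resolving overload)
while the controls stay near the origin — the carrier-up/control-null
arrow pattern that `plot_rate_arrows(res$rates$changes, co$samples)`
draws.

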