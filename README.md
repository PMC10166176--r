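# seqpsm

A treatment-sequencing clinical simulation for transplant-ineligible newly
diagnosed multiple myeloma (TIE NDMM): a three-state partitioned survival
model — first line (1L), second line and beyond (2L+), death — that
compares the long-term overall survival (OS) of competing sequences such
as starting daratumumab–lenalidomide–dexamethasone (D-Rd) in 1L versus
saving daratumumab-based therapy for 2L after bortezomib–lenalidomide–
dexamethasone (VRd) or lenalidomide–dexamethasone (Rd).

The package is aimed at modellers in health economics and outcomes
research who need a transparent, testable implementation of this class of
simulation: parametric extrapolation of right-censored time-to-event
data, comparator arms derived by proportional hazards, explicit attrition
between treatment lines, life-table background mortality, and
probabilistic sensitivity analysis (PSA).

## The model

Occupancy of 1L is the 1L time-to-next-treatment (TTNT) curve
S<sub>1</sub>(t) on a monthly grid. The mass leaving 1L during cycle *t*,
e(t) = S<sub>1</sub>(t−1) − S<sub>1</sub>(t), splits in fixed
proportions: a fraction *a* — the **attrition rate**, the share of 1L
leavers who die before ever starting 2L — goes directly to death, and the
rest enters 2L+. Second-line occupancy is a semi-Markov convolution over
entry times on the 2L OS curve S<sub>2</sub>:

    occ_2L(t) = Σ_{u ≤ t} (1 − a) · e(u) · S₂(t − u)

Model OS is occ<sub>1L</sub> + occ<sub>2L</sub>, floored against
general-population mortality: per cycle the effective hazard is
max(model hazard, −ln(1 − q<sub>x</sub>)/12) at the cohort's attained
age. Outcomes are median OS (first grid crossing of 0.5), 5/10/15-year
landmark rates, and life-years (restricted mean survival over the
15-year horizon), plus pairwise differences between sequences.

Input curves are fitted by maximum likelihood over the standard
six-family extrapolation suite (exponential, Weibull, Gompertz,
log-logistic, log-normal, generalized gamma) with AIC selection;
comparator 1L curves can be derived as S(t)<sup>HR</sup> from a published
hazard ratio. The PSA redraws survival parameters (multivariate normal on
the unconstrained scale), attrition rates (beta from their defining
counts) and hazard ratios (lognormal matched to the 95% CI), reruns the
engine per draw, and reports equal-tailed 95% credible intervals.

Because the underlying trial and registry patient-level data are not
distributable, the package ships a synthetic-data generator that emulates
their statistical structure (proportional-hazards arms with a target TTNT
HR of 0.47, censoring, per-arm attrition truths, two 2L cohorts with
distinct hazards) so the entire pipeline is reproducible end to end. See
`vignettes/treatment-sequencing-model.Rmd` for the full methods account.

## Worked example

```r
library(seqpsm)
run <- cmd_run(default_run_config(seed = 1))
print(run)
```

```
Sequence comparison (reference: D-Rd -> Pom/Car)
            label median_os_years life_years rate_5y rate_10y rate_15y
1 D-Rd -> Pom/Car           7.083      7.948  0.6462   0.3455  0.20065
2     VRd -> Dara           6.333      6.844  0.6188   0.2242  0.06916
3      Rd -> Dara           5.500      6.189  0.5449   0.1799  0.05567
  d_median_vs_ref d_life_years_vs_ref
1           0.000               0.000
2          -0.750              -1.103
3          -1.583              -1.759
```

On the synthetic base case, starting with the D-Rd-like regimen yields a
median OS of 7.08 years versus 6.33 (VRd-first) and 5.50 (Rd-first)
years: delaying the daratumumab-class regimen to 2L costs 0.75 and 1.58
years of median OS (1.10 and 1.76 life-years) respectively, because the
weaker 1L curves both shorten time in 1L and expose more patients to
attrition before 2L. The absolute numbers describe the synthetic cohorts,
not any published trial population; the *ordering* is the structural
result.

Attrition estimators reproduce count arithmetic exactly:

```r
predicted_attrition(110, 368)   # <attrition_estimate 'predicted'> 29.9% (110/368)
pool_attrition(predicted_attrition(110, 368),
               predicted_attrition(90, 369))
                                # <attrition_estimate 'pooled'> 27.1% (200/737)
```

`cmd_psa()` and `cmd_scenarios()` run the PSA and the scenario grid
(uniform attrition 58.8% / 27.2%, alternative hazard ratio, best/worst
parametric families) from the same configuration;
`inst/extdata/config-base.yaml` is the equivalent YAML, and
`inst/exec/seqpsm` is a thin command-line wrapper with `run`, `psa`,
`scenarios`, `fit` and `synth` subcommands.

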