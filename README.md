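# t2dsubgroups

Data-driven subgrouping of type 2 diabetes (T2DM) from routinely collected
primary-care measures, with downstream evaluation of glycaemic control,
treatment initiation and vascular outcomes — built for multi-ethnic
UK-style primary-care populations where the biomarkers used by
experimental diabetes-subtype studies (C-peptide, insulin assays) are not
available.  The intended users are epidemiologists and health-data
scientists who want a tested, reproducible implementation of the
subgroup-at-diagnosis workflow, including a calibrated synthetic cohort
generator for method development where the underlying patient data cannot
be shared.

## The model

Subgroups are derived at diagnosis from four indicators — age $a$, HbA1c
$h$ (NGSP %), BMI $b$ and male sex $s$ — with a latent-class
(latent-profile) model: patient $i$ belongs to an unobserved class
$z_i \in \{1..K\}$ with weights $\pi_k$, and, given the class, the
continuous indicators are independent Gaussians and sex is Bernoulli:

$$
L_i = \sum_{k=1}^{K}\pi_k\,
\mathcal{N}(a_i;\mu_{ka},\sigma_{ka}^2)\,
\mathcal{N}(h_i;\mu_{kh},\sigma_{kh}^2)\,
\mathcal{N}(b_i;\mu_{kb},\sigma_{kb}^2)\,
p_k^{s_i}(1-p_k)^{1-s_i}.
$$

The likelihood is maximised by EM (`fit_lca()`); $K = 2..5$ are compared
by BIC together with a 70% mean-posterior rule and a 1% class-share rule
(`select_lca()`); classes are labelled by their standardised means
(`assign_and_label()`): highest HbA1c → **SHD** (severe hyperglycaemic
diabetes), highest BMI among the rest → **MOD** (mild obesity-related),
remainder → **MARD** (mild age-related).  Subgroup differences in outcomes
are then estimated with age- and sex-adjusted cause-specific Cox
proportional-hazards models (Breslow ties) against the MARD reference,
overall and within each ethnic group, plus yearly-mean HbA1c trajectories
over five years.

See `vignettes/methods.Rmd` for the full account of assumptions,
tunable parameters and limitations.

## Worked example

The repository is organised as an analysis workflow: numbered scripts
under `analysis/` drive the package functions in `R/` and write their
tables under `results/`.

```sh
Rscript analysis/01_simulate.R 2     # seed 2
Rscript analysis/02_prepare.R
Rscript analysis/03_cluster.R 2
Rscript analysis/04_trajectories.R
Rscript analysis/05_survival.R
Rscript analysis/06_report.R
```

`01_simulate.R` generates a synthetic 31 931-patient cohort whose
subgroup structure, missingness, treatment and event hazards are
calibrated to a published multi-ethnic East-London T2DM population:

```
simulated 31931 patients (366913 observations, 33341 prescriptions, 29104 clinical events)
              MARD  MOD  SHD
  black       76.6 13.1 10.3
  mixed_other 82.8  9.4  7.8
  south_asian 84.3  8.7  7.1
  white       36.8 54.6  8.6
```

`03_cluster.R` then prints:

```
stratum overall      selected K = 4 (rules passed)
stratum white        selected K = 3 (rules passed)
stratum south_asian  selected K = 3 (rules passed)
stratum black        selected K = 3 (rules passed)
```

Within every ethnic group the three configured subgroups are recovered.
On the pooled cohort the deterministic criteria prefer four classes — the
pooled population really is a mixture of ethnicity-specific profiles
(white MARD has mean age 71.7 y vs 50.1 y in South Asians) and BIC
detects that extra structure, splitting MARD by age into `MARD` +
`other_1`; the methods vignette discusses why the published analyses
nevertheless report three classes.  `05_survival.R` prints the age- and
sex-adjusted hazard ratios vs MARD from the fitted labels:

```
vascular hazard ratios vs MARD, overall:
 outcome subgroup n_events crude_pct        hr     ci_lo    ci_hi
   macro     MARD      975       5.6 1.0000000        NA       NA
   macro      MOD      284       7.2 1.3311801 1.1636991 1.522765
   macro  other_1      378       6.2 0.9062393 0.7675145 1.070038
   macro      SHD       90       6.2 1.1417537 0.9197827 1.417293
   micro     MARD     5474      29.8 1.0000000        NA       NA
   micro      MOD     1251      30.8 1.0619793 0.9978389 1.130243
   micro  other_1     2246      34.8 1.0366526 0.9666763 1.111694
   micro      SHD      548      35.9 1.3641506 1.2492688 1.489597
```

The severe-hyperglycaemia subgroup carries the highest microvascular
hazard (HR 1.36, 95% CI 1.25–1.49, against a generating value of 1.38)
and the obesity-related subgroup the highest macrovascular hazard
(HR 1.33, CI 1.16–1.52, generated at 1.50 and attenuated because many
true-MOD patients — especially white-profile ones, and those missing a
baseline indicator — end up labelled MARD) — the pattern the pipeline is
designed to surface, with the attenuation behaviour discussed in the
vignette.

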