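# vmbsim

An *in silico* framework for the rational design of vaginal probiotic
therapy against bacterial vaginosis (BV).

BV is a shift of the vaginal microbiome away from *Lactobacillus*
dominance toward a diverse anaerobic community; antibiotics clear it
short-term but recurrence is the norm, and live biotherapeutics
(probiotic strains) are hard to evaluate clinically. `vmbsim` simulates
candidate probiotic strains and dosing regimens across heterogeneous
virtual patient populations so that strain selection criteria and
regimen design can be compared before anything reaches a trial.

The community model is a four-species generalized Lotka-Volterra (gLV)
system over non-optimal anaerobic bacteria (nAB), *L. iners* (Li),
optimal *Lactobacillus* spp. (oLB), and the probiotic (P):

$$\frac{dx_i}{dt} = x_i\Big(k_{grow,i} + \sum_j \alpha_{j\to i}\,x_j\Big),$$

with the nAB growth rate replaced by a negative kill rate
$k_{kill}$ during antibiotic (metronidazole) exposure. On top of the
simulator the package provides:

- **Virtual BV+ populations** — Latin Hypercube Sampling of resident
  parameter ranges, analytic fixed-point and stability analysis,
  equilibrium-behavior labelling (`1SS nAB`, `2SS nAB/Li`, ...), and
  resampling to the clinically observed behavior distribution
  (60/31/9%).
- **Strains and regimens** — a library of benchmark hypothetical strains
  (null, traditional, 1/2/3-parameter best, oLB-boosting, Lactin-V
  benchmark set) and regimens (7-day probiotic course, antibiotic-only,
  antibiotic + probiotic, the Lactin-V phase-2b schedule), plus
  dose-frequency and dose-amount sweeps.
- **Community-state classification** — a configurable nearest-centroid
  rule standing in for VALENCIA; default one-hot centroids give plain
  dominance semantics.
- **Sensitivity analysis** — one-at-a-time sweeps with the normalized
  sensitivity metric $S = (\Delta Y/\Delta P)(P_0/Y_0)$ and the 81-point
  four-parameter combination grid.
- **Systematic strain screening** — 500-strain LHS screens, modal
  response profiling, PLS-DA of strain parameters against response
  class, and best-fit selection against clinical recurrence rates, with
  chi-square / rank-sum / Benjamini-Hochberg statistics.

## Worked example

```r
library(vmbsim)

pop <- generate_population(pool_size = 6000, n = 600, seed = 101)
pop
#> virtual BV+ population: 600 patients
#> labs
#>     1SS nAB  2SS nAB/Li 2SS nAB/oLB
#>         360         186          54

dose <- calibrate_dose(pop)          # median P rel. abundance 0.5 at day 1
round(dose, 2)
#> [1] 71.68

prof <- evaluate_regimen(pop, make_strain("traditional"),
                         make_regimen("short_term", dose_amount = dose))
prof
#> response profile: strain 'traditional', regimen 'short_term', n = 587 (13 excluded)
#>        nAB    Li   oLB     P
#> d7   0.135 0.003 0.005 0.857
#> d14  0.440 0.015 0.010 0.535
#> d37  0.516 0.049 0.024 0.411
#> d97  0.518 0.061 0.024 0.397
#> d187 0.518 0.063 0.024 0.395
#> d372 0.518 0.063 0.024 0.395
```

Each row is an evaluation day (d7 = therapy cessation, d37 = 1 month
post-cessation, d372 = 12 months); columns are the fraction of the
population whose community is dominated by each species at that time.
The `nAB` column is the treatment failure (BV recurrence) rate — here
the traditional strain stabilises at ~52% failure from 1 month on, and
comparing strains or regimens is a matter of comparing these columns
(`response_fraction(prof, "nAB", 372)`). The excluded patients are
parameter draws whose unconstrained interaction terms produce unbounded
(mutualistic) dynamics once treatment perturbs the community; exclusions
are counted and reported with every profile.

A thin command-line wrapper over the same functions is installed at
`inst/cli/vmbsim.R` with subcommands `make-population`,
`simulate-regimen`, `sensitivity`, `screen`, and `dose-sweep`.

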