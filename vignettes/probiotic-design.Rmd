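---
title: "Designing vaginal probiotic therapy in silico: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing vaginal probiotic therapy in silico: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`vmbsim` simulates the vaginal microbiome as a four-species generalized
Lotka-Volterra (gLV) community: non-optimal anaerobic bacteria (nAB, the
group associated with bacterial vaginosis), *Lactobacillus iners* (Li),
optimal *Lactobacillus* spp. (oLB: *L. crispatus*, *L. gasseri*,
*L. jensenii*), and a probiotic strain (P) introduced by treatment. Each
abundance $x_i$ (arbitrary density units) evolves as

$$\frac{dx_i}{dt} = x_i\Big(k_i + \sum_j \alpha_{j\to i}\, x_j\Big),$$

where $k_i$ (d$^{-1}$) is the intrinsic growth rate and
$\alpha_{j\to i}$ (density$^{-1}$ d$^{-1}$) the effect of species $j$ on
the per-capita growth of species $i$. Self-interactions are negative
(finite carrying capacity); interspecies terms may take either sign, so
the model can express amensal, commensal, competitive or mutualistic
pairs. During antibiotic exposure (metronidazole), the nAB growth rate is
replaced by a negative first-order kill rate $k_{kill}$ (default
$-2.64$ d$^{-1}$, the moderate literature-derived decay; $-3.82$ d$^{-1}$
for the most sensitive strains); *Lactobacillus* spp. and the probiotic
are resistant and unaffected.

Model assumptions worth keeping in view: interactions are pairwise,
constant in time, and abundance- rather than resource-mediated; there is
no host variation (hormones, menses, behavior), no spatial structure, and
no demographic noise. Probiotic doses are instantaneous boluses added to
P — the simplest semantics consistent with discrete dosing, since the
residence time of a dose is short relative to community dynamics.

# Numerical integration

The dynamics are piecewise smooth between discrete events (doses,
antibiotic window boundaries), so `simulate_glv()` integrates segment by
segment with an adaptive stiff-capable solver (`deSolve::lsoda`, compiled
right-hand side), restarting at every event. Tolerances default to
`rtol = 1e-6`, `atol = 1e-9`. gLV dynamics preserve non-negativity
analytically; solver undershoot in $(-100\,\mathrm{atol}, 0)$ is clipped
to zero and anything more negative raises an error rather than being
silently repaired. The state reported at a dose time is the post-bolus
state. Halving tolerances changes evaluation-time abundances by less than
$10^{-5}$ relative (asserted in the test suite against a fixed-step RK4
oracle).

Calendar constants are fixed: 1 month = 30 d, 3 months = 90 d,
6 months = 180 d, 12 months = 365 d; daily dosing is at 24 h intervals
from the regimen start.

# Virtual patient populations

A virtual patient is a resident-community parameter set (3 growth rates,
3 self-interactions, 6 interspecies terms). `generate_population()`
draws a large pool by Latin Hypercube Sampling from uniform ranges:
growth 0.1–1 d$^{-1}$, self-interaction $-0.04$ to $-0.004$, interspecies
terms $\pm 0.10$ density$^{-1}$ d$^{-1}$. The interspecies bounds are
configurable (YAML) including sign restrictions, because the empirical
literature constrains directionality (e.g. *Lactobacillus* inhibition of
nAB via lactic acid and H$_2$O$_2$) more tightly than magnitude; the
package default leaves signs free.

For each draw, all $2^3$ support subsets of the resident system are
solved for equilibria; a point is stable iff every Jacobian eigenvalue
has real part below $-10^{-9}$ (marginal cases count as unstable). Each
stable point is labelled by the community-state classifier, and the
attractor structure is summarised as mono-stable (`1SS X`), bi-stable
(`2SS X/Y`) or `other`. Patients are *BV+* when a stable nAB-dominant
state exists; their initial condition is that state (the highest-nAB one
if several), with P absent.

One structural detail matters greatly for treatment simulations. Many
nAB-dominant equilibria are *boundary* fixed points with one or both
*Lactobacillus* groups at exactly zero, and zero abundance is absorbing
in gLV dynamics: a species at 0 can never regrow, which would make
antibiotic clearance pointless for such patients by construction.
Clinically, both BV-associated anaerobes and *Lactobacillus* spp.
persist at low levels in communities dominated by the other, so resident
species absent from the equilibrium are initialized at a detection-floor
inoculum (default 0.01 density units, roughly 0.1% of a typical
equilibrium abundance — far below any classification threshold, but able
to regrow over the weeks-long post-antibiotic window). The floor is a
structural correction for the gLV absorbing state, not a fitted
quantity. The pool is then resampled (largest-remainder
rounding, without replacement when strata suffice) to the clinically
observed distribution of BV-compatible equilibrium behaviors in the
Human Microbiome Project cohort: 60% `1SS nAB`, 31% `2SS nAB/Li`, 9%
`2SS nAB/oLB`. Defaults: a 30,000-draw pool resampled to 2,000
patients.

# Community-state classification

`classify_cst()` is a nearest-centroid rule on relative abundances. The
default centroids are one-hot unit vectors, which reduces classification
to dominance (argmax of relative abundance); centroid tables derived from
the VALENCIA classifier can be loaded from CSV instead. Ties break by the
fixed priority nAB > Li > oLB > P, so an ambiguous state counts as
treatment failure — the conservative choice. Classification is scale
invariant by construction; the published taxonomy-level classifier itself
is out of scope.

# Strains, regimens and dose calibration

The strain library (`make_strain()`) encodes the benchmark hypothetical
designs: the null strain ($k_{grow,P} = 0.5$, $\alpha_{P\to P} = -0.022$,
no cross terms), the traditional strain
($\alpha_{P\to nAB} = -0.01$), the 1/2/3-parameter best strains (adding
$\alpha_{nAB\to P} = +0.01$ and a $+0.01$ growth increment), the
2-parameter counter strain, the oLB-boosting series ($\pm 0.05$
modifications), and the Lactin-V benchmark set anchored at
$\alpha_{P\to nAB} = -0.012$ with "moderate" and "bad" variants. For the
latter two, "strong competition with endogenous *Lactobacillus*"
(3× the anchor) is applied symmetrically to all four Li/oLB ↔ P cross
terms at $-0.036$; the narrower reading (scaling only one term) can be
reproduced via the `competition` argument.

Regimens: a short-term course (7 once-daily doses, evaluated at
cessation and 1 wk, 1, 3, 6, 12 months post-cessation), an
antibiotic-only course (7-day window), antibiotic followed by the
short-term probiotic, and the Lactin-V phase-2b schedule (5-day
antibiotic window, 4 once-daily doses on days 5–8, then twice-weekly
maintenance through week 11, evaluated at weeks 12 and 24 from treatment
start). Maintenance-frequency variants (bi-weekly to daily) and dose
multipliers support the dosing sweeps. Short-term timepoints are measured
post-cessation, Lactin-V timepoints on the absolute trial clock, matching
the corresponding clinical reporting conventions.

The bolus size is the one deliberately calibrated quantity. Clinical
post-dose relative abundance distributions are reported only at the
cohort level, with no numeric calibration target to borrow;
`calibrate_dose()` therefore chooses the dose so that the population
median probiotic relative abundance one day after a first dose is 0.5 — a
probiotic that transiently co-dominates — and this stand-in is used
throughout. Because the null strain is decoupled from the residents, its
long-run outcome is insensitive to the dose, which limits how much this
choice can distort the headline comparisons.

# Sensitivity analysis

`local_sweep_1d()` perturbs one probiotic parameter at a time
(interspecies terms over $[-0.10, 0.10]$, growth over $[0, 1]$,
self-interaction over $[-0.04, -0.004]$; 11 points by default),
evaluating the population response at 12 months post-cessation around the
null strain. Sensitivity uses the normalized metric
$S = \frac{\Delta Y}{\Delta P}\cdot\frac{P_0}{Y_0}$ with $P_0 = 0.01$ for
interspecies terms (the reference magnitude of a meaningful interaction)
and the null value itself for growth and self-interaction. $S$ could be
summarised from sweep endpoints or by regression; the package computes
it pointwise at every grid value against the null response and reports
the mean over the sweep (`S_mean`), keeping the pointwise table
available so either convention can be recovered.
`four_parameter_grid()` runs the $3^4 = 81$ combination analysis over
$\{-0.01, 0, +0.01\}$ for the four decisive interaction terms, with
chi-square tests against the null combination.

# Strain screening and statistics

`screen_strains()` samples candidate strains by LHS from the same
numeric ranges as the population parameters, with the single constraint
$\alpha_{P\to nAB} < 0$ (a probiotic is not designed to feed the
anaerobes). Each strain's modal response class is the response type with
the highest population frequency at the final evaluation timepoint, ties
toward nAB. The association between strain parameters and modal class is
summarised by a two-latent-variable PLS-DA (via `mixOmics`), with
10-fold cross-validated accuracy; the test suite cross-checks scores and
loadings against an independently coded NIPALS oracle.
`select_best_fit_strains()` ranks strains by the sum of absolute
distances between predicted and clinically observed recurrence (34.6% at
12 weeks, 48.4% at 24 weeks) and returns the top five. The statistics
layer uses Pearson chi-square without continuity correction (arms of
~2,000 make it immaterial), two-sided Wilcoxon rank-sum tests, and
Benjamini-Hochberg adjustment.

# What the generator does and does not emulate

The synthetic population emulates between-patient heterogeneity in
growth and interaction parameters, multistability of community states,
and the clinical mix of equilibrium behaviors. It does not emulate
longitudinal within-patient variability, measurement noise in relative
abundances, taxonomic resolution below the three resident groups, or any
host covariates. Passing tests therefore demonstrate internal
consistency of the dynamical framework and reproducibility of the
screening logic — not clinical validity for any particular patient.

A known quantitative limitation follows from the sampling ranges. The
empirical literature constrains interspecies-interaction directionality
and strength more tightly than the uniform defaults used here, and with
those defaults the BV+ filter (which requires invasion resistance of the
nAB state) selects communities whose nAB equilibrium abundance is large
relative to the null probiotic's carrying capacity (0.5/0.022 ≈ 22.7).
Regenerated populations consequently show higher absolute failure rates
than comparable modelling of the Lactin-V cohort reports, while the
relative orderings between strains and regimens — the results the
framework is designed to rank — are preserved. The configurable ranges
exist precisely so literature-derived bounds can be dropped in.

# Problem sizes

Default protocol sizes are a 30,000-draw pool, 2,000 patients and a
500-strain screen; the package's own test suite exercises the
same code paths at reduced sizes chosen to keep a full run comfortable on
a laptop (pools of a few thousand, populations of 120–600, three seeds
for the stochastic tier, 30-strain screens), relying on the ±5
percentage-point comparison tolerance to absorb the extra sampling noise.

# Worked example

```{r, eval = FALSE}
library(vmbsim)
pop <- generate_population(pool_size = 6000, n = 600, seed = 101)
dose <- calibrate_dose(pop)
prof <- evaluate_regimen(pop, make_strain("traditional"),
                         make_regimen("short_term", dose_amount = dose))
prof
```
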