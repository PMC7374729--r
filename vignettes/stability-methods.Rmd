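---
title: "Two-state denaturation analysis and variant stability comparison with stabscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state denaturation analysis and variant stability comparison with stabscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabscan)
library(dplyr)
```

## The scientific problem

Missense variants in the androgen receptor (AR) cause androgen
insensitivity syndrome (AIS) with severities graded complete (CAIS),
partial (PAIS) and mild (MAIS), and AR somatic variants are common in
prostate cancer. One mechanistic route from a single residue change to
loss of function is destabilisation of the folded protein: a mutant whose
folding free energy is raised by a few kcal/mol populates the unfolded
state, aggregates, or is degraded. stabscan implements the two analysis
layers needed to examine this hypothesis quantitatively:

1. a **variant catalog layer** that harmonises single-residue variants on
   the 920-residue AR reference, assigns them to domains (NTD, DBD, hinge,
   LBD), normalises phenotype annotations and joins them to predicted
   stability changes (FoldX `Dif` output), supporting class-wise
   comparisons such as disease-associated versus polymorphic variants; and
2. a **chemical-denaturation layer** that turns circular-dichroism (CD)
   GdmHCl titrations of purified AR ligand-binding domain (LBD) into
   folding free energies by the two-state linear extrapolation method
   (LEM), yielding the experimental ddG of a mutant relative to wild type.

## The two-state LEM model

For a monomeric protein unfolding in a two-state equilibrium
$F \rightleftharpoons U$, the CD ellipticity at 222 nm,
$\theta$, is an occupancy-weighted average of the folded and unfolded
baselines, so the folded fraction at the $i$-th denaturant concentration
is

$$\alpha_i = \frac{\theta_i - \theta_U}{\theta_F - \theta_U},$$

the folding constant is $K_i = \alpha_i / (1 - \alpha_i)$, and the
point-wise folding free energy is $\Delta G_i = -RT \ln K_i$ with
$R = 1.9872 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 298.15$ K by default
(the titrations the package was built around were equilibrated at 25 °C;
both constants are arguments everywhere they appear). Because free energy
is, to good approximation, linear in denaturant,

$$\Delta G_i = \Delta G_0 + m\,[\mathrm{GdmHCl}],$$

an ordinary least-squares line through the retained $(\!c_i, \Delta G_i)$
points extrapolates to the folding free energy at zero denaturant
$\Delta G_0$ (intercept, kcal/mol, negative for a stable protein), the
$m$ value (slope, kcal mol⁻¹ M⁻¹, a proxy for the change in
solvent-accessible surface on unfolding) and the transition midpoint
$C_{1/2} = -\Delta G_0 / m$, the concentration at which the fitted line
crosses $\Delta G = 0$. The package deliberately implements this
point-wise-then-linear composition rather than a global non-linear fit of
the sigmoid: the two give identical answers on clean two-state data, and
the composition exposes an auditable per-point table
(concentration, $\theta$, $\alpha$, $K$, $\Delta G$, retained flag).

The experimental stability change of a mutant is
$\Delta\Delta G = \Delta G_0(\text{mutant}) - \Delta G_0(\text{reference})$,
positive = destabilising, matching the sign convention of FoldX
predictions, so predicted and measured values are directly comparable.

```{r lem-demo}
baselines <- list(theta_folded = -20, theta_unfolded = -5)
wt <- simulate_curve(dg0 = -5.3, m_value = 1.7, sample_id = "WT")
mut <- simulate_curve(dg0 = -1.5, m_value = 0.6, sample_id = "L813F")

fit_wt <- analyze_curve(wt, baselines = baselines)
fit_mut <- analyze_curve(mut, baselines = baselines)
glance(fit_wt)
ddg_relative(fit_mut, fit_wt)
```

## Tunable parameters and their defaults

* **Thermodynamic constants.** `gas_constant = 1.9872e-3`
  kcal mol⁻¹ K⁻¹ and `temperature_K = 298.15` K. Change
  `temperature_K` if titrations were equilibrated at another temperature.
* **Retention window** (`alpha_window`, default `c(0.02, 0.98)`).
  $\ln K$ diverges as $\alpha \to 0$ or $1$, so points outside the window
  are flagged `retained = FALSE` (never dropped) and excluded from the
  regression. Two practical regimes deserve emphasis. For *noiseless
  synthetic* curves every point carries exact information and the window
  may be opened fully (`c(0, 1)`); the analysis then reproduces the
  generating $(\Delta G_0, m)$ to better than $10^{-6}$ kcal/mol over the
  whole realistic parameter box. For *noisy measured* curves the
  transform is convex near the baselines, so points with $\alpha$ near
  0 or 1 contribute a systematic (not merely random) error: at ellipticity
  noise of 2% of the baseline span the default window leaves a bias of
  roughly half a kcal/mol in $\Delta G_0$, while a transition-only window
  of `c(0.1, 0.9)` reduces it to a few hundredths. We therefore recommend
  `alpha_window = c(0.1, 0.9)` whenever the data are appreciably noisy,
  and keep the wider default for consistency with common LEM practice on
  well-averaged curves.
* **Baseline policy.** If baselines are not supplied,
  $\theta_U$ is the mean ellipticity of points at $\ge$ 5 M GdmHCl (the
  protein is assumed fully unfolded there) and $\theta_F$ the mean at
  $\le$ 0.25 M. Note that for a protein of moderate stability the 5 M
  point retains a sub-percent folded population, so estimated baselines
  carry a small systematic offset; supply measured baselines when you
  have them. Sloped pre/post-transition baselines are out of scope.
* **Fit guards.** At least 3 retained points spanning more than 0.2 M are
  required; a non-positive fitted $m$ is flagged (`noncooperative`) with a
  warning rather than an error, since it usually signals an unstable
  protein or a failed titration rather than a programming mistake.
* **Destabilisation threshold** (`classify_destabilizing`, default
  3 kcal/mol, symmetric): a destabilisation of that order is typically
  enough to trigger cellular degradation, and the labels
  `stabilizing`/`neutral`/`destabilizing` use it symmetrically.
* **Group test** (`compare_groups`, default Welch). The contrasted
  variant classes have very different sizes (hundreds of disease variants
  versus a few dozen polymorphisms), so a paired test is not applicable
  and a pooled-variance test is fragile; Welch's unpaired two-sided t-test
  is the default, with `student` and `wilcoxon` available. No
  multiple-testing correction is applied by default (per-contrast values
  are reported raw); `compare_all_pairs(p_adjust = "bonferroni")` covers
  the three-way contrast family.

## The variant catalog layer

Positions follow the 920-residue NM_000044.2 protein reference
(`offset` supports legacy 919-residue coordinates). The domain map is
NTD 1–559 (residue 559, the NTD–DBD linker, is assigned to the NTD so the
intervals partition the sequence), DBD 560–620, hinge 621–690 and
LBD 691–920; the bipartite nuclear localisation signal (617–634) is kept
as an annotation attribute. Variant identity is the key
(position, ref_aa, alt_aa); dataset-specific identifiers ride along as
metadata. `domain_stats()` reports per-domain mutated-residue fractions
and variant counts, and `dataset_overlap()` enumerates the seven Venn
regions of three catalogs, always summing to the union size.

```{r catalog-demo}
sim <- simulate_catalogs(seed = 1)
dataset_overlap(sim$catalogs)
joined <- join_ddg(sim$combined, sim$ddg)
compare_groups(joined, ddg_pred, source, "HGMD", "polymorphism")
```

## What the synthetic-data generator emulates — and what it does not

`simulate_curve()` inverts the LEM model exactly and adds homoscedastic
Gaussian ellipticity noise on a 0–5 M grid in 0.25 M steps (the range in
which 5 M GdmHCl fully unfolds the AR-LBD). Real CD titrations violate
this in known ways: baselines drift with denaturant (sloped baselines),
noise grows at low signal, and proteins can aggregate instead of
unfolding reversibly. Passing round-trip tests therefore demonstrates the
correctness of the analysis algebra and fitting, not that any particular
measured curve is two-state.

`simulate_catalogs()` generates three overlapping variant sets with exact
sizes (defaults 337 disease-associated, 323 somatic, 39 polymorphism —
the sizes of the AR extracts the package emulates) and exact pairwise and
triple overlaps, with per-class ddG distributions: disease
$\mathcal{N}(2.5, 1.5)$ truncated below at −1 kcal/mol (disease variants
average above 2 kcal/mol and are rarely strongly stabilising), somatic
$\mathcal{N}(0.8, 1.0)$ and polymorphism $\mathcal{N}(1.0, 0.8)$
(polymorphism effects cluster around 1 kcal/mol, somatic slightly lower).
Default overlaps (25 disease∩somatic, 3 disease∩polymorphism,
3 somatic∩polymorphism, 2 triple) are small, as expected for germline
disease, tumour and population sets drawn from the same gene; they are
plain arguments, not estimates. Positions default to the DBD and LBD
intervals because those are the domains with crystal structures, hence
the ones a structure-based predictor covers. The generator does not
emulate the published databases themselves: the multi-database
compilation behind domain-level percentages (e.g. 56% of LBD residues
mutated) is not deposited, so those figures can be emulated by
construction but not reproduced.

## Numerical choices and degenerate inputs

* Identical folded and unfolded baselines are a hard error (the folded
  fraction is undefined), as is a curve whose every point lies outside
  the retention window (no transition information).
* A retained $\alpha$ of exactly 0 or 1 is a domain error naming the
  offending point; with the default window this cannot occur.
* Replicate FoldX rows for one mutation are aggregated by their mean with
  the replicate count recorded; unparseable rows and malformed variant
  rows are collected into rejects reports with reasons, never silently
  dropped.
* `compare_groups()` keeps the contrast defined when both groups are
  constant (statistic 0 and p 1 when equal; ±Inf and p 0 when not), which
  `t.test()` alone refuses.
* All simulation randomness flows through explicit `seed` arguments
  evaluated in a local RNG scope, so library calls never disturb the
  caller's RNG state, and reruns of `run_pipeline()` with one seed are
  byte-identical.
* Reported parameters keep full precision; rounding to one decimal is
  applied only when comparing against tabulated reference values.

The printed midpoint of a titration is sometimes read off the raw curve
rather than derived; stabscan reports the derived $C_{1/2} = -\Delta
G_0/m$ (for the packaged wild-type panel entry this gives 3.12 M against
a printed 3.0 M) and keeps any printed midpoint as a separate column of
the reference fixture rather than overwriting either value.

## Problem sizes used in the shipped checks

The test-suite simulations are sized to be exact or statistically stable
at desk scale: 20 random specs for noiseless round-trips (machine-precision
identity), 50 replicate curves for the noisy-recovery check, 1,000
simulated null datasets (two groups of 30) for the Welch type-I-error
calibration, and catalogs of a few hundred variants throughout.

## Known limitations

* Strict two-state, monomer model; three-state or dimer unfolding and
  thermal (temperature-ramp) denaturation are out of scope, as are sloped
  baselines.
* The pipeline consumes FoldX *output*; it does not run FoldX, repair
  structures or compute energies.
* Catalogs operate at protein-residue level; genomic coordinates,
  transcript mapping and VCF consequence calling are out of scope.
* The default retention window is a compromise (see above); for noisy
  data prefer `c(0.1, 0.9)`, or supply measured baselines and inspect the
  audit table.
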