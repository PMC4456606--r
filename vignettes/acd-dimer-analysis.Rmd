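---
title: "Quantifying pH-dependent dissociation of an sHSP ACD dimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pH-dependent dissociation of an sHSP ACD dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdimer)
library(dplyr)
```

## The system and the question

Small heat shock proteins (sHSPs) such as HSPB5 (alphaB-crystallin) are
ATP-independent chaperones that assemble into large polydisperse
oligomers. Their conserved core, the alpha-crystallin domain (ACD),
forms a dimer through antiparallel pairing of the long beta6+7 strands,
and this dimer is usually taken as the building block of the oligomer.
Cellular stress is often accompanied by acidosis, so the stability of
the ACD dimer across the physiological pH range (7.5 down to ~6.5) is a
functional question, not a biophysical curiosity: a dimer interface that
loosens as pH falls changes both oligomer architecture and chaperone
activity.

`acdimer` implements the quantitative chain used to characterise such a
dimer-monomer equilibrium from solution measurements:

1. closed-form dimer-monomer equilibrium and the kinetic decomposition
   of NMR exchange rates (`solve_dimer_monomer()`, `decompose_kex()`,
   `predict_kex()`, `subunits_from_mw()`);
2. two-site chemical-exchange CPMG relaxation dispersion: forward
   models, chi-square fitting with model selection, screening,
   and Monte Carlo errors (`carver_richards_r2eff()`,
   `bloch_mcconnell_r2eff()`, `fit_dispersion()`, `global_fit()`,
   `monte_carlo_errors()`);
3. histidine pK_R titration fitting and ring classification
   (`fit_pkr()`, `classify_tautomer()`, `flag_hbonded_nh()`);
4. chemical-shift-perturbation analysis and the concordance of
   dispersion-derived shift differences with pH-difference shifts
   (`csp_table()`, `compare_dw_csp()`);
5. dilution isothermal titration calorimetry for a dissociating
   homodimer (`forward_isotherm()`, `fit_dilution()`);
6. seeded generators for all of the above (`sim_*()`), so that every
   fitting stage has ground truth to be tested against.

## Dimer-monomer equilibrium and kinetics

The dissociation constant is defined in subunit-molar units,
$K_D = [M]^2/[D]$, with mass balance $[M] + 2[D] = c_{tot}$. This gives
the closed form

$$[M] = \frac{-K_D + \sqrt{K_D^2 + 8 K_D c_{tot}}}{4},$$

the unique non-negative root. Two anchor points are worth keeping in
mind: with $K_D = 2\ \mu M$ at $c_{tot} = 700\ \mu M$ about 4% of the
subunits are monomeric, while $K_D = 36\ \mu M$ puts roughly
$100\ \mu M$ of subunits in the monomer pool.

```{r}
solve_dimer_monomer(kd = c(2, 36), c_total = 700)
```

Relaxation dispersion reports the exchange rate
$k_{ex} = k_{md}[M] + k_{dm}$, with $k_{md}$ the bimolecular
association rate constant and $k_{dm}$ the dimer dissociation rate.
A single measured $k_{ex}$ at known $c_{tot}$, combined with detailed
balance $K_D = k_{dm}/k_{md}$, determines both constants:

```{r}
decompose_kex(kex = 1500, kd = 36, c_total = 700)
```

A two-concentration linear solve would be the more obvious route, but
with realistically noisy $k_{ex}$ values it is fragile (it can return
negative rate constants), so the single-point + detailed-balance route
is the one implemented. The package exposes `predict_kex()` so the
concentration dependence implied by a decomposition can be checked
against measurements at other concentrations; when measured and
predicted values disagree, that disagreement is the result, and the
package reports it rather than reconciling it.

## CPMG relaxation dispersion

### Forward models

The effective relaxation rate from the two-point constant-time scheme
is $R_{2,eff} = -\ln(I/I_0)/T$ with $T = 20$ ms. The observable is
measured as a function of the refocusing frequency
$\nu_{CPMG} = n/(2T)$, where $n$ is the number of 180-degree pulses;
the conventional schedule (25, 50, 75, 100, 150, 175, 200, 300, 600,
1000 Hz, duplicates at 25 and 200 Hz, fields 600 and 800 MHz) gives
integer $n$ throughout.

The closed-form model is the all-timescale Carver-Richards expression
for two-site exchange with equal intrinsic rates, parameterised by
$k_{ex}$, the minor population $p_b \le 0.5$, and the shift difference
$\delta\omega$. $\delta\omega$ is carried in ppm, which is
field-invariant; conversion to rad/s uses the $^{15}$N/$^1$H
gyromagnetic ratio (600 MHz $^1$H corresponds to 60.82 MHz $^{15}$N).

The numerical cross-check, `bloch_mcconnell_r2eff()`, propagates
two-site transverse magnetisation through the explicit pulse train with
ideal refocusing pulses. Two detection conventions are provided and the
difference between them matters:

* `"asymptotic"` (default) extracts the decay rate of the dominant
  eigenvalue of the two-echo cycle propagator. This is exactly the
  quantity the Carver-Richards formula describes, and the two agree to
  machine precision over the whole regime grid
  ($k_{ex} \in [100, 5000]$ s$^{-1}$, $p_b \le 0.15$,
  $\delta\omega \le 6$ ppm).
* `"signal"` propagates magnetisation started at the equilibrium
  populations through the finite 20 ms block and reads out the major
  site. This includes initial-condition transients that the closed form
  neglects; in slow exchange at large $p_b$ the two definitions differ
  by up to a few s$^{-1}$. Fits of experimental data are insensitive to
  the distinction at the noise levels considered here, but oracle
  comparisons must compare like with like.

A related numerical honesty note: in slow exchange
($k_{ex} \ll \delta\omega$) the exact per-cycle rate is not strictly
monotone in $\nu_{CPMG}$ - small coherent ripples ride on the decaying
envelope. The dispersive-profile tests therefore assert strict
monotonicity only for intermediate-to-fast exchange.

### Fitting

`fit_dispersion()` minimises
$\chi^2 = \sum_\nu ((R_{2,eff}^{obs} - R_{2,eff}^{calc})/\sigma)^2$
jointly over fields, with per-point $\sigma$ estimated from the
duplicate frequencies (pooled $\sqrt{\overline{d^2}/2}$ per curve, with
a configurable floor). Optimisation is bounded quasi-Newton (L-BFGS-B)
on log/logit-transformed parameters, multi-started from a grid
($k_{ex} \in \{200, 500, 1000, 2000, 4000\}$,
$p_b \in \{0.02, 0.05, 0.1\}$, $\delta\omega \in \{1, 2, 4\}$ ppm); the
best few grid points by unrefined chi-square are refined and ties are
broken by lowest chi-square, then lowest $k_{ex}$. Model naming follows
the fast/slow convention: model-2 fits $k_{ex}$ and the composite
$\Phi = p_a p_b \delta\omega^2$ (Luz-Meiboom), model-3 and the general
model fit the full Carver-Richards parameterisation.

Residues enter fitting only if their dispersion amplitude
$R_{2,eff}(25\,\mathrm{Hz}) - R_{2,eff}(1000\,\mathrm{Hz})$ exceeds
8 s$^{-1}$; fits with reduced $\chi^2 \ge 10$ are flagged rejected.
Both thresholds are recorded in `analysis_config()` and echoed into
every result bundle. Parameter uncertainties follow the conventional
Monte Carlo recipe: resample synthetic datasets from the fitted curve
plus Gaussian noise at $\sigma$, refit, and report the standard
deviation over (by default) 100 replicates.

`global_fit()` shares $(k_{ex}, p_b)$ across a residue group (the
natural model when one process, dimer dissociation, drives every
interface residue) while keeping per-residue $\delta\omega$ and
per-field $R_2^0$.

## Histidine pK_R titrations

Observed shifts follow the single-site Henderson-Hasselbalch form

$$\delta_{obs}(pH) = \delta_{HA} +
 (\delta_A - \delta_{HA})\,\frac{10^{pH - pK_R}}{1 + 10^{pH - pK_R}},$$

with the Hill coefficient fixed at 1 (one protonation site per ring).
Fits use Levenberg-Marquardt least squares over
$(pK_R, \delta_{HA}, \delta_A)$ on the nine-point pH grid from 9.3 to
6.0.

When the inflection lies below the sampled range the problem becomes
ill-conditioned: $pK_R$ and the unobserved protonated-state shift
$\delta_{HA}$ are strongly correlated, and point estimates scatter over
a pH unit or more while their nominal confidence can look acceptable.
The package therefore reports a bound ("<6"-style) rather than a
number when the fitted $pK_R$ falls more than 0.5 units below the
lowest sampled pH, or falls below the lowest pH with a standard error
above 0.2 units. Simulations at 0.01 ppm noise show this keeps every
in-range value ($pK_R \ge$ grid minimum) as a point estimate while
consistently converting the unbracketed cases to bounds. In-range
recovery is essentially unbiased (bias $< 0.01$ units), with
single-fit scatter of 0.02-0.06 units depending on distance from the
grid edges.

Tautomer classification uses the canonical ring-nitrogen shift ranges:
a protonated (amine-like) ring $^{15}$N sits far upfield of a
non-protonated (pyridine-like) one, and 190 ppm - the midpoint of the
canonical ranges - separates them. A protonated N$\delta$1 with
pyridine-type N$\epsilon$2 is the less common N$\delta$1H tautomer; the
converse is N$\epsilon$2H; both protonated is the cationic ring.
An exchangeable ring NH observed at or beyond 12 ppm is flagged as
hydrogen bonded.

## Chemical shift perturbations

The combined amide perturbation uses the conventional scaling

$$\Delta\delta = \sqrt{\tfrac{1}{2}\left(\Delta_{HN}^2 +
  (\Delta_N/5)^2\right)},$$

with both scale factors configurable. Classes are left-closed:
$\Delta\delta \in [0.1, 0.2]$ ppm is moderate, above 0.2 ppm strong.
Exchange-regime calls work from curated peak lists: a residue that
never doubles titrates in fast exchange, one doubled at every condition
is slow, and doubling over part of the range is mixed. Doubling is an
explicit column, not inferred from spectra - peak-list curation is
upstream of this package.

`compare_dw_csp()` pairs the dispersion-fitted $|\delta\omega|$ (ppm)
with the directly measured $^{15}$N shift difference between two pH
conditions. When the minor species at high pH *is* the low-pH state,
the two agree residue by residue; the Pearson correlation and mean
absolute difference quantify that concordance. Because per-residue
experimental values are not tabulated anywhere reusable, this
concordance is validated on synthetic data in which the generator
programs the identity to be true.

## Dilution ITC

In a dilution experiment, concentrated and therefore predominantly
dimeric protein (1 mM subunits in the syringe) is injected in forty
1 ul steps into a 200 ul buffer-filled cell; each aliquot dissociates
on dilution and the instrument integrates the heat. The forward model
tracks cell composition with the standard displaced-volume overflow
approximation (an injection of volume $v$ expels $v$ of the
pre-injection mixture), equilibrates the new total concentration with
`solve_dimer_monomer()`, and computes

$$q_i = \Delta H \cdot \Delta n_{diss},$$

where $\Delta n_{diss}$ is the increase in moles of dissociated dimer
relative to injecting pre-equilibrated syringe material. $\Delta H$ is
carried as the dissociation enthalpy in cal per mol of dimer; with the
measured heats exothermic, the instrument-sign convention is available
via `sign = -1`, and the package does not silently reconcile the sign
question - the fitted $|\Delta H|$ is unaffected.

`fit_dilution()` does least squares over $(K_D, \Delta H,
\text{baseline})$, with $K_D$ on a log scale, a constant baseline for
the mechanical heat of injection, and Jacobian-based standard errors.
Identifiability needs the syringe concentration about ten-fold above
$K_D$; the fitter warns when that fails and flags flat (non-dissociating)
isotherms instead of returning arbitrary numbers. In the measured
regime ($K_D = 36\ \mu M$, $\Delta H = 9328$ cal/mol, 1% heat noise)
recovery is within a few percent for both parameters, and the
noiseless round trip is exact to optimiser tolerance.

## What the generators emulate - and what they do not

The `sim_*()` generators reproduce the *geometry and statistics* of the
measurements: the exact $\nu_{CPMG}$ schedule with independent
duplicates at two fields, exchange parameters in the experimentally
observed window ($k_{ex}$ 760-1119 s$^{-1}$, $p_b \approx 5\%$),
Gaussian noise at 0.3 s$^{-1}$ on rates; the nine-point pH grid with
0.01 ppm shift noise; paired-condition peak lists whose $^{15}$N
monomer-dimer offsets equal the dispersion $\delta\omega$ so the
concordance analysis has positive ground truth; and the 40 x 1 ul
dilution geometry with 1% heat noise. Every generator takes an explicit
seed (default 7304) and emits its truth table.

They do not emulate: peak overlap, assignment errors, or exchange
broadening beyond detectability (the reason one histidine's ring pK_R
is experimentally undeterminable); pulse imperfections and
off-resonance effects in the CPMG train; temperature- or
concentration-dependent baseline drifts in ITC; or any coupling between
titrating sites. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated noise model, not
robustness to every pathology of real spectra.

## Numerical choices and problem sizes

* Optimisers: L-BFGS-B for dispersion (bounded, transformed
  parameters), Levenberg-Marquardt for titrations, restarted
  Nelder-Mead for the 3-parameter ITC problem.
* The dispersion test suites use 20-residue two-field datasets; the
  concordance analysis 12 residues; Monte Carlo error checks use 10-25
  replicates in tests while the package default stays at the
  conventional 100.
* Degenerate inputs are defined, not exceptional: $K_D = 0$ gives a
  fully dimeric solution (and a degenerate kinetic decomposition, with
  a warning); $\delta\omega = 0$ or $p_b = 0$ gives flat dispersion;
  flat titrations and isotherms are reported as undetermined /
  unidentifiable rather than fitted.
* Subunit counts from SEC-MALS masses round half-up, so 40.5 subunits
  reports as 41.

## Known limitations

* The Carver-Richards model assumes equal intrinsic rates in the two
  states and ideal pulses; no 3-site or off-resonance extensions are
  provided.
* The kinetic decomposition assumes the two-state dimer-monomer model
  end to end. Where measured concentration dependence disagrees with
  the model's prediction, the package surfaces the discrepancy; it has
  no mechanism to explain it.
* CSP scaling conventions differ across the literature; both scale
  factors are arguments, and comparisons should state the convention
  used.
* The ITC model treats each injection as instantaneous and the cell as
  perfectly mixed; kinetic ITC effects are out of scope.
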