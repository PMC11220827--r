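---
title: "Methods: exposure-led next-generation risk assessment by read-across"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-led next-generation risk assessment by read-across}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngra)
```

# The assessment problem

`ngra` implements an exposure-led, non-animal safety assessment (NGRA) for a
cosmetic ingredient whose systemic toxicity data gap is filled by read-across
from a data-rich structural analogue. The packaged worked example is the
isoflavone pair daidzein (target, treated as data-poor) and genistein
(source, with legacy in vivo data): the question answered is *the highest
concentration of the target ingredient that can safely be used in a leave-on
body lotion*.

The assessment runs in three tiers:

* **Tier 0** — establish the use scenario and analogue suitability:
  physicochemical similarity, concordance of categorical in silico profiler
  calls, and cross-assay potency ratios.
* **Tier 1** — systemic bioavailability: forward PBPK dosimetry converts the
  source chemical's in vivo NOAEL (0.3 mg/kg/day, rat oral) into internal
  plasma metrics (Cmax,total and Cmax,fu) that anchor in vitro testing
  concentrations and the later concordance check.
* **Tier 2** — derive the target's point of departure (PoD) from in vitro
  panels, convert it through reverse dosimetry into a safe external dose and
  product concentration, and summarize the margin as bioactivity-exposure
  ratios (BER).

# The PBPK model

The engine is a generic, calibratable perfusion-limited whole-body model.
Each tissue `i` (default set: gut, liver, kidney, skin, rest-of-body)
exchanges with a central plasma pool:

$$\frac{dA_i}{dt} = Q_i\,C_{pl} - \frac{Q_i}{V_i K_{p,i}} A_i$$

with amounts `A` in nmol, blood flows `Q` in L/h, volumes `V` in L, and
tissue:plasma partition coefficients `Kp`. Gut venous blood drains through
the liver (portal routing), and hepatic elimination acts on the unbound
venous liver concentration, `CL_int · fu · C_liver/Kp`. Eliminated mass and
metabolites are tracked as a cumulative sink (metabolite kinetics are out of
scope). Because every process is first order, the full right-hand side is a
constant rate matrix; the implementation builds that matrix once per
simulation and hands it, with its exact Jacobian, to the stiff-capable
`lsoda` integrator (`rtol = 1e-8`, `atol = 1e-10`). Plasma concentration in
nM is amount/volume; external doses are converted through the molecular
weight (mg/kg/day oral, µg/cm² × treated area dermal).

Absorption:

* **Oral** — a gut-lumen depot with first-order `ka` feeding the gut tissue;
  the non-absorbed fraction `1 − f_abs_oral` is tracked as unabsorbed mass.
  `ka = Inf` boluses the dose directly (the one-compartment analytic limit
  used in tests).
* **Dermal** — the absorbed fraction `f_abs_dermal` of the applied dose
  enters a skin surface depot where permeation into skin tissue
  (`k_perm_skin`) competes with first-order cutaneous metabolism
  (`k_met_skin`). This reproduces dermal first-pass metabolism: the fold
  effect on parent Cmax of switching metabolism off is
  `skin_firstpass_effect()`, calibrated to 3-fold in the shipped human
  config.

Mass balance (administered = in body + unabsorbed + skin-metabolized +
eliminated) is asserted after every simulation to a relative 1e-6; with the
rate-matrix formulation it typically closes near machine precision.

**Steady state** is defined operationally as the final interval of a 7-day
once-daily schedule; `cmax_metrics()` reads Cmax over that interval, and
`cmax_fu = fu × cmax_total` exactly, per individual.

# Population variability

Inter-individual variability is modelled as independent, median-preserving
lognormal multipliers on named parameters
(`exp(N(0, σ))`, `σ² = log(1 + CV²)`). The shipped configurations place a
single aggregate CV on hepatic intrinsic clearance: among the available
knobs it is the one steady-state Cmax actually responds to in these
absorption- and flow-limited regimes (volume perturbations barely move Cmax
under repeated dosing), so one clearance CV serves as a documented proxy for
all sources of kinetic variability. The CV was calibrated once to the width
(95th/5th percentile ratio) of the case study's reported confidence
intervals and then frozen: 0.62 for the rat oral config, 1.6 for the human
dermal config — the human value is large precisely because hepatic
extraction partially saturates the response of Cmax to clearance. The
reported CI *bounds* are reproduced approximately (the printed intervals are
not consistent with any single lognormal; see the calibration notes below),
and they are treated as descriptive, not as validation targets.
`population_simulate()` is bit-reproducible for a fixed seed; individual
integration failures are excluded and counted, and more than 10% failures
aborts.

# Reverse dosimetry

`reverse_dosimetry()` inverts the forward model by bisection on the log dose
until the chosen plasma statistic matches the target concentration to a
relative 1e-3, after probing that the forward model is increasing in dose.
The initial bracket is centred on the dose-proportional guess (for this
first-order model the first midpoint is already essentially exact) and
expands by decades, capped at a factor 1000 each way. When a population
statistic is requested, the same seed is reused at every bisection step so
the objective is smooth in dose.

The packaged case study inverts to the **95th percentile** individual
(`statistic = "ci95"`): the safe product concentration is the one at which
even the upper tail of the population stays at or below the safe internal
concentration. This convention is also what makes the case study's numbers
mutually consistent — at the derived dose of ≈0.5 µg/cm² the *mean* Cmax is
≈5.95 nM while the CI95 is ≈10 nM, and it is the 10 nM figure that the safe
internal concentration matches.

# Point of departure and safety factors

`select_pod()` encodes the governing-endpoint rule: the PoD is based on
biological *functional* activity, never binding affinity. Receptor-binding
and transcriptomic-pathway results are supporting evidence that flags
targets; among the functional classes the lowest LOEC governs, with the
priority order functional transactivation > enzyme inhibition /
steroidogenesis > cell stress used only to break value ties. When the same
assay was run with and without a metabolic S9 fraction, the pair is
collapsed to its minimum, and the log records whether the two values overlap
within their reported standard deviations (they are not tested formally —
the check is informational). Every exclusion is written to a selection log.

`derive_pod()` applies the safety-factor chain at full precision:

$$\text{NOEC} = \text{LOEC}/3, \qquad
  C_{safe} = \text{NOEC}/3.3$$

where 3 converts a lowest-observed- to a no-observed-effect concentration
and 3.3 covers intra-individual variability. Display rounding is separated
from computation: concentrations print as integers at ≥10 nM and to three
significant figures below (so 33.33 → 33, 10.1 → 10, 1.733 → 1.73), and BERs
print as integers at ≥20, one decimal in [1, 20), one significant figure
below 1 (`display_conc()`, `display_ber()`). Fold ratios quoted as "n-fold"
round half-up to integers from 2-fold upward (`bmd_fold_ratio()`).

Transcriptomic PoDs aggregate gene-level benchmark doses (BMDs, upstream
inputs — curve fitting is out of scope) into pathway medians over genes
passing the upstream filters; a pathway needs at least 3 (conservative) or 5
(higher-confidence) passing genes, and the lowest pathway median summarizes
a chemical/cell-line combination. Ties on the minimum break
lexicographically by pathway id and are flagged.

# Exposure arithmetic and BER

The dermal applied dose is `daily product amount × ingredient fraction /
treated area`, with the treated area defaulting to the SCCS Notes of
Guidance whole-body figure of 15,670 cm² (`SCCS_BODY_SURFACE_CM2`) — the
value that makes 0.1% of 7.82 g/day come out at 0.5 µg/cm². The
product-amount-per-body-weight figure used for systemic exposure doses
(123.2 mg/kg bw/day for a 60 kg consumer) is a distribution-based guidance
value carried as an independent input, never recomputed as 7.82/60.
`compute_ber()` is the internal-exposure analogue of a margin of exposure:
PoD(internal)/exposure metric, with BER > 1 read as an acceptable margin and
anything near or below 1 flagging the assessment for refinement.
`margin_of_safety()` provides the traditional external-dose MoS for
comparison.

# Calibrated configurations

Three YAML configurations ship with the package as **regression anchors**,
fitted once to the case study's printed values and frozen. They make the
pipeline runnable end-to-end and pin its behaviour; they are *not* claims of
equivalence to the original study's model, whose compartment structure and
parameter values are not reproducible from the published summary.

* `genistein-rat-oral` — clearance fitted so the population-mean Cmax,total
  at 0.3 mg/kg/day × 7 days is 24.1 nM; `fu = 0.0199` (back-calculated from
  the printed Cmax,fu/Cmax,total pair 0.48/24.1).
* `daidzein-rat-oral` — hepatic clearance read across from the source
  config; the absorbed oral fraction fitted so reverse dosimetry of the
  33 nM NOEC returns 4.1 mg/kg/day. Under a dose-linear model this anchor is
  mutually exclusive with the separately printed forward value (45.17 nM at
  0.3 mg/kg/day); the risk-assessment-relevant reverse-dosimetry anchor was
  chosen and the forward value is deliberately not reproduced.
* `daidzein-human-dermal` — `f_abs_dermal = 0.25` (measured dermal
  absorption), `fu = 0.0504` (from the printed 0.3/5.95 pair), cutaneous
  metabolism rate fitted to the 3-fold first-pass effect and clearance to a
  population-mean Cmax,total of 5.95 nM at 0.5 µg/cm² over 15,670 cm².

# The synthetic-data generator

`synthetic_spec()` fixes the study conditions for everything the pipeline
consumes that is not a packaged fixture:

* **Chemical pairs** — a source panel drawn around baseline potencies
  modelled on the packaged source panel, and a target panel whose LOECs are
  `potency_ratio` (default 15, an order of magnitude as in the case study)
  times the source values times independent lognormal noise
  (`assay_noise_cv`, default 0.3). All noise is lognormal because
  concentrations are positive and errors multiplicative. Each assay appears
  once in the synthetic panel: collapsing a *noised* ±S9 duplicate by
  minimum would bias the recovered potency ratio downward by a few percent —
  a min-of-two-lognormals artifact, not a pipeline property — so the
  S9-collapse rule is exercised on the fixture panels instead, and the
  synthetic recovery test remains an unbiased estimator of the configured
  ratio.
* **Gene BMD tables** — 20 pathways × 10 genes by default; one designated
  pathway is rescaled so its passing-gene median equals
  `lowest_pathway_median` exactly, all other pathway medians are drawn at
  least 2-fold higher (guarded at generation time), and genes pass the
  upstream filters with probability 0.8 outside the designated pathway.
* **Biokinetics time courses** — medium concentrations near nominal with
  mild loss and 5% measurement noise, lysate amounts accumulating to a
  plateau chosen for >1000-fold concentrative uptake, and stable no-cell
  controls (the cell count and volume defaults, 51,000 cells and 2 pL,
  are documented placeholders at 48-well scale).

What the generator does **not** emulate — correlated errors across assays,
non-lognormal outliers, saturable kinetics, or real pathway co-membership
structure — bounds what passing tests show: they demonstrate that the
pipeline recovers the parameters the generator encodes under its noise
model, not that it is robust to real-data pathologies outside that model.

# Numerical choices and problem sizes

* `lsoda` with analytic constant Jacobian; output grids of 0.5 h (history)
  and 0.05 h (final dosing interval, from which Cmax is read); dose events
  applied exactly at dose times. The reported value at t = 0 precedes the
  first dose event.
* Reverse-dosimetry bisection in log-dose, relative tolerance 1e-3, bracket
  expansion capped at 10³.
* Monte Carlo sizes: 1000 individuals in the shipped variability specs
  (also used per reverse-dosimetry step when inverting to a population
  percentile; the interactive workflow default is 200 for responsiveness),
  200 replicate pairs in the end-to-end recovery analysis, and 1500–4000
  individuals in the one-off calibration runs. The
  test suite uses 20–1000 individuals depending on what the property needs;
  these sizes were chosen so each check is comfortably resolved at its
  tolerance.
* Ties: equal LOECs resolve by endpoint-class priority then assay id; equal
  pathway medians resolve lexicographically and are flagged.

# Known limitations

Perfusion-limited tissues only (no permeability-limited compartments or
transporters); metabolites are treated as eliminated mass; no enterohepatic
recirculation or mechanistic gut segmentation; the population CIs are
approximate reconstructions with a single aggregate variability knob; the
shipped configurations are regression anchors, so agreement with the
anchored values is calibration, not independent validation — the model's
evidential weight rests on the property suite (mass balance, dose linearity,
analytic limits, forward/reverse consistency, seed reproducibility).
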