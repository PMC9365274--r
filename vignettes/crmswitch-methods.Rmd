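---
title: "Modeling concentration-dependent switching at the CLV3 cis-regulatory module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling concentration-dependent switching at the CLV3 cis-regulatory module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmswitch)
```

## The biological problem

WUSCHEL (WUS) is a homeodomain transcription factor that forms a
concentration gradient across the cell layers of the *Arabidopsis* shoot
apical meristem: low in the outer central zone (L1–L3), high in the inner
rib meristem. Its target *CLAVATA3* (*CLV3*) responds to this gradient
with a switch rather than a monotone dose-response — WUS activates *CLV3*
at low concentration and represses it at high concentration. The switch
is implemented by a homotypic cis-regulatory module (CRM): five TAAT-core
cis-elements (named 950, 970, 997, 1007, 1060 after their promoter
coordinates) that each bind WUS first as a monomer (activating: the
monomer recruits RNA polymerase II) and then, at higher WUS, as a dimer
(repressing: the dimer cannot recruit Pol II).

`crmswitch` implements a stochastic single-cell model of this CRM, an
exact chemical-master-equation (CME) oracle for validating it, a grammar
of promoter genotypes, a 3D half-dome tissue model, calibration routines,
synthetic-data generators, and a TAAT-core cluster scanner.

## The single-cell model

Each cis-element `i` is in one of three occupancy states — empty, monomer
bound, dimer bound — with Markovian transitions:

* monomer binding at propensity `kon_M * [WUS]` (empty, functional
  elements only);
* monomer unbinding at `koff_M = Kd_M(i) * kon_M`, so the stationary
  bound/unbound ratio is `[WUS]/Kd_M(i)`;
* dimer formation by recruitment of a second WUS molecule at
  `kon_D * [WUS]`;
* dimer dissociation at `koff_D = Kd_D(i) * kon_D`.

`[WUS]` is constant during a simulation: the model deliberately excludes
the CLV3→WUS feedback loop, and binding at one locus does not deplete the
nuclear pool.

Two non-Markovian constraints act on transcription:

* **Pol II refractory gap.** Successive initiations are at least
  `pol_gap = 4` s apart — the time an 80-bp polymerase footprint needs to
  clear the start site at a 1.2 kb/min elongation rate
  (80 bp × 60 s / 1200 bp = 4 s). Between initiations Pol II is recruited
  at `k_pol` per transcriptionally *active* monomer per second; each
  recruitment counts one mRNA (no decay term is modelled).
* **Residence-time limit.** A bound monomer stays transcriptionally
  active only for its first `tau_res` seconds of occupancy (default 10 s
  for single-element promoters); beyond that age it remains bound but can
  no longer recruit Pol II, and the site stays blocked until the stale
  molecule dissociates. The biological reading is progressive
  modification and turnover of actively transcribing factors. A
  count-based alternative (deactivate after *k* recruitments) is
  available behind `residence_mode = "count"`.

The engine is an exact Gillespie direct-method simulation (implemented in
C++ for speed) with the two deterministic clocks — monomer deactivation
at age `tau_res`, refractory expiry at `pol_ready_at` — interleaved by
advancing to whichever event comes first and redrawing the exponential
waiting time, which is exact for the Markovian channels by memorylessness.

### Cooperativity

Cooperativity among cis-elements acts on *off*-rates as multiplicative
stabilisation: the off-rate of the species bound at element `i` is
multiplied by `c^w(d_ij)` for every qualifying occupied neighbour `j`.
The factor `c` lies in (0, 1]; smaller is stronger (ten times the
cooperativity of `c = 0.01` is `c = 0.001`). The two channels are
independent because they drive opposite outcomes:

* **monomer cooperativity** (`c_monomer`, default 0.01) stabilises a
  bound monomer for every occupied neighbour (monomer or dimer) — the
  activation channel;
* **dimer cooperativity** (`c_dimer`, default 0.2) stabilises a bound
  dimer for dimer-occupied neighbours only — the repression channel.

Both neighbour rules are configurable. The distance kernel is
`w(d) = min(1, d_ref / d)`: full strength up to the reference gap
(`d_ref`, resolved once from the smallest inter-element gap of the
geometry the config is built with — 10 bp for the wild-type CRM) and
inverse decay beyond it. This is the simplest parameter-free kernel that
is maximal for nearest neighbours and vanishing at long range; it is
exposed as a pluggable setting (`mode = "none"`, `"equal"`, or
`"distance"`). We chose off-rate (not on-rate) modification because it
preserves the linear-in-`[WUS]` binding law; an optional on-rate
multiplier (`on_rate_boost`) exists for exploring binding-side
cooperativity but defaults to off.

## Parameters, defaults, and how they were chosen

Dissociation constants are in arbitrary WUS-concentration units anchored
to measured affinity *ratios*: `Kd(970) = 1` (the tightest wild-type
element), `Kd(970M4) = 1/3` (the affinity-raising mutant binds three-fold
tighter), `Kd(1060) = 21.4 × Kd(970M4) ≈ 7.13` (the measured
highest/lowest intrinsic affinity ratio), and `Kd = 3` for the three
intermediate elements, for which no printed ratio exists. Dimer constants
default to the monomer constants per element. All are configurable per
element.

The free kinetic parameters were calibrated once, analytically and with
pilot simulations of the intrinsic (single-element) regime, and then
frozen:

* `kon_M = kon_D = 0.15` per concentration-unit per second. This places
  monomer dwell times on either side of the 10-s residence limit across
  the affinity series (`1/(0.15 × 1/3) = 20 s` for the tightest element,
  `≈ 0.9 s` for the weakest), which is the regime in which the limit
  equalises intrinsic elements of very different affinity: much larger
  `kon_M` makes even the weakest element's tenure shorter than 1 s and
  the limit inert; much smaller `kon_M` lets the age-inheritance blockade
  (a stale monomer cycling through dimer states without clearing)
  suppress the high-affinity element far below the low-affinity one.
* `k_pol = 0.1` per active monomer per second — deliberately below the
  refractory ceiling `1/pol_gap`, so mRNA output is approximately
  proportional to time-averaged active-monomer occupancy.

Because the *stationary* occupancy law depends on rates only through the
dissociation constants, these kinetic choices do not affect any
equilibrium property of the multi-element (no-residence-limit) analyses.

The default WUS gradient is a geometric ladder `w_k = w1 · 2^(k−1)` with
a plateau from L5 (deep-layer fold changes are not constrained by data).
The two-fold step reflects that dimerisation is promoted over a small
two- to four-fold concentration increase, so neighbouring layers must sit
within that scale of each other. `w1 = 0.25` was calibrated once against
the wild-type cooperative dose-response, whose interior maximum sits near
`W ≈ 0.3` under the defaults: L1 then lies on the rising limb just below
the peak while L2 (0.5) and deeper layers are past it, reproducing the
outer-layer maximum of wild-type *CLV3*.

## Genotype grammar

`build_variant()` constructs every analysed promoter variant from three
mutation kinds: *loss* (sets `functional = FALSE`; the element keeps its
coordinates but contributes no propensities), *affinity* (divides both
dissociation constants; `970M4` = 3-fold), and *spacing* (`DS-997`
doubles the two gaps flanking element 997, shifting downstream
coordinates consistently and touching no Kd). Intrinsic variants
(`950i` … `1060i`, `970M4i`) retain a single functional element; they
default to the no-cooperativity, 10-s-residence-limit regime, while
multi-element variants default to distance-dependent cooperativity with
the limit disabled — the two regimes the single-cell analyses use.
Spacing mutations keep the cooperativity kernel's reference gap resolved
from the pre-mutation geometry, so increasing the spacing weakens
cooperativity instead of silently recalibrating the kernel.

## The CME oracle and the fine-grid oracle

For up to 8 functional elements the binding subsystem's `3^N` occupancy
configurations are enumerated exactly; `build_generator()` transcribes
`propensity_table()` into a rate matrix and `stationary_distribution()`
solves `piQ = 0` by a dense linear solve with the normalisation replacing
one balance row (residual under 1e-10). States that can never be entered
(e.g. dimer states when `kon_D = 0`) are removed iteratively before the
solve; genuinely reducible chains are reported, not silently normalised.
State encoding is a base-3 integer in promoter order, which makes the
`mode = "none"` Kronecker-sum structure directly testable.

The CME cannot carry molecule age, so the residence limit and refractory
gap are validated against a second, independent oracle: a fixed-step
Bernoulli-event simulation (`fine_grid_oracle()`, pure R) that requires
`dt ≤ 0.01 / max total propensity` and converges to the SSA's statistics
as `dt → 0`. The stochastic engine is C++; both oracles are R, so
engine/oracle agreement cross-validates the two code paths as well as the
mathematics.

## The 3D tissue model

`build_dome()` arranges unit-sphere cells on concentric hemispherical
shells, L1 outermost; per-shell cell counts scale with shell area via a
deterministic Fibonacci lattice (the full dome holds ≈ 560 cells; the
reduced dome used in tests, `cells_l1 = 36`, holds 103). Only layer
membership matters for dosing: `assign_gradient()` gives every cell its
layer's constant WUS concentration, and `simulate_tissue()` runs the
single-cell model independently in each cell. Sub-seeds are derived from
`(seed, cell_id)` by a counter-based hash, so per-cell results are
reproducible and independent of simulation order. Layer summaries (mean
and SD of mRNA, mean monomer/dimer occupancy over functional elements)
are recomputed from the per-cell table and exposed via
`layer_summary()`, `occupancy_maps()`, `tidy()`, and `autoplot()`.

## Calibration

`fit_binding_rates()` fits Kd scale factors to EMSA-style bound-fraction
tables by least squares weighted with per-row trial counts (the
binomial-variance weighting), using a deterministic 3-start bounded
optimisation. A structural identifiability fact is surfaced rather than
papered over: stationary fractions depend on the rates only through Kd,
so equilibrium tables leave the absolute `kon` along a flat direction —
the fit warns and reports the template `kon` unchanged unless the table
contains pre-equilibrium (kinetic) information. `fit_concentration_scale()`
aligns a per-layer expression profile to a simulated dose-response curve
over a single scale factor, profiling out the arbitrary fluorescence
amplitude analytically; a flat curve triggers a non-identifiability
warning.

## Synthetic data

The generators provide every input with known ground truth:
`synth_emsa_table()` draws multinomial bound-state counts from the exact
stationary law; `synth_layer_profile()` perturbs simulated layer means
with multiplicative log-normal noise (positive, heteroscedastic — the
natural model for reporter intensities, for which no empirical noise
model is available) across a configurable number of pseudo-transformants
(default 4); `synth_gradient()` is the gradient factory above. All carry
their generating parameters as metadata, enabling the closed-loop
recovery tests in the calibration module. What passing recovery tests
show is that the *pipeline* is consistent; they cannot show that real
gels or micrographs follow these noise models.

## Motif scanner

`find_cores()` reports TAAT occurrences on both strands at forward,
0-based half-open coordinates (a `-` hit is an `ATTA` in forward text);
`find_clusters()` groups hits whose consecutive starts are at most
`window_bp` apart and keeps maximal groups of at least `min_cores` hits.
The defaults (`min_cores = 3`, `window_bp = 60`) are set so that the CLV3
CRM's own arrangement — five cores with gaps 20, 27, 10 and 53 bp — is
detected as a single cluster; they are flags, not constants, because the
reference clustering procedure is not published in detail. The scanner is
therefore a documented, parameterised stand-in, and no attempt is made to
reproduce genome-wide target-gene counts, which depend on external
annotation.

## Numerical choices

* Burn-in: `dose_response()`, `simulate_tissue()` and the synthetic
  profile generator discard the first 20% of each run before
  accumulating statistics (configurable). Raw `simulate_cell()`
  trajectories keep the transient by design; comparisons against
  stationary laws must therefore use the burnt-in interfaces.
* Seeds: every entry point takes an integer seed; replicate, dose and
  cell sub-seeds come from a counter-based hash of labels, keeping
  streams order-independent and below 2^31.
* Dimer dissociation: the surviving monomer inherits the original
  arrival time (oldest-molecule-stays), configurable to reset; with
  inheritance, age accrues through dimer interludes, which produces the
  site-blockade behaviour discussed under calibration.
* Ties and degenerate inputs: zero total propensity fast-forwards to the
  end time; dose 0 yields exactly zero binding; non-functional elements
  contribute no channels anywhere, including the oracle.
* Problem sizes in the shipped tests: dose-responses use 1500–2500
  simulated seconds with 16–200 replicates per dose; tissue runs use the
  103-cell reduced dome at 1200–1500 s. These sizes give Monte-Carlo
  standard errors comfortably inside the 3-SE bands the tests assert.

## Known limitations

* Absolute parameter values (Kd table, kon, simulated spans) are not
  published; defaults respect all printed ratios and are configurable,
  but quantitative outputs are in arbitrary units.
* With the pinned affinity anchors, element 970 (Kd = 1) sits inside the
  default tissue dose range, so the `970i` intrinsic variant retains
  substantial outer-layer expression — its experimentally observed
  confinement to inner layers is not reproduced, and the intermediate
  (Kd = 3) intrinsics are marginal on the same property. Because
  stationary occupancy depends only on `W/Kd`, no kinetic setting can
  change this; it would require larger absolute Kd values relative to
  the gradient than the printed ratios pin down.
* `DS-997` reproduces deep-layer derepression (weaker distance-dependent
  dimer cooperativity) but not the observed outer-layer increase, which
  biochemistry attributes to increased monomer binding at larger spacing
  — an affinity change this model intentionally does not apply.
* The model omits CLV3→WUS feedback, WUS diffusion and nuclear
  transport, mRNA decay, cell growth and division, and sequence-level
  binding-energy prediction.

## A worked example

```{r example, eval = FALSE}
wt <- build_variant("WT")
dr <- dose_response(wt, doses = c(0.05, 0.125, 0.25, 0.5, 1, 2, 4),
                    t_end = 1500, replicates = 60, seed = 1)
tidy(dr)
autoplot(dr)

tissue <- assign_gradient(build_dome(7, cells_l1 = 36), synth_gradient())
res <- simulate_tissue(tissue, wt, t_end = 1500, seed = 1)
layer_summary(res)
plot_occupancy_maps(res)
```
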