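---
title: "Multi-ensemble Markov models of ion translocation: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ensemble Markov models of ion translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memmkin)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the places where
the design was genuinely open and a choice had to be made. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not verify.

## The problem

A monovalent cation travels through the transmembrane bundle of a receptor:
from the extracellular bulk, into an allosteric binding well near the
middle of the bundle, and (rarely) onward across a high barrier into the
cytosol. Binding stabilizes one receptor conformation over the other, which
in turn modulates agonist binding at the orthosteric site. Three coupled
estimation problems follow:

1. the free-energy profile G(z) of the ion along the pore axis,
2. binding/dissociation/egress kinetics at physiological concentrations,
3. the allosteric shift of agonist binding as a function of ion
   concentration.

None of these is accessible from one simulation type. Umbrella-sampling
windows resolve G(z) everywhere but perturb the kinetics; unbiased runs
carry kinetics but never cross the egress barrier. A multi-ensemble Markov
model (MEMM), estimated by discrete TRAM, combines both.

## The synthetic system

Because no desk-scale computation can reproduce microsecond atomistic
simulations, the package ships a generator whose ground truth is known in
closed form. The energy surface is a sum of two-dimensional Gaussians over
the translocation coordinate z (Å, domain [−35, 40]) and a dimensionless
conformational coordinate c, plus harmonic confinement of c:

U(z,c) = Σ_g A_g exp(−(z−z_g)²/2σ_{z,g}² − (c−c_g)²/2σ_{c,g}²) + ½κ c².

Gradients are analytic, so the same object drives the Euler–Maruyama
integrator and the quadrature/linear-solve oracles
(`ground_truth_profile()`, `oracle_mfpt()`). The `"receptor"` preset has:

* flat bulk plateaus on both sides,
* a bound well centered at z = 0 whose depth couples to c (the well exists
  in the c ≈ +1 conformational channel; the c ≈ ±1 bistability is the
  slow mode tICA must find),
* a +4 kcal/mol egress barrier at z = −12 and a smaller barrier at z = 18,
* shallow vestibule wells at z = 35 and z = −31.5, which give the
  extracellular and cytoplasmic regions genuine metastability — without
  them no spectral method can identify an "extracellular state", because
  free diffusion in a flat bulk is not metastable.

Defaults: k_BT = 0.616 kcal/mol (310 K), D_z = 50 Å²/ns, D_c = 2 /ns,
integration step 2×10⁻⁴ ns with frames every 0.002 ns. The step obeys the
stability criterion drift-per-step = D|∇U|dt/k_BT < 0.5 Å, enforced at
simulation time; the harmonic-window variance test in the suite documents
the O(dt) variance inflation of Euler–Maruyama and uses a smaller dt where
that matters.

The bound-well depth is not a free parameter in the study configurations:
`calibrate_bound_well()` adjusts it so the analytic binding isotherm has a
requested dissociation constant (23 mM for the inactive-like variant,
850 mM for the active-like one), under the same grand-canonical convention
the allosteric model uses. The "neutral" (protonated) variant raises the
bound well by 3 kcal/mol.

What the generator deliberately does *not* emulate: three-dimensional ion
coordinates, competing ions, explicit solvent friction memory, or
force-field error. Passing tests on this system demonstrates estimator
correctness — not that any particular biological receptor behaves this way.

## Umbrella design at desk scale

The classical design — stiff springs (10 kcal/mol/Å²) every 0.5 Å — costs
~150 windows. At desk scale we keep the same *overlap ratio* (window width
≈ 1–2× spacing) with fewer windows: soft springs (0.3–0.5 kcal/mol/Å²) on
a 1–2 Å ladder. `umbrella_ladder()` keeps the classical defaults; the
pipeline configuration carries the desk ladder.

Two non-obvious failure modes shaped this design, and both are worth
knowing about when analyzing real data:

* **Window overlap is not optional.** With stiff springs on a sparse
  ladder the window histograms do not overlap, the multi-ensemble problem
  decomposes into disconnected fragments, and the stitched profile is
  anchored arbitrarily per fragment. `wham_weights()` detects this and
  fails loudly naming the disconnected bins.
* **Soft springs slide off steep slopes.** A window with k = 0.5 on a
  1.5 kcal/mol/Å slope is displaced ~3 Å from its nominal center, so soft
  ladders leave barrier tops unsampled and no unbiased continuation ever
  starts there. The pipeline therefore adds stiff auxiliary "pin" windows
  (k = 4, 1 Å spacing) across the egress barrier; every pin gets an
  unbiased continuation so the barrier region joins the kinetic state set.

Each window discards a 1 ns burn-in before production (the conformational
coordinate starts on its saddle and must commit to a basin first), and
unbiased continuations start from the final window states — one per third
window but three times longer, rather than one short run per window.
Short unbiased runs started everywhere carry a strong initial-placement
signature; since TRAM's reversible likelihood ties transition counts to
the stationary law, that signature leaks into the thermodynamics. Fewer,
longer runs sample closer to their local equilibrium at the same total
cost. Per-trajectory seeds are spread by a multiplicative counter hash —
consecutive integer seeding of a Mersenne-Twister produces visibly
correlated streams across windows, which we diagnosed as a systematic
distortion of the stitched profile against a binless reference estimator.

## Discretization and the state-level bias

Microstates are (z-bin, conformational cluster) pairs: 100 equal z bins
across the umbrella range crossed with N k-means clusters in the space of
the two dominant tICA components (`microstate_id()` is the bijection
`id = (z_bin−1)·N + (cluster−1)`). tICA uses a 0.1 ns lag, symmetrized
time-lagged covariances, a 10⁻¹⁰ ridge, and pooled (biased + unbiased)
frames with joint mean removal; components are sign-fixed by their largest
loading and whitened to unit variance.

Discrete TRAM needs one bias energy per (ensemble, microstate). With a
0.75 Å bin and any realistic spring the continuous bias varies by several
k_BT *within* a bin, so evaluating it at the bin center misweights window
tails catastrophically. The package uses the within-bin Boltzmann average
b_i = −ln⟨e^{−b(z)}⟩ and, by default, a second pass that recomputes the
average weighting the bin interior by the first pass's interpolated
profile (`estimate_tram(refine_bias = TRUE)`). On the calibrated test
landscapes this second pass removes a ~20% systematic in the recovered
dissociation constant.

## The TRAM estimator

For ensembles k with bias factors γ_i^(k) = e^{−b_i^(k)} and unknown
unbiased weights w, the reversible transition matrix of ensemble k with
stationary vector π^(k) ∝ γ^(k) w has the closed form

T_ij^(k) = (c_ij + c_ji) γ_j w_j / (ν_i γ_j w_j + ν_j γ_i w_i),

with Lagrange multipliers ν enforcing row normalization. The solver
alternates the ν self-map with the multiplicative w update from the
likelihood gradient, in C++, until the log-likelihood increment falls
below 10⁻¹⁰ (cap 50,000 sweeps). Properties verified by the suite:

* with a single unbiased ensemble the fixed point coincides with the
  classic reversible MSM maximum-likelihood estimator to < 10⁻⁸
  element-wise (the oracle is an independent symmetric-flux iteration);
* the log-likelihood is non-decreasing once the iteration reaches the
  feasible set (the first few sweeps move an infeasible initialization);
* WHAM and TRAM stationary distributions agree within counting noise on
  equilibrium-sampled data.

The estimate is restricted to the largest microstate set connected by
transitions in any ensemble (π = 0, Ḡ = +∞ outside). The returned
transition matrix is additionally restricted to the largest
unbiased-connected component and flux-symmetrized, so detailed balance
holds exactly against its own stationary vector; states seen only under
bias keep their thermodynamic weight but carry no kinetics. Counting uses
a sliding window at the lag (default 200 frames = 0.4 ns, chosen where the
implied timescales plateau; `implied_timescales_ladder()` reproduces that
diagnostic).

Bootstrap errors follow the resample-unbiased-trajectories scheme: whole
trajectories with replacement up to 90% of the unbiased frame count, the
umbrella set unchanged, microstate definitions reused from the full sample
(re-clustering would change state identity); summaries are medians with
1st/3rd-quartile errors over the replicas plus the full estimate.

## Coarse kinetics, constant pH, and bulk coupling

PCCA+ memberships come from the inner-simplex construction on the dominant
right eigenvectors; the coarse chain is the Hummer–Szabo projection
T̂ = I + 1π̂ᵀ − Ẑ⁻¹ with Ẑ = D̂⁻¹χᵀΠ(I − T + 1πᵀ)⁻¹χ, which preserves
stationary weights exactly and is exact for lumpable chains. Macrostates
are labeled cytoplasmic/bound/extracellular when ≥ 90% of their
(π-weighted) microstates fall in the z-bin ranges 1–10, 30–60, 90–100;
others remain explicit unassigned intermediates. On desk-scale chains
PCCA+ occasionally produces near-zero-weight single-microstate vertices;
they are harmless (unassigned) but motivate the default of 8 macrostates.
When the 90% rule labels no state of a group, bulk coupling falls back to
the macrostate carrying the most weight in that group's z-range.

The constant-pH model combines the charged (α) and neutral (β) variants on
their shared microstates. Energies are put on a common scale by anchoring
each variant's extracellular-bulk weight (protonation is ion-independent
there) and shifting the charged variant by ΔG0 = k_BT ln10 (pKa − pH); at
pKa 9, pH 7 and 310 K the formula gives 2.84 kcal/mol. Deprotonation runs
at the constant rate k_off (default 10⁶ s⁻¹); reprotonation at
k_off e^{ΔG(z,i)/k_BT} with ΔG = ε_α − ε_β. Defining ΔG as this energy
difference (rather than through the charged-fraction identity, which the
two-level formula only approximates in the fully-charged limit) makes the
product-space chain satisfy detailed balance against Boltzmann(ε) exactly
— an invariant the suite checks to 10⁻⁸ — and the marginal charged
probability per z equals the two-level formula exactly.

Bulk coupling follows the stepwise scheme: an extracellular bulk state
feeds the extracellular (encounter) states at the Smoluchowski rate
k⁺ = 4πD r [Na⁺] (D = 20 nm²/μs, r = 1.5 nm; 34.05 μs⁻¹ at 150 mM), the
encounter-escape rate is fixed by the capture probability γ (the
flux-ratio convention γ = Σk_ij/(k⁻ + Σk_ij) is the default; the inverted
printed convention is available via `gamma_form = "printed"`), and an
absorbing intracellular bulk receives the cytoplasmic flux — no binding
from the intracellular side. γ can be counted directly from unbiased
trajectories (`estimate_gamma()`). Three conventions are deliberate:

* **Dissociation** is the MFPT bound → EC bulk with the intracellular leak
  cut (otherwise the rare egress pathway makes the expectation infinite).
* **Egress** is the MFPT bound → IC bulk with the EC-bulk detour cut;
  leaving the detour in makes egress inherit the 1/[Na⁺] rebinding wait,
  contradicting its concentration independence in this kinetic scheme.
* **Occupancy** is the equilibrium bound fraction of the reversible
  extracellular subnetwork. For the explicit bulk ⇌ encounter ⇌ bound toy
  the 50% crossing is algebraic,
  c₅₀ = (1−γ) k_b k_f / (γ k⁺ (k_f − k_b)), and the suite verifies the
  computed affinity against it exactly. Note this kinetic-chain affinity
  is a different convention from the thermodynamic (grand-canonical)
  affinity c_ref·U/B that the landscape calibration targets; both are
  reported by the acceptance script.

## The allosteric prediction

The two-state receptor model needs only the ratio of partition functions
of the inactive and active systems as a function of sodium. Ion-bound
states are weighted grand-canonically by c/c_ref (c_ref = 150 mM, the
simulated concentration); this convention reproduces two-state binding
isotherms exactly on toys and makes ρ(0) = 1 by construction. The bound
set is taken from the bound-labeled macrostates, with microstates outside
the kinetic set assigned by z-range so that purely-thermodynamic weight is
not lost. The percent change of agonist binding at reduced ligand
concentration x = [L]/L50(0) is (1−ρ)/(x+ρ); with 1 nM ligand and a 4 nM
active-state affinity, x = 0.25. The half-reduction concentration is found
by bisection on log-concentration (0.1 mM tolerance) on the log-linearly
interpolated ρ curve; the receptor activation free energy μ never enters
(it cancels in ρ) and is not a model parameter.

## Problem sizes and what the checks show

The default pipeline configuration runs, per system, 75 soft windows of
48 ns plus 11 pins, with 25 unbiased continuations of 36 ns — about 5 μs
of aggregate dynamics per system, a few minutes on one CPU. At these sizes
the recovered two-well profile matches the analytic reference within
0.1–0.2 kcal/mol RMS over well-sampled bins, recovered dissociation
constants land within ~10–20% of their calibrated values, and the
end-to-end half-reduction concentration lands within ~5–20% of the
closed-form value of the calibrated landscape pair. The residual error is
dominated by window-alignment noise in the deep bound well, which
propagates multiplicatively into affinities — a structural feature of all
histogram-reweighting estimators, not a bug the suite could remove by
running longer within desk budgets.

Known limitations: the generator is one-dimensional in z (the flat-bottom
transverse restraint is inert metadata); the per-ensemble transition
matrices assume Markovian dynamics at the lag on the binned space; the
unbiased ensemble's non-equilibrium start leaves a small thermodynamic
pull that shrinks, but does not vanish, with longer continuations; and
PCCA+ vertex selection is a heuristic whose degenerate-spectrum behaviour
is tie-broken by index and reported.
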