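---
title: "Stochastic thin-filament activation: model, protocols, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic thin-filament activation: model, protocols, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`thinfil` simulates calcium regulation of the cardiac thin filament as a
chain of 26 regulatory units (RUs) coupled in series. Each RU is a
24-state continuous-time Markov chain over the product of four components:

* `ca` — Ca²⁺ bound to the troponin C regulatory site (0/1),
* `sp` — the troponin I switch peptide docked on the TnC N-lobe (0/1),
* `ip` — the troponin I inhibitory peptide bound to actin (0/1),
* `tpm` — the azimuthal position of tropomyosin: blocked **B**,
  closed **C**, or open/myosin-bound **M** (position index
  x(B)=0, x(C)=1, x(M)=2).

Force is the fraction of units in the M state — myosin crossbridge
mechanics are not modeled explicitly; M-state occupancy is the force (and,
for motility comparisons, the sliding-velocity) proxy.

Only one component may change per transition, and tropomyosin steps only
between adjacent positions (B↔C, C↔M). The troponin rates form
thermodynamically closed squares: `eta` couples Ca²⁺ binding to
switch-peptide docking (docking is `eta`-fold faster with Ca²⁺ bound,
Ca²⁺ release `eta`-fold slower with the peptide docked), and `mu` makes
the switch and inhibitory peptides mutually exclusive. Every troponin
4-cycle therefore satisfies detailed balance by construction — this is
asserted numerically in the test suite at machine precision.

Tropomyosin dynamics follow:

* **B→C**: `kref_BC · K_BC^delta · Γ_BC`, **C→B**:
  `kref_BC · K_BC^(delta−1) · Γ_CB`, where
  `Γ = exp(−(γ/RT)·Δ)` and `Δ` is the change in summed azimuthal distance
  between the unit's tropomyosin and its present neighbors'. The B/C rate
  ratio is `K_BC` exactly whenever the coupling terms cancel.
* **C→M**: `kMD_plus + f_XY · nM`, with `nM` the number of neighbors
  already in M — crossbridge-mediated cooperative attachment.
* **M→C**: `kMD_minus · exp(−(γ/RT)·nM)` — through the end-to-end overlap,
  an open stretch of tropomyosin holds itself open; `γ` (J/mol, divided by
  RT = 2494 J/mol) is the holding energy.
* **Troponin gate**: both forward shifts (B→C and C→M) run at full rate
  only while the RU is *switched and released* (`sp = 1`, `ip = 0`) and
  carry the attenuation `lam` otherwise.

Chain ends have a single neighbor (missing neighbors contribute nothing);
a periodic option exists for sensitivity checks.

### Why this rate law

The published description of the underlying model names the parameters but
not the complete transition graph, so the law above is this package's
reconstruction, chosen and then frozen against the qualitative behavior
the source system is known to exhibit. Three choices were genuinely open
and deserve a record:

1. **The troponin gate.** Gating tropomyosin only by the inhibitory
   peptide (`ip`) leaves a large resting leak: with the packaged rate
   constants the inhibitory peptide is unbound roughly a quarter to a
   third of the time even at diastolic Ca²⁺, and during those windows the
   B→C→M pathway runs at full speed. The chain then rests at 0.4–0.75 of
   maximal force and no force–pCa sigmoid exists. Requiring the
   switched-and-released state (`sp = 1 ∧ ip = 0`) makes the open-gate
   duty cycle strongly Ca²⁺-dependent (≈6% diastolic → ≈50% at 1 μM) and
   yields a clean sigmoid (Set 1: floor ≈0.035, F_max ≈0.89,
   pCa₅₀ ≈6.10, n_H ≈2.0).
2. **Where the chain-stiffness energy acts.** With `γ` on B↔C only, the
   mutation signatures come out wrong (halving `γ` *raises* maximal
   force). Splitting the coupling between B↔C (cooperative inhibition)
   and an M-state holding term (cooperative activation) reproduces all
   the reported directionalities simultaneously: halving `γ` lowers
   F_max (≈−23%) and n_H (≈−50%) with only a small rightward pCa₅₀ shift
   (≈−0.2), scaling `K_BC` by 0.74 shifts pCa₅₀ rightward (≈−0.13) with
   F_max essentially unchanged, and the combination lowers all three.
3. **γ units.** The parameter tables print `γ` in an energy-like unit; it
   is divided by RT = 2494 J/mol (≈300 K) to give the dimensionless
   exponent (Set 1: γ/RT ≈ 1.43, i.e. ≈4.2-fold retardation per
   myosin-bound neighbor). The `rt` field of `param_set()` exposes the
   conversion.

### Known limitations

The reconstruction is *not* guaranteed identical to the unpublished
original, and one family of its predictions is known to differ: with the
packaged kinetic parameter set (`set2`), the 0.1→1 μM twitch rides the
shallow foot of the reconstructed force–pCa relation, so (a) peak twitch
force falls only a few percent across the 0–100% mutant-expression sweep
rather than tens of percent, and (b) RT50 *rises* monotonically with
expression (loss of cooperative inhibition dominates at low activation)
instead of falling first and rising only above ~50% expression. The
falling phase requires cooperative activation (the holding term) to
dominate at low expression, which needs substantially higher M-state
occupancy at the twitch peak than the reconstruction produces at 1 μM.
Consequently, inferring the mutant-expression level from the measured
tissue twitch changes does not land in the 30–40% window here; the
corresponding acceptance checks are left failing by design rather than
weakened, and the expression-inference machinery itself is validated by
round-trip tests on synthetic sweeps. Calcium-handling feedback (mutation
effects on the Ca²⁺ transient itself) is deliberately out of scope: the
transient is a fixed input.

## Simulation engine and its oracle

Trajectories are generated by an exact event-driven (Gillespie) algorithm
written in C++: no time-step discretization error. Calcium waveforms are
discretized to piecewise-constant segments (default 1 ms); within a
segment all rates are constant, so advancing to a segment boundary and
redrawing the exponential waiting time is exact by memorylessness. Each
trajectory draws from its own counter-derived random stream
(splitmix64-seeded xoshiro256++), so ensembles are bit-reproducible for a
given master seed and independent of scheduling.

The independent oracle is `master_equation_force()`: for chains of up to
3 units the full joint generator (24ⁿ states) is built from the *R-level*
rate law and solved directly for its stationary distribution. The test
suite requires the stochastic steady state to agree with this exact
solution within 3 Monte-Carlo standard errors for 1- and 2-unit chains
across a grid of calcium levels — the two implementations share only the
written rate law, not code.

Every unit starts in the resting state (no Ca²⁺, switch off, inhibitory
peptide on, tropomyosin blocked); a burn-in at the initial calcium level
precedes all recording.

## Protocols

**Steady state.** `run_pca_sweep()` holds calcium constant and averages
the M fraction over the final quarter-to-half of the record (the full
study protocol is 10 s with the final 2.5 s averaged; tests and examples
use shorter records after verifying relaxation is complete — a drift flag
compares the two halves of the averaging window). `fit_hill()` fits
`F = F_max / (1 + 10^{n_H (pCa − pCa₅₀)})` by Levenberg–Marquardt and
fails loudly on flat or one-sided data rather than returning garbage.

**Twitch.** `ca_transient()` builds a difference-of-exponentials pulse
rising from 0.1 to 1 μM, with the rise constant solved so the peak lands
exactly at `time_to_peak` (default 50 ms; decay 150 ms; these defaults
are configurable and only the endpoints are data-anchored).
`simulate_twitch()` equilibrates at diastolic calcium, applies the
transient at t = 0, and averages `n_repeats` ensembles (study scale:
1920 trajectories × 10 repeats; scaled down in tests).
`twitch_metrics()` extracts peak force above baseline (mean force over
the 50 ms before the stimulus), time to peak, RT50 (time from peak to 50%
relaxation; the relaxation limb is projected onto a monotone-decreasing
curve by isotonic regression before the crossing is interpolated, which
stabilizes the estimate on shallow tails), and the normalized force–time
integral from the stimulus to the end of the record. An optional running-
mean `smooth_window` serves noisy measured records; `expression_sweep()`
applies a 20 ms window by default because averaged stochastic traces
carry residual Monte-Carlo noise.

## Fitting and inference

`grid_search_ivma()` scans multiplicative scalings of `γ` and `K_BC`,
rerunning the steady-state protocol per cell with a shared seed (so cell
differences reflect parameters, not sampling) and scoring
`(ΔpCa₅₀, %ΔV_max)` against targets with each squared error divided by
the squared target magnitude — pCa units and percentages are not
commensurate and the normalization makes the two terms comparable; an
exactly-zero target falls back to an unnormalized term. Default axes are
ten values each over γ-scale 0.1–1.0 and K_BC-scale 0.55–1.0.

`expression_sweep()` interpolates `γ` and `K_BC` linearly between wild
type and full mutant in proportion to the expression fraction (0–100% in
10% steps by default) and tabulates twitch metrics and percent changes
against the 0% row. `infer_expression()` returns the expression
minimizing the equally-weighted sum of squared differences across the
percent changes in peak force, RT50 and nFTI (time-to-peak is reported
but deliberately excluded from inference), plus, when standard-error
half-widths are supplied, the admissible set where every prediction falls
inside mean ± SEM. `bootstrap_compare()` is a percentile bootstrap of the
difference in group means (default 10,000 resamples).

## Synthetic data

The generators replace wet-lab inputs so the whole pipeline is testable:
`gen_ivma_points()` draws a Hill curve plus i.i.d. Gaussian noise (no
noise model is published for the motility assay; additive Gaussian is the
conventional neutral choice), and `gen_twitch_trace()` builds
`(1 − e^{−t/τ_r})⁸ · e^{−t/τ_d}` — a sigmoidal rise times an exponential
relaxation — with the two time constants root-found to hit the requested
(TTP, RT50) exactly. A plain difference of exponentials was tried first
and rejected: that family cannot reach RT50 below ≈1.7×TTP, which
excludes realistic twitch geometry (e.g. TTP 150 ms, RT50 120 ms); the
power-8 rise lowers the attainable floor to ≈0.46×TTP. What these
generators do *not* emulate: motility filament breakage, tissue
viscoelasticity, pacing artifacts, or correlated noise — passing
round-trip tests demonstrates estimator correctness, not robustness to
every real-world artifact.

## Numerical choices

* State order is lexicographic in (`ca`, `sp`, `ip`, `tpm`) and frozen;
  `ru_state(0, 0, 1, "B")` (index 4) is the resting initial condition.
* The stationary solve replaces one balance equation with the
  normalization constraint; a sparse solver covers the 3-unit (13,824
  state) case.
* Hill fits refuse data whose response range is under 2% of its
  magnitude or that lies entirely on one side of half-activation.
* Trace metrics interpolate linearly between samples; the RT50 crossing
  uses the isotonic projection described above.
* Simulation sizes in the tests are reduced from the study scale with
  tolerances held at 3 Monte-Carlo standard errors; the two
  twitch-phenotype acceptance checks instead run at 2048 trajectories per
  expression level, where the claimed relaxation effects would be clearly
  resolved if the model produced them.

## Reproducibility

All randomness flows from integer seeds: per-trajectory C++ streams are
derived from the master seed; R-level noise generators save and restore
the global RNG state. `run_pipeline()` snapshots its configuration,
parameter provenance, seeds and artifact paths into `manifest.json`, and
deterministic stages reproduce bit-identical artifacts when re-run.
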