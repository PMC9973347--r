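---
title: "Quantifying stable RNA outside balanced growth: models and design choices"
author: "spikeQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stable RNA outside balanced growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeQuant)
```

## The problem

Relative quantification of rRNA and tRNA in bacteria that have left balanced
growth is riddled with hidden biases. RNA extraction methods differ sharply in
overall yield, are biased against large RNAs, and — critically — recover less
RNA from starved or drug-treated cells than from exponentially growing ones.
Northern probes add a second layer: probes that overlap a bulky base
modification (such as acp3U near the anticodon) hybridize differently to
mature and to newly made, hypomodified tRNA, so a change in the modification
state masquerades as a change in abundance. A naive pipeline can therefore
"measure" rapid tRNA degradation in cells whose tRNA pool is perfectly
stable.

Two normalization strategies are robust to these biases, and this package
implements both, together with a complete simulator of the experiments that
produce their raw data:

1. **Dual-isotope radiolabeling.** The sample culture is labeled with
   [^14^C]-uracil; a fixed amount of a [^3^H]-labeled culture harvested in
   steady state is added to every sample *before* extraction. Whatever the
   extraction method loses, it loses from both channels of the same tube, so
   the ^14^C/^3^H ratio — taken relative to the mean ratio of steady-state
   reference samples — cancels extraction and handling losses that act on
   both populations alike. What it cannot cancel, and what the simulator
   exposes, is a bias that acts on the *sample* cells only (the growth-state
   penalty).
2. **Whole-cell spike-in northerns.** Spike cells overexpressing the rare
   tRNA-selC are added before extraction; each lane's target signal is
   corrected for the spike cells' endogenous expression of the target and
   divided by the selC signal of the same lane, then referenced to the
   steady-state mean.

## Core model

Every species `s` carries a steady-state labeled mass fraction and a
ground-truth trajectory. The intact labeled amount follows

\[ F_s(t) = a_s^{\,t/T_s}, \]

a geometric interpolation through the anchor fold \(a_s\) at anchor time
\(T_s\): it is monotone, hits \(F(0)=1\) and \(F(T)=a\) exactly, and needs no
functional-form assumptions beyond "steadily changing". Transient dips and
plateaus (a drop-and-recover tRNA, a level that saturates) use the
piecewise-linear mode through explicit anchor points instead. Degraded mass
splits into TCA-precipitable fragments and acid-soluble short oligomers in
proportion `f_sol`; mass balance
\(\mathrm{intact} + \mathrm{fragments} + \mathrm{solubles} = \mathrm{const}\)
holds exactly at every time for decaying species.

Extraction methods are recovery functions

\[ r_s(t) = e_0 \cdot s(L_s) \cdot g(t), \qquad
   s(L) = \mathrm{floor} + \frac{1-\mathrm{floor}}{1+e^{(L-L_{50})/w}}, \qquad
   g(t) = p + (1-p)e^{-kt}, \]

with the size bias \(s\) logistic in species length and the growth-state
factor \(g\) applied only to perturbed populations — steady-state spike cells
always get \(g = 1\). That asymmetry is the load-bearing property of the
whole method: the ^3^H channel of every simulated record is invariant to the
sample's perturbation time, which the test suite asserts for every record
type.

The hypomodified tRNA fraction is `h0` during growth and decays as
\(h_0 e^{-k_{mod} t}\) once stable-RNA synthesis stops. A probe's apparent
signal mixes the two forms at its two affinities, so an anticodon probe over
acp3U (affinity ratio 2) reads \((1+h(t))/(1+h_0)\) on a perfectly stable
target — an apparent ~9% decline with `h0 = 0.10`, while 5′/3′/shifted
probes on the same truth stay at exactly 1.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| mass fractions 23S/16S/5S/tRNA/other | 0.50/0.27/0.03/0.16/0.04 | — | literature-typical composition of exponentially growing *E. coli* labeled RNA; the rRNA operon dominates, tRNA is the second-largest stable pool. These are the calibration anchor for every composite endpoint. |
| `dna_fraction` | 0.08 | — | the alkali-stable share of incorporated label; assumed constant (DNA is not degraded on these time scales). |
| `f_sol` | 0.35 | — | chosen once by mass balance so that with 23S/16S at 0.75, 5S at 0.95 and tRNA at 1.10 after 80 min, the TCA-precipitable total sits at ≈95% of steady state. |
| `h0`, `k_mod` | 0.10, 0.1 | —, min⁻¹ | an order-of-magnitude hypomodified pool that matures within the first tens of minutes after shutoff, making the probe artifact visible inside a 5–80 min window. |
| hot phenol | e0 0.45, no biases | — | the reference method: inside the measured 31–56% steady-state yield range, recovers composition proportionally. |
| cold phenol | e0 0.30, L50 300 nt, w 60 nt, floor 0.05; p 0.35, k 0.04 min⁻¹ | | reproduces a sub-10% overall yield dominated by tRNA/5S, and the collapse of recovery from starved cells. |
| TRI Reagent | e0 0.28, L50 200 nt, w 50 nt, floor 0.02; p 0.55, k 0.05 min⁻¹, state bias only for L ≥ 100 nt | | short species (tRNAs) escape the growth-state penalty, which is why its whole-extract ratio tracks the TCA ratio while its rRNA bands still fall. |
| `sample_dpm`, `spike_dpm` | 10⁶, 5·10⁵ | dpm | typical liquid-scintillation magnitudes for ~0.5 µCi of incorporated label; they set the Poisson noise floor and cancel from every normalized quantity. |
| `spike_endog_frac` | 0.05 | — | endogenous target expression in spike cells as a fraction of their selC signal; the correction removes it exactly in noiseless mode. |
| `n_replicates` | 3 | — | reported levels are means of three simulated biological replicates, matching routine experimental practice; steady references pool 3 samples × 3 replicates. |
| densitometry CV / load CV | 0.05 / 0.1 (noise mode) | — | multiplicative log-normal, mean 1: band-quantification error scales with intensity; membrane transfer and loading are lane-level multiplicative effects absorbed into the load factor. |

## What the simulator emulates — and what it does not

The generator reproduces the *observables* of the wet-lab designs:
scintillation records of TCA precipitates, NaOH-treated (DNA-only)
precipitates, whole extracts and excised PAGE bands on both isotope channels;
and northern lanes with per-lane loading factors, spike-cell endogenous
background and modification-sensitive probe signals, including steady-state
reference lanes and a spike-only lane per blot.

It deliberately does **not** model: lysis mechanics or phase-partition
chemistry (methods are phenomenological recovery functions), nucleotide-pool
and (p)ppGpp kinetics (ground truth is anchored to measured endpoint folds,
not generated by a metabolic model), probe thermodynamics, channel spillover
in the scintillation counter, or gel-image processing (the pipeline starts
from intensity tables). Passing tests therefore demonstrate that the
*quantification pipeline* is correct and that the stated biases are
sufficient to reproduce the published artifacts — not that the presets are a
mechanistic account of any particular protocol.

Ground-truth trajectories between printed anchor values are interpolated, so
intermediate time points are model output, not measurements. The long-term
(hours-scale) rRNA plateaus and tRNA folds are shipped as plausible defaults
and flagged `uncalibrated` in every run manifest.

## Numerical and design choices

* **Geometric vs linear interpolation.** Geometric is the default because it
  is monotone, positive and hits both anchors exactly; the piecewise-linear
  mode exists for non-monotone shapes. The choice is visible only between
  anchors.
* **Endogenous correction scaling.** The spike-only lane gives the
  endogenous-to-selC ratio; each sample lane's correction is that ratio
  times the lane's own selC band. Protocol descriptions of this correction
  leave the scaling open; scaling through selC is the only choice that keeps
  it loading-invariant, so that is what the pipeline does.
* **Fragment recovery ρ = 0.** Degradation fragments are TCA-precipitable in
  the lysate but absent from extracted, band-resolved RNA; this is what
  reconciles a ~95% TCA ratio with a ~80% whole-extract ratio at 80 min.
* **One global state factor per method.** A single \(g(t)\) per method is
  parsimonious but cannot reproduce every band-level endpoint of the most
  biased method simultaneously (cold-phenol rRNA bands are reported near 40%
  where a global factor predicts ~28–38%); the package does not target
  those numbers.
* **Pool vs member bookkeeping.** Mass bookkeeping (TCA, bands) runs on the
  five pool species; named tRNAs are members of the tRNA pool with private
  trajectories, probes and hypomodification. The per-lane tRNA-fraction
  ^14^C signal used by the radiolabel normalization route is the sum of the
  member amounts of that lane, so member-level series normalize against
  member-level truth.
* **Degenerate inputs.** DNA subtraction and the endogenous correction clamp
  small negatives (within 3 noise SDs) to zero with a warning and refuse
  larger ones; selC or denominator signals of zero are hard errors; Welch
  tests on degenerate (zero-variance, noiseless) data report `NA` rather
  than a fabricated p value.
* **Determinism.** Each run consumes a single seeded RNG stream in a fixed
  iteration order; identical (scenario, seed) pairs produce byte-identical
  tables. Seeds are restored on exit so package calls never disturb the
  caller's RNG.

## Problem sizes

The shipped designs use 3 steady-state samples plus 5–8 perturbation time
points, 3 replicates, up to three extraction methods and up to twelve probes
per scenario — a few hundred scintillation records and lanes per run, which
simulate and quantify in well under a second. The noisy parameter-recovery
property is evaluated over 100 seeded replicate experiments of the
single-method design, a scale chosen to estimate a mean absolute error of a
few percent with negligible sampling uncertainty.

## Known limitations

* Preset parameters are endpoint calibrations, not mechanism measurements;
  different (e0, size, state) combinations could fit the same endpoints.
* The "other" ncRNA pool absorbs the unmodeled mRNA/stable-RNA ambiguity of
  labeled material at sampling time.
* Whether residual synthesis or precursor maturation drives a >100% tRNA
  band signal after starvation is left open; trajectories are agnostic about
  the cause of their anchors.
* The t test machinery applies no multiple-testing correction by default,
  mirroring the experimental practice it simulates; `quantifyRun(...,
  p_adjust = "bonferroni")` corrects within each probe series when wanted.
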