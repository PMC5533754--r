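# slc11kit

Analysis toolchain for the structural dynamics and transport kinetics of
SLC11/DMT1-family proton-coupled divalent metal transporters (Fe²⁺, Mn²⁺,
Cd²⁺). It is written for two audiences that usually meet in one project:
people analysing MD trajectories of these transporters, and people
analysing their functional data (radiotracer uptake and two-electrode
voltage-clamp recordings).

## What it computes

**Structural side** — from multi-MODEL PDB trajectories:

* backbone (φ/ψ) and side-chain (χ₁, χ₂, …) dihedral time series,
  IUPAC convention, with chain-break and missing-atom handling;
* the per-residue dihedral-sum statistic **s_i(t) = ψ_i + φ_{i+1}**,
  which is ≈ −105° in an α-helix and ≈ +200° across a flipped peptide
  bond, with debounced flip-event detection;
* per-residue helicity from a φ/ψ-window criterion (plus a parser for
  external per-residue secondary-structure tables);
* rotamer-state clustering on the (χ₁, χ₂) torus (wrap-aware
  density-based clustering, medoid centroids, occupancies, transition
  counts);
* metal coordination shells (count, distances, angles, an octahedricity
  score in [0, 1]) and intracellular-gate metrics (tyrosine-pocket,
  methionine-pocket and stub-extension distances with explicit
  open/closed thresholds).

**Functional side** — from uptake plates and voltage-step traces:

* influx rates: rate = counts × [S] / (total counts × time), background
  subtraction and surface-expression normalization;
* Michaelis–Menten fits v = v_max·S/(K_m + S) and the 4-parameter
  Hill-with-leak model **I = i^U + I_max·S^n_H/(K₀.₅^n_H + S^n_H)**;
* pre-steady-state analysis: two-exponential isolation of the
  transporter relaxation from capacitive transients, charge integration
  Q = A_p·τ_p, Boltzmann Q–V fits
  **(Q − Q_hyp)/Q_max = 1/(1 + exp[z(V − V₀.₅)F/RT])**, and the derived
  transporter number N_T = Q_max/(|z|·e) and turnover −I_max/Q_max;
* per-pH Q_max profiles normalized to a reference pH.

A synthetic-data module generates all of the above inputs (helices with
scheduled peptide flips, Markov rotamer chains, metal sites, gate
ensembles, TEVC step families, uptake plates) with serialized ground
truth, so every analysis stage is verifiable by parameter recovery. A
config-driven pipeline (`run_pipeline()`, with a thin CLI in
`inst/scripts/slc11pipe.R`) chains the stages deterministically.

## Worked example

```r
library(slc11kit)

## --- structural chain: helix with one scheduled peptide flip
h  <- make_ideal_helix(20, n_frames = 50, thermal_sd = 5, seed = 1)
fl <- inject_flips(h, data.frame(resno = 10, start = 21, duration = 20))
bb <- backbone_dihedrals(fl$trajectory)
prof <- dihedral_sum_profile(bb$phi, bb$psi)
circ_mean(prof$mean[prof$resno %in% 2:18])
#> [1] -105.4
detect_flips(prof)
#>   resno frame    from      to
#> 1    10    21 helical flipped
#> 2    10    41 flipped helical

## --- functional chain: simulated TEVC family -> Boltzmann Q-V
p <- tevc_params_default(); p$noise_frac <- 0.02
sim <- simulate_tevc(params = p, seed = 1)
qa  <- charge_movement_analysis(sim$traces)
qa$fit
#> ChargeMovement Q-V fit
#>   Qmax 81.49 nC  Qhyp -0.07049 nC  V0.5 61.01 mV  z -1.97  r2 0.99993
derived_params(qa$fit, Imax_nA = -2000)
#> N_T = 2.585e+11 transporters; turnover = 24.54 s^-1
```

The interior-residue dihedral-sum average sits at the α-helical landmark
(−105°); the injected flip is recovered as one enter/exit event pair at
exactly its scheduled frames; and the full isolate → integrate → fit
chain recovers the generating Boltzmann parameters (Q_max 80 nC,
V₀.₅ +60 mV, z −2) within ~2% at 2% trace noise. A turnover near 25 s⁻¹
is what a maximal transport current of −2000 nA implies for this much
movable charge.

See `vignettes/slc11kit-methods.Rmd` for the models, parameter defaults
and numerical choices, and `?run_pipeline` for the pipeline surface.

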