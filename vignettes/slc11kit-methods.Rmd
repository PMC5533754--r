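---
title: "Methods: transporter geometry and kinetics analysis in slc11kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transporter geometry and kinetics analysis in slc11kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

slc11kit implements the computational chain used to characterize
proton-coupled divalent metal transporters of the SLC11/DMT1 family from
two sides: structural dynamics (backbone and side-chain dihedral analysis
of MD trajectories, metal-site and gate geometry) and functional kinetics
(radiotracer uptake, steady-state and pre-steady-state voltage-clamp
analysis). This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Dihedral analysis and the peptide-flip statistic

Backbone torsions are computed from coordinates with the standard
four-atom definition (phi: C⁻–N–CA–C; psi: N–CA–C–N⁺), IUPAC sign
convention, degrees on (−180, 180]. The central statistic is the
per-residue sum

  s_i(t) = psi_i(t) + phi_{i+1}(t),

which is ≈ −105° for every interior residue of an ideal alpha-helix and
moves to ≈ +200° when the peptide bond between residues i and i+1 flips.
Two numerical choices matter here:

* **Canonical interval [−135°, 225°).** Sums are angles, so they live on
  a circle; we cut that circle at −135°/225° because both landmark
  regimes (−105°, +200°) then appear un-wrapped and a flip is a single
  continuous excursion rather than a jump across ±180°.
* **Circular averaging.** Time averages use the unit-vector (resultant)
  mean, since arithmetic means of wrapped angles depend on the cut
  point. Per-residue spread is the circular SD, sqrt(−2 log R).

Flip events are detected by classifying each frame as *helical*,
*flipped* (distance < `tolerance`, default 60°, from the respective
center on the canonical interval) or *other*, then emitting an event at
every state change that persists at least `min_dwell` frames (default 5).
Distances are taken on the canonical interval — measuring them fully
circularly would make the two default bands overlap behind the cut.
State changes shorter than `min_dwell` are debounced away, which is what
makes recovery on noisy trajectories exact: with ~5° thermal torsion
jitter the sum fluctuates ~11° around its center, far from the 60° band
edge, so spurious events require many-sigma excursions sustained for 5
frames.

Helicity uses a documented phi/psi-window criterion — residue i is
helical in a frame iff phi ∈ [−100°, −30°], psi ∈ [−80°, −5°], and it
belongs to a run of ≥ `min_run` (default 4) consecutive residues
satisfying the window. This is a stand-in for assignment tools driven by
hydrogen-bond energetics; for users who want an external assignment, a
parser for per-residue state tables (`parse_secondary_structure_table`)
is provided. Terminal residues that lack both torsions are reported
absent (NA), never 0.

## Rotamer clustering on the torus

Side-chain states are clusters in (chi1, chi2) space, which is a torus:
distances use d = sqrt(dc(chi1)² + dc(chi2)²) with dc the circular
difference, so clusters straddling ±180° are never split. Clustering is
density-based (DBSCAN with grid-binned neighbour queries): points whose
eps-neighbourhood holds at least `min_members` points (defaults 30°, 10)
seed clusters; unreachable points are labelled noise. The defaults
resolve canonical rotamer wells (~±15–20° spread) while never merging
wells ≥ 60° apart. Cluster *centroids are medoids* — the member
minimizing summed circular distance to the others — so a centroid is
always a real conformation that can be handed to downstream structural
tools. Clusters are numbered by descending occupancy (ties: ascending
centroid chi1); occupancies plus the noise fraction sum to exactly 1.
Transitions are counted between consecutive frames within one
trajectory only, diagonal excluded, noise-involving changes tallied
separately.

## Metal coordination and gate geometry

The coordination shell of the bound metal is the set of donor atoms
(O/N/S by default) within `cutoff` of the ion; the default 3.0 Å covers
typical Cd²⁺–O/N bond lengths (2.2–2.6 Å) plus thermal slack.
Octahedricity is scored as

  score = clamp((6 − penalty)/6, 0, 1),
  penalty = (6 − count) + mean over ligand–metal–ligand angles of
            min(|θ−90°|, |θ−180°|)/45°,

a deliberately simple functional that is 1 exactly for a complete ideal
octahedron, loses 1/6 per missing ligand, and decreases smoothly and
monotonically with angular distortion.

Gate opening is quantified by three named distances: the gate-tyrosine
aromatic-ring centroid to its pocket (side chains of the pocket
residues), the gate-methionine side-chain tip to the hydrophobic pocket,
and the extension of the N-terminal stub (first modeled C-alpha to the
C-alpha k = 8 residues downstream). A frame is called *open* iff
tyr_pocket > 8 Å AND met_pocket < 7 Å. The residue identities ship as
configuration (ScaDMT numbering: tyrosine 47, methionine 48, pockets
L265/Q82/N229 and V271/L275/W53/F183/L180/I176) and are overridable for
other numbering schemes. The thresholds are explicit stand-ins for a
visual criterion; raw distances are always reported next to the calls.

## Uptake and current kinetics

Radiotracer counts convert to influx rates as
rate = counts × [S] / (total counts × time), i.e. pmol well⁻¹ min⁻¹ when
total counts are per litre of medium. Background (untransfected) wells
are subtracted per condition and rates divided by a surface-expression
factor; negative corrected rates are kept and flagged, never truncated,
so downstream averages stay unbiased.

Saturation models are fitted by trust-region least squares
(`minpack.lm::nlsLM`) with analytic, data-driven starts — plateau for
vmax/Imax, interpolated half-max crossing for Km/K0.5, nH = 1, the
lowest-concentration current for the leak offset i^U — so fits are
deterministic without any random restarts. The four-parameter
Hill-with-leak model I = i^U + Imax·S^nH/(K0.5^nH + S^nH) reduces
exactly to Michaelis–Menten when nH is fixed at 1 and i^U at 0, and the
package tests enforce that the two routes agree to 1e-6. Proton
concentrations derive from pH as [H⁺] = 10^(6−pH) µM; no activity
corrections are applied. Fits are reported non-converged with
diagnostics rather than silently clamped, and a fitted nH outside
(0.3, 4) warns. Weighting is available but off by default.

Fluorescence uptake is quantified as the trapezoidal area under the
baseline-corrected trace over the post-addition window.

## Pre-steady-state charge movement

Each voltage step is decomposed as

  I(t) = A_c·exp(−t/τ_c) + A_p·exp(−t/τ_p) + I_ss,  τ_c < τ_p,

after discarding a 0.4 ms dead time at the step edge. The faster
component is deemed the membrane-capacitive transient and the slower one
the transporter charge relaxation — an interpretation of the isolation
procedure, made explicit here. Numerically the decomposition is staged:
the dominant exponential is fitted first (baseline from the trace tail,
time constant from the smoothed 1/e crossing), a second exponential is
fitted to its residual to seed the remaining parameters, and all five
parameters are then refined jointly. A single-exponential description is
preferred unless the second component improves the residual sum of
squares by more than 1%; a lone component is classified as capacitive if
its τ ≤ 2 ms (`tau_c_split`) and as the transporter relaxation
otherwise. Components separated by less than 3× in τ are flagged
unresolvable and propagate NA rather than a silent number; exactly equal
time constants are information-theoretically a single exponential and
are handled by the τ classification. A fitted "slow" component with τ
longer than 1.5× the analysed window is reclassified as baseline: a
relaxation slower than the record is not measurable, and such
pseudo-components otherwise contaminate the Q–V curve.

The transporter charge is the closed form Q = A_p·τ_p (1 nA·ms =
1 pC), cross-checked against trapezoidal integration of the isolated
component. Q(V) is fitted with the Boltzmann relation
(Q − Q_hyp)/Q_max = 1/(1 + exp[z(V − V0.5)F/RT]) with Q_max = Q_dep −
Q_hyp enforced by the parameterization; Q_hyp is free, so raw charges
need no pre-zeroing (the fit provably absorbs any constant offset).
Temperature defaults to 295.15 K (room-temperature oocyte recordings),
F and R are CODATA values. Derived quantities: N_T = Q_max/(|z|·e) with
e = 1.6×10⁻¹⁹ C — |z| keeps transporter counts positive under the
negative-valence convention, the signed z stays in the fit record — and
turnover = −I_max/Q_max (s⁻¹ for nA/nC). Charge analyses default to the
ON edge; the OFF edge is available and ON/OFF charges must cancel on
two-state traces. Per-pH Q_max values are normalized per cell to the
Q_max at the reference pH (default 5.5).

## What the synthetic generators emulate

Every generator takes a mandatory seed, draws from a local RNG stream
(the session RNG is untouched), and records a ground-truth object that
regenerates the dataset bit-identically.

* **Backbones** are built by sequential internal-coordinate placement
  (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, idealized angles, ω = 180°),
  so requested torsions are realized exactly; thermal motion is emulated
  as Gaussian torsion jitter (5° in the flip-recovery experiments).
  Peptide flips are injected by setting (psi_i, phi_{i+1}) to 100°/100°
  (an arbitrary, recorded split summing to 200°) over scheduled frames
  and rebuilding coordinates.
* **Rotamer dynamics** are a discrete-state Markov chain over (chi1,
  chi2) centers with wrapped-Gaussian emission (8°); the 5-state preset
  uses wells ≥ 120° apart with 0.005/frame jump probability (mean dwell
  50 frames).
* **Metal sites** place ligand oxygens on octahedral vertices (the first
  four are equatorial, so n = 4 is the trans-vacant geometry), with
  angular jitter applied as small random rotations of each ligand
  direction.
* **TEVC traces** superpose a capacitive exponential (C_m = 200 nF,
  τ_c = 0.5 ms), a two-state transporter relaxation whose step charge
  ΔQ(V) follows the Boltzmann law (defaults Q_max 80 nC, V0.5 +60 mV,
  z = −2, τ_p = 10 ms), a linear leak, and Gaussian noise, at 5 kHz
  over a +90…−110 mV step family from V_h = −50 mV (50 ms pre, 200 ms
  step, 200 ms post). "x% noise" means a noise SD of x% of the largest
  transporter-relaxation amplitude across the step family.
* **Uptake plates** invert the influx-rate equation from
  Michaelis–Menten rates (Km 2 µM, vmax 10, 0.1–20 µM design, 15 min,
  triplicates, matched background wells) with proportional Gaussian
  (default 5%) or Poisson noise on counts.

What they deliberately do **not** emulate: force-field ensembles and
their correlated fluctuations, protonation-state physics, series
resistance and electrode artifacts, P/N leak protocols, pipetting and
plate-position effects. Passing recovery tests therefore demonstrates
that the analysis chain inverts its own generative model at realistic
parameter scales and noise levels — a necessary condition — not that it
is robust to every systematic error of real recordings.

## Problem sizes and reproducibility

The recovery experiments run at desk scale, chosen to exercise each
stage meaningfully: flip recovery uses a 200-residue × 500-frame
trajectory with 20 scheduled flips; rotamer recovery a 10,000-frame
5-state chain; Q–V recovery 100 seeds × 11 potentials at 2% noise;
Hill-with-leak 100 seeds on a pH 5.5–7.5 grid; uptake 200 seeded plates
at 5% noise. Pipeline runs with identical config and seed are
byte-identical; effective configs are written next to every run's
outputs.

## Known limitations

* The helicity criterion is a torsion-window proxy; it does not
  distinguish 3₁₀/π-helices and ignores hydrogen-bond energetics.
* The capacitive/transporter split rests on the τ separation; a genuine
  transporter component with τ near the membrane time constant, or a
  small same-τ contamination, cannot be isolated and is flagged (or
  absorbed) accordingly.
* Gate open/closed calls are threshold-explicit stand-ins for a visual
  criterion; interpret the raw distances, not only the binary call.
* The Hill-with-leak leak term is a constant offset, not a
  voltage-dependent conductance model.
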