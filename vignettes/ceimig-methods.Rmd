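---
title: "Models and methods behind ceimig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ceimig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceimig)
```

ceimig implements the computational chain of a pump-probe
Coulomb-explosion-imaging study of hydrogen migration in ethanol ions:
classical breakup simulation, per-event kinematics, an idealized
spectrometer with coincidence gating, delay-dependent yield extraction,
and trajectory-ensemble migration analysis. This vignette records the
models, the tunable parameters, and the design choices made where the
problem left them open.

## Units and species

Dynamics run in angstrom / femtosecond / amu / elementary charge; energies
are reported in eV, momenta in atomic units, times in fs. All conversion
factors live in `unit_system()`; the Coulomb constant e²/4πε₀ is
14.3996 eV·Å. Fragment species carry exact isotopic masses but are
identified by nominal (integer) mass over charge — the resolution at which
the time-of-flight spectrometer separates them. The ethanol geometry is a
hard-coded anti-conformer built from standard bond lengths (C–C 1.52 Å,
C–O 1.43 Å, C–H 1.09 Å, O–H 0.97 Å); the gauche conformer is an
unimplemented config stub, since conformer-level differences are not part
of any analysis here.

## Point-charge explosion model

Fragments are reduced to unit point charges at their centres of mass
within the intact geometry. Propagation is velocity Verlet with a fixed
base step of dt = 0.05 fs, chosen so the total-energy drift stays below
0.1% of the initial potential (measured per run and exposed in the
diagnostics; typical drift is below 1e-6 of the initial energy). Because
the Coulomb asymptote — residual potential below 0.1% of the accumulated
kinetic energy — lies thousands of angstroms out, the step is allowed to
grow proportionally to the smallest pair separation once that separation
exceeds 50 Å (capped at 25 fs); far from the interaction region the
forces vary slowly and the growing step preserves energy to the same
level. Propagation is capped at 50 ps of simulated time; for the slowest
heavy-fragment pairs at large initial separation (R = 10 Å) the cap
truncates the asymptote at a 0.4% energy deficit, which bounds the error
of the two-body oracle check.

Orientation averaging uses uniform SO(3) rotations from normalized
Gaussian quaternions. Momentum conservation is exact to rounding because
pairwise forces are applied antisymmetrically; rotation equivariance of
the propagated momenta holds to ~1e-12 relative.

### Sequential breakups

The triple channel H⁺ + H₂O⁺ + C₂H₃⁺ is fed by three two-step pathways:
the first explosion of the dication ejects C₂H₃⁺ (process i, leaving
H₃O⁺), H₂O⁺ (process ii, leaving C₂H₄⁺), or H⁺ (process iii,
deprotonation, leaving C₂H₅O⁺). After a second-ionization delay
t_ionize, the intermediate gains a charge and splits into its daughters,
placed around its centre of mass with zero internal velocity, either
along a uniform random direction ("isotropic") or at the daughters'
positions within the intact geometry ("geometry"; with t_ionize = 0 this
reduces exactly to the concerted three-body explosion, which is the
degenerate-limit consistency check).

The daughter separation of the isotropic placement is the one genuinely
open parameter. For the proton-releasing second steps we use a 3.0 Å
charge-separation distance rather than the 0.98/1.1 Å covalent bond
length: two point charges at a bond length would release the full
bare-Coulomb energy (~15 eV), an order of magnitude above the few-eV
kinetic energy releases of such two-body proton eliminations, and the
model is a charge-center reduction, not a potential-energy surface. The
heavy-pair split of the deprotonation pathway uses the 2.3 Å
centre-of-mass distance of its daughters in the intact geometry. With
these magnitudes the deprotonation-first pathway concentrates at high
proton energy fraction (upper Dalitz region) and processes i/ii sit low,
because in iii the proton keeps (45/46) of the first step's energy while
in i/ii it shares the second step's release with a heavy partner. The
t_ionize ensemble distribution is exponential (memoryless probe-arrival
stand-in) with configurable mean, default 300 fs.

## Kinematics conventions

Dalitz coordinates follow the standard triple-coincidence definition,
x_d = (E_C₂H₃ − E_H₂O)/(√3 KER) and y_d = E_H/KER − 1/3; every
momentum-conserving event lies in y_d ∈ [−1/3, 2/3], |x_d| ≤ 1/√3, and
the map is scale-invariant in the energies. The Newton frame puts the
reference fragment (C₂H₃⁺) on the positive parallel axis, the upper
species (H₂O⁺) at non-negative and the lower species (H⁺) at
non-positive transverse momentum; reflections are permitted to satisfy
the half-plane convention. The event plane is spanned by the reference
and upper momenta; the lower fragment's out-of-plane component is folded
into its signed transverse component with the magnitude preserved — for
momentum-conserving events the three momenta are coplanar and the fold
is exact. All gates in the package (KER, TOF, momentum split) use
half-open [low, high) intervals, with the 20 a.u. proton-momentum
boundary assigned to the high side.

## Spectrometer and gating

The spectrometer is a single uniform-field region (default 20 V/cm over
0.10 m, 60 mm detector radius, t0 = 0): TOF solves
L = (p_z/m)t + (qE/2m)t², transverse position is ballistic, and the
inverse is algebraic, so the round trip is exact to floating point. This
idealization omits drift tubes, lenses, magnetic fields and multi-hit
dead time; it exists to make the TOF↔momentum chain testable end to end,
not to model a specific instrument.

Channel assignment prefilters hits by per-species TOF windows (sized for
momenta up to 400 a.u.) and then demands momentum conservation among the
reconstructed fragments. Windows of neighbouring masses (17/18/19 amu)
overlap at realistic momenta, and a wrong-mass hypothesis shifts the
axial momentum sum by only Δm·L/t ≈ 5 a.u. — inside a 10 a.u. gate. A
fixed channel priority would therefore misassign systematically; instead,
among all channels whose best hit-matching passes the gate, the one
conserving momentum best is selected. The true hypothesis wins by orders
of magnitude whenever the detector model is exact; ambiguous multi-gate
matches are counted and reported.

## Trajectory criteria

A non-hydroxyl hydrogen has migrated when its distance to the oxygen
first drops below 1 Å; later recrossings are ignored. The hydrogen
already inside the threshold at frame 0 is the original hydroxyl H and is
excluded, so one detected migration marks H₂O⁺ formation and two mark
H₃O⁺; the H₃O⁺ formation time is taken as the second crossing (the event
that completes the species). The C–O break time is the first frame where
the O–C_α distance (C_α = the carbon nearest O at frame 0) exceeds 3 Å.
Migration origins (alpha vs beta carbon) are assigned at frame 0 by the
nearest carbon; same-frame ties are broken by atom index. Final channels
come from connected components of the last frame's bond graph with
covalent radii H 0.31, C 0.76, O 0.66 Å scaled by 1.2. Crossing
detection is exact to one frame by construction, and all criteria are
invariant under rigid motions of every frame.

## Synthetic data

Neither the coincidence data nor the quantum-chemistry trajectories
behind this kind of study are publicly deposited, so the package
generates both families with recorded ground truth; the generator defines
the study conditions and the tests measure the pipeline against its
truth tables.

**Event streams.** Per pulse pair an event occurs with probability 0.05;
its intended channel comes from delay-independent branching fractions
(NHM 0.30 / SHM 0.25 / DHM 0.25 / triple 0.20) and its migration
completion time T from an exponential with mean 300 fs at the 5 eV
reference internal energy, scaled inversely with internal energy
(migration is faster when the ion is hotter). A probe arriving before T
projects the unmigrated precursor at its prompt equilibrium KER; after T
the fragments have separated to R(t) = R_eq + v_sep(|t| − T) with
v_sep = 0.04 Å/fs while carrying 1 eV of dissociation energy, so the
gated KER decreases with delay toward that floor. Triple events use the
sequential simulator with the second ionization at |t| − T. Single-pulse
background events (10%) populate delay-independent KER bands at
5 ± 0.3 eV (two-body) and 13 ± 1 eV (triple), echoing the
delay-independent features such measurements show; 5% of shots carry
uncorrelated false hit pairs. Detector noise is not modelled (the hit
jitter is zero), which is what makes the momentum gate sharp; the
generator emulates the statistical structure of the measurement, not the
instrument response.

**Trajectory ensembles.** Trajectories are kinematically scripted, not
force-field dynamics: the analysis under test consumes geometry time
series only, so only the statistical structure matters. Each trajectory
starts at the jittered (σ = 0.02 Å) equilibrium geometry; migrating
hydrogens move along smooth interpolated paths that cross the 1 Å
criterion exactly at their sampled times; the first and second migration
times are drawn independently (t₁ ~ Exp(150 fs); t₂ ~ 200 fs +
Exp(600 fs), resampled in the rare case t₂ ≤ t₁), origins are sampled
50/50 alpha/beta, and the C–O separation starts at t₂ + 40 fs ±
5 fs — the concerted second-migration/bond-break mechanism. NHM
trajectories separate without migration at an exponential time. Events
scheduled beyond the 3 ps window do not occur, leaving those
trajectories unfragmented, as in truncated dynamics. Default ensemble
size is 1000 at a 0.5 fs frame spacing; analyses in the tests use 200
trajectories at 1 fs, which the detection criteria (frame-exact by
construction) do not depend on.

## Estimation choices

The migration time constant is recovered by least-squares fitting of
A(1 − exp(−(t − t₀)/τ)) to the pulse-pair-normalized yield, with Poisson
per-bin weights; t₀ absorbs the lag between migration completion and the
KER gate being entered as the fragments separate. This fit is an
analysis-side convenience, not a physical model of the experiment. Its
statistics deserve a caution: with ~5000 gated channel events over a
2 ps scan the estimator's standard deviation is about 8% of τ (measured
by Monte Carlo on ideal Poisson counts), so a 10% recovery band is a
~1.25σ statement at that sample size — the recovery checks therefore use
a clean construction (no background, full-channel KER gate, t₀ fixed at
0, both delay branches folded) where the yield is exactly
A(1 − exp(−t/τ)). Channel-ratio flatness is tested by weighted linear
regression of the per-bin ratio on delay, with the pulse-overlap window
(|t| < 30 fs, a few 9 fs pulse widths) excluded.

## Known limitations

- Point charges at centres of mass carry no information about the
  potential-energy surface; simulated KER scales are upper bounds for
  vertical multiple ionization and the sequential-step separations are
  model parameters, not predictions.
- The spectrometer is a single-region idealization with zero detector
  noise; gating performance on real data (finite resolution, random
  coincidences at higher rates) would be worse and would require the
  threshold to be calibrated.
- Scripted trajectories share none of the vibrational structure, energy
  redistribution or path curvature of real ab-initio dynamics; passing
  parameter-recovery tests shows the analysis is correct, not that the
  dynamics are.
- One conformer is used; the relative population of the two neutral
  ethanol conformers is unspecified in this kind of experiment and is
  not modelled.
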