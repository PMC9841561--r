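---
title: "Methods: detecting dynamic diastereomerism in desorption ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting dynamic diastereomerism in desorption ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirodyn)
```

## The question the package answers

A chiral molecule leaving an intrinsically chiral surface samples a
potential-energy landscape that has no mirror-image counterpart. Its
angular momentum **L** is a pseudovector: a vertical mirror plane flips the
component parallel to the plane, so the surface-normal component
$L_z$ is the one observable that only a chiral adsorbate/surface system can
bias. `chirodyn` implements the full chain needed to detect such a bias in
a trajectory ensemble — initial-condition sampling at the transition state,
microcanonical propagation (on a built-in synthetic potential or ingested
from any engine), desorption filtering, $\mathbf{L}(t)$ analysis, and
distributional statistics — and the diagnostics that distinguish *directed
rotation* (single-signed $L_z$, growing $|\mathbf{L}|$) from *mirror-balanced
rotation* (two sign subpopulations averaging to zero).

## Initial-condition model

Normal modes come from diagonalising the mass-weighted Hessian
$M^{-1/2} H M^{-1/2}$; a Hessian can be read from file or built by central
finite differences of any force provider. At a first-order saddle exactly
one eigenvalue is negative (the reaction coordinate); two or more is an
error, none leaves it absent. The imaginary-mode tolerance is
$\omega^2 < -10^{-6}\,\mathrm{rad^2\,fs^{-2}}$, separating genuine saddle
curvature from numerical noise; modes with $|\omega^2|$ below
$10^{-8}$ are classified *free* (rigid-body directions after projection).

Equipartition sampling assigns each oscillatory mode a **total** energy
$k_B T$, split between kinetic and potential parts by a uniformly random
phase $\varphi$: the realised mass-weighted mode velocity is
$\dot q = \sqrt{2 k_B T}\cos\varphi$, and **no positional displacement is
applied** — the system starts exactly at the transition-state geometry.
This is the default (`sampling.scheme = "total_energy_phase"`) because it
reconciles a fixed per-mode energy with phase-randomised initial
velocities; the alternative reading (kinetic energy exactly $k_BT$ per
mode, phase contributing only a sign) is available as `"fixed_kinetic"`.
The reaction coordinate is a single quadratic degree of freedom and
receives kinetic energy exactly $k_B T/2$, signed so that the mode's
mass-weighted displacement moves the adsorbate centre of mass toward
$+z$; a zero projection is an error, never a guess. Free modes follow the
same $\cos\varphi$ velocity rule; their assigned energy is purely kinetic
with mean $k_BT/2$, the equipartition value for an unbound degree of
freedom. Desorption additionally requires a translational kick: every
adsorbate atom is boosted by $\sqrt{2E/M_\mathrm{ads}}$ along the surface
normal, raising the COM kinetic energy by exactly $E$.

One integer seed per trajectory drives the phases in fixed mode order, so
ensembles are bit-reproducible; the pipeline expands a master seed through
a fixed-stride counter recorded in the report.

## The synthetic chiral world

The toy engine replaces a first-principles potential with a conservative
analytic one so every stage is testable in seconds. Each adsorbate atom
feels a Morse attraction in $z$ plus a helical corrugation winding with
height:

$$V = D\left(1 - e^{-a(z - z_e)}\right)^2 - D +
\kappa_\mathrm{eff}\, s(\rho)\, e^{-(z-z_e)/\lambda}
\cos\!\big(\varphi - h_s \gamma (z - z_e) - \varphi_0\big),
\qquad \kappa_\mathrm{eff} = \kappa_0 (1 + \beta h_m h_s),$$

with $s(\rho) = 1 - e^{-\rho^2/\rho_0^2}$ regularising the helix axis.
Forces are analytic; the surface is implicit (no substrate atoms are
integrated, though surface-tagged atoms from external engines are honoured
and held frozen).

| parameter | default | units | role |
|---|---|---|---|
| `D` | 0.5 | eV | Morse well depth per adsorbate atom |
| `a` | 1.0 | 1/Å | Morse width |
| `z_e` | 2.0 | Å | well minimum height |
| `kappa0` | 0.14 | eV | corrugation amplitude |
| `beta` | 0.8 | — | diastereomeric contrast: matched/mismatched coupling ratio $(1+\beta)/(1-\beta) = 9$ |
| `lambda` | 2.0 | Å | corrugation decay with height |
| `gamma` | 1.0 | rad/Å | groove pitch; its sign times $h_s$ sets the rotational sense |
| `rho0` | 0.5 | Å | core-softening radius |
| `bond_k` | 1.0 | eV/Å² | intramolecular bond stiffness |
| kick | $1.2\,n_\mathrm{ads}D$ | eV | translational energy along $+z$ |
| `temperature_K` | 300 | K | equipartition temperature |
| `dt_fs`, `n_steps` | 0.5, 400 | fs, — | NVE schedule (200 fs trajectories) |
| `n_traj` | 48 | — | ensemble size |

The molecule is a fixed five-atom template: four 3 amu atoms wound along a
right-handed helix of radius 1.1 Å at **half** the groove pitch, plus a
24 amu counterweight near the axis that puts the COM exactly on the helix
axis (the $h_m = -1$ molecule is its exact xz-mirror image). The
half-pitch choice is deliberate: the matched enantiomer spans only
$(\gamma - 0.5)\,\Delta z$ of groove phase and couples near-coherently to
the corrugation, the mirror image spans $(\gamma + 0.5)\,\Delta z$ and
partially self-cancels, yet **both** enantiomers respond to the bare
corrugation. Setting $\beta = 0$ therefore really does abolish the
statistical difference between the two ensembles, while at $\beta = 0.8$
the ninefold $\kappa_\mathrm{eff}$ contrast times the coherence ratio
yields a matched-handedness torque well clear of the thermal dispersion. A
molecule nested at the full groove pitch would make the contrast purely
geometric (surviving $\beta = 0$), and a generic compact molecule leaves
the coherent torque buried in 300 K rotational noise; both fail the
detection regime this generator is required to realise.

Several numbers were fixed by explicit design constraints rather than
taste, in one calibration pass whose outcome is frozen:

* **Bond stiffness and masses.** Velocity Verlet at the prescribed
  $dt = 0.5$ fs must conserve energy to $10^{-4}$ relative over 400 steps.
  The choice `bond_k = 1` eV/Å² with 3 amu atoms keeps
  $\omega_\mathrm{max} dt \approx 0.05$, meeting that budget with margin;
  stiff chemical bonds (tens of eV/Å²) on desk-scale masses would not.
* **Start height** (`com_height = 3.3` Å): the lowest helix atom starts
  just above $z_e$. Starting inside the steep Morse wall dominated the
  integration error.
* **Kick energy.** The per-atom Morse binding totals $n_\mathrm{ads} D$,
  so the kick is specified per adsorbate atom ($1.2 D$ each): 20 % above
  the well, the high-energy tail in which most trajectories fully desorb.
* **Desorption criterion.** COM height above the surface reference
  exceeding $z_e + 4$ Å continuously over the final 20 fs with outgoing
  final velocity. At $z_e + 4$ the residual Morse attraction is below 2 %
  of $D$; the persistence window rejects transient bounces; threshold
  crossings are reported with linear interpolation.

### What the generator emulates, and what it does not

It reproduces the *structure* of an ab initio desorption study — thermal
transition-state ensembles, NVE propagation on a handedness-dependent
landscape, stochastic initial phases against a deterministic chiral
torque — and the qualitative phenomenology: directed rotation for matched
handedness, sign-balanced subpopulations for mismatched, spread-angle
narrowing, unimodal vs bimodal folded $|L_z|$ shapes. It does **not**
model bond breaking (trajectories start past the transition state; the
transferring hydrogen is represented only as a tagged atom in ingested
data), energy exchange with substrate phonons (the implicit surface is
rigid), or any system-specific numbers: a green test establishes that the
machinery detects a planted diastereomeric signal at realistic noise, not
that any particular molecule/surface pair shows one of a given size.

## Mirror symmetry, exactly

Reflection through a vertical plane maps the world $(h_m, h_s)$ onto
$(-h_m, -h_s)$ and must negate every $L_z(t)$ *exactly* when the random
seeds match. Two implementation details make this hold to the last bit
rather than approximately: the force field is analytically equivariant
(reflection only negates $y$-factors), and initial velocities are sampled
in a *handedness-canonical frame* — modes are always built on the
$h_m = +1$ mirror image of the molecule and the sampled velocities
reflected back. Diagonalising the mirrored Hessian independently would
break the symmetry at machine precision, because LAPACK eigenvectors carry
arbitrary signs and, in the sixfold-degenerate rigid-body subspace, an
arbitrary rotation.

## Angular-momentum analysis

$\mathbf{L}(t) = \sum_i m_i (\mathbf{r}_i - \mathbf{R}) \times
(\mathbf{v}_i - \mathbf{V})$ over the adsorbate subset, about the
instantaneous subset COM with the COM velocity subtracted: intrinsic
rotation only, invariant under Galilean boosts and lab-origin choices.
Units are au with $1\,\mathrm{au} = \hbar$
($1\,\mathrm{amu\,Å^2\,fs^{-1}} = 157.46\,\hbar$). The transferring
hydrogen is excluded by default (it stays at the surface while the
molecule leaves); both the subset and the exclusion are arguments.
Reported ensemble products: per-frame mean ± sample standard deviation
(overall and per sign subpopulation), the percent growth of the mean
$|\mathbf{L}|$ from the first recorded frame (baseline configurable), and
the mean angle between individual $\mathbf{L}$ vectors and the ensemble
mean at probe times (default 10 %, 30 % and 100 % of the trajectory
length). Spread angles use unweighted directions; zero-magnitude vectors
are skipped and counted, and a zero ensemble-mean vector yields `NA` at
that time rather than a fabricated angle.

## Distributional statistics

The per-trajectory classification statistic is the mean $L_z$ over the
final half of the frames — more robust to terminal oscillation than the
final-frame value, which remains available. Sign splitting sends exact
zeros to the positive group (logged). The two-component Gaussian mixture
is fitted by EM with ten seeded starts (two quantile-based), convergence
when the log-likelihood moves less than $10^{-9}$ for five consecutive
iterations, components reported in ascending-mean order, and a variance
floor of $10^{-3}$ times the sample range preventing collapse onto a
point; fewer than four samples or all-identical values is a degenerate
input error. On genuinely unimodal data the two components typically share
the variance budget at overlapping means — the fitted *density* stays
within a small $L_1$ distance of the single Gaussian, which is the
documented degenerate outcome the tests assert.

Goodness of fit uses the Cramér–von Mises statistic
$W^2 = \tfrac{1}{12n} + \sum_i \big(F(x_{(i)}) - \tfrac{2i-1}{2n}\big)^2$.
Because the mixture parameters are estimated from the same sample, the
classical null tables are invalid (anti-conservative); the p-value is a
parametric bootstrap — draw replicate samples from the fitted mixture,
refit each, recompute $W^2$, report
$p = (1 + \#\{W^2_b \ge W^2_\mathrm{obs}\})/(n_\mathrm{boot}+1)$ — with the
asymptotic-table value reported alongside, clearly labelled, via the
Bessel-function series for the limiting distribution. More than 10 % failed
refits aborts with an unreliable-p error.

Folded $|L_z|$ densities are $g(x) = f(x) + f(-x)$ on $x \ge 0$; modality
is classified by counting local maxima of $g$ on a dense grid (a maximum
at the origin counts). A symmetric well-separated mixture folds onto one
interior mode; an asymmetric, barely-resolved one keeps two — the
qualitative contrast between the two diastereomers' $|L_z|$ histograms.

## Other design choices

* Config files are JSON (no YAML parser is available in the supported
  dependency set); unknown keys are rejected before any computation.
* Extended-XYZ is the canonical trajectory format, written at full
  `%.17g` precision so write→read round trips are bit-exact; plain XYZ is
  accepted with velocities reconstructed by central differences
  (one-sided at the ends). Ensembles are one concatenated `.xyz` plus a
  JSON sidecar carrying seeds, handedness and frame counts.
* The pipeline decision rule labels an ensemble "directed rotation" when
  $|\bar{L}_z| > 2\,\mathrm{SEM}$, and reports the majority-sign fraction
  and a two-sided binomial p-value for the sign split alongside.

## Known limitations

* The implicit surface cannot exchange energy or angular momentum with
  the substrate; whether real surface atoms were mobile in the reference
  workflow is unknown, so ingested ensembles with explicit surface atoms
  are analysed but the toy engine cannot emulate that coupling.
* The synthetic molecule is rigid-bonded and non-reactive; O–H
  dissociation chemistry preceding desorption is out of scope.
* EM with $k = 2$ only; heavier-tailed or $k > 2$ structure will show up
  as a poor CvM fit rather than being modelled.
* The bootstrap p-value is exchangeable-seed Monte Carlo: with
  `n_boot = 99` its resolution is 0.01.
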