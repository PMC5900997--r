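---
title: "A virtual specific-ventilation-imaging experiment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual specific-ventilation-imaging experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Specific ventilation (SV) is the volume of fresh gas a lung region receives
per breath divided by its end-expiratory gas volume, $SV = \Delta V_A / V_0$.
Oxygen-enhanced proton-MRI specific ventilation imaging (SVI) estimates SV
voxel-by-voxel from how quickly each voxel's signal equilibrates while the
subject alternates between breathing room air and 100% O~2~: dissolved
molecular O~2~ shortens T1, so the washin/washout rate of the local [O~2~]
is imprinted on the image series. `svisim` builds the entire measurement
chain *in silico* — a forward physiological simulator of ventilation,
perfusion and O~2~ exchange on a synthetic anatomically structured lung,
plus the MR-side pipeline (voxelization, venous-signal contamination,
response-curve inference, in-plane misalignment) — so that the inferred SVI
maps can be compared against the simulated ground truth.

This vignette records the science of each stage, the tunable parameters
with their defaults and units, the numerical schemes, and the design
decisions taken where the design was genuinely open. The worked pipeline is

```{r}
library(svisim)
run <- svi_experiment(svi_config(), seed = 1)
run$comparison
```

# The synthetic lung

**Host volume.** Two disjoint ellipsoidal lungs (x left–right, y
anterior–posterior, z cranio–caudal) are scaled so the enclosed volume
equals the functional residual capacity target (`frc_L`, default 2.64 L).
All simulations are supine, so gravity points along $-y$ and "height" is
measured dorsally-upward from the most dependent lung edge. The default
semi-axis proportions give a right lung about 105 mm wide (seven 15 mm
sagittal slabs) and an anterior–posterior extent of about 13 cm, which is
what makes gravitational gradients over height meaningful. An analytic
host rather than an image-derived surface removes any data dependency;
the price is that lobar fissures, the hilum and the flattened lateral
profile of a real lung are absent, so edge-related quantities (for
example the volume fraction held by the central sagittal slab, which for
an ellipsoid is necessarily ~20%) differ from image-derived anatomy.

**Airway tree.** The conducting tree is grown by volume-filling branching:
uniformly seeded terminal target points (minimum separation twice the
minimum branch length) are recursively bisected by a plane through the
parent direction, and a daughter grows toward each half's center of mass,
advancing a fraction `branching_fraction` (0.4) of the distance with a
branching-angle cap of 60°. Each target point receives exactly one
terminal branch ending on it. The default scale is `n_terminals = 500`
(one acinus per terminal, so each model acinus lumps roughly 30 real
acini); the generator accepts thousands of terminals if a finer lung is
wanted, at proportional cost.

**Diameters and vessels.** Branch diameters follow a Strahler-order
geometric rule, $D(\text{order}) = D_\text{root}\, R_d^{\,\text{order} -
\text{order}_\text{max}}$. On a 500-terminal tree the Strahler depth is
only 9–10 orders (a full human tree has ~16), so the per-order ratio must
be steeper than in full-depth morphometry for distal airways to come out
at duct-like calibers: the defaults are $R_d = 1.30$ for airways (18 mm
tracheal root, ~2 mm terminal ducts, ~125 mL anatomical dead space) and
1.35 for arteries (24 mm root), with veins 20% wider than arteries.
Arterial and venous trees share the airway centerlines exactly, so all
three networks terminate at the same acinar locations. Anatomical dead
space is the sum of branch cylinder volumes and is kept separate from
acinar gas volume.

**Gravitational tissue mechanics.** A parameterized stand-in for a
continuum tissue-mechanics model: acinar FRC volumes vary linearly with
height (`v0_gradient_per_cm`, default 0.060 per cm; dependent units
smaller), rescaled to preserve total FRC exactly, and the local elastic
recoil pressure is `pe_ref_cmH2O` (5 cmH~2~O) with a height gradient of
0.25 cmH~2~O/cm. The volume gradient is the calibration handle for the
vertical SV gradient: 0.060/cm places the simulated-true-SV slope of the
default lung at about −0.017 per cm of height, the magnitude expected in
healthy supine lungs. Acinar compliances share a lung total of 100
mL/cmH~2~O with a 5% log-normal unit-to-unit variability — a deliberately
mild iso-gravitational heterogeneity; see *Limitations*.

# Ventilation

Tidal flow is a square wave derived from tidal volume and timing: 650 mL
per 5 s breath at an inspiratory:expiratory ratio of 1:1, hence 0.26 L/s.
(The alternative convention of fixing the flow amplitude first is not
used: tidal volume and timing are authoritative, the amplitude is
derived.) Conducting airways are rigid; each branch carries a Poiseuille
resistance $R_p = 8\mu L/(\pi r^4)$ multiplied by a Pedley-type
bifurcation energy-dissipation factor $Z_{pe} = \max\!\big(1,\;
\gamma\sqrt{Re\,D/L}\big)$ with $\gamma = 0.327$, which reduces to 1 in
the laminar limit. Terminal branches feed elastic acini with pressure
$V_a/C - P_e$.

Numerically, each time step (default 0.01 s) solves one sparse
symmetric-positive-definite system for nodal pressures with the acinar
elastance folded in semi-implicitly, so flow is conserved at every
junction to solver precision at every step. $Z_{pe}$ is refreshed by a
short fixed-point iteration at the start of each phase and then frozen
(the square-wave flows barely change within a phase). Breaths repeat
until per-acinus tidal volumes drift less than 0.5% between cycles (three
warm-up breaths typically suffice); non-convergence is an error, not a
warning. The breath-averaged acinar volumes $\Delta V_A$ divided by $V_0$
give the simulated **true SV** field against which the imaging chain is
judged.

# Perfusion

Steady blood flow is solved on the combined artery–capillary–vein network
with inlet pulmonary-arterial and outlet left-atrial pressures (2000 and
666 Pa). Each branch obeys $\Delta P = 128 \mu L \dot Q / (\pi D^4)$ plus
the hydrostatic column $\rho_b g L \cos\theta$; the hydrostatic term is
handled exactly by working in the potential $P + \rho_b g h$. Vessel
diameters follow the linear tube law $D = D_0 (1 + \alpha P_{tm})$ with
$\alpha = 1.49\times10^{-4}$ Pa^-1^ and $P_{tm}$ the local blood pressure
plus elastic recoil ($\alpha$ has units of 1/Pa; a transmural pressure at
or below $-1/\alpha$ is vessel collapse and raises an error). Each acinus
closes the circuit with a lumped capillary: a shared reference resistance
(`cap_resistance_lung_Pa_s_mm3` × number of acini; default tuned so
cardiac output is ~7.5 L/min and the mean ventilation–perfusion ratio is
~1) subject to the same transmural tube law, which is what carries the
gravitational perfusion gradient into the capillary bed, and a blood
volume share of 100 mL lung-total, giving red-cell transit times near
0.8 s. The fixed-point iteration between the linear network solve and the
diameter update converges to a relative diameter change below 10^-6^ in a
handful of iterations; with $\alpha = 0$ it collapses to a single linear
solve. A detailed morphometric capillary-sheet model is intentionally out
of scope: what the downstream gas exchange needs is per-acinus flow,
capillary volume and transit time.

# Airway gas transport

O~2~ moves through the tree by 1D advection–diffusion,
$\partial_t c + u\, \partial_x c = D\, \partial_x^2 c$, with the O~2~–N~2~
binary diffusivity $D = 22.5$ mm²/s and per-branch time-averaged
velocities from the ventilation solution. The solver splits operators per
time step (default 0.05 s):

1. **Advection** by a conservative finite-volume upwind sweep,
   sub-stepped to the CFL bound of the fastest cell. Because every
   internal flux appears once as a gain and once as a loss, advection is
   exactly mass-conserving; boundary fluxes (tracheal inlet, acinar
   terminals) are accounted explicitly and feed the per-breath O~2~ mass
   audit.
2. **Diffusion** by an implicit Galerkin linear-element solve, assembled
   only over branches with Péclet number $Pe = Lu/D < 5$; high-Péclet
   branches are advection-only, and excluding their elements entirely
   keeps the split conservative at the regime boundary.

During inspiration the tracheal node is held at the inspired fraction and
terminals are zero-flux; during expiration the terminal nodes receive the
acinar concentration advectively (an influx formulation rather than a
hard overwrite, again to keep the mass audit exact) and the trachea is
free outflow. Mesh spacing defaults to 3 mm, widened to the branch radius
in the proximal airways where fast cells would otherwise dominate the CFL
sub-stepping without adding information; halving the transport step
changes end-of-breath alveolar PO~2~ by less than 0.2%.

# Acinar gas exchange

Each acinus holds three coupled compartments. Alveolar gas is a
well-mixed bag whose volume follows the acinar inflow; its O~2~ fraction
is diluted by the incoming airway gas during inspiration and changes only
through exchange during expiration. Tissue PO~2~ relaxes as
$\dot P_t = k_{ta}(P_A - P_t) - k_b(P_t - \bar P_b)$, O~2~ always moving
down partial-pressure gradients. Capillary blood enters at the fixed
mixed-venous pressure of 40 mmHg and is integrated along the red-cell
transit with the hemoglobin-buffered update
$\dot P_b = \tfrac{T_b}{v_b \sigma}\big[1 + \tfrac{4\,\mathrm{Hb}}
{\sigma}\tfrac{dS}{dP}\big]^{-1} (P_t - P_b)$, where
$S(P) = P^n/(P_{50}^n + P^n)$ with $P_{50} = 26.8$ mmHg and $n = 2.7$;
the end-capillary value after one transit is what the venous tree
receives. O~2~ solubility is $\sigma = 1.4\times10^{-3}$ mmol/L/mmHg and
hemoglobin 2.3 mmol/L. All integrations are semi-implicit with a Picard
refresh of the buffering factor, so the stiff saturated regime (where the
factor approaches 1 and the blood equilibrates within a fraction of the
transit) is stable at the default step.

The transfer factors are not standard literature constants at this lumped
granularity, so they are specified as lung totals and apportioned to acini
by tissue and blood volume: $T_{ta} = 0.010$ and $T_b = 0.025$
mmol/(mmHg·s) lung-total, chosen once so that a unit with a
ventilation–perfusion ratio near 1 settles at an alveolar PO~2~ of
~105–115 mmHg and an end-capillary PO~2~ of ~95 mmHg on room air — i.e.
textbook resting gas exchange. The mixed-venous inflow stays at 40 mmHg
even during O~2~ blocks, a deliberate simplification that slightly
overstates total uptake at high FIO~2~.

# The virtual SVI protocol

The inspired-gas schedule is five cycles of 20 room-air breaths followed
by 20 breaths of 100% O~2~, with 20 further O~2~ breaths appended: 220
breaths, one image per breath, sampled at end-expiration. Six warm-up
breaths of room air precede the recorded protocol so the lung starts from
its own steady state. A per-breath audit checks that the O~2~ content of
the airway tree plus acinar gas changes exactly by boundary inflow minus
outflow minus exchange uptake; the worst per-breath closure on the
default run is a few parts in 10^4^.

**Signal model.** Proton-MR signal comes from water, so the O~2~-sensitive
part of a voxel's signal is taken as the dissolved O~2~ in tissue water
and capillary blood: per acinus, $\sigma (v_t P_t + v_b P_c)$, and per
venous branch, blood volume × $\sigma P$. Alveolar gas contributes no
protons and acts only through the tissue PO~2~ it sets. A consequence
worth stating: venous blood carries roughly four times the O~2~-sensitive
signal per unit volume of parenchyma (which is mostly gas), so voxels
containing large veins are venous-dominated — the mechanism by which
venous blood contaminates SVI.

**Venous propagation.** End-capillary PO~2~ series are swept from the
acinar terminals to the venous root; at each confluence the output is the
flow-weighted mean of the upstream series, and each branch delays its
series by its blood residence time (volume/flow), linearly interpolated
between the once-per-breath samples. At steady state the root series
equals the flow-weighted mean of all end-capillary values. Within-branch
transport is plug flow (pure delay); axial dispersion in blood is
neglected.

**Voxelization.** The grid is 1.6 × 1.6 mm in the sagittal plane with
15 mm slabs. Tissue: each acinus is a sphere of its FRC volume sampled
with a symmetric half-offset lattice (1.6 mm spacing); the acinar volume
is apportioned over the lung voxels the kernel hits, making the partition
exact by construction. Veins: each branch is a cylinder at its strained
diameter, rasterized as a uniform point cloud of configurable unit volume
(default 0.1 mm³ — comfortably sub-voxel; the classical 10^-3^ mm³
density is supported and used in the rasterization-fidelity tests, but at
whole-lung scale it would cost ~10^8^ points for no added accuracy at
1.6 mm voxels). Voxel tissue-fill fractions come from subsampling the
host surface; voxels less than half filled are excluded (the rule is
strictly "less than", so exactly-half-filled voxels are retained).

**Inference.** The response library holds 50 characteristic curves for SV
values in a geometric series from 0.01 with 15% increments (maximum
≈ 9.42), each generated by the inert single-compartment end-expiratory
update $c' = c + \tfrac{s}{1+s}(c_{insp} - c)$ driven by the schedule —
rate-of-equilibration templates with the closed form
$c_n = c_\infty + (c_0 - c_\infty)(1+s)^{-n}$ within a block. Each
voxel's 220-sample series is Spearman-rank-correlated with all curves;
the highest correlation gives the estimate, kept when significant at
P ≤ 0.05 by the large-sample t approximation (an exact view is
unnecessary at n = 220); ties break toward the lower SV; constant series
are discarded as zero-variance.

**Misalignment.** In-plane misalignment is modeled by fixing the apex and
stretching the slice cranio-caudally until the per-image volume change
matches a prescribed end-expiratory lung-volume (EELV) series within 10%;
acinar positions and volumes, and the venous point cloud, follow the
deformation, and signals are re-binned on the original grid. The EELV
series is drawn from a normal distribution (mean 9%, SD 12%) truncated at
|40%|, with an optional shuffle. The re-binned voxel signal is the
volume-weighted mean concentration of whatever occupies the voxel in each
image, so motion exchanges contributing units (pseudo-unit mixing) rather
than modulating amplitude. Two masks define the analyzable region, both
analogues of discarding tissue outside the initial boundary: voxels must
contain lung in every image, and their imaged composition must be stable
(voxels that a large vein slides in and out of alternate between
tissue-level and blood-level signal at this model granularity and have no
single response curve).

# Analysis

SV fields are summarized as in the imaging literature: 10 mm
iso-gravitational sections, ordinary least-squares slope of per-section
mean SV against height in cm (the gravitational gradient, negative when
SV falls with height above the dependent edge), the mean, and the
coefficient of variation over all retained values in the region (COV =
100·SD/mean; computed over voxels, not over section means). Whole-lung
summaries include both lungs; per-slice analyses use the right lung, with
the mid-sagittal slice taken as the slab holding the largest retained
cross-section.

# What the generator does and does not emulate

The synthetic lung reproduces: a supine gravitational SV gradient of
realistic magnitude (via the FRC-volume gradient), a gravitational
perfusion gradient (via the transmural tube law), anatomically matched
airway/vascular topology, realistic dead space, and textbook resting gas
exchange. Passing tests therefore show that the measurement chain —
washin dynamics through a dead-sparse conducting tree, venous mixing and
delay, voxel partial-volume mixing, template matching — behaves correctly
under these conditions.

It does **not** emulate: fractal, spatially clustered iso-gravitational
heterogeneity of ventilation and perfusion (unit-to-unit variability is a
mild 5% log-normal on compliance); subject-specific central airway and
vessel topology; lobar fissures and hilar anatomy; capillary recruitment.
Three consequences, quantified on the default run and worth knowing
before extrapolating to real data:

* **Dead space slows apparent washin.** With the inert response library,
  the inferred SV of a full-physics voxel sits systematically below true
  SV by roughly the per-breath fresh-gas deficit $V_D/\Delta V_A$
  (~1.5 library bins at ~125 mL dead space). This is physics, not
  numerics — mesh refinement does not move it — and it is the reason the
  recovery test isolates the *translation* step (voxelization + binning +
  rank matching) by driving it with noise-free inert responses, where
  recovery within one bin is essentially perfect. In real SVI the same
  effect is part of why absolute SV values are calibration-sensitive,
  while gradients and heterogeneity, which the acceptance bands target,
  are robust.
* **The venous contribution is mild and slightly low-biased here.** A
  vein's series is the lagged, flow-weighted mixture of its subtree; with
  a gravity-only perfusion gradient the flow weighting raises the
  mixture's effective SV by only a few percent, while rank-matching of
  rate mixtures is tail-weighted and biases slightly low — so
  vein-dominated voxels do not develop the strikingly high apparent SV
  that strong, spatially concentrated perfusion heterogeneity would
  produce. Reproducing that regime would need the capillary bed model
  this package deliberately lumps.
* **Misalignment effects are second order on a smooth SV field.** The
  pseudo-unit mixing bias toward lower SV requires neighboring units to
  differ appreciably in SV; with mild local heterogeneity and an SV field
  nearly constant along the stretch axis, the default misalignment
  experiment shifts means and gradients only marginally.

# Numerical and reproducibility notes

Default problem sizes — 500 terminals, ~2,600 transport nodes, 220 breaths
at a 0.05 s transport step — run the full experiment in about two minutes
on one core; the unit-test fixtures use an 8-terminal hand-built
symmetric bundle where conservation and symmetry hold to machine
precision. Everything stochastic (terminal seeding, compliance
variability, the EELV series) derives from one master seed, and repeated
runs are bit-identical. Degenerate inputs fail loudly by design:
over-packed hosts, collapsing vessels, non-convergent cycles,
out-of-range PO~2~, unknown configuration keys and mismatched topologies
all raise errors naming the offending quantity.
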