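---
title: "Modeling tumor treating fields in synthetic head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor treating fields in synthetic head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttfieldsim)
```

## The physical model

Tumor treating fields (TTFields) are intermediate-frequency (~200 kHz)
alternating electric fields delivered to the brain through two pairs of 3×3
scalp electrode arrays. At these frequencies the electromagnetic wavelength
is far larger than the head and tissue permittivity contributes negligibly
to the impedance, so each instant of the cycle can be treated as an
electrostatic problem in a volume conductor: the potential satisfies

$$\nabla\cdot(\sigma\,\nabla V) = 0$$

with a symmetric positive-definite conductivity tensor field $\sigma(x)$
(S/m), Dirichlet conditions on the electrode contact surfaces, and
insulating (natural Neumann) conditions elsewhere on the skin. The electric
field is $E = -\nabla V$ and the current density follows Ohm's law,
$J = \sigma E$. Because the problem is linear, the electrodes are first set
to arbitrary potentials (±0.5 V per array) and the entire solution is then
rescaled so that the prescribed peak current — 0.9 A per active array pair,
i.e. 1.8 A peak-to-peak — passes through the source array.

The package computes this forward problem end to end on synthetic
tetrahedral phantoms, and summarizes the resulting field-strength
distribution the way the TTFields dosimetry literature does: the
volume-weighted median of $|E|$ in a region of interest as the "dose", and
the interquartile range (IQR) as the measure of field non-uniformity.

## Phantoms

Two phantom families are generated, both meshed on a structured lattice in
which every hexahedral cell is split into six tetrahedra around its main
diagonal (a conforming subdivision), and every element is labelled by the
compartment containing its centroid (points exactly on an interface belong
to the inner compartment).

* **Layered slabs** (`build_slab_phantom()`) stack homogeneous tissue
  layers between two full-face plate electrodes. Layer interfaces are
  forced onto lattice planes, so piecewise-linear exact solutions are
  reproduced to solver precision; these phantoms carry the closed-form
  validation cases. A CSF-filled slot can be carved with
  `add_box_region()` to emulate a sulcus for hot-spot experiments.
* **A five-tissue head** (`build_head_phantom()`): concentric ellipsoidal
  shells of skin, bone (skull), CSF, gray matter and white matter. The
  outer semi-axes default to (75, 95, 85) mm, matching a 150 mm left/right
  by 190 mm anterior/posterior adult head extent; shell thicknesses default
  to skin 6, bone 7, CSF 3 and GM 4 mm, representative adult values exposed
  as configuration (they are not prescribed by the modeling literature this
  emulates). The remainder is white matter.

Spherical tumors (`embed_tumor()`) are introduced by relabelling: a 20 mm
outer sphere of active tumor tissue, optionally with a 14 mm necrotic core
(a 3 mm active brim). Tumors must fit entirely inside the GM/WM
compartments — the analog of keeping lesions inside the dural boundary —
otherwise embedding fails loudly, and position sweeps skip and report such
positions.

The geometry of real heads that these phantoms deliberately do **not**
reproduce: gyral/sulcal folding (only the slab slot emulates a sulcus),
ventricles, anatomical asymmetry, and subject-specific segmentation.
Passing the phantom test suite therefore demonstrates correctness of the
numerical pipeline and of conductivity-contrast mechanisms, not fidelity to
any individual anatomy; externally meshed heads can be supplied through the
Gmsh MSH / legacy VTK readers.

## Conductivity models

Isotropic tissue conductivities default to skin 0.465, bone 0.010, CSF
1.654, tumor shell 0.24 and necrotic core 1.00 S/m — in vivo / in vitro
literature values at TTFields-like frequencies. The GM (0.275 S/m) and WM
(0.126 S/m) scalar references are literature-typical stand-ins, exposed as
mandatory-visible configuration because published pipelines derive them
per subject.

White- and gray-matter anisotropy is modelled by *direct mapping* from a
diffusion-like tensor field: the conductivity tensor shares the
eigenvectors of the local fiber tensor, with eigenvalues rescaled per
element so their geometric mean equals the tissue's scalar reference
(volume-normalized mapping). This keeps the effective tissue conductivity
consistent with the isotropic table; an unnormalized per-tissue
global-scale variant is available behind a flag. Eigenvalues are floored at
1e-6 S/m so the assembled system stays positive definite. Since no
diffusion MRI is available for a synthetic phantom, `synth_fiber_field()`
generates prolate tensors (two equal minor eigenvalues) whose principal
direction follows a chosen pattern — uniform, radial, or circumferential
"tangential shells" — and whose eigenvalue ratio realizes a requested
fractional anisotropy exactly; FA = 0.7 is the default, a typical value for
coherent deep white-matter bundles.

To isolate the effect of anisotropy from the mean conductivity level,
`mean_conductivity()` replaces every tensor by the arithmetic mean of its
eigenvalues times the identity (the *mean conductivity*, MC, surrogate);
`anisotropy_comparison()` runs the anisotropic and MC models on the same
mesh and returns signed difference maps.

## Finite elements and numerics

First-order (P1) tetrahedral elements give a constant field per element,
consistent with recovering $E$ as the numerical gradient of the potential.
Geometry enters in millimetres and is converted to SI metres before
assembly, so potentials are volts, fields V/m, current densities A/m² and
currents amperes. The stiffness matrix is assembled sparsely from the
analytic shape-function gradients; before boundary conditions its rows sum
to zero (constants span its null space), which the tests assert at 1e-12.

The reduced Dirichlet system is solved by Jacobi-preconditioned conjugate
gradients to a **relative** residual below 1e-9 (the tolerance semantics
are configurable, and a sparse-Cholesky direct solver is available for
batch runs; it satisfies the same residual bound with margin).
Electrode currents are measured discretely exactly as the residual of the
unconstrained equations summed over an array's nodes, which makes
source/sink cancellation and the post-hoc current rescaling exact to
solver precision.

Discretization error is dominated by the staircase representation of
curved interfaces under centroid labelling and converges at first order.
Measured on the Maxwell-sphere benchmark (a 20 mm sphere of 1.00 S/m in a
0.24 S/m box of five sphere diameters, uniform 100 V/m drive): the
labelled tumor volume overshoots the analytic sphere volume by ~1.6% at
2 mm resolution, and the interior-field error is 4.5% at 2.5 mm, 2.5% at
1.25 mm; the finite box itself contributes only ~0.2% (measured by
enlarging it to seven diameters). Interior fields are therefore measured
over the inner 70% radius, clear of the interface layer, and the
equivalent-conductivity check compares two FEM solutions on the *same*
mesh so the staircase bias cancels.

## Dosimetry conventions

Per-element field strengths are summarized by quantiles weighted by element
volume, interpolated linearly on the cumulative-volume curve with knots
$p_i = (C_i - u)/(C_n - u)$, $u = \min_i w_i$; with equal volumes this
reduces exactly to `stats::quantile(type = 7)` and it is invariant to
rescaling all volumes. Unweighted statistics are available
(`weighted = FALSE`) since published work rarely states which convention
was used. Ties in the pairwise montage comparison count toward the
"equal or higher" fraction. Hot spots are elements strictly above a
volume-weighted percentile of $|E|$ (percentile 0 returns the whole
region, so a uniform field has no hot spots at any positive percentile).

For tumor-position sweeps the default region of interest is the **active
tumor tissue**: the shell for necrotic tumors and the entire sphere for
solid ones. This is the like-for-like reading of "field strength in the
tumor tissue": the necrotic core is fluid, not tumor tissue, and because
the well conducting core channels current away from the surrounding shell,
including it depresses the whole-sphere median by 18–33% on the default
phantom, whereas the active-tissue medians of necrotic and solid tumors
agree within 15% at every position and montage — the "nearly identical
medians, very different IQR" pattern that motivates the necrotic/solid
comparison in the first place. `roi = "whole"` restores the whole-sphere
statistic.

## The in-silico experiments

`run_position_sweep()` reproduces the tumor-translation design: the
default lateral (x) positions are (30, 32.5, 35, 37.5, 42.5, 45, 47.5,
50) mm, with y and z translation lists around a lateral tumor at
x = 40 mm. These coordinate lists were designed for a real head; on the
default phantom the most lateral position (x = 50 mm) does not fit inside
the GM shell and is skipped and reported rather than silently dropped (the
remaining lists are kept verbatim for external-mesh runs). Each contained
combination of position, tumor type, montage and conductivity model is
solved at the 0.9 A target and tabulated. The pipeline contains no random
number draws — meshing, montage placement and solving are deterministic —
so repeated runs with one seed and configuration produce byte-identical
tables; the seed is recorded for forward compatibility with stochastic
options.

Montages follow the clinical layout: 3×3 arrays of 20 mm discs at 45 mm and
22 mm centre-to-centre pitches, centred over the ear canals (left/right
pair) and forehead/occiput (anterior/posterior pair), left and posterior
arrays acting as sources. Which pitch runs along which head axis is not
fixed by the published description, so the 22 mm pitch is placed along the
circumferential (z) direction and both pitches are configurable. All nine
discs of an array are equipotential ideal Dirichlet patches directly on
skin nodes (no gel/ceramic layer is parameterized). The planar grid is
projected onto the scalp by nearest-surface-point projection and disc
footprints use a Euclidean — not geodesic — radius; both are documented
approximations. Where scalp curvature crowds the projected grid, each
surface node is assigned to its nearest disc centre so footprints stay
disjoint; since an array is equipotential this does not change the
electrical model.

## Problem sizes used by the tests

The test-suite and acceptance script run entirely on one CPU: the
two-layer slab at 1 mm (24k elements, exact to solver precision), the
Maxwell sphere at 2.5 and 1.25 mm (up to 3.1M elements), the
shelled-vs-equivalent comparison at 2 mm, and the head-phantom sweeps at
6 mm (73k elements, ~14k nodes per solve). These sizes were chosen from
the convergence measurements above: coarse enough to run a full sweep in
about a minute, fine enough that the oracle comparisons sit inside their
stated bands with the discretization error documented here.

## Known limitations

* Ellipsoidal anatomy and centroid-labelled staircase interfaces (first
  order in resolution); no hanging-node local refinement.
* Ideal equipotential electrodes without gel/ceramic impedance layers; no
  per-disc current balancing — whether hardware drives discs individually
  is not public, and the Dirichlet formulation matches the published
  modeling practice.
* Electrostatic only: no permittivity/frequency dependence, no thermal
  model, no vasculature.
* The GM/WM scalar conductivity references (and hence absolute field
  magnitudes) carry substantial literature uncertainty; trends driven by
  conductivity *contrasts* are the robust outputs.
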