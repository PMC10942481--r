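---
title: "The SR-EV chromatin chain model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SR-EV chromatin chain model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srev)
```

## The model

Chromatin in interphase nuclei is a nucleosome fiber whose imaged
structure alternates dense packing domains with dilute, accessible
space, while sequencing-based contact maps show power-law contact
scaling.  `srev` generates such structures from two stochastic rules
plus physical interactions.

**Self-returning random walk (SRRW).**  A walk in continuous 3D space
takes, at each step, either

* a *return*: it exactly reverses the most recent un-returned forward
  step, with probability
  \(P_R(U_0) = U_0^{-\alpha}/\alpha\),
  where \(U_0\) is that step's length in unit lengths, or
* a *forward jump* of length drawn from the heavy-tailed density
  \(P_J(U) = (\alpha+1)\,U^{-(\alpha+2)}, \; U > 1\),
  in a uniformly random direction.

The folding parameter \(\alpha > 1\) controls both rules: smaller
\(\alpha\) gives more returns and heavier jump tails.  One unit length
is 10 nm, the diameter of a nucleosome, so each visit of the walk is
one nucleosome.  Returns create revisited sites; the walk is a linear
backbone decorated with tree-like branches whose branch points are
coincident beads.  Un-returned forward steps live on a stack, so a
revisited site is identified by stack position, never by floating-point
coordinate comparison.  Forward jumps are truncated at `u_max = 100`
unit lengths (1 µm) by rejection resampling: jumps beyond the
confinement scale are unphysical, and the truncated tail mass is below
\(10^{-4}\) for \(\alpha \ge 1.1\).  A global spherical cutoff of
radius \(R_c\) (650 nm at full scale) is applied during generation,
measured from the running center of mass of the already-generated
nodes; rejected forward jumps are fully resampled (direction and
length), with a budget of \(10^4\) tries per step.  Whether the
original procedure rejects or reflects such jumps is not specified;
rejection keeps the jump-length law clean, and at full scale fewer
than 1 % of steps are affected.

**Excluded volume (SR-EV).**  The walk violates excluded volume at
every revisited site.  `expand_overlaps()` turns each visit into one
bead of a linear chain (bonds join consecutive visits; bond rest
lengths are the traversed step lengths) and `relax_chain()` resolves
all overlaps with a soft repulsive pair potential
\(E = k_{rep}(2r_o - r)^2\) for \(r < 2r_o\), harmonic bonds
\(E = k_{bond}(r - r_0)^2\), and a reflecting confinement sphere of
radius \(R_c\); the non-overlap radius is \(r_o = 4.9\) nm.
Relaxation terminates the moment no bead pair is closer than
\(2 r_o = 9.8\) nm.  The overall volume fraction is
\(\phi = N (r_o/R_c)^3\); the four production values
\(\phi = 0.08, 0.12, 0.16, 0.20\) correspond to
\(N \approx 1.9, 2.8, 3.7, 4.7 \times 10^5\) beads at
\(R_c = 650\) nm.

Because the walk's confinement is enforced around a *running* center
of mass, a finished walk has drifted; the chain is recentered on its
center of mass before relaxation so that the relaxation sphere
coincides with the configuration.  Skipping this recentring crushes
the configuration against one side of the sphere and distorts every
density statistic downstream.

## Numerical choices in the relaxation

* **Integrator.**  The production integrator is damped inertial
  molecular dynamics with FIRE adaptive time-stepping, a standard
  minimiser for packing problems; `method = "descent"` selects plain
  overdamped gradient descent, which is strictly energy-decreasing at
  zero temperature and is used by the test suite to audit the descent
  contract.  FIRE reaches zero overlaps in roughly 200 iterations for
  \(N = 5\times10^4\) at \(\phi = 0.16\); plain descent needs over
  \(10^4\).
* **Contact margin.**  A soft core whose force vanishes exactly at
  contact can never finish: bond tension holds pairs at an
  infinitesimal overlap.  The repulsion range is therefore inflated by
  `contact_margin` (default 10 %) beyond \(2r_o\), while termination
  still tests true \(2 r_o\) overlaps.  The margin leaves a restoring
  force alive at the contact distance itself.
* **Initialisation.**  Co-located beads are placed on consecutive
  shells of a close-packed (FCC) ball around their site, randomly
  rotated per site and jittered by `perturbation` (0.5 nm).  This
  seeds every cluster overlap-free inside the volume it must occupy;
  the random rotation plays the symmetry-breaking role that thermal
  noise would otherwise play, so the default relaxation temperature is
  exactly zero and relaxation is deterministic given the chain.
* **Neighbor search.**  A counting-sort linked-cell structure plus a
  Verlet pair list with a one-bead-radius skin; the list is rebuilt
  when the two largest accumulated displacements could let an unlisted
  pair enter the force range, at most every few iterations, and
  convergence is always re-verified against a freshly built list.
* **Stiffness calibration.**  The repulsion stiffness sets the energy
  scale (\(k_{rep} = 1\)).  The bond stiffness is the one genuinely
  free mechanical parameter: it controls how much the excluded-volume
  expansion stretches bonds before termination, which is what the
  linker-DNA statistics record.  It was calibrated once, on a pilot
  grid of six (\(\alpha\), \(\phi\)) corner conditions at
  \(N = 2\times10^4\), so that the mean linker reproduces the
  146 + ~40 bp nucleosome repeat and its \(\phi\) trend, giving
  \(k_{bond} = 0.05\); it was then frozen.  Stiffer bonds suppress the
  crowding stretch (mean linker drops toward the raw-walk value),
  softer bonds overshoot and slow convergence.

## Genomic annotation

Each bead carries 147 bp of wrapped DNA.  A bond of length
\(U_i \ge 10\) nm carries linker DNA of
\(\mathrm{nint}\big((U_i - r_o)/0.34\,\mathrm{nm}\big)\) bp —
the bond length beyond the bead radius divided by the rise per base
pair, rounded half away from zero.  Shorter bonds carry no linker and
are excluded from linker means.  The offset convention is exposed as
`bead_offset`; the default (radius, 4.9 nm) is the convention under
which the model bond-length distribution reproduces the canonical
35–45 bp linker range, while `bead_offset = 9.8` counts only length
beyond bead contact.  Genomic coordinates are 1-based and cumulative;
bead \(i\) spans \([s_i, s_i + 146]\).

## Ensemble statistics

**End-to-end scaling and contacts.**  \( \langle R^2(s)\rangle^{1/2}\)
and the contact probability \( \langle C_p(s)\rangle\) (35 nm cutoff)
are accumulated against genomic separation in log-spaced bins (20 per
decade).  Full pair enumeration is \(O(N^2)\); instead each bin draws
a fixed number of stratified random pairs (uniform bead, uniform
side, uniform partner within the bin), which is unbiased within
narrow bins.  Fit windows follow the intra/inter-domain transition
near \(4\times10^4\) bp: intra \([10^3, 4\times10^4]\) bp, inter
\([4\times10^4, 10^6]\) bp at full scale.  In scaled-down ensembles
the confinement plateau moves to smaller \(s\) roughly as
\(R_c^{1/\nu}\), so inter-domain fits use ensembles whose \(R_c\) is
large enough that the window stays below the plateau (the package
generates them at \(\phi = 0.08\), exploiting the documented
insensitivity of these curves to \(\phi\)).

**Density statistics.**  Coordination numbers count neighbours within
11.5 nm.  The chromatin volume concentration (CVC) is measured on a
cubic grid of 120-nm probing volumes centred in the confinement
sphere, crediting each bead's full volume to the cube holding its
centre (the bead diameter is 12 times smaller than the cube edge, so
the boundary error is a few percent).  The pair correlation
\(g(r)\) restricts reference beads to an interior sphere of radius
\(R_c - r_{max}\) so shell normalisation needs no boundary
correction; \(G(r) = \int_0^r 4\pi r'^2 g(r')\,dr'\) is integrated by
the trapezoidal rule, and the packing parameter \(D\) is the log-log
least-squares slope of \(G\) over 40–120 nm.  Per-configuration
\(D_i\) and local volume fraction \(\langle\phi_i\rangle\) are
measured in the same 240-nm sphere centred on the configuration's
centre of mass — a domain-agnostic choice.

**Rendering.**  Density images deposit each bead as an isotropic
Gaussian (\(\sigma = r_o\)) integrated over pixels: slabs are 100 nm
thick at 2 nm/pixel, volumes use 4 nm voxels.  Total deposited mass
equals the bead count up to clipped tails; slab images are normalised
to their maximum, matching how electron-tomography density maps are
presented.

## Packing-domain identification

Rendered slabs are smoothed (Gaussian, 5 px radius), contrast-enhanced
(CLAHE, 120 px tiles; a single-tile equalisation fallback handles
small images), and rescaled to \([0,1]\).  Domain centres are local
density maxima above 10 % of the image maximum, non-maximum-suppressed
within 10 px (these two thresholds suppress noise maxima from finite
sampling and are not part of the published procedure, which leaves
them unstated).  Around each centre an 11 × 11 pixel window of
mass-scaling curves \(M_p(r)\) is averaged, weighted by the density at
each window pixel.  The domain radius \(R_d\) is the smallest radius
at which any of three criteria fires:

1. \(M(r)\) deviates by more than 5 % from the power law fitted on the
   inner 20–60 nm region — applied only when the inner region itself
   obeys a power law to within the same tolerance, otherwise there is
   no relationship to deviate from;
2. the sliding-window local exponent of \(M(r)\) (centred log-log
   difference over 5 bins) reaches 3;
3. the radial CVC profile has a strict local minimum followed by a
   material (≥ 5 %) rise — the rise guard rejects discretisation
   ripples in near-empty tails.

Domains where no criterion fires before the curve ends have undefined
radius and are dropped.  Criteria only fire beyond 20 nm, shielding
the core oscillations.

## What the synthetic data do and do not show

All inputs are generated: the model is its own data source, and the
test suite builds every fixture in code (random flights for scaling
oracles, FCC shells for coordination, uniform clouds for \(g(r)\),
parabolic density domes for domain-radius recovery).  Passing tests
demonstrate internal consistency of the implementation and
reproduction of the model's published summary statistics at reduced
scale; they say nothing about biological chromatin beyond what the
model itself claims, and the domain-finder thresholds have only been
exercised on rendered model slabs and synthetic images, not on
experimental tomograms.  Scaled-down ensembles (the acceptance suite
uses \(N = 5\times10^4\) beads for linker statistics, \(10^5\) for
scaling exponents, \(2\times10^4\) for packing statistics, with
\(R_c\) rescaled to preserve \(\phi\)) reproduce intensive quantities;
extensive ones (total genome length, domain counts per configuration)
scale with system size and are only compared across conditions at
equal size.

## Known limitations

* Single-chain configurations only: no chromosome territories or
  multi-chain nuclei.
* No genomic identity: no A/B compartments, TADs, CTCF or
  cohesin-site placement; the loss of cohesin-mediated loops is
  modelled only as a reduction of \(\alpha\) at fixed \(\phi\).
* The relaxation is a minimisation, not a thermal ensemble: chains are
  zero-temperature packings whose bond-scale fluctuations are set by
  the termination rule, not by a Boltzmann distribution.
* Inter-domain scaling exponents at reduced system size sit below the
  full-scale values whenever the fit window brushes the confinement
  plateau; full-scale runs (\(N \approx 4.7\times10^5\), 1000
  replicates) are supported but take hours, not minutes.
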