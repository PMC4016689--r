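---
title: "Design-based stereology on synthetic phantoms: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Design-based stereology infers three-dimensional quantities — the volume of
a cell layer, the number of neurons it contains, and their individual somal
volumes — from measurements on thin histological sections, using sampling
designs whose unbiasedness depends only on the randomization, not on any
geometric model of the tissue. `stereovol` implements the complete classical
workflow for a two-group animal experiment on a neuronal cell layer (the
motivating setting is the pyramidal layer of the hippocampal cornu ammonis):

* **Cavalieri point counting** for the reference volume,
  `V = t · ΣP · a(p)`, with `t` the distance between sampled section planes,
  `P` the test points hitting the layer and `a(p)` the area per point;
* the **physical disector** for numerical density,
  `Nv = ΣQ⁻ / Σ(a·h)`, counting cell profiles that appear in a reference
  section but not in its adjacent look-up section, inside unbiased counting
  frames of area `a` and height `h` equal to the section thickness;
* total number as the product `N = Nv · V`;
* the **nucleator** on vertical uniform random sections for mean somal
  volume, `v̄ = (4π/3) · mean(l³)`, with `l` the distance from the nucleolus
  to the cell boundary along isotropically weighted rays, corrected for
  tissue shrinkage `s` by dividing each per-cell volume by `(1 − s)`;
* a statistical layer reporting group means, coefficients of variation
  (CV = SD/mean), pooled two-sample t-tests, and a binned comparison of
  somal-size distributions.

Because none of these estimators can be validated on real tissue (the truth
is unknown), every estimator here runs against **synthetic phantoms**:
bounded 3D cell layers whose volume, cell count and somal-size distribution
are known exactly by construction.

## The phantom model

A phantom is an axis-aligned box (µm) containing `n` convex cells — spheres
by default, axis-aligned triaxial ellipsoids optionally — with somal volumes
drawn from a log-normal distribution parameterised by its mean (µm³) and CV.
If `V ~ logN(µ, σ²)`, the equivalent radius `(3V/4π)^(1/3)` is log-normal
too, which keeps every ground-truth moment analytic. Each cell carries a
nucleolus, at its center by default or displaced uniformly within a
configurable eccentricity fraction of the cell. Cells are placed uniformly,
entirely inside the box, under a minimum center-separation rule
(`min_sep_frac` of the summed equivalent radii, default 0.6): neighbours may
overlap moderately, as somata in a packed layer do, but cannot reach one
another's nucleoli. Sequential placement with rejection is used; at the
densities of the default phantoms this departs from strict uniformity only
negligibly, and an infeasible request fails with an explicit packing error.

Ellipsoid cells are axis-aligned rather than individually rotated: an
*aligned* anisotropic population is precisely the situation in which naive
section-plane measurements are biased, so it is the sharper stress test for
the vertical-sections design, and it keeps every section profile an
axis-aligned ellipse with closed-form geometry.

What the phantom deliberately does **not** model: staining, optics,
section compression or loss, curvature of the real layer, or non-convex
somata. Passing tests therefore demonstrate the correctness of the
estimators and sampling designs — not robustness to segmentation error or
histological artefact.

## The virtual microtome

Serial sectioning tiles the box along z with slabs of thickness `t`
(default 2 µm, as for semi-thin plastic sections); slab `i` covers
`[i·t, (i+1)·t)`, half-open so each boundary belongs to one slab. A cell is
present in a slab if its open z-extent intersects the open slab interior —
a sphere exactly tangent to a cutting plane is not credited with a zero-area
appearance. Two profile views are recorded per (cell, slab): the exact
mid-plane cross-section (used for areas) and the largest cross-section the
cell attains inside the slab (the "slab view" the disector sees, since a
profile is visible in a section if the cell enters the slab at all).

Pair sampling is systematic uniform random: the first consecutive pair
starts at a uniform integer in `[0, period)`, subsequent pairs follow every
`period` sections. With 2600 sections and period 200 this yields 13 pairs
for starts 0–198 and 12 for start 199 — the design that motivated the
defaults reports "approximately 13–15" pairs.

For the disector the stack is extended by one empty guard section at each
end (`disector_pair_design`): the microtome cuts past the layer, so the
first and last tissue sections still have adjacent look-ups. Without the
guards, cells whose top profile falls in an end section can never be
counted, and on a scaled phantom (where one slab is a non-negligible
fraction of the stack) this produces a measurable negative bias in `Nv`.
Guard reference sections examine zero layer area and enter neither sum.

Vertical sections: the box is split into bars, each bar receives an
independent uniform azimuth in `[0, π)` about the fixed vertical axis (z),
and is cut serially along the rotated horizontal normal, so every section
plane contains the vertical direction as the design requires.

## Estimator details and numerical choices

**Point counting.** The test grid has spacing `s` with a uniform random 2D
offset in `[0, s)²` and optional rotation. Points on the region boundary
are resolved by a half-open rule (a point on a "left/bottom"-type edge
counts, on the opposite edge it does not) so that tiling the plane with
congruent regions counts every grid point exactly once; an axis-aligned
square of side `k·s` aligned with the grid scores exactly `k²`.

**Coefficient of error.** The CE of a systematic count sequence uses the
Gundersen–Jensen smoothness-class m = 1 estimator with the point-counting
nugget: `noise = 0.0724 (b/√a) √(nΣP)`,
`totalvar = (3(A − noise) − 4B + C)/240 + noise`, `CE = √totalvar / ΣP`,
with `A = ΣPᵢ²`, `B = ΣPᵢPᵢ₊₁`, `C = ΣPᵢPᵢ₊₂`. The profile shape factor
`b/√a` defaults to `2√π`, the value for circular profiles. Two numerical
notes: the systematic term is clamped at zero when the finite-sequence
expression goes negative, and a perfectly constant sequence retains the
covariogram end effect `2c²/240` — i.e. `CE = √(2/240)/n`, which vanishes
as the number of sections grows but is not identically zero.

**Counting frame.** The frame's forbidden line is the classical one: it
descends from infinity along the left edge line, runs along the bottom
edge, and drops to infinity below the bottom-right corner; the top and
right edges admit. A profile is counted iff it intersects the frame and
does not touch the forbidden line (tangency counts as touching). With this
rule a tiling of frames counts every convex profile exactly once — a
property the test suite verifies on random ellipse fields. Profile identity
across the two sections of a disector is resolved by cell id (the phantom
knows it); matching by centroid proximity, as needed for imported real
data, is out of scope here.

**Nucleator.** Rays are measured in the vertical plane through the
nucleolus itself (not the slab mid-plane): this makes a centred-nucleolus
sphere exact per cell, `v = (4/3)πr³` to machine precision, and mirrors the
practice of focusing the measurement at the nucleolus. The in-plane angle
`α` to the vertical axis is drawn sine-weighted (`P(α) ∝ sin α`), which
together with the random azimuth renders the ray directions isotropic in
3D; each direction is paired with its antipode (one "bidirectional" pair by
default, configurable). Dropping the sine weighting is available as a
deliberate negative control: on aligned flattened ellipsoids it produces a
~20% bias that the test suite requires to be *detected*. Cells are sampled
by disector selection on the vertical sections, so sampling is
number-weighted; each disector event is kept as a distinct sampling item —
collapsing a twice-hit cell into one item would make inclusion probability
depend on the cell's extent modulo the period and bias the size
distribution.

**Shrinkage.** Tissue shrinkage is simulated by scaling every cell about
its center by a volume factor `(1 − s)` before the vertical arm is
measured, and corrected by dividing per-cell volumes by `(1 − s)` — the
correction the glycolmethacrylate arm of the motivating design applies with
`s = 0.15`. The Cavalieri arm is left uncorrected, mirroring the asymmetric
treatment of the two embeddings. Fresh volumes derive from weight via
1.04 cm³/g.

**Degenerate inputs.** Zero-thickness plans, zero-extent regions, empty
phantoms, odd ray counts, nucleoli outside cells, mixed `a(p)` or `t`
across records, and shrinkage ≥ 1 all raise immediate errors; zero counts
propagate as zero estimates; a t-test between two zero-variance groups with
equal means returns `p = 1` by convention.

## The simulated study and its conditions

`run_study()` draws one phantom per animal (two balanced groups), runs both
arms on every animal, and reports the four parameters in a table mirroring
the conventional layout ("mean (CV)" per group plus a pooled t-test
p-value). All randomness descends from one master seed through
hierarchically derived child seeds, so a report is byte-reproducible.

The default conditions are a deliberate scale model of the motivating rat
study, chosen once: 500-cell phantoms in a 192 × 192 × 160 µm box — the
numerical density (≈ 85 × 10³/mm³) and mean somal volume (3600 µm³, CV
0.25) match the reference magnitudes while the absolute size stays
tractable; 2 µm sections with period 6 over ~82 slabs giving 13–14 pairs;
counting frames tiling the footprint so the summed disector count lands in
the conventional 100–200 design window (CE < 0.10); ~100 cells measured per
animal with one bidirectional ray pair; 15% applied and corrected
shrinkage; 8 animals per group with 7% between-animal CV (the magnitude of
typical between-animal CVs in such reports); and a treated condition with somal
volumes ×0.85 and layer volume ×0.92 at unchanged cell number — the
headline effect structure. The type-I calibration study uses a further
reduced model (4 animals per group, 120-cell phantoms, 1000 simulated
studies), sized so a thousand full pipeline replicates remain cheap while
the t-test still operates on genuine end-to-end estimates.

## Known limitations

* The ratio form of a *single-direction* disector estimate on one finite
  stack carries a small bias (the number of in-tissue reference sections
  varies with the random start while tops are depleted near the layer
  faces); the default pools both directions, which is verified unbiased.
  Single-direction estimates are exposed for inspection, not recommended.
* RSA cell placement is not perfectly uniform at high packing fractions.
* Between-animal variability multiplies mean somal volume and layer volume
  log-normally but keeps the cell count at the group value; count
  variability between animals enters only through volume jitter.
* No section compression, loss, over-projection, or profile-matching error
  is modelled; estimator performance under those artefacts is untested.
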