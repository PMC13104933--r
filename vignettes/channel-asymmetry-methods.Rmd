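---
title: "Methods: sidechain dynamics, pore hydration and proton flux in designed pentameric channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sidechain dynamics, pore hydration and proton flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poresym)
```

# The scientific problem

Designed pentameric helical bundles conduct protons through a narrow pore
lined by a ring of five glutamines (and, in more polar variants, serines).
Conduction proceeds by Grotthuss shuttling along transient hydrogen-bonded
water wires, so the quantities that matter are not static structure but the
*dynamics* of the polar ring: which rotameric states the Gln sidechains
sample, whether the five chains move in concert or independently, how
hydrated the pore is, and how residues and waters wire up into
hydrogen-bond networks. `poresym` implements that analysis chain for
labelled multi-frame coordinate data, together with the liposomal
proton-flux assay computation used to measure conduction, and a synthetic
generator that makes every stage testable against exact ground truth.

# Trajectory model and orientation

Trajectories are long-format atom tables (frame, chain, residue, atom,
x/y/z in Angstrom) with a fixed frame spacing `dt` in picoseconds; frames
are numbered from 0. Readers accept multi-model PDB and a plain CSV frame
table; an identical atom roster across frames is enforced at construction
so that every downstream per-frame operation is well defined. Binary MD
formats are out of scope: the analysis needs only labelled coordinates, and
converters are a user concern.

All geometry is measured in a frame where the pore runs along +z.
`orient_pore_axis()` makes that explicit rather than assumed: per frame,
the principal axis (largest-variance eigenvector) of the C-alpha covariance
is rotated onto +z and the selection centroid moved to the origin. The sign
convention places the N-terminal side up (+z points from the residue-22
C-alpha centroid towards residue 5's); both anchors are configurable. The
operation is idempotent and rigid, which the tests check on random rigid
placements. The in-plane rotation is deliberately left free - nothing
downstream depends on it.

# Sidechain orientation, states, and the symmetry statistic

For a pore-lining Gln the orientation vector runs from its C-alpha to its
NE2 amide nitrogen (Gln has no "NE"; NE2 is the sidechain amide nitrogen in
PDB nomenclature). Its signed z-offset is measured against the plane
`z = mean z` of the five Gln C-alpha atoms of that frame. A least-squares
plane would add complexity without changing results at the precision that
matters here, because after orientation the five C-alpha atoms of a
near-symmetric bundle are nearly coplanar and normal to z.

z-offsets are classified into three states with half-open intervals:

* down: `z < 0`
* neutral: `0 <= z < t_high`
* up: `z >= t_high`

The default `t_high` is 2.5 Angstrom, with 2.4 exposed as the common
alternative; the boundary assignment is a measure-zero convention made
explicit for reproducibility. The pairwise state-agreement matrix is the
per-chain-pair fraction of frames in which both chains occupy the same
state, pooled over all supplied replicates (frames are concatenated before
averaging). It is symmetric with unit diagonal; for independent chains with
marginal state probabilities p the off-diagonal entries converge to
`sum(p^2)`, which the tests verify at 30,000 pooled frames.

# Rotamer dihedrals, clustering, and background contours

chi1 (N-CA-CB-CG) and chi2 (CA-CB-CG-CD) are signed IUPAC torsions computed
with the atan2 formulation and checked against an independently coded
oracle to 1e-9 degrees on random geometries. Clustering uses DBSCAN on the
4-dimensional embedding (sin chi1, cos chi1, sin chi2, cos chi2) so the
+-180 degree seam is continuous; `eps` is stated in degrees of arc and
converted to the equivalent chord `2 sin(eps/2)` per angle. DBSCAN is
implemented in-package from the textbook region-query algorithm (no
density-clustering package ships with the supported stack); defaults are
`eps = 20` degrees and `min_samples = max(10, 0.5%)`, which separate
clusters tens of degrees apart while absorbing thermal jitter. Cluster
labels are reported in descending membership order, and the fraction table
reports both conventions for the denominator (noise included and excluded)
because published cluster percentages rarely say which one they use.

The background contour map is a 2-D Gaussian KDE on the torus: reference
(chi1, chi2) points are replicated at +-360 degree shifts within a margin,
bandwidths follow Scott's rule, and the returned thresholds are
highest-density-region levels enclosing 70% and 90% of the reference
probability mass (the (1-p) quantile of the density evaluated at the
reference points). A Monte-Carlo oracle on fresh samples checks the
enclosed mass to +-0.03.

# Pore region, hydration, and hydrophobic length

The pore volume is approximated by the convex hull of the C-alpha atoms of
residues 5 and 22 on all five chains - ten points forming a pentagonal
prism in an ideal bundle. The hull is represented by supporting planes
enumerated over all point triplets (exact for ten points, tolerant of the
coplanar pentagonal faces), and membership is closed: a water whose oxygen
lies on the hull is inside. Waters are identified by residue name
(configurable set: HOH/SOL/TIP3/WAT) with the oxygen as positional proxy.

Per-frame counts feed three analyses:

* **Residence times.** Maximal runs of consecutive inside-frames per water;
  duration = run length x dt. Intervals touching the first or last frame
  are censored and flagged, not dropped.
* **Density profiles.** Per-frame z histograms (counts per Angstrom, so the
  integral equals the per-frame water count), averaged over frames,
  smoothed with a Savitzky-Golay filter (window 11 bins, order 3,
  configurable) and differentiated twice by central differences. Smoothing
  before differentiation is a necessity, not a refinement: second
  derivatives of raw histograms are noise-dominated.
* **Hydrophobic length.** Inflection points are the sign changes of the
  smoothed second derivative (linearly interpolated between bins). A gap
  between consecutive inflection points counts as hydrophobic when its
  interior mean density is below 25% of the profile maximum (configurable);
  the effective hydrophobic length is the longest qualifying span. The
  low-density criterion is needed to exclude fully hydrated segments
  between incidental inflections; analytic sum-of-logistic fixtures with
  known inflection positions verify recovery within one bin width.

Wet/dry pooling uses a hysteresis rule: scanning frames in order, the state
becomes wet at the first frame with n >= 10 waters and stays wet until a
frame with n <= 1, and vice versa; intermediate counts inherit the current
state, and intermediate frames before any crossing are labelled
`transition` and excluded from wet/dry pooled statistics. The hysteresis
reading absorbs small fluctuations around the wet threshold; excluding the
pre-crossing ambiguous band is the conservative choice.

# Hydrogen-bond networks

Geometric criteria: donor-acceptor heavy-atom distance <= 3.5 Angstrom
plus, when a donor-bound hydrogen exists, a D-H...A angle >= 150 degrees.
Hydrogen-free inputs (common for coarse fixtures) are evaluated
distance-only and flagged. Chemistry is restricted to the atoms that matter
in this pore: Gln NE2 (donor) and OE1 (acceptor), Ser OG (both), backbone
carbonyl O (acceptor), water O (both).

Two residues interact in a frame when a path in the bond graph connects
them through at most five interior waters; the bridge length is the
minimum interior count (0 = direct). The search is a breadth-first
expansion through water nodes only, checked against brute-force path
enumeration on random graphs. Network edges aggregate a frame window
(default: the second half of the run): occupancy is the fraction of window
frames with the interaction, edges under 10% occupancy and nodes outside
the residue 6-20 core are dropped, and `mean_bridge_waters` averages the
per-frame minimum bridge length over frames where the edge exists (the
aggregation rule is stated in the output because published "average
bridging waters" figures rarely define it). Interaction-type fractions
classify each bond touching a pore-facing sidechain atom by its endpoint
types over {Gln, Ser, water}; water-water bonds are not counted.

# Proton-flux assay computation

The ratiometric HPTS calibration is
`pH = -log10(A * B^Ratio - 1)` with published constants `A = 8.959e-8`,
`B = 1.185`, valid for pH 3-9. Calibration fitting is least squares in
Ratio space (the measured quantity), Levenberg-Marquardt, initialised at
the published constants. The buffer correction adds protons bound to
monobasic phosphate, `H_total = h + P * h / (Ka + h)` with `h = 10^-pH`,
`Ka = 6.31e-8` and `P = 0.03` M - the only chemically standard reading of
the published correction consistent with its symbol definitions; phosphate
is treated with a single effective pKa. The free-proton limit (`P = 0`) and
half-saturation (`bound = P/2` at `h = Ka`) are closed-form checks, and an
independently coded Henderson-Hasselbalch speciation oracle agrees to
1e-12 relative.

Two numerical points deserve emphasis:

* These constants make the calibration extremely stiff: the whole pH 3-9
  range maps to Ratio values between 95.6480 and 95.6544, so a
  double-precision ratio resolves pH only to about `1e-15 / 10^-pH` units
  (~3e-8 at pH 7.5, ~1e-6 at pH 9). The conversions use `expm1`/`log1p` to
  reach that conditioning limit, and the tests assert the
  conditioning-derived bounds rather than pretending to more precision
  than a double can carry.
* ΔpH traces subtract the mean of all pre-valinomycin points (the baseline
  definition is otherwise ambiguous).

Initial rates are ordinary least-squares slopes of `H_total` versus time
over `(t_val, t_val + 60 s]`, closed on the right, with the buffer
correction applied point-wise before fitting. With the standard 10-s
sampling this window holds 6 points; the fitted slope's standard error
therefore carries 4 degrees of freedom, and a +-2 SE interval covers the
truth in only ~88% of repetitions (the t(4) value) - a property worth
remembering when comparing recovery claims against nominal 95% coverage.
Technical triplicates are averaged point-wise before fitting; biological
replicates are the statistical units. Variants are compared by one-way
fixed-effects ANOVA with Tukey HSD post-hoc tests (`stats::aov` /
`stats::TukeyHSD`; the test suite re-derives F from hand sums of squares
and checks the two-group Tukey p against the pooled t-test identity). The
degenerate all-identical input returns F = 0 rather than 0/0.

# The synthetic-data generator

`generate_trajectory()` builds an ideal C5-symmetric scaffold: five
straight chains of 25 residues on a circle of radius 8 Angstrom, 1.5
Angstrom rise per residue, pore along z, N-terminal side up. Each frame's
scripted state (explicit script or a Markov chain with stay probability
0.98 per frame, mimicking slow rotamer switching) is realised by an ideal
Gln sidechain built in internal coordinates: chi2 is fixed per state, chi1
is solved numerically so the NE2 z-offset hits the state's target exactly,
and the solved chi values are recorded as ground truth so the dihedral and
clustering stages are testable too. Default targets are -1.0 / 1.2 / 3.3
Angstrom for down / neutral / up - generator defaults motivated by reported
per-variant means in this design family, not assertions about any specific
system - and the generator's validator requires every target to clear the
classification thresholds by at least 0.5 Angstrom so scripted states are
recovered exactly at zero noise. Waters follow an explicit
interval schedule: inside the pore they sit near the axis (+-1 Angstrom
jitter, uniform z inside the anchor range), outside they are parked more
than 10 Angstrom beyond the hull, so membership is unambiguous by
construction. Optional scripted bridges place chains of waters between two
chains' Gln amide atoms at spacings under the bond cutoff. Gaussian
positional jitter and all stochastic choices run on a private seeded RNG
stream, making outputs byte-identical for a fixed spec.

`generate_flux_traces()` scripts
`pH(t) = pH0 - a (1 - exp(-(t - t_val)/tau))`, maps it through the inverse
calibration to a ratio, carries multiplicative ratio noise on the F460
channel, and reports the analytic ground-truth rate as the OLS slope of the
exact `H_total` at the window's sample points. The default ratio noise s.d.
is 1e-10 - tiny in ratio units precisely because of the calibration
stiffness described above; it corresponds to ~0.02 pH units of scatter,
typical for this assay class.

What the generator does *not* emulate: forcefield physics, realistic water
exchange kinetics, correlated sidechain-water motion, bleaching or drift in
the fluorescence channels. Passing tests therefore demonstrate that the
analysis chain computes its defined quantities correctly, not that those
quantities behave on real MD or plate data exactly as they do here.

# Problem sizes and runtime choices

The test suite and the acceptance script use the study's bookkeeping scale
where it is cheap (three replicates of 1,000 frames at 200 ps for the frame
accounting; 30,000 pooled frames for the agreement limit; 100 seeded plates
for rate-recovery coverage) and smaller trajectories (tens to hundreds of
frames, a few waters) for geometric fixtures, keeping the whole suite in
well under a minute of compute per module. The analysis scripts under
`analysis/` run two archetypes at 500 frames x 3 replicates; all sizes are
package choices and scale linearly if raised.

# Known limitations

* Periodic-boundary imaging is not performed; inputs are assumed
  whole-molecule with the protein centred.
* The pore region is anchored to two residue rings; strongly tilted or
  broken helices would need a different region definition.
* Hydrogen-bond detection has no energetic or orientation-dependent
  scoring beyond the distance/angle criteria.
* Density profiles are per unit length along z within the pore region, not
  per volume; the two differ by the (roughly constant) cross-section.
* The calibration's numerical stiffness (above) bounds any pH round-trip
  accuracy at roughly 1e-6 near the alkaline end of the range.
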