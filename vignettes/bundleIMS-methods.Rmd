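---
title: "Methods: IM-MS characterization of DNA helix-bundle assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IM-MS characterization of DNA helix-bundle assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundleIMS)
```

## The system and the measurement

A six-helix-bundle (6HB) DNA nanostructure assembles from six 50-mer
oligonucleotides (labelled I-VI) arranged on a cycle: each strand pairs
with its two cyclic neighbours over 21-bp duplex regions, so the six
duplexes close into a barrel. Native ion mobility-mass spectrometry
(IM-MS) characterizes this assembly along three axes:

* **mass** - which oligomeric species exist (monomer through hexamer,
  plus 12-mer and 18-mer multimers), resolved through their charge-state
  series;
* **abundance** - how the species distribution shifts with the ionic
  strength of the ammonium acetate (AmAc) buffer;
* **shape** - collision cross sections (CCS) from calibrated drift
  times, compared against calculated CCS of candidate bead-model
  geometries.

`bundleIMS` implements each stage as a testable unit plus an end-to-end
pipeline, and ships a synthetic data generator so the whole chain can be
exercised, with known ground truth, on a laptop.

## Mass chemistry

Strand masses are average (chemical) masses: at 15 kDa and above the
isotope envelope is unresolved on a native-MS instrument, and the
reported masses in this regime are averages. The elemental composition
of a strand is the sum of 2'-deoxyribonucleoside-5'-monophosphate
residues minus one water per internal linkage, adjusted for the declared
5'/3' terminal state (phosphate or hydroxyl; the difference is one HPO3,
79.98 Da). Atomic masses come from a single embedded table (IUPAC 2021
abridged standard atomic weights); a monoisotopic table is available
behind a flag. The proton is fixed at 1.00728 Da.

Cation adducts (Na+, K+, NH4+) replace a backbone proton: they shift
mass (+21.98 Da for sodium) without changing the charge bookkeeping.
Registered neutral losses cover the terminal phosphate, adenine, and an
adenosine unit - the last in both a nucleoside and a nucleotide reading,
because an observed "adenosine loss" mass shift does not distinguish
them; neither is asserted as the canonical interpretation.

Because the design's strand sequences live in supplementary material not
shipped here, the package carries six *synthetic surrogate* 50-mers
(`surrogate_strands()`, also under `inst/extdata/`) that reproduce the
published mass regime. The strand-I surrogate's base composition
(A15 C6 G5 T24, one terminal phosphate) reproduces the published
calculated mass of 15,397.98 Da exactly - average mass depends only on
base composition, not order, so any quantity derived from masses is
unaffected by the (unknowable) sequence order.

## Assembly combinatorics

On the cyclic connectivity map, any partial assembly is a contiguous run
of strands. For the 6-cycle there are exactly six distinct k-mers for
every k < 6 (one per starting strand - e.g. six distinct trimers) and a
single closed hexamer once rotations are identified; 31 species in all,
plus ring multimers (12-mer, 18-mer) built from whole hexamers. The
pentamer is deliberately a first-class enumerable species: its absence
in measured spectra is the data-level signature of positive binding
cooperativity, so the analysis must be able to report a zero for it
rather than excluding it by construction.

## Synthetic IM-MS data

`simulate_dataset()` renders a 2-D (m/z x drift) intensity grid from an
abundance scenario, a species table and a spectrum configuration, and
returns it together with its full ground truth. The generator emulates
the statistical structure of native IM-MS spectra of this system:

* **Narrow integer charge-state envelopes.** Each species' charge
  distribution is a discretized Gaussian over round(center) +/- 2 whose
  center scales with the square root of mass, anchored at 16+ for the
  ~92 kDa hexamer; this reproduces the observed narrow native envelopes
  (monomer ~6-7+, hexamer 14+ to 18+ with mode 16+) without a physical
  electrospray model.
* **Sodium-adduct tailing.** Adduct counts are Poisson distributed
  (default mean 1.0), each adduct adding 21.98 Da.
* **Drift times from ground-truth CCS.** The truth CCS is reduced for
  charge and reduced mass and pushed through the *inverse* of a
  travelling-wave power-law calibration (default A = 750, B = 0.55,
  chosen to place all species at realistic millisecond drift times);
  zero-noise data therefore round-trip exactly through the calibration
  stage.
* **Salt-dependent abundances.** The `"assembly"` preset interpolates
  per-order fractions smoothly in AmAc concentration (20-1000 mM): small
  oligomers decay monotonically with salt, the hexamer becomes the
  single dominant species above ~200 mM and exceeds 70 % of total
  intensity above 700 mM, ring multimers appear as minor high-salt
  species, and the pentamer fraction is identically zero. The logistic
  midpoints/widths (240/65 mM for the small-oligomer envelope, 280/110
  for the multimer onset) were tuned once against those stated
  behaviours and are not free parameters of any test.
* **Surrogate true CCS.** The species table defaults to the published
  experimental values for monomer, hexamer, 12-mer and 18-mer (4457,
  4740, 7545, 9578 square Angstrom); orders 2-4 continue the
  monomer-to-tetramer near-linear trend with an increment of 160 square
  Angstrom per subunit, chosen so the extrapolated order-6 value lies
  ~10 % above the barrel - the qualitative gap the compaction index is
  designed to measure.
* **Noise.** Additive Gaussian, clipped at zero; no heteroscedastic
  model. This supports signal-to-noise-controlled tests but does not
  emulate detector saturation or chemical background.

What passing tests on these data do *not* show: correctness on real
vendor data (peak shapes are exactly Gaussian here), robustness to
isotope structure or to non-contiguous aggregates, or any claim about
real charge-state intensity ratios (the synthetic envelopes are
shape-plausible only).

## Spectral analysis

**Peak picking** finds 8-neighbourhood local maxima above `min_snr`
times a robust noise scale. The noise scale is the median of the
positive grid cells divided by 0.6745 - the median of a zero-clipped
Gaussian floor when signal occupies few cells. The default `min_snr = 8`
sits above the expected extreme (~5-6 sigma) of pure Gaussian noise over
a megacell grid. Areas come from local integration: every above-noise
cell is assigned to its nearest retained peak in merge-radius-scaled
coordinates.

**Series detection** visits anchor peaks in decreasing area order, tries
every candidate charge, predicts companion m/z values at neighbouring
charges, and keeps the longest consistent run (ties broken by the
variance of the per-member deduced masses). Two safeguards matter in
this system, where the 6-, 12- and 18-mers are exact mass multiples of
each other and their series alias heavily in m/z:

* **Drift monotonicity.** One species at fixed CCS drifts faster the
  more charge it carries, so along a genuine series drift must fall as z
  rises. This rejects chimeric series gluing members of different
  species - m/z alone cannot, by the mass-multiple degeneracy.
* **An absolute m/z tolerance floor** (default 2.5 Th) alongside the ppm
  tolerance, because centroids from a gridded profile are quantized to
  the grid pitch; at low m/z a ppm-only tolerance falls below the pitch
  and true companions are missed.

**Assignment** matches each deconvolved mass against the species table
on a continuum: unresolved sodium satellites merge into the centroid and
shift the apparent mass upward by a *fractional* number of adduct
masses, so the match is against [mass, mass + max_adducts x 21.98 Da]
within tolerance. Ties are always reported in full - both the candidate
compositions within an order (the six trimers are near-degenerate by
construction) and multi-order matches - and never silently resolved.

**Quantification** sums member-peak areas per uniquely-assigned order
and normalizes to 100 %. Peaks overlapping in m/z but separated in drift
were never merged (picking and series membership both operate in two
dimensions), so mobility does the disentangling, as in the measurement
protocol this mirrors. Multi-order series are excluded from the
percentages and listed.

## CCS calibration

The travelling-wave protocol: measured drift times are corrected for
m/z-dependent flight time (t' = t - c sqrt(m/z)/1000, c defaulting to
1.41 and always instrument-specific), reference CCS of calibrant
proteins are reduced for charge and reduced mass in the drift gas (N2 by
default), and ln(reduced CCS) is fit on ln(t') by unweighted least
squares, giving the power law Omega' = A t'^B. Applying the fit inverts
the reduction; uncertainty propagates the residual spread on the log
scale; analytes outside the calibrant t' range are flagged, not
rejected. The shipped default calibrant table names the conventional
protein standards (beta-lactoglobulin through glutamate dehydrogenase,
18-336 kDa) but its reference CCS column is a synthetic stand-in
following the globular scaling 2.435 M^(2/3): published reference values
are not reproduced here, and any real analysis must supply a measured
table. The table carries a gas tag so users state the convention.

## Bead models

Geometries are coarse-grained: three beads per nucleotide (phosphate,
sugar, base) on an ideal B-form helix (rise 3.38 Angstrom, twist 34.3
degrees, backbones 154 degrees apart), six duplexes per barrel with
axes on a circle of radius s / (2 sin(pi/n)) at inter-axis spacing
s = 22 Angstrom (helix diameter plus 2 Angstrom; not a measured value,
deliberately exposed), 4-thymidine loops as four-bead arcs bridging
adjacent helix ends at alternating barrel ends, and uniform 2.9 Angstrom
collision radii with no probe-gas correction factor.

One calibration step replaces the atomistic modelling pipeline this
stands in for (Web-3DNA construction, MD relaxation): a three-bead chain
leaves see-through gaps that an all-atom surface does not have, so the
radial bead placements (9.8/7.4/4.8 Angstrom) were set once so that the
assembled 6HB barrel's projection-approximation CCS reproduces published
atomistic PA values, and are then used unchanged for every other
geometry - the 12- and 18-helix predictions inherit the calibration
rather than being fit. This idealized-geometry substitution is the
package's main fidelity limitation: no sequence specificity, no
energy minimization, no backbone relaxation.

The **squish** transform emulates lateral gas-phase compaction of
hollow barrels. For 12 or more helices the axes move to a stadium
("cigar") cross-section whose rounded caps are 3-helix arcs with the
curvature of the 6-helix ring and whose straight segments carry the
remaining helices, all cyclically adjacent spacings preserved exactly.
That construction degenerates to the unchanged ring at n = 6, so the
6-helix case instead uses a spacing-preserving hinge fold of the hexagon
of axes, controlled by a flatten ratio (1 = ring; 0.5 = two staggered
close-packed rows of three). The default, 0.53, was calibrated once to
the ~4 % PA reduction reported for mildly compacted hexamer models - the
displacement magnitude used in the original interactive modelling is not
published, so the package pins it to the published *outcome* instead.

## CCS computation

* **PA** (projection approximation): for each orientation, the projected
  area of the hard-sphere beads is estimated by uniform rejection
  sampling over the bounding rectangle; the CCS is the orientation
  average.
* **EHSS** (exact hard-sphere scattering): parallel trajectories reflect
  specularly off the spheres (first entry intersection from outside;
  spheres containing the current point are interior to the union and
  ignored; at most 30 bounces), each trajectory weighted by its momentum
  transfer 1 - cos(total deflection). Hit points are snapped back onto
  the sphere surface and the direction renormalized after every
  reflection - without this, sub-nanometre off-surface errors amplify
  multiplicatively along deep bounce chains in concave pockets. EHSS
  equals PA on a single sphere and exceeds it on concave bodies.
* **TJM rescale**: a recorded deterministic transform
  scale x PA^exponent with user-supplied coefficients; no default is
  shipped because published recalibrations are tool-specific, and the
  package makes no claim of reproducing trajectory-method or EHSS
  columns of published tables - PA is the comparable quantity.

Orientations default to a spherical Fibonacci lattice randomly rotated
as a whole by the seed ("quasi-uniform sphere point picking"). The
lattice integrates the smooth orientation dependence far more
efficiently than independent draws: on the barrel models the
ring-vs-squished PA difference is stable to ~0.01 percentage points
across seeds at 1000 orientations, where independent sampling still
scatters by half a point. The reported standard error treats
orientations as independent and is therefore conservative under the
lattice. Every `ccs_result` records method, sampling counts, seed and
radii set, and is bit-reproducible from them; the RNG is a private
Mersenne Twister keyed by the seed, independent of R's RNG state.

Default sampling is 300 orientations x 10^4 samples (seconds per barrel
model, relative SE well under 1 %); validation tests use a deterministic
0.1-Angstrom rasterization oracle on models of up to 50 beads, and the
acceptance script uses 2000 x 2 x 10^4 on the 780-bead barrels.

## Interpretive stage

The size trend fits an unweighted line to CCS over oligomer orders 1-4
(unweighted because the trend this mirrors is stated visually, without
per-point uncertainties; a weighted option exists). Extrapolating to
order 6 and comparing with the observed barrel CCS gives the compaction
index (predicted - observed)/predicted - the fractional shortfall of the
closed barrel below the open-sheet trend. Model comparison reports
signed percent differences and a rank for every candidate geometry and
flags one-sigma-consistent candidates; it never auto-selects a winner,
because the gas-phase-compaction interpretation is an argument over the
whole ranked table, not a single best hit. Cooperativity is reported as
a boolean signature (order-5 fraction below 1 % of total), matching the
qualitative character of the claim it encodes.

## Numerical and interface choices

* Display rounding is 2 decimals for masses and integers for percent
  differences; all comparisons use full precision internally with a
  default 0.25 Da absolute tolerance for intact-strand masses.
* Ring multimer species (12-mer/18-mer) are modelled as whole-ring
  multiples; non-contiguous aggregates are out of scope, mirroring the
  contiguity assumption of the design.
* The pipeline derives all stage seeds from one master seed and its
  written reports are byte-identical across reruns; logs carry every
  parameter.
* The package's interface is its functions, the YAML-configurable
  `run_pipeline()`, and this vignette; no shell entry point is shipped,
  as the expected user drives analyses from R.

## Problem sizes

The shipped tests run the full chain at reduced but non-trivial sizes:
synthetic grids of ~1-2 million cells, twenty seeded abundance-recovery
replicates at signal-to-noise 20 or better, CCS estimates at 40-400
orientations in unit tests and 2000 in the acceptance script. These
sizes keep the whole suite in the minutes range on one CPU while leaving
every Monte Carlo check at least three standard errors away from its
decision boundary.
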