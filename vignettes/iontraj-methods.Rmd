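---
title: "iontraj: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{iontraj: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iontraj)
```

# Scope

`iontraj` analyses molecular-dynamics trajectories of cation-bound
P-type ATPase intermediates — the motivating system is SERCA, the
sarcoendoplasmic reticulum Ca^2+^ pump, in its Mg^2+^- and K^+^-bound E1
states — and characterises:

* metal-ion **coordination numbers** (oxygen neighbours within a
  species-specific cutoff) and their population distributions;
* **ion–ligand distance tables** with bonding filters;
* **binding-event timing** and entry-pathway (TM1 gateway) contact order;
* a nonbonded **interaction-energy estimate** (Coulomb + 12-6 LJ);
* side-chain **χ~2~ dihedral classification** (lumen- vs cytosol-facing
  carboxylates, e.g. the gating glutamate E309);
* per-domain **RMSD/RMSF** with explicit alignment semantics and the
  **axial rotation** of the actuator domain about the membrane normal;
* **interdomain Cα–Cα distance distributions** of the cytosolic headpiece
  with one/two-component Gaussian decomposition and crystal anchors.

Microsecond production trajectories cannot be regenerated at desk scale, so
the package ships a seeded synthetic-trajectory generator whose presets
encode the published summary statistics as *ground truth*; every analysis
stage is then validated by parameter recovery against a manifest.

Units are nm and µs everywhere inside the package; PDB Ångströms are
converted only at the file boundary. This removes mixed-unit bugs in
cutoffs such as 0.21 nm.

# Models and conventions

## Coordination numbers

For an ion at position $\mathbf{x}_I(t)$, the coordination number is the
count of oxygen atoms (protein *and* water — real Mg^2+^ shells contain
waters) with $|\mathbf{x}_O - \mathbf{x}_I| < r_c$, strictly. Cutoffs
$r_c$ are 0.21 nm (Mg^2+^) and 0.30 nm (K^+^). Bonding in the ligand
table applies the same thresholds (plus 0.25 nm for Ca^2+^) to the *mean*
distance: a mean at or above the threshold is non-bonding, matching the
convention of removing non-bonding rows from published tables. Per-frame
standard deviations are reported (not block averages).

## χ~2~ classification

χ~2~ is the Cα–Cβ–Cγ–Cδ torsion (IUPAC sign convention, range
(−180°, 180°]). The published integer windows leave (−40°, 40°), ±(119°,
120°) unassigned; we adopt the continuous reading **lumen**: |χ~2~| ≥
120°, **cytosol**: 40° ≤ |χ~2~| < 120°, **unclassified**: |χ~2~| < 40°,
and report the unclassified fraction explicitly rather than absorbing it.
Occupancies are percentages of *all* frames, so the three fractions sum
to 100.

## RMSD and RMSF

Superposition is the closed-form least-squares (Kabsch/SVD) rotation with
reflections excluded. `rmsd_series()` aligns each frame on an alignment
selection (default: TM backbone, where backbone = N, CA, C, O) and then
evaluates the RMSD of the analysed selection *without re-fitting*, so
rigid-body displacement of a cytosolic domain relative to the membrane
frame is captured — this is what produces the large (0.4–0.7 nm) plateau
values seen for domain motions; a per-domain self-fit mode is available
behind a flag for internal-deformation-only curves. Backbone atoms are
used for the cytosolic domains (the choice is flagged; all-heavy-atom
analysis can be selected explicitly). RMSD/RMSF are mass-unweighted.

`rmsf()` aligns to an iteratively re-estimated mean structure (two
passes — deterministic, standard practice) and reports
$\sqrt{\langle|\mathbf{x}_i - \bar{\mathbf{x}}_i|^2\rangle_t}$ per atom.
For isotropic per-axis jitter of sd σ the expectation is $\sigma\sqrt3$,
which is the identity the synthetic site preset uses to state its RMSF
ground truth.

## Axial rotation

The actuator-domain rotation is measured as the best-fit in-plane rotation
about a fixed axis (default +z, the membrane normal): after removing
centroids, $\theta = \operatorname{atan2}\!\big(\sum \hat{a}\cdot(\mathbf
r_i\times\mathbf f_i),\ \sum \mathbf r_i\cdot\mathbf f_i\big)$ over the
components perpendicular to the axis; counter-clockwise positive viewed
from +axis.

## Headpiece distance distributions

Interdomain geometry is tracked by three Cα–Cα marker pairs: K515–T171
(N–A), R489–E680 (N–P), T171–E680 (A–P). The distance distribution
ρ(R) is a normalised histogram (default bin width 0.05 nm, range padded
by one bin). One- and two-Gaussian models are fitted by **nonlinear least
squares to the histogram density at the bin centers**, not by maximum
likelihood, because the reported fit-quality statistic is a correlation
coefficient between fitted and empirical density — a curve-fit
diagnostic. Initialisation is deterministic (order 1: histogram
mean/sd; order 2: weighted 25th/75th-percentile means, equal weights),
optimisation is bounded L-BFGS-B on transformed parameters (log sd, logit
weight) with a Nelder–Mead fallback; components are always reported
sorted by mean, so labels never switch.

Model choice is an explicit two-part rule: order 2 is selected only if its
correlation coefficient beats order 1 by ≥ 0.01 *and* the component means
are separated by more than the larger component sd; ties go to order 1
(parsimony). The published r thresholds (≥ 0.97 / ≥ 0.99) describe fit
quality and are not used as a decision rule.

## Interaction energy

`interaction_energy()` sums, per frame and partner atom, the Coulomb term
$332.0636\, q_i q_j / (\varepsilon_r r_{\text{Å}})$ and a 12-6
Lennard-Jones term with Lorentz–Berthelot combining (geometric ε,
arithmetic $r_{\min}$; the per-atom parameter is the self-pair
minimum-energy distance in nm). Defaults are vacuum dielectric and no
cutoff, both configurable. The result is an **estimate**: reproducing any
published force-field value requires the original parameter set and
protocol, which this package does not bundle.

# The synthetic generator: what it emulates, and what it does not

Each generator draws a stated world and writes it into a ground-truth
manifest (all parameters plus analytic expectations), so recovery tests
compare against the manifest, never against numbers re-derived at test
time.

**Markov switching.** Discrete states (coordination number, dihedral
orientation, mixture component) follow a "sticky redraw" chain: with
probability $1/\tau$ the state is redrawn from the stationary law,
otherwise kept. The stationary distribution is exact by construction and
$\tau$ sets the correlation time. The generic default is $\tau = 20$
frames, because analyses must be robust to temporal correlation. The
*site and dihedral presets* use $\tau = 2$: their frames represent one
sample per 0.01 µs while shell/side-chain exchange happens on the
nanosecond scale, so successive samples are nearly decorrelated. This is
also what makes the stated recovery tolerances (±2–3 percentage points at
20 000 frames) statistically comfortable: with $\tau = 2$ the standard
error of an 80% occupancy estimate is ≈ 0.5 points, whereas $\tau = 20$
would put it at ≈ 1.8 points, right at the tolerance.

**Ion site geometry** (`gen_ion_site()`). The ion jitters isotropically
about the origin with per-axis sd chosen so the expected RMSF is 0.04 nm
(0.04/√3 per axis). Ligand oxygens occupy fixed, well-separated cage
directions; the Markov CN state decides how many (in fixed priority
order: the four carboxyl oxygens of E771/D800, then N796, then waters)
sit *inside* the cutoff. Bound oxygens are placed at their target
distance from the *instantaneous* ion position (truncated-normal radial
jitter, sd 0.01 nm, capped 0.002 nm inside the cutoff), emulating the
correlated breathing of a real first shell; unbound oxygens are displaced
beyond the cutoff (0.35 ± 0.02 nm, floored 0.05 nm outside). Protein
oxygens carry a *static* anchor carbon one bond further out; RMSF
alignment uses these anchors (`"element C"`), mirroring the real practice
of aligning on the protein rather than on the mobile shell, and
decoupling the RMSF ground truth from the tight coordination distances.
Manifest expectations for per-ligand mean distances use the
truncated-normal closed form weighted by the analytic bound probability.

**Dihedral preset** (`gen_dihedral()`). A four-atom glutamate fragment
with ideal sp3 geometry; χ~2~ follows the two-state chain (centers
+150°/+80°, jitter 10°). Stationary lumen fractions are 0.62 (Mg-bound
ensemble) and 0.69 (2K-bound). The manifest corrects the expected
occupancy for the ≈ 0.1% of jitter mass that leaves the lumen window, and
records a warning whenever window-crossing probability exceeds 1%.

**Headpiece preset** (`gen_headpiece()`). The three constrained pairs
form a chain (K515–T171–E680–R489), so any positive distance triple is
embeddable exactly; coordinates are rebuilt per frame from the three
scalar processes (mixture-state Markov chain, correlation 20 frames, plus
within-state AR(1) jitter, correlation 5 frames, whose stationary law is
exactly the component Gaussian). E1-Mg: unimodal N–A 2.7 nm, N–P
0.95 nm, A–P 2.6 nm. E1-2K: bimodal N–A 3.3/3.8 nm and N–P 1.6/2.4 nm
(equal weights), unimodal A–P 2.6 nm. Since component sds are not printed
anywhere, they are fixed package constants (0.15 nm unimodal, 0.12 nm per
bimodal component). The E1-Mg A–P mean is likewise a package choice (the
source text gives it only relative to an unprinted crystal value, with a
labelling ambiguity that we resolve by the figure colour legend:
two-Gaussian fits belong to the 2K ensemble).

**What a green test does not establish.** The generators emulate the
*statistical structure* the analyses assume — stationary laws, temporal
correlation, geometric conventions — not the physics: no force field, no
water/membrane, no correlation between the site, dihedral and headpiece
components, and no slow drift or aging. Recovery therefore validates the
measurement pipeline, not the simulations themselves; agreement with the
published values shows the code reproduces the published *procedures* on
data with the published summary statistics.

# Numerical choices and degenerate inputs

* Coordination cutoffs compare strictly (`<`); bonding thresholds apply to
  means (`>=` threshold ⇒ non-bonding).
* Kabsch rejects < 3 points and collinear sets; determinant correction
  excludes reflections (det = +1 within 1e-9).
* `dihedral_angle` errors on coincident consecutive points; angles are
  mapped to (−180°, 180°] with −180° → +180°.
* Histogram fitting floors the sd at bin_width/10 and constrains means to
  the padded data range; a fit that still fails to produce finite
  parameters raises a `fit_failure_error` with diagnostics.
* Binding events need a dwell of ≥ `dwell` consecutive sampled frames
  (default 10) with the ion within the cutoff of ≥ 1 site atom; the event
  time is the first frame of the first qualifying run. The source gives an
  event time but no criterion; the default is documented and configurable.
* altloc resolution defaults to first-listed; waters are HOH/TIP3/WAT,
  ions MG/K/POT/CA/CAL; residue numbers are author numbering, never
  renumbered.
* Domain boundaries for N/P/A/TM are not published per residue; the
  shipped SERCA1a map is an approximate block partition and a documented
  package default (`default_serca_domain_map()`), not a claim about the
  authors' partition.

# Known limitations

* Only multi-model PDB trajectories are supported (by design: text,
  diffable, self-contained); no DCD/XTC.
* The interaction-energy stage is an estimate with user-supplied
  parameters; published force-field energies (−950 kcal/mol etc.) are
  context, not targets.
* Crystal-reference comparisons require user-supplied structure files;
  the package does not download from the PDB.
* No PCA/clustering, no kernel density estimation, no > 2 mixture
  components, no free-energy methods.
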