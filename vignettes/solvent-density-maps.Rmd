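---
title: "Time-averaged solvent density maps and map-based hydrogen-bond networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-averaged solvent density maps and map-based hydrogen-bond networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvmap)
```

## The model

Crystalline molecular dynamics — simulating a full periodic unit cell of a
protein crystal — produces coordinate ensembles that can be compared
*directly* with crystallographic data, by converting the ensemble into the
same observable the experiment measures: an electron-density map. solvmap
implements that conversion and the downstream solvent analyses.

For a set of frames and a selected atom species, the mean structure factor
at Miller index $h$ is

$$ F(h) \;=\; \frac{1}{N}\sum_{i=1}^{N}\ \sum_{a}
   f_{e(a)}\!\left(|s_h|\right)\, e^{2\pi i\, h\cdot x_{a,i}} , $$

with $x_{a,i}$ the fractional coordinates of atom $a$ in frame $i$,
$f_e$ the element's X-ray scattering factor, and the reflection list the
sharp sphere $|s| \le 1/d_\mathrm{min}$. The density is the inverse Fourier
sum $\rho(x) = V^{-1}\sum_h F(h)\,e^{-2\pi i h\cdot x}$, evaluated by FFT.
Because $F(000)$ equals the electron count of the selection, dividing by
the cell volume puts the map on an absolute e/Å³ scale with no further
scaling: every species map integrates to its electron count exactly, which
the test suite asserts to machine precision.

Three modelling choices matter here:

* **No B-factors, no bulk solvent.** The ensemble spread itself encodes all
  disorder; applying per-atom smearing on top would double-count it.
* **Scattering factors.** Four-Gaussian-plus-constant X-ray coefficients
  per element, rescaled multiplicatively so that $f(0)$ equals the electron
  count exactly (the raw published fits are off by up to 0.13%, e.g.
  $f_O(0)=7.9994$). Without the rescale, the conservation identity and the
  "single oxygen gives $F(000)=8$" anchor would hold only approximately.
* **Sharp resolution cutoff.** The sphere $|s|\le 1/d_\mathrm{min}$ mirrors
  standard crystallographic practice; the resulting Fourier truncation
  ripple (small negative lobes around strong peaks) is accepted and left
  visible rather than apodized away.

Species decomposition (`select_species`) builds maps from all water atoms,
water oxygens, the H1 or H2 hydrogens only, or a single molecule.
Per-molecule maps of a molecule that occupies a site only part of the time
use its occupancy-weighted electron count as $F(000)$; this keeps both the
conservation identity and per-molecule additivity (the maps of all
molecules sum to the all-water map) exact, and simply means a half-time
occupant carries half its electrons in the time average.

## The synthetic ensemble generator

Real trajectories of a photosystem-scale crystal are far outside a desk
budget, so validation runs on synthetic crystalline water ensembles with
known ground truth. `generate_water_wire()` places rigid TIP3P-geometry
waters (O–H 0.9572 Å, H–O–H 104.52°) on a line at a chosen spacing
(default 2.8 Å, the canonical hydrogen-bond O–O distance), pads the
orthorhombic box by 8 Å to keep periodic images from interacting, and
samples frames as site mean plus isotropic Gaussian jitter. Hydrogen
orientation comes in three modes:

* `chain` — H1 of each site points at the next site's mean oxygen: an
  ordered donor chain whose directed edges $i \to i{+}1$ are the ground
  truth network. H2 is placed at the water angle, tilted off the wire axis
  so it cannot fake a backward bond.
* `rotor` — both hydrogens precess about the donation axis on the
  half-angle cone, a water that "points the right way" but has no fixed
  hydrogen position: oxygen density stays sharp while hydrogen density
  smears along the cone.
* `random` — a fresh uniform orientation every frame; the null control
  with no orientational order at all.

`generate_exchange_site()` scripts a change of occupying molecule at a
chosen frame under an otherwise stationary density, giving the dynamics
module a fixture where the map looks perfectly stable but the occupancy
series contains exactly one exchange.

What the generator deliberately does **not** emulate: correlated motions,
anisotropic disorder, protein atoms and their hydrogens, long-range density
gradients, and experimental noise in the reference map. Tests passing on
these fixtures therefore demonstrate the *machinery* — scaling,
peak-finding, matching, direction inference — not force-field realism.

## Peak analysis and water matching

`find_peaks` takes voxels exceeding all 26 periodic neighbours and a
threshold, refines positions by a separable quadratic fit (clipped to half
a voxel), and merges peaks closer than half a voxel edge, keeping the
higher (ties broken by grid index, so output order is deterministic). The
reported height is the interpolated maximum; the raw voxel value is kept
alongside. Default analysis levels are 2.08 e/Å³ for water/oxygen maps and
0.26 e/Å³ for hydrogen maps; `sigma_to_absolute()` converts σ-relative
contour levels of experimental maps (mean + n·σ) to the same absolute
scale.

`match_waters` computes $r_\mathrm{MD\text{-}xtal}$, the minimum-image
distance from each reference water to the nearest peak. Assignment is
non-exclusive — the statistic is per-water, and nothing in it requires a
bipartite matching. Shells follow the boundaries inner $r<0.3$ Å, middle
$0.3 \le r<0.5$, outer $0.5\le r<1$, distant $r\ge 1$; boundary values go
to the upper class (the source inequalities are strict on both sides, so a
convention had to be fixed — upward assignment keeps "within 1 Å" meaning
strictly within). `fraction_recovered` counts waters whose nearest peak
passes both the distance cut (default 1 Å) and the height cut (default
2.08 e/Å³). Pearson correlations between simulated and experimental peak
heights are computed per shell, with fewer than two pairs reported as
undefined rather than an error.

The 25 Å analysis sphere used for region statistics is a `region_spec`
preset whose centre the caller supplies (it is a feature of the reference
structure, not of this package). Channel-boundary regions are realized as
unions of spheres about residue-pair midpoints.

## MADI: map-based acceptor–donor identification

MADI infers *directed* hydrogen bonds from density alone: an oxygen-peak
pair $(i,j)$ with O–O distance in the window 2.4–3.5 Å becomes an edge
$i \to j$ when a hydrogen peak lies within 1.2 Å of $O_i$ and within 30°
of the $i\to j$ axis. The supporting hydrogen peak height is the strength
score — orientational disorder smears hydrogen density, so a tall hydrogen
peak is direct evidence of a well-ordered, persistent bond. Class bounds
default to weak < 0.5 ≤ medium < 1.5 ≤ strong (upper-inclusive); a
donor-height-normalized variant is reported alongside. Evidence in both
directions collapses to a single edge flagged ambiguous — the
hydrogen-swap situation — rather than two opposing arrows. External
(protein) sites participate as acceptors only, since water-species maps
contain no protein hydrogens. H1 and H2 peaks are pooled for assignment
but keep their provenance tags. These geometric constants are standard
hydrogen-bond heuristics, exposed in the configuration and echoed in every
run manifest; they are this package's choices, not published values.

**Analysis-map resolution.** The MADI stage synthesizes its own oxygen and
hydrogen maps, by default at $d_\mathrm{min} = 1.5$ Å rather than the
2.0 Å used for the experimental-comparison map. The reason is a hard
ceiling: a perfectly rigid water hydrogen band-limited to 2.0 Å peaks at
only ≈ 0.28 e/Å³, so the 0.26 e/Å³ hydrogen level leaves no margin — with
realistic positional spread (σ ≈ 0.15 Å) ordered hydrogens drop to ≈ 0.25
and become undetectable, while the level itself cannot be lowered much
before cone-smeared hydrogens (≈ 0.18 at 1.5 Å) leak through. At 1.5 Å the
same ordered hydrogens peak near 0.42, the free-rotation null stays below
0.10, and the rotor cone below 0.19: the detection level then separates
order from disorder with wide margins on both sides. Nothing else changes;
matching against reference waters still uses the 2.0 Å map.

`extract_wires` enumerates maximal simple directed paths (water wires) by
depth-first extension from source nodes, in deterministic order; nodes on
directed cycles are reported separately instead of being traversed.

## Dynamics

`site_occupancy` records, per frame and site, the nearest water oxygen
within a capture radius (default 1.2 Å — above typical site jitter, below
half the nearest-neighbour water spacing). `count_exchanges` debounces the
series: an exchange requires both the outgoing and incoming occupant to
persist at least `min_dwell` frames (default 5), so boundary flicker does
not masquerade as exchange. The bookkeeping identity occupied-fraction ×
frames = occupied-frame count is tested directly.

## The direct-summation oracle

The FFT pipeline is validated against an independent implementation that
never synthesizes a grid by FFT. Each atom's band-limited radial profile

$$ \rho_e(r) = 4\pi \int_0^{s_\mathrm{max}} s^2 f_e(s)\,
   \frac{\sin 2\pi s r}{2\pi s r}\, ds $$

is tabulated and summed over atoms, frames and periodic images in real
space. Two numerical points deserve record:

* The sharp cutoff makes $\rho_e$ ring with a $1/r^2$ envelope, so the
  image sum is only conditionally convergent — truncating it at any
  tractable image count leaves errors two orders of magnitude above the
  intended 10⁻³ e/Å³ agreement. The oracle therefore splits the sphere at
  the band edge: the interior (cosine-windowed over the outermost
  0.06 Å⁻¹) has a fast-decaying profile and is summed in real space, while
  the thin band-edge shell is summed reflection-by-reflection with
  explicit trigonometric sums on the grid. Both parts avoid the FFT and
  share only the scattering-factor table with the production path.
* The oscillatory radial integral is evaluated with a Filon-type rule
  (piecewise-linear amplitude, oscillatory factor integrated analytically
  per interval). An ordinary quadrature's absolute error grows as $r^4$
  and swamps the decaying profile exactly where the image sum needs it.

The oracle itself is checked against brute-force Fourier summation at
arbitrary points; the FFT map then agrees with it to max |Δ| ≈ 4×10⁻⁴
e/Å³ (correlation ≈ 1.0) on a three-water fixture at $d_\mathrm{min}$ =
0.8 Å in a 20 Å cell. It is restricted to orthorhombic cells and small
systems; that is its job.

## Problem sizes and determinism

The shipped tests and the acceptance script use: the three-water oracle
fixture above; five-site chains of 2000 frames (≈ 30,000 atom-frames) for
peak matching and MADI recovery over ten seeds; 1000-frame free-rotation
ensembles over twenty seeds for the null control; and 100–300-frame runs
for pipeline-level checks. These sizes give stable statistics while the
whole suite completes in minutes on one CPU.

All randomness flows from one integer seed, split deterministically per
stage; reruns from a saved configuration reproduce byte-identical CSV
outputs, and the run manifest records the configuration, seed, package
version and MD5 digests of every text output.

## Known limitations

* No space-group symmetry averaging by default (synthetic systems are P1);
  an operator-supplied post-step is the natural extension.
* No anomalous scattering, anisotropic displacement, or experimental
  amplitude scaling — comparisons to measured data are by map
  interpolation, not R-factors.
* The MADI geometric criteria are heuristics; on real maps they should be
  scanned, not trusted blindly, and the configuration makes that cheap.
* The oracle supports orthorhombic cells only; the FFT path itself is
  general triclinic.
* Protein donors are not modelled (no protein-hydrogen density is
  available in water-species maps); protein partners act as acceptors.
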