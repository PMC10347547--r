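# solvmap

Time-averaged solvent electron-density maps and map-based hydrogen-bond
networks from molecular-dynamics ensembles.

## What problem this solves, and for whom

Crystalline MD — simulating a full periodic unit cell of a protein crystal —
lets a simulation be compared *directly* against crystallography, by turning
the trajectory into the observable the experiment produces: an
electron-density map. This package is for structural biologists and
simulators who want to

1. convert coordinate ensembles into **absolute-scale, species-resolved
   density maps** (all waters, water oxygens, H1/H2 hydrogens, or single
   molecules),
2. **match density peaks against reference (crystallographic) water
   positions** with the standard distance/shell/correlation statistics, and
3. infer **directed, strength-scored hydrogen-bond networks and water
   wires** from separate oxygen and hydrogen maps — MADI, map-based
   acceptor–donor identification — plus site-occupancy/exchange analysis of
   the fast dynamics the time-averaged map cannot show.

The core quantities:

* Mean structure factors
  `F(h) = (1/N) Σ_frames Σ_atoms f_elem(|s|) exp(2πi h·x)` on the sphere
  `|s| ≤ 1/d_min`, with `F(000)` equal to the electron count of the
  selection, so FFT synthesis divided by the cell volume lands directly on
  an absolute e/Å³ scale (every map integrates to its electron count).
* `r_MD-xtal`, the minimum-image distance from each reference water to the
  nearest map peak, with inner/middle/outer shells at 0.3/0.5/1.0 Å, the
  per-shell Pearson correlation of simulated vs experimental peak heights,
  and the fraction of waters recovered by a strong (≥ 2.08 e/Å³) peak
  within 1 Å.
* MADI: a directed bond `i → j` is declared when a hydrogen peak sits
  within 1.2 Å of oxygen peak `i`, within 30° of the `i → j` axis, and the
  O–O distance is in 2.4–3.5 Å; the hydrogen peak height is the bond
  strength, and maximal directed paths are the water wires.

Everything is validated on synthetic crystalline water ensembles with
machine-readable ground truth (ordered donor chains, free-rotor cones,
random-orientation nulls, scripted site exchanges) — see the methods
vignette (`vignettes/solvent-density-maps.Rmd`) for the model, parameter
choices, and limitations.

## Worked example

A five-site hydrogen-bonded water wire, 500 frames of 0.1 Å jitter; map,
peaks, matching, and the recovered directed network:

```r
library(solvmap)

ens <- generate_water_wire(n_sites = 5, spacing = 2.8,
                           direction_mode = "chain",
                           jitter_sigma = 0.1, n_frames = 500, seed = 42)

m_O <- map_from_sf(structure_factors(select_species(ens$snapshots, "water_O"), 2.0))
m_O
#> density map [water_O]: 45 x 24 x 24 grid, mean 0.005744, sigma 0.1122 e/A^3

peaks <- find_peaks(m_O, threshold = 2.08)
as.data.frame(peaks)[, c("id", "x", "y", "z", "height")]
#>   id      x     y     z height
#> 1  1  7.978 8.001 8.001  2.997
#> 2  2 10.819 8.000 8.001  3.079
#> 3  3 13.602 7.997 8.000  2.992
#> 4  4 16.387 8.002 8.008  3.071
#> 5  5 19.230 8.003 8.000  2.999

ref    <- truth_to_reference(ens$truth, ens$snapshots$cell)
report <- match_waters(peaks, ref)
fraction_recovered(report)$fraction   # strong peak within 1 A, per water
#> [1] 1
mean(report$r)                        # mean r_MD-xtal in Angstrom
#> [1] 0.0181

net <- madi_network(ens$snapshots)    # O/H1/H2 maps -> directed H bonds
net$edges[, c("donor", "acceptor", "OO_A", "H_height_e_A3", "class")]
#>   donor acceptor OO_A H_height_e_A3 class
#> 1     1        2 2.78         0.443  weak
#> 2     2        3 2.79         0.440  weak
#> 3     3        4 2.80         0.437  weak
#> 4     4        5 2.79         0.448  weak
extract_wires(net)$wires
#> [[1]]
#> [1] 1 2 3 4 5
```

All five sites are recovered with sub-0.02 Å peak displacement, the map
integrates to the 40 electrons of the five oxygens, and MADI returns
exactly the four ground-truth donor→acceptor edges forming one five-node
wire. The heights (~3 e/Å³ for oxygen peaks, ~0.44 for hydrogen peaks at
the 1.5 Å MADI analysis resolution) are what 0.1 Å of positional disorder
leaves of the band-limited atom peaks.

`run_pipeline(run_config(...), "out/")` chains
simulate → density → peaks → match → MADI → occupancy, writing CSVs, CCP4
maps, wire tables and a reproducibility manifest; a thin command-line
front end with the same stages as subcommands is installed at
`inst/cli/solvmap.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "solvmap.R", package = "solvmap"))')" \
    run --out-dir out --seed 1
```

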