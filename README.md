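# helixtraj

Structural analysis of molecular-dynamics trajectories of four-α-helical
bundle proteins in R.

Four-helix bundles — the helical-hairpin homodimer fold (2 chains × 63
residues, two antiparallel helices joined by a short loop) and its
"loopless" four-helix tetramer relative (4 chains × 58 residues) — are
model systems for studying how a short-range change in topology reshapes
thermal stability.  Comparing them across simulation temperatures takes a
fixed battery of trajectory measures.  `helixtraj` implements that battery
for anyone analysing helical-bundle trajectories (multi-model PDB in,
CSV/JSON out), together with a synthetic structure/trajectory generator
with exactly known ground truth used to validate every stage.

The measures, in the field's standard notation:

* **rmsd(t)** = √( (1/N) Σᵢ ‖rᵢ(t) − rᵢʳᵉᶠ‖² ) over selected Cα atoms
  after Kabsch superposition, with the conventional tail (last 7) and,
  for the tetramer, head (first 4) residue exclusions;
* **%D(tᵢ)** = |rmsd_T(tᵢ) − rmsd_ref(tᵢ)| / rmsd_ref(tᵢ), the relative
  deviation contrast between a hotter and a reference series;
* **rmsfᵢ** = √( (1/T) Σⱼ ‖rᵢ(tⱼ) − rᵢʳᵉᶠ‖² ) per residue, optionally
  averaged over equivalent chains;
* geometric **hydrogen bonds** (donor–acceptor ≤ 0.35 nm, H–D–A ≤ 30°):
  P–P / P–W / W–W-per-water censuses, interchain/intrachain splits,
  per-helix i→i+4 backbone counts, and loop-residue → helix bridge
  tables;
* cross-set **g(r)** between Cβ atoms of hydrophobic residues of
  different chains/chain-pairs, plus hydrophobic centre-of-mass
  distances;
* **φ/ψ torsions**, Ramachandran region percentages (α / β / left-α /
  other), per-residue (φ,ψ) time maps, per-helix circular-mean torsions;
* **helix geometry**: rise d, length L = d·n, radius r, twist θ per
  residue, end-to-end distance;
* **block averaging** over a trailing window with std-across-blocks
  error bars, behind every trajectory-level summary.

## Worked example

Build a hairpin-dimer bundle, generate a "cold" and a "hot" synthetic
trajectory, and compare them:

```r
library(helixtraj)

bundle <- build_bundle("wtrop_like")
bundle$system
#> <molecular_system> 630 atoms, 126 residues, chains: A,B

sigma <- sigma_profile(bundle$annotation)        # 0.01 / 0.03 / 0.05 nm
cold <- generate_trajectory(bundle$system, 100, noise_model(sigma, seed = 1))
hot  <- generate_trajectory(bundle$system, 100, noise_model(3 * sigma, seed = 2))

sel <- select_atoms(bundle$system, "CA", exclude = "tail7")
rmsd_cold <- rmsd_series(cold, bundle$system, sel)
rmsd_hot  <- rmsd_series(hot,  bundle$system, sel)
rmsd_cold
#> <deviation_series> 100 frames, 112 atoms, fit=TRUE, mean 0.0302 nm
percent_increase(rmsd_hot, rmsd_cold)
#> <percent_d> mean 204.4% over 100 points (0 undefined)

helix_i_to_i4(cold, bundle$annotation)
#>   helix_id n_res  mean      error
#> 1       A1    22 17.32 0.21587033
#> 2       A2    23 18.24 0.08602325
#> 3       B1    22 17.36 0.10677078
#> 4       B2    23 18.41 0.12000000

ca1 <- selection_coords(select_atoms(bundle$system, "CA",
         annotation = bundle$annotation, region = "HELIX1", chains = "A"),
         bundle$system)
helix_metrics(ca1)
#> <helix_metrics> n=22 d=0.1440 nm L=3.169 nm r=0.2369 nm theta=95.85 deg
```

Reading the numbers: the 112-atom selection is Cα of both chains minus
the 7 flexible tail residues each.  The cold tier sits 0.03 nm from the
reference (essentially the noise floor); tripling the noise amplitude
raises the deviation ~3-fold, a mean %D of ~204%.  Each ~22-residue helix
carries ~17–18 of its 18–19 possible i→i+4 backbone hydrogen bonds per
frame, and the fitted helix geometry (rise 0.144 nm, radius 0.237 nm,
twist 95.9°/residue, here measured on one noiseless helix after lattice
assembly) sits at the canonical α-helix scale.

The same battery runs end-to-end from a YAML config, over synthetic noise
tiers or a multi-model PDB trajectory from disk:

```sh
Rscript inst/cli/analyze.R run -c config.yaml -o outdir --seed 7
Rscript inst/cli/analyze.R fixture -c config.yaml -o fixture_dir
```

writing `rmsd_series.csv`, `percent_d.csv`, `rmsf.csv`,
`hbond_census.csv`, `helix_hb.csv`, `loop_bridge.csv`, `rdf.csv`,
`cm_distance.csv`, `rama_percent.csv`, `helix_torsions.csv`,
`helix_metrics.csv`, `end_to_end.csv` and a `manifest.json` (config hash,
package version, per-stage warnings/failures).  Fixed config + seed gives
byte-identical tables.

## Scope

The package analyses trajectories; it does not run MD, process CD
spectra, or wrap external analysis tools.  Temperature tiers in the
synthetic generator are labels on noise amplitudes, not thermodynamics.
See `vignettes/helix-bundle-analysis.Rmd` for the model assumptions,
parameter defaults and their rationale, and known limitations.
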