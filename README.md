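# poresym

Trajectory and assay analysis for designed pentameric proton channels:
sidechain dynamics, pore hydration, water-mediated hydrogen-bond networks,
and ratiometric proton-flux rates.

## The problem

Minimalist pentameric helical bundles conduct protons through a narrow
pore lined by a ring of five glutamines (plus serines in more polar
variants). Conduction happens by Grotthuss shuttling along transient
hydrogen-bonded water wires, so what matters is dynamic: which rotamer
states the Gln sidechains sample, whether the five chains move in concert
or break symmetry, how hydrated the pore is, and how residues and waters
wire into hydrogen-bond networks. `poresym` implements that analysis chain
for anyone working with labelled multi-frame coordinate data of such
bundles, together with the liposomal HPTS assay computation used to
measure proton flux, and a synthetic generator that provides exact ground
truth for every stage.

The core quantities:

* **Orientation vector and z-offset.** For each pore-lining Gln, the
  vector from its C-alpha to its NE2 amide nitrogen; its z-component is
  measured against the plane `z = mean z` of the five Gln C-alpha atoms.
  States: down (`z < 0`), neutral (`0 <= z < 2.5` Å), up (`z >= 2.5` Å).
* **Pairwise state agreement.** For chains i, j the fraction of frames
  with `state_i = state_j` — a 5×5 symmetry statistic: near 1 for
  concerted rings, `sum(p^2)` (= 1/3 for uniform states) for independent
  chains.
* **Rotamers.** chi1/chi2 torsions, DBSCAN clusters on the periodic
  sin/cos embedding, and 70%/90% highest-density KDE background contours.
* **Hydration.** Waters inside the convex hull of the residue-5/22
  C-alpha anchors; residence times; z density profiles; hydrophobic length
  = longest low-density span between inflection points of the smoothed
  second derivative; wet/dry frame labels with an n≤1 / n≥10 hysteresis.
* **Hydrogen-bond networks.** Residue pairs connected directly or through
  up to five bridging waters, aggregated over the last half of a run,
  filtered at 10% occupancy inside the residue 6–20 core.
* **Proton flux.** `pH = -log10(A·B^Ratio - 1)` with A = 8.959e-8,
  B = 1.185; buffered total protons
  `H = h + P·h/(Ka + h)` (h = 10^-pH, Ka = 6.31e-8, P = 0.03 M); 60-s
  initial-rate fits; one-way ANOVA + Tukey HSD across variants.

## Worked example

Simulate a channel whose five Gln switch states independently, then ask
how symmetric its dynamics are:

```r
library(poresym)

spec <- trajectory_spec(n_frames = 300, stay_prob = 0.9, seed = 1)
g <- generate_trajectory(spec)
v <- compute_gln_vectors(orient_pore_axis(g$traj), 10)
m <- pairwise_agreement(classify_states(v))
round(m, 2)
#>      A    B    C    D    E
#> A 1.00 0.27 0.40 0.34 0.40
#> B 0.27 1.00 0.36 0.36 0.26
#> C 0.40 0.36 1.00 0.28 0.33
#> D 0.34 0.36 0.28 1.00 0.24
#> E 0.40 0.26 0.33 0.24 1.00
```

Off-diagonal values near 1/3 are the independent-chain limit — an
asymmetric channel. A ring scripted to move in concert returns 1.00
everywhere. The same objects feed the hydration and network stages
(`define_pore_region()`, `count_pore_waters()`, `density_profile()`,
`hydrophobic_length()`, `frame_hbonds()`, `water_bridges()`,
`build_network()`).

The flux side, end to end on synthetic plates:

```r
gen <- generate_flux_traces(flux_spec(amplitude = 0.35, seed = 9),
                            variant = "double")
rates <- plate_rates(gen$plate, gen$layout, t_val = 120)
mean(rates$rate)      # 1.791e-05 M/s: fitted initial proton influx
gen$truth$rate        # 2.003e-05 M/s: the scripted ground truth
```

## The analysis workflow

`analysis/` holds the numbered drivers; each prints what it found and
writes tables under `results/`:

1. `01_simulate.R` — three replicates each of a "symmetric" (shared state
   script) and an "asymmetric" (independent chains) archetype, plus flux
   plates for three variants.
2. `02_rotamer_states.R` — z histograms, agreement matrices, rotamer
   clusters. Printed: symmetric mean off-diagonal agreement 1.000;
   asymmetric 0.313 (independent-chain limit 1/3).
3. `03_hydration.R` — counts, residence times, density profiles,
   hydrophobic spans, wet/dry labels; the analytic two-inflection fixture
   recovers 12.00 Å.
4. `04_hbond_network.R` — windowed bonds, water bridges, filtered network
   edges (the scripted A–C bridge comes back at its scripted 0.50
   occupancy with 4.0 bridging waters), interaction-type fractions.
5. `05_flux_assay.R` — per-replicate rates and statistics. Printed:
   F(2,21) = 19.3, p = 1.8e-05; Tukey separates the high-amplitude
   variant from both others (adj p ≈ 7e-05) and not the two similar ones
   (adj p ≈ 1.0).

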