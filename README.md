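# iontraj

Ion-site and domain dynamics analysis for membrane-pump MD trajectories.

P-type ATPases such as SERCA (the sarcoendoplasmic reticulum Ca2+ pump)
couple ATP hydrolysis to selective cation transport. Their E1
intermediates can be occupied by Mg2+ or K+ instead of Ca2+, and the
identity of the bound ion reshapes both the transmembrane binding sites
and the cytosolic headpiece (N, P, A domains). `iontraj` provides the
trajectory-analysis battery needed to characterise such states from
molecular-dynamics output stored as multi-model PDB:

- **Coordination analysis** — per-frame counts of oxygen neighbours within
  a species cutoff (0.21 nm Mg2+, 0.30 nm K+) and their population
  distribution; ion–ligand mean-distance tables with bonding filters.
- **Binding kinetics** — first sustained-entry times and entry-pathway
  (TM1 gateway residue) contact ordering; a Coulomb + Lennard-Jones
  interaction-energy estimate.
- **Side-chain gating** — χ2 (Cα–Cβ–Cγ–Cδ) dihedral series with
  lumen/cytosol classification (lumen |χ2| ≥ 120°, cytosol 40° ≤ |χ2| <
  120°) and state occupancies.
- **Domain dynamics** — Kabsch superposition, per-domain RMSD with
  explicit alignment semantics, per-atom RMSF, and the axial rotation of
  the A domain about the membrane normal.
- **Headpiece geometry** — interdomain Cα–Cα distance distributions
  ρ(R) (pairs K515–T171, R489–E680, T171–E680), one/two-Gaussian
  least-squares decomposition with a parsimony-based model choice, and
  comparison against open/compact crystal anchor distances.
- **Synthetic generator** — seeded trajectories with ground-truth
  manifests (Markov-switching coordination shells, two-state dihedrals,
  mixture-law headpiece traces, noisy rigid rotations) so every stage is
  testable by parameter recovery.

At its statistical core: for a distance trace $R(t)$ the package fits
$\rho(R) = \sum_k w_k\, \mathcal N(R;\mu_k,\sigma_k^2)$, $k \in \{1,2\}$,
by weighted nonlinear least squares against the histogram density, reports
the Pearson correlation r between fitted and empirical density, and keeps
the two-component model only when it clearly wins (Δr ≥ 0.01 and mean
separation > the larger component sd).

## Worked example

```r
library(iontraj)

# a synthetic Mg2+ coordination site whose manifest states the truth
g   <- gen_ion_site(site_preset("MG"), frames = 20000, seed = 1)
pop <- coordination_population(
         coordination_series(g$trajectory, g$manifest$ion_index, cutoff = 0.21))
print(pop)
#> <coordination_population> MG, n = 20000 samples
#>  cn percent
#>   4   1.195
#>   5  13.720
#>   6  80.385
#>   7   4.700

rmsf(g$trajectory, g$manifest$ion_index, "element C")
#>         1
#> 0.04000552
```

The population table mirrors the published Table-2 layout: this ion holds
six coordinating oxygens ~80% of the time (octahedral Mg2+), and its
positional fluctuation after aligning on the static cage anchors is
0.040 nm — both equal to the preset's encoded ground truth.

```r
g2 <- gen_headpiece(headpiece_preset("E1_2K"), frames = 20000, seed = 1)
dd <- estimate_density(interdomain_series(g2$trajectory, "N-A"))
select_model(fit_mixture(dd, 1), fit_mixture(dd, 2))
#> <mixture_fit> N-A: order 2, r = 0.9990
#>  weight  mean    sd
#>   0.503 3.301 0.122
#>   0.497 3.794 0.122
```

The N–A (K515–T171) distance distribution of the 2K+-bound ensemble is
resolved as two Gaussians at 3.30 and 3.79 nm — the open-headpiece
bimodality — while the Mg2+-bound preset stays unimodal.

A command-line interface (`inst/exec/iontraj`) exposes `analyze`,
`synth`, `compare` and `crystal-distances` verbs driven by YAML configs.

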