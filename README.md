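# lectinet

Dynamical-network and coevolution analysis of bulb-type lectin dimer
recognition, in R.

Bulb-type (mannose-binding) plant lectins are active as dimers: two
single-domain monomers must recognise each other at long range and dock
through a specific interface, whereas double-domain lectins fuse both
domains with a short linker and never need long-range recognition.
`lectinet` implements the three quantitative analyses that contrast
those situations:

* **Structure** — Shrake–Rupley solvent accessibility, residue
  classification by burial on complex formation (*interface*: relative
  SASA > 0.2 in the monomer and ≤ 0.2 in the complex; *surface*,
  *interior*, *ligand-binding* analogously), and interacting cross-chain
  residue pairs under the 4 Å minimum heavy-atom distance rule.
* **Dynamics** — residue networks from trajectories: motion correlation
  `C_ij` of Cα displacements, edges for persistent contacts (< 4.5 Å in
  ≥ 75% of frames, nonconsecutive residues, positive correlation only)
  weighted by `W_ij = −log(C_ij)`; Floyd–Warshall shortest paths with
  path counts; closeness `C(x) = (n−1)/Σ_y d(x,y)`, raw-count
  betweenness, characteristic path length (CPL) and delta path length
  (DPL = change in CPL on node removal), z-score flags (1.5 / 1.0) and
  closeness tiers (top 20% / 20–60% / rest).
* **Sequence** — mean-field direct coupling analysis: >50% gap-column
  filter, 80%-identity reweighting (`M_eff = Σ 1/m_a`), pseudocount
  λ = 0.5 frequencies, covariance inversion on the 20-state reduced
  basis (gap as gauge state), per-pair two-site model and direct
  information `DI_ij = Σ P²_ij ln(P²_ij / f_i f_j)` with the DI > 0.8
  coevolution flag; entropy-based 9-grade conservation; and the
  hydrophobic–polar interaction-pattern resampling (31 of 46
  single-domain vs 11 of 16 double-domain sequences, five replicates).

MD trajectories and curated alignments are not reproducible on a
workstation, so the package ships generators with machine-readable
ground truth — correlated-Gaussian trajectories with a planted
correlation matrix, Potts-model alignments with planted coupled column
pairs, and toy dimers with a designed interface — and the tests verify
that every analysis recovers the planted truth.

## Worked example

The numbered scripts under `analysis/` run the full story on synthetic
inputs. `analysis/02_dynamical_network.R` simulates a 3000-frame
trajectory for a 16-residue system with a planted bottleneck residue
(`F:1`, the only short route between two contact cliques), builds the
dynamical network and prints:

```
Network: 16 nodes, 35 edges, CPL = 2.3984

Flagged high-betweenness residues (z > 1.5):
 node betweenness z_betweenness
  A:1          47      1.915198
  F:1          53      2.245286
  G:1          47      1.915198

Flagged high-DPL residues (z > 1.0):
 node      dpl    z_dpl
  A:1 1.780284 1.995488
  F:1 1.925881 2.200083
  G:1 1.787641 2.005827

Planted bottleneck: F:1 | top betweenness: F:1 | top DPL: F:1
```

The bridge residue tops both metrics and its two gateway contacts (`A:1`,
`G:1`) are flagged beside it — exactly the signature used to nominate
communication-critical residues near a dimer interface. Likewise,
`analysis/03_coevolution_dca.R` samples a "single-domain" alignment
(five planted coupled pairs, L = 30, M = 2000) and an uncoupled
"double-domain" control, and prints:

```
single-domain: M = 2000, L = 30, M_eff = 2000.0
  pairs with DI > 0.8: 5
 pos_i pos_j       DI
    17    22 2.609929
    14    28 2.558381
     2     9 2.501070
     5    20 2.491874
    11    25 2.475467
  planted pairs recovered in top 10: 5 / 5

double-domain: M = 2000, L = 30, M_eff = 2000.0
  pairs with DI > 0.8: 0
```

All five planted pairs — and only they — exceed the DI > 0.8 flag in the
coupled alignment, while the uncoupled control stays below threshold:
the coevolution signal separates the two domain classes cleanly.
Scripts 01 and 04 do the same for interface classification (exact
recovery of the designed interface set) and the conservation/HP-pattern
analyses.

## Layout

```
R/                  package code (structure/SASA, trajectory/network,
                    graph metrics, DCA, sequence analysis, generators,
                    pipeline)
src/                Floyd–Warshall with shortest-path counts (Rcpp)
analysis/           numbered narrative drivers writing results/analysis/
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests with
                    independent oracles (exhaustive path enumeration,
                    analytic sphere areas, direct-formula evaluation)
vignettes/          methods vignette (model, parameters, design choices)
```
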