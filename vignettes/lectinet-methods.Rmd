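---
title: "Methods: dynamical networks and coevolution analysis of lectin dimer recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamical networks and coevolution analysis of lectin dimer recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectinet)
```

# The scientific problem

Bulb-type (mannose-binding) plant lectins fold into a beta-prism II of
three beta-sheet subdomains and are biologically active as dimers. Two
single-domain monomers must find each other in the crowded cell and dock
through a specific interface; the double-domain relatives fuse the two
domains with a short linker, so their domains never need long-range
recognition. Contrasting the two families is therefore a natural
experiment for separating *short-range* interface complementarity from
*long-range* steering.

`lectinet` implements the three quantitative legs of that comparison:

1. **Structure**: classify residues of a dimer complex into interface,
   surface, interior and ligand-binding sites from solvent-accessible
   surface area (SASA), and extract the interacting cross-chain residue
   pairs.
2. **Dynamics**: build a weighted residue network from trajectory motion
   correlations restricted to persistent contacts, and score residues by
   closeness, betweenness, characteristic path length (CPL) and delta
   path length (DPL).
3. **Sequence**: mean-field direct coupling analysis (DCA) of
   single-domain versus double-domain alignments, an entropy-based
   conservation grade, and a hydrophobic–polar (HP) pattern resampling
   at interface positions.

Because molecular-dynamics trajectories and curated alignments cannot be
regenerated on a laptop, the package ships synthetic generators with
machine-readable ground truth for every stage; the tests and the
acceptance script run the analyses on those generated inputs and check
recovery of the planted truth.

# Residue classification from solvent accessibility

SASA is computed by Shrake–Rupley sampling: each atom's accessible
sphere (van der Waals radius + probe, probe 1.4 Å) carries a
deterministic golden-spiral lattice of sample points (default 960), and
a point is accessible when it lies outside every neighbouring accessible
sphere. Per-atom areas are summed per residue; relative SASA divides by
a bundled table of per-residue-type theoretical maxima (Tien et al.
2013 values), and van der Waals radii come from a bundled NACCESS-style
element table. Both tables are override-able arguments.

A residue is **exposed** when its relative SASA exceeds a threshold,
0.20 by default. The threshold is a genuine free parameter of this kind
of analysis — published conventions range from 0.05 to 0.25 — and 20%
whole-residue accessibility is the mainstream choice; it is configurable
everywhere it appears. Classification then follows the burial logic of
dimer formation:

* **interface** — exposed in the isolated monomer, not exposed in the
  complex;
* **surface** — exposed in both;
* **interior** — not exposed in the monomer;
* **ligand-binding** — within 3.9 Å of a ligand heavy atom (a
  distance stand-in for interaction-diagram software); takes precedence
  in the single category label but is also reported as an independent
  flag, since binding sites may overlap the other classes.

Interacting interface pairs use the standard 4 Å heavy-atom rule: a
cross-chain residue pair is reported when its minimum heavy-atom
distance is below 4 Å. Distances are stored at full precision and
formatted to two decimals in the written table. Hydrogens and waters are
dropped on reading; for alternate locations the highest-occupancy
conformer is kept.

The toy-dimer generator (`make_toy_dimer()`) wraps a sealing shell of
pseudo-atoms around a randomly placed patch of a linear chain. The shell
radius (3.0 Å) and point spacing (1.5 Å) are chosen so that no 1.4 Å
probe can reach a wrapped residue (the gaps between shell spheres are
smaller than a probe), which makes the designed buried set a geometric
certainty rather than an empirical observation; the two bond-neighbours
of the patch sit inside the sealing halo (a 3.8 Å bond cannot escape a
3.0 Å cap) and are part of the designed buried set, while the next
residues out are clearly exposed (relative SASA ≈ 0.67 versus the 0.20
threshold). Residues use standard names (ALA/GLY) so the reference-max
table applies, but chain B is geometry, not chemistry.

# The dynamical residue network

For residues $i,j$ with C$\alpha$ displacement vectors
$\Delta\vec r_i(t) = \vec r_i(t) - \langle \vec r_i(t)\rangle$, the
motion correlation is

$$C_{ij} = \frac{\langle \Delta\vec r_i \cdot \Delta\vec r_j\rangle}
{(\langle \Delta\vec r_i^2\rangle\,\langle \Delta\vec r_j^2\rangle)^{1/2}},$$

computed over all frames, with the diagonal forced to exactly 1 and the
matrix symmetrised against floating-point asymmetry. A residue pair is a
**persistent contact** when its minimum heavy-atom distance is below
4.5 Å in at least 75% of frames ("at least": the boundary counts);
sequence-consecutive residues of the same chain are excluded, since a
backbone bond is not an interaction. Edges connect persistent pairs with
$C_{ij} > 0$ — anticorrelated pairs are removed because the analysis
targets residues moving together — and carry weight

$$W_{ij} = -\log C_{ij}.$$

**Log base.** The natural log is used. Shortest-path structure,
betweenness and closeness *rankings* are invariant to the base (a
uniform scale factor on all weights), so only CPL/DPL magnitudes depend
on the choice; the tests pin the ranking invariance.

**Superposition and frame windows.** No rigid-body alignment is applied
by default: the synthetic generator adds no global motion, and for real
input removing it is the trajectory producer's decision. A
`frame_start`/`frame_end` window on reading supports the common practice
of analysing only the equilibrated tail of a run. Networks are built per
trajectory; no cross-replica averaging is attempted.

# Graph metrics

All-pairs shortest paths are computed by Floyd–Warshall (in C++ via
Rcpp) together with shortest-path counts; path-length ties are resolved
under an absolute tolerance of $10^{-9}$, which is what "two distinct
shortest paths" must mean once weights are floating-point. With strictly
positive weights the counts are exact; zero-weight edges (perfect
correlation) make "distinct shortest path" genuinely ambiguous, which
the documentation flags rather than hides.

* **Closeness** $C(x) = (n-1)/\sum_y d(x,y)$, with $n$ and the sum
  restricted to the connected component of $x$ (isolated nodes score 0
  with a warning).
* **Betweenness** counts, over unordered pairs $\{s,t\}$,
  the number of distinct shortest $s$–$t$ paths with $x$ interior. Raw
  counts are used, not Brandes fractions — that is the literal reading
  of "counting the number of shortest paths … that also pass through the
  node" — and the z-scoring used for flagging removes the scale anyway.
* **CPL** is the mean shortest-path length over unordered reachable
  pairs.
* **DPL**$(x)$ = CPL(after removing $x$) − CPL(before), so positive
  means removal lengthens communication. When removal disconnects pairs
  they are dropped from the post-removal average and the node is flagged
  `dpl_disconnects`; if nothing remains reachable the DPL is `NA`. This
  exclusion convention is a design choice (the alternative is an
  infinite penalty) and is surfaced in the output so downstream users
  can see where it acted.
* **Z-scores** use the population standard deviation (the node set is
  the population, not a sample of one); flags use $z > 1.5$ for
  betweenness and $z > 1.0$ for DPL by convention.
* **Closeness tiers** split nodes into high (top 20%), intermediate
  (20–60%) and low (rest) by rank percentile, ties sharing the better
  tier.

The trajectory generator plants a correlation matrix: displacements per
coordinate axis are drawn as $N(0, a^2 R)$ through the symmetric matrix
square root of $R$, so the measured correlation converges to $R$ in
expectation, and heavy atoms ride rigidly on their residue's C$\alpha$
so the contact set is controlled by the reference geometry. The
fluctuation amplitude defaults to 0.5 Å per axis — a typical C$\alpha$
RMSF — which leaves designed contacts (≈3.4 Å) inside the 4.5 Å/75%
persistence criterion and designed non-contacts (≥4.8 Å) outside it
with wide margins. The bottleneck fixture
(`make_bottleneck_system()`) places two five-residue contact cliques,
one bridge residue joining their gateways, and a weak six-link backup
chain, every residue on its own chain; all inter-cluster shortest paths
cross the bridge, and its removal forces long detours instead of
disconnection, so top betweenness and top DPL are properties of the
construction, not luck. Its planted matrix is built from design values
and, if needed, shrunk uniformly toward the identity until positive
semi-definite — shrinkage preserves the sign and ordering of every
entry.

# Mean-field direct coupling analysis

The alignment alphabet has 21 states (20 amino acids + gap). The
pipeline follows the standard mean-field route:

1. **Gap filter**: columns with strictly more than 50% gaps are dropped
   (a column at exactly 50% stays); the column map preserves original
   numbering.
2. **Reweighting**: sequence $a$ gets weight $1/m_a$, where $m_a$ counts
   sequences (including itself) with identity strictly above 0.8,
   identity computed over all columns with the gap as a 21st state.
   $M_\mathrm{eff} = \sum_a 1/m_a$.
3. **Frequencies** with pseudocount $\lambda = 0.5$:
   $f_i(A) = \frac{1}{\lambda + M_\mathrm{eff}}\left(\frac{\lambda}{21}
   + \sum_a \frac{1}{m_a}\,\delta_{A,A_i^a}\right)$, and the analogous
   pair form with $\lambda/21^2$. The marginal identity
   $\sum_B f_{ij}(A,B) = f_i(A)$ holds exactly and is asserted to
   $10^{-12}$ in the tests. $\lambda$ is configurable; note that this is
   the *bare* pseudocount form — some mean-field implementations scale
   the pseudocount with $M_\mathrm{eff}$, which is a much stronger
   regulariser.
4. **Couplings**: the covariance
   $C_{ij}(A,B) = f_{ij}(A,B) - f_i(A) f_j(B)$ is assembled on the
   reduced basis of the 20 amino-acid states per column — the gap is the
   reference (gauge) state, because the full 21-state matrix is singular
   by construction — and inverted:
   $e_{ij}(A,B) = -\left(C^{-1}\right)_{ij}(A,B)$. Diagonal blocks use
   the single-site multinomial covariance
   $f_i(A)\delta_{AB} - f_i(A)f_i(B)$: pair frequencies are defined for
   pairs of *distinct* sites, and evaluating the pair formula at
   $i = j$ would give identical rows for states unseen in a column and
   an exactly singular matrix.
5. **Direct information**: per pair, an isolated two-site model
   $P^{(2)}_{ij}(A,B) \propto \exp\{e_{ij}(A,B) + \tilde h_i(A) +
   \tilde h_j(B)\}$ is fitted so its marginals equal $f_i, f_j$, by
   alternating multiplicative field updates (Sinkhorn-style matrix
   scaling; convergence when the maximum marginal error is below
   $10^{-6}$, cap 1000 iterations, failure is an error naming the
   pair). A constant shift of the couplings is absorbed by the
   normaliser, so the exponent is centred before exponentiation for
   numerical range. DI is the KL divergence (natural log) of the fitted
   two-site distribution from $f_i \otimes f_j$; it is nonnegative and
   zero exactly when the pair decouples.
6. **Ranking**: pairs sorted by DI; pairs with DI > 0.8 and sequence
   separation ≥ 2 are flagged as coevolution candidates. The 0.8 level
   is the conventional significance threshold when the sequence count is
   comparable to the protein length.

**Numerical behaviour of the bare pseudocount.** The smallest eigenvalue
of each diagonal covariance block is of the order of the
reference-state frequency. When gaps are absent from a column and
$\lambda$ is 0.5, that eigenvalue is $\sim \lambda/(21 M_\mathrm{eff})$
and the inverse amplifies sampling noise into raw couplings of order
$10^2$–$10^3$; the DI, which is gauge-invariant, remains small for null
pairs, but the two-site fit can fail to converge in extreme cases. This
is a property of the method at these settings, not of the
implementation: with populated gap states (real alignments) and
alignments of a few hundred sequences or more the pipeline is
well-behaved, and the planted-pair recovery conditions (L = 30,
M = 2000) separate planted pairs from background by a factor of ~5 in
DI. For very small alignments a larger $\lambda$ is the appropriate
lever, and it is exposed.

**Interface-column subset.** Mapping structure numbering to alignment
columns is data-dependent, so `run_dca(columns = ...)` takes an explicit
column subset instead of guessing a mapping.

The Potts generator samples the pairwise model
$P(A_1,\ldots,A_L) \propto \exp\{\sum_{i<j} e_{ij}(A_i,A_j) + \sum_i
h_i(A_i)\}$ by single-site Gibbs sampling over the 20 amino-acid states
(one chain; 100 burn-in sweeps, one sample kept every 10 sweeps —
defaults configurable), then overlays gaps independently per cell
(default probability 0.05, a realistic low gap rate that also keeps the
reference state of the reduced basis populated). Planted pairs use
match-favouring couplings $e_{ij}(A,B) = s\,[A=B]$; $s = 2.0$ is the
"strong coupling" regime, giving a matched-state probability of ≈0.28
versus 0.05 under independence.

# Conservation grades and HP patterns

The conservation score of a column is $1 - H/\log 20$, with $H$ the
Shannon entropy of the amino-acid distribution (gaps excluded; columns
over 50% gaps flagged, all-gap columns undefined). Scores are binned
into 9 equal-width grades over $[0,1]$, grade 9 most conserved. This is
an explicit stand-in for phylogenetic rate-based conservation: no tree
is inferred, and grade values are not comparable to rate-model outputs —
which is why no numeric conservation values from rate-based tools are
used as test expectations anywhere in the package.

`classify_hp()` uses a configurable hydrophobic set, default
{A, V, L, I, M, F, W, C}. Methionine is hydrophobic under every standard
scale, yet interface literature sometimes groups GLU–MET contacts with
"polar pairs"; the set is an argument precisely so such conventions can
be reproduced, and the default is not silently bent.

`hp_pattern_analysis()` mirrors the study's resampling: per replicate,
31 of 46 single-domain and 11 of 16 double-domain sequences are drawn
without replacement and the residue pair at the two positions is
classified polar–polar / polar–hydrophobic / hydrophobic–hydrophobic;
five replicates by default, one RNG stream per run, seed recorded in the
output. Sequences with a gap at either position are counted in a
separate `gapped` column rather than forced into a class, so the counts
still sum to the subsample size.

# Pipeline, determinism and problem sizes

`run_pipeline()` takes one configuration (list or YAML) with every
threshold pre-filled to the conventions above, validates ranges and file
existence, executes whichever stages the inputs enable in dependency
order, and writes TSV/GraphML/JSON outputs plus a manifest carrying the
parameters, seed and a config hash. Identical configurations produce
byte-identical outputs; the test suite asserts this end to end. The
numbered scripts under `analysis/` are thin narrative drivers over these
same functions.

Problem sizes used by the tests and the acceptance script were chosen as
the smallest at which each property is sharp rather than marginal:
exhaustive path-enumeration oracles run on 200 random graphs of up to 8
nodes (brute force is exact there); the betweenness–DPL sign comparison
uses 20 random connected 50-node graphs; correlation recovery uses 5000
frames (±0.05 tolerance, ~3 standard errors of the estimator);
DCA recovery uses L = 30, M = 2000 and five planted pairs over three
seeds; classification recovery uses ten independently generated dimers.

# What the synthetic data do and do not show

The generators match the *statistical assumptions* of each analysis, not
the physics: correlated Gaussian displacements have no force field,
solvent or thermostat; rigid side-chain riding removes internal residue
flexibility; the Potts sampler has no phylogeny, so sequence weights are
exercised only by explicit duplication fixtures, not by realistic
redundancy structure; the toy dimer's occluder is geometry, not
chemistry. Passing tests therefore demonstrate that each method recovers
exactly the signal class it assumes, at the stated sizes — they do not
validate force fields, alignment quality, or the biological claims one
would draw from real lectin data. Conversely, the crystal-structure
contact table in the acceptance suite runs against the real garlic
lectin structure when a copy is supplied, and the structure-facing code
paths (PDB parsing, SASA, contacts) contain nothing
synthetic-specific.

# Known limitations

* The SASA sampler is pure R and intended for single structures, not
  trajectories of SASA profiles.
* Bare-$\lambda$ mean-field DCA is numerically fragile for very small
  alignments (see above); the pseudocount argument is the remedy.
* Shortest-path counts in graphs with zero-weight edges depend on the
  tie tolerance.
* Multi-model PDB is the only trajectory format read natively;
  coordinates round-trip at PDB's three-decimal precision.
* The conservation grade is an entropy scale, not an evolutionary rate.
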