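---
title: "Depth-based profiling of missense mutation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based profiling of missense mutation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitedepth)
```

## The model

`sitedepth` quantifies where a mutation site sits in a protein and where
its side chain points, using an exposed-volume notion of atom depth. For a
heavy atom $i$ the depth index is

$$D_i = 2\,\frac{V_{\mathrm{exposed}}(i, r)}{V_{\mathrm{sphere}}(r)},$$

the (doubled) fraction of a reference sphere of radius $r$ centered on the
atom that lies outside the protein body. The normalization is chosen so
that the three qualitative regimes are immediately readable: an isolated
atom approaches 2, an atom sitting on an extended flat surface is near 1
(half its reference sphere is inside the body), and a deeply buried atom
is 0. The classification thresholds (0.2 and 0.5 below) live on this
scale.

A residue is summarized by two numbers: $D_{i\alpha}$, the depth of its
C$\alpha$ atom, a proxy for where the residue sits overall; and
$D_{iSC}$, the arithmetic mean depth over its side-chain heavy atoms. A
side chain with $D_{iSC} > D_{i\alpha}$ (strictly) points toward the
surface ("outward"); ties and the reverse ordering are "inward".

Mutation sites are partitioned into three clusters from the wild-type
residue and this summary:

| cluster | rule | interpretation |
|---|---|---|
| 1 | $D_{i\alpha} \le 0.2$, $D_{iSC} < D_{i\alpha}$, wild type in {Ala, Cys, Gly, Ile, Leu, Met, Phe, Val} | inner layer: buried, inward, small/hydrophobic |
| 2 | $D_{iSC} > 0.5$, $D_{iSC} > D_{i\alpha}$, wild type in {Tyr, Phe, Leu, Ile, Val, Trp, Met, Asp, Glu, His, Lys, Arg} | outer layer: exposed, outward, bulky/charged |
| 3 | everything else | intermediate |

The two rule sets are provably disjoint: cluster 1 forces
$D_{iSC} < 0.2 < 0.5$. Cluster-2 sites whose substitution replaces the
wild type by a much smaller residue — volume ratio $V/v > 1.3$, strictly,
with $V$ the wild-type and $v$ the mutant residue volume — are flagged as
candidates for mutation-induced surface pockets. Classification uses the
wild-type structure only; no mutant modeling is attempted, because the
question asked is "what does this substitution remove", not "what does the
mutant fold look like".

### Assumptions

* **Monomeric view.** One chain, first model; quaternary context, ligands,
  waters and ions are excluded. An interface residue will therefore look
  more exposed than it is in the assembly — this is deliberate and should
  be kept in mind when reading cluster-2 calls on oligomeric proteins.
* **Heavy atoms only.** Experimental entries usually lack hydrogens;
  one consistent convention beats two inconsistent ones. The side chain is
  every heavy atom except N, C$\alpha$, C, O and OXT, so C$\beta$ counts
  as side chain.
* **Static geometry.** Depth is computed on a single conformation. Whether
  a flagged void persists or is closed by relaxation is exactly the
  question this tool does *not* answer; it prioritizes sites for dynamics
  or experiment.

## Numerical realization

The protein body is rasterized on a cubic voxel grid: a voxel is occupied
when its center lies within the van der Waals radius of any atom
(Bondi-type radii: C 1.70, N 1.55, O 1.52, S 1.80, Se 1.90 Å, default
1.70 Å; configurable). $D_i$ is then twice the fraction of free voxel
centers among all voxel centers within $r$ of the atom center. The
voxel-center containment test keeps the estimator simple and unbiased in
practice; its quantization error is bounded empirically by the grid
convergence checks in the test suite (halving the spacing moves the
analytic fixtures by well under 0.02).

**Cavity filling.** Internal voids that solvent cannot reach would
otherwise inflate the depth of atoms lining them. With
`fill_cavities = TRUE` (default) the probe-accessible region — voxel
centers at least `probe_radius` (default 1.4 Å) beyond every atom
surface — is flood-filled (6-connected) from the grid boundary; that
reachable region is then dilated back toward the protein by the probe
radius plus half a voxel diagonal, and every free voxel left outside the
dilation is declared cavity and counted as body. The dilation step
matters: without it the thin shell of voxels hugging the *outside* of the
surface (closer than one probe radius, hence not probe-accessible) would
be misclassified as cavity, and even an isolated atom would grow a
1.4 Å crust. One consequence of grid-based accessibility worth knowing:
a channel narrower than about one voxel can connect a void to the outside
on the grid even when a spherical probe could not quite pass — sealed-shell
tests in the suite use comfortably sub-probe gaps, where this cannot
happen.

**Defaults and why.**

| parameter | default | rationale |
|---|---|---|
| `reference_radius` | 10 Å | puts flat surfaces at $D \approx 1$ and keeps the 0.2/0.5 thresholds meaningful; large enough to average over local bumps, small enough that a 25 Å-scale protein still has a buried regime |
| `grid_spacing` | 0.5 Å | ~33,500 sample voxels per reference sphere; quantization ≤ 0.02 on the analytic fixtures; memory a few MB per structure |
| `probe_radius` | 1.4 Å | water-sized probe, the conventional choice for solvent accessibility |
| `fill_cavities` | `TRUE` | buried atoms next to packing defects should read as buried; flag exposed for sensitivity analysis |

The depth literature this index family belongs to does not fix a single
reference radius, and published depth tables rarely state theirs; where a
published value must be matched, `reference_radius` is the knob to
calibrate, and any residual disagreement should be reported together with
the parameter set used.

**Edge conventions.** The atom's own sphere counts as occupied (so an
isolated atom scores $2(1-(r_{vdw}/r)^3) \approx 1.99$, not exactly 2).
Ties: $D_{iSC} = D_{i\alpha}$ is inward; $D_{i\alpha} = 0.2$ is still
cluster-1-eligible (the rule table's $\le$ wins over prose readings);
$D_{iSC} = 0.5$ and $V/v = 1.3$ are not enough (strict). A residue depth
ratio is only reported when $D_{i\alpha} > 0$.

**Glycine.** Gly has no side-chain heavy atom, so $D_{iSC} := D_{i\alpha}$
by convention — under which the strict inward inequality of cluster 1
could never fire, yet Gly is explicitly part of the inner-layer set. The
package therefore relaxes the inward condition for Gly alone: a Gly site
is cluster 1 iff $D_{i\alpha} \le 0.2$, else cluster 3. Relatedly, at
*exact* full burial ($D_{i\alpha} = D_{iSC} = 0$) the strict inequality
fails for every residue and such sites fall to cluster 3; real structures
essentially never produce exact zeros for both, but synthetic ones can,
which is why the planted cluster-1 fixture (below) uses partial burial.

**Alternate locations** keep the highest-occupancy conformer (ties: first
encountered); non-standard residues are skipped with a warning (or
rejected, per configuration).

## Volume table

Residue volumes default to Zamyatnin's classical set (Gly 60.1 Å³ …
Trp 227.8 Å³). Published worked examples of $V/v$ in this field are
sometimes derived from other volume compilations; across common tables the
ratios differ by up to ~3% (e.g. Val→Gly 2.33 here where 2.37 is printed
elsewhere; Trp→Gly 3.79 vs 3.89; Ile→Thr 1.44 vs 1.45). Because the
classification threshold is 1.3 and the interesting substitutions sit far
above it, this systematic difference does not move any pocket-candidate
calls among the worked substitutions. The table is data, not code: supply
any other source via `load_volume_table()` (TSV/CSV, columns `residue`,
`volume`) or `--volume-table`.

## Variant ingestion

Mutations arrive as `Aaa<N>Bbb` strings ("Val149Gly") joined to structures
by file stem, with an optional chain and an explicit per-structure
numbering `offset` (author numbering = sequence position + offset).
Offsets are exposed rather than resolved: reconciling deposited author
numbering with sequence positions is a real, documented source of
off-by-one confusion in published site lists, and a download-free tool
should make the choice visible instead of guessing. The wild-type identity
check is a hard per-row failure (`residue_mismatch`, carrying what was
found) — silently profiling the wrong residue is the worst failure mode of
this kind of analysis. Other non-profiled rows carry `missing_structure`,
`missing_residue` or `plddt_filtered`; every input record appears exactly
once in the output, in input order, and depth is computed once per
structure (the cache provably cannot change results, which the suite
checks by profiling duplicate records).

Predicted models are filtered on confidence: chain-mean pLDDT > 0.8 and
site pLDDT > 0.8, both strict, with the 0–100 scale auto-detected (any
B-factor above 1.5) and rescaled.

## What the synthetic generators emulate — and what they do not

The generators stand in for the experimental/predicted structures a real
study would download, with ground truth known by construction:

* `single_atom`, `lattice_ball`, `slab`, `shell_with_cavity`: carbon
  pseudo-atom bodies whose expected depths are closed-form (isolated atom
  1.990; solid ball of radius 5 Å at $r = 10$: 1.75 at the center; slab
  face 1.00; enclosed atom 0). Lattice balls carry an exact spherical
  shell of atoms at `radius − vdw` so the body surface sits at the nominal
  radius rather than at the lattice quantization.
* `make_helix_bundle`: four (by default) parallel ideal helices (rise
  1.5 Å, 100°/residue) on a circle, each residue an approximate backbone
  plus a single C$\beta$ pseudo-atom planted along the bundle-radial
  direction, outward or inward, with the planted label recorded. A
  1.8 Å pseudo-C$\beta$ (slightly longer than the covalent 1.53 Å) keeps
  the planted orientation unambiguous against grid noise.
* `make_buried_site_fixture`: a solid lattice ball (radius 12 Å) with a
  full residue embedded at radial distance 3.5 Å, C$\beta$ pointing
  inward. The two-sphere intersection formula (`analytic_ball_depth`)
  gives $D_{i\alpha} \approx 0.11$ and $D_{iSC} = 0$ — robust cluster-1
  geometry. This exists because a desk-scale helix bundle *cannot* bury
  anything below 0.2 at $r = 10$ (its whole cross-section fits inside one
  reference sphere), so cluster-1 ground truth needs a bigger body.
* `make_variant_fixture` combines both: outward surface sites renamed Trp
  (→ Gly: cluster 2, pocket candidate) or Lys (→ Arg: cluster 2, $V/v <
  1$, not a candidate), inward sites renamed Ser — chosen precisely
  because Ser belongs to *neither* amino-acid set, so its expected cluster
  (3) is independent of how deep the bundle core happens to be — plus a
  surface Gly site exercising the Gly convention and the buried-ball
  Ala→Val site. Only "robust" bundle positions are planted (|facing
  cosine| ≥ 0.5, away from helix ends).

Passing on these fixtures shows that the geometry engine, the rule logic
and the plumbing are right. It does **not** show that real proteins are
well described: pseudo-C$\beta$ side chains have no rotamers, the bundle
has no loops, turns, or packing heterogeneity, and no fixture reproduces
the depth distribution of a globular proteome. Conclusions about real
variant sets still require real structures.

## Verification strategy and problem sizes

The suite is built around independent oracles rather than frozen outputs:
closed-form sphere geometry for the fixtures; a Monte-Carlo estimator
(10⁵ uniform samples in the reference sphere, point-in-union occupancy,
agreement required within 3σ — run with cavity filling off so both routes
integrate the identical body); an independently coded scalar rule table
swept over all 20 × 31 × 31 = 19,220 classifier inputs; an array-shift
flood fill checking the BFS cavity detection; and `bio3d` as a second
opinion on PDB parsing. Property tests cover range ($D_i \in [0, 2]$),
exact monotonicity under atom addition (on a fixed bounding box, where the
voxel lattice is identical), rigid-motion invariance within quantization
(|ΔD| ≤ 0.05 at h = 0.5), grid convergence, determinism under seed, and
byte-identical CLI reruns.

Default problem sizes keep the full suite around half a minute on one
core: 30-atom blobs for the stochastic properties, a 4 × 20 bundle
(400 atoms) end to end, 28,600-atom slab and 7,300-atom ball lattices for
the analytic checks (depth evaluated at the target atoms only). All of
these are the package's own choices of scale, made to keep the analytic
expectations sharp.

## Known limitations

* Depth values depend on the reference radius; comparisons against other
  depth software require calibrating `reference_radius` first, and
  residual differences at the third decimal are expected from the grid.
* Exact published $V/v$ tables cannot be reproduced without the original
  volume reference; the default table lands within ~3%.
* The monomer assumption inflates exposure at interfaces; the pLDDT
  filter does not rescue badly predicted but confident regions.
* Grid accessibility can open channels within about one voxel of the
  probe diameter; sealed-cavity semantics are exact only for gaps
  comfortably below the probe size.
* No pathogenicity, stability, or pocket-geometry prediction is included
  or implied: the output is a structural prioritization, not a verdict.
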