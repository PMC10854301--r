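---
title: "Methods: differential SASA, cavity detection and interface geometry in strucdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential SASA, cavity detection and interface geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strucdiff` compares two conformations of a multi-chain protein
complex by asking where solvent accessibility, interior void space
and inter-subunit contacts differ.  This vignette explains the models
behind each stage, the tunable parameters and why their defaults are
what they are, the synthetic fixtures the test suite is built on, and
the numerical choices and limitations a careful user should know
about.

## Solvent-accessible surface area

The SASA of an atom is the area traced by the centre of a probe
sphere (water, radius 1.4 Å) rolled over the van der Waals surface.
`atom_sasa()` implements the Shrake–Rupley point method: `n_points`
quasi-uniform directions (a golden-spiral lattice, deterministic for
a given count) are scaled to the expanded radius $R_i = r_i + p$; a
sample point is accessible iff it lies outside every other included
atom's expanded sphere, and

$$A_i = 4\pi R_i^2 \cdot \frac{\#\,\text{accessible}}{n\_points}.$$

Assumptions worth stating explicitly:

* SASA is *local* geometry.  A point is accessible whenever no
  expanded sphere covers it — the method does not ask whether solvent
  could physically reach it.  Residues lining an enclosed cavity
  therefore have nonzero SASA; two atoms stop occluding one another
  as soon as their centres are farther apart than
  $r_1 + r_2 + 2p$ (≈ 6.2 Å for two carbons), the *occlusion
  horizon* used throughout this vignette.
* Hydrogens are excluded by default (experimental models usually lack
  them); waters and other HETATM records are excluded from both the
  target and occluder sets by default, since deposition practice for
  ligands varies.  Both are flags on `sasa_params()`.

Parameters and defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water probe |
| `n_points` | 960 | – | see convergence below |
| `radii` | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, else 1.70 | Å | common vdW set; swappable, and every result records the set name |
| reference table | `tien2013` | Å² | theoretical Gly-X-Gly maxima used for the percent ratio |

Numerical behaviour, as measured by the test suite on the ideal-helix
fixture: doubling `n_points` from 960 moves total SASA by under
0.5 %; a rigid-body rotation changes the total by under 0.5 % but can
move an *individual* atom's area by up to about 1 % of its full
sphere area, because the point lattice is fixed in space while the
neighbour geometry rotates through it.  Per-residue percent ratios
inherit this granularity; the 2.5-point exclusion threshold of the
differential stage is more than an order of magnitude above it.

Neighbour search uses spatial binning with cell size twice the
largest expanded radius; its output is contractually identical to the
all-pairs scan (`method = "allpairs"`), and the suite enforces that.
An independent Monte-Carlo estimator (`mc_sasa()`, uniform sampling
on each expanded sphere, seeded, with per-atom standard errors)
serves as the verification oracle: the lattice and the oracle agree
within three combined standard errors on random clusters, where the
lattice's own sampling error is bounded binomially at
$4\pi R^2\sqrt{0.25/n\_points}$.

## Differential analysis

`align_residues()` pairs analogous residues chain-by-chain with a
global Needleman–Wunsch alignment on one-letter sequences (identity
+1, mismatch −1, gap −2, linear).  Traceback ties are broken
deterministically toward the diagonal, then the gap in the second
sequence.  Identical chains therefore map one-to-one regardless of
author-numbering offsets; indels go to unpaired lists and drop out of
the comparison.

`sasa_ratio_table()` computes, per pair,
$\Delta = |v_a - v_b|$ and the fold ratio
$\max(v_a,\varepsilon)/\max(v_b,\varepsilon)$, on the relative
(percent-of-reference) scale by default.  The floor
$\varepsilon = 0.1$ is applied to *both* operands so that swapping
the two structures maps every ratio to its exact reciprocal — the
antisymmetry the suite tests — while buried-vs-buried pairs (both
below the floor) are excluded as `both-buried` rather than binned as
spurious >50× changes.  Exclusion reasons, in precedence order:
`incomplete-residue` (either partner is missing heavy atoms; repair
is out of scope, and a partial side chain would bias the ratio),
`no-reference` (nonstandard residue type), `both-buried`, and
`small-delta` ($\Delta <$ `exclusion_delta`, default 2.5 points).

The interpretation of the 2.5 threshold is a genuinely open choice:
it could mean percentage points of relative SASA or a percent change
of the ratio.  We default to percentage points of relative SASA —
the natural reading when values are "expressed as a percent ratio"
of a reference maximum — and keep the absolute-Å² mode as an option
(`ratio_mode = "absolute"`), where the same 2.5 is then in Å².

Fold bins are half-open on the greater side, $[3,10)$, $[10,50)$,
$[50,\infty)$, mirrored by reciprocal on the smaller side (so exactly
3.0 is "3–10× greater" and exactly 1/3 is "3–10× smaller"), with
within-3× neutral.  The seven bins carry colour labels (red, orange,
yellow, grey, light green, cyan, dark blue) used by the emitted
colouring script and the B-factor-encoded PDB.

## Cavity detection

`detect_cavities()` quantifies interior voids with one explicit,
testable definition applied identically to both structures of a
comparison:

1. a grid (default 0.5 Å) covers the structure with a margin wide
   enough that all box faces are bulk solvent; each grid point's
   *clearance* is its distance to the solvent-excluded envelope
   (vdW + probe), so EMPTY means positive clearance;
2. bulk solvent is found by flood-filling, from the box faces,
   through points where a sphere of the **detection radius**
   (`detection_multiplier` × probe, default 3 solvent radii) fits,
   and then sweeping that sphere over every reached position
   (a morphological dilation);
3. the remaining EMPTY space is **opened with the solvent probe**: a
   cavity must contain at least one position where a full solvent
   sphere fits, and only space reachable by such a sphere counts.
   Without this step, the sub-probe film left in the crevices between
   the surface atoms of any atomistic wall — space where a probe
   *centre* fits but a probe sphere does not — shows up as dozens of
   meaningless few-Å³ "pockets";
4. connected components (6-connectivity by default, 26 by flag) are
   the cavities and deep pockets; components below `min_volume`
   (5 Å³, single-voxel noise) are dropped, and a boundary-connected
   component whose mouth hosts an inscribed empty sphere larger than
   the **cutoff radius** (`cutoff_multiplier` × probe, default 4
   solvent radii) is open solvent, not a cavity.  With the default
   multipliers the mouth rule is inert (mouth voxels sit below the
   detection radius by construction); it becomes active when the
   cutoff is set below the detection radius.

Volume is voxel count × spacing³.  Ball kernels are rasterised with a
half-voxel tolerance (midpoint rasterisation); an exact-radius kernel
systematically under-covers on coarse grids, and with the correction
the cage fixture's volume changes by well under 10 % when the grid is
halved from 0.5 to 0.25 Å.  Rigid-body transforms move volumes only
within the grid-orientation tolerance (tested at 10 %).  Each
cavity's report carries volume, centroid, bounding box, maximal
inscribed-sphere radius, boundary connectivity, and the residues with
an atom within `lining_distance` (5 Å) of a cavity voxel;
`cavity_between()` keeps only components lined by both of two
selections, which is how "void between subunit A and subunit B"
comparisons are made.

## Interface geometry

* `contacts()`: all and only atom pairs across two non-overlapping
  selections strictly below the cutoff (default 4.0 Å, heavy atoms
  only), with a deduplicated residue-pair summary; verified identical
  to an all-pairs brute-force scan.
* `hydrogen_bonds()`: hydrogen-free criteria for experimental models
  — donor/acceptor elements N, O, S; heavy-atom distance ≤ 3.5 Å; and
  where a covalent antecedent (nearest heavy atom within 1.8 Å) is
  identifiable, an antecedent–atom–partner angle ≥ 90°, enforced on
  both ends since donor and acceptor roles are ambiguous without
  hydrogens.  Criteria are echoed in every output.
* `superpose()`: Kabsch least-squares superposition via SVD with the
  usual determinant correction, requiring ≥ 3 non-collinear pairs;
  cross-checked in the tests against an independent quaternion
  (Horn) implementation.  One numerical fact is worth knowing: for a
  copy with a single atom displaced by 1 Å, the naive expectation
  $1/\sqrt n$ ignores re-centring; the minimized value is
  $\sqrt{(n-1)/n}\,/\sqrt n$, and the optimal rotation removes a
  further share that grows with the displaced atom's distance from
  the centroid.
* `proline_pucker()`: least-squares plane through N, Cα, Cβ, Cδ;
  signed displacements of Cγ and of the backbone carbonyl carbon
  relative to that plane.  Same side → *endo*, opposite → *exo*,
  |Cγ| below `planarity_threshold` (0.1 Å) → *planar*.  This is the
  standard Cγ-endo/Cγ-exo convention, stated here because the
  terms are often used without definition.

Region definitions (a receptor's TM6/TM7/H8, a Gα switch II or Ras
domain) are user configuration — named selection expressions in the
run config — never hard-coded residue ranges.  Generic residue labels
(Ballesteros–Weinstein, CGN) may be attached to `residue_ref()`s as
annotations but are never parsed for geometry; author numbering is
authoritative.

## The synthetic fixtures and what they do (and do not) show

All expected values in the test suite come from construction:
analytic solids (isolated spheres, the two-sphere spherical-cap
formula), brute-force oracles, or generated complexes whose
behaviour follows from geometry.  The generators are deterministic,
parameter-echoing, and deliberately geometric rather than biological
— poly-alanine helices and pseudo-glycine shells validate the
pipeline, not any particular protein.

The central fixture is the **socket complex**
(`make_socket_complex()`): a 40-residue ideal helix (chain A) capped
by a concave two-layer shell (chain B) built as an offset surface of
the helix top — at 4.6 Å over a polar cone (inside the 5 Å interface
cutoff) and 5.6 Å further out, with a cylindrical sleeve hugging the
flank below the rim.  The design exploits the occlusion horizon: a
displacement $d$ along the interface axis moves an atom pair at
distance $D$ and axis angle $\theta$ to
$\sqrt{D^2 + d^2 + 2Dd\cos\theta}$, so contacts at $D \ge 4.6$ Å
within the cone (and any orientation at $D \ge 5.4$) leave the
horizon entirely after a 3 Å opening.  The generator verifies this
release inequality constructively and drops any shell atom that
would violate it.  The result is an interface that the opening
motion *fully disengages*: interface residues are strongly buried
when closed and essentially free when open, so their fold changes
land deep in the "greater" bins, while residues far from the
interface are untouched.  A conventionally packed helix dimer
(`make_helix_dimer()`, 10 Å axis separation, van der Waals contact)
deliberately remains in the suite for SASA subadditivity and contact
tests; note that a rigid 3 Å translation merely *stretches* its
tight lateral contacts (pairs at vdW distance and
$\theta \gtrsim 45^\circ$ stay inside the horizon), producing fold
changes below 2× — a useful reminder that per-residue fold-change
analysis highlights released interfaces, not stretched ones.

The sleeve serves the cavity study: it slides *along* the flank when
chain B lifts, keeping the space between helix top and cap sealed
against the detection probe at every separation.  With the cap
engaged (`chamber = 0`) that space is thinner than a water sphere and
counts as no void; with the cap pre-lifted (`chamber = 6` Å) it is an
enclosed inter-chain cavity at every $d$ whose volume grows
monotonically with the separation — the configuration used for the
void-growth tests.  The sphere cage (`make_sphere_cage()`, 60 atoms
on an 8 Å sphere) enquires the volumetric accuracy: its enclosed void
is compared against the idealised interior sphere of radius
$8 - (1.70 + 1.4)$ Å within 15 % — the tolerance absorbs the real
difference between the idealised sphere and the lumpy true void
between discrete atoms — and removing a 70° polar cap opens a mouth
wider than the detection radius, turning the void into bulk solvent.

What passing these tests does **not** show about real data: the
fixtures have no side-chain rotamers, no B-factor/occupancy
heterogeneity, no missing loops, no ligands or lipids, and their
"open" state is a rigid translation rather than a remodelled
interface.  On experimental structures the analyst must still choose
whether ligands occlude (`include_hetero`), check the
incomplete-residue report (the package detects but never rebuilds
missing side chains), and remember that differential results compare
*models*, inheriting whatever refinement choices the models embody.

## Determinism and the run manifest

Every stage is deterministic given its inputs: generators take no
hidden state, the SASA lattice is fixed, alt-loc resolution and
alignment tie-breaks are specified, and `run_comparison()` writes a
manifest recording every parameter (including defaults) alongside
fixed-format TSV/JSON outputs, so a re-run is byte-identical — which
the acceptance suite verifies with checksums.  The Monte-Carlo oracle
is the only randomised component and is seeded explicitly.

## Problem sizes

The shipped studies run at deliberately modest scale: 40–48-residue
helices (a few hundred atoms), 960 lattice points, 0.5 Å cavity
grids over ~1–3 million voxels, and 20-atom clusters with 20 000
Monte-Carlo samples per atom.  These sizes keep every oracle
comparison exact or tightly bounded while exercising the same code
paths a full receptor–heterotrimer comparison would use; the
algorithms scale with atom count × neighbours (SASA), grid volume
(cavities) and selection sizes (contacts).
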