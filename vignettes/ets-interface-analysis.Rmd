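---
title: "Analysing Ets domain-DNA interfaces with etsface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing Ets domain-DNA interfaces with etsface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etsface)
library(dplyr)
```

## The problem

Ets transcription factors recognise DNA through an ~85-residue winged
helix-turn-helix domain whose recognition helix inserts into the major groove
at an invariant 5'-GGA(A/T)-3' core; the full Ets-binding site (EBS) spans
nine base pairs, numbered -3 to +6 with the first G of the GGA at +1 (there is
no position 0). `etsface` packages the quantitative analyses such complexes
call for:

* **Contact anatomy** — hydrogen bonds, salt bridges and van der Waals
  contacts at the protein-DNA interface, classified by the DNA moiety they
  touch (phosphate backbone, sugar, major- or minor-groove base edge) and by
  EBS position.
* **Interface burial** — Shrake-Rupley solvent-accessible surface area (SASA)
  and buried contact area, for protein-DNA complexes and for protein-protein
  (e.g. disulfide-linked dimer) interfaces.
* **DNA deformation** — Watson-Crick pair detection, per-pair reference
  frames, helix bend, and raw cross-strand P-P groove widths, all reported
  against an idealized straight B-form rebuild of the same sequence.
* **Water-mediated readout** — bridging waters between protein and DNA, their
  conservation across superposed complexes, and exhaustive enumeration of the
  hydrogen donor/acceptor assignment over the local network.
* **Modifications** — in-silico 5-methylcytosine and phosphoserine with rigid
  steric clash scanning.
* **Order-disorder profiling** — mean-centred per-residue B-factor profiles
  for apo versus DNA-bound comparison, plus pairwise global sequence identity.
* **Binding energetics** — simulation and fitting of EMSA-style equilibrium
  isotherms under the specific one-site model with Hill slope, and
  fold-inhibition statistics.

Everything operates on a tidy atom table (`ets_structure`, a tibble with one
row per atom carrying author residue numbering), read from PDB or mmCIF files
or generated synthetically.

## The synthetic-structure generators

Real deposited coordinates are inputs the user supplies
(`read_deposited()`); every algorithm in the package is additionally
exercised against synthetic structures with planted ground truth, generated
by three functions.

`build_bdna()` constructs an idealized straight-fiber B-DNA duplex: twist
36 degrees and rise 3.38 A per step, planar Watson-Crick pairs built from
literal 2D base templates (regular-ring idealization with standard bond
lengths), C1'-C1' = 10.4 A, and a cylindrical sugar-phosphate backbone. The
phosphorus cylinder (radius 9.918 A, azimuth 87.77 degrees, z offset
-1.879 A) was fixed once so that successive intra-strand P-P distances are
7.0 A and the cross-strand P-P groove baselines fall at 11.93 A (minor) and
17.74 A (major), close to the canonical raw B-form values of roughly 11.7 and
17.5 A. Base-pair hydrogen-bond distances close at 2.80-2.97 A. The model is
deliberately sequence-independent: it is the *reference* that deformed DNA is
compared against, not a shape predictor, so features of real DNA such as
sequence-dependent roll/twist variation, propeller twist and backbone
conformational substates are absent. Tests passing on the fiber therefore
demonstrate correctness of the geometric machinery, not fidelity of the fiber
to any particular crystal.

`build_planted_complex()` adds side-chain fragments (Ser, Gln, Lys, Arg, Asp,
Tyr, Ala templates) positioned so that one named atom sits at an exact
requested distance from a named DNA atom, the fragment body pointing away
from the duplex, plus optional waters placed at explicit points or between
two anchors. A builder-level check rejects geometries in which any
non-bonded atom pair comes closer than 1.5 A.

`build_water_network_fixture()` is a synthetic stand-in for the conserved
four-water recognition cluster seen upstream of the GGA core in
high-resolution Ets-DNA complexes. It chains four waters from the free amino
edge of the -1 cytosine (N4) out to the phosphate backbone and surrounds them
with aspartate, arginine, serine and tyrosine fragments, choosing positions
by deterministic clearance-maximizing scans so that the hydrogen-bond graph
at the 3.5 A cutoff contains *exactly* the designed twelve edges. One detail
is worth stating plainly: inside a straight fiber the phosphates of the -1
and -2 cytosines are 12-16 A from the -1 base edge, too far for a four-water
chain, so the fixture anchors the chain instead on the -2 pair guanine O6,
the CpG-step phosphate and the following core phosphate. The chemistry-class
composition (carboxylate, guanidinium, hydroxyls, amino group, phosphate
oxygens), the bridging property of all four waters, the forced uniqueness of
the hydrogen assignment, and the conclusion that the base-facing water must
*accept* from the -1 base are all preserved; the exact anchor atoms are not
those of a real complex, in which groove widening changes the reachable set.
The builder verifies the realized edge set and the uniqueness at run time and
aborts on any mismatch, so the fixture cannot silently drift.

## Models and conventions

**Hydrogen bonds (heavy-atom criterion).** Deposited structures at these
resolutions carry no hydrogens, so a hydrogen bond is a donor-acceptor pair
from the internal per-residue chemistry dictionary at D-A <= 3.5 A, with an
antecedent-donor-acceptor angle >= 90 degrees where the donor has a covalent
antecedent (a proxy excluding geometrically impossible hydrogen positions).
Histidine ring nitrogens are treated as neutral and ambivalent. Salt bridges
are Lys/Arg nitrogen to carboxylate/phosphate oxygen pairs at <= 4.0 A
(minimum N-O per residue pair), and atom pairs that qualify as salt bridges
are excluded from the hydrogen-bond list, keeping the three contact classes
mutually exclusive. The any-atom "contact" cutoff used for the base-pair
span is 3.9 A. The cutoffs are package defaults exposed through every
function signature and through `default_thresholds()`; none of them is stated
in the source study, so they are calibration choices.

**Buried area.** `interface_area()` reports the contact area in the
half-dSASA convention, `(SASA(A) + SASA(B) - SASA(AB)) / 2`, the one-face
convention used by assembly-analysis servers; `convention = "sum"` gives the
unhalved total. Per-side percent-of-monomer burial uses that side's unhalved
dSASA over its separated SASA. SASA itself is Shrake-Rupley with a
deterministic Fibonacci sphere (default 960 points, probe 1.4 A, literal vdW
radii C 1.70 / N 1.55 / O 1.52 / S 1.80 / P 1.80 A); waters are excluded by
default. Refining 960 to 3840 points moves totals by under 0.5% on the test
fixtures.

**DNA geometry.** Pairs are detected by complementary identity, Watson-Crick
edge N1-N3 distance <= 3.5 A, C1'-C1' in 9.5-11 A, and base-plane normal
angle <= 65 degrees, then reduced to the maximal non-conflicting set (greedy
by edge distance -- deterministic and order-invariant). The pair frame puts
its origin at the WC-nitrogen midpoint, y toward the reference strand's C1',
z along the mean base normal (5'->3'), x into the major groove. The bend is
the angle between the mean z-axes of the terminal four pairs at each end;
pair origins lie off the helix axis, so averaging normals is the stable
local-axis estimator at these lengths (a 10-mer has no well-defined global
curvature). Groove widths are raw cross-strand P-P minima over pair-level
offset windows fixed from the fiber geometry (minor: offsets 2-5, the
j = i - 3 region; major: offsets -5..-1); no probe-radius subtraction is
applied, because the published groove extrema sit near raw-P-P baselines.
Both windows are arguments, since groove conventions differ between programs.

**Hydrogen-assignment enumeration.** The network around chosen waters is a
graph whose nodes carry a chemistry class -- `donor_only` (Lys NZ, Arg NE/NH,
amide NH2, base exocyclic amino groups), `acceptor_only` (carboxylate and
phosphate oxygens, carbonyls, ring N acceptors), `ambivalent` (hydroxyls,
His ring N; 1 donation / 2 acceptances) or `water` (2 donations / 2
acceptances) -- and whose edges are candidate bonds within the cutoff
involving at least one water. Bifurcated bonds are disallowed: each edge
takes exactly one direction. `enumerate_h_assignments()` expands the 2^E
orientation space edge by edge, discarding partial assignments only when a
capacity or class constraint is already violated, so the enumeration is
exhaustive and exact; graphs above 25 edges are refused rather than searched
heuristically. Waters below occupancy 0.5 are ignored by the bridging-water
search (the study restricts ordered-water analysis to < 2.0 A resolution
data; the package warns when no waters are present).

**Modifications.** 5-methylcytosine places the methyl in the base plane at
1.50 A from C5 on the external ring-angle bisector; phosphoserine builds a
PO3 group with P-OG 1.61 A and P=O 1.48 A at tetrahedral angles, with the
CA-CB-OG-P torsion exposed for rotamer scanning
(`phosphoserine_scan()`). No relaxation follows the modification: the clash
report (`clash_scan()`, positive vdW overlap, "clash" at >= 0.4 A overlap) is
a rigid-model statement, which is the stated limitation of this kind of
static modelling.

**Binding model.** Isotherms follow the specific one-site model with Hill
slope, f(c) = Bmax c^h / (Kd^h + c^h), on a default 12-point log grid over
1e-14..1e-6 M. Fitting is Levenberg-Marquardt least squares in log10(Kd)
with multi-starts at every decade of the grid, Hill constrained to (0.2, 5)
and Bmax to (0.05, 1.2); standard errors come from the Jacobian covariance
(delta method back to the Kd scale). Curves whose top-of-titration signal
stays below 0.05 are flagged non-binding rather than fitted, mirroring the
"undetectable binding" entries of published affinity tables. No
probe-depletion correction is applied by default -- experimentally the probe
concentration was lowered instead -- and `redox_mixture_model()` provides the
two-species monomer/dimer additive curve used to emulate glutathione
titration series qualitatively.

## Design choices that were genuinely open

* The superposition pairing defaults to alpha-carbons matched by author
  residue number; cross-protein comparisons renumber through the published
  residue-correspondence offsets first. The original study does not state
  which atoms defined its superpositions.
* The "contact area" convention (half versus sum) and the denominator of
  percent-burial are both unstated in the source; the package defaults (half;
  separated-side SASA) make the published dimer numbers internally
  consistent, and both are switchable.
* Sequence identity uses Needleman-Wunsch with identity scoring (+1/0, gap
  -1) and excludes terminal gaps from the denominator, since domain-range
  inputs make internal gaps rare. Identities are computed over domain
  sequences, not full-length proteins.
* B-factor profiles average all atoms of a residue by default (backbone-only
  is available) and are mean-centred only -- no variance scaling -- exactly
  as order-disorder profile figures are usually normalized.

## Problem sizes

The shipped test-suite and acceptance computations use 6-20-mer duplexes
(400-900 atoms), toy complexes under 500 atoms (where detection is verified
against exhaustive all-pairs oracles), SASA at 960-10,000 points, random
assignment networks of up to 12 edges against a recursive backtracking
oracle (100 seeds), and 100 seed pairs of simulated isotherm fits for the
fold-inhibition recovery. These sizes make every property cheap to verify
exhaustively while leaving the algorithms identical to what runs on full
crystal structures.

## A worked example

```{r example}
# a toy complex: serine hydrogen-bonded to the +1 phosphate, lysine
# salt-bridged to the complementary strand
cpx <- build_planted_complex(
  hbonds = list(list(res = "SER",
                     target = list(chain = "A", resno = 4, elety = "OP1"),
                     distance = 2.9)),
  salt_bridges = list(list(res = "LYS",
                           target = list(chain = "B", resno = 4, elety = "OP2"),
                           distance = 3.2))
)
pairs <- find_base_pairs(cpx)
cm <- contact_map(cpx, pairs = pairs)
cm$contacts |> select(kind, resid1, resno1, atom1, atom2, distance,
                      dna_part, ebs_position)

interface_area(cpx, list(kind = "protein"), list(kind = "dna"))

# binding: simulate at the wild-type affinity, refit, compare with a mutant
wt <- fit_isotherm(simulate_isotherm(2.7e-10, noise_sd = 0.02, seed = 1))
mut <- fit_isotherm(simulate_isotherm(2757e-10, noise_sd = 0.02, seed = 2))
fold_inhibition(mut, wt, "R->A variant", "wild type")
```

## Known limitations

* The fiber model is straight and sequence-independent; `compare_to_bform()`
  deltas on real DNA mix true deformation with the idealization error of the
  reference.
* Heavy-atom hydrogen-bond criteria cannot distinguish donor tautomers
  beyond the fixed chemistry classes; the enumeration reports ambiguity
  rather than guessing when more than one arrangement satisfies the network.
* Clash scanning is rigid -- no side-chain relaxation -- so reported overlaps
  are upper bounds on the steric cost of a modification.
* Assemblies are analysed as given: no symmetry-mate generation beyond
  user-supplied copies, no electron-density or refinement handling.
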