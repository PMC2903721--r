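---
title: "Annotating RNA 3D structures and querying them as a knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating RNA 3D structures and querying them as a knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnakb)
```

## What the package computes

`rnakb` turns an RNA coordinate file into a queryable knowledge graph in
four stages:

1. **Parsing** (`read_pdb()`): a PDB file becomes a molecular structure
   file object — one structure model per `MODEL` record (NMR ensembles),
   chains of residues ordered by author numbering, and per-residue atom
   tables. Residues are classified as standard ribonucleotides (`A`, `C`,
   `G`, `U`), `modified` (a nucleobase ring with a nonstandard name or a
   missing 2'-OH), or `non_nucleic`, purely from atom content.
2. **Annotation** (`annotate_model()`): geometric detection of hydrogen
   bonds, base pairs classified on the Leontis–Westhof edges
   (Watson–Crick / Hoogsteen / sugar) and the finer Lemieux–Major
   sub-edges ("faces", e.g. `Ww`, `Hh`, `O2p`), base stacks with
   sequence-adjacency and base-normal-orientation qualities, ribose
   pucker (envelope / twist, with endo / exo apex sides), and glycosidic
   conformation (syn / anti).
3. **Population** (`build_graph()`): the structure and its annotations
   become RDF-style triples under a bundled ontology catalog
   (`load_schema()`). Information content entities (the file, its
   structure models) are kept distinct from the material entities they
   are about (molecules, residues, atoms, base pairs, base stacks) and
   from the qualities those bear.
4. **Querying** (`evaluate_expression()`, `run_stored_query()`): a
   Manchester-syntax subset — named classes, `and`/`that`, `or`, `some`,
   `exactly n`, `inv(p)`, nominals — is evaluated closed-world over the
   saturated graph.

## The interaction model and its thresholds

Hydrogen bonds are detected between heavy atoms only, from a bundled
donor/acceptor table (ring N–H donors, sp² amino donors, the 2'-hydroxyl
in both roles; N/O acceptors). A candidate bond must satisfy, with
defaults from `annotation_params()`:

* donor–acceptor distance within **[2.4, 3.5] Å**, the usual heavy-atom
  window for N/O hydrogen bonds;
* antecedent–donor–acceptor angle **≥ 90°**, ruling out bonds that would
  point back through the donor's covalent frame;
* the donor–acceptor direction within **45°** of the nearest plausible
  hydrogen direction. Ring N–H hydrogens sit on the outward bisector of
  the two ring bonds; amino hydrogens sit in the base plane at ±60° from
  the bisector; the 2'-OH hydrogen is torsionally free and is modeled as
  a 60° cone about the C2'–O2' extension.

A base pair is any residue pair with at least one hydrogen bond between
face atoms (`pair_min_interactions = 1`); bonds are grouped by (face,
face) into sub-edge interactions. The Leontis–Westhof edge on each side
is the edge of the face carrying the most bonds (ties fall back to the
first interaction), and the pair is `cis` when the two glycosidic bonds
point to the same side of the pair axis. The face table assigns each base
atom to exactly one Lemieux–Major face; only the O2'/C8 atom-level faces,
the N9/N1 sugar-side extension, and the face-to-edge agglomeration are
pinned by the published classification — per-atom assignments in between
are a documented approximation, chosen so canonical Watson–Crick pairing
yields `Ww/Ww` (plus `Wh/Wh`, `Ws/Ws`) interactions.

Stacking uses base reference frames (`base_frame()`): ring-atom centroid
and least-squares plane normal, with handedness fixed by the tabulated
ring traversal so file order is irrelevant. Two bases stack when their
centroids are within **5.5 Å**, the angle between normals (or its
supplement) is at most **35°**, and the centroid offset projects at least
**2.0 Å** onto the mean normal (this last test is what separates a
stacked neighbor from a hydrogen-bonded partner, whose offset is in-plane).
The orientation quality follows the signs of the projections of the
centroid offset on the two normals: (+,+) upward, (−,−) downward, (+,−)
inward, (−,+) outward.

Pucker classification follows the plane-based definition: an **envelope**
has one ring atom displaced from the plane of the other four (the quad
coplanar within `pucker_tol` = 0.10 Å, the apex beyond it), a **twist**
has two atoms on opposite sides of the plane of the remaining three. The
apex is `endo` when displaced to the same side as C5', `exo` otherwise.
When several candidates qualify, the largest apex deviation wins; on
symmetric constructed rings the winning *pair* of twist apexes can be
ambiguous, which is why the generator's recovery guarantees are stated
for envelopes only. The glycosidic torsion is O4'–C1'–N9–C4 (purines) /
O4'–C1'–N1–C2 (pyrimidines), `syn` within [−90°, +90°].

## URI naming and graph shape

Local names follow one scheme throughout (prime characters become `p`):
`PDBID` (file), `PDBID_mM` (structure model), `PDBID_cC` (chain
molecule), `PDBID_cC_rR` (residue), `PDBID_cC_rR_aATOM` (atom),
`_ns`/`_rib`/`_nb` residue parts, `PDBID_mM_cC_rR_QUALITY` (per-model
qualities), `..._bp`/`..._stk` (pair/stack individuals),
`PDBID_mM_cC_rR_seFACE` (sub-edge participants). Residues, atoms and
molecules are model-independent material entities; features and
qualities are minted per model, which preserves provenance across an NMR
ensemble.

Two representational choices matter for querying:

* **No edge individuals are asserted.** Pair participants are typed at
  the sub-edge level, as the annotator observes them. Edge-level queries
  work through the agglomerating sub-edge classes (e.g. the Hoogsteen
  agglomerate is the union of the `C8`, `Hh`, `Hw`, `Bh` classes) and
  their axioms (each agglomerate is part of its edge). The evaluator
  honors these axioms with a TBox shortcut: an individual typed `C`
  satisfies `p some E` when the schema asserts `C SubClassOf (p some D)`
  with `D` below a named disjunct of `E`. For the positive-existential
  fragment the stored queries use, this returns exactly what a
  description-logic reasoner would certify, without materializing
  anonymous individuals. The shortcut requires a named (or
  union-of-named) filler; other fillers under an axiom-bearing property
  raise an unsupported-expression error rather than a silent wrong
  answer.
* **Parthood is transitive and counting is not.** `has part` / `part of`
  are transitive and close through residues: a pair *has part* every
  sub-edge participant attached to its residues — in any model, since
  residues are model-independent. This is the entailment a reasoner
  would draw from the same assertions, and the planned-fixture ground
  truth reproduces it combinatorially. Qualified cardinality
  (`exactly n`) instead counts only `has proper part` fillers, the
  non-transitive subproperty, which is what makes patterns like "a base
  pair with exactly 2 residues" well-defined.

Saturation (`saturate()`) materializes subclass and union membership,
sub-properties, inverses, symmetry (`externally connected to`) and
transitivity to a fixed point; it is idempotent, and serialization
(N-Triples or a line-oriented Turtle) is sorted and deterministic.

## The synthetic duplex generator

`make_duplex()` builds an idealized A-form-like duplex with known ground
truth and no downloads. Bases are planar idealized templates (regular
hexagons, fused regular pentagons, 1.38 Å ring bonds, radial exocyclic
substituents). A Watson–Crick pair frame is constructed deterministically:
the two complementary bases' hydrogen-bond rails are aligned in parallel
with every canonical bond at 2.9 Å, a base whose ring body would face the
wrong half-plane is flipped 180° about the rail line (a proper rotation
for a planar base, giving the antiparallel base normals of a real
duplex), and the frame is recentred on the mean ring centroid. Pairs are
stacked with the canonical A-form rise (2.81 Å) and twist (32.7°);
riboses are attached with an exact C3'-endo envelope (apex displacement
0.5 Å) and an anti glycosidic torsion (χ = −160°).

Two aspects are deliberately stylized rather than chemically realistic,
and both are documented because they define what passing tests do and do
not show:

* The helix axis passes through the base-pair centroids (no x
  displacement, no inclination). Real A-form helices displace the pairs
  ~4.4 Å off-axis, which brings cross-strand neighbors close enough that
  real annotators report cross-strand stacks. The idealized geometry
  keeps the ground truth clean: exactly the n complementary `Ww/Ww`
  pairs and the 2(n−1) intra-strand adjacent stacks, stable for n from 2
  to 12 and under ±10% variation of every threshold.
* The O2' is placed over the ribose ring on the C5' side. Every
  chemically faithful placement tried put some 2'-hydroxyl within
  hydrogen-bond distance of a neighboring residue's face atoms for some
  sequence, contaminating the ground truth with spurious O2'-mediated
  pairs; the stylized position keeps all such contacts either outside
  the distance window or rejected by the hydrogen-direction test.

Gaussian coordinate noise (`noise_sigma`, per model, seeded) probes
robustness. At σ = 0 the annotator recovers the ground-truth pair and
stack sets exactly; under noise, agreement is measured as the F1 score
over the union of pair and stack sets (recall stays 1.0; the errors are
false-positive borderline 2'-hydroxyl contacts): about 97.6% at σ = 0.05
and 95.4% at σ = 0.1 over 20 seeds. Because the fixture is idealized —
planar bases, uniform helical parameters, no loops, bulges, tertiary
contacts or modified residues — passing on it validates the pipeline's
internal consistency, not annotation accuracy on experimental NMR
ensembles.

`make_kb_fixture()` bypasses geometry entirely: a planned set of pairs
and stacks (with chosen sub-edge interactions) is pushed through the
regular emission rules, and the expected answer sets of the six stored
query templates are computed combinatorially from the plan. This is the
oracle used for the query-engine equivalence tests.

## Worked example

```{r pipeline}
schema <- load_schema()
d <- make_duplex("GGCGCC", n_models = 2, pdb_id = "SYN1")
g <- saturate(build_graph(d$structure, schema = schema), schema)
g

run_stored_query("A", g, schema, pdb_id = "SYN1")$cardinality

length(instances_of(g, "nucleotide_base_pair"))

evaluate_expression(
  "'nucleotide base pair' that 'has proper part' exactly 2 'nucleotide residue'",
  g, schema)$cardinality
```

## Numerical choices and degenerate inputs

* Plane fitting is least-squares (smallest singular direction)
  everywhere a plane is needed, for robustness to noisy rings; collinear
  inputs raise a degenerate-plane error.
* Torsions use the IUPAC sign convention (verified against an
  independent projection construction and against `bio3d`); collinear
  triples raise an undefined-torsion error.
* Alternate locations keep the highest-occupancy atom per name, ties
  broken by file order. Hydrogens are kept when present but never
  required.
* Tie-breaks in ordering are lexicographic by (chain, residue number,
  insertion code, atom name); serialization sorts triples, so repeated
  runs are byte-identical.
* Detector failures on incomplete residues (missing ring atoms, missing
  sugar) degrade to per-residue warnings, never a global failure; a
  standard-named residue stripped of its nucleobase is flagged
  explicitly.

## Known limitations

* Pair typing is purely geometric; there is no probabilistic
  classification, and bifurcated faces (`Bw`, `Bh`, `Bs`) are reachable
  through planned fixtures but not asserted by the geometric detector.
* Only pairwise interactions are represented; base triples appear as
  multiple pairs.
* The query fragment is positive-existential with qualified cardinality;
  negation, universal restrictions and datatype restrictions are out of
  scope, as is full OWL-DL consistency checking.
* The bundled catalog is a static minimal-import subset; external
  ontology identifiers are carried as cross-references, not resolved
  live.
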