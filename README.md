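# rnakb

Structure-based RNA knowledge in a queryable graph. `rnakb` parses RNA 3D
coordinate files (PDB format, including multi-model NMR ensembles),
annotates their structural features, populates an RDF-style knowledge
graph under a bundled ontology catalog, and answers description-logic
style class-expression queries over it. It is aimed at structural
bioinformaticians who want to ask ontology-level questions of structure
annotations — "which base pairs involve a Hoogsteen edge on a guanosine?"
— without running a reasoner stack.

## What it computes

* **Base pairs** classified on the Leontis–Westhof edges (Watson–Crick,
  Hoogsteen, sugar) and the finer Lemieux–Major *sub-edges* / faces
  (`Ww`, `Wh`, `Hh`, `C8`, `O2p`, ...), detected from heavy-atom
  hydrogen-bond geometry (donor–acceptor distance 2.4–3.5 Å, antecedent
  angle ≥ 90°, implied-hydrogen deviation ≤ 45°), with cis/trans
  orientation.
* **Base stacks** with sequence-adjacency and base-normal-orientation
  qualities (upward / downward / inward / outward from the signs of the
  centroid offset on the two base normals).
* **Ribose pucker** (envelope / twist, endo / exo apex sides, from
  least-squares ring planes) and **glycosidic conformation** (syn / anti
  from χ = O4'–C1'–N9/N1–C4/C2).
* **A knowledge graph**: file and structure-model individuals (information
  content entities) linked to molecules, residues, atoms, pairs, stacks
  (material entities) and their qualities, with URIs minted as
  `PDBID_cA_r34`, `PDBID_m5_cA_r34_anti`, `PDBID_m5_cA_r34_cA_r36_bp`, ...
* **Queries**: a Manchester-syntax subset (`and`/`that`, `or`, `some`,
  `exactly n`, `inv(p)`, nominals) evaluated closed-world after
  saturation (subclass/union, inverse, symmetric and transitive closure).
  Edge-level questions work over sub-edge-level assertions through
  agglomerating sub-edge classes — e.g. the Hoogsteen sub-edge class is
  the union of the C8, Hoogsteen-Hoogsteen, Hoogsteen-Watson and
  bifurcated-Hoogsteen sub-edge classes, each axiomatized as part of the
  Hoogsteen edge. Six query templates (A–F) covering model counting and
  Hoogsteen-involvement patterns ship with the package
  (`run_stored_query()`).

Synthetic generators (`make_duplex()`, `make_pucker_ring()`,
`make_kb_fixture()`) produce idealized A-form duplexes, constructed
pucker rings and planned knowledge graphs with exact ground truth, so the
whole pipeline is testable offline.

## Worked example

```r
library(rnakb)

schema <- load_schema()
d <- make_duplex("GGCGCC", n_models = 2, pdb_id = "SYN1")
d$structure
#> <molecular structure file PDB:SYN1, 2 model(s), 2 chain(s), 12 residues/model>

g <- saturate(build_graph(d$structure, schema = schema), schema)
g
#> <kb graph: 7241 triples, 491 typed individuals, 3 labels>

# how many structure models does the file carry?
run_stored_query("A", g, schema, pdb_id = "SYN1")$cardinality
#> [1] 2

# base-pair individuals: 6 Watson-Crick pairs in each of 2 models
length(instances_of(g, "nucleotide_base_pair"))
#> [1] 12

# every pair has exactly two residues through the non-transitive
# counting property
evaluate_expression(
  "'nucleotide base pair' that 'has proper part' exactly 2 'nucleotide residue'",
  g, schema)$cardinality
#> [1] 12
```

The first number answers the model-count template over the file nominal;
the second is the extension of the pair class after saturation; the third
shows qualified cardinality over `has proper part` (counting is kept off
the transitive `has part` on purpose). A command-line wrapper is
installed as `exec/rnakb`:

```sh
rnakb fixtures duplex --seq GGCGCC --models 2 --out toy.pdb
rnakb annotate toy.pdb --model 1 --out annotations.json
rnakb build-kb toy.pdb --format turtle --out kb.ttl
rnakb query kb.ttl --expr "'nucleotide base pair'"
```

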