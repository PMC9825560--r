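# megasynth

Simulation and search tools for modular megasynthase assembly lines —
type I polyketide synthases (PKS), nonribosomal peptide synthetases
(NRPS), and their hybrids — aimed at people designing chimeric enzymes:
which natural cluster to start from, what every module's intermediate
looks like, and which concrete domain changes turn one architecture into
another.

Because these assembly lines are collinear, the ordered domain
architecture of a cluster deterministically predicts its chemistry.
`megasynth` exploits that three ways:

* **Product simulation.** A rule engine applies each domain's reaction to
  a carrier-bound chain: KS/AT decarboxylative Claisen extension with the
  AT-selected extender (mal/mmal/emal/mxmal); the KR → DH → ER reductive
  loop (β-ketone → β-hydroxyl → *E*-alkene → methylene) with
  Keatinge-Clay-style KR typing (A/B stereo series, C1 passthrough, C2
  α-epimerase); α- and N-methylation, N-formylation, L→D epimerization;
  C-domain amide condensation (LCL/DCL/Glycopeptide/Dual) and Cy
  heterocyclization of Cys/Ser/Thr to thiazolines/oxazolines with
  A-domain oxidation/reduction to azoles/azolidines; release by TE
  (hydrolysis, macrolactone, macrolactam) or terminal reductase R
  (aldehyde, alcohol). All five loading configurations are supported
  (AT+ACP, CAL+ACP, CAL+PCP, A+PCP, standalone N-terminal ACP with an
  arbitrary acyl-SMILES starter). A structure-informed repair step
  inactivates reductive domains whose prerequisite reaction is missing
  (e.g. an annotated DH with no KR) before any chemistry runs.
* **Domain architecture search.** Each active domain configuration becomes
  one Unicode character via a persistent alphabet registry; clusters are
  ranked by Levenshtein distance with similarity
  `1 − d / max(|query|, |hit|)`, and every hit carries an edit script —
  delete/replace/add operations over the query's domain list — as
  chimera-design instructions.
* **Structure search.** Every simulated per-module intermediate (rendered
  as its free acid) is fingerprinted with counted atom pairs
  (element, heavy-degree, π-count descriptors × shortest-path distance)
  and ranked against a target molecule by multiset Tanimoto similarity,
  recommending a truncation/graft point.

Chemistry (SMILES parsing, canonicalization, formulas, SMARTS counting) is
backed by OpenBabel via ChemmineOB/ChemmineR; clusters are interchanged as
schema-validated JSON (`inst/schema/cluster.schema.json`); substrate and
stereo-convention tables are editable TSVs under `inst/extdata/`.

## Worked example

```r
library(megasynth)

cl <- make_named_fixture("triketide")
cl
#> <ms_cluster> fx-triketide (triketide): 1 subunit(s), 2 module(s)
#>   module 0 [loading]: AT-ACP
#>   module 1: KS-AT-KR-ACP-TE

simulate_cluster(cl)
#> <simulation_result> fx-triketide
#>   module 0: CCC(=O)O
#>   module 1: CC[C@H]([C@H](C(=O)O)C)O
#>   product: CC[C@H]([C@H](C(=O)O)C)O
```

The loading module binds propionate (shown as its free acid,
`CCC(=O)O`); the extension module condenses methylmalonate and its B1
ketoreductase sets the β-hydroxyl, giving 3-hydroxy-2-methylpentanoic
acid with the conventional descriptors — the classic triketide test
product. A cluster annotated with a DH but no KR is repaired before
simulation rather than producing impossible chemistry:

```r
res <- simulate_cluster(make_named_fixture("dh-no-kr"))
res$log[1]
#> [1] "repair: module 1: inactivated DH (no active reducing KR provides the beta-hydroxyl)"
res$product   # beta-ketone retained, no unsaturation
#> [1] "CC(=O)CC(=O)O"
```

Architecture search returns ranked hits plus the concrete domain changes
that convert the query into each hit:

```r
cls  <- make_random_clusters(5, seed = 11)
repd <- lapply(cls, function(x) repair_reductive_domains(x)$cluster)
reg  <- new_alphabet_registry(unlist(lapply(repd, architecture_of)))
db   <- lapply(repd, encode_architecture, registry = reg)
hits <- search_architecture(repd[[2]], db, reg, top_k = 3)
hits$hits
#>   rank cluster_id distance similarity
#> 1    1    rnd-002        0  1.0000000
#> 2    2    rnd-004        9  0.3076923
#> 3    3    rnd-003       14  0.3000000
head(hits$instructions[[2]], 3)
#> [1] "replace domain at position 10 with DH"
#> [2] "replace domain at position 9 with KR:B1"
#> [3] "replace domain at position 8 with AT:mxmal"
```

The query matches itself at similarity 1 with an empty script; the second
hit is nine domain edits away, listed explicitly. Structure search works
from a target molecule toward a starting point:

```r
idx <- build_intermediate_index(cls[1:3])
search_structure("CC(O)CC(=O)O", idx, top_k = 3)$recommendation
#> [1] "truncate cluster rnd-001 after module 1 (similarity 0.225) as graft point"
```

A command-line front end wraps the same functions
(`simulate`, `repair`, `encode`, `search-domains`, `search-structure`,
`fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","megasynth.R",package="megasynth"))')" \
    simulate --cluster triketide.json --out sim.tsv
```

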