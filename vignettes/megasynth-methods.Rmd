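---
title: "Predicting megasynthase products and searching architectures: methods"
author: "megasynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting megasynthase products and searching architectures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megasynth)
```

## The model

Type I modular polyketide synthases (PKS) and nonribosomal peptide
synthetases (NRPS) are assembly lines: polypeptide subunits carry ordered
modules, each module carries ordered catalytic domains, and — with few
exceptions — the domain sequence deterministically predicts the chemical
structure of every carrier-bound intermediate and of the released product.
`megasynth` models exactly this collinearity. A cluster is an ordered list
of subunits, of modules, of attributed domains; simulation walks the
modules once, applying each active domain's reaction as a structural edit
to a single growing chain.

The chain is represented internally as a list of *units* rather than a raw
molecular graph: an acyl starter (its structure minus the thioester
carbonyl), ketide units (the alpha-substituent set plus the oxidation
state of the beta-carbon — which is physically the previous unit's former
thioester carbonyl), and amino-acid residues (template pieces with
N-decorations, an alpha stereo flag, and an optional azoline ring state).
SMILES is generated from this structure on demand and canonicalized by
OpenBabel (through ChemmineOB); *molecular equality in this package always
means string equality of canonical isomeric SMILES*. The carrier
(ACP/PCP phosphopantetheine arm) is abstracted to a terminal thioester
sulfur; intermediates are displayed and indexed in their free-acid
rendering, which is also the form the structure search compares.

Domain chemistry, in the order dispatched within a module (annotation
order in input files is deliberately ignored — file order is unreliable,
chemistry order is not):

1. **Loading** (module 0): AT+ACP, CAL+ACP, CAL+PCP (starter code or an
   arbitrary acyl thioester SMILES), A+PCP (aminoacyl with free
   alpha-amine), or a standalone N-terminal ACP that attaches its
   `starter_smiles` verbatim.
2. **KS/AT extension**: decarboxylative Claisen condensation adds one
   ketide unit; the AT-selected extender contributes the alpha
   substituent (`mal` H, `mmal` methyl, `emal` ethyl, `mxmal` methoxy).
3. **MT**: one alpha-methylation of the current beta-keto unit
   (gem-dimethylation of an already disubstituted alpha-carbon errors).
4. **KR**: beta-ketone to beta-hydroxyl for reducing types
   (A1/A2/B1/B2/U); C1 is a passthrough; C2 epimerizes the
   alpha-substituent only.
5. **DH**: beta-hydroxyl to the *E*-configured alpha,beta-alkene
   (cis-specific dehydratases are out of scope).
6. **ER**: alkene to the saturated beta-methylene.
7. **C/Cy condensation**: amide condensation of the A-selected amino acid
   (the incoming alpha-amine attacks the thioester carbonyl), or
   heterocyclization of cys/ser/thr into a thiazoline/oxazoline fused at
   the previous carbonyl carbon (net one extra water lost).
8. **Azoline redox**: oxidation aromatizes to the azole (−H2), reduction
   gives the azolidine (+H2); dispatched only when the module's Cy just
   formed the azoline.
9. **E**: alpha-epimerization (L⇄D); Dual-type C domains epimerize
   immediately after condensing.
10. **nMT**: one methyl on the newest backbone nitrogen (on a loading
    aminoacyl with no amide yet, the free alpha-amine is methylated and a
    warning recorded).
11. **F**: N-formylation of the free primary N-terminal amine.
12. **Release**: TE hydrolysis (free acid), macrolactone/macrolactam
    closure onto the `ring_site` unit's nucleophile, or R-domain reductive
    release to aldehyde or primary alcohol.

X domains contribute provenance only; AOX domains load their substrate
like an A domain with a provenance note (their monooxygenation chemistry
is not modeled).

## The repair rule

Annotation pipelines and natural cluster evolution occasionally leave a
module with reductive domains whose prerequisite reaction is missing —
e.g. an active DH with no KR to produce the beta-hydroxyl it would
dehydrate. `repair_reductive_domains()` enforces the per-module
prerequisite chain KR → DH → ER: if the KR is absent, inactive, *or of a
non-reducing type* (C1 passthrough, C2 alpha-epimerase), DH and ER are
marked inactive; if the DH is absent or inactive, ER is. Extending the
rule to non-reducing KR types is this package's own choice: a C1/C2 KR
leaves the ketone in place, so a downstream DH has no substrate and would
otherwise be a guaranteed runtime error. Domains are flipped inactive, not
deleted, so provenance and edit scripts survive; the operation is
idempotent and only ever deactivates.

## Tunable parameters and conventions

* **Substrate tables** (`inst/extdata/substrates.tsv`): TSV of `code`,
  `smiles`, `role`, `display_name`. Starters are written as acyl
  thioesters with the literal trailing motif `C(=O)S` (the attachment
  contract also applied to user `starter_smiles`); extenders carry exactly
  one `[*]` attachment point; amino acids follow the residue template
  `N…C(=O)S` with the alpha-amine first and the acyl carbon last. The
  shipped starter set is intentionally small (acetyl, propionyl, butyryl,
  isobutyryl, benzoyl) — arbitrary-SMILES loading covers the rest — and
  the 20 proteinogenic residues are included. Unknown codes are hard
  errors naming the nearest known codes; `lenient = TRUE` substitutes
  `ace`/`mal`/`gly` with a warning, mirroring what a database-ingestion
  pipeline needs when loading imperfect annotations.
* **Stereochemical conventions** (`inst/extdata/kr_stereo.tsv`, editable
  without code changes): A-type KRs write the beta-hydroxyl as `[C@H](O)`,
  B-types as `[C@@H](O)`; subtype suffix 1 sets the alpha-substituent
  descriptor to `@@`, suffix 2 to `@`; U reduces without stereo
  assignment; the `ER` row gives the alpha descriptor restored after
  enoylreduction. These follow the standard A/B ketoreductase
  classification in spirit, but the concrete `@`/`@@` assignments are
  package conventions — isolated as data precisely so they can be
  corrected without touching code.
* **Macrocyclization**: the nucleophile is never guessed; `ring_site` is
  an explicit 0-based unit ordinal. Supported nucleophiles: a surviving
  ketide beta-hydroxyl or a hydroxylated acyl starter (lactone), ser/thr
  side chains (lactone), the free N-terminal alpha-amine or a lys side
  chain (lactam). Ring size is computed from the unit list and reported;
  rings below four atoms are rejected.
* **Similarity normalization**: architecture similarity is
  `1 − d / max(|query|, |hit|)` (two empty strings score 1), keeping the
  score symmetric in `[0, 1]`. Edit operations all cost 1; weighted costs
  are a documented extension point, off by default.
* **Atom pairs**: counted (multiset) atom pairs with descriptor
  (element, heavy-atom degree, pi-bond count) and shortest-path
  topological distances, uncapped. Counted pairs rather than hashed bit
  vectors: every fingerprint is exactly reproducible by desk-scale
  enumeration, which is what makes the brute-force cross-checks in the
  test suite meaningful.

## Encoding and search

`architecture_of()` serializes a repaired cluster to one token per
*active* domain in N-to-C order; the token carries the chemistry-relevant
attributes (AT substrate, KR type, C type, A substrate and modification,
TE mode, R level, loading starter), so two domains of the same kind but
different configuration encode differently. The alphabet registry maps
tokens bijectively to single Unicode characters (codepoints handed out
sequentially from U+2500), is append-only, and persists to a TSV sidecar —
re-encoding a corpus after reload is byte-identical. Tokens known at
corpus build time are registered in sorted order for reproducibility.

Levenshtein distance is computed by the standard dynamic program with a
backtrace whose tie-breaking prefers replace over delete over add. The
edit script is emitted in decreasing position order so every position
refers to the original query token list (0-based) while remaining
sequentially applicable; `apply_edit_script()` replays it exactly, and the
rendered instructions ("replace domain at position 3 with KR:A1") are the
chimera-design recipe. Hits are ranked by non-increasing similarity with
ties broken by cluster id in C-locale lexicographic order. Whole-cluster
strings are the default search granularity; `by_subunit = TRUE` encodes
subunits separately for callers who want subunit-level comparison.

## The synthetic-data generator

`make_random_clusters()` emulates the *layout* diversity of annotated
clusters: all five loading configurations; PKS extension modules with the
four extenders, optional alpha-methylation and every reductive-loop stage;
NRPS modules with the C-domain types, heterocyclization and its redox
states, epimerization, N-methylation and N-formylation; and all release
modes including macrocyclization when a valid nucleophile exists. About
15% of reductive loops are generated "broken" (KR dropped, DH/ER left
active) to emulate the inconsistent annotations the repair rule exists
for. The generator is constructive: it only composes layouts whose
chemistry is defined (Cy only with cys/ser/thr; MT only on a free alpha
position; nMT never on proline's ring nitrogen or an azoline; F and
head-to-tail lactams only when a free primary N-terminus exists), so
every generated cluster validates and simulates after repair.

What it does *not* emulate: real substrate frequencies, trans-AT systems,
tailoring enzymes, iterative modules, or any sequence-level signal.
Passing tests on generated clusters therefore demonstrate the internal
consistency and chemical validity of the rule engine across the full
combinatorial layout space — not predictive accuracy on any natural
product, which depends on annotation quality upstream of this package's
ingestion boundary.

## Numerical and degenerate-input choices

* OpenBabel silently repairs many malformed SMILES, so user input passes a
  strict syntax pre-check (balanced brackets and parentheses, paired ring
  closures, legal tokens) before the backend parses it.
* The N-formylation bookkeeping delta is net +CO (the installed CHO
  consumes one N-H); the azoline route costs one extra water over plain
  condensation; R-domain release is −O (aldehyde) or −O +H2 (alcohol)
  relative to the free acid. `ledger_formula()` recomputes an expected
  product formula from these per-transform deltas without ever touching
  the structure renderer, giving an independent audit of the engine that
  the test suite and acceptance script check on hundreds of random
  clusters.
* Intermediate counts equal loading plus elongating modules; a module
  whose extension domains are all inactive is skipped with a provenance
  note rather than guessed at.
* Thr-derived oxazolines drop the side-chain C5 stereodescriptor
  (the ring fusion redraws that center; assigning it is not attempted).
* Donor-configuration mismatches at LCL/DCL condensations (a D donor
  before an LCL, an L donor before a DCL) warn and proceed — annotations
  are too often incomplete to make this fatal. Glycopeptide-type C
  condenses exactly like LCL, with the type retained as metadata.
* Test problem sizes are chosen to keep the full suite around a minute on
  one CPU: the formula ledger runs on 200 random clusters, the repair
  property on 500, the Levenshtein oracle on 1000 random pairs and
  triples, and the search oracles on 20-cluster / 30+-intermediate
  corpora.

## Known limitations

Tailoring chemistry (glycosylation, halogenation, oxidative crosslinking
by X domains, AOX monooxygenation), trans-acting domains, iterative module
use, kinetics and yields are out of scope. The schema is the ingestion
boundary: antiSMASH/MIBiG output must be converted to the cluster JSON by
the caller. KR stereo outcomes and DH geometry follow the shipped
convention tables, not per-enzyme prediction. Macrocyclization supports
the documented nucleophile classes only, and azoline units cannot serve as
ring sites.
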