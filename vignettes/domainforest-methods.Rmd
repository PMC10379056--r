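---
title: "Domain-centric featurization and forest prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-centric featurization and forest prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainforest)
```

# The problem

Protein–protein and protein–nucleic-acid interactions are orchestrated by a
small set of recurring structural mechanisms: oligomerization (a protein's
quaternary assembly behaviour), liquid–liquid phase separation (LLPS, the
formation of membraneless condensates such as nucleoli or P bodies),
domain–domain and domain–motif interactions (DDI/DMI), and post-translational
modification.  Each of these is catalogued in its own database keyed, more or
less directly, by Pfam protein domains.  `domainforest` turns such
heterogeneous annotation snapshots into one common currency — mixed
categorical feature tables over proteins, genes or transcription factors —
and runs a reproducible classification and association protocol over them.
Every input is a plain-text table with a documented schema, and a seeded
generator produces miniature snapshots of all of them, so the entire pipeline
runs and is tested offline.

# Reduced alphabets and trimer profiles

To compare DNA-binding domains and binding motifs in a low-dimensional space,
sequences are recoded into *group alphabets*.  The shipped protein alphabet
collapses the 20 amino acids into five groups by side-chain polarity and
charge — P (R,K,S,T: positive/polar), N (D,E,N,Q: negative/polar), H
(A,V,I,L,M: hydrophobic), R (F,W,Y: rings), S (C,G,H,P: special) — and the
DNA alphabet collapses the 15 IUPAC codes into G / Z (ambiguity codes that
can be G) / X (codes that are never G) / N.  Group membership is a modelling
choice, not a fact of nature: for cysteine-rich proteins one may want C as
its own group, so `alphabet_spec()` accepts arbitrary user tables and the
encoders are total, case-insensitive functions that *error* on any letter
outside the declared input alphabet (a silent skip would desynchronise
positions).  Protein ambiguity codes (U, B, Z, X) are therefore rejected by
the default spec but can be mapped by a custom one.

A sequence of length $L$ has $\max(0, L-2)$ overlapping trimers; the dense
profile vector enumerates all $|G|^3$ group trimers (125 protein, 64 DNA) in
lexicographic order over the declared group order — the enumeration order is
a convention we fix, since any fixed order works.  Family-level profiles for
nucleotide-binding motifs are the *mean* of per-member normalized vectors:
member sequences differ in length, so normalizing before aggregation stops
long members from dominating; the aggregation is exposed as a parameter
(`mean`/`sum`).

The 24 nucleotide-containing ligands recognised by conserved binding
profiles are grouped into 11 moiety codes (RBP, RBPF, RBPN, RBPS, RBPSO,
RBSO, TOP, OP, TP, RPF, RPFO) built from the letters R (ribose/ribitol),
B (base), P (phosphate), F (flavin), N (nicotinamide), S (sulfur), T
(thiamine/thiazole) and O (other).  No authoritative per-ligand table
exists, so the shipped map (`default_ligand_groups()`) applies standard
moiety decomposition — e.g. NAD(H) = ribose + adenine + phosphate +
nicotinamide → RBPN, FMN = ribitol + phosphate + flavin (no base) → RPF,
thiamine pyrophosphate → TP — and is deliberately a plain named vector the
user can replace.  The reading of T as the thiamine/thiazole moiety and O
as any residual moiety is our interpretation of the letter key, documented
here because the code letters TOP/OP/TP are otherwise underdetermined.

# Oligomerization taxonomy

Assembly clusters arrive as stoichiometry strings (`"A2BC"`) and point-group
symmetry tokens (`"C1"`, `"C2"`, `"D3"`).  A cluster is *homo* when one
distinct chain letter occurs and *hetero* otherwise; its state is *oligomer*
when the symmetry order (the integer suffix of the token) is at least 2,
*monomer* for a single-copy C1 assembly, and *single* for multi-chain C1
assemblies without symmetry.  The special label `CMA` marks the
crystallographic-monomer case C1-A1.  Dihedral groups contain twice as many
subunits as their rotational order; whether `D3` reads as 3 or 6 is a
configuration flag (`dihedral_double`), defaulting to the rotational order.

Composite labels aggregate all clusters observed for one protein.  Because
only a handful of composite strings are printed in any reference lexicon,
the full grammar is our design: the composition part (`homo`, `hetero`, or
`homo_hetero` when both occur) followed by one token per distinct observed
(obligacy, state) pair, ordered monomer < single < oligomer and obligate <
moderate < transient < unknown, with monomer/single pairs rendered
`obligacy_state` and oligomer pairs `state_obligacy` (reproducing composites
such as `homo_obligate_monomer_oligomer_moderate`).  The grammar is
deterministic, permutation-invariant over the cluster list, and every
emitted label parses back (`parse_oligomer_label()`).  Unknown obligacy is
its own category — silently coercing it to a real class would fabricate
evidence.  The 19-feature reduction of raw assembly variables
(`derive_protcad_features()`) is likewise a documented default recipe
(counts, maxima and means over the cluster set, plus the composite label),
since the identity of the original raw-variable reduction is not public.

# Interface fragments and cluster comparison

Interface residue positions are split into *fragments*: maximal runs with no
internal gap of more than 3 missing residues ("gaps larger than 3" read
literally — a gap of exactly 3 stays joined, 4 splits).  Entries sharing an
unordered domain pair divide into a non-redundant cluster (architectures
where each member domain occurs once, Dom1–Dom2) and a redundant one (any
repeat, Dom1–Dom2–Dom1).  Each cluster is summarised by 13 named values
(membership size, motif-entry count, fragment-count and amino-acid-count
means and SDs, maximum fragment size, assembly-symmetry maxima/means, total
fragments), and each per-entry measurement is compared across the two
clusters with one-way ANOVA.  The ANOVA is applied *regardless of
normality* — the magnitude of the difference is the quantity of interest
and no non-parametric statistic reports it on the same scale — so every
p-value carries a `normality_caveat` attribute rather than being replaced
by a rank test.  Degenerate cases are defined, not left to the fitter:
identical clusters give $F=0,\,p=1$; perfectly separated clusters (zero
within-cluster variance) give $F=\infty,\,p=0$; a comparison with an empty
or too-small cluster is emitted with the ANOVA marked not-applicable.

Physicochemical and PTM annotations map onto a tiling of each protein:
declared domain spans plus their complement (interdomain regions) cover
positions $1..L$ exactly once.  Overlapping domain annotations keep the
longer span (ties: earlier start) and log the discard — the alternative,
splitting at overlap midpoints, would invent boundaries no database
asserted.  Position-borne features (PTM sites) assign by containment;
protein-global features (GRAVY, pI, subcellular location) attach to every
region, flagged as protein-level.

# Condensate annotations

Proteins are typed by the *set* of condensates they associate with; the
canonical key is the sorted, `|`-joined set of snake_case vocabulary tokens
("others" is a real category).  Unit–type frequency matrices count Pfam
domains, LLPS functional types (client / regulator / scaffold) or unordered
within-protein domain pairs per type key; dimer self-pairs (PF_a–PF_a) count
only when a Pfam genuinely occurs twice in a protein.  Partial matching
flags proteins whose entire Pfam set is contained in a *strictly larger*
candidate molecule (hetero-oligomers, multi-gene factors), reporting the
largest match's domain count.  The 13 special flags are evidence joins: 9
are fixed (RNA-binding domain, DNA-binding domain, DMI participation,
low-complexity, disorder, repeat, coiled-coil, phosphorylation site, active
site) and the remaining 4 slots default to transmembrane helix, signal
peptide, domain linker and glycosylation — chosen from the standard
physicochemical property list as a documented gap-filling default, and
freely reconfigurable.  A flag whose evidence table is missing is `NA`
(unknown), never silently false.

# GO/PO categories

Annotation records are matched against four subcategory kinds —
signaling-pathway words, 34 major GO analysis terms, regulatory-role words
(enhancer, suppressor, chaperon(e), activator, ...), and the verbatim
database qualifiers — by case-insensitive whole-word matching; word-boundary
matching was chosen over substring matching so that "activators" does not
hit "activator" twice via stems.  The shipped 34-term list is populated
from a generic GO-slim-style vocabulary and is explicitly a stand-in: the
lexicon is a constructor argument, validated to exactly 34 entries.  Ten
frequency features summarise the hits per gene; duplicate records count
twice by default (frequency semantics) with `dedupe` available.

# Binding sites on gene features

All interval arithmetic is 0-based half-open internally (BED convention);
GFF3's 1-based closed coordinates are converted at the reader.  A binding
site increments every feature interval it overlaps by at least one base —
bedmap-style indicator counting — so adjacent intervals share no position
and zero-length overlaps never count.  Gene models expand into exons, CDSs,
UTRs (inferred as exon − CDS when absent, and logged), introns (gene span −
exons) and strand-aware upstream/downstream windows of 2,000 bp by default
— a conventional promoter-window width in plant regulatory genomics; the
width is a parameter, not a constant.  The overlap engine is
`GenomicRanges::findOverlaps`; the test suite checks it against a naive
all-pairs oracle including boundary cases.

# The prediction protocol

The classification pipeline follows a fixed, leak-free order inside every
train/test split:

1. numeric array variables are converted to categoricals (`direct` mapping,
   k-means, Gaussian-mixture EM, or a 1-d density valley cut) with the
   conversion *fitted on the training fold only* and applied to the test
   fold; cluster labels are `cluster_0, cluster_1, ...` by descending size
   so refits are stable;
2. the training fold only is rebalanced — `resample` (stratified bootstrap
   with bias-to-uniform 1, 100% size) or `spread_subsample` (downsample
   majorities to `max_spread` × minority; spread 1 equalizes);
3. a bagged random forest of 100 trees is trained on one-hot encodings of
   the categoricals (portable across forest implementations); levels unseen
   in training map to an explicit `__unseen__` indicator at prediction
   time, because tiny classes make unseen levels routine and erroring would
   discard test instances;
4. the held-out fold is predicted; argmax ties break to the
   lexicographically smallest class label.

Evaluation schemes are stratified ten-fold cross-validation (`cv10`), a
single stratified 66/34 split (`split66`), and a persisted stratified
holdout.  Reports carry accuracy, per-class precision/recall/F1, the
confusion matrix and the per-instance class-probability table (rows sum
to 1), and serialize deterministically: identical seeds give byte-identical
report files.  Before any stratified scheme, `prepare_dataset()` removes
duplicate rows and, on request, singleton classes — a class with one
instance cannot appear in both a training and a test fold.

The package's reference prediction study (`signal_study_table()`) plants a
known dependence: 4 classes, 3 informative binary features whose log-odds
shifts (8 per unit effect, so a single full-strength entry moves a class
from 50% to $\mathrm{logit}^{-1}(8) \approx 99.97\%$) make the class nearly
a deterministic function of the first two features, plus 5 uninformative
4-level features, at $n = 600$.  The generating model's exact Bayes
accuracy is computed in closed form by enumerating feature cells, and the
protocol is expected to approach it (cross-validated accuracy ≥ 0.90)
while collapsing to the binomial chance band around 1/4 after label
permutation; the permutation null is estimated as the mean over 20
relabelled copies, matching the variance of the band it is compared to.
These sizes (600 instances, 100 trees, 10 folds) keep the full study at a
few seconds per run while leaving the planted effect unambiguous.

# Association structure

**FAMD.**  Factor analysis of mixed data standardizes continuous columns
(population scaling), indicator-codes each categorical column with every
indicator divided by $\sqrt{p_j}$ (its level frequency) and centered, and
diagonalizes the result with uniform row weights.  The eigenvalue sum then
equals the total inertia $K_\mathrm{cont} + \sum_c (m_c - 1)$, per-dimension
variable contributions sum to 100%, and an all-continuous table reduces
exactly to standardized PCA — all three identities are asserted in the
tests rather than assumed.  Constant variables carry no inertia and are
dropped with a warning.

**Association matrix.**  Pearson's $r$ for numeric–numeric pairs, the
correlation ratio $\eta$ for categorical–numeric (oriented: the categorical
explains the numeric; stored symmetrically), and Cramér's V for
categorical–categorical (classic $\chi^2$ form without continuity
correction; the Bergsma bias correction is a flag).  A reporting helper
screens pairs above a threshold, defaulting to 0.6 — the conventional
"relatively high" screening level for this kind of mixed matrix.

**Hotspot rules.**  A greedy best-first tree toward a target class: every
`(variable = level)` extension is scored by confidence
$P(\text{class}=\text{target} \mid \text{conditions})$, the top `branching`
children that strictly improve the parent and keep support (covered
fraction of the target-class mass) at or above `min_support` are expanded
to `max_depth`.  Defaults (support 0.3, branching 3, depth 3) follow the
customary defaults of rule-mining tools of this family.  When the target
class's relative frequency is below `min_support`, high-confidence rules
cannot reach the support floor and the function warns and returns only the
root rather than an arbitrary fragment.

# The synthetic generator, and what passing tests do not show

`generate_bundle()` emulates the *schemas and join structure* of the real
annotation sources — stoichiometry/symmetry grammar, interface position
lists, condensate sets over the real 40-term vocabulary, GAF-style
annotation lines, IUPAC consensus strings, BED/GFF3 coordinate conventions,
referentially consistent identifiers — under a single mandatory seed with
no global state.  Default sizes (50 proteins, 20 Pfams, 10 TFs, 15 genes)
are miniature on purpose: large enough that every code path (redundant
architectures, DMI entries, multi-condensate proteins, minus-strand genes)
is exercised, small enough to run in milliseconds.  It does *not* mimic the
marginal distributions of real databases: real LLPS types are far sparser,
real class imbalance far more extreme (the generator can reproduce
tiny-class regimes down to 0.08% on request), and real features are
correlated in ways no independence-based generator produces.  Passing
tests therefore certify the *mechanics* — parsing, counting, splitting,
leak-freedom, determinism — and the recovery of planted signal, not any
biological claim about real snapshots.

# Known limitations

* The composite-label grammar, the 19-feature assembly reduction, the 13
  comparison values, the 34-term GO list, the 10 GO/PO features' mapping
  and the 4 unnamed special-flag slots are documented defaults where the
  reference material is silent; all are constructor arguments or configs.
* The forest consumes one-hot encodings; native categorical splits are not
  implemented.
* Holdout persistence writes index sets, not separate ARFF files.
* FAMD supplements (projecting held-out rows) are not implemented.
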