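---
title: "Predicting in vivo metabolites of natural compounds with reaction rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting in vivo metabolites of natural compounds with reaction rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmetab)
```

## The model

`ncmetab` treats *in vivo* biotransformation of a natural compound as a
one-step application of enzyme-free transformation rules followed by a
ranking problem. The modelling assumptions are deliberately coarse:

* **Rules, not enzymes.** Each rule is a reaction SMARTS describing the net
  chemical change observed *in vivo* (ester hydrolysis, deglycosylation,
  aromatic hydroxylation, ...), with no organ, isoform or phase annotation.
  This matches how substrate–metabolite pairs are reported in the natural
  product literature, where the mediating system (liver vs. microbiota) is
  often unknown.
* **Single metabolic step.** The candidate pool is built from one round of
  rule application (`depth = 1`); a `depth` parameter re-applies rules to
  products for users who want two-step products, but ranking quality
  degrades quickly as pools grow multiplicatively.
* **2D structures only.** Matching, identity and steric scoring work on the
  molecular graph. Stereochemistry is ignored throughout: the identity key
  is the canonical SMILES after stripping stereo annotations, because
  literature metabolite SMILES frequently omit stereocenters; two
  predictions differing only in stereochemistry are the same metabolite
  here.

Ranking is a stable three-key sort. The primary key is the *priority tier*:
the position, in a permutation of the eight functional-group categories, of
the best-ranked category among the rules that produced the candidate. The
secondary key is the steric-hindrance score of the reaction site (below);
the tertiary key is the lexicographic canonical key, which exists purely to
make output deterministic and testable. The top 50 candidates are reported
by default; 50 is the recommendation cutoff used in evaluation as well, so
a known metabolite outside the returned list counts as a miss.

## The eight categories and their detection

Rules are grouped into `alcohols, alkanes, alkenes, amines, aromatics,
esters, ethers, others`. The vocabulary is closed: rule files using any
other spelling fail validation. For reporting, molecules themselves can be
classified by `classify_functional_groups()`, with substructure patterns
chosen by this package (the category names imply but do not define them):

| category | detection |
|---|---|
| alcohols | hydroxyl on sp3 carbon |
| esters | `C(=O)O-C` |
| ethers | `C-O-C`, neither carbon a carbonyl carbon (ester oxygens are not ethers) |
| alkenes | non-aromatic `C=C` |
| aromatics | any aromatic atom |
| amines | trivalent N bonded to carbon, not adjacent to a carbonyl (amides excluded) |
| alkanes | sp3 C–H with no heteroatom within two bonds |
| others | none of the above |

The alkane convention deserves a note: a plain "sp3 C–H" pattern would tag
nearly every organic molecule (ethanol's methyl group is an sp3 C–H), which
would make the category meaningless. Requiring the center to sit at least
three bonds from any heteroatom confines `alkanes` to genuinely
hydrocarbon-like regions, so ethanol classifies as an alcohol only, while
cyclohexanol still shows both an alcohol and an alkane region. `others` is
assigned exactly when no named category matches, so it never co-occurs with
one.

A candidate's ranking category is the category of the rule that produced
it, not of the product's own structure: the priority order expresses which
*chemistry* fires first, and the rules (not the products) are what carry
that chemistry. When several rules produce the same product, the candidate
keeps the full set of producing categories and its tier is the best of
them; the provenance shown in output is resolved under the active order.

## The steric-hindrance score

The fine sort needs a number expressing how crowded a reaction site is. The
score used here is a distance-weighted neighbor count on the molecular
graph: for site atoms *S* (the atoms matched by the rule's reactant
template),

$$\mathrm{steric}(S) \;=\; \sum_{\substack{a \notin S \\ d(a,S) \le r}} w(d(a, S)),
\qquad w(d) = \frac{1}{d+1},\; r = 3,$$

with `d` the minimum bond-count distance to the site. This is a
reconstruction: it was designed for this package as the smallest scheme
that (a) distinguishes primary, secondary and tertiary site environments —
methanol's hydroxyl scores 0.5, ethanol's 0.833, *tert*-butanol's 1.5 —
(b) is invariant to atom renumbering and SMILES respelling, and (c) is
hand-checkable in tests. Both the radius and the weight function are
exposed (`steric_radius`, `steric_weight`) so other conventions can be
swapped in. It is intentionally not a 3D descriptor: conformer-dependent
measures would break determinism and add a dependency far heavier than the
signal the fine sort needs.

When several applications of rules produce the same candidate from
different sites, the candidate keeps the *minimum* score over those sites
(the least hindered route). Because that choice is independent of the
priority order, re-sorting a cached pool under a new order is exactly
equivalent to re-running the whole prediction — the property the order
optimizer relies on, and one that is verified against naive re-prediction
in the tests.

By default the steric sort runs across a whole priority tier. Arguably it
should only discriminate between *structural isomers* (same formula, e.g.
the same rule applied at different sites); `rank_candidates(isomer_only =
TRUE)` implements that stricter reading by sorting on (tier, molecular
formula, steric, key). The default stays tier-wide because cross-formula
steric comparisons within a tier still correlate with reactivity and give
the same behavior on isomer groups.

## Evaluation: the CS score

For a dataset of known substrate–metabolite pairs,

$$CS = 100 \cdot C \cdot S, \qquad
C = \frac{n_{\mathrm{hit}}}{n_{\mathrm{total}}}, \qquad
S = \frac{1}{n}\sum_{i=1}^{n} \frac{1}{\mathrm{Order}_i},$$

where a pair is a hit when the known metabolite's identity key appears in
the returned top-50 list and $\mathrm{Order}_i$ is its 1-based rank. The
definition of $n$ in $S$ is ambiguous where it matters (ranks exist only
for hits): this package defaults to $n = n_{\mathrm{hit}}$, making $S$ the
mean reciprocal rank of the correct predictions, and exposes
`s_denominator = "all"` to average over all known metabolites instead
(misses then drag $S$ down as zeros). Under either convention CS is 0–100
and reaches 100 exactly when every known metabolite ranks first.

Rank distributions of two configurations are compared with a two-sample
Student t-test on reciprocal ranks with misses entered as 0, so the
statistic reflects both coverage and top-heaviness; the degenerate
zero-variance case (e.g. an order compared with itself) is reported
explicitly rather than producing NaN. The t-test is cross-checked in the
tests against an exhaustive permutation test on small lists.

## The order optimizer

All $8! = 40{,}320$ permutations of the categories are enumerated in
lexicographic sequence and scored either by CS or by Top-1 count
(`objective = "cs"` is the default; the choice genuinely matters on small
data, so both are offered). Candidate pools and steric scores are computed
once per substrate and only re-sorted per permutation; scoring all 40,320
orders on a 50-pair dataset takes a few seconds. Ties on the objective
resolve to the lexicographically smallest order, so results are
reproducible. A seeded random subsample of orders (`sample`, `seed`) is
available for quick exploratory runs.

## Fixtures and what passing them shows

The package is testable offline because its datasets are built by
construction:

* `builtin_toy_pairs()` — 18 hand-curated pairs, at least two per category,
  each metabolite the product of exactly one shipped rule (ethyl acetate →
  acetic acid for esters; a phenyl glucoside → phenol for ethers, a
  deglycosylation in miniature). Full coverage on this set is a *closure*
  property: the generator that made the ground truth is the generator under
  test.
* `make_randomized_dataset()` — draws scaffolds from a ~30-structure
  embedded library, applies a seeded random rule of the requested category
  and records the product as the "known" metabolite. The ester scaffolds
  deliberately carry aromatic rings, ether, amine, alkene, alcohol and
  carbonyl handles, so decoy candidates from *other* categories always
  arise naturally — that is what makes planted-order recovery a meaningful
  test: an esters-first order must beat orders led by the decoy categories.
  Generation is bit-reproducible for a seed and leaves the caller's RNG
  stream untouched.

Passing these fixtures demonstrates the machinery — matching, editing,
identity, ranking, scoring — not chemical accuracy on real data. Real
metabolite records contain stereochemistry, multi-step products,
conjugations with large leaving groups and tautomer ambiguity that the
fixtures do not emulate. Benchmark-scale figures require a real pair
collection in the documented CSV schema, which `evaluate_pairs()` and the
`evaluate` subcommand consume directly; external predictors can be scored
with the identical metric through rank-list CSVs (`evaluate_rank_list()`).

## Numerical and engineering choices

* **Sanitization and identity** are delegated to OpenBabel: every input and
  every generated product must survive a canonicalization round trip, and
  the canonical SMILES (stereo-stripped) is the identity key. A strict
  in-package SMILES parser runs first, because OpenBabel silently repairs
  some malformed strings (an unbalanced `"C("` becomes methane) where an
  error is the right answer.
* **SMARTS support is a documented subset** — element/atomic-number,
  aromatic case, `X`/`D`/`H`/`R`, charge, `!`/`&`/`,`/`;` logic, atom maps —
  with load-time errors for anything outside it (notably recursive
  `$(...)` patterns). The shipped rules and classifier patterns stay inside
  the subset; rule files are validated record by record with the first
  offender named.
* **Products failing sanitization** (e.g. a rule breaking an aromatic
  system) are dropped with a warning, never aborting the run; fragments
  with fewer than two heavy atoms are discarded as leaving groups; identity
  products are excluded — a metabolite must differ from the prototype.
* **Determinism everywhere**: set-semantics generation (rule order in the
  file cannot change the pool), total-order ranking keys, lexicographic
  tie-breaks in the optimizer, seeded fixtures. Repeated runs are
  byte-identical, which the tests assert literally.
* **Problem sizes** used in the shipped tests and the acceptance script —
  18 toy pairs, 50-pair planted fixtures, full 40,320-order searches — were
  chosen so the whole suite exercises every layer, including two exhaustive
  order searches, in about a minute on one core.

## Known limitations

* Rule coverage is a representative subset (18 rules); real sourcing-scale
  collections are expected to be plugged in via `load_ruleset()`.
* No enzyme, organ or species attribution; no reaction feasibility model
  beyond the category priority and steric sort.
* Single-step metabolism by default; no metabolic network assembly.
* Stereochemistry is stripped, so stereo-divergent metabolism is invisible.
* Aromaticity perception follows OpenBabel; exotic ring systems that
  OpenBabel and other toolkits perceive differently may match rules
  differently than in RDKit-based pipelines.
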