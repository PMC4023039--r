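---
title: "Methods: structural phylogenetics and chronology of RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural phylogenetics and chronology of RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rnaphylo reconstructs the history of RNA molecules from the statistics of
their secondary-structure ensembles. This vignette explains the models the
package implements, the conventions and tunable parameters behind them, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices a user auditing results should know about.

## The retrodiction strategy

The pipeline has five stages:

1. **Folding.** Each sequence is folded over the ensemble of all
   pseudoknot-free secondary structures with canonical pairs (GC, AU, GU)
   under a transparent energy model; the partition function yields the
   base-pairing probability matrix `p_ij` and unpaired probabilities `q_i`.
2. **Morphospace statistics.** Each molecule (or each cloverleaf
   substructure) is summarised by three statistics: the Shannon entropy of
   the base-pairing probability matrix
   `Q = -(1/n) [sum_{i<j} p_ij log2 p_ij + sum_i q_i log2 q_i]` (bits per
   nucleotide), the base-pairing propensity `P` (fraction of positions
   paired in the minimum free energy structure), and the mean stem length
   `S` (pairs per helix in the MFE structure). Low `Q` and high `P`, `S`
   indicate conformational order: a molecule committed to one stable fold.
3. **Character coding.** The statistics are discretised into `k` linearly
   ordered states (default `k = 24`, the full `0-9A-N` parsimony alphabet)
   by equal-width binning, arranged as taxa-by-characters matrices (taxa =
   molecules for a ToM, taxa = substructures for the transposed ToS), and
   polarised by appending a hypothetical ancestor `ANC`: maximal entropy
   (state `k-1`) and minimal propensity/stem length (state 0) are declared
   ancestral, encoding the assumption that conformational order increases
   as structures canalise in evolution.
4. **Parsimony.** Rooted most-parsimonious trees are sought under Wagner
   parsimony (a change from state `i` to `j` costs `|i - j|`). Including
   `ANC` as an ordinary leaf roots every tree on its attachment edge
   (Lundberg rooting), so rooting is an optimisation outcome, not a choice.
   Homoplasy is reported as CI = M/s, RI = (G - s)/(G - M), RC = CI x RI
   (M, G: minimum and maximum conceivable steps; s: observed steps), and
   phylogenetic signal as the g1 skewness of the tree-length distribution
   over uniformly sampled rooted topologies.
5. **Chronology.** Node distances nd (internal nodes between root and leaf)
   are converted to relative ages `1 - nd/nd_max` and calibrated against
   geological ages by ordinary least squares (the linear clock of domain
   structures). RNA substructures are then anchored onto the protein-domain
   timeline through RNA-protein interactions: a substructure inherits the
   age of its oldest interacting domain.

## Folding model

The energy model is deliberately minimal: per-pair energies in kT
(GC `-3.0`, AU `-2.0`, GU `-1.0`), a `-1.0` kT bonus per stacked adjacency
`(i,j)/(i+1,j-1)`, and a minimum hairpin loop of 3 nt. Structure weight is
`exp(-E)`. Two properties motivated this choice over a full nearest-neighbour
parameter set: the model keeps an exact brute-force oracle feasible (every
structure of short sequences can be enumerated, so the dynamic-programming
inside/outside recursions are verified to 1e-9 against direct summation), and
it is swappable — the folding stage is an interface, and any engine producing
a `bpp_matrix` can stand behind it. The qualitative ranking of sequences by
conformational order, which is all the downstream coding consumes, is robust
to the exact parameter values.

`P` and `S` are computed on the MFE structure by default, matching the
morphospace literature; ensemble-averaged variants (`weighted = TRUE`) use
`P = 1 - mean(q_i)` and expected pairs per expected helix start. MFE ties are
broken deterministically: minimum energy, then fewest pairs, then the
lexicographically smallest pair set, so results are platform-independent.
Per-substructure statistics restrict the sums and the MFE pair set to the
region's index range; pairs crossing the boundary are excluded and counted in
a `context` diagnostic column rather than silently attributed to a region.

## Cloverleaf conventions

The default template places the acceptor stem at 1-7/66-72, D arm 10-25,
anticodon arm 27-43 (anticodon 34-36), variable loop 44-48, and T arm 49-65
on a 76-nt numbering. These coordinates are a documented convention, not a
standard: the template is configuration, and every decomposition carries it.
The variable loop is typed II when its range exceeds 10 nt, a threshold
chosen because type II tRNAs (serine, leucine cognates) carry variable loops
well above that length while type I loops sit at 4-5 nt; the cutoff is a
package convention and adjustable. Pseudoknots are rejected rather than
dropped because every statistic downstream assumes nested structures.

## Coding conventions

Discretisation bins `[min, max]` into `k` equal widths; boundary values go
to the lower state and rounding is half-up, for cross-platform determinism.
Constant columns are retained but flagged parsimony-uninformative so matrix
dimensions always match the input. Abundance censuses (domains x proteomes)
are coded as `round_half_up((k-1) ln(g+1) / ln(g_max+1))` with `g_max` the
per-proteome maximum — a log rescaling that is monotone and scale-free.

Two polarity questions were genuinely open and are answered as follows:

- **Domain abundance.** The default declares *high* abundance ancestral
  (ANC = `k-1`). Under an accretion process the oldest domains are the most
  abundant and ubiquitous, so by the generality criterion they are the
  ancestral condition; with this convention the reconstruction places the
  most abundant domains basally, and synthetic censuses with known birth
  order confirm that a root-born domain attains the smallest node distance
  in the large majority of replicates. The opposite convention remains
  available (`polarity = "low"`), and every matrix records which was used.
- **Transposition.** Per-statistic polarity does not survive transposing a
  matrix (characters become molecules); ToS matrices built from statistics
  keep the per-statistic convention, and raw transposes reset polarity
  rather than guessing.

## Search machinery

`wagner_length()` uses the Farris interval algorithm on binary trees,
vectorised over characters in compiled code; it is verified against complete
enumeration of internal labelings. `exhaustive_search()` enumerates each
unrooted topology exactly once (sequential insertion with the anchor taxon
fixed) and refuses beyond 9 free taxa. `branch_and_bound()` starts from a
heuristic upper bound and prunes with partial length plus the per-character
state range not yet spanned, which preserves exactness; equality with
exhaustive search is asserted on random 7-taxon matrices. The heuristic is
random-addition stepwise insertion plus best-improvement nearest-neighbour
interchange, fully deterministic given its seed; on 7-taxon problems with 10
restarts it finds the proven optimum in well over 90% of trials. Ties among
equally parsimonious trees are retained (up to 1,000) with a strict
consensus; traversal tie-breaks are fixed by construction order.

g1 uses moment skewness of lengths over uniformly sampled rooted labelled
topologies (sequential random attachment, which is exactly uniform); with at
most 7 taxa the distribution is enumerated completely instead. A
zero-variance distribution yields `NA`, never 0. The default sample size is
10,000.

## Chronology choices

The clock regresses age on relative node distance (`1 - nd/nd_max`) rather
than raw nd so calibrations transfer across trees of different depth.
Predictions are clamped to `[0, 4.2]` Gy with an explicit flag, never
silently. "The age of an interaction is the age of the interacting
components" is operationalised with two visible rules: an interaction is as
old as its *youngest* component (coexistence bound), while a substructure's
anchored age is the *maximum* over its interacting domains' ages (the oldest
partner sets a lower bound on the substructure). Conflicts between anchored
ages and the rank order of a substructure tree raise flags carrying both
values — the package reports disagreement, it does not adjudicate it.

## What the generator emulates, and what it does not

The synthetic module provides every input with known truth: a
uniform-attachment rooted reference topology, a 76-nt consensus cloverleaf
scaffold (a synthetic sequence consistent with the default template, not any
organism's tRNA), sequence evolution along the tree, drifted ordered
character matrices, and an accretion census of domain abundances with a
faithful interaction map.

Character drift is *punctuational*: Poisson(1.0) upward minus Poisson(0.1)
downward per edge, i.e. change is associated with cladogenetic events. This
matches the package's own chronology, which reads node distance — a count of
cladogenetic events — as relative age; under a strict time-clock model,
node distances would not be an age proxy in the first place. A consequence
worth understanding is that a directional, order-increasing drift carries
most of its tree signal in shared sparse increments: parallel increments on
both sides of a split are homoplasy, and lineages with few nodes behind them
genuinely retain near-ancestral states.

That consequence bounds what root recovery can achieve. With Lundberg
rooting of purely order-increasing characters, the cost of attaching the
ancestor on the true root edge is `sum_char max(min_left, min_right)`, which
can never beat the cost at the pendant edge of the globally least-derived
taxon; the root edge wins only when different characters attain their minima
in different taxa on both sides of the root. At the experiment size used in
the acceptance suite (8 taxa, 40 characters, 20 replicates), topologies are
recovered at mean normalised Robinson-Foulds distance well under 0.2, but
exact root-edge recovery plateaus near two thirds of replicates, with the
failures almost always one edge away toward the least-derived lineage. This
is an identifiability property of ancestor-based rooting at that problem
size — the searches themselves are provably exact — and it is reported
honestly by the acceptance tests rather than patched in the generator.

Sequence evolution mutates each site with probability 0.05 per edge, and
stem mutations are compensatory (partner switches to the Watson-Crick
complement) with probability 0.9, preserving pairing the way covariation
does in real tRNA stems; there are no indels, so the position template stays
valid. Emitted leaf structures keep exactly the scaffold pairs that remain
canonical, so arms erode under low compensation and survive at
`p_comp = 1`. End-to-end recovery from these families (fold, code, search)
is markedly weaker than from drifted matrices: MFE-derived statistics
respond near-chaotically to single mutations, so the 18
statistic-by-region characters of an 8-taxon family are only weakly
phylogenetic. The acceptance script reports this number as measured. Neither
result transfers directly to the 571-molecule scale of real analyses —
passing synthetic recovery shows the machinery is correct and the signal
model coherent, not that real tRNA statistics contain this much or this
little signal.

The census generator births each domain once (geometric trials with
probability 0.25 along the preorder internal nodes), grows abundance by a
factor 1.5 per edge with lognormal noise (sigma 0.25), and maps the five
cloverleaf substructures to the domains defining their true ages. Abundance
noise is multiplicative because growth is multiplicative. Root-born domains
are present in every proteome by construction.

## Numerical choices

- Tolerances: folding oracle equivalence at 1e-9; BPP normalisation checked
  at 1e-12; tree-length ties compared at 1e-9 (lengths are integral, so the
  branch-and-bound upper bound uses a 0.5 margin to admit exact ties).
- Degenerate inputs: empty pair sets, all-zero censuses, constant columns,
  single-taxon matrices and zero-variance g1 distributions all have defined,
  tested behaviour (never silent NaN).
- Problem sizes in the shipped tests and acceptance script — 100 folding
  oracle sequences up to 20 nt, 200 brute-force parsimony cases, 50
  branch-and-bound/exhaustive comparisons at 7 taxa, 20 recovery replicates
  at 8 taxa x 40 characters, and one 64-taxon end-to-end demonstration —
  were chosen as the sizes at which every exact oracle is still feasible
  while the full suite completes in minutes on one core.

## Known limitations

- The energy model is not a thermodynamic parameter set; absolute energies
  and probabilities are not comparable to nearest-neighbour engines, only
  the induced ordering of molecules is meaningful.
- Root-edge identification by a polarised ancestor degrades gracefully (to
  an adjacent edge) on small matrices, as analysed above.
- Heuristic search offers no optimality certificate; branch-and-bound above
  ~25 taxa is not attempted by default.
- The clock is linear by design; nonlinearity in real calibrations appears
  only through the reported R-squared, not through model extensions.
- Bootstrap support is not implemented.
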