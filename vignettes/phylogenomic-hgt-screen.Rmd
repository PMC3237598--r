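---
title: "Screening gene trees for endosymbiotic and horizontal gene transfer"
author: "phylograft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gene trees for endosymbiotic and horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylograft)
```

## The problem

Photosynthetic microbial eukaryotes such as diatoms carry plastids acquired
through serial endosymbiosis, and their nuclear genomes retain genes
transferred from those endosymbionts (endosymbiotic gene transfer, EGT) as
well as genes acquired laterally (HGT). The operational signal of either
process is a *non-lineal gene history*: a gene tree in which diatom (or,
more broadly, stramenopile) sequences form a strongly supported clade with a
phylum — red algae (Rhodophyta) or green algae/plants (Viridiplantae) —
that vertical descent would not place there.

phylograft implements that screen as a pipeline of small, testable steps:

1. **Homolog sets** from pairwise similarity tables, by a simplified
   reciprocal-hit intersection with taxonomic sampling filters.
2. **Exclusive phyletic association**: queries whose significant hits fall
   only in diatoms plus one other phylum.
3. **Phylogeny sorting**: eligibility filtering of bootstrap-annotated gene
   trees, deterministic outgroup rooting, a supported-clade scan with an
   interruption tolerance, and a codified origin classification.
4. **Topology tests**: for trees where algae nest inside the stramenopiles,
   a constrained null topology (algae moved outside) is compared with the
   inferred tree by the one-sided and two-sided Kishino–Hasegawa (KH) tests,
   the Shimodaira–Hasegawa (SH) test and expected likelihood weights (ELW),
   all on RELL-resampled per-site log-likelihoods under WAG+Γ.
5. **Synthetic data** with planted transfer histories, so every stage is
   validated end to end without any external download.

The package is organised as an analysis: the numbered drivers under
`analysis/` narrate a complete run over a simulated cohort and write their
tables under `results/`, while all computation lives in exported functions
so the test suite and `scripts/acceptance.R` exercise the same code paths.

## Homolog sets and sampling filters

For a query protein, the hit lists of the query and of each of its top five
hits (ranked by e-value, ties broken by bitscore then by subject ID — the
ranking the screen needs to be deterministic, since similarity tables do not
order ties) are intersected; every list contains its own query. Hits are
included at e-value ≤ 1e-10. The resulting set is then balanced: at most 5
sequences per species (more are likely paralogs), at most 5 distinct
prokaryote subgroups, and at most 15 members each from Fungi and Metazoa,
which otherwise dominate public databases. Caps are applied in that fixed
order; each step only removes members, ranked by bitscore to the query, so
the operation is idempotent and the final state satisfies every cap. The
subgroup cap is read as a cap on the *number of subgroups* (the best-scoring
subgroups are kept), not on total prokaryote sequences. A family enters tree
building only with 4–100 members and ≥ 50 aligned sites after trimming.
`mask_columns()` provides a simple gap-fraction column mask (default: drop
columns more than half gaps) as a documented stand-in for block-based
trimmers; externally trimmed alignments can be supplied directly.

For exclusive associations, the breadth statistic *x* counts the hits drawn
from the two phyla together (query included); associations are tabulated at
x ≥ 2, ≥ 10 and ≥ 20 because associations backed by many hits are less
likely to be artifacts of sparse taxon sampling.

## Phylogeny sorting

A tree is screen-eligible with ≥ 3 distinct phyla and ≥ 30 leaves. Rooting
follows a fixed precedence — prokaryotes if present, else Metazoa, else
Fungi — placing the root on the edge subtending the **largest clade composed
purely of the outgroup phylum** (ties: higher support, then the
lexicographically smallest leaf set). With none of the three present the
tree stays unrooted, both orientations of every edge are scanned, and the
verdict is recorded as `UndeterminedOutgroup` no matter what the scan finds.

The scan tests every edge with bootstrap support ≥ 70 (missing support never
qualifies — the screen relies on strongly supported nodes only). A clade is
a hit for a partner phylum when it holds ≥ 2 leaves of the target rank
(diatoms, or all stramenopiles), ≥ 2 of the partner, and *interrupting*
leaves — anything else — make up ≤ 30 % of its leaves. "Lineages within the
clade" is counted as terminal leaves: leaves are countable and match how the
tolerance is stated. When a clade carries ≥ 2 red and ≥ 2 green leaves the
combined "Plantae-both" partner supersedes the two single-phylum readings of
the same clade: a thoroughly mixed clade is red-and/or-green evidence, not a
green clade interrupted by reds. Nested qualifying clades with the same
partner collapse to the outermost, so one biological signal is not counted
twice.

Classification is a pure function of the hit list and the outgroup: green
hits only → `Green`; red only → `Red`; disjoint red and green clades →
`RedPlusGreen`; overlapping or mixed red/green evidence → `RedOrGreen`;
hits only with the other stramenopiles → `Stramenopile` (vertical descent);
another single phylum → that phylum's category; anything else →
`Unresolved`. The original sorting's second phase was a manual inspection;
this rule set codifies the outcomes it reports and deliberately refuses to
guess beyond them. Trees sharing ≥ 3 proteins are pooled into clusters
(connected components), mirroring how related gene trees are reviewed
together.

All thresholds (70, 2, 0.30, 3 phyla, 30 taxa, 3-overlap, p ≤ 0.05,
e ≤ 1e-10) are arguments with these defaults; a support threshold of 90
reproduces the stricter preset.

## Likelihood machinery

Per-site log-likelihoods are computed by Felsenstein pruning (C++ core) under
WAG with discrete-gamma rate heterogeneity: 4 equal-weight categories with
mean-of-bin rates normalised to mean 1. The rate matrix is built as
R·diag(π), normalised to one expected substitution per site, and
exponentiated through its symmetric eigendecomposition (exact for a
reversible model; no series truncation). Gaps and the ambiguity codes X, B,
Z, U are fully missing states (partial likelihood 1 over all residues).
Duplicate site patterns are collapsed with weights.

Branch lengths are optimised coordinate-wise: each sweep computes the
rootward and tipward partial likelihoods once and maximises every branch on
its local edge profile (bounded golden-section search), which makes a sweep
cost a small multiple of one likelihood evaluation; the exact pruning total
then verifies the sweep, and a sweep that fails to improve it falls back to
branch-at-a-time Brent search against the full likelihood, so the total is
non-decreasing across rounds. The
gamma shape is optimised by the same scalar search in [0.05, 20]. Two
choices the original description leaves open are fixed here and matter for
test conservativeness: the shape is estimated on the inferred (alternative)
topology and **reused** for the null, so the two site-likelihood vectors
differ only by topology and branch lengths; and branch lengths **are
re-optimised** on the rearranged null topology — comparing a rearranged tree
with stale lengths would bias the tests against the null. Stationary
frequencies default to the published WAG vector (the behaviour of the
classic test implementations); empirical frequencies are available via
`wag_model(freqs = ...)` but off by default.

## Null topologies and the four tests

For a flagged clade (the *anchor*), `make_null_topology()` prunes every red
and green algal leaf inside the anchor (suppressing degree-2 nodes and
summing merged branch lengths), keeps their induced subtree intact, and
re-attaches it as the single sister group of the algae-free remainder —
satisfying both readings of the constraint: the two phyla become sisters,
and the algae move outside the stramenopiles. The attachment splits the
clade's subtending branch 50/50. No other branching position changes, which
the tests verify by comparing bipartition sets restricted to unmoved leaves.
Where a tree has several flagged clades, each anchor is tested separately.

RELL resampling draws sites with replacement and re-sums the per-site
log-likelihoods — no re-optimisation — giving replicate totals per topology.
From replicates centred on their mean difference, the two-sided KH p-value
counts replicates at least as extreme as the observed difference and the
one-sided (Goldman) variant counts only the upper tail, appropriate because
the null is specified a priori. The SH test centres each topology's
replicates separately and uses the max statistic over the set; with two
topologies it is never more rejective than one-sided KH. ELW averages the
normalised likelihood weights across replicates; the null is rejected when
its expected weight falls below 0.05 (outside the 0.95 confidence set).
Rejection of the null at p ≤ 0.05 across **all four** tests is the
strongest evidence tier; per-test tiers are also reported. `n_rell`
defaults to 1000 and the seed is a mandatory argument — results are
bit-reproducible, never clock-seeded.

## What the synthetic data emulate — and what they do not

`simulate_gene_tree()` builds a fixed species backbone (prokaryote outgroup;
Metazoa+Fungi; Rhodophyta+Viridiplantae as Plantae; diatoms beside the other
stramenopiles within the chromalveolate assemblage) with random coalescent
subtrees inside each phylum. The backbone is fixed rather than sampled so
that "vertical" has one unambiguous meaning for ground truth. The default
plan — 38 species over 9 phyla — sits comfortably above the eligibility
floor of 3 phyla and 30 taxa, matching the regime of the screened trees.
An HGT event grafts a clade of donor-phylum leaves inside the diatom clade
on a stalk of 0.2 substitutions/site (default), splitting the diatoms —
exactly the nested signal the screen targets. Transfers are whole, clean
subtree grafts, matching the screen's whole-gene assumption.

Sequences evolve under WAG+Γ (α = 0.8, a typical protein-family level of
rate heterogeneity; 300 sites by default, 500 in the strong-signal
recovery experiments, within the 50+-site regime of real trimmed
alignments; backbone edges 0.15 substitutions/site). Bootstrap supports for
fixtures come from 100 site-resampled neighbour-joining trees on
Poisson-corrected distances — realistic *inputs* to the screen, not
publication-grade ML bootstraps. Hit tables decay exponentially with
patristic distance with a monotone e-value map, so families delimit
correctly by construction.

The simulator does not model incomplete lineage sorting, gene duplication
and loss, partial-gene transfer, alignment error, or compositional
heterogeneity. Passing tests therefore show that the pipeline recovers what
its rules define on clean data of realistic size — not that those rules are
robust to every artifact real gene families exhibit; the original screen's
e-value, support and interruption thresholds exist precisely to blunt such
artifacts.

## Numerical and design notes

* Supports are integers on internal-node labels; other Newick dialects are
  rejected, not guessed. Missing support fails every threshold.
* Trees are conceptually unrooted; rooting is an explicit operation and
  supports stay attached to the edges they came from (`edgelabel`-style
  re-attachment).
* Tie-breaks everywhere (top-hit ranking, cap ranking, rooting) are
  score-then-lexicographic, chosen purely so results are deterministic and
  testable.
* Transition matrices are clipped at 0 for negative round-off and validated
  as stochastic to 1e-10; P(0) = I and the semigroup property hold to 1e-8.
* Branch-length bounds are [1e-8, 10] substitutions/site; ties in the
  topology-test summary (Δ = 0) count toward the inferred tree but are
  flagged.
* Degenerate inputs error early and loudly: empty alignments, inverted
  alpha bounds, anchors without algae, zero-variance RELL replicates (the
  p-value is reported as 0 with a warning flag).
* Percentages print at one decimal, rounded half away from zero, and every
  printed percentage is re-derivable from its count/denominator pair.
* Problem sizes for the validation experiments — 100 null datasets of 300
  sites for calibration, 20 datasets per length for the power curve, 100
  families per history class of 500 sites for end-to-end recovery — were
  chosen as the smallest cohorts at which binomial noise is clearly inside
  the acceptance margins.

## Known limitations

Phase 2 of the original sorting was manual; the codified rules reproduce
its described outcome categories but cannot reproduce judgment calls on
pathological trees (those fall into `Unresolved`). The NJ-bootstrap
supports of the simulator are weaker than ML bootstraps on deep, short
edges, which makes the end-to-end recovery conservative. The topology
tests compare exactly two topologies per anchor; multi-topology confidence
sets and the AU test are out of scope.
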