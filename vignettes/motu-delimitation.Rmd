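---
title: "Delimiting MOTUs from DNA barcode libraries: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting MOTUs from DNA barcode libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A DNA barcode library is a set of aligned mitochondrial COI fragments
(~650 bp), each attached to a specimen identified to a morphospecies by a
taxonomist. Two questions drive the analysis. First, do the sequence
clusters match the morphological labels? Second, where they do not, is the
mismatch hidden diversity (cryptic species concealed under one name), an
undescribed taxon deserving its own molecular operational taxonomic unit
(MOTU), or an artifact (misidentified voucher, hybridization, incomplete
sorting)? `motudelim` implements the full decision chain: genetic
distances, a guide tree, three independent delimitation methods, and a
congruence layer that converts their joint output into per-species
verdicts.

# Distances

Pairwise distances use the Kimura 2-parameter model,

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

with $P$ and $Q$ the transition and transversion proportions among the
compared sites, plus JC69 ($d = -\tfrac34 \ln(1 - \tfrac43 p)$) and the raw
mismatch proportion $p$. Sites where either sequence carries a gap or an
IUPAC ambiguity code are deleted *pairwise* — the default behavior of the
BOLD workbench and MEGA — so each pair keeps its own comparable-site count.
When the logarithm's argument is non-positive the pair is flagged
saturated rather than given a fabricated value. Percentages in reports are
printed with two decimals, matching field convention.

Species with fewer than three specimens are excluded from intraspecific
summaries (threshold configurable via `min_n_intra`), because a single
pairwise distance is not an estimate of within-species spread. "Maximum
similarity" to a nearest neighbor is defined as $100(1 - p_{\min})$ from
the p-distance; BOLD's exact similarity metric is unpublished, and this
documented stand-in reproduces the worked example's printed values.

# The guide tree

Neighbor joining follows Saitou & Nei's Q-criterion, with two determinism
guarantees layered on top: ties in the Q matrix are broken by the
lexicographically smallest pair of member identifiers, and negative
branch-length estimates are clamped to zero with the deficit transferred
to the sibling edge so path lengths are preserved. On additive matrices
the algorithm is exact; the test suite certifies this by checking that the
recovered tree's path metric reproduces the input matrix, and by
brute-force enumeration of all unrooted topologies (least-squares fit per
topology) for small taxon sets.

Clade exclusivity of a morphospecies is assessed on unrooted bipartitions
(a species is exclusive if some edge isolates exactly its specimens), so
the statistic is invariant to rooting; singletons count as exclusive.

# Delimitation methods

**ABGD.** For each prior intraspecific limit $P$ in a log-spaced sweep
(20 steps, 0.001–0.1), ranked pairwise distances are scanned above the
prior region for the first gap wider than $X$ times the mean gap in the
sliding window of the preceding $W = 10$ ranked distances ($X = 1$ by
default). The matrix is split into single-linkage components at the gap
midpoint and the scan recurses within each component until no gap remains.
The original publication's slope heuristic is under-specified, so this
concrete window rule is fixed and exposed in `abgd_config()`. Two
consequences are worth knowing: window means include distances at or below
the prior, which is what lets the first supra-prior jump register against
the intra-prior gap scale; and scans with fewer than three preceding
ranked gaps do not trigger, so groups of one or two members are final.
Small priors sit inside the intraspecific cloud and oversplit — that is
inherent to the method and the reason the sweep exists. Following survey
practice, `select_partition()` retains the sweep partition with the
highest Rand agreement with a companion clustering (ties to the smaller
prior).

**BIN-style clustering.** The Barcode Index Number system behind BOLD
(RESL) is not published in implementable detail. The surrogate here is a
stated stand-in, not a reimplementation: single-linkage clusters at the
BIN literature's 2.2% seed threshold, then a within-cluster re-run of the
gap scan that honors only gaps at least as wide as the seed threshold.
Under a true metric, stage 2 is deliberately conservative: two subgroups
whose cross-distances all exceed the seed threshold are already separated
in stage 1, so refinement fires only on unusual distance configurations.

**PTP, maximum likelihood and Bayesian.** The Poisson tree processes model
classes every branch of a phylogeny as "speciation" or "coalescent", each
class exponential with its own rate. A delimitation is a *cut*: an
antichain of nodes covering all tips, each cut node rooting one MOTU whose
internal edges are coalescent-class. Rates are profiled out at their
per-class maximum-likelihood estimates ($\hat\lambda = n/L$), giving the
criterion

$$\ell = n_s \ln(n_s/L_s) - n_s + n_c \ln(n_c/L_c) - n_c.$$

The ML search is a greedy split/merge descent from the all-singleton
state with 20 seeded random restarts — deterministic and adequate at desk
scale, in place of the original's simulated annealing. The Bayesian
flavor samples cuts in proportion to the same profile likelihood under a
flat prior, via split/merge Metropolis proposals with a Hastings
correction for the varying move count (defaults follow common practice:
500,000 generations, thinning 100, 10% burn-in). MOTU support is the
posterior frequency of the exact tip set; the returned partition stacks
the highest-support non-conflicting sets. Zero-length branches are floored
at $\varepsilon = 10^{-8}$ to keep densities finite. Unrooted input is
midpoint-rooted first — as the public PTP server does — because a species
clade spanning an arbitrary basal trifurcation could otherwise never form
a single MOTU.

One model property deserves emphasis: on trees whose within-species
structure is shallow (near-star genealogies), the two-class exponential
likelihood can genuinely prefer singletonizing small sub-lineages — we
verified numerically that such oversplit cuts beat the generating
partition's likelihood. This is the documented oversplitting tendency of
vanilla PTP, not an implementation defect, and it is one reason the
decision layer requires congruence across methods rather than trusting
any single one.

# The congruence layer

Evidence per morphospecies — maximum/mean intraspecific divergence,
nearest neighbor and similarity, per-method cluster counts, cluster
sharing and exclusivity — feeds two rules.

**Described species.** A described binomial is a *cryptic-species
candidate* when its maximum intraspecific divergence exceeds the 2%
threshold, no cluster holding its specimens also holds another nominal
species, and the three methods agree on a cluster count of at least two;
the count minus one is the number of putative extra MOTUs. Deep
divergence *with* cluster sharing signals misidentification or
hybridization (COI alone cannot distinguish the two, so both collapse
into one suspect verdict); method disagreement leaves the species
unresolved. "Agreement" is strict equality of the three counts by
default, with a configurable relaxed mode accepting a count supported by
two of three methods — the relaxed mode mirrors how surveys in practice
treat taxa where one method lags the other two.

**Open-nomenclature taxa.** A taxon identified only to genus or family
("sp.", subfamily labels) is assessed cluster by cluster. A cluster is
*assignable* when it is not a single-specimen cluster, its nearest
neighbor is an identifiable nominal label (a binomial, or a "cf."/"aff."/
"gr." qualified name — not another "sp."), and similarity is at least 98%
(equivalently, less than 2% divergence). Taxa whose every cluster assigns
are referred to the nominal neighbor; any exclusive cluster makes the
taxon a *new MOTU*. Exclusive clusters count as *cryptic* only when the
label shows deep intraspecific divergence (structural fallback when no
divergence estimate exists: at least two exclusive clusters), and one
exclusive cluster is discounted as the label's own nominal MOTU when the
label shares no cluster with any other label. This separates two
biologically different findings: an endemic novelty (one cohesive
exclusive cluster — a new MOTU but nothing hidden) and a cryptic split
(more structure than the label admits).

The monotonicity the thresholds imply — raising the intraspecific
threshold never increases the cryptic count — is asserted in the test
suite over both rule paths.

# The worked example

The package ships plain-text transcriptions of a published Neotropical
freshwater-fish survey's evidence tables (undescribed-taxa
nearest-neighbor/BIN table; deep-divergence table; a notes table
compiling prose-stated counts), under `inst/extdata/`. `table_fixtures()`
recomputes exclusivity and sharing from the transcribed BIN
classifications and nearest-neighbor nomenclature at run time, and
`cmd_flag(from_fixtures = TRUE)` runs the full decision layer on them. In
the relaxed congruence mode this reproduces the survey's headline count
of 12 putative cryptic-species MOTUs; the strict mode yields 8, dropping
the taxa where one method disagreed. `scripts/acceptance.R` reports the
relaxed-mode tally.

# The synthetic generator

`simulate_library()` builds libraries with known truth. A random species
tree (pendant branches uniform on [`min_inter`/2, `min_inter`], internal
branches 0.2–1 × `min_inter`) guarantees all between-species path lengths
exceed `min_inter` (default 5%). Within species, specimens sit on a star
genealogy with branch length `expected_intra`/2 (default pairwise
divergence 0.5%), chosen to keep intraspecific expectations closed-form
rather than modeling a full coalescent. Sequences evolve by the K2P
process itself (transition:transversion rate ratio `kappa = 4`; 1 gives
JC69), so the distance model's assumptions are exactly met. Genera and
families follow the species tree (single-linkage groups at 2.5 and 5 ×
`min_inter`), which makes rank-level distance summaries ordered the way
real libraries are.

Coding integrity is maintained by a codon guard: any mutation that would
create an in-frame stop codon (vertebrate mitochondrial code: TAA, TAG,
AGA, AGG) is redirected to a different target base at the same site. The
guard preserves the per-site substitution count, so realized p-distances
are unbiased and realized K2P divergence matches `expected_intra` to
first order — the calibration test asserts agreement within three
standard errors over 20 replicate libraries.

Three perturbations emulate the failure modes real libraries show: a
*cryptic injection* adds a within-label split at `cryptic_depth` (default
8%); a *label swap* relabels one specimen to another species
(misidentification); a *shared haplotype* copies a heterospecific
sequence onto a specimen (hybridization/introgression mimic). Injections
target disjoint species so each event's signature stays identifiable.

What the generator does not emulate — indels, sequencing error,
population structure, uneven sampling, recent divergence with incomplete
lineage sorting — bounds what passing tests show: the pipeline is
validated on libraries where the barcode gap exists by construction.
Real libraries violating that premise (gap ratio near 1) will not and
should not yield clean method agreement.

# Problem sizes and runtime choices

The validation suite uses 10 species × 5 specimens × 658 bp libraries
(the scale at which every method's behavior is exact and enumerable), 20
replicate libraries for truth-recovery checks, 10 for the end-to-end
flagging check, and Bayesian PTP chains of 20,000 generations on 50-tip
trees (200,000 when matching exhaustive enumerations on ≤4-tip trees,
where the full posterior has at most a few dozen states). Method defaults
remain at survey scale (500,000 generations). These sizes were chosen so
the whole suite completes in about a minute while every assertion stays
exact rather than approximate.

# Known limitations

* The BIN surrogate approximates an unpublished algorithm; cluster counts
  can differ from BOLD's on borderline (2–3%) splits.
* PTP inherits the oversplitting tendency discussed above; treat its
  counts as one vote, not ground truth.
* The congruence rules encode the field's 2%/1%/98% conventions; lineages
  younger than the 2% horizon are invisible to them by design.
* Hybridization and misidentification are indistinguishable from COI
  alone; the suspect verdict deliberately refuses to choose.
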