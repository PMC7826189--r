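---
title: "Methods: models, parameters and design choices in chromaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in chromaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chromaforge` implements the computational stages used to study how the
photosynthetic amoeba *Paulinella micropora* integrated its young
("chromatophore") organelle: which nuclear-encoded proteins are imported
into it, how its gene families were gained and lost, which genes arrived
by horizontal (HGT) or endosymbiotic (EGT) gene transfer, which genes
cycle with the day/night rhythm, and whether virus-derived genomic
regions are shared between related strains. This vignette documents the
models behind each stage, the tunable parameters, the synthetic data the
package validates itself on, and the design decisions taken where more
than one reasonable construction existed.

## Chromatophore transit-peptide (crTP) prediction

Long chromatophore-imported proteins carry an N-terminal transit peptide
of roughly 200 residues. The predictor reproduces the standard
profile-search design:

1. **Seed discovery.** Validated crTPs from a related species are used
   as local-alignment queries against the target proteome
   (`find_seeds()`, E ≤ 1e-20 by default). The matched region of each
   seed protein is retained.
2. **Seed alignment.** Seeds are aligned progressively in discovery
   order: the first seed region is the master and every other region is
   projected onto its columns (a master–slave alignment; insertions
   relative to the master are dropped). A hand-curated alignment, when
   available, takes precedence — the automatic alignment only stands in
   for it.
3. **Profile construction** (`build_profile()`). Columns with ≤ 50% gaps
   become match states. Emissions use the pseudocount rule
   (count + 0.5)/(n + 20·0.5), converted to log2-odds against a
   Robinson–Robinson background; transition penalties are estimated from
   the alignment's gap structure with Laplace smoothing and shared
   across positions (a single penalty tuple rather than per-state
   tables: the seed sets here are small, and position-specific
   transition estimates would be dominated by the prior).
4. **Calibration** (`calibrate_profile()`). Viterbi scores of 1000
   i.i.d.-background decoys (fixed seed) are fitted with a Gumbel
   distribution by the method of moments;
   E(S) = n_db · exp(−λ(S − μ)) thereafter. A decoy-based Gumbel fit is
   the standard way to attach significance to profile scores; the
   decoy count, length and seed are exposed so users can tighten the
   fit.
5. **Scan with positional filters** (`scan_proteome()`). The profile is
   aligned to each protein by Viterbi over match/insert/delete states,
   global in the profile and local in the sequence. Viterbi (best path)
   rather than Forward (total probability) is used deliberately: the
   filters need unambiguous hit coordinates. A hit is reported iff
   E ≤ 1e-5, the match starts within the first 50 residues (1-based),
   and the mature protein after the match exceeds 250 residues. Every
   rejected protein is logged with the filters it failed.
6. **Reciprocal extension** (`extend_candidates()`). Each accepted
   crTP region becomes a pairwise query against the proteins the
   profile missed, at E ≤ 1e-10 with the same positional filters. The
   1e-10 cutoff mirrors the package's phylogenomic search threshold;
   the profile and pairwise routes are kept disjoint so the combined
   candidate count is a simple sum.
7. **Cross-species shared set** (`shared_candidates()`). Candidates of
   two species are paired by reciprocal best hit (full-length local
   alignment, E ≤ 1e-10). RBH is the conventional ortholog-pairing
   heuristic; it is recorded as an assumption since the matching rule
   for a shared candidate set is a design choice.

Pairwise alignment throughout is affine-gap Smith–Waterman (BLOSUM62,
gap open −11, extend −1; a gap of length k costs 11 + k) with gapped
Karlin–Altschul parameters λ = 0.267, K = 0.041 — the community defaults
of BLASTP-style tools. E-values are approximate (no edge-effect
correction); every use in the pipeline is thresholding with generous
margins. Unknown residues (X) score 0 against everything.

## Dollo parsimony on gene-family presence/absence

Orthologous gene families (OGFs) evolve under a single-gain,
multiple-loss model: a family originates once and can only be lost
afterwards. Under that constraint the maximum-parsimony reconstruction
is closed-form (`dollo_reconstruct()`): the gain node is the MRCA of the
species carrying the family; a node inside the gain clade is present iff
its subtree contains a carrier; a loss is counted on each branch from a
present parent to an absent child. Per-node ancestral family counts and
per-branch gain/loss tallies aggregate over families and satisfy
`count(v) = count(parent) + gains(v) − losses(v)` on every branch.
Polytomies need no special handling — the MRCA and subtree-presence
rules generalize directly. Families observed in a single species still
receive a gain, on that terminal branch.

Because parsimony collapses parallel losses it can only *undercount* the
true number of loss events; the package checks exactly this inequality
against the simulator's truth, and checks exact equality of ancestral
counts when evolution is loss-free.

**Relative age** (`assign_relative_age()`): given a ladder of nested
strata along the focal lineage (oldest first), a family's age is the
oldest stratum intersecting its presence set. The ladder is user data
(an editable list), not code; `ladder_from_tree()` derives one from a
species tree by walking root-to-focal-tip. **Rhythmic-OGF overlap**
(`rhythmic_ogf_overlap()`): an OGF is rhythmic in a species iff ≥ 1 of
its genes there is rhythmic; the full inclusion–exclusion (Venn) table
over species is returned.

## Sorting gene trees into HGT/EGT candidates

A gene tree supports a transfer when the focal species' sequence sits in
a well-supported clade composed (almost) exclusively of donor-group
sequences. `sort_tree()` applies, in order:

* **Discard filters**: fewer than 10 leaves; fewer than 5 bacterial
  taxa; multiple *Paulinella* sequences that are not monophyletic. The
  monophyly test is performed on the unrooted topology (the leaves must
  form one side of some edge), so an arbitrary input rooting cannot
  manufacture polyphyly. Reasons are checked in that order and the first
  failure is reported.
* **Candidate clades** (`find_target_clades()`): both sides of every
  internal edge are evaluated, making the verdict independent of
  rooting. A side qualifies when its subtending support is ≥ 70 (0–100
  scale; absent support counts as 0, the conservative reading of
  "well-supported"), ≥ 95% of its leaves are target (query ∪ other
  *Paulinella* ∪ donor group), it contains ≥ 70% of the tree's target
  leaves, and it holds at least one query and one donor leaf.
  The 70%-of-target denominator is the target leaves *present in the
  tree* (the PhySortR convention); the alternative — targets in the
  whole study — is not computable from a single tree and is therefore
  not used.
* **Verdict**: EGT when a cyanobacterial donor clade containing at
  least one α-cyanobacterium qualifies (EGT takes precedence, since the
  chromatophore donor is an α-cyanobacterium and such clades also
  satisfy the generic bacterial test); HGT when a bacterial donor clade
  qualifies; otherwise negative.

One topological subtlety: at a bifurcating root, the two root edges are
a single edge of the unrooted tree, and the "complement" of one root
child is exactly the other child's clade. Each bipartition is therefore
evaluated once, with the support label written on the clade that
represents it — evaluating a root child's complement under its *own*
label would attach the wrong support to the sibling's bipartition.

Multiple query paralogs are allowed inside one candidate clade (expanded
families); the polyphyly filter applies across the whole tree. The
manual alignment-quality screen used alongside tree sorting in practice
(conserved-region inspection) is approximated by an optional,
off-by-default occupancy-window rule and is not part of any default
verdict.

## JTK rhythmicity with an exact tie-corrected null

For a gene measured at timepoints t with replicates, the test compares
the data against cosine references r(t) = cos(2π(t − lag)/24) for each
candidate lag, via the Kendall sum
S = Σ_{i<j} sign(x_i − x_j)·sign(r_i − r_j). Replicates share their
timepoint's reference value, so the reference has tie groups; the exact
null distribution of S under exchangeable data orderings is computed by
convolving Gaussian-binomial generating functions (Harding's recursion)
over those tie groups (`jtk_null_distribution()`). The distribution
depends only on the multiset of group sizes, is symmetric about zero,
and is validated against full permutation enumeration for all patterns
with n ≤ 8.

Reported per gene (`jtk_test()`): the best lag, S, τ = S/max|S|, and a
Bonferroni-adjusted p — the minimum raw two-tailed p multiplied by the
number of *distinct* lag/sign references. With the 0/6/12/18 h design
the sign flip of each reference equals another lag's reference
(−cos(t − l) = cos(t − l − 12)), so there are 4 distinct references, not
8; counting duplicates would double the correction for no gain in
control, and the original JTK software folds signs into the lag grid the
same way. Two further conventions: data ties contribute sign(0) = 0 to
S, and the period search space is {24 h} — four points at 6-h spacing
cannot resolve any other period. The cosine reference is used without
the asymmetric-triangle option: at four timepoints per period both
induce identical rank references, so nothing is lost at this design.
Across genes no multiple-testing correction is applied to the reported p
(the rhythmicity call is `p < 0.01` on the per-gene adjusted p); a
Benjamini–Hochberg column is emitted alongside for users who want it.

DEG filtering (`filter_degs()`) applies strict inequalities
(padj < 0.05, |log2FC| > 1) to an externally produced
differential-expression table; `intersect_deg_rhythmic()` intersects the
two gene sets and logs all three sizes.

## Region-class breadth of coverage

`breadth_per_class()` reports, per region class (e.g. "viral" vs
"non-viral"), the fraction of bases covered by ≥ 1 alignment interval.
Same-class regions and alignments are unioned first (IRanges interval
arithmetic — an exact sweep), so duplicated alignments cannot inflate
breadth; all coordinates are 0-based half-open end to end, with SAM
input converted at the boundary using reference-consuming CIGAR
operations only. Depth (×-coverage) is deliberately not computed — the
quantity of interest is breadth — and no mapping-quality filter is
applied (any ≥ 1× overlap counts); strand is ignored. Alignment "modes"
(global/local) arrive as separately produced files and are compared by
label only (`compare_classes()`), with no inferential statistic: the
comparison is descriptive.

## The synthetic-data generator

Every input the pipeline consumes can be generated from one seeded
configuration (`synth_config()`), with machine-readable truth alongside;
all validation consumes truth, never eyeballed values. One root seed
feeds per-generator substreams (derived from the generator's name), so
adding a generator never perturbs the others; the RNG is R's
Mersenne-Twister throughout.

Defaults are the study conditions the package validates under:

* **Gene families**: 8 species, 300 families; each family originates on
  a uniformly chosen branch (root included) and is lost on descendant
  branches with probability 0.1; zero-survivor families are regenerated
  (bounded retries). Uniform origination is the natural neutral choice
  under the single-gain constraint; the configured gain entry is kept as
  a reserved weight.
* **Proteome**: 500 proteins, 50 planted crTPs (random 200-residue
  consensus, 10% per-position substitution noise — enough conservation
  for a profile to learn, mirroring a conserved presequence family),
  prefixes of 0–49 residues and mature tails of 260–400 residues, plus
  20 decoys that each violate exactly one positional filter (block
  starting after residue 50, or mature tail ≤ 250) and 5 noisy
  consensus copies standing in for validated crTPs of a related
  species.
* **Time course**: 1200 genes at 0/6/12/18 h × 3 replicates; 200
  rhythmic genes with relative amplitude a = CV × (amplitude/σ) =
  0.2 × 3, phases drawn from the sampled timepoints; lognormal
  multiplicative noise (CV 0.2) and integer rounding. Lognormal noise is
  a deliberately simple stand-in for count overdispersion — the JTK
  statistic is rank-based, so the exact noise family is secondary.
* **Gene trees**: 200 trees — 80 HGT (query nested in an exclusively
  bacterial clade), 40 EGT (query among α-cyanobacteria), 60 negative
  (query nested *inside* the eukaryote clade, with eukaryotes on both
  sides so that no unrooted split groups it with bacteria), 20
  filter-fodder violating one discard rule each.
* **Regions/reads**: a 200 kb genome in 10 alternating viral/non-viral
  block pairs; Poisson-placed reads of 100 bp at depth 0.03 (viral)
  vs 0.7 (non-viral), chosen to reproduce the study's contrast of a few
  percent versus ~50% breadth; expected breadth ≈ 1 − e^(−depth), with
  per-block breadths serving as Monte-Carlo replicates for its standard
  error. Reads are placed fully inside blocks; the ≈ 4% of bases near
  block edges see slightly reduced coverage, a bias well inside the
  3-SE band used for validation.

What the generator does **not** emulate: sequence evolution with indels
(planted crTPs differ from the consensus by substitutions only),
sequencing error or quality scores, genuine phylogenetic signal in
background proteins, count overdispersion beyond lognormal noise, or
correlated gene expression. Passing the truth-recovery checks therefore
demonstrates the correctness of the algorithms under their stated
assumptions — not the field performance of, say, the crTP predictor on
deeply diverged real proteomes.

## Numerical choices and degenerate inputs

* Support values are normalized to the 0–100 scale at parse time; an
  explicit flag declares a 0–1 input scale.
* All interval arithmetic is 0-based half-open; a single convention at
  every boundary prevents off-by-one drift.
* Smith–Waterman ties are broken toward the smallest (q_start, t_start);
  a non-positive optimal score means "no alignment" rather than a hit of
  score 0.
* Cosine references are rounded to 9 decimals before ranking so that
  quarter-period zeros are exact ties (cos(π/2) is ~6e-17 in floating
  point; without rounding the exact tie-corrected null would not apply).
* Constant expression series give S = 0, p = 1 — a non-call, not an
  error. Empty reference databases classify everything dark, with a
  warning.
* Profile calibration refuses degenerate decoy score distributions
  (zero variance), and scanning an uncalibrated profile is an error.

## Problem sizes

The validation suite runs the Dollo-vs-enumeration check on a fixed set
of eleven 3–6-leaf shapes (caterpillar, balanced, polytomous) against
all distinct presence patterns drawn from 500 random ones per shape; the
exact-null check enumerates all tie patterns with n ≤ 8; alignment is
cross-checked against an independent quadratic DP on 200 random pairs of
length ≤ 50; and the end-to-end demonstration runs the full default
configuration above, twice, to confirm byte-identical reports. These
sizes keep the whole suite comfortably within a desktop run while still
exercising every code path at the study's own design points.

## Known limitations

* The profile calibration is Gumbel-by-moments on i.i.d. decoys; HMMER's
  calibrated E-values would differ in the constant, though not in the
  thresholding behavior at the margins used here.
* The E-value model has no edge-effect or composition correction, so
  absolute E-values for short sequences are conservative.
* The master–slave seed alignment drops insertions relative to the
  master; a severely gapped seed family would lose match states. A
  user-supplied curated alignment avoids this entirely.
* Dollo parsimony is a lower bound on loss events by construction;
  branches with multiple independent losses of the same family are
  merged.
* With four timepoints the JTK phase grid is 6 h; finer phase claims are
  not possible at this design.
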