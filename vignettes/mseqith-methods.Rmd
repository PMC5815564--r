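---
title: "Models and methods behind mseqith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mseqith}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseqith)
```

`mseqith` analyses multi-region tumour sequencing: several spatially
separated biopsies of one tumour, each yielding somatic variant calls with
read counts, allele-specific copy-number segments, a purity estimate and
immunohistochemistry-derived immune counts. This vignette documents the
models the package implements, the assumptions they rest on, the parameters
that matter, and the choices made where the design was genuinely open.

## The CCF model

All clonal inference rests on the standard deconvolution of the variant
allele fraction. A mutation carried by a fraction `CCF` of tumour cells, on
`m` of the `CN_t` tumour copies at its locus, in a sample of purity
$\rho$, has expected VAF

$$\mathrm{E}[v] \;=\; \frac{\rho \, m \, \mathrm{CCF}}{\rho\, CN_t + 2(1-\rho)}.$$

`compute_ccf()` inverts this at the observed VAF and attaches an interval
obtained by transforming a Jeffreys binomial interval on the alt-read
success probability; `estimate_multiplicity()` chooses the integer
$m = \mathrm{clip}(\mathrm{round}(v(\rho CN_t + 2(1-\rho))/\rho),\,1,\,CN_\text{major})$.
Assumptions: clonal copy number (no subclonal CN deconvolution — a stated
non-goal), diploid normal contamination, and independent binomial read
sampling. Point estimates are clipped to $[0, 1.5]$; values above 1 are
flagged as purity/copy-number inconsistencies rather than silently
truncated to 1, because persistent overshoot is diagnostic of a wrong
input, not of sampling noise.

## Subclone clustering

Mutations of one patient are clustered across regions with a finite
mixture: cluster $k$ has a CCF vector $f_k \in [0,1]^R$ and each mutation
contributes, in every region, a binomial likelihood at success probability
$c_{ir} f_{kr}$, where $c_{ir}$ is the site- and region-specific
VAF-per-unit-CCF factor above. A mutation with zero alt reads in a region
still contributes its term there — absence is informative, and is exactly
what separates region-confined subclones.

Fitting is EM with the number of clusters chosen by BIC over
$K = 1..K_{max}$ (default 6) and a seed-controlled multi-start (default 10
restarts seeded from randomly chosen per-site CCF estimates). This is a
deliberate, deterministic replacement for Dirichlet-process MCMC samplers
used for the same task: given the seed, the answer is reproducible, the
log-likelihood is provably non-decreasing (a property the test suite
asserts per iteration), and desk-scale data (tens to hundreds of mutations,
2–4 regions) do not need a nonparametric prior. The M-step maximises a
concave one-dimensional weighted binomial log-likelihood per cluster and
region; it is solved with a bracketed Newton iteration on the gradient, and
boundary optima at exactly 0 or 1 are detected from the gradient sign so a
truncal cluster can sit exactly at CCF 1. Responsibility ties break towards
the lowest cluster index; labels are then ordered by decreasing mean CCF so
output is stable under relabelling.

A cluster is *clonal* when its CCF is at least `clonal_threshold`
(default 0.9) in **every** region, else subclonal. The 0.9 default absorbs
the CCF sampling noise of cluster means at depth ~100 while still
separating genuine 0.7-CCF subclones.

## Clone trees

`build_clone_tree()` reconstructs the evolutionary history from cluster CCF
vectors under two constraints, each enforced with an absolute CCF tolerance
(default 0.05, sized for binomial noise at depth ~100 on clusters of tens
of mutations):

- crossing rule: a child's CCF cannot exceed its parent's in any region;
- sum rule: the children of one parent cannot jointly exceed it.

Clusters attach greedily in decreasing mean-CCF order to the *deepest*
feasible parent; ties over deepest parents are all explored and every
admissible tree is returned — when the data do not determine one tree, the
ambiguity is reported, not resolved, and downstream timing uses only
clonality, which is tree-independent. The search backtracks, and if the
depth-preferring strategy fails entirely it falls back to exploring all
feasible parents before declaring a cluster unattachable. For up to five
clusters the test suite checks the result against exhaustive enumeration of
all rooted trees.

Parallel evolution is reported for any gene (or configured gene set, e.g. a
Wnt-pathway set) with at least two distinct non-silent variants assigned to
pairwise non-ancestral clusters whose per-region CCF sums stay within
$1 + $ tolerance — i.e. mutually exclusive subclones converging on one
target. Chain (ancestor/descendant) configurations never qualify; the suite
verifies zero false positives across 1,000 chain simulations.

## Heterogeneity metrics

*Presence classes.* A mutation is detected in a region at ≥ 2 alt reads and
VAF ≥ 0.02. A region may only count as a true absence if it is
*assessable*: its depth must give ≥ 95 % probability of detection were the
mutation clonal there (binomial power at the expected clonal VAF,
$\rho/2$ at a diploid locus). Without this rule, shallow regions inflate
the private class. Ubiquitous / shared / private then means present in all
/ several-but-not-all / exactly one of the assessable regions; the three
counts partition each patient's mutation set by construction, and the
suite asserts that identity cohort-wide.

*FGA.* Fraction of genome altered is the union across regions of bases
whose total copy number differs from the neutral baseline — 2, or 4 in
regions called whole-genome doubled (a region is WGD when > 50 % of its
segmented genome has major-allele copy number ≥ 2) — divided by the
autosomal genome length. Sex chromosomes are excluded by default because
hemizygosity in a male cohort muddles the neutral state. Union-across-
regions (rather than a per-region mean) was an open choice; union is
implemented as the default because it measures the tumour's total altered
territory, and the per-region alternative is one flag away.

*Heterogeneous SCNA fraction.* All altered intervals of all regions are
broken at the union of their breakpoints; an altered base is homogeneous
only when every region carries an alteration of the same direction there.
Direction matters: a gain in one region over a loss in another is
heterogeneous even though both are "altered". Both metrics are invariant
to splitting segments into abutting pieces (asserted in the suite).

*Group comparisons.* One Mann–Whitney implementation serves every
comparison in the package. For small groups (smaller side ≤ 8 by default)
it computes the exact permutation distribution of the rank sum — including
ties, via midranks — by a subset-sum dynamic program over doubled ranks,
which reproduces classical exact p-values (e.g. {1,2,3} vs {4,5,6}: U = 0,
two-sided p = 0.1) and agrees with full enumeration for all group sizes up
to 6 (exhaustively tested). Larger samples use the normal approximation
with tie correction and continuity correction; the two paths agree within a
few percent at n = 12 vs 13.

## Locus enrichment and the burden control

A region carries a locus event when segments altered in the event's
direction cover at least 50 % of the locus (an open parameter; exposed as
`overlap_threshold`). Patient status is ubiquitous / heterogeneous / absent
by region concordance, collapsed to carrier/non-carrier for the 2×2 Fisher
exact test.

Carrier frequencies can differ between clinical groups merely because one
group carries more SCNA genome-wide. The burden-controlled permutation
test conditions exactly on each patient's altered-segment length spectrum:
in each permutation every altered segment is re-placed uniformly at random
on the genome (length and copy number preserved, independently per
region), the locus is re-called, and the group difference in carrier
frequency recomputed; $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_\text{perm})$. Under a null in which segments genuinely are placed at
random, the p-value is uniform (checked by a KS test over 200 simulated
cohorts). The procedure for "controlling for SCNA levels" was an open
design point; length-preserving re-placement was chosen because it holds
per-patient burden fixed by construction rather than modelling it.

## Mutational signatures

Spectra use the standard 96 trinucleotide classes in pyrimidine-strand
convention; purine-centred records are folded by reverse complement (an
involution, tested over all keys). Attribution is nonnegative least
squares of the normalised spectrum on the catalogue columns, weights
renormalised to 1, with cosine distance as the reconstruction diagnostic.
NNLS was preferred over a multinomial EM for determinism; at desk scale the
two agree to well within sampling noise. Fitting the ubiquitous and
non-ubiquitous sets separately asks whether a process acted before or
after the most recent common ancestor; sets under 20 mutations are fitted
but flagged low-confidence, as 96-bin spectra are badly undersampled there
(at 50 mutations, a 70/30 two-signature mixture is recovered within ±0.15
about 90 % of the time — the Monte-Carlo calibration is in the test
suite).

The shipped catalogue contains three *synthetic stand-in* columns — flat,
an age-like process concentrated on N[C>T]G, and an MMRD-like process
concentrated on G[C>T]N with a T>C component. They exist so signature
logic can be tested without downloads; their concentrations were chosen
once to make the three columns well separated, and no numerical
correspondence to any reference catalogue is claimed. Real analyses should
pass their own catalogue via `read_catalogue()`.

## Genotype flags and immune association

Wnt activation is flagged on any of: a CTNNB1 variant in the configured
exon-3 gain-of-function list (ships with p.S33P, p.S33C, p.T41A;
extensible), RSPO2 at ≥ 2× the region's neutral baseline, or a homozygous
deletion over APC, RNF43 or ZNRF3. Mismatch-repair deficiency requires two
hits on one MMR gene — deleterious variants count one each, a heterozygous
deletion one, a homozygous deletion two — and single-hit genes are
reported explicitly as monoallelic, because the contrast between biallelic
and monoallelic loss is scientifically meaningful (only the former
hypermutates). Flags are monotone: adding qualifying evidence can never
turn a flag off. Gene coordinates are configuration (approximate GRCh37
tables ship in `inst/extdata/`), never code.

The CD8+/FOXP3+ ratio pools counts by sum-then-divide across regions
before dividing — robust to zero FOXP3 in single regions — with per-region
ratios reported alongside; how multi-region counts should pool was
unstated in the motivating analyses, so the choice is documented and the
per-region values are kept. Ratio comparisons are restricted to
digital-analysis-eligible patients (INIF at or above the cohort median,
default 8 %, in at least one region), mirroring the eligibility rule of
the imaging workflow that produces the counts.

## The synthetic cohort generator

The generator is first-class, tested code: it is how every inference stage
is validated. Per patient it draws a random rooted clone tree; per-region
clone CCFs descend the tree by stick-breaking — each parent's CCF is
divided among its children with a Beta(1.2, 1.5) stick and a configurable
per-region absence probability (default 0.25) — so the sum rule holds
exactly by construction, with no rejection sampling. Read counts are
binomial at the CCF-model VAF with Poisson per-site depth (mean 100,
floored at 1); purity is uniform on [0.4, 0.8]; copy-number events are
drawn to hit a per-patient altered-fraction target (group means 0.30 for
mHNPC vs 0.12 for hrlPC, SD 0.09, matching the within-group spreads such
cohorts report), split 60/40 between truncal events and region-private
events assigned to non-trunk clones; trinucleotide contexts are drawn from
per-clone signature mixtures (age-like trunk, flat branches; MMRD patients
switch to the MMRD-like column and a tenfold mutation load); immune counts
follow a Beta INIF model whose mean shifts for MMRD patients and a
log-normal patient-level CD8/FOXP3 ratio with means 6.08 (wild-type) and
2.65 (Wnt-activated) — the effect sizes the association tests are asked to
recover. The cohort defaults (25 patients, 2–4 regions, 2–6 clones,
12 mHNPC / 13 hrlPC) are the study conditions the package targets.

What the generator does **not** emulate: subclonal (fractional) copy
number, mutation multiplicities above 1, indels/fusions/structural
variants, overdispersed (beta-binomial) read counts, sequencing artefacts,
and spatial correlation between regions beyond the clone mixture itself.
Passing recovery tests therefore demonstrates correctness of the inference
machinery under the stated model, not robustness to every failure mode of
real panels; the depth and exome target size are configurable defaults,
not claims about any particular study's library design.

## Numerical choices and degenerate inputs

- EM convergence: absolute log-likelihood change < 1e-4, cap 150
  iterations; non-convergence returns the best solution with a classed
  warning.
- Binomial probabilities are clamped to [1e-6, 1−1e-6] inside likelihoods;
  cluster CCFs are reported clipped to [0, 1].
- Interval arithmetic uses IRanges/GenomicRanges (1-based closed
  coordinates end to end, matching the SEG-convention files); no second
  internal convention exists, by design.
- Empty segment sets are an error for FGA (neutral and missing are
  indistinguishable); single-region patients return NA with a warning for
  the heterogeneous fraction; all-tied group comparisons return p = 1 with
  a warning; zero-total spectra and zero FOXP3 totals are errors/NA with
  warnings rather than silent zeros.
- All randomness flows from one integer seed; per-patient substreams are
  derived arithmetically and stay below 2^31.

## Problem sizes in the test suite

The suite validates at sizes chosen to finish in minutes while keeping
Monte-Carlo noise well inside the asserted margins: 10,000 sites for CCF
calibration; 20 seeds × 100 mutations for cluster recovery; exhaustive
tree enumeration up to 5 clusters; 1,000 chain replicates for
parallel-evolution specificity and 300 noisy sibling replicates (100
mutations per cluster, the regime in which multi-variant parallel events
are realistically observed) for sensitivity; all group sizes up to 6 for
exact Mann–Whitney enumeration; all 2×2 tables with n ≤ 30 for the Fisher
oracle; 200 cohorts × 199 permutations for null calibration of the
burden-controlled test; and 500 replicates for the immune power/type-I
check at the 7-vs-8 study size.

## Known limitations

Clonal copy number is assumed at mutated sites; heavily rearranged genomes
with subclonal SCNA will bias CCFs. BIC can under-split clusters whose CCF
vectors differ by less than read noise (such clusters are also
biologically indistinguishable at that depth). The burden control
conditions on segment lengths but not on chromatin context or fragile
sites, so it controls burden, not every placement bias. The greedy tree
search returns all admissible trees only among deepest-parent choices
(with a full-feasibility fallback); at desk scale the exhaustive check
covers the cases that matter. Exact Mann–Whitney enumeration is used only
when the smaller group has ≤ 8 samples; beyond that the corrected normal
approximation is standard practice.
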