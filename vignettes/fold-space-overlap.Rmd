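---
title: "Testing fold-space segregation of a protein class"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing fold-space segregation of a protein class}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sharedfolds)
```

## The question and the statistic

Some protein classes — viral capsid proteins being the motivating example —
assemble into architectures that no cellular complex reproduces. Are such
classes also *structurally* set apart, i.e. do their folds occupy a region
of fold space that generic proteins rarely visit? `sharedfolds` frames this
as an overlap test. Given a *focus set* of domains (the class under test)
and a large background set with SCOP fold labels:

1. every background domain is assigned the structural distance to its
   nearest neighbour in the focus set;
2. background domains closer than a retention cutoff (default 0.6) are the
   focus set's structural *relatives*;
3. the test statistic is the number of distinct SCOP folds (`class.fold`
   prefixes of the sccs string, e.g. `b.121`) those relatives cover —
   the *shared folds*;
4. its null distribution is estimated by repeatedly partitioning the total
   set at random into a pseudo-focus set A of the same size and its
   complement B, recomputing the statistic for B against A with *self-fold
   exclusion* (folds already present in A are discarded, a conservative
   lower bound on folds shared with genuinely non-self proteins);
5. the one-tailed p-value is the left-tail probability of a null count at
   or below the observed one — a small overlap is the alternative of
   interest.

Both the raw fraction `b / n_perm` and the conservative estimate
`(b + 1)/(n_perm + 1)` are reported; when no null count reaches the
observed value the honest statement is the upper bound `p < 1/n_perm`,
never `p = 0`.

By default the *observed* statistic is computed **without** self-fold
exclusion while the null permutations use exclusion. This mirrors how the
overlap of a real class is described (a fold can both contain focus
members and be shared) while keeping the null conservative; both flags are
configurable, and the calibration experiment below uses exclusion on both
sides so that observed and null are exchangeable.

## Structural distance

Pairs of CA traces are compared with a TM-score-style alignment. For a
residue correspondence with per-pair distances $d_i$, the score under
normalization length $L$ is

$$\mathrm{TM}(L) \;=\; \max_{\text{superpositions}} \frac{1}{L}
\sum_i \frac{1}{1 + (d_i/d_0(L))^2},
\qquad d_0(L) = \max\!\big(1.24\,(L-15)^{1/3} - 1.8,\; 0.5\big)\ \text{Å},$$

the standard size-independent scale. The `max` is searched by seeding
superpositions from contiguous aligned fragments (lengths $L_{ali}$,
$L_{ali}/2$, $L_{ali}/4$, minimum 4) and refining each on the subset of
pairs closer than a growing inclusion cutoff until that subset is stable.

TM-scores are normalized by one chain length, so the score of a pair is
not symmetric when lengths differ. Distances used for clustering must be
symmetric; we therefore report both single-sided scores and use their mean
as the symmetrized score,

$$d(A, B) \;=\; 1 - \tfrac{1}{2}\big(\mathrm{TM}(L_A) + \mathrm{TM}(L_B)\big) \in [0, 1),$$

which reduces to the ordinary score for equal lengths and is bounded. The
conventional reading of the scale carries over: scores above 0.5 usually
mean the same fold, 0.4 is a common similarity criterion, and the
retention cutoff 0.6 on the distance scale corresponds to score 0.4. Which
normalization stood behind published threshold choices is generally not
recoverable; exposing `tm_norm_A` and `tm_norm_B` on every result lets a
user re-threshold on either side.

The full pairwise alignment is a heuristic in the fr-TM-align spirit:
seeds come from gapless threading at offsets strided by
$\lceil \max(L_A, L_B)/20 \rceil$, from the best-matching pair of
contiguous 8-residue fragments, and from a dynamic-programming alignment
of 3-state secondary-structure strings assigned from CA pseudo-dihedrals
(the right-handed $\sim$50° twist reads as helix, $|\theta| \ge 140°$ as
strand). Each seed is refined by iterating superposition → score matrix
$S_{ij} = 1/(1 + (d_{ij}/d_0)^2)$ → sequential dynamic programming → new
pair set, until the pair set repeats (cycle detection) or 30 iterations.
The alignment maximizing the symmetrized score is reported. Bit-exact
agreement with any particular TM-align implementation is a non-goal;
self-alignment, rigid-motion invariance and exhaustive-offset bounds on
short structures are enforced by tests instead.

### Numerical choices

* DP gap penalty: constant $-0.6$ per gap column, terminal gaps free;
  tie-breaks prefer diagonal, then up, then left, for cross-platform
  determinism.
* During refinement candidates are ranked by the score normalized with the
  shorter length; the two-sided score is evaluated for the top four
  distinct candidates at the end.
* Kabsch superposition corrects the reflection case so rotations are
  always proper (determinant $+1$ within $10^{-9}$); collinear point sets
  are rejected as degenerate.
* Score comparisons in tests use an absolute tolerance of $10^{-3}$
  unless the quantity is exact by construction.
* Symmetry of `structural_distance` is enforced exactly by canonical
  (lexicographic) argument ordering, so distance matrices are bitwise
  symmetric regardless of evaluation order or parallel scheduling.

## Reducing the focus set: clustering and medoids

Real focus sets are structurally redundant (virus families share folds at
low sequence identity), which would bias a permutation test that draws
sets of equal *size*. The focus set is therefore reduced in two steps:

1. a greedy sequence-identity cull (default threshold 40%, identity =
   matches / shorter length, longest-first visiting order) — the
   conservative denominator removes more, and the greedy order mirrors
   common culling practice;
2. unweighted average-linkage clustering of the structural distance
   matrix, cut at the *minimal* number of clusters such that every
   within-cluster pairwise distance is strictly below 0.6, and each
   cluster replaced by its medoid (the member minimizing the summed
   distance to co-members; ties go to the smallest id).

Minimality is found by scanning $k = 1, 2, \dots$ cuts of the dendrogram;
$k = n$ always satisfies the criterion, so the scan terminates. The
distances checked are the original ones, not cophenetic heights, and the
criterion is strict (`< 0.6`; boundary equality violates it). The
agglomeration itself is `stats::hclust(method = "average")`; its
tie-breaking convention applies, which is immaterial on the continuous
distances used here. `separation_stats()` reports how many inter-cluster
pairs fall below a probe cutoff (default 0.4) as a cluster-quality
diagnostic. Min-sum rather than min-max was chosen as the medoid
objective because it is the standard "most central member" notion; tests
verify it by brute force on every cluster.

## What the synthetic generators emulate

Because the real inputs (a capsid-structure database and a non-redundant
SCOP background) are large external downloads, the package ships two
generators that reproduce the *statistical* structure the analysis relies
on, at desk scale.

**Latent fold families.** Families are isotropic Gaussian clouds
(`within_sd`, default 0.3) around centres drawn at `center_scale`
(default 1.0) in an 8-dimensional latent space; Euclidean distances $e$
are squashed to $d = e/(e+c)$ with $c = 2.5$, a smooth, order-preserving
map into $[0, 1)$ that mimics the bounded distance scale. With the
defaults, within-family distances typically fall below 0.4 and
cross-family distances concentrate above 0.6 with a substantial tail
below it — generic folds are *connected* in fold space, which is exactly
what makes the permutation null non-degenerate. Focus families are
additionally displaced by `focus_displacement` (default 10 =
10 × `center_scale`) along a fixed axis, placing them beyond 0.6 from
everything else: the planted analogue of a segregated class.

The default problem size is 24 families × 4 members (96 domains) with 8
focus families. Eight was chosen, rather than one or two, because the
motivating class spans dozens of distinct folds; with very few focus
clusters the permutation null (which draws pseudo-focus sets of medoid
count) degenerates at small scale. The focus fraction (~8%) is far above
the real study's (~0.6%) — the price of desk-scale runtimes — which makes
planted p-values *less* extreme than the real analysis, not more.

**Toy structures.** Three ideal-geometry CA templates — a four-helix
bundle (1.5 Å rise, 100° twist), an eight-strand single-sheet meander and
an eight-strand two-sheet sandwich with cross-sheet connectivity
(3.3 Å rise, 4.8 Å strand spacing, 9 Å sheet separation) — are stitched
with bridging loops keeping adjacent CA–CA steps in [2.8, 4.2] Å, then
perturbed with isotropic coordinate noise and per-copy length jitter.
They are geometric motifs, not physical models: no side chains, no
energetics, no sequence-structure coupling. Passing tests on them shows
the alignment engine separates genuinely different topologies and
tolerates moderate noise; it does not show performance on real,
loop-rich, flexibly divergent protein pairs.

```{r toy, eval = FALSE}
hb <- generate_toy_structures(
  structure_template_config("helix_bundle", n_residues = 120, seed = 1))[[1]]
sj <- generate_toy_structures(
  structure_template_config("sandwich_jellyroll_like", 120, seed = 2))[[1]]
structural_distance(hb, sj)   # ~0.79: different folds
```

## The permutation experiment, end to end

```{r pipeline, eval = FALSE}
cfg <- run_config(synthetic = latent_config(seed = 1),
                  n_perm = 2000, seed = 1, output_dir = "run1")
report <- run_full_analysis(cfg)
report$summary$observed          # 0 shared folds for the displaced class
report$summary$p_conservative    # ~5e-4 at 2000 permutations
```

The pipeline logs one line per stage with its counts (loaded, filtered,
clustered, retained), writes each stage's artifact (cluster TSV, Newick
dendrogram, distance TSVs, ECDF of nearest-neighbour distances, null
histogram, JSON summary, per-fold report), and derives every random
stream from the single config seed, so reruns are byte-identical.
Functional-class runs (`run_functional_class()`) use the same machinery
with the class list as the focus set and no clustering reduction, the
convention for classes compared at full size.

## Calibration, problem sizes and known limitations

* **Calibration.** When the focus set itself is drawn uniformly at random
  (no displacement), the permutation p-value should be uniform. The
  packaged calibration experiment (80 families × 3 members,
  `center_scale` 1.8 so that family closeness is genuinely stochastic,
  focus size 20, 199 permutations, 200 replicates) yields a
  Kolmogorov–Smirnov statistic of about 0.08, below the 1% critical value
  0.115. Note an honest caveat: the shared-fold count is integer-valued,
  so the conservative p-value `(b+1)/(n+1)` is slightly *super*-uniform
  by construction; with unlucky dataset draws the KS statistic can
  approach or cross the critical value even though the test is valid
  (conservative). Configurations in which the count is nearly
  deterministic make this severe — a degenerate statistic cannot be
  calibrated — which is why the calibration experiment uses a dataset
  with widely dispersed counts.
* **Problem sizes.** The shipped tests and the acceptance script use 96-
  to 240-domain latent datasets, 24 toy structures of ~100 residues,
  and 199–2000 permutations; a full synthetic run completes in seconds
  and the entire suite in about a minute on one CPU. These sizes were
  chosen as the smallest at which every qualitative property of the
  analysis (recovery, segregation, calibration) is stable.
* **Limitations.** The aligner is sequential only — no circular
  permutations, no non-sequential topologies, no multiple alignment.
  Identity filtering is percent-identity based, not profile-based. Domain
  *definition* is out of scope: the package consumes pre-cut domains and
  cannot reproduce any manual dissection or compactness screening that
  produced them. Conclusions from synthetic data transfer to real sets
  only to the extent that the latent-family picture (tight families,
  connected background, displaced focus class) describes them.
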