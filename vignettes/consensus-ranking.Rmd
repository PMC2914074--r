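---
title: "Consensus ranking of structure decoys by Pareto optimality and fuzzy dominance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking of structure decoys by Pareto optimality and fuzzy dominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocrank)
```

## The problem

Structure prediction pipelines — loop modelling in particular — generate
hundreds to thousands of candidate conformations ("decoys") per target and
then rely on a scoring function to pick the best one. No single
knowledge-based or physics-based energy (Rosetta, DFIRE, DOPE, backbone
dihedral potentials, force-field energies with implicit solvation, ...) is
reliably best across targets: a function that identifies the near-native
decoy for one loop can place a 3 Å model at the top of the next. Averaging
scores or fitting regression weights to combine functions has its own
failure mode: a weighted sum is a linear functional, so decoys on concave
regions of the Pareto-optimal front of the multi-function score space can
never minimise it, no matter the weights.

`pocrank` implements a consensus that needs no weights and no training.
Treat each decoy as a point in the K-dimensional space of (oriented,
normalized) scores, all lower-is-better. Decoy $u$ *dominates* $v$ when

1. $g_i(u) \le g_i(v)$ for every scoring function $i$, and
2. $g_j(u) < g_j(v)$ for at least one $j$.

The decoys dominated by nobody form the Pareto-optimal front — the set of
candidates that are defensible under *some* monotone combination of the
scoring functions, including non-linear ones a regression cannot reach.

## Normalization

Raw energies live on wildly different scales, so each column is mapped by
the strictly increasing affine map

$$g(f) = \delta + (1-\delta)\,\frac{f - \min f}{\max f - \min f}$$

onto $[\delta, 1]$. The codomain is conceptually $[0,1]$; the floor
$\delta$ (default 0.01, configurable in `normalize_scores()`, valid range
$(0, 0.1]$) keeps every normalized score strictly positive so that the
ratio-based fuzzy memberships below never divide by zero, at the cost of a
negligible compression of the scale. Because the map is strictly increasing
per column, crisp dominance — and therefore the front and the front
partition — is identical on raw and normalized scores; the package computes
on normalized scores as its one canonical path and asserts the equivalence
in its test suite (order preservation and invariance under positive affine
transforms of any raw column). A column that is constant across decoys
carries no ranking information; it maps to all-1, which contributes a
neutral factor 1 to every membership product — numerically identical to
dropping the column while keeping matrix shapes stable.

## Fuzzy dominance and the ranking value

Crisp dominance is binary, but dominance has a strength: a decoy far into
the dominated region is "more dominated" than one just inside it. With the
linear membership $\min(x, y)/y$ and the bounded division
$x \div y = \min(1, x/y)$, decoy $u$ dominates $v$ by degree

$$\mu_a(u, v) = \prod_i \frac{\min(g_i(u), g_i(v))}{g_i(u)}$$

and is dominated by $v$ by degree

$$\mu_p(u, v) = \prod_i \frac{\min(g_i(u), g_i(v))}{g_i(v)},$$

products over all normalized scoring functions. Both lie in $(0, 1]$, the
diagonal is exactly 1, and the roles are two views of one quantity:
$\mu_a(u,v) = \mu_p(v,u)$. A crisp dominator has $\mu_a = 1$ exactly (every
factor caps at 1 — the implementation guarantees this without
floating-point slack), while its own $\mu_p$ against the dominated decoy
shrinks with the margin of dominance, which is exactly the grading a
dominance count cannot express.

```{r fuzzy-example}
tab <- score_table(rbind(A = c(0.2, 0.2), B = c(0.4, 0.6), C = c(0.9, 0.3),
                         D = c(0.8, 0.8)))
class(tab) <- c("normalized_score_table", class(tab))
fdm <- fuzzy_dominance(tab)
fdm$mu_a["A", "B"]   # crisp dominator: exactly 1
fdm$mu_p["A", "B"]   # (0.2/0.4) * (0.2/0.6) = 1/6
```

The ranking value of a decoy aggregates these degrees over a reference set:

$$r(x_i) = \max_{x_j \in R,\, j \ne i} \mu_p(x_i, x_j),$$

the worst-case degree to which $x_i$ is dominated by anyone — the
fuzzy-dominance ranking of the fuzzy-Pareto literature. Smaller is better.
The display form was a genuinely open design point; this choice satisfies
the three properties any admissible aggregation must have (a decoy crisply
dominating all others ranks first; identical score vectors tie exactly;
the value is invariant to input order) and reproduces the intended grading:
in the example above, A dominates C more strongly than B
($\mu_p(A,C) = `r round(fdm$mu_p["A","C"], 3)` < \mu_p(A,B) = 0.167$).

## Front peeling

The full ranking stratifies the set: extract the Pareto front, order its
members by $r$, remove them, and repeat on the remainder until no decoys
are left. Every decoy gets a front index (front 1 = the front of the whole
set) and fronts are emitted in order, so the partial order of crisp
dominance is never violated by the final ranking.

```{r peel}
poc_rank(tab)
```

Two documented choices here:

* **Reference set.** After a front is peeled, its members are removed, so
  the ranking value of a front-k member is computed against the decoys
  *still remaining* at that peel (`reference_policy = "remaining"`, the
  default; `"full"` ranks every front against the complete set, and the
  policy used is recorded in the output's provenance).
* **Ties.** Exact ties on $r$ break by smaller mean normalized score, then
  input order; duplicated score vectors do not dominate each other, land in
  the same front with identical $r$, and are never deduplicated. Output is
  therefore deterministic for identical input.

Fuzzy degrees are computed once on the full set and sliced per front —
values are identical to recomputation because $\mu$ depends only on the
pair. The pairwise matrices make the procedure $O(N^2 K)$ time and
$O(N^2)$ memory; ~20k decoys is a practical ceiling. Membership products
over more than 16 functions are accumulated in log space to avoid
underflow; the two paths agree to better than $10^{-12}$ (asserted in
tests), and typical consensus settings use 3–8 functions anyway.

## Baselines

For comparison the package ships the classical consensus strategies, all
consuming the same normalized table so per-function values are
commensurable: `rank_by_number()` (ascending mean normalized score),
`rank_by_rank()` (ascending mean per-function rank; ties share fractional
ranks), `rank_by_vote()` (each function votes for its top $k\%$; default
$k = 2$), and `rank_by_single()` (one function alone). The vote slot count
is $\lceil kN/100 \rceil$ with a minimum of one — the rounding is not
standardised anywhere, and the ceiling avoids zero-vote degenerate targets
at small $N$, which matters because the vote threshold is exactly the kind
of artificial sensitivity this strategy is criticised for. Vote-count ties
break by mean normalized score, then input order; this tie policy is a
documented choice, not a community standard.

## Evaluation against RMSD ground truth

When decoys carry an RMSD-to-native label, `evaluate_target()` scores any
ranking by:

* **Near-native false positives** — a decoy is near-native when RMSD is
  strictly below the cutoff (default 0.5 Å; membrane-protein studies use
  1.0 Å); the summary flags whether the top-1 decoy is a false positive and
  whether *all* top-5 are. Boundary conventions are deliberate constants:
  strict `<` for near-native, `≤ best + c` for coverage.
* **Pareto coverage** — whether the front contains a decoy within
  $c \in \{0, 0.1, 0.4\}$ Å of the set-best RMSD, plus front size/fraction.
* **Ranked-data ROC/AUC** — positives are decoys with RMSD $\le r$ where
  $r$ is the 10th-best RMSD in the set (ties at $r$ all count as positives,
  the literal reading of the construction); sweeping a cutoff $N$ down the
  ranking traces the (FPR, TPR) polyline, integrated by trapezoid. AUC 1 is
  a perfect ranking, 0.5 chance level; the trapezoid value coincides with a
  Mann–Whitney pair-count on these step curves, which the tests verify
  against an independent pair-counting oracle. Sets smaller than the
  positive rank follow `roc_policy`: skip (AUC `NA`, excluded from
  aggregate means, the default) or error.
* **Best-of-top-k RMSD** — the best model actually delivered if a user
  inspects the top k (default k ∈ {1, 5}).

`aggregate_evaluations()` rolls per-target results up per method (counts
and fractions of false-positive targets, mean AUC, mean best-of-top-k
RMSD, optionally grouped by a manifest-supplied label such as loop length —
metadata, never inferred).

## Synthetic decoy sets

Real decoy sets with externally computed scores are bulky and
license-bound, so the generator in `generate_decoy_set()` emulates their
statistical shape: per decoy an RMSD drawn from a folded normal
$|N(\mu = 1.5, \sigma = 1)|$ Å truncated by rejection to $[0.05, 12]$ —
a right-skewed pile of mediocre models with a thin near-native tail, the
qualitative shape of sampled loop ensembles — and per function the linear
model

$$\mathrm{score}_{ij} = \alpha_i\,\mathrm{rmsd}_j + \sigma_i\,\epsilon_{ij},
\qquad \epsilon_{ij} \sim N(0,1)\ \text{i.i.d.}$$

$\alpha_i \ge 0$ is the function's informativeness, $\sigma_i$ its noise;
scores are correlated with each other only through the shared RMSD
(correlated residuals are deliberately out of the default model). The
defaults — 300 decoys, 5 functions, $\alpha = 1$, $\sigma = 0.5$ — describe
a moderately informative five-function consensus setting and are the
conditions under which the package's recovery property is stated: the
POC top-1 decoy lies within 0.5 Å of the set-best RMSD in at least 90% of
200 seeded replicates. The generator emulates noisy monotone score–RMSD
trends only; it does not reproduce energy magnitudes, score-score residual
correlations, loop-length effects, or multimodal decoy clusters, so passing
tests demonstrate correctness of the machinery and sane behaviour under
the stated noise model — not performance claims on any real benchmark.
Generation is deterministic given the config seed (Mersenne-Twister,
inversion normals, recorded in provenance) and restores the caller's RNG
state.

## Numerical and degenerate-input choices

* $\delta = 0.01$ floor: distortion of relative ratios is at most ~1% per
  function while excluding zero denominators; $\delta > 0.1$ is rejected as
  it would visibly distort memberships.
* Single-decoy tables normalize to all-1 and rank trivially; all-identical
  tables form one front in input order.
* Missing score cells are a hard error by default; opting into
  `missing = "impute_worst"` fills the column's worst value and warns,
  because silent imputation can move Pareto fronts.
* With one scoring function the whole apparatus degenerates to the plain
  sort by that score — asserted in tests.

## Problem sizes used in the shipped validation

The self-contained validation runs at desk scale, chosen to exercise every
code path well beyond its edge cases: 500 random tables (up to 64 decoys,
6 functions) against a brute-force dominance oracle; 200 random ROC
instances against pair counting plus 10,000 random permutations for the
chance-level mean; and 200 seeded replicates of the 300-decoy recovery
preset. Published benchmark figures on real loop decoy sets require the
original decoy structures and externally computed scores; the evaluation
module computes all the per-target and aggregate quantities needed to
reproduce such tables when that data is supplied via a manifest.

## Known limitations

* $O(N^2)$ pairwise cost in decoys — inherent to dominance evaluation.
* No per-function weighting or training-coupled bias; deliberately out of
  scope (the method's point is to avoid it).
* The front of a large, noisy, high-K set can be broad; front fraction is
  reported so users can see when Pareto optimality alone is weakly
  selective.
* Evaluation assumes the RMSD label is trustworthy ground truth; no
  uncertainty in RMSD is modelled.
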