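---
title: "Coexpression segmentation: model, search, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression segmentation: model, search, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexseg)
```

## The probability model

`coexseg` assumes a chromosome arm can be partitioned into contiguous runs
of genes — *coexpression segments* — such that, in any one tissue, all
genes of a segment share a latent expression level. For gene $i$ of a
segment in tissue $t$:

$$x_{it} = s_t + e_{it}, \qquad s_t \sim f, \qquad e_{it} \sim g = N(0, \sigma^2).$$

The segment effect $s_t$ is drawn independently per segment and tissue and
models shared, regional regulation; the gene-specific deviation $e_{it}$
absorbs private regulation and measurement noise. A segment may hold one
gene or many.

$f$ is a two-component normal mixture
$\phi\,N(\mu_1,\sigma_1^2) + (1-\phi)\,N(\mu_2,\sigma_2^2)$. Two components
fit multi-tissue expression atlases well because log-scale expression is
typically bimodal: an "off/low" mode and an "expressed" mode. A single $f$
and a single $g$ apply to all tissues (no tissue-specific parameters), and
$f$ is estimated once — by EM on the pooled values over all genes and
tissues (`fit_mixture_em()`) — then frozen for the whole segmentation
analysis. Only $\sigma$ is trained against the segmentation objective.

The probability of one segment's data in one tissue integrates the effect
out,

$$P(x_{1..n}) = \int \prod_{i=1}^n g(x_i - s)\, f(s)\, ds,$$

which is available in closed form per mixture component by normal–normal
conjugacy:

$$\log M_k = -\tfrac{n}{2}\log 2\pi - (n-1)\log\sigma
  - \tfrac12\log(\sigma^2 + n\tau_k^2)
  - \frac{S}{2\sigma^2}
  - \frac{n(\bar x - \mu_k)^2}{2(\sigma^2 + n\tau_k^2)}$$

with $S = \sum_i (x_i - \bar x)^2$ and $\tau_k$ the component sd. The two
components are combined with a max-shifted log-sum-exp; everything stays in
log space, so segments of hundreds of genes at extreme values cannot
underflow. `segment_log_marginal_quadrature()` evaluates the defining
integral by adaptive quadrature (windowed around the conjugate posterior
mode, $\pm 30$ posterior sds) and exists purely as an independent oracle
for the closed form; the test suite holds them to $10^{-8}$ agreement on
randomized instances.

Tissues and segments are independent, so an arm's log likelihood is the
sum over segments and tissues. A segmentation is scored by

$$\mathrm{score} = -2\log P(x\mid\theta) + K\log n,$$

lower is better. Two accounting choices deserve transparency:

* **$K$** counts one parameter per segment (its length) plus the free
  distribution parameters. Because $f$ is frozen, the default is
  `n_free_dist_params = 1` ($\sigma$ only). Any fixed alternative shifts
  every segmentation's score by the same constant, so move selection and
  the argmin are unchanged; the argument exists so users can reproduce
  other accounting conventions.
* **$n$** is the number of data points *on the arm* (genes × tissues).
  Arms are analyzed separately, so the per-arm count is the
  self-consistent reading of "data points in the dataset".

## Search

Exhaustive search over the $2^{G-1}$ segmentations of a $G$-gene arm is
impossible at scale, but the score is additive over segments, which gives
two complementary engines:

**Greedy descent** (`greedy_descent()`): from an initial segmentation,
three move types are considered — *split* a multigenic segment at any
internal position, *merge* two adjacent segments, *shift* an existing
boundary to any alternative position within its two flanking segments
(each side keeps at least one gene; shifts are not restricted to ±1). At
every iteration the score change of every candidate move is evaluated
incrementally — only the one or two segments a move touches are re-scored;
the rest of the arm cancels — and the single best strictly-improving move
is applied, until no move improves the score by more than
$\varepsilon = 10^{-9}$ (the floating-point guard that forces
termination). Ties are broken by a fixed enumeration order (splits by
segment then position, merges by boundary, shifts by boundary then
position), making every descent deterministic. The compiled core memoises
interval likelihoods in a hash map shared across all replicates at fixed
parameters, because locally optimal intervals recur constantly.

**Exact dynamic programming** (`dp_optimal_segmentation()`): since each
segment contributes $-2\,\ell(a,b) + \log n$ independently, a standard
$O(G^2)$-evaluation partition DP finds the certified global optimum. It is
practical to a few hundred genes and serves as the gold standard the
greedy search is tested against (and as an `exact = TRUE` mode in
`cmd_segment()`).

Greedy descent is strictly downhill, so it is restarted from many
independent random initial segmentations — *replicates*, 1024 by default
(`run_replicates()`). Initial segment lengths are geometric with mean 2;
the choice has little effect on the optima reached, it only sets where
descents start. The **median** of the replicate final scores is the
objective value assigned to a parameter setting (the median is robust to
the occasional poor local optimum; `best` and `mean` aggregators are also
available). All replicate starts are drawn from a single RNG stream seeded
by `master_seed` — one seed reproduces the entire replicate set
bit-identically, and re-evaluating the objective at the same seed is
deterministic by construction.

**Training $\sigma$** (`train_sigma()`): the one free parameter is
optimised by a one-dimensional Nelder–Mead simplex on $\log\sigma$
(positivity for free): reflect the worse of two points through the better,
expand on success, contract otherwise, and stop when the simplex width
drops below `tol = 1e-3` (relative, since it lives on the log scale).
Every objective evaluation reuses the same `master_seed` — common random
numbers across candidate $\sigma$ values — so the objective is a smooth,
deterministic function of $\sigma$ and the simplex is not chasing Monte
Carlo noise. The reported segmentation is the best-scoring single
replicate at the trained $\sigma$. A hard floor $\sigma \ge 10^{-4}$
(expression units) prevents the likelihood divergence at $\sigma \to 0$.

`replicate_agreement()` quantifies robustness to the starting
segmentation: the fraction of the best replicate's internal boundaries
shared with the second-best and the worst replicate, and the fraction of
distinct segments (by gene span) present in more than half of the
replicates.

## The simulator

`simulate_dataset()` generates data *exactly* under the model: geometric
segment lengths (mean 2 by default) truncated at the arm end, one effect
draw from $f$ per segment and tissue, one deviation draw from $g$ per gene
and tissue, added. Ground truth (segmentation, effects, deviation sd) is
retained, and `score_against_truth()` reports boundary precision/recall/F1
(empty boundary sets score vacuously 1), an exact-match flag, and a Rand
index over the induced gene partition.

Defaults are chosen to resemble a multi-tissue expression atlas arm on the
log scale: $f = 0.4\,N(3.5, 1.2^2) + 0.6\,N(7.5, 1.8^2)$ (an off/low mode
and an expressed mode), $\sigma = 0.6$, 2000 genes × 27 tissues for the
full-scale configuration of `cmd_validate()`. The heteroscedastic variant
draws an independent $\sigma$ for every effect draw from a log-normal with
median $\sigma$ and geometric sd `sigma_spread = 1.5` — log-normal keeps
positivity and a symmetric multiplicative spread, a choice this package
makes explicitly since "an independent sd per draw" underdetermines the
distribution.

What the simulator does *not* emulate: probe-level microarray noise,
replicate structure, batch effects, mappability or annotation errors,
heavy-tailed deviations, or spatial autocorrelation of effects beyond
segment boundaries. Passing recovery tests on simulated data therefore
certifies the estimator under its own assumptions — it does not certify
that real chromosomes satisfy those assumptions.

### What recovery to expect at which scale

The test suite and the acceptance script run a scaled-down recovery
experiment: 5 datasets of 300 genes × 8 tissues, 64 replicates, chosen so
the full pipeline (simulate → train → score) completes in seconds on one
CPU. At that size the experiment is *information-limited*, and two
quantitative facts matter when reading its results:

* The within-segment residual degrees of freedom are roughly
  $(G - \#\text{segments}) \times T \approx 1200$, so the maximum-likelihood
  $\sigma$ carries an intrinsic sampling sd of about 1.5%. The trained
  value agrees with the fixed-segmentation MLE to four decimals — the
  simplex adds essentially no error — but individual datasets can
  legitimately land 2–5% from the generating value, and the maximum over
  five datasets frequently exceeds 2%.
* With only 8 tissues, adjacent segments occasionally draw effect vectors
  similar enough that the BIC *global* optimum (certified by the exact DP)
  merges them: the recovered segmentation then differs from the truth by
  one or two boundaries (boundary F1 ≈ 0.99). This is a property of the
  criterion at that data size, not of the search — the greedy replicates
  attain the DP optimum in essentially every instance.

At full-atlas scale (2000 genes × 27 tissues) both limitations vanish:
recovery is exact and the trained $\sigma$ lands well within 1% of the
generating value.

## Downstream characterization

`segment_profiles()` takes a segment's per-tissue value to be the mean of
its genes' values, then summarises each segment by its across-tissue mean
and sample sd. `classify_segments()` restricts to segments with ≥ 3 genes,
labels the top quartile of across-tissue sd *tissue-restricted* (ties at
the cutoff included) and the rest *housekeeping-like*, and lists the
tissues in which a segment's value exceeds the dataset-wide median gene
expression value (strictly greater); exactly one such tissue flags a
single-tissue-restricted segment. Only the one-tissue class gets a hard
definition — "few tissues" is left as the user-visible
`n_restricted_tissues` count rather than an arbitrary cutoff.

Intergenic regions are start-to-start spans between adjacent transcription
starts (`intergenic_regions()`), an intersegment region being the
intergenic region between the proximal genes of adjacent segments.
`compare_intergenic_lengths()` applies a two-sample Kolmogorov–Smirnov
test; `orientation_test()` counts same / head-to-head / tail-to-tail
adjacent pairs per class and compares two classes by a 2×3 chi-squared
test without continuity correction; `endpoint_sharing_test()` builds the
2×2 both/segment-only/domain-only/neither table over intergenic regions
and applies a two-sided Fisher exact test.

`peak_enrichment()` counts peaks overlapping each region set by ≥ 1 bp
(once per region set, never per region — a peak spanning two regions is
not double-counted), converts to peaks per kilobase, reports the density
ratio, and tests a 2×2 Fisher table whose rows are
`[peaks, non-peaks]`. The non-peak count expresses the remaining bases in
peak-sized units, `(bases − peaks × mean peak length) / mean peak length`,
rounded — this keeps the table's margins coherent; the literal alternative
`(bases − peaks) / mean peak length` is available via
`nonpeak_rule = "literal"`. Peaks can be pre-masked by fixed-width windows
centred on interaction-domain boundaries (`boundary_windows()`, default
2 kb). When several peak families are screened in one batch, Bonferroni
within the family is the intended correction.

Null segmentations come from `shuffle_segmentation()`: permute the segment
lengths over the fixed gene order and resample until no internal boundary
coincides with an original one (an explicit error when impossible, e.g.
all-equal lengths). `term_enrichment()` tests each term in each multigenic
segment by a hypergeometric upper tail against the genome background,
Bonferroni-corrected within the segment, discards significant hits carried
by a single gene, and compares the count of enriched segments against the
pooled count over 10 shuffled segmentations by Fisher's exact test.
Intersegment regions bordering a segment of a given type belong to that
type's analysis set on either-side qualification.

## Data handling conventions

* Internal coordinates are 0-based half-open. BED is read as-is; GFF3 is
  converted on read.
* Gene order is by annotated transcription start; equal starts are broken
  by gene id (lexicographic) for determinism — annotation formats do not
  say how nested genes should be ordered, so the package picks a stable
  rule.
* Matrix genes without annotation are dropped with a warning; annotated
  genes absent from the matrix are ignored.
* Replicate QC keeps a tissue only if every pair of its biological
  replicates has Pearson correlation ≥ 0.98 across genes; a zero-variance
  replicate makes the correlation undefined and drops the tissue with a
  warning. Kept tissues are averaged per gene. Values are assumed already
  normalized.
* The expression TSV round-trips bit-identically: values are written at
  full precision (`%.17g`) and re-read through base R's exact decimal
  parser.

## Problem sizes used by the tests

The suite certifies each layer at the smallest size that exercises it
honestly: likelihoods on 1000 randomized 1–6-gene segments against
quadrature; search on 50 simulated 12-gene × 4-tissue arms against
exhaustive enumeration (2¹¹ segmentations) and the exact DP, with
100-replicate greedy runs; recovery on 5 arms of 300 genes × 8 tissues
with 64 replicates; statistics against brute-force oracles on fixed small
tables and 1000-draw null calibrations. The full-scale validation
configuration (40 datasets, 2000 × 27, `cmd_validate()`) is exported for
users who want the complete experiment.

## Known limitations

* Segment effects are exchangeable across tissues and segments; real
  regional regulation is probably autocorrelated along the arm and across
  related tissues.
* One $f$, one $g$ per arm: strong tissue-specific variance differences
  are absorbed into $\sigma$, and the heteroscedastic simulator variant
  has no matching heteroscedastic *estimator*.
* BIC with $K = \#\text{segments} + 1$ is one defensible accounting; the
  package exposes the count rather than claiming it is canonical.
* The greedy search carries no optimality guarantee on real data (the DP
  does, but only to a few hundred genes); replicate agreement metrics are
  the practical diagnostic.
* Term enrichment treats the term map as flat (GO-slim style); it does not
  propagate a DAG.
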