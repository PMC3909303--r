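# coexseg

Chromosomes are not transcriptional confetti: neighbouring genes are often
expressed together, in coordinated runs, across tissues. `coexseg`
partitions each chromosome arm into contiguous **coexpression segments**
from a genes-by-tissues expression matrix (microarray or RNA-seq, on a
normalized log scale), using an explicit probability model rather than
correlation cutoffs. It is aimed at genomicists studying the chromatin- and
domain-level organisation of transcription: the segmentation itself, and
the downstream questions — are segment borders enriched for insulator
binding? do they coincide with physical interaction domain boundaries? are
head-to-head promoters over-represented inside segments?

## The model

For the genes of one segment in one tissue, expression is

```
x_i = s + e_i ,   s ~ f ,   e_i ~ g = N(0, sigma^2)
```

where `s` is a latent segment effect shared by all genes in the segment
(drawn independently per tissue) and `e_i` is a gene-specific deviation.
`f` is a two-component normal mixture, `phi N(mu1, sigma1^2) +
(1-phi) N(mu2, sigma2^2)`, fitted once by EM to the pooled expression
values and then frozen. The probability of a segment's data in one tissue
integrates the effect out:

```
P(x_1..x_n) = \int prod_i g(x_i - s) f(s) ds
```

which has a closed form per mixture component (normal-normal conjugacy).
Tissues and segments are independent, and a segmentation of an arm is
scored by a BIC criterion

```
score = -2 log P(x | theta) + K log n ,   K = #segments + 1 ,  n = genes x tissues
```

(lower is better; the `+1` counts the trained deviation sd). The search
runs many greedy descents over split / merge / shift moves from random
geometric starting segmentations ("replicates", 1024 by default), takes
the median replicate score as the objective, and trains `sigma` — the only
free distribution parameter — by a one-dimensional Nelder–Mead simplex on
`log(sigma)`. An exact dynamic-programming solver
(`dp_optimal_segmentation()`) provides the global optimum for small arms
and is used throughout the tests to certify the greedy search.

## Worked example

Simulate one arm under the generative model, re-fit the mixture, train the
deviation sd, and compare the best segmentation with the truth:

```r
library(coexseg)

sim <- simulate_dataset(n_genes = 300, n_tissues = 8, seed = 42)
#> Simulated arm 'sim': 300 genes x 8 tissues in 160 segments

fit <- fit_mixture_em(as.vector(sim$matrix), seed = 42)
#> Normal mixture EM fit (2 components, n = 2400)
#>   loglik = -5653.0993 after 162 iterations (converged)
#>   component 1: weight 0.4241, mean 3.4803, sd 1.4186
#>   component 2: weight 0.5759, mean 7.6037, sd 1.8411

training <- train_sigma(sim$expr, fit$params, sigma_init = 1,
                        n_replicates = 64, master_seed = 42)
#> Deviation-sd training: sigma = 0.625784 (median replicate score 9931.8421,
#>   20 objective evaluations)
#>   best segmentation: 159 segments, score 9931.8421

score_against_truth(training$best, sim$truth)
#> # A tibble: 1 x 7
#>   precision recall    f1 exact rand_index n_inferred n_truth
#> 1         1  0.994 0.997 FALSE      1.000        159     160
```

The generating deviation sd was 0.6; training lands at 0.626 (4.3% off —
within the sampling precision this data size supports). The 159 recovered
segments miss one of the 159 true internal boundaries (recall 0.994) and
invent none (precision 1). Per-segment expression profiles then classify
segments the way multi-tissue atlases are usually read — broad
"housekeeping-like" segments versus top-quartile-variability
"tissue-restricted" ones:

```r
profiles <- segment_profiles(sim$expr, training$best$lengths)
classes <- classify_segments(profiles)
dplyr::count(classes, class, single_tissue)
#> # A tibble: 2 x 3
#>   class             single_tissue     n
#> 1 housekeeping-like FALSE            26
#> 2 tissue-restricted FALSE             9
```

(Only segments with at least 3 genes are classified.) `autoplot()` methods
draw the mixture fit, the mean-vs-SD profile scatter, the trained-sd
objective surface, and the segmentation along the arm; `tidy()`/`glance()`
turn every fitted object into tibbles.

Downstream interval statistics (`peak_enrichment()`,
`endpoint_sharing_test()`, `orientation_test()`,
`compare_intergenic_lengths()`, `term_enrichment()`,
`shuffle_segmentation()`) take plain interval/strand/term tibbles read from
BED and TSV via the bundled readers. End-to-end runs with manifests are
available both as R functions (`cmd_fit()`, `cmd_segment()`,
`cmd_simulate()`, `cmd_analyze()`, `cmd_validate()`) and as a shell
front-end in `inst/cli/coexseg`.

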