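# poolgt

Cost-saving SNP genotyping by combinatorial pooling plus imputation, as a
reusable R toolkit.

Genotyping every individual of a large cohort on SNP arrays is often
prohibitively expensive, yet the interesting variants — the rare ones — are
exactly the ones a sparse assay misses. `poolgt` implements a group-testing
alternative: mix samples into overlapping pools, genotype the pools, decode
individual genotypes combinatorially, and impute whatever remains ambiguous.
It is aimed at researchers designing or simulating pooled genotyping
experiments (wildlife monitoring, plant and animal breeding, any budget-bound
cohort study) and at methodologists who want a fully seeded, self-contained
testbed for pooled-data imputation.

## What is inside

* **Design** — the square NORB (nonadaptive overlapping repeated block)
  scheme: a block of $n_B = q^2$ samples on a $q \times q$ grid assayed by
  $2q$ row- and column-pools (pool degree $q$, sample weight 2, pool
  intersection 1, reduction factor $\rho = q/2$; for $q = 4$: 8 pools per 16
  samples, $\rho = 2$).
* **Codec** — error-free pool encoding (a pool is 0/2 iff all members are,
  else 1) and block decoding by arc-consistent constraint propagation,
  yielding full calls, half-calls (`./1`, `0/.`) and missing genotypes.
  Below the decodability bound $\delta_{MAF} = d_0 G_1 / (2 n_B) \approx
  3.1\%$ (for $q = 4$), blocks are near-certainly decoded.
* **Block posteriors** — for undecoded cells, genotype probabilities
  conditioned on the block pattern $\psi$ and pool pair $(r, c)$: an exact
  dynamic-programming conditioning oracle, a marginal maximum-likelihood
  estimator, and the self-consistent EM-type estimator with heterozygote
  degeneracy weights $w = (1, 2, 1)$ that the pipeline tabulates per design
  and attaches to study data as GP/GL priors.
* **Imputation** — a genotype-likelihood-aware diploid Li–Stephens HMM
  (Rcpp core): hidden states are ordered pairs of reference haplotypes, all
  panel haplotypes serve as templates, one forward–backward pass per sample,
  switch probability $\theta_j = 1 - e^{-\rho d_j / H}$ per marker interval.
* **Evaluation** — genotype concordance with the half-mismatch rule,
  cross-entropy with a $10^{-5}$ floor, MAF-binned and rolling summaries,
  ggplot2 `autoplot()` methods.
* **Synthetic scenarios** — seeded founder-mosaic populations with a
  rare-skewed MAF spectrum, split into a phased reference panel and a study
  cohort; classical low-density→high-density masking and the pooled
  high-density scenario, both producing VCF-ready long tibbles.
* **VCF 4.2 I/O** (GT/GP/GL dialects, half-call spellings, phased panels)
  and a thin CLI (`inst/cli/poolgt.R`) chaining
  `simulate → pool → estimate-table → impute → evaluate`.

## A worked example

One marker, one block of 16 samples, a single heterozygous carrier:

```r
library(poolgt)

x <- matrix(0L, 4, 4)       # true genotypes on the 4 x 4 block grid
x[3, 1] <- 1L               # one heterozygous carrier
obs <- encode_block(x)
obs
#> Block observation (q = 4 )
#>   row-pools   : 0 0 1 0
#>   column-pools: 1 0 0 0
#>   pattern psi : (3,1,0) x (3,1,0)

decode_block(obs)
#> Decoded block (q = 4 )
#>      [,1] [,2] [,3] [,4]
#> [1,] 0    0    0    0
#> [2,] 0    0    0    0
#> [3,] ./m  0    0    0
#> [4,] 0    0    0    0
```

Eight pool assays genotyped 15 of 16 samples exactly and identified the
16th as a carrier of the minor allele — only its zygosity is open. The
block-posterior estimators quantify that remaining ambiguity:

```r
self_consistent_estimate(obs$pattern, r = 1, c = 1)$estimate
#>  p0  p1  p2
#> 0.0 0.5 0.5
posterior_exact(obs$pattern, r = 1, c = 1)   # phased prior (0.25, 0.5, 0.25)
#>    p0    p1    p2
#> 0.000 0.667 0.333
```

And the full pipeline on a seeded synthetic cohort (here a small one: 300
markers, 60 panel + 32 study individuals, imputing one 16-sample block):

```r
library(dplyr)
pop    <- simulate_population(sim_config(n_markers = 300, n_panel = 60,
                                         n_study = 32, seed = 7))
tbl    <- build_posterior_table(4)
bundle <- build_pooled_scenario(pop, q = 4, table = tbl, seed = 7)
glance(bundle)
#>   scenario n_entries prop_full prop_half prop_missing
#> 1 pooled        9600     0.578    0.0182        0.404

sub  <- bundle$assignment$sample_id[bundle$assignment$block == 1]
post <- impute_cohort(bundle$study_gl, pop$panel, hmm_params(), samples = sub)

truth <- tibble(sample_id = rep(pop$study_ids, each = 300),
                marker_id = rep(pop$markers$marker_id, 32),
                g_true    = as.vector(t(pop$study_truth)))
df <- inner_join(post, truth, by = c("sample_id", "marker_id"))
concordance(df$g_true, cbind(df$p0, df$p1, df$p2))
#> [1] 0.9148
```

Pooling decoded 57.8% of all genotypes outright; after imputation the
reconstruction reaches 91.5% concordance overall, and stratifying by MAF
shows the signature of the design — rare variants come out essentially
perfect while common ones carry the ambiguity:

```r
mm <- marker_metrics(df) |>
  left_join(pop$markers[, c("marker_id", "maf_study")], by = "marker_id") |>
  rename(maf = maf_study)
summarize_by_maf(mm, values = c("concordance", "cross_entropy"), window = 20)$bins
#>   bin         maf_lo maf_hi n_markers concordance cross_entropy
#> 1 [0,0.02]      0      0.02        78       1           0.00131
#> 2 (0.02,0.04]   0.02   0.04        30       0.991       0.0861
#> 3 (0.04,0.06]   0.04   0.06        23       0.978       0.103
#> 4 (0.06,0.1]    0.06   0.1         32       0.953       0.255
#> 5 (0.1,0.2]     0.1    0.2         37       0.916       0.451
#> 6 (0.2,0.4]     0.2    0.4         71       0.820       0.848
#> 7 (0.4,0.5]     0.4    0.5         29       0.747       1.07
```

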