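# segtrends

Permutation analysis of long-term trends in arthropod trunk segmentation.

## The problem

Trilobites added trunk segments over post-embryonic development; the mature
body carried a thorax of `T` articulated tergites and a pygidium of `P` fused
segments. Species-level compilations of `T` and `P` across the ~250 Myr of the
Palaeozoic let palaeobiologists ask whether segment number and allocation
shifted through time: did the median count move between periods, did the
*range* of counts contract (canalization), did families become internally more
conservative, and are such shifts explained by taxonomic turnover or by
defensive enrolment strategy?

Per-time-bin distributions of segment counts are right-skewed and heavy-tailed
with wildly unequal sample sizes, so mean-based tests are a poor fit. The
statistic of interest is the **median**, and because every pair of time bins is
compared at once, the familywise error rate (FWER) must be controlled.

## The method

For groups `g = 1..k` (time bins, clades, or enrolment types) with medians
`m_g`, the observed statistic for pair `(i, j)` is the unstudentized absolute
difference `d_ij = |m_i - m_j|`. Under the null that all groups share one
distribution the pooled values are exchangeable, so for each of `B`
permutations the values are reassigned to groups (sizes preserved) and

```
D_b = max over all pairs (i,j) of |median_i(b) - median_j(b)|
```

is recorded. The **single-step** adjusted p-value is the add-one estimator

```
p_ij = (1 + #{b : D_b >= d_ij}) / (B + 1)
```

Referring every pair to the one max-statistic distribution gives strong FWER
control without normality or equal-n assumptions. The **step-down** variant
(conservative maximal subsets) revisits hypotheses in decreasing order of
`d_ij`, re-referencing each to permutation nulls restricted to the maximal
subsets of groups still jointly consistent with the unrejected hypotheses, and
taking the most conservative candidate p; it is uniformly at least as powerful
as the single-step procedure. An exact enumeration oracle
(`exhaustive_null()`) computes the same p-values by brute force on small
instances and anchors the test-suite.

Around the tests sit the standard sensitivity analyses: leave-one-clade-out
jackknife (`jackknife_taxa()`), range rarefaction to a common sample size
(`rarefied_range()`), within-family range trends
(`family_range_by_interval()`), and enrolment-strategy subsets
(`enrolment_analyses()`), plus a synthetic species-table generator
(`generate_dataset()`) reproducing the skew/heavy-tail/unequal-n structure so
the whole pipeline is testable without any data download.

## Worked example

```r
library(segtrends)

rec <- generate_dataset(scenario_preset("pygidium_trend", seed = 42, shift_size = 3))
res <- run_timescale(rec, analysis_plan(variables = c("pygidium", "proportion"),
                                        config = permutation_config(10000, seed = 42)))
format_table1(res)$sequential
#>               comparison pygidium proportion
#> 1    Cambrian–Ordovician   1.0000     0.9996
#> 2    Ordovician–Silurian   0.9926     0.8927
#> 3      Silurian–Devonian   0.9926     0.9980
#> 4 Devonian–Carboniferous   0.9999     0.9980
#> 5  Carboniferous–Permian *0.0434*   *0.0089*
```

The preset plants a +3 shift in the pygidial median of the Permian bin only;
the table shows exactly that: every adjacent comparison is null except
Carboniferous–Permian, which is significant (starred at the familywise 0.05
level) for the pygidial count and for the proportion of trunk segments
allocated to the pygidium (`P / (T + P)`), the derived variable that tracks
caudalization. The per-bin summary confirms the construction — the Permian
median is 8 against 4–5.5 elsewhere, with positive skewness and excess
kurtosis throughout:

```r
summarize_distributions(rec, "pygidium", "period")
#>   variable         group   n min q1 median q3 max  skewness ex_kurtosis
#> 1 pygidium      Cambrian 100   1  3    5.0  8  21 1.1114035   1.1935772
#> ...
#> 6 pygidium       Permian 100   4  6    8.0 11  25 1.3393266   1.6305393
```

The same machinery runs from the shell:

```sh
Rscript inst/cli/segtrends.R simulate --preset pygidium_trend --seed 42 --out counts.csv
Rscript inst/cli/segtrends.R run --data counts.csv --out results_dir \
    --permutations 10000 --seed 42 --print
```

writing tidy CSVs (all-pairs and sequential p-value tables, jackknife runs and
significance flips, rarefied ranges, family ranges, enrolment arms) plus a
`manifest.json` with seeds, configuration and md5 digests; rerunning with the
same seed reproduces every output byte-identically.

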