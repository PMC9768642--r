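---
title: "Methods: permutation tests for median shifts in segment-count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation tests for median shifts in segment-count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segtrends)
```

## The data model

A record is one species: thoracic tergite count `T >= 0`, pygidial segment
count `P >= 0` (possibly unrecorded), order, family, a coarse time bin (one of
the six Palaeozoic periods) and optionally a finer series bin and an enrolment
type. Two variables are derived exactly: the trunk count `T + P` and the
pygidial proportion `P / (T + P)`, which lies in (0, 1] and equals 1 exactly
when the thorax is absent. Records missing `P` stay in the table and serve
thorax-only analyses — real compilations have many such species, which is why
thorax and pygidium panels of the same study can have different n. Records
violating an invariant (non-Palaeozoic bin, negative count, `T + P = 0`) are
rejected row-by-row with reasons, never silently; a numeric but non-integer
count is treated as file corruption and is an error rather than a rejection,
because it usually means a mis-mapped column.

## The test

All group comparisons use one statistic: the unstudentized absolute difference
of sample medians, with medians and quartiles under the linear-interpolation
(type 7) convention, even-sized groups taking the midpoint of the two central
order statistics. The choice of an *unstudentized* statistic is deliberate:
the max-statistic construction supplies familywise control regardless of
scaling, a studentized version would need a variance estimate that is
unstable for small heavy-tailed groups, and nothing in the procedure requires
it. Ties are left as they are; permutation inherently respects them.

**Single-step.** Pool all values, reassign them to groups of the observed
sizes `B` times (default `B` = 10 000; sampling with replacement from the
assignment space), record the max over pairs of the absolute median
difference, and refer every observed `d_ij` to that one null distribution.
Monte Carlo p-values use the add-one convention `(1 + count) / (B + 1)`: never
zero, conservatively biased, bounded below by `1/(B+1)`, which is also why
rendered tables print a floor value like `<0.0001` rather than 0. Within one
result, `p` is by construction monotone non-increasing in `d`; the
implementation asserts this on every run.

**Step-down (conservative maximal subsets).** Hypotheses are visited in
decreasing order of `d_ij`. At any step, the pairs not yet rejected define a
graph on the groups; a set of groups could still be jointly homogeneous
exactly when it forms a clique in that graph. For every *maximal* clique
containing the current pair, a permutation max-statistic null restricted to
that clique's values is computed (B draws, a deterministic substream per
clique), and the *largest* candidate p is taken — the conservative choice that
gives the variant its name. Two guard rails are enforced: p-values are
monotone non-decreasing down the ordering, and no pair's step-down p exceeds
its single-step p under the shared stream (the first hypothesis's only maximal
clique is the full group set, so its p *is* the single-step p). With two
groups there is no subset structure and the two procedures coincide exactly.
The clique search is brute-force over the joint neighbourhood and is capped at
12 groups; the coarse timescale has 6. Descriptions of this variant in the
applied literature are terse, so the concretization is declared here as the
package's reading: ordering by observed effect, restriction to
still-plausible homogeneous subsets, and the most conservative candidate p.

**Oracle.** `exhaustive_null()` enumerates every labelled assignment of the
pooled values to the group sizes (guarded at 1e6 assignments) and computes
exact p-values by counting. It shares no code with the Monte Carlo path — the
Monte Carlo null lives in compiled code, the oracle in plain R recursion —
and the suite checks the two agree within binomial tolerance on ~100 random
small instances.

## Sensitivity analyses

*Jackknife*: the timescale analysis is re-run with each order (or family)
removed, and any comparison whose rejection status flips is flagged. A
left-out run that empties a time bin is recorded as degenerate, not fatal.
*Rarefaction*: each bin is subsampled without replacement to the smallest
bin's size (1000 iterations by default) and the distribution of subsample
ranges is summarized; a rarefied range can never exceed the observed range,
and its expectation is non-decreasing in the subsample size. *Family ranges*:
within every (family, bin) cell with at least 2 species, the range of the
thoracic count; per-bin medians and means of those ranges track within-clade
conservation. *Enrolment*: both arms (between strategies pooling the era;
within each strategy across bins) drop groups under n = 5 — the literature
reports only that some subsets were "too small to test", so the floor is this
package's declared choice — and an arm with fewer than two usable groups
returns a captured error rather than aborting the other arm.

Multiple variables and timescales are *not* jointly corrected: familywise
control is within each all-pairs analysis, matching how such results are
conventionally tabulated. Sequential (adjacent-bin) tables are a row subset
of the all-pairs analysis, never a separate run.

## The synthetic world

The generator emulates what makes this kind of data statistically awkward,
and nothing more. Counts come from a shifted negative binomial — minimum
count plus `NB(size, mu)`, right-skewed with positive excess kurtosis — with
optional small-probability right-tail contamination (a geometric excess)
fattening the tail without moving the median. Defaults: thorax
`2 + NB(3, 8)`, pygidium `1 + NB(2, 5)`, 2% contamination, giving trunk
medians near 17 and heavier pygidial than thoracic tails. Per-period sample
sizes default to (475, 434, 131, 235, 191, 123) — 1589 species in total,
early-Palaeozoic-heavy, a declared stand-in since the real per-bin n are not
fixed by any value this package can cite. Enrolment labels are drawn from
per-bin mixes (diversity shrinking, spheroidal dominance growing through
time) and recorded for 40% of species.

Family structure is a switch, and the reason is instructive. When
`family_structure = TRUE`, each (bin, family) gets a latent thoracic location
drawn from the bin law and species scatter around it with sd
`family_effect_sd` — values within a bin are then *clustered*, which is what
the family-range analyses need to have something to measure. But clustered
values are not exchangeable, and a permutation test fed such data will
(correctly, from its own premises) reject far too often; an early version of
the `global_null` preset made exactly this mistake and produced a familywise
error rate near 0.7. The null preset therefore draws every species
independently from one identical law, with family labels as pure metadata.
A green FWER test consequently establishes error control *under
exchangeability* — it says nothing about robustness to within-bin
phylogenetic clustering, which real data certainly have; that caveat applies
equally to the published analyses this package's methods mirror.

Presets: `global_null` (iid, one law, unequal default n),
`pygidium_trend` (+`shift_size` added to every pygidial draw in the last bin,
n = 100/bin — an exact distributional median shift), `range_contraction`
(discrete uniform thorax laws, common centre 14, half-widths 12 down to 2:
range contracts while the law median is pinned), and `family_conservation`
(`family_effect_sd` falling 8 to 0.3 on a ratio-~0.55 geometric schedule,
chosen by simulating the construction so that the median within-family range
decreases strictly in essentially every generated dataset; a finer schedule
left the first step inside sampling noise). One master seed drives
everything; substreams are derived arithmetically, and the C++ permutation
core consumes R's own RNG stream, so every result — including whole
`run_all()` output directories and their manifests, which deliberately carry
no timestamps — is byte-reproducible.

## Numerical and design notes

- Proportions are tested raw, not transformed; the statistic is a median
  difference of proportions on (0, 1].
- Permutations are sampled with replacement from the assignment space;
  guaranteed-distinct sampling buys nothing at B = 10 000.
- Degenerate input (all pooled values identical) short-circuits to p = 1
  everywhere, logged, in both procedures.
- Zero-variance groups report `NA` skewness/kurtosis markers, not errors.
- Shape measures are the moment estimators `g1 = m3/m2^{3/2}` and
  `g2 = m4/m2^2 - 3`; the suite checks `g1` against the closed-form negative
  binomial skewness `(2 - p) / sqrt(r(1 - p))` at n = 1e5.
- Test simulations run at B = 2000 (scaled down from the production default
  10 000) where the design prescribes it; unit tests use smaller B still,
  since determinism and structure, not precision, are under test there.

## Limitations

No phylogenetic comparative structure: species are treated as exchangeable
observations within groups, families as labels. The generator reproduces
marginal shape and clustering, not ontogeny, preservation bias, or
geographic/stratigraphic heterogeneity — so green tests certify the
statistical machinery, not any empirical claim about trilobites. Reproducing
published period-level p-value tables requires the deposited species
compilation, which must be downloaded separately; with such a table loaded via
`read_segment_data()`, `run_timescale()` plus `format_table1()` produce the
comparable matrix directly.
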