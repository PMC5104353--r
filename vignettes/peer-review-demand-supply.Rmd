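---
title: "Modelling the demand, supply and imbalance of journal peer review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the demand, supply and imbalance of journal peer review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerload)
```

## The question

Scientific output grows by a few percent a year, and every peer-reviewed
article consumes several reviews before it appears — more when it is rejected
and resubmitted elsewhere, and more again when a journal runs a second review
round. Is the pool of researchers large enough to absorb that demand, and how
evenly is the reviewing effort spread across them? `peerload` implements a
closed-form demand–supply model of journal peer review plus the simulation
machinery needed to study the distribution of the workload over individual
reviewers.

## The model

### Demand side

Let $N_p$ be the number of articles published in a year and $\gamma$ the
fraction of all ultimately-submitted manuscripts that never get published;
the unpublished count solves $N_u = \gamma (N_p + N_u)$, i.e.
$N_u = N_p\,\gamma/(1-\gamma)$ (`unpublished_from_gamma()`). Published and
unpublished manuscripts are assumed to share one resubmission distribution:
$R'_i$ is the probability that a manuscript is submitted exactly $i$ times
($i = 1..I$), and $R_i = \sum_{k \ge i} R'_k$ the probability of at least
$i$ submissions. Only the product of an unpublished-specific distribution
with the (unknowable) unpublished count would be identified, so a single
shared distribution is the identifiable parameterization; the package makes
no separate unpublished distribution representable.

The total submission volume is counted as

$$N_s = (N_p + N_u)\sum_{i=1}^{I} i\,R_i .$$

Note the weight $i$ on the $i$-th-submission term: this accounting
(deliberately implemented exactly as the model states it) is heavier than
the plain expected submission count $\sum_i R_i$. Equivalently, a
manuscript submitted exactly $k$ times contributes $k(k+1)/2$ submission
units — a triangular-weight identity
$\sum_i i R_i = \sum_k R'_k\,k(k+1)/2$ that the test suite asserts, and the
form the brute-force oracle simulator mirrors. With the worked inputs
$R' = (0.05, 0.10, 0.85)$ the inner sum is $5.45$, and $800$ published plus
$200$ unpublished manuscripts yield $N_s = 5450$.

A fraction $d$ of submissions is desk-rejected; the rest receive $r_s$
reviews per round, and a second round happens with probability $\beta$,
giving $S_i = \beta (N_p + N_u) R_i$ second-round occasions and

$$N_\mathrm{reviews} = (1-d)\, r_s \left(N_s + \sum_i S_i\right).$$

The $(1-d)$ factor multiplies first- and second-round occasions alike —
again exactly as the model is stated, although $\beta$ is defined per
non-desk-rejected submission; no "corrected" variant is offered, and the
oracle tests mirror the printed composition. Reviews convert to reviewers
through the effort distribution $P_j$ (proportion of active reviewers
completing $j$ reviews a year):
$N_\mathrm{reviewers} = N_\mathrm{reviews} / \sum_j j P_j$.

### Supply side

Potential reviewers are counted from the authorship record: every author of
a paper in the census year (scenario 1); first or last authors over the
three years ending at the census year (scenario 2); first, second or last
authors of the census year (scenario 3); first or last authors of the
census year (scenario 4). Author identity is the exact
(last name, fore name, initials) triplet after trimming and case-folding —
no algorithmic disambiguation, mirroring how large bibliographic databases
index names. Two readings of scenario 2's "previous 3 years" are possible;
the window $[y-2, y]$ *including* the census year is used, which preserves
the nesting scenario 2 ⊇ scenario 4. The potential review supply is
$N_\mathrm{reviewers\text{-}supply} \times \sum_j j P_j$, and the headline
comparison statistic is the relative difference
$100\,(\mathrm{supply}-\mathrm{demand})/\mathrm{demand}$, with the boundary
(supply equal to demand) classed as a surplus.

### Workload imbalance

A full-time researcher's annual research budget is
$t_\mathrm{res} = 8 \times (365 - 104 - 25.3) = 1885$ hours (truncated to
whole hours); part-time fractions multiply the truncated figure and round
half-up, giving 943 and 566 hours at 50% and 30%. Truncation-then-half-up is
the only rounding convention consistent with all three published figures;
it is adopted as such. Each simulated reviewer draws an annual review count
from $P_j$, sums that many independent review durations (a probability-
weighted bin, then a uniform draw on the closed bin interval), and draws a
work-time category from a configurable mixture (default: 100% full-time).
Review counts and durations are independent — review duration is not
assumed to depend on reviewer load. Summaries report total hours, the hours
carried by the top $p$ of contributors, and the proportions of reviewers
spending at most 1% (or at least 13%) of their research time on review.
The top-share-of-reviews statistic is computed analytically:
`top_share_of_reviews()` ranks a pool in which only the active reviewers
carry effort-distributed counts and allocates fractionally inside a tied
count class, so degenerate cases are exact rather than simulated.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `d` | desk-rejection proportion | 0.25 |
| `r_s` | reviewers per review round | 2.5 |
| `beta` | probability of a second review round | 0.9 |
| `gamma` | unpublished fraction of submitted manuscripts | 0.20 |
| work time | 8 h/day, 365 d, 104 weekend d, 25.3 holiday d | $t_\mathrm{res} = 1885$ h |

`gamma` is interpreted as a fraction of all ultimately-submitted
manuscripts (so $N_u = N_p \gamma/(1-\gamma)$): this matches both the
"20% of submissions ultimately remain unpublished" framing and the
800/200 worked example, whereas reading it against total submission
*events* yields no consistent equation.

## What the synthetic generator emulates — and what it does not

Real inputs to this model are a 26-year bibliographic corpus, a
reviewer-recognition platform's self-reported effort distribution and a
survey-derived resubmission pattern; none are redistributable at package
scale. The generator therefore produces:

* **Corpora** (`generate_corpus()`): a fixed author pool with heavy-tailed
  (lognormal, `sdlog = 1.25`) appearance weights — mimicking real
  authorship skew, where a minority of prolific authors appears on many
  papers — and per-paper author counts defaulting to a shifted Poisson with
  mean ≈ 5, typical of biomedical bylines. Authors within a paper are
  distinct; byline order is random.
* **Effort distributions** (`effort_from_power_law()`): truncated discrete
  power laws $P_j \propto j^{-a}$; `calibrate_effort_exponent()` solves by
  bisection for the exponent reproducing the empirical anchor that about
  42% of reviewers report a single review ($a \approx 1.9$ at $J = 20$).
* **Resubmission distributions** (`generate_resubmission()`): two-point
  mixtures hitting any feasible value of the inner sum $\sum_i i R_i$,
  whose feasible range on support $1..I$ is $[1, I(I+1)/2]$ (the upper
  bound is a point mass at $I$).

What passing tests on synthetic data show is that the pipeline computes its
closed forms exactly and that the structural properties (scenario nesting,
monotonicity in every parameter, demand–supply consistency) hold for any
valid input. What they cannot show is agreement with the published
full-corpus figures (9.0M reviews, 1.8M reviewers, 63.4M hours in 2015 and
scenario surpluses of 15–249%): those require the actual MEDLINE corpus and
the unpublished effort/resubmission data, and no synthetic stand-in can
certify them.

## Numerical choices

* Probability vectors must sum to 1 within `1e-6` or they are rejected —
  silently renormalizing would hide data-entry errors; inside the
  tolerance, residual floating-point slack is normalized away so
  downstream identities hold to ~1e-9.
* Sparse effort mappings (e.g. `{1: 0.5, 4: 0.5}`) densify with explicit
  zeros; counts are 1-indexed throughout.
* All demand/supply quantities stay real-valued internally; rounding to
  whole counts or one-decimal percentages happens only in reports.
* Review-time bins are closed intervals with finite upper edges; an
  open-ended ">20 hours" bin must be closed at a stated maximum before
  entering a config.
* One seed governs each simulation (`withr::with_seed`), so a run is
  reproducible end to end and independent of call order; generators take
  explicit seeds and never touch the global RNG state outside their scope.
* Zero demand (e.g. full desk rejection, `d = 1`) yields an undefined
  relative difference, reported as `NA` by the pipeline; the scalar
  `relative_difference()` keeps its strict positive-demand contract.

## Problem sizes

The packaged checks run the brute-force manuscript-level oracle at 10^6
manuscripts, the workload Monte Carlo at 10^5 reviewers, the demand–supply
consistency property over 1,000 random effort distributions and the census
nesting property over 100 random corpora of 50 authors × 2 years — sizes
chosen so the full statistical battery completes in well under a minute
while leaving Monte Carlo standard errors far below the effects being
checked.

## Known limitations

* The census counts name triplets, not people: homonyms merge and spelling
  variants split, with opposing biases the model cannot separate.
* The effort distribution is held fixed across years (the empirical source
  only exists from 2012 onward), and resubmissions are assumed to complete
  within a calendar year.
* Bulk acquisition of bibliographic corpora is out of scope: the parser
  handles MEDLINE-style XML of any size presented to it, but nothing
  downloads or shards the real database.
* Geographic breakdowns, monetary costing and market-style models of the
  reviewing economy are not modelled.

## A worked run

```{r worked}
resub <- resubmission_distribution(c(0.05, 0.10, 0.85))
effort <- effort_distribution(c(`1` = 0.6, `2` = 0.4))
run_demand_supply(
  c(`2015` = 800), resub, effort,
  census = tibble::tibble(year = 2015L, scenario = 1L,
                          n_reviewers_supply = 20000)
)
```
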