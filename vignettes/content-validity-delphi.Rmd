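---
title: "Content validity analysis for Delphi expert panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content validity analysis for Delphi expert panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphivalidity)
```

## The problem this package addresses

When a new questionnaire is built — here the motivating instrument is the
Chem-Sex Inventory (CSI), a screening questionnaire for health-risk
behaviors associated with chemsex — its candidate items are usually
vetted by a panel of subject-matter experts before any field testing.
Each expert rates every item on a 1–5 Likert scale on two dimensions:
*relevance* (is this item pertinent to the construct?) and
*comprehensibility* (is the wording clear?). The panel is consulted in
anonymous rounds (the Delphi method); after each round, items that fail
quantitative validity criteria are dropped, near-duplicate items are
merged, and unclear items are reworded, until a defensible item set
remains.

`delphivalidity` implements the quantitative core of that workflow: the
per-item validity indices, the retention rules, the multi-round
bookkeeping, and a calibrated simulator of expert panels that makes the
whole pipeline testable without access to any real panel's raw ratings.

## The indices

For one item rated by $N$ experts, with $A$ of them giving a top-box
rating (4 or 5 on a 1–5 scale):

**Item content validity index.** $\mathrm{CVI} = A/N$, the endorsement
proportion. It ignores *how high* the endorsements are, only whether
each expert cleared the top-box threshold.

**Chance agreement and modified kappa.** Under a null model in which
each expert independently flips a fair coin between "relevant" and "not
relevant", the probability of observing exactly $A$ endorsements is the
binomial point mass
$P_c = \binom{N}{A} (0.5)^N$. The modified kappa
$$\kappa = \frac{\mathrm{CVI} - P_c}{1 - P_c}$$
discounts the CVI by how easily the observed count could arise by
chance. $\kappa \le \mathrm{CVI}$ always, with the gap largest for
middling $A$ where the binomial mass concentrates. `chance_agreement()`
evaluates the mass in the log domain via `lchoose()`, which is exact to
double precision and stable far beyond realistic panel sizes; naive
factorials would overflow past $N \approx 20$.

**Aiken's V.** $V = (\bar X - l)/R$, the mean rating $\bar X$ rescaled
to $[0,1]$ by the scale minimum $l$ and range $R$ (here $l=1$, $R=4$).
Unlike the CVI it uses the full ordinal information.

**Score-method interval for V.** The 95% interval is the Wilson-type
score interval treating $nR$ as the effective number of binomial
trials:
$$L,U = \frac{2nRV + z^2 \mp z\sqrt{4nRV(1-V) + z^2}}{2(nR + z^2)}.$$
The endpoints are exactly the roots $p$ of
$(V-p)^2\,nR = z^2\,p(1-p)$ — the property the test suite checks to a
residual below $10^{-9}$ — so the interval always contains $V$ and
respects $[0,1]$. With $z = 0$ it collapses to the point $V$. The $nR$
effective-trial device is a working approximation, not an exact
sampling model for ordinal means: a rating contributes $R$
pseudo-trials as if its $[0,1]$ rescaling were a sum of $R$ independent
Bernoulli draws. Simulation under this package's rating model (below)
puts its empirical coverage between roughly 93% and 97% for
$V \in (0.2, 0.8)$ with 30 raters, i.e. close to, and never far below,
nominal. `cvi_wilson_ci()` offers the companion Wilson interval around
the CVI itself ($N$ trials) for comparison.

The package uses $z = 1.96$ at 95% confidence rather than the
full-precision quantile; the published tables this package reproduces
were computed with 1.96, and the difference never reaches the third
decimal.

## Decision rules and their edge cases

`decision_rules()` gathers the tunables:

* `index_cutoff` (default **0.6**, on both CVI and V, unitless
  fractions of 1). 0.6 sits deliberately below the classical 0.8
  (CVI) / 0.7 (V) conventions: with a large panel the indices are
  estimated precisely enough that a lower bar is defensible, and later
  psychometric phases prune further.
* `indicator_rule`: `both_ge_cutoff` (default) demands CVI **and** V
  clear the cut-off; `either_ge_cutoff` accepts one. Published practice
  is genuinely inconsistent here — panels have retained items failing
  one indicator — so the rule is configuration, not code.
* `comprehension_high` = 4 and `comprehension_low` = 3.5 (scale
  points): mean clarity $\ge 4$ is "high", $[3.5, 4)$ "medium", below
  "low". Whether a mean of exactly 4 is high or medium is ambiguous in
  the applied literature; this package treats the boundary as high by
  default, and the bound is a plain parameter for the stricter reading.
* `top_box_min` = 4: the endorsement threshold, kept explicit so scales
  other than 1–5 remain usable.

All comparisons use unrounded values; rounding (half *up*, three
decimals — `round_half_up()`, not base R's round-half-even) exists only
in rendered reports. That choice is forced by reproduction: printed
values like 0.565 arise from 0.56495…, which half-even rounding would
print as 0.564.

Retention percentages in flow summaries are *truncated* to one decimal
(`retention_pct()`): 52 of 56 is reported as 92.8%, matching the
truncation convention of published Delphi flow figures (92.857% would
half-up to 92.9%).

## The round pipeline

`run_round()` applies, in a fixed order: (1) index computation, (2) the
index rule, (3) the comprehension rule among survivors — items below
the "high" bound are eliminated unless flagged for reformulation, in
which case they are retained for re-evaluation — then the overrides:
(4) duplicate merges, (5) relevance exclusions, (6) forced inclusions,
which reverse only eliminations from (2)–(3). Ordering matters and is
part of the contract: a forced inclusion can never resurrect a merged
duplicate or an excluded item, and a merge aimed at an item the index
rule already eliminated leaves the elimination in place (with a
warning) so every item keeps exactly one terminal status.

The qualitative decisions — which items are duplicates, which are
off-topic despite good indices — are deliberately *inputs*
(`override_ledger()`), not algorithms. Those judgments are made by
panels reading item wording; inventing a text-similarity heuristic to
reproduce them would manufacture a method where the workflow has
expert judgment.

`run_delphi()` chains rounds, passing survivors forward, and the
disposition ledger satisfies conservation invariants checked in the
tests: per round, entering = retained + eliminated (all causes), and
across the run, final + all eliminations = initial bank. Re-running the
survivors under the same rules with no overrides is a no-op.

## The synthetic panel generator

`panel_scenario()` / `generate_panel()` emulate the data structure the
analysis assumes. Expert $j$'s rating of item $i$ is a discretized
latent-normal draw
$$r_{ij} = \mathrm{clamp}\!\big(\mathrm{round}(\mu_i + \sigma_i
\varepsilon_{ij} + \delta_j),\ 1..5\big),$$
with a persistent rater-leniency effect
$\delta_j \sim N(0, \tau^2)$. Because the marginal latent score is
$N(\mu_i, \sigma_i^2 + \tau^2)$ and a rating is $\ge 4$ exactly when
the latent score is $\ge 3.5$, the item location that delivers a target
endorsement probability $p_i$ has the closed form
$\mu_i = 3.5 + s\,\Phi^{-1}(p_i)$, $s = \sqrt{\sigma_i^2 + \tau^2}$ —
exact, with no search error. A single location parameter thus moves CVI
and V together, which is how the two indices co-vary in real panels.

Defaults are fixed as the study conditions the package emulates: 36
experts in round one, 30 in round two (attrition of six), 1–5 scale,
$\sigma_i = 0.9$ and $\tau = 0.4$, i.e. a total latent spread of about
one scale point — a realistic amount of disagreement for a vetted
expert panel rating mostly-plausible items.

Randomness is organized as one Mersenne–Twister substream per
(item, round, dimension), with all raters drawn sequentially from that
stream and the substream seed derived from the scenario seed by a
mixing step. Consequences: a fixed seed reproduces the panel byte for
byte; growing the item bank leaves existing items' draws untouched; and
within a panel the rater draws are genuinely iid — an earlier design
that gave each (item, expert) cell its own single-draw stream produced
small cross-seed correlations that inflated the variance of $\bar V$
noticeably, which is why the per-cell scheme was rejected.

`scenario_from_table()` inverts the model: given target (CVI, V) pairs
— e.g. rows of a published validity table — it sets $p_i$ to the CVI
and root-finds the dispersion so the model-implied V matches.
Feasibility is bounded analytically first: CVI $= p$ forces
$V \in [3p/4, (1+p)/2]$ (endorsers rate at least 4, the rest at most
3), so pairs like (1.0, 0.1) are rejected rather than fitted. The root
search runs over $s \in [0.05, 8]$ on a log grid with `uniroot()`
refinement; if no sign change exists, the nearest grid value is
accepted only when its residual is below 0.005.

What the generator does **not** emulate: heterogeneous expert
expertise, item-by-expert interactions, systematic drift in standards
between rounds, non-response within a round, or correlated errors
across items sharing a theme. Passing tests therefore certify the
pipeline's arithmetic and bookkeeping under a clean rating model, not
the behavior of any real panel.

## Verification strategy and problem sizes

The test suite works at sizes chosen to keep the full run near twenty
seconds: exact binomial normalization up to $N = 60$; 100 random
score-interval root checks; 500 single-item panels for CVI
unbiasedness (the estimator is exactly unbiased by construction, so the
check is pure Monte-Carlo noise); 200 panels per setting for interval
coverage at two locations inside $V \in (0.2, 0.8)$, accepted between
90% and 99%; and a deterministic, engineered two-round 114-item
scenario that reproduces the canonical flow shape
(114 → 56 → 42, with 5 + 2 duplicate merges, 2 late index
eliminations and 10 relevance exclusions) to exercise every ledger
invariant at realistic scale.

A packaged reference table (`csi_validity()`, 42 items) provides a
regression surface. Its printed kappas are reproduced exactly from
$A = \mathrm{round}(\mathrm{CVI} \cdot 30)$, and both interval bounds
are reproduced exactly — all 42 rows, three decimals — once the
unrounded V is reconstructed as
$V = \mathrm{round}(120\,V_{\text{printed}})/120$, which is exact
because a 30-rater mean on a range-4 scale is an integer multiple of
$1/120$ (`reconstruct_reference()`). Recomputing from the printed
3-decimal V instead leaves 19 of the 42 rows one unit off in the third
decimal of a bound; the package's regression test asserts both facts,
and the drift is a rounding artifact of the source table, not a formula
discrepancy.

## Degenerate inputs and numerical conventions

A single-expert item is legal ($N = 1$: CVI $\in \{0, 1\}$,
$P_c = 0.5$). Empty rating sets are rejected at construction. Items
with no comprehensibility ratings skip the comprehension rule rather
than being imputed. Missing experts simply lower that item's $N$; no
imputation anywhere. An empty surviving set ends a Delphi run cleanly.
Ties at thresholds: all rules use $\ge$ comparisons on unrounded
values, so an item at exactly the cut-off is retained, and a mean of
exactly 3.5 is "medium".

## Limitations

The chance-agreement model is a fair coin per expert — a convention,
not an estimate of real base rates; kappa inherits it. The $nR$
effective-trial interval for V is approximate (see above). The package
reproduces and systematizes a published validation workflow; it does
not assess reliability, factor structure, or any downstream
psychometrics of the resulting instrument.
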