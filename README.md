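# delphivalidity

Quantitative content-validity analysis for questionnaire development
with Delphi expert panels.

When a new health questionnaire is drafted — the motivating instrument
here is the Chem-Sex Inventory (CSI), a screening questionnaire for
risk behaviors associated with chemsex — a panel of experts rates every
candidate item on a 1–5 Likert scale for *relevance* and
*comprehensibility*, over two anonymous consultation rounds. Items are
retained or dropped by per-item validity indices plus documented expert
judgments (duplicate merges, topic exclusions, rewordings). This
package implements that pipeline end to end, for methodologists and
instrument developers who want the arithmetic reproducible and the
item-selection audit trail explicit.

## The statistics

For an item rated by *N* experts, *A* of whom endorse it (rating ≥ 4),
with mean rating X̄ on a scale with minimum *l* and range *R* (1–5
scale: *l* = 1, *R* = 4):

* **I-CVI** = A / N — the endorsement proportion;
* **chance agreement** Pc = C(N, A) · 0.5^N — the fair-coin
  probability of that endorsement count;
* **modified kappa** κ = (CVI − Pc) / (1 − Pc) — the CVI corrected
  for chance;
* **Aiken's V** = (X̄ − l) / R — the rescaled mean, in [0, 1];
* **score-method 95% CI** for V, the Wilson-type interval with *nR*
  effective trials:
  L, U = (2nRV + z² ∓ z √(4nRV(1−V) + z²)) / (2(nR + z²)), z = 1.96.

Retention: both CVI and V must reach 0.6 (configurable to
either-of-two); surviving items need a mean comprehensibility ≥ 4 or a
documented reformulation. Merges, exclusions and forced inclusions are
data (`override_ledger()`), applied in a fixed, audited order.

## Worked example

Score one item rated by 30 experts (twenty 5s, seven 4s, three 2s):

```r
library(delphivalidity)
item <- item_ratings(c(rep(5, 20), rep(4, 7), rep(2, 3)), item_id = "csi_01")
evaluate_item(item)
#>   item_id round n_experts mean_rating   cvi         pc kappa     v ci_lower
#> 1 csi_01      1        30        4.47   0.9 0.00000378 0.900 0.867    0.794
```

A = 27 of 30 gives CVI 0.900; the chance of 27/30 by coin-flipping is
≈ 3.8 × 10⁻⁶, so kappa barely differs from the CVI; the mean 4.47
rescales to V = 0.867 with 95% interval (0.794, 0.916).

Simulate a 30-expert panel calibrated to target (CVI, V) pairs, run one
selection round, and render the report:

```r
sc <- scenario_from_table(cvi = c(0.90, 0.667, 0.45),
                          v   = c(0.90, 0.725, 0.55),
                          n_experts = 30, seed = 42)
panel <- generate_panel(sc, rounds = 1L)
led <- run_round(panel, decision_rules())
cat(render_validity_table(led[led$status == "retained", ]), sep = "\n")
#> item_id,cvi,kappa,aiken_v,ci_95
#> i001,0.967,0.967,0.942,(0.884–0.971)
#> i002,0.700,0.696,0.808,(0.729–0.869)
cat(render_flow_summary(flow_summary(led)), sep = "\n")
#> round 1: 3 entering, 2 retained (66.6%); eliminated: 1 index, 0 comprehension, 0 merged, 0 relevance
```

The third item (target CVI 0.45, below the 0.6 cut-off) is eliminated
by the index rule; the single simulated panel lands near, not on, each
item's targets, as it should.

The packaged reference table of the 42 retained CSI items is available
as `csi_validity()`; `reconstruct_reference()` recomputes every printed
kappa and confidence bound from it exactly (three decimals, all rows)
after reconstructing the unrounded inputs.

A command-line wrapper for `evaluate` / `simulate` / `report` lives at
`system.file("cli", "delphivalidity.R", package = "delphivalidity")`;
see `?cli_main`.

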