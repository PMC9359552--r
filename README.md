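# congestr

Congestion — the local density of players around the ball or the
ball-carrier — is a central descriptor of modern Australian football:
it conditions passing capacity, pressure, scoring, and the evaluation of
rule changes, yet it has traditionally been coded by hand from video.
`congestr` computes two automated congestion measures from 10 Hz player
tracking streams synchronised with a match event feed, and is aimed at
sports scientists and performance analysts working with positional data in
invasion sports.

**Continuous congestion.** Every 0.1 s frame of the 36 on-field players is
density-clustered (an OPTICS ordering with maximum radius ε, clusters
extracted at the ε threshold). A player *p* is a *core point* when at least
MinPts = 3 *additional* players lie within ε = 7.5 m; the core distance is

    core-distance(p) = UNDEFINED            if |N_eps(p)| < MinPts
                       dist to MinPts-th nearest other player, otherwise

and the reachability of *o* from *p* is
`max(core-distance(p), dist(o, p))` when defined. The largest cluster in a
frame is *primary* congestion, every other cluster *secondary*, noise
*outside*; per-frame proportions of the 36 players are aggregated as
mean ± SD of per-match means by field zone (D50 / DM / AM / F50) and
quarter.

**Disposal congestion.** At each kick or handball, nine spatiotemporal
features around the ball-carrier — player and defender counts within 5 m
and 10 m (IPC, EPC, IDC, EDC), four 90° quadrant counts relative to the
carrier's heading (FPC, RPC, LPC, BPC), and the available space (area of
the 10 m disc clipped to the field, AS) — feed a Random Forest
(500 trees, depth 10, min split 50, min leaf 5, Gini) that classifies the
disposal as under *high*, *nearby*, or *low* congestion, evaluated with
per-class precision / recall / F1, the confusion matrix, and one-vs-all
ROC-AUC and PR-AUC with a micro-average curve. Impurity-guided feature
elimination is included.

A synthetic match and disposal generator with planted ground truth
(`simulate_match()`, `simulate_disposals()`) makes the whole pipeline
testable without proprietary tracking data.

## Worked example

```r
library(congestr)

# a synthetic match: 4 quarters, 30 s each at 10 Hz, planted clusters
m <- simulate_match(sim_config(seed = 42, frames_per_quarter = 300L))
s <- run_match(m$tracking, m$events, m$attack)
aggregate_congestion(s, by = "zone")
#>    group_type group     label   mean sd n_matches
#> 1        zone    AM   primary 0.2500  0         1
#> 2        zone    AM secondary 0.0643  0         1
#> 3        zone    AM   outside 0.6857  0         1
#> 4        zone   D50   primary 0.2500  0         1
#> ...
```

The generator plants a densest group of 9 players in every passage of play,
so a quarter of the 36 on-field players (0.25) sit in primary congestion in
every zone — the pipeline recovers the planted value exactly. The
`secondary` share varies with the random passage plans, and `outside` is
the complement.

```r
# disposal classification end to end: 1943 labelled synthetic disposals
d <- simulate_disposals(1943, sim_config(seed = 42))
head(d$features, 3)
#>   IPC EPC IDC EDC FPC RPC LPC BPC       AS
#> 1   6   7   3   4   4   0   1   2 314.1553
#> 2   5   8   1   3   4   2   1   1 314.1553
#> 3   1   5   0   1   1   2   2   0 314.1553

cfg <- rf_config(seed = 42)           # the final model hyperparameters
sp  <- split_data(d$features, d$labels, cfg)   # stratified 80:20 -> 1554/389
model  <- train_rf(d$features[sp$train, ], d$labels[sp$train], cfg)
evaluate_model(model, d$features[sp$test, ], d$labels[sp$test])
#> <eval_report>
#>        precision recall f1 roc_auc pr_auc
#> high           1      1  1       1      1
#> nearby         1      1  1       1      1
#> low            1      1  1       1      1
#> macro-F1 1.000 | accuracy 1.000 | micro ROC-AUC 1.000
```

Synthetic disposals are generated with well-separated label semantics
(high: several players within 5 m; nearby: space but multiple players
within 10 m; low: at most one player within 10 m), so the classifier is
expected to be near-perfect here; real, manually labelled disposals overlap
between categories and score lower. The impurity importances confirm that
the immediate and extended counts carry most of the signal
(IPC 0.339, EPC 0.362, IDC 0.124, ...).

A thin command-line front end over the same functions ships in
`inst/cli/congestion.R` (subcommands `simulate`, `cluster`, `summarise`,
`features`, `train`).

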