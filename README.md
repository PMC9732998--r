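# fitsort

Multicriteria sorting of inventory items into ordered monitoring
classes, for analysts supporting hospital (or any) stock managers who
must decide how closely to watch each item. Single-criterion schemes
(ABC by value, VED by criticality, FSN by turnover) each ignore factors
the other schemes exist for; `fitsort` instead sorts items with an
additive multiattribute value model whose criteria weights are only
*partially* known, so the decision maker never has to state exact
weights — only a criteria ranking and the paired-comparison answers they
are comfortable giving.

## The model

Each item (alternative) *a<sub>j</sub>* is scored on *n* criteria by
marginal value functions *v<sub>i</sub>* mapping raw performance onto
[0, 1] (1 = preferred end), and aggregated as

> v(a<sub>j</sub>) = Σ<sub>i</sub> k<sub>i</sub> v<sub>i</sub>(a<sub>j</sub>),  Σ k<sub>i</sub> = 1, k<sub>i</sub> ≥ 0.

The scaling constants *k* are never pinned down. Preference information
— the ranking k<sub>1</sub> > k<sub>2</sub> > … and tradeoff statements
of the form "criterion *i* at the level worth λ beats criterion *j* at
best" (λ·k<sub>i</sub> ≥ k<sub>j</sub> + ε) — defines a polytope of
admissible weight vectors. For every item two linear programs bound its
global value over that polytope:

> s<sub>1</sub>(a<sub>j</sub>) = min<sub>k</sub> v(a<sub>j</sub>),  s<sub>2</sub>(a<sub>j</sub>) = max<sub>k</sub> v(a<sub>j</sub>).

Ordered classes are bands of the 0–1 scale (here M ≤ 0.4 < B ≤ 0.7 < W ≤ 1,
for monthly / biweekly / weekly monitoring); an item's *viable* classes
are all bands its interval [s<sub>1</sub>, s<sub>2</sub>] touches, and
items spanning two classes are monitored at the cadence of the more
critical one. Each answered comparison shrinks the polytope, narrows
every interval, and can only move items from "two viable classes" to
"exactly one". A Monte Carlo module perturbs the class thresholds
(±10% by default) to check how robust the final assignment is.

The package bundles a real 48-item hospital dataset (26 medicines, 22
materials; criteria: unit cost, monthly demand, lead time, criticality
1–3, storage volume) including the published per-item value bounds and
class labels, plus a synthetic-problem generator and a simulated
decision maker so the whole loop is testable end to end.

## Worked example

```r
library(fitsort)
fx <- huol_fixture()              # 48-item matrix, profile, ranking
v  <- compute_value_matrix(fx$matrix)
ws <- weight_space(fx$ranking, epsilon = 1e-6)
res <- classify_all(v, ws, fx$profile)
attr(res, "n_single")
#> [1] 1
head(res[c("alternative", "s1", "s2", "viable", "recommended")], 2)
#>                                  alternative        s1     s2 viable recommended
#> 1         Alteplase, 50 mg, lyophylic powder 5.077e-05 0.6101    B|M           B
#> 2  Calcium folinate, 50 mg, lyophylic powder 5.696e-03 0.5203    B|M           B
```

With only the criteria ranking, intervals are wide: the alteplase row
can score anywhere from ≈0.0 to 0.61, so both M and B are viable and
the safer B (biweekly) is recommended. Answering one tradeoff question
— "demand at 50% of its range beats volume at best" — adds the
constraint 0.5·k<sub>demand</sub> ≥ k<sub>volume</sub> + ε:

```r
ws2 <- add_constraint(ws, tradeoff_constraint(1, 5, 0.5, "prefer_upper"))
weight_ranges(ws2)
#>     criterion      min   max
#> 1      demand 0.222224 1.000
#> 2 criticality 0.000003 0.500
#> 3   lead_time 0.000002 0.333
#> 4        cost 0.000001 0.250
#> 5      volume 0.000000 0.167
```

`run_elicitation()` automates this loop (interactive prompts, recorded
answers, or a simulated decision maker). The bounds published for this
dataset after its full 20-question elicitation ship as a fixture; the
assignment rule reproduces the published classes exactly:

```r
rb <- huol_reference_bounds()
sets <- mapply(function(a, b) assign_classes(a, b, fx$profile),
               rb$s1, rb$s2, SIMPLIFY = FALSE)
sum(lengths(sets) == 1); sum(lengths(sets) == 2)
#> [1] 34
#> [1] 14
sum(sapply(sets, function(s) "W" %in% s))
#> [1] 4
```

34 items resolve to a single class, 14 span two, and only 4 of 48
involve class W — a better-than-90% reduction in items needing weekly
attention. Threshold robustness:

```r
run_sensitivity(rb[lengths(sets) == 1, ], fx$profile, delta = 0.10,
                n_draws = 10000, seed = 1)
#> threshold sensitivity: 10000 draws, delta = 10%, seed = 1, metric = viable
#>   singly classified group:   88.00% stable
```

i.e. under ±10% threshold perturbation, a singly classified item keeps
exactly its nominal class in ≈88% of draws.

A command-line wrapper with `classify`, `elicit`, `sensitivity` and
`simulate` subcommands is installed at
`system.file("scripts", "fitsort", package = "fitsort")`.

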