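# lmarel

Inter-rater reliability for graph-structured movement annotations.

## What this package is for

Laban Movement Analysis (LMA) codes human movement through four categories
— Effort, Space, Shape and Phrasing. In a structured assessment, expert
raters annotate a movement by traversing a directed decision graph of
multiple-choice questions (*is there a change? in which category? which
element?*); the sequence of answers is the annotation, one of 27 terminal
codes in the default trimmed graph. Raters code each stimulus twice,
ranking the most and second most salient change.

`lmarel` is for researchers who need to quantify how well such raters
agree. It provides:

* a validated **decision-graph** data model with path-length equalization
  (trimming) and path enumeration;
* the **path-overlap difference** between annotations,
  `d(s, s') = 1 − N_equal / N_total`, counting positionally matching
  answers over the longer path length (the complement is the overlap
  similarity used for individual-level analysis);
* **Krippendorff's α** with that custom metric,
  `α = 1 − D_o/D_e` with `D_o = Σ o_ck δ(c,k)` and
  `D_e = Σ n_c n_k δ(c,k)/(n−1)`, built on the standard coincidence
  matrix of pairable values (each within-unit ordered pair weighted
  `1/(m_u − 1)`);
* four **round-combination strategies**: round 1 only, order-dependent
  (R1, R2) pairs, order-independent (overlap-maximizing alignment), and
  the agreement-maximizing *R-optimal* selection — an exhaustive per-unit
  search over all `2^m` ways of taking R1 or R2 from each rater (C++
  backend);
* subset α by gesture or intended variation category, per-rater
  similarity to the modal annotation, and viewing-behavior statistics
  (paired t-tests, Pearson correlations);
* a **rater-noise simulator** generating complete synthetic datasets with
  known ground truth — 18 raters × 22 units × 2 rounds by default — with
  tunable error rates, a within-category confusion kernel, priority-swap
  probability and a lognormal viewing model.

## Worked example

```r
library(lmarel)

cfg <- simulation_config(seed = 42)   # 18 raters, 22 units, default noise
ds  <- simulate_dataset(cfg)
report <- run_analysis(data = ds)
report
```

```
<lma_report>  graph: lma-default-trimmed   raters: 18   units: 22
  alpha by strategy:
    r1_only    0.401
    ordered    0.391
    unordered  0.472
    r_optimal  0.745
  alpha by intended category (r_optimal):
    Effort     0.417
    Neutral    -0.001
    Phrasing   0.431
    Shape      0.632
    Space      0.571
```

Reading the numbers: with the default noise regime, round-1 agreement is
moderate (α ≈ 0.40). Treating the ordered (R1, R2) pair as one atomic
value depresses α — the value space squares, so chance agreement
collapses. Aligning the rounds so that opposite prioritizations of the
same two changes count as agreement recovers part of it (0.47), and the
per-unit optimal selection of one round per rater raises agreement
markedly (0.75). The per-category table recomputes α on each unit subset
independently; the neutral (no-change) units carry almost no expected
disagreement, so their α sits near zero by construction.

The viewing summary from the same report:

```
knocking vs direction views: t(17) = 9.06, p = 6.5e-08 (M = 45.4 vs 24.1)
round-1 vs round-2 views per question: t(17) = -11.72, p = 1.4e-09
viewing consistency across rounds: r = 0.98
similarity vs views: r = 0.20 (p = 0.43)
```

Raters replay knocking stimuli more, watch more before answering
round-2 questions, are highly self-consistent in viewing style across
rounds — and none of this viewing behavior predicts how closely a rater
matches the modal annotation (the simulator draws views independently of
answers by design).

A thin command-line wrapper ships at `inst/cli/lmarel.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lmarel.R", package="lmarel"))')" \
  simulate --seed 7 --out data.csv
Rscript .../lmarel.R alpha  --data data.csv --strategy r_optimal
Rscript .../lmarel.R report --data data.csv --out report.json --tables-dir tables/
```

See `vignettes/lma-reliability.Rmd` for the model, its assumptions, the
simulator's generative design and the package's numerical choices.

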