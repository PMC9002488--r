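# dietrec

Quantifying the habitual component of diet from longitudinal food diaries.

Diet-tracking apps produce long, irregular logs of what people eat at each
meal occasion. `dietrec` turns such logs into per-individual, per-occasion
**consumption sequences** of meals (a meal = the set of distinct food-item
names logged for one occasion on one day) and measures how habitual the
individual's behavior is. It is intended for researchers in nutritional
epidemiology and behavioral science working with food-diary exports, and
for anyone building diet-personalization tools on top of them.

## The measures

For a sequence $[m_t]_{t=1}^{n}$ and a choice $c$ (a food-item or a whole
meal) occurring on the day set $T_c$:

- **relative frequency** $= |T_c| / n$ — occurrences per recorded day;
- **span** $= (\max T_c - \min T_c)/n$ — spread of first-to-last occurrence.

A choice is **recurrent** when relative frequency ≥ 1/7 (roughly weekly)
and span ≥ 1/2 (present across at least half the window). With $\tilde D$
the recurrent item set and $\tilde M$ the recurrent meal set, the
**recurrence strength tuple** is

$$\alpha = \tfrac{1}{n}\textstyle\sum_t \mathbb{1}[\,|m_t \cap \tilde D| \ge 1\,],\quad
\beta = \tfrac{1}{n}\textstyle\sum_t \tfrac{|m_t \cap \tilde D|}{|m_t|},\quad
\gamma = \tfrac{1}{n}\textstyle\sum_t \mathbb{1}[\,m_t \in \tilde M\,],$$

with $0 \le \gamma \le \beta \le \alpha \le 1$ always. The package also
ships the preprocessing filters for raw app exports, a truncation-based
estimation-error analysis of measurement reliability (with Kaplan–Meier
summaries of sequence lengths), occasion and weekday/weekend contrasts,
and a synthetic diary generator with known habitual structure.

## Worked example

A 14-day breakfast log where a latte features almost daily:

```r
library(dietrec)

entries <- read_diary(example_diary_path())
prep    <- preprocess_diary(entries, preprocess_config(min_sequence_length = 14))
s       <- Filter(function(x) x$occasion == "breakfast", prep$sequences)[[1]]
recurrence_profile(s)
#> <recurrence_profile> 1 / breakfast (n = 14)
#>   recurrent items: latte, muffin
#>   recurrent meals: 2
#>   (alpha, beta, gamma) = (1.00, 0.93, 0.86)
```

Reading: on every day (α = 1) at least one habitual item was eaten; on
average 93% of a breakfast's items were habitual (β = 13/14); on 86% of
days the *entire* breakfast was one of the two recurrent meals
{latte, muffin} or {latte} (γ = 12/14). Item recurrence exceeding meal
recurrence is typical: people repeat items far more reliably than exact
item combinations.

The same analysis runs file-to-file:

```r
run_pipeline("diary.csv", "out/",
             preprocess  = preprocess_config(),
             thresholds  = recurrence_thresholds(),
             reliability = list(baseline_length = 112, grid = seq(14, 98, 14)),
             context     = TRUE)
```

writing `sequences.jsonl`, `profiles.jsonl` (one JSON record per
individual × occasion with the libraries, recurrent sets and the tuple),
`errors.csv`, `context.json` and a `manifest.json` with the cohort funnel.
A thin CLI wraps the same functions:

```sh
exec/dietrec run --in diary.csv --out-dir out/ --min-days 28
```

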