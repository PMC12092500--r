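# metacrit

Normative analysis of confidence criterion setting in signal detection
theory (SDT), for researchers studying metacognition and decision-making.

An observer discriminating two stimulus classes S1 and S2 draws evidence
`x` from `N(-d'/2, 1)` or `N(+d'/2, 1)` and responds "S2" when `x`
exceeds a type 1 criterion `c1`. A binary confidence ("type 2") report is
governed by response-specific type 2 criteria `c2_"S1" <= c1 <= c2_"S2"`:
an "S2" response is high confidence when `x > c2_"S2"`, an "S1" response
when `x < c2_"S1"`. Where those confidence criteria *should* go depends on
what the observer is optimizing. `metacrit` implements the closed-form
optimal type 1 and type 2 criteria under four objectives:

| objective | optimal `c2_"S2"` |
|---|---|
| type 2 accuracy | `max(c1_A, c1)` with `c1_A = ln(p(S1)/p(S2)) / d'` |
| type 2 reward | `max(c1_A + ln(Q2)/d', c1)`, `Q2 = (R_CR2-R_FA2)/(R_hit2-R_miss2)` |
| calibration to accuracy `p_T` | `max(c1_A + ln(O_T)/d', c1)`, `O_T = p_T/(1-p_T)` |
| HR2 − FAR2 | `max(ln(HR1/FAR1)/d', c1)` |

(mirrored `min(...)` forms for "S1" responses), together with:

* a deterministic forward model of type 1 and type 2 rates, accuracies and
  expected rewards;
* a brute-force outcome-curve oracle (`outcome_curve()`, `argmax_c2()`)
  that independently verifies every closed form by grid search;
* generative process models of suboptimal metacognition — type 2 noise
  (`x2 = x1 + e`) and type 2 signal loss (`x2 = (1-k) x1 + e`) — with an
  exact bivariate-normal engine and a common-random-numbers Monte-Carlo
  engine for model-aware criterion optimization;
* maximum likelihood meta-d' and M-ratio estimation from binary-confidence
  count data (`fit_metad()`);
* a command-line interface (`inst/cli/metacrit`) with subcommands
  `optimal`, `curve`, `simulate`, `fit-metad`, `sweep`.

## Worked example

An unbiased observer (`d' = 2`, equal priors) keeps confidence criteria
one unit to either side of the type 1 criterion. Shifting `c1` from 0 to 1
raises overall confidence even though the type 2 criteria never moved
relative to `c1`:

```r
library(metacrit)

s0 <- type2_summary(sdt_params(2, 0, 0.5), type2_criteria(-1, 1))
s1 <- type2_summary(sdt_params(2, 1, 0.5), type2_criteria(0, 2))
round(c(p_high_c1_0 = s0$p_high, p_high_c1_1 = s1$p_high,
        p_high_S1 = s1$p_high_S1, p_high_S2 = s1$p_high_S2,
        p_resp_S1 = s1$p_resp_S1), 2)
#> p_high_c1_0 p_high_c1_1   p_high_S1   p_high_S2   p_resp_S1
#>        0.52        0.58        0.68        0.31        0.74
```

The criterion shift makes "S1" responses both more common (0.74) and more
confident (0.68), while "S2" responses become rarer and less confident
(0.31); the net effect is a rise in average confidence from 0.52 to 0.58 —
a change driven entirely by type 1 bias, not by metacognitive strategy.

Optimal criteria and their brute-force check:

```r
p <- sdt_params(2, 0, 0.5)
c2_opt_reward(p, Q2 = 5.37)$c2_S2_star          # 0.8404 = ln(5.37)/2
c2_opt_calibration(p, 0.843)$c2_S2_star         # 0.8403 (O_T = 5.37)
argmax_c2(outcome_curve("reward", p,
          reward_matrix2(1, 0, 5.37, 0), "S2"))$c2   # 0.840
```

Rewarding low-confidence errors 5.37 times as much as high-confidence
corrects is the same policy as reporting high confidence only when the
response is at least 84.3% likely to be correct.

Suboptimal metacognition changes the optima. With type 2 noise
`sigma2 = 0.8` the reward-optimal criterion (Q2 = 3) moves from 0.549 to
about 0.18 (more liberal), while the HR2 − FAR2 optimum moves from 0.834
to about 1.07 (more conservative):

```r
pm <- process_model("noise", sigma2 = 0.8)
optimize_c2_under_model("reward", pm, p,
                        reward_matrix2(1, 0, 3, 0))$optimal
fit_metad(counts_from_trials(
  simulate_trials(pm, p, type2_criteria(-1, 1), 1e5, seed = 1)))$m_ratio
#> ~0.6  (meta-d' < d' under type 2 noise)
```

## Command line

```sh
inst/cli/metacrit optimal --context=calibration --d_prime=2 --c1=0 \
    --p_correct_T=0.8 --out=report.json
inst/cli/metacrit sweep --d_prime=2 --parameter=sigma2 --values=0,0.4,0.8 \
    --out=sweep.csv
```

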