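# glucotrial

Analytics for remote cross-over trials instrumented with flash continuous
glucose monitoring (CGM) sensors and a smartphone event log.

Flash CGM devices estimate interstitial glucose every 15 minutes but hold
only the most recent 8 hours in memory: the wearer must scan the device
regularly or data are lost. When such devices replace clinic visits in a
nutrition or medical-food trial, the analyst has to (i) reconstruct a
continuous trace from overlapping buffer downloads, (ii) quantify the
primary endpoint — the glucose response to self-administered fasted
meal-tolerance tests (MTTs) — in a small-sample cross-over design, and
(iii) exploit the continuous record for compliance and glycemic metrics
that a clinic-based design cannot see. `glucotrial` implements that
pipeline for biostatisticians designing or analyzing such studies, together
with a seeded synthetic-data generator so every stage is testable without
device exports.

## The model at the core

For one MTT starting at intake time \(t_0\), with glucose \(g(t)\) sampled
on a 15-minute grid over \([t_0, t_0 + 120\,\mathrm{min}]\) (9 samples),
the **incremental AUC** uses baseline \(b = g(t_0)\):

\[ \mathrm{iAUC} = \int_{t_0}^{t_0+120} \max\{g(t) - b,\, 0\}\, dt \]

evaluated trapezoidally on the grid (the positive-increment convention;
a signed `net` convention is also available). Each subject performs four
MTTs — at the beginning and end of both the placebo and the product period
of a 2×2 cross-over — giving within-arm changes and the per-subject
treatment contrast

\[ \Delta \mathrm{AUC}_{\mathrm{arm}} = \mathrm{iAUC}_{\mathrm{end}} -
   \mathrm{iAUC}_{\mathrm{begin}}, \qquad
   \Delta\Delta \mathrm{AUC} = \Delta \mathrm{AUC}_{\mathrm{product}} -
   \Delta \mathrm{AUC}_{\mathrm{placebo}} . \]

A negative \(\Delta\Delta\mathrm{AUC}\) means the product lowered the MTT
response. The cohort-level test is the one-sided Wilcoxon signed-rank test
of \(H_0: \Delta\Delta\mathrm{AUC} \ge 0\) against
\(H_1: \Delta\Delta\mathrm{AUC} < 0\), with the *exact* null distribution
obtained by enumerating all \(2^n\) sign assignments (exact even under
mid-ranked ties — essential at pilot sample sizes). Power for a follow-up
study is estimated by Monte-Carlo simulation of that exact test under a
normal effect model.

Around the primary endpoint the package provides spike-function peak
detection (Palshikar-style scoring), scan-gap compliance analytics against
the 8-hour buffer, a pre-MTT fasting check, annotation-rate metrics, and
consensus glycemic metrics (time in range 70–180 mg/dL, hypoglycemic
episodes below 70 mg/dL sustained for ≥ 2 consecutive samples, 2-hour
postprandial tolerance at 140 mg/dL).

## Worked example

Simulate a six-subject cross-over study in which the product scales the
incremental MTT response by 0.7, then run the full analysis:

```r
library(glucotrial)

sim    <- simulate_study(n_subjects = 6, product_effect = 0.7, seed = 42)
report <- run_study_report(sim$traces, sim$events, sim$designs)

do.call(rbind, lapply(report$subjects, \(s) as.data.frame(s$contrast)))
#>  subject_id delta_auc_placebo delta_auc_product delta_delta_auc
#>          S1          -365.540           -210.46        155.0797
#>          S2           966.755           -431.61      -1398.3620
#>          S3           -82.098          -1427.87      -1345.7764
#>          S4           247.937           -622.13       -870.0660
#>          S5           369.325            361.64         -7.6852
#>          S6           459.770          -1244.34      -1704.1138

report$cohort$signed_rank
#> $w_plus: 2        $n_effective: 6
#> $p_value: 0.046875        (exact_enumeration, alternative "less")
```

Five of six subjects have a negative contrast; the exact one-sided p-value
3/64 ≈ 0.047 comes from enumerating all 64 sign assignments of the six
ranked contrasts. A power analysis for a 35-subject follow-up at the
responders' mean effect:

```r
ctr <- do.call(rbind, lapply(report$subjects, \(s) as.data.frame(s$contrast)))
power_by_simulation(effect_mean = mean(ctr$delta_delta_auc[ctr$delta_delta_auc < 0]),
                    effect_sd = sd(ctr$delta_delta_auc),
                    n_subjects = 35, n_sim = 5000, seed = 1)
#> <power_estimate> n = 35, alpha = 0.05: power 1.000 (MC se 0.0000, 5000 sims)
```

The continuous record yields per-subject behavioral summaries, e.g. for
subject S1: 2.9 detected peaks/day, 27% of sampled time inside glucose
peaks, 99.1% time in range, 3.22 app logs/day.

A thin command-line wrapper is provided in `exec/glucotrial`
(`simulate`, `report`, `power` subcommands).

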