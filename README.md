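# graphomarker

Digital-biomarker screening for mild cognitive impairment (MCI) from
touch-screen handwriting. Subjects write the six-stroke Chinese
character for "rice" (米) ten times with the index finger; the
timestamped touch-event stream is segmented into strokes and pauses and
condensed into 21 kinematic biomarkers — ten information-processing-speed
features (total/process/writing time, initial and inter-stroke pauses
and their variability, within-stroke pause count) and eleven
executive-function features (task score, stroke counts, trajectory
lengths, speeds and their variability). A cohort pipeline then
reproduces the associated statistical analysis: a normality-routed
differential battery (independent t-test or Mann–Whitney U per marker,
chi-square for categorical demographics), likelihood-ratio stepwise
logistic biomarker selection, and ROC/AUC with DeLong confidence
intervals, plus the a priori two-sample t-test sample-size computation.

With J strokes of duration $t_j$, length $D_j$ and speed
$v_j = D_j/t_j$, gaps $g_1..g_{J-1}$ and initial pause $p_0$, the core
features are the exact decomposition
$\text{total} = p_0 + \sum t_j + \sum g_j$ and the derived battery
(e.g. average process pause $\sum g_j/(J-1)$, pause variability
$\mathrm{CV}(g)$, writing efficiency $\sum t_j/\text{total}$, speed
variability $\mathrm{CV}(v)$). Definitions: `?biomarkers`.

Because no raw subject data are deposited for this paradigm, the
package includes a seeded synthetic-session generator whose extracted
biomarker distributions are calibrated to the published per-group
medians/IQRs (38 MCI / 34 HC), making every stage testable end to end.
The methods vignette (`vignettes/writing-biomarkers.Rmd`) documents the
generative model, the calibration and its limits.

## Worked example

```r
library(graphomarker)

# a synthetic cohort at the study's group sizes
cohort <- simulate_cohort_table(n_mci = 38, n_hc = 34, seed = 1)
report <- run_screening_pipeline(cohort)
report
#> <screening_report>
#>  - cohort: 38 MCI, 34 HC
#>  - differential battery: 14 of 21 markers significant at p < 0.05
#>  - stepwise selection retained 4 marker(s): IPSDB_9, EFDB_11, IPSDB_6, IPSDB_7
#>  - joint-model AUC = 0.974 (0.939-1.000)
```

About fourteen markers separating the groups at p < 0.05 (the clinical
study this pipeline models reported 13), a handful of pause and
speed-variability markers retained by the stepwise screen, and a joint
logistic model whose AUC shows the two groups are almost fully
separable on these features. The battery itself is a tibble:

```r
dplyr::filter(compare_groups(cohort), significant)
head(tidy(report$model))          # coefficients of the joint model
glance(report$roc_joint)          # AUC with DeLong interval
autoplot(report)                  # ROC curves

# the published a priori sample-size computation
sample_size_ttest(d = 0.7, alpha = 0.05, power = 0.8)
#>   n_group1 n_group2 n_total achieved_power     d alpha power_target ratio tails
#> 1       34       34      68          0.812   0.7  0.05          0.8     1     2
```

Single sessions work the same way:

```r
s <- simulate_session(group = "MCI", seed = 7)
extract_biomarkers(s)     # 1 x 21 feature row
plot_session(s)           # the written characters
```

A thin command-line interface binds the stages
(`inst/exec/graphomarker`): `simulate`, `extract`, `analyze` and
`report`, each writing a manifest with arguments, seeds and input
checksums.

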