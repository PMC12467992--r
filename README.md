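# flowconn

Directed-connectivity and deep-learning analysis of resting-state EEG
cohorts, for researchers comparing clinical groups (here: concussed vs.
non-concussed athletes) on source-reconstructed brain signals.

The package has two tracks:

**Causal connectivity.** For every ordered pair of ROI source signals
(v_i transmitting, v_j receiving) it estimates the Liang–Kleeman
information flow rate from population cross-covariances and the
receiver's forward-difference derivative,

    T_{i→j} = r_ij / (1 − r_ij²) · (r_{i,dj} − r_ij · r_{j,dj})   [nats/unit time]

and normalizes it by the receiver's entropy-rate budget,
τ_{i→j} = T/Z with Z = |T| + |self| + |noise|, so |τ| ≤ 1 and
|τ| > 0.05 marks an *active* connection. On top of the per-participant
10×10 flow matrices it provides group averaging, top-k rankings,
permutation significance nulls (transmitter shuffling, pooled per
group, 95th-percentile threshold), pooled-distribution statistics and
comparisons (Kolmogorov–Smirnov, Kruskal–Wallis, Cohen's d, subsampled
COV/skewness/kurtosis feature clouds), and weighted directed degree
assortativity r_w with Welch-t group comparison.

**Classification.** A bidirectional-LSTM classifier (two stacked bLSTM
layers of 24 units/direction, dropout 0.32, dense-8 ReLU head, softmax;
31,514 parameters; Adam, cross-entropy) operating on 10-s, 64-channel
epochs of minimally preprocessed EEG (trim 4 s, resample to 250 Hz,
5th-order Butterworth low-pass at 100 Hz), evaluated under strictly
subject-wise ensemble cross-validation (e.g. 5 repeats × 6 folds with
train 8+8 / validation 1+1 / test 6+2 participants) with confusion
matrix, ROC and AUC summaries.

Both tracks are driven by a seeded synthetic-cohort generator
(Ornstein–Uhlenbeck ROI dynamics with planted directed couplings and a
group gain; 64-channel oscillation-plus-1/f recordings with a class
band-power effect), so every stage is testable against analytic ground
truth without access to restricted clinical data. The recurrent
network's forward/backward passes are compiled (RcppArmadillo) and
gradient-checked.

## Worked example

```r
library(flowconn)

# two-group cohort of coupled ROI dynamics with a 1.5x gain for the
# concussed-like group (6 + 6 participants, 60 s at 250 Hz)
cohort <- genVarCohort(6, n_samples = 15000, group_gain = 1.5, seed = 7)
#> SyntheticCohort: 12 participants (concussed-like n=6, control-like n=6)

flow <- lapply(participants(cohort), ifrMatrix)
groups <- split(flow, groupLabels(cohort))

mean_conc <- meanGroupMatrix(groups[["concussed-like"]], "concussed-like")
topConnections(mean_conc, 3)
#>   transmitter receiver mean_abs_tau
#> 1          RP       LP   0.10569469
#> 2          RC       LC   0.09589159
#> 3          LO       LC   0.08179655
```

The three strongest group-mean connections are exactly the three
planted couplings (RP→LP, RC→LC, LO→LC), all above the 0.05 activity
threshold.

```r
pool_ctl  <- poolGroupValues(groups[["control-like"]])
pool_conc <- poolGroupValues(groups[["concussed-like"]])
round(rbind(control = pool_ctl$stats, concussed = pool_conc$stats), 4)
#>             mean median     sd    cov skewness kurtosis
#> control   0.0107 0.0050 0.0148 1.3824   2.6277  12.0378
#> concussed 0.0133 0.0063 0.0203 1.5289   3.3046  16.1916

cmp <- compareGroups(pool_conc, pool_ctl)
unlist(cmp[c("ks_p", "kw_p", "cohens_d")])
#>       ks_p       kw_p   cohens_d
#> 0.02805686 0.02003268 0.14192866
```

The 540 pooled |τ| values per group (6 participants × 90 ordered
pairs) show the planted magnitude effect: the concussed-like
distribution sits higher and heavier-tailed, and both distribution
tests reject at the 5% level.

```r
rw <- lapply(flow, degreeAssortativity)
rw_groups <- split(rw, groupLabels(cohort))
acmp <- compareAssortativity(rw_groups[["concussed-like"]],
                             rw_groups[["control-like"]])
round(unlist(acmp[c("mean_a", "mean_b", "t_stat", "df", "p")]), 3)
#> mean_a mean_b t_stat     df      p
#>  0.216  0.130  0.985  7.136  0.357
```

Mean degree assortativity is higher in the concussed-like group but
not significantly so at this cohort size (Welch's t-test).

For the classifier track, `genRawEEGCohort()` + `runEnsemble()` run
the full subject-wise ensemble; `runPipeline(runConfig(...))` drives
everything from one seeded configuration and writes CSV/JSON outputs
with a provenance manifest. A command-line wrapper lives at
`inst/scripts/flowconn.R`.

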