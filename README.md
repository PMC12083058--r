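# jmsched

Risk-profile based adaptive scheduling of biomarker monitoring visits for
patients with stable chronic heart failure, built on a joint model for
multivariate longitudinal biomarkers and competing time-to-event outcomes.

## Who this is for

Biostatisticians studying personalized monitoring programs: how often
should a stable patient return for biomarker measurements (here log
NT-proBNP and log troponin T), when should monitoring be interrupted to
adjust therapy, and how much measurement burden does an adaptive,
risk-driven schedule save relative to fixed annual/semi-annual/quarterly
schedules — in the presence of a competing risk (all-cause mortality) next
to the event of interest (heart-failure hospitalization)?

## The model and the scheduling rule

Each biomarker follows a linear mixed model on the log scale,
η<sub>ip</sub>(t) = β<sub>p0</sub> + β<sub>p1</sub>t + b<sub>ip0</sub> +
b<sub>ip1</sub>t with b<sub>i</sub> ~ N(0, D), and the cause-specific
hazards are Weibull-baseline proportional hazards driven by the *current
values* of the two linear predictors and the baseline MAGGIC risk score:

h<sub>ik</sub>(t) = h<sub>k0</sub>(t) exp{γ<sub>k</sub> maggic<sub>i</sub> +
α<sub>k1</sub> η<sub>i1</sub>(t) + α<sub>k2</sub> η<sub>i2</sub>(t)},  k = 1 (HF hospitalization), 2 (death).

Given a fitted posterior and a patient's history to time t, the package
estimates the conditional cumulative incidence
π<sub>ik</sub>(t, s) = Pr(T\*<sub>ik</sub> < s | T\*<sub>i</sub> > t,
history, data) by Monte Carlo (posterior draws of θ, conditional draws of
b, quadrature for the window risk). Monitoring is interrupted when
π̂<sub>i1</sub>(t, t+Δ) ≥ κ; otherwise the next visit is scheduled after
the interval u solving π̂<sub>i1</sub>(t, t+u) = λ (capped at u<sub>max</sub>;
a conservative variant solves the same equation on the upper 97.5%
posterior quantile). Defaults: λ = 1%, κ = 10%, Δ = u<sub>max</sub> = 1 year,
quarterly warm-up visits to 0.5 years.

The simulation study generates cohorts of 381 training + 50 test patients
(quarterly training visits, administrative censoring at 20 years, Weibull
scales calibrated to 90/381 hospitalizations and 14/381 deaths), refits the
joint model each iteration, runs five scheduling strategies on the same
test patients, and scores measurement burden, interruption accuracy, and
interruption-timing RMSE against the generative truth. A misspecification
scenario (exponential NT-proBNP residuals, time-increasing troponin
association) probes robustness.

## Worked example

```r
library(jmsched)

params <- default_params()                    # shipped generative truth
cfg    <- simulation_config()                 # 381 train / 50 test, 20 y
ds     <- generate_dataset(params, cfg, seed = 42)

fit <- fit_joint_model(ds$train$longitudinal, ds$train$survival,
                       method = "laplace", seed = 1)
summary(fit)[c(1, 2, 19, 20), ]
#>    parameter       mean          sd    lower95    upper95      rhat      ess
#> 1    beta1_i 2.89487792 0.038944778 2.82156072 2.97705338 0.9992298 500.0000
#> 2    beta1_s 0.05467692 0.004956011 0.04409776 0.06450696 0.9980484 500.0000
#> 19  alpha1_1 0.42110090 0.083893573 0.25886927 0.58390667 1.0006016 444.1116
#> 20  alpha1_2 1.03861507 0.091363951 0.85724069 1.21226595 0.9982952 450.0764
```

The troponin intercept and slope (true values 2.8788 and 0.0537) and the
two hospitalization association coefficients (true values 0.5080 and
0.9957) are recovered within their 95% intervals. Predict and schedule for
one test patient:

```r
subj <- ds$test$truths[[1]]
recs <- ds$test$longitudinal[ds$test$longitudinal$subject_id == subj$subject_id, ]
hist <- patient_history(subj$subject_id, recs, subj$baseline_covariates, t = 0.5)

set.seed(7)
predict_cif(fit, hist, cause = 1, s = 1.5)$point_estimate
#> [1] 0.0004039947

tr <- run_strategy(subj, params, fit, default_strategies()$risk_based, cfg)
head(tr$visit_times, 7); tr$termination
#> [1] 0.00 0.25 0.50 1.50 2.50 3.50 4.50
#> [1] "censored"
```

This patient's predicted 1-year hospitalization risk at the end of warm-up
is about 0.04%, far below the λ = 1% limit, so the adaptive rule uses the
full 1-year cap between visits — 22 visits over 20 years where the
quarterly schedule would take 80. A five-iteration study comparing all
strategies:

```r
study <- run_study(study_config(n_iterations = 5, fit_method = "laplace",
                                mc = mc_control(50, 3, 15), master_seed = 1))
study$aggregate[, c("strategy", "measurements_per_patient_year_median",
                    "accuracy_pct_median", "rmse_interruption_median")]
```

Fixed schedules measure at their design rates (1, 2, 4 per patient-year);
the adaptive rule measures far less often than quarterly at comparable
accuracy, and the conservative variant sits between the two.

## Command-line tool

`inst/cli/jmsched.R` wraps the package for shell use:

```sh
Rscript inst/cli/jmsched.R simulate --config config.yaml --out simdata --seed 1
Rscript inst/cli/jmsched.R fit --longitudinal simdata/train_longitudinal.csv \
    --survival simdata/train_survival.csv --method laplace --out posterior.rds
Rscript inst/cli/jmsched.R predict --posterior posterior.rds \
    --history history.csv --maggic 20 --t 0.5 --cause 1 --horizon 1.5
Rscript inst/cli/jmsched.R schedule|evaluate|report ...
```

`vignettes/adaptive-monitoring.Rmd` documents the model, the generator's
assumptions, all numerical choices, and known limitations.
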