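# vpsbi — virtual patients by simulation-based inference

`vpsbi` builds **virtual patients** — individual parametrizations θ of a
mechanistic ODE disease-and-treatment simulator — from sparse, noisy,
partially missing biomarker time series, the data shape of individual-level
clinical trial readouts. It is written for quantitative-systems-pharmacology
modellers who need per-patient parameter *distributions* rather than point
estimates, and for methods researchers studying likelihood-free inference
on mechanistic models.

## What it does

For each patient the package learns the posterior p(θ | x_o) by
**sequential neural posterior estimation**: rounds of draw → simulate →
retrain, where a masked autoregressive conditional density estimator
(Gaussian MADE, 100 hidden features) is trained with the atomic
proposal-corrected loss on (θ, x) pairs from a stochastic simulator. The
observation x is the patient's summary vector — per-biomarker median and
Q0.9−Q0.1 spread, robustly normalized — and the simulator adds
multiplicative lognormal noise whose scale σ is itself a fitted parameter.
Priors are independent lognormals, `LogNormal(log θ_ref, 0.25)`, centered
on an expert reference parametrization.

The **nearest patient fit (NPF)** pipeline raises cohort-level performance
by reusing knowledge: successful fits (those beating the reference loss)
enter a *knowledge container*; each new patient's prior is recentered on
the learned parametrization of its most similar already-fitted patient,
with similarity measured by a missing-data-aware distance on the normalized
summary features,

    d(P_i, P_j) = sqrt( 3/(2|CB|) * Σ_{b ∈ CB} (Δmedian_b)² + (Δspread_b)² )

over the common biomarkers CB. Fit quality uses the max-scaled loss

    L(θ, c) = 1/(Σ_b T_b) Σ_b Σ_t ((sim_{b,t}(θ) − c_{b,t}) / max_t c_{b,t})²

and performance against the reference is the relative loss reduction
`gap = (L_ref − L)/L_ref ≤ 1`. A posterior is summarized by the best of 100
draws and by the fraction of draws beating the reference.

Supporting modules: a small surrogate treatment-response simulator plus a
synthetic-cohort generator (the package's study conditions), Saltelli/Sobol
total-order sensitivity analysis with variance-weighted aggregation for
fitting-parameter selection, a Nelder–Mead baseline with twofold bounds
around the reference, and CSV/YAML/HDF5 I/O with a CLI. See the vignette
(`vignettes/virtual-patients.Rmd`) for the model equations, the inference
scheme and every numerical design choice.

## Worked example

```r
library(vpsbi)

spec <- simulator_spec()               # surrogate model, 8-point week grid
ch   <- generate_cohort(4, spec, seed = 42)

cfg <- pipeline_config(mode = "npf", batch_size = 2,
                       engine = engine_config(n_rounds = 3, n_sims_per_round = 30,
                                              n_atoms = 10, steps_per_round = 60),
                       n_posterior_samples = 50, seed = 7)
res <- run_pipeline(ch$patients, spec, cfg)
for (r in res) print(r)
```

```
Fit P001 - loss 0.01027 (ref 0.04186 ) gap 0.755 frac_better 0.88 gate TRUE prior from reference 
Fit P002 - loss 0.008451 (ref 0.2531 ) gap 0.967 frac_better 0.94 gate TRUE prior from reference 
Fit P003 - loss 0.006916 (ref 0.1516 ) gap 0.954 frac_better 0.98 gate TRUE prior from P001 
Fit P004 - loss 0.02013 (ref 0.06053 ) gap 0.667 frac_better 0.2564103 gate TRUE prior from P001 
```

Reading: patient P003's best-of-50 posterior sample reaches loss 0.0069
against 0.1516 for the reference parametrization — a 95.4% relative loss
reduction (`gap`) — and 98% of its posterior draws beat the reference
(`frac_better`), so the fit passes the quality gate and its parametrization
becomes available as a prior center for later, similar patients (P003's own
prior came from its nearest fitted neighbour, P001). The per-patient
posterior objects yield as many alternative virtual-patient
parametrizations as needed via `posterior_sample()`.

The same run from the shell:

```sh
Rscript inst/cli/vpsbi.R simulate-cohort --seed 42 --out cohort.csv
Rscript inst/cli/vpsbi.R fit --mode npf --cohort cohort.csv --seed 7 --out results.h5
Rscript inst/cli/vpsbi.R report --cohort cohort.csv --results results.h5 --out report/
```

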