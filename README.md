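# pulsecue

Amplitude-modulation analysis of cue-locked neural responses during
pulsatile evidence accumulation.

## The problem

In navigation-based evidence-accumulation tasks (the virtual T-maze
"accumulating towers" paradigm), discrete visual cues appear at random
positions along both walls of a corridor and the subject is rewarded for
turning to the side with more cues. Calcium imaging of visual and
posterior cortex during this task reveals a minority of neurons whose
fluorescence is time-locked to individual cues: each cue evokes a
stereotyped impulse response, but with an amplitude that varies from cue
to cue. Those amplitude fluctuations are not pure noise — they carry
visual (cue angle), motor (running speed), cognitive (upcoming choice,
accumulated evidence), and memory (previous trial) signals.

`pulsecue` is an R toolkit for this analysis chain, aimed at systems
neuroscientists who want to quantify gain modulation of pulsatile sensory
responses. It provides:

* a **synthetic task and neural generator** — virtual T-maze sessions
  (spatial-Poisson cue trains with a 12 cm same-side refractory period,
  majority:minority means 7.7:2.3 on a 200 cm cue region, kinematics,
  lapse-mixed logistic choice behavior with de-biasing) and a forward
  model of dF/F traces, so every estimator can be validated by parameter
  recovery against known ground truth;
* **impulse-response deconvolution** per cell: dF/F(t) = Σᵢ Aᵢ g(t − tᵢ −
  τ_lag − δτᵢ) + noise, with g a two-sided Gaussian (rise σ↑, fall σ↓)
  convolved with a difference-of-exponentials calcium kernel (τ↑ = 35 ms,
  τ↓ = 300 ms, peak-normalized), non-negative amplitudes Aᵢ, and
  L2-penalized per-cue time jitters δτᵢ; scored by small-sample AICc and a
  shuffled-cue-timing null (cells with z > 3 are "cue-locked");
* **amplitude-modulation models**: Gamma-likelihood mean models μ_A =
  ρ(φ_cue) × f(v) × g(·) with four branches — angular receptive field ×
  flexible speed spline (null), stimulus-specific adaptation with
  exponential recovery (ξ, λ), choice-dependent spatial ramps, and
  cumulative cue-count dependence — selected and averaged by AICc, plus
  the normalized choice-modulation strength δA(y);
* **population decoding** of six task variables from cue-locked amplitude
  vectors (linear SVM, trial-stratified 3-fold CV, trial-block permutation
  nulls, Benjamini–Hochberg correction), uncorrelated task-variable modes
  via polar decomposition, and a session-level meta-regression;
* **behavioral metrics**: 4-parameter psychometric sigmoid over 11
  evidence bins, spatially binned evidence-weight logistic regression with
  bootstrap intervals, sliding-window session inclusion, quantile-based
  spread statistics and Jeffreys binomial intervals.

## Worked example

Simulate a session and a small labeled population, identify a cue-locked
cell, and ask how its amplitudes are modulated:

```r
library(pulsecue)

session <- generate_session(maze_config(), agent_params(), n_trials = 40,
                            seed = 7)
print(session)
#> session_log: 40 trials (40 included), accuracy 85.0%, seed 7

pop <- generate_population(session,
  population_spec(n_null = 1, n_ssa = 1, n_choice = 1, n_counts = 1,
                  n_distractor = 1), seed = 8)

# cell 3 was generated with choice-dependent amplitude modulation
fit <- fit_impulse_model(pop$traces[[3]], session)
sig <- cue_locking_significance(pop$traces[[3]], session, fit,
                                n_shuffles = 50, seed = 9)
print(fit)
#> impulse_fit: R-preferring, tau_lag 126 ms, sigma 97/170 ms, 150 cues,
#>   AICc -14818.3
classify_cue_locked(sig$z)   # z = 10.04 >> 3
#> [1] TRUE

truth <- pop$truth[pop$truth$cell_id == 3, ]
idx <- match(paste(fit$events$trial_id, fit$events$cue_index),
             paste(truth$trial_id, truth$cue_index))
cor(fit$amplitudes, truth$A[idx])
#> [1] 0.94

amp <- amplitude_table(fit, cell_ids = 3)
amp$A <- substitute_zero_amplitudes(fit, seed = 10)
branches <- lapply(setNames(c("null", "ssa", "choice", "counts"),
                            c("null", "ssa", "choice", "counts")),
                   function(m) fit_amp_model(amp, session$config, m,
                                             seed = 11))
ens <- select_and_average(branches)
print(ens)
#> amp_model_ensemble: best choice; weights null 0.00, ssa 0.00,
#>   choice 0.76, counts 0.24

cm <- choice_modulation_strength(ens, sigma_f = fit$sigma_f)
mean(abs(cm$delta_a))
#> [1] 0.273
```

The fitted kernel (lag 126 ms, rise/fall 97/170 ms) and the cue-locking
score z = 10 say the cell's trace is far better explained by impulses at
the true cue times than at shuffled times; the amplitude correlation of
0.94 against ground truth shows the deconvolution recovered the per-cue
gains; and model selection attributes those gains to the upcoming choice
(Akaike weight 0.76), with a choice-modulation strength of ~0.27 of the
cell's mean amplitude. Behavioral summaries work the same way:

```r
pf <- psychometric_fit(generate_session(maze_config(), agent_params(),
                                        1000, seed = 12,
                                        kinematics = FALSE))
print(pf)
#> psychometric_fit: p0 0.113, B 0.760, Delta0 -0.30, lambda 2.23
```

(The generating agent lapses 10% of the time, so p0 ≈ 0.1 and B ≈ 0.8.)

`run_pipeline(pipeline_config(...))` chains all stages — behavior, neural
forward model, cell filtering, impulse fits with significance, amplitude
models, decoding, and behavioral metrics — into one reproducible,
seed-determined run; `save_session()`, `load_session()` and
`save_results()` serialize everything as plain JSON/CSV.

The methods vignette (`vignettes/pulsecue-methods.Rmd`) documents the
models, conventions, tolerances and known limitations in detail.

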