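# serialdep

Analysis pipeline for serial-dependence experiments in which a continuous
orientation **adjustment task** is interleaved with a discrimination task
containing a to-be-ignored oriented **distractor**, presented on half the
trials either at a fixed, predictable location or at a random one. The
package answers, on trial-level data: does the distractor orientation bias
(attract or repel) the next adjustment report; is the bias from the
previous trial's probe a single component or a mixture of attraction and
repulsion; does the distractor interfere with that trace when it resembles
the previous probe; and does distractor-location predictability show up in
discrimination reaction times (attentional capture, proactive
suppression)?

It is written for psychophysicists who have (or want to simulate) tidy
per-trial tables of such an experiment and want the full inference chain
as tested, reusable functions rather than one-off analysis code.

## The model at the core

The adjustment error *y* is regressed on derivative-of-Gaussian (DoG)
transforms of the wrapped orientation difference Δ ∈ (−90°, 90°] between
an inducing stimulus (previous probe, or current distractor) and the
current probe:

    g_w(Δ) = Δ · exp(−Δ² / (2 w²))

Five nested models are compared — intercept only (`d0`), one kernel
(`d1`), two kernels of different widths capturing an attraction/repulsion
mixture (`d2`), and variants whose kernel amplitudes interact with the
location condition (`d1xloc`, `d2xloc`). Kernel widths are chosen by r²
grid search over 10–80° (jointly for `d2`, with a minimum separation that
keeps the two components identified); models are scored by Gaussian BIC,
reported as ΔBIC with the worst model at 0 (≥2 positive, ≥6 strong
evidence). Fitted coefficients convert to **peak biases** in degrees
(`b·w·e^−1/2`, attained at Δ = w); positive = attraction.

Around that core the package provides the exclusion rules of the paradigm
(RT window, two-step ±45°/1.5·IQR error outliers, 10 s adjustment timeout;
participant screens including a Fisher–Lee circular correlation), a
similarity-split z-test contrasting kernel coefficients between
distractor-similar and -dissimilar trials, an inverse-Gaussian
identity-link mixed model of discrimination RT (participant random
intercepts, fit by adaptive Gauss–Hermite quadrature on an exact
sufficient-statistic reduction), and a fully parameterized synthetic
observer so that every stage can be validated by parameter recovery.

## Worked example

```r
library(serialdep)

cfg <- pipeline_config(seed = 1,
                       design = design_params(n_participants = 6),
                       observers = sample_cohort(6, observer_params(), seed = 2))
print(run_pipeline(cfg))
```

```
Pipeline run (seed 1): 12000 trials, 11762 retained, 6 participants

-- previous-probe effect --
Model comparison (delta BIC: worst model = 0, larger = better)
  model widths r_squared n_params   bic delta_bic evidence_vs_worst
     d0         0.000000        1 53555     0.000              weak
     d1     22  0.002032        2 53540    14.526            strong
     d2  35/80  0.003263        3 53535    19.656            strong
 d1xloc     22  0.002035        3 53549     5.187          positive
 d2xloc  35/80  0.003271        5 53554     1.016              weak
best model: d2 
  term width  peak location
1 dog1    35  1.44       35
2 dog2    80 -1.07       80

-- distractor effect --
  ...
best model: d0 

-- RT analysis --
Inverse-Gaussian RT mixed model (agq_inverse_gaussian), n = 11419
         term estimate     se      t    df          p    lower   upper
1 (Intercept)  488.513 17.993 27.150 11415 2.378e-157 453.2464 523.780
2    location    2.954  1.782  1.658 11415  9.742e-02  -0.5388   6.447
3  distractor   16.985  1.816  9.351 11415  1.025e-20  13.4251  20.545
4 interaction   -7.987  2.569 -3.109 11415  1.879e-03 -13.0215  -2.952
  random-intercept SD: 43.96 ms, IG shape lambda: 24893
```

Reading the output: the simulated observers attract toward the previous
probe (generative peak +1.42°) with a repulsive tail (−0.53°), and the
two-component model `d2` wins the BIC comparison with an attractive peak
of +1.44°; they carry no distractor kernel, and the distractor comparison
correctly selects the null model. The RT fixed effects recover the
generative pattern (slower with a distractor, smaller capture in fixed
blocks). At this small cohort size the fitted tail width (80°) illustrates
a documented caveat: kernel *widths* are weakly identified and conclusions
should rest on peak biases and model selection — see the methods vignette
(`vignettes/serial-dependence-pipeline.Rmd`).

The numbered scripts under `analysis/` run the same chain as a narrative:
`01_simulate.R` (two experiment-like cohorts), `02_preprocess.R`
(exclusions), `03_serial_dependence.R` (model family, both predictors),
`04_interference.R` (similarity split), `05_rt_analysis.R` (capture and
the RT mixed model), writing summary tables under `results/` and bulky
trial tables under `scratch/`.

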