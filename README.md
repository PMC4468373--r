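# promcap

Information transmission through gene promoter channels.

Cells encode the identity and intensity of a stimulus in the nuclear
dynamics of transcription factors — a sustained pulse of graded
**amplitude** (AM) or trains of short pulses of graded **frequency**
(FM) — and target promoters must decode those dynamics into expression
levels in the presence of biochemical noise. `promcap` treats the
promoter as a noisy communication channel and quantifies, in bits, how
much stimulus information single-cell gene-expression outputs can
carry. It is aimed at quantitative/systems biologists analysing
single-cell reporter time-lapse data (and at anyone who wants a
well-tested discrete channel-capacity estimator with undersampling
correction).

## The estimator

For a signal $S$ (stimulus condition) and a discretized response $R$
(single-cell expression level),

$$MI(R;S)=\sum_{i,j} p(R_i,S_j)\,\log_2\!\frac{p(R_i,S_j)}{p(R_i)\,p(S_j)},
\qquad
I(R;S)=\max_{p(S)} MI(R;S),\ \ \sum_j p(S_j)=1,\ p(S_j)\ge 0 .$$

The capacity $I$ is computed by the iterative **Blahut–Arimoto**
algorithm, the positive small-sample bias of the plug-in histogram
estimator is removed by **jackknife subsampling** (capacities at
sampling fractions 1, 1/2, 1/4, extrapolated linearly in inverse
sample size), and the result is reported as mean ± SD over a sweep of
bin counts (15–35 for one reporter, 8–20 per reporter for the joint
two-reporter capacity via the chain rule
$MI(R_1,R_2;S)=MI(R_1;S)+MI(R_2;S\,|\,R_1)$).

On top of this the package implements:

* **trace processing** — 11-point moving-average smoothing of 64-frame
  fluorescence traces and reduction to the plateau maximum (frames
  33–64);
* **dual-reporter noise decomposition** — intrinsic/extrinsic variance
  split from paired CFP/YFP expression via their covariance;
* **intrinsic capacity** — the gamma-deflation algorithm: fit each
  condition's response to $\Gamma(a,b)$, remove the extrinsic
  (covariance) component from the variance at fixed mean, and
  re-estimate capacity on the inferred extrinsic-noise-free channel;
* **stochastic simulation** — an exact Gillespie simulator for a
  library of ten linear/nonlinear gene-expression models with
  per-cell extrinsic parameter variation and dual reporters, plus the
  in-silico validation grid for the intrinsic algorithm.

## Worked example

Simulate a dual-reporter AM dose-response (8 amplitudes, 500 cells
each, extrinsic CV 0.3) from a Hill-coupled telegraph promoter model,
then estimate the raw and the intrinsic (extrinsic-noise-corrected)
capacity:

```r
library(promcap)

model <- sim_model("hill2_telegraph", "fast")
data  <- generate_dual_reporter_dataset(model, am_schedule(8),
                                        n_cells = 500, extrinsic_cv = 0.3,
                                        seed = 7)

capacity_sweep(data, reporter = "yfp", seed = 8)
#> <capacity_estimate> I = 1.224 +/- 0.039 bits (21 bin counts, yfp)

intr <- intrinsic_capacity_sweep(data, seed = 9)
intr
#> <intrinsic_estimate> I_int = 1.639 +/- 0.013 bits (sampled mode)
#>   raw:       I     = 1.225 +/- 0.038 bits
```

Read: through this promoter the eight TF amplitudes transmit 1.22 bits
— enough to distinguish ON from OFF reliably, far short of the 3 bits
eight fully resolvable inputs would need. Filtering out the extrinsic
(cell-state) noise via the CFP/YFP covariance raises the promoter's
own limit to 1.64 bits: a substantial part of the loss is extrinsic,
but even the intrinsic channel cannot resolve all eight amplitudes.
`tidy()`, `glance()` and `autoplot()` work on every estimate;
`noise_components(data)` gives the per-condition intrinsic/extrinsic
noise split, and `run_validation_grid()` reproduces the accuracy study
of the intrinsic algorithm against simulated ground truth.

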