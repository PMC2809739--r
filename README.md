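# adipowaves

Bayesian detection of temporal periodicity in longitudinal adipose
cell-size distributions.

## What problem this solves

Growing adipose tissue alternates between hypertrophy (existing adipocytes
fill with lipid and enlarge) and hyperplasia (new small adipocytes are
recruited). Longitudinal micro-biopsies of one animal's fat depot yield, on
each of a handful of irregular days, replicate cell-size histograms —
~6,000 cells counted into 80 logarithmic diameter bins over 20–240 µm,
with a characteristic bimodal shape. Does the shape of that distribution
vary *periodically* over the months-long time course?

With sparse, irregular sampling (days 0, 2, 6, 9, 13, 23, 33, 57, 69, 86,
98, 134, 141, 150, 156, 162) and no plausible parametric waveform,
spectral methods do not apply. This package implements discrete Bayesian
model comparison instead. A candidate model splits a period of
`T = N_b · d` days into `N_b` period-bins of `d` days with an integer
phase `φ`; each biopsy day gets the bin index

    floor((day + φ) / d) mod N_b

and the model asserts that the cell-size distribution is exchangeable
within a period-bin across repetitions of the period. For each cell-size
bin `i` and period-bin `b`, observed percentages are lognormal with their
own `(μ_ib, σ_ib)`; the model score is the marginal likelihood with
`(μ, σ)` integrated against proper uninformative priors (uniform `μ`,
log-uniform `σ`), summed over period-bins and over all cell-size bins but
one (the percentage normalisation removes one degree of freedom):

    log Z(model) = Σ_{i≠i0} Σ_b log ∫∫ Π_y LN(y | μ, σ) p(μ) p(σ) dμ dσ.

Candidate models are enumerated (`N_b` ∈ 2–10, `d` ∈ 5–50 d, all phases),
deduplicated when indistinguishable on the sampled days, and pruned: every
period-bin must receive non-contiguous biopsy days (otherwise apparent
constancy could be mere continuity) and the period must lie in 30–100 d.
Evidences are computed by parallel-tempered Monte Carlo with thermodynamic
integration (validated against a deterministic 2-D quadrature oracle), and
the evidence is marginalised over models into a posterior on 5-day period
intervals. A synthetic-data generator reproduces the statistical structure
of the biopsy data (bimodal lognormal mixture, periodic modulation,
multinomial counting plus multiplicative replicate noise) for testing and
calibration, and a small ODE model of PPAR-driven adipocyte recruitment
shows how a flux/capacity switch yields relaxation oscillations whose
period falls with increasing lipid flux.

Intended users: quantitative physiologists and biostatisticians analysing
longitudinal histogram-valued data with suspected periodicity, and anyone
who needs a worked, tested implementation of evidence-based discrete
period detection on irregular schedules.

## Worked example

Simulate a study — 16-day irregular schedule, 4 replicates/day, 6,000
particles per measurement, bimodal diameters whose small-cell weight
alternates with a 56-day period — then fit the full model comparison:

```r
library(adipowaves)

cfg <- generator_config(grid = log_diameter_grid(20), seed = 7)
sim <- sample_dataset(cfg)
sim$dataset
#> <cellsize_dataset> 'synthetic': 64 measurements on 16 days (day 0-162), 20 diameter bins

fit <- fit_periodicity(sim$dataset, pt = pt_config(preset = "reduced", seed = 7))
fit
#> Periodicity analysis of longitudinal cell-size distributions
#>   dataset 'synthetic': 16 biopsy days; 529 periodic models scored (engine pt)
#>   best model: 7 period-bins x 8 d, phase 7 -> period 56.0 d
#>   gap to next-best model: 255.17 nats; gap to no-period model: 1347.46 nats
#>   modal period interval: [55, 60) d with probability 1.000

head(fit$ranking$entries, 3)
#>  rank n_bins bin_width phase period ambiguity total_logZ
#>     1      7         8     7     56         0  -1317.918
#>     2      2      5        11     3     55         0  -1573.087
#>     3      3      4         9     1     36         0  -1584.284
```

Reading the output: 529 testable periodic models survive pruning on this
schedule; the winner groups the days into 7 period-bins of 8 days
(period 56 d, phase 7), recovering the generating period exactly. The gap
of 255 nats to the next-best model and 1347 nats to the no-period model
means the data overwhelmingly prefer this periodic grouping; the posterior
over 5-day period intervals puts essentially all mass on [55, 60). The
fitted object also carries `fit$profiles`, the mean cell-size distribution
in each period-bin of the best model — the inferred progression of the
distribution through one period.

`simulate_adipo(adipo_params())` runs the recruitment oscillator;
`period_vs_flux()` sweeps the lipid flux and shows the period shortening
as flux rises.

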