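# lassensim

Monte Carlo study of **Lassen's linearization correction** for Tc-99m
HMPAO brain-perfusion SPECT, aimed at methodologists who validate
correction parameters against correlation statistics.

HMPAO counts underestimate regional cerebral blood flow (rCBF) at high
flow: back-diffusion of the trapped tracer saturates the count-versus-flow
relationship and flattens image contrast. With all quantities expressed as
ratios to a reference region, the expected count ratio follows

    C/Cr = (F/Fr)(1 + alpha_t) / (F/Fr + alpha_t),

and Lassen's correction inverts it at a chosen parameter `alpha`:

    A/Ar = alpha (C/Cr) / (1 + alpha - C/Cr).

The simulated measurement adds square-root count-statistics noise,

    C/Cr = E + NL * sqrt(E) * N(0,1),   E = expected count ratio,

with noise level `NL` in {0, 0.0125, 0.025, 0.05} and generative
`alpha_t = 0.5`. The package sweeps the correction `alpha` over a grid for
each noise level, regresses corrected accumulation on true flow, and shows
*why the Pearson correlation coefficient barely depends on alpha under
realistic noise* — strong correction (small `alpha`) amplifies noise
exactly where it would otherwise reveal the truth — while the slope, and
noiseless data, recover `alpha_t = 0.5` cleanly.

## Worked example

```r
library(lassensim)

d <- simulate_dataset(nl = 0.05, seed = 42)   # 1000 paired (F/Fr, C/Cr)
head(d, 3)
#>   flow_ratio expected_count_ratio count_ratio
#> 1  1.2467725            1.0706367   1.1909254
#> 2  0.8983543            0.9636553   0.9893807
#> 3  1.0653631            1.0208779   1.0699187

cfg <- sweep_config(alpha_grid = c(0.5, 1, 1.5, 2), nl_list = c(0, 0.05),
                    replicates = 20, seed = 42)
smry <- summarize_sweep(run_sweep(cfg))
print(smry, digits = 4)
#>   alpha   nl mean_r      sd_r mean_slope  sd_slope mean_flagged n_replicates
#> 1   0.5 0.00 1.0000 7.204e-17     1.0000 7.204e-17            0           20
#> 2   1.0 0.00 0.9963 3.653e-04     0.6737 4.023e-03            0           20
#> 3   1.5 0.00 0.9932 7.017e-04     0.5663 4.654e-03            0           20
#> 4   2.0 0.00 0.9913 9.316e-04     0.5124 4.826e-03            0           20
#> 5   0.5 0.05 0.7451 1.320e-02     1.0362 3.765e-02            0           20
#> 6   1.0 0.05 0.7649 1.238e-02     0.6765 1.940e-02            0           20
#> 7   1.5 0.05 0.7687 1.205e-02     0.5651 1.520e-02            0           20
#> 8   2.0 0.05 0.7702 1.189e-02     0.5101 1.334e-02            0           20

peak_alpha(smry)
#>        nl peak_alpha peak_mean_r
#> 0    0.00        0.5   1.0000000
#> 0.05 0.05        2.0   0.7701826
```

Reading the table: with no noise (`nl = 0`), correcting at the true
`alpha = 0.5` regains linearity completely (`mean_r = 1`, `mean_slope = 1`
to machine precision) and any larger `alpha` under-corrects (slope falls
toward 0.5). At medium noise (`nl = 0.05`) the ordering *inverts*: mean r
is lowest at the true `alpha = 0.5` (0.745) and creeps upward with weaker
correction (0.770 at `alpha = 2`), because strong correction magnifies
noise at high flow. `peak_alpha()` makes the contrast explicit: the
correlation picks 0.5 only in the noiseless world. The slope column, by
contrast, barely moves between noise levels (1.0000 vs 1.0362 at
`alpha = 0.5` — a slight upward noise bias), which is why the slope, not
the correlation coefficient, carries the information about `alpha`.

`plot_dataset(d, alpha = 0.5)` and `plot_sweep(smry, "r")` render the
corresponding scatter and curve figures (qualitative).

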