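# cattleRSPF

Count-based resource selection probability functions (RSPF) for
GPS-collared cattle on a fenced silvopastoral paddock.

Free-roaming cattle distribute themselves unevenly over heterogeneous
wooded pastures, and managers need to know which habitat features drive
that distribution. Given GPS collar fixes and a handful of GIS layers
(DEM, cover map, fence, water point), this package estimates the herd's
utilization distribution over circular sampling plots with a
negative-binomial count regression,

```
ln E[l_i] = ln(total) + b0 + b1*X1 + ... + bp*Xp,
```

where `l_i` is the number of fixes in plot *i* and the `ln(total)` offset
converts counts to relative frequencies, so the fitted surface is a true
probability of use. Around that core the package implements the full
workflow: fix cleaning (fence/speed/course/edge-day rules), fix-rate
accounting, a pairwise spatiotemporal association screen, a 75/25
development/validation split, terrain predictors (Horn slope, aspect
quadrants, TRI, TPI), cover areas and distance predictors per 50-m plot,
collinearity screening (|r| > 0.60), enumeration of the a-priori candidate
set (up to 5 predictors, paired quadratic terms, collinear swaps), AIC
ranking, percentile bootstrap confidence intervals, 20-class binned
Spearman validation, quartile probability-of-use classes with estimated
marginal means, marginal-effect curves and a 25-m prediction raster.

Because the original telemetry is not public, the package ships a
synthetic module that generates landscapes with the study's statistical
structure (54.3-ha fenced paddock, published cover shares, 660–731 m
elevation, one low-lying water point) and simulates collar tracks from a
*known* selection truth, complete with 3-minute schedules, log-normal
EHPE, missed fixes and out-of-fence artifacts. Every stage is therefore
testable against ground truth or a brute-force oracle.

## Worked example

```r
library(cattleRSPF)

land  <- generate_landscape(54.3, seed = 42)          # 54.3-ha paddock
plots <- sample_plots(land$fence, 194, seed = 43)     # 50-m-diameter plots
tab   <- extract_predictors(plots, land)

truth <- c(elevation = -0.03, distfeed = -0.0015, distfence = 0.006)
tab$dev_count <- simulate_plot_counts(tab, truth, 10000, seed = 1)
tab$val_count <- simulate_plot_counts(tab, truth,  3000, seed = 2)

fit <- fit_nb_rspf(names(truth), tab)
fit
#> Negative-binomial RSPF fit: distfeed+distfence+elevation
#>   n = 194 plots, total = 10000, theta = 3.64e+03, AIC = 1273.6
#>              estimate       se         p
#> (Intercept) 15.360000 7.94e-01  2.45e-83
#> elevation   -0.030270 1.16e-03 7.05e-151
#> distfeed    -0.001545 5.56e-05 2.55e-170
#> distfence    0.005814 1.19e-04  0.00e+00

spearman_validation(predict_use(fit, tab), tab$val_count)$rs
#> [1] 0.9887136
```

The fitted coefficients sit on top of the simulated truth (elevation
−0.03, distfeed −0.0015, distfence +0.006), and the hold-out binned
Spearman score of 0.99 says the 20 ranked probability classes order the
validation counts almost perfectly.

The `analysis/` directory holds the numbered end-to-end drivers
(landscape → tracks → cleaning → fit → validation → seasonal refits →
simulation studies); each writes its tables under `results/`.

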