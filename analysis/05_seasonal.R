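#!/usr/bin/env Rscript
# Stage 5: refit the final model per season (summer drops the quadratic
# distance-to-feed term) and compare coefficients and validation scores.

library(cattleRSPF)

seed <- 42L
land <- generate_landscape(54.3, seed = seed)
terrain <- compute_terrain(land$dem, land$cell_size)
plots <- sample_plots(land$fence, 194, seed = seed + 1L)
table <- extract_predictors(plots, land, terrain)

fixes <- read_fixes_csv("results/fixes_clean.csv")
periods <- reference_table("periods")
season_of <- function(ts) {
  s <- rep(NA_character_, length(ts))
  for (i in seq_len(nrow(periods))) {
    inside <- ts >= as.POSIXct(periods$start[i], tz = "UTC") &
      ts <= as.POSIXct(periods$end[i], tz = "UTC") + 2 * 86400
    s[inside] <- periods$season[i]
  }
  s
}
fixes$season <- season_of(fixes$timestamp)

sr <- seasonal_refit(fixes, plots, table, seed = seed + 4L)
write.csv(sr$comparison, "results/seasonal_rs.csv", row.names = FALSE)
write.csv(sr$coefficients, "results/seasonal_coefficients.csv",
          row.names = FALSE)
print(sr$comparison)
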