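# Shared synthetic fixtures, built once per test run.

# study-scale landscape (54.3 ha, published cover shares)
land_std <- generate_landscape(54.3, seed = 42)
terr_std <- compute_terrain(land_std$dem, land_std$cell_size)
plots_std <- sample_plots(land_std$fence, 194, seed = 5)
table_std <- extract_predictors(plots_std, land_std, terr_std)

# hand-built miniature landscape with fully known structure: 5x5 grid,
# square fence covering all cells, water at the centre cell
make_toy_landscape <- function(dem = matrix(seq(660, 684, length.out = 25),
                                            5, 5),
                               cover_code = matrix(1L, 5, 5),
                               cell_size = 10) {
  n <- nrow(dem)
  ext <- n * cell_size
  fence <- rbind(c(0, 0), c(ext, 0), c(ext, ext), c(0, ext), c(0, 0))
  land <- list(dem = dem, cover = cover_code,
               in_fence = matrix(TRUE, n, n), fence = fence,
               water_point = c(x = ext / 2, y = ext / 2),
               cell_size = cell_size, xmin = 0, ymin = 0,
               crs_note = "toy", seed = NULL)
  class(land) <- "rspf_landscape"
  land
}

# simple fix frame builder
make_fixes <- function(x, y, t0 = as.POSIXct("2019-03-02 00:00:00", tz = "UTC"),
                       interval = 180, animal = "cow01", ehpe = 900) {
  data.frame(animal_id = animal,
             timestamp = t0 + interval * seq_along(x),
             x = x, y = y, ehpe_cm = ehpe)
}
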