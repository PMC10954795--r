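# Plot sampling, predictor extraction, fix counting and the collinearity
# screen, each against brute-force oracles.

test_that("sampled plots respect the fence-distance rule (brute-force check)", {
  d <- vapply(seq_len(nrow(plots_std)), function(i)
    brute_boundary_dist(plots_std$x[i], plots_std$y[i], land_std$fence),
    numeric(1))
  expect_identical(nrow(plots_std), 194L)
  expect_true(all(d >= 13))
  expect_true(all(point_in_polygon(cbind(plots_std$x, plots_std$y),
                                   land_std$fence)))
  # fast distance agrees with the brute-force oracle
  expect_equal(dist_to_boundary(cbind(plots_std$x, plots_std$y),
                                land_std$fence), d, tolerance = 1e-9)
})

test_that("the fence-distance rule is strict: 13.0 m retained, 12 m rejected", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(0, 0))
  expect_true(dist_to_boundary(c(13, 50), sq) >= 13)   # exactly 13 -> keep
  expect_false(dist_to_boundary(c(12, 50), sq) >= 13)  # 12 m -> reject
  # infeasible request exhausts the attempt budget
  expect_error(sample_plots(sq, 50, min_fence_dist = 13, min_spacing = 50,
                            seed = 1, max_attempts = 5000),
               "attempt budget")
})

test_that("plot spacing constraint is enforced when requested", {
  pl <- sample_plots(land_std$fence, 40, min_spacing = 60, seed = 8)
  dm <- as.matrix(dist(pl[, c("x", "y")]))
  expect_true(all(dm[upper.tri(dm)] >= 60))
})

test_that("fix counting matches a brute-force scan and uses a closed 25-m disk", {
  set.seed(4)
  n <- 3000
  fx <- data.frame(x = runif(n, 0, 900), y = runif(n, 0, 700))
  counts <- count_fixes_in_plots(fx, plots_std)
  brute <- vapply(seq_len(nrow(plots_std)), function(j)
    sum(sqrt((fx$x - plots_std$x[j])^2 + (fx$y - plots_std$y[j])^2) <= 25),
    numeric(1))
  expect_identical(counts, as.integer(brute))

  one <- data.frame(plot_id = 1L, x = 100, y = 100, radius = 25)
  expect_identical(count_fixes_in_plots(data.frame(x = 100, y = 100), one), 1L)
  expect_identical(count_fixes_in_plots(data.frame(x = 125.01, y = 100), one), 0L)
  expect_identical(count_fixes_in_plots(data.frame(x = 125, y = 100), one), 1L)
})

test_that("predictor extraction: cover areas, distances and conservation", {
  toy <- make_toy_landscape(dem = matrix(700, 5, 5),
                            cover_code = matrix(2L, 5, 5))
  # plot centred mid-grid, wholly in one cover class
  pl <- data.frame(plot_id = 1L, x = 25, y = 25, radius = 20)
  tab <- extract_predictors(pl, toy)
  # disk of radius 20 at (25,25) captures 12 of the 25 cell centres
  in_disk <- sum((grid_cells(toy)$x - 25)^2 + (grid_cells(toy)$y - 25)^2 <= 400)
  expect_equal(tab$shrub, in_disk * 100)
  expect_equal(tab$wood + tab$grasslands + tab$rock + tab$feedwater, 0)
  # conservation: class areas sum exactly to disk cell area
  expect_equal(tab$wood + tab$shrub + tab$grasslands + tab$rock +
                 tab$feedwater, in_disk * 100)
  # centroid at the water point
  expect_equal(tab$distfeed, 0)
  expect_error(extract_predictors(data.frame(plot_id = 1, x = 20, y = 20,
                                             radius = 2), toy),
               "no cell centres")

  # distances on a 3-plot layout against the segment-wise oracle
  pl3 <- data.frame(plot_id = 1:3, x = c(60, 300, 500), y = c(60, 200, 350),
                    radius = 25)
  t3 <- extract_predictors(pl3, land_std, terr_std)
  d_oracle <- vapply(1:3, function(i)
    brute_boundary_dist(pl3$x[i], pl3$y[i], land_std$fence), numeric(1))
  expect_equal(t3$distfence, d_oracle, tolerance = 1e-9)
  expect_equal(t3$distfeed,
               sqrt((pl3$x - land_std$water_point["x"])^2 +
                    (pl3$y - land_std$water_point["y"])^2),
               ignore_attr = TRUE)
})

test_that("cover-area conservation holds over the full synthetic plot frame", {
  cell_area <- land_std$cell_size^2
  cells <- grid_cells(land_std)
  for (i in sample.int(nrow(plots_std), 10)) {
    in_disk <- (cells$x - plots_std$x[i])^2 + (cells$y - plots_std$y[i])^2 <=
      plots_std$radius[i]^2
    covered <- sum(!is.na(land_std$cover[cells$cell[in_disk]])) * cell_area
    total <- table_std$wood[i] + table_std$shrub[i] +
      table_std$grasslands[i] + table_std$rock[i] + table_std$feedwater[i]
    expect_equal(total, covered)
  }
})

test_that("collinearity screen flags strictly above the threshold", {
  set.seed(6)
  tab <- data.frame(a = rnorm(194))
  tab$b <- 2 * tab$a
  tab$c <- rnorm(194)
  sc <- screen_collinearity(tab, c("a", "b", "c"))
  expect_identical(nrow(sc$flagged), 1L)
  expect_setequal(c(sc$flagged$var_a, sc$flagged$var_b), c("a", "b"))
  expect_equal(sc$flagged$r, 1)

  # strictness: a threshold equal to the observed |r| must not flag
  r_ac <- abs(cor(tab$a, tab$c))
  sc2 <- screen_collinearity(tab, c("a", "c"), threshold = r_ac)
  expect_identical(nrow(sc2$flagged), 0L)

  # independent predictors at n = 194: no flags at 0.60
  tab2 <- as.data.frame(matrix(rnorm(194 * 6), 194, 6))
  sc3 <- screen_collinearity(tab2, names(tab2))
  expect_identical(nrow(sc3$flagged), 0L)

  # zero-variance predictor reported as degenerate
  tab$z <- 1
  sc4 <- screen_collinearity(tab, c("a", "z"))
  expect_identical(sc4$degenerate, "z")
})
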