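# Binned Spearman validation, quartile classification, class marginal means,
# marginal effects and the prediction raster.

test_that("binned Spearman statistic matches the rank-correlation oracle and its extremes", {
  set.seed(30)
  pred <- runif(194)
  # monotone counts in predicted order -> rs = 1
  counts <- integer(194)
  counts[order(pred)] <- seq_len(194)
  v <- spearman_validation(pred, counts)
  expect_equal(v$rs, 1)
  expect_identical(sum(v$class_table$n_plots), 194L)
  expect_true(all(v$class_table$n_plots %in% c(9L, 10L)))
  expect_equal(v$class_table$val_mean,
               v$class_table$val_sum / v$class_table$n_plots)

  # reversed -> rs = -1
  v2 <- spearman_validation(pred, max(counts) - counts)
  expect_equal(v2$rs, -1)

  # arbitrary counts: equals the oracle on the 20 (rank, count) pairs
  set.seed(31)
  cnt <- rpois(194, 5)
  v3 <- spearman_validation(pred, cnt)
  expect_equal(v3$rs, rank_cor_oracle(seq_len(20), v3$class_table$val_mean))

  # all-zero validation counts: undefined, reported as such
  v4 <- spearman_validation(pred, integer(194))
  expect_true(is.na(v4$rs))
  expect_match(v4$note, "undefined")
  expect_error(spearman_validation(runif(10), 1:10), "n >= n_classes")
})

test_that("null calibration: uniform validation counts give rs near zero on average", {
  set.seed(32)
  pred <- predict_use(
    fit_nb_rspf("elevation",
                transform(table_std,
                          dev_count = simulate_plot_counts(
                            table_std, c(elevation = -0.03), 8000, seed = 33))),
    table_std)
  rs <- replicate(50, {
    vc <- as.integer(rmultinom(1, 2000, rep(1 / 194, 194)))
    spearman_validation(pred, vc)$rs
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("quartile classes partition plots with near-equal sizes, invariant to monotone transforms", {
  set.seed(34)
  p8 <- runif(8)
  c8 <- classify_quartiles(p8)
  expect_identical(as.integer(table(c8$class)), rep(2L, 4))

  p194 <- runif(194)
  c194 <- classify_quartiles(p194)
  sizes <- as.integer(table(c194$class))
  expect_true(all(sizes %in% c(48L, 49L)))
  expect_identical(sum(sizes), 194L)
  # exact partition: every plot assigned exactly once
  expect_identical(sort(c194$plot_id), seq_len(194))

  # invariance under strictly monotone transforms
  expect_identical(classify_quartiles(exp(p194))$class, c194$class)
  expect_identical(classify_quartiles(rank(p194))$class, c194$class)
  # class order consistent with probability order
  expect_true(all(diff(as.integer(c194$class[order(p194)])) >= 0))

  expect_warning(classify_quartiles(rep(0.5, 8)), "identical")
})

test_that("class marginal means match closed-form pooled-variance SEs and letter logic", {
  # balanced classes with known means
  set.seed(35)
  n_per <- 30
  cls <- data.frame(plot_id = seq_len(4 * n_per),
                    predicted = seq_len(4 * n_per),
                    class = factor(rep(c("low", "moderate", "high",
                                         "very_high"), each = n_per),
                                   levels = c("low", "moderate", "high",
                                              "very_high"), ordered = TRUE))
  tab <- data.frame(plot_id = cls$plot_id,
                    distfeed = rnorm(4 * n_per, rep(c(100, 300, 310, 900),
                                                    each = n_per), 40),
                    distfence = rnorm(4 * n_per, 100, 20),
                    elevation = rnorm(4 * n_per, 695, 10))
  em <- class_emmeans(cls, tab)
  df <- em[em$predictor == "distfeed", ]
  # emmean is the class mean; SE = sqrt(MSE / n_k), MSE pooled
  mns <- tapply(tab$distfeed, cls$class, mean)
  expect_equal(df$emmean, as.numeric(mns), tolerance = 1e-10)
  fitlm <- lm(distfeed ~ class,
              data = transform(merge(cls, tab, by = "plot_id"),
                               class = factor(as.character(class))))
  mse <- sum(residuals(fitlm)^2) / fitlm$df.residual
  expect_equal(df$se, rep(sqrt(mse / n_per), 4), tolerance = 1e-10)
  # far-apart classes get different letters; the close pair shares one
  expect_false(df$letter[df$class == "low"] ==
                 df$letter[df$class == "very_high"])
  expect_true(any(duplicated(df$letter[df$class %in% c("moderate", "high")])) ||
                df$letter[df$class == "moderate"] ==
                df$letter[df$class == "high"])

  # identical values across classes: everyone shares a letter
  tab2 <- tab; tab2$distfence <- 42
  em2 <- suppressWarnings(class_emmeans(cls, tab2, predictors = "distfence"))
  expect_identical(unique(em2$letter), "a")
})

test_that("marginal-effect curves agree with predict_use and report the turning point", {
  tab <- table_std
  beta <- c(distfeed = 0.004, distfeed2 = -0.000004)
  tab$dev_count <- simulate_plot_counts(tab, beta, 20000, seed = 36)
  fit <- fit_nb_rspf(names(beta), tab)
  me <- marginal_effects(fit, "distfeed", tab)
  expect_equal(attr(me, "turning_point"),
               unname(-fit$beta["distfeed"] / (2 * fit$beta["distfeed2"])),
               tolerance = 1e-12)
  # concave with an interior maximum
  expect_lt(fit$beta["distfeed2"], 0)
  imax <- which.max(me$prediction)
  expect_gt(imax, 1); expect_lt(imax, nrow(me))

  # curve values equal direct predict_use on the grid table
  nd <- tab[rep(1, nrow(me)), ]
  for (b in c("distfeed")) nd[[b]] <- me$value
  for (b in setdiff(c("elevation", "slope", "TRI", "TPI", "wood", "shrub",
                      "grasslands", "feedwater", "rock", "distfence"),
                    "distfeed")) nd[[b]] <- mean(tab[[b]])
  expect_equal(me$prediction, predict_use(fit, nd), tolerance = 1e-12)

  # linear-only spec: monotone curve, no turning point
  tabL <- table_std
  tabL$dev_count <- simulate_plot_counts(tabL, c(distfeed = -0.002), 8000,
                                         seed = 37)
  fitL <- fit_nb_rspf("distfeed", tabL)
  meL <- marginal_effects(fitL, "distfeed", tabL)
  expect_null(attr(meL, "turning_point"))
  expect_true(all(diff(meL$prediction) < 0) || all(diff(meL$prediction) > 0))

  expect_warning(marginal_effects(fitL, "distfeed", tabL,
                                  grid = c(-10, 100, 5000)),
                 "outside the observed range")
  expect_error(marginal_effects(fitL, "elevation", tabL), "not a predictor")
})

test_that("prediction raster: constant on a uniform landscape, normalized, hotspot located", {
  flat <- make_toy_landscape(dem = matrix(700, 8, 8),
                             cover_code = matrix(1L, 8, 8),
                             cell_size = 10)
  tabF <- data.frame(plot_id = 1:30, elevation = rnorm(30, 700, 5),
                     dev_count = rpois(30, 10))
  fitF <- fit_nb_rspf("elevation", tabF)
  mapF <- suppressWarnings(render_use_map(fitF, flat, resolution = 20,
                                          plot_radius = 15))
  vals <- mapF$prob[!is.na(mapF$prob)]
  expect_equal(sum(vals), 1, tolerance = 1e-6)
  expect_lt(diff(range(vals)), 1e-12)

  # single hotspot: a Gaussian elevation bump at a known location puts the
  # raster argmax at the bump, next to the most-preferred plot
  ncell <- 40; cs <- 10
  xy <- expand.grid(col = seq_len(ncell), row = seq_len(ncell))
  bump_x <- 120; bump_y <- 290
  cxv <- (xy$col - 0.5) * cs; cyv <- (ncell - xy$row + 0.5) * cs
  dem <- matrix(0, ncell, ncell)
  dem[cbind(xy$row, xy$col)] <-
    700 + 25 * exp(-((cxv - bump_x)^2 + (cyv - bump_y)^2) / (2 * 60^2))
  hill <- make_toy_landscape(dem = dem, cover_code = matrix(1L, ncell, ncell),
                             cell_size = cs)
  pl <- sample_plots(hill$fence, 80, seed = 44)
  tab <- extract_predictors(pl, hill)
  tab$dev_count <- simulate_plot_counts(tab, c(elevation = 0.4), 20000,
                                        seed = 38)
  fit <- fit_nb_rspf("elevation", tab)
  map <- render_use_map(fit, hill, resolution = 25)
  idx <- which(map$prob == max(map$prob, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ny <- nrow(map$prob)
  cx <- map$xmin + (idx["col"] - 0.5) * map$cell_size
  cy <- map$ymin + (ny - idx["row"] + 0.5) * map$cell_size
  expect_lt(sqrt((cx - bump_x)^2 + (cy - bump_y)^2), 60)
  best_plot <- tab[which.max(predict_use(fit, tab)), ]
  expect_lt(sqrt((best_plot$x - bump_x)^2 + (best_plot$y - bump_y)^2), 120)

  expect_error(render_use_map(fitF, flat, resolution = 500),
               "coarser")
})
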