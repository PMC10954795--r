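# Candidate enumeration, NB fitting with offset, AIC ranking, bootstrap and
# the odds-ratio transform.

test_that("candidate enumeration matches exhaustive counting oracles", {
  # 12 predictors, base terms only, up to 5: sum of C(12, k)
  base_only <- enumerate_candidates(paste0("p", 1:12),
                                    quadratic_eligible = character(0))
  expect_identical(length(base_only), as.integer(sum(choose(12, 1:5))))

  # one quadratic-eligible predictor: {x} and {x, x2}
  one <- enumerate_candidates("elevation")
  expect_identical(length(one), 2L)
  expect_setequal(names(one), c("elevation", "elevation+elevation2"))

  # every quadratic term is accompanied by its linear form
  some <- enumerate_candidates(c("elevation", "distfeed", "wood"),
                               max_base = 3)
  for (tm in some) {
    quads <- grep("2$", tm, value = TRUE)
    expect_true(all(sub("2$", "", quads) %in% tm))
  }

  # collinear pair: no spec retains both; swap variants are present
  pairs <- data.frame(var_a = "elevation", var_b = "wood")
  swapped <- enumerate_candidates(c("elevation", "wood", "distfeed"),
                                  collinear_pairs = pairs, max_base = 3)
  expect_false(any(vapply(swapped, function(tm)
    all(c("elevation", "wood") %in% tm), logical(1))))
  expect_true(all(c("distfeed+elevation", "distfeed+wood") %in%
                    names(swapped)))
})

test_that("intercept-only fit recovers log(mean/total) and the offset only shifts the intercept", {
  tab <- table_std
  tab$dev_count <- simulate_plot_counts(tab, c(elevation = -0.02), 8000,
                                        seed = 14)
  f0 <- fit_nb_rspf(character(0), tab)
  expect_true(f0$converged)
  expect_equal(unname(f0$beta["(Intercept)"]),
               log(mean(tab$dev_count) / sum(tab$dev_count)),
               tolerance = 1e-6)

  terms <- c("elevation", "distfeed")
  f1 <- fit_nb_rspf(terms, tab)
  f2 <- fit_nb_rspf(terms, tab, total = 2 * sum(tab$dev_count))
  expect_equal(unname(f2$beta["(Intercept)"] - f1$beta["(Intercept)"]),
               -log(2), tolerance = 1e-6)
  expect_equal(f2$beta[terms], f1$beta[terms], tolerance = 1e-6)
})

test_that("near-Poisson data reproduces a Poisson-GLM oracle within 3 SE", {
  tab <- table_std
  beta <- c(elevation = -0.025, distfence = 0.004)
  tab$dev_count <- simulate_plot_counts(tab, beta, 20000, seed = 15)
  fit <- fit_nb_rspf(names(beta), tab)
  off <- rep(log(sum(tab$dev_count)), nrow(tab))
  oracle <- glm(dev_count ~ elevation + distfence + offset(off),
                family = poisson, data = tab)
  oc <- coef(oracle); ose <- sqrt(diag(vcov(oracle)))
  for (nm in names(oc))
    expect_lt(abs(fit$beta[nm] - oc[nm]), 3 * ose[nm])
})

test_that("AIC ranking is ascending with ties broken by size then id, excluding failures", {
  mk <- function(id, terms, aic, conv = TRUE) {
    f <- list(id = id, terms = terms, aic = aic, theta = 1, converged = conv)
    class(f) <- "rspf_fit"
    f
  }
  fits <- list(mk("b", c("x", "y"), 12), mk("a", "x", 10),
               mk("c", c("x", "y", "z"), 11),
               mk("fail", "q", NA, conv = FALSE),
               mk("d", "y", 11))
  rk <- rank_by_aic(fits)
  expect_identical(rk$id, c("a", "d", "c", "b"))
  expect_identical(rk$aic, c(10, 11, 11, 12))
  expect_identical(nrow(rank_by_aic(fits, k = 2)), 2L)
  expect_error(rank_by_aic(list(mk("f", "x", NA, FALSE))), "no converged")
})

test_that("on data generated from a known spec, that spec leads the candidate ranking", {
  tab <- table_std
  beta <- c(elevation = -0.04, distfeed = -0.002, distfence = 0.008)
  tab$dev_count <- simulate_plot_counts(tab, beta, 10000, seed = 16)
  cands <- enumerate_candidates(c("elevation", "distfeed", "distfence",
                                  "TPI", "slope"),
                                quadratic_eligible = character(0),
                                max_base = 3)
  fits <- lapply(cands, fit_nb_rspf, table = tab)
  rk <- rank_by_aic(fits, k = 10)
  expect_true(spec_id(names(beta)) %in% rk$id[1:3])
})

test_that("bootstrap intervals are seeded, ordered and zero-width for exactly determined coefficients", {
  tab <- table_std
  beta <- c(elevation = -0.03, distfeed = -0.0015)
  tab$dev_count <- simulate_plot_counts(tab, beta, 10000, seed = 17)
  fit <- fit_nb_rspf(names(beta), tab)
  b1 <- bootstrap_cis(fit, tab, B = 60, seed = 4)
  b2 <- bootstrap_cis(fit, tab, B = 60, seed = 4)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$upper))
  expect_identical(b1$significant, b1$lower > 0 | b1$upper < 0)

  # two-level design with constant counts per level: the slope is exactly
  # log(c2/c1) in every replicate containing both levels
  dg <- data.frame(g = rep(c(0, 1), each = 40),
                   dev_count = rep(c(5L, 20L), each = 40))
  fg <- fit_nb_rspf("g", dg)
  bg <- bootstrap_cis(fg, dg, B = 50, seed = 5)
  row <- bg[bg$term == "g", ]
  expect_equal(row$lower, row$upper, tolerance = 1e-8)
  expect_equal(row$estimate, log(4), tolerance = 1e-6)
})

test_that("odds-ratio transform matches its closed form", {
  expect_equal(round(odds_ratio_percent(-5.99e-2), 2), -5.81)
  expect_identical(odds_ratio_percent(0), 0)
  expect_equal(odds_ratio_percent(log(2)), 100)
})

test_that("predicted use is a normalized UD, monotone in a single positive predictor", {
  tab <- table_std
  tab$dev_count <- simulate_plot_counts(tab, c(distfeed = -0.002), 8000,
                                        seed = 18)
  fit <- fit_nb_rspf("distfeed", tab)
  p <- predict_use(fit, tab)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  ord_sign <- if (fit$beta["distfeed"] > 0) 1 else -1
  expect_identical(order(ord_sign * tab$distfeed), order(p))

  same <- tab[rep(1, 10), ]
  expect_equal(predict_use(fit, same), rep(0.1, 10))
  expect_error(predict_use(fit, tab[, setdiff(names(tab), "distfeed")]),
               "unresolvable")
})

test_that("simulated truth is recovered: correct signs and bootstrap coverage (small study)", {
  tab <- table_std
  beta <- c(elevation = -0.03, distfeed = -0.0015, distfence = 0.006)
  hits <- 0L
  n_runs <- 5L
  for (r in seq_len(n_runs)) {
    tab$dev_count <- simulate_plot_counts(tab, beta, 10000, seed = 100 + r)
    fit <- fit_nb_rspf(names(beta), tab)
    ci <- bootstrap_cis(fit, tab, B = 99, seed = 200 + r)
    ok <- TRUE
    for (nm in names(beta)) {
      row <- ci[ci$term == nm, ]
      if (sign(row$estimate) != sign(beta[nm])) ok <- FALSE
      if (beta[nm] < row$lower || beta[nm] > row$upper) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits, n_runs - 1L)
})
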