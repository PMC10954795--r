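# Fix cleaning, fix-rate accounting, association screening and the
# development/validation split.

test_that("cleaning removes out-of-fence, over-speed and edge-day fixes with a log", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000), c(0, 0))
  t0 <- as.POSIXct("2019-03-02 00:00:00", tz = "UTC")
  # day 1 (edge), then interior day: inside, 10 m outside, inside, and a
  # 600 m jump in 180 s (3.33 m/s) ending inside the fence
  fx <- data.frame(
    animal_id = "cow01",
    timestamp = c(t0 - 86400, t0 + 180 * (1:4)),
    x = c(100, 100, 1010, 100, 700),
    y = c(100, 100, 500, 100, 100),
    ehpe_cm = 900)
  win <- data.frame(animal_id = "cow01", start = t0 - 86400,
                    end = t0 + 86400)
  cl <- clean_fixes(fx, sq, deployment_windows = win, speed_max = 3)
  log <- attr(cl, "removal_log")
  expect_identical(unname(log["edge_day"]), 1L)
  expect_identical(unname(log["out_of_fence"]), 1L)
  expect_identical(unname(log["speed"]), 1L)
  expect_identical(nrow(cl), 2L)
  expect_true(all(point_in_polygon(cbind(cl$x, cl$y), sq)))
})

test_that("injected out-of-fence artifacts are removed exactly and cleaning is idempotent", {
  t0 <- as.POSIXct("2019-04-06 00:00:00", tz = "UTC")
  cfg <- sim_config(c(distfence = 0.05), n_animals = 2, start = t0,
                    end = t0 + 5 * 86400, missed_fix_prob = 0.1,
                    out_of_fence_prob = 0.01, ehpe_mean = 900, seed = 52)
  fx <- simulate_tracks(land_std, cfg)
  k <- sum(attr(fx, "truth")$artifact)
  # windows wider than the fix span so no edge-day removal interferes
  win <- data.frame(animal_id = unique(fx$animal_id),
                    start = t0 - 2 * 86400, end = t0 + 7 * 86400)
  cl <- clean_fixes(fx, land_std$fence, deployment_windows = win)
  expect_identical(unname(attr(cl, "removal_log")["out_of_fence"]), k)

  cl2 <- clean_fixes(cl, land_std$fence, deployment_windows = win)
  expect_identical(cl2$timestamp, cl$timestamp)
  expect_identical(cl2$x, cl$x)
  expect_identical(sum(attr(cl2, "removal_log")), 0L)
})

test_that("fix rate is 100 * recorded / scheduled with floor(window/interval) scheduled", {
  t0 <- as.POSIXct("2019-02-26 00:00:00", tz = "UTC")
  win <- data.frame(animal_id = "cow01", start = t0, end = t0 + 86400)
  full <- make_fixes(rep(25, 480), rep(25, 480), t0 = t0)
  fr <- compute_fix_rate(full, 180, win)
  expect_identical(fr$scheduled, 480)
  expect_equal(fr$fix_rate, 100)
  half <- full[seq_len(240), ]
  expect_equal(compute_fix_rate(half, 180, win)$fix_rate, 50)
  bad_win <- data.frame(animal_id = "cow01", start = t0, end = t0)
  expect_error(compute_fix_rate(full, 180, bad_win), "zero-length")
})

test_that("association uses strict thresholds and is symmetric", {
  t0 <- as.POSIXct("2019-07-16 00:00:00", tz = "UTC")
  a <- make_fixes(1:100, rep(0, 100), t0 = t0, animal = "a")
  # identical track
  b <- a; b$animal_id <- "b"
  r <- assess_association(rbind(a, b))
  expect_equal(r$fraction_time_apart, 0)
  expect_false(r$non_associated)

  # constantly 1 km apart
  c_ <- a; c_$animal_id <- "c"; c_$y <- 1000
  r2 <- assess_association(rbind(a, c_))
  expect_equal(r2$fraction_time_apart, 1)
  expect_true(r2$non_associated)

  # exactly 75% of matched times apart: strict ">" keeps the pair associated
  d <- a; d$animal_id <- "d"; d$y <- c(rep(1000, 75), rep(0, 25))
  r3 <- assess_association(rbind(a, d))
  expect_equal(r3$fraction_time_apart, 0.75)
  expect_false(r3$non_associated)

  # symmetry: animal order must not matter
  r4 <- assess_association(rbind(c_, a))
  expect_equal(r4$fraction_time_apart, r2$fraction_time_apart)
  expect_identical(r4$non_associated, r2$non_associated)

  # disjoint time coverage -> indeterminate
  e <- a; e$animal_id <- "e"; e$timestamp <- e$timestamp + 10 * 86400
  r5 <- assess_association(rbind(a, e))
  expect_true(r5$indeterminate)
})

test_that("dev/val split is an exhaustive seeded partition with round(0.75 n) development rows", {
  fx <- make_fixes(runif(1000), runif(1000))
  sp <- split_dev_val(fx, 0.75, seed = 9)
  expect_identical(nrow(sp$dev), 750L)
  expect_identical(nrow(sp$val), 250L)
  expect_identical(sort(c(as.numeric(rownames(sp$dev)),
                          as.numeric(rownames(sp$val)))),
                   as.numeric(seq_len(1000)))
  sp2 <- split_dev_val(fx, 0.75, seed = 9)
  expect_identical(rownames(sp2$dev), rownames(sp$dev))
  sp3 <- split_dev_val(fx, 0.75, seed = 10)
  expect_false(identical(rownames(sp3$dev), rownames(sp$dev)))
  expect_error(split_dev_val(fx[1:10, ], 0.75), "fewer than 20")

  # the study-scale count: 149,898 pooled fixes -> 112,424 development
  big <- data.frame(i = seq_len(149898))
  spb <- split_dev_val(big, 0.75, seed = 1)
  expect_identical(nrow(spb$dev), 112424L)
  expect_identical(nrow(spb$val), 149898L - 112424L)
})
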