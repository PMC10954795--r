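# Simulation of GPS collar tracks over a synthetic landscape, with known
# selection coefficients and configurable collar artifacts.

#' Build a track-simulation configuration
#'
#' Collects the parameters of the collar simulation: the true selection
#' coefficients (the ground truth that downstream fitting must recover), the
#' fix schedule, the horizontal-error model, and artifact rates.
#'
#' @param true_beta named coefficient vector (see [true_utilization()]);
#'   NULL for uniform (null) use.
#' @param n_animals number of collared animals.
#' @param start,end period bounds (POSIXct, UTC). Fixes are scheduled at
#'   `start + fix_interval * (1:n)` with `n = floor(period / fix_interval)`.
#' @param fix_interval seconds between scheduled fixes (default 180 s, the
#'   3-minute collar schedule).
#' @param ehpe_mean,ehpe_sd mean and s.d. (cm) of the log-normal estimated
#'   horizontal position error; the drawn EHPE is used as the RMS magnitude
#'   of the isotropic position error added to true positions.
#' @param missed_fix_prob probability a scheduled fix is not recorded.
#' @param out_of_fence_prob probability a recorded fix is displaced to a
#'   gross-error position outside the fence.
#' @param autocorrelation step-kernel radius in metres; 0 (default) draws
#'   cells independently from the utilization distribution, matching the
#'   static model fitted downstream. Positive values restrict each step to
#'   cells within the radius of the previous true position.
#' @param seed integer seed recorded in the output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(true_beta = NULL,
                       n_animals = 3L,
                       start = as.POSIXct("2019-02-26 00:00:00", tz = "UTC"),
                       end = start + 6 * 86400,
                       fix_interval = 180,
                       ehpe_mean = 1100, ehpe_sd = 800,
                       missed_fix_prob = 0.15,
                       out_of_fence_prob = 0.002,
                       autocorrelation = 0,
                       seed = 1L) {
  stopifnot(fix_interval > 0, n_animals >= 1,
            missed_fix_prob >= 0, missed_fix_prob <= 1,
            out_of_fence_prob >= 0, out_of_fence_prob <= 1,
            ehpe_mean > 0, ehpe_sd >= 0, autocorrelation >= 0)
  if (end <= start) stop("end must be after start")
  structure(list(true_beta = true_beta, n_animals = as.integer(n_animals),
                 start = start, end = end, fix_interval = fix_interval,
                 ehpe_mean = ehpe_mean, ehpe_sd = ehpe_sd,
                 missed_fix_prob = missed_fix_prob,
                 out_of_fence_prob = out_of_fence_prob,
                 autocorrelation = autocorrelation, seed = as.integer(seed)),
            class = "sim_config")
}

# log-normal parameters from mean/sd on the natural scale
lnorm_pars <- function(m, s) {
  if (s == 0) return(c(meanlog = log(m), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate GPS collar fixes over a landscape
#'
#' For each animal, scheduled fixes are drawn at the configured interval;
#' each recorded fix occupies a grid cell drawn with probability
#' proportional to exp(beta' x) over in-fence cells (the true utilization
#' distribution), with uniform jitter within the cell. Reported positions
#' add isotropic Gaussian error whose RMS magnitude is the drawn EHPE.
#' Collar artifacts: scheduled fixes are missed independently at
#' `missed_fix_prob`, and recorded fixes are displaced outside the fence at
#' `out_of_fence_prob` (pushed 5-50 m beyond the nearest boundary point).
#'
#' @param landscape an `rspf_landscape`.
#' @param cfg a [sim_config()].
#' @return data.frame `animal_id, timestamp, x, y, ehpe_cm`, ordered by
#'   animal and time. Attribute `truth` is a parallel data.frame with the
#'   true cell, true coordinates and artifact flag; attribute `schedule`
#'   counts scheduled/recorded/missed fixes per animal; attribute `seed`
#'   records the seed.
#' @export
simulate_tracks <- function(landscape, cfg) {
  stopifnot(inherits(landscape, "rspf_landscape"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ud <- true_utilization(landscape, cfg$true_beta)
  cells <- grid_cells(landscape)
  in_idx <- which(!is.na(ud))
  if (length(in_idx) == 0L) stop("empty feasible region inside fence")
  p <- ud[in_idx]
  cs <- landscape$cell_size
  lp <- lnorm_pars(cfg$ehpe_mean, cfg$ehpe_sd)

  n_sched <- floor(as.numeric(difftime(cfg$end, cfg$start, units = "secs")) /
                   cfg$fix_interval)
  if (n_sched < 1L) stop("period shorter than one fix interval")

  per_animal <- vector("list", cfg$n_animals)
  sched_tab <- data.frame(animal_id = character(0), scheduled = integer(0),
                          recorded = integer(0), missed = integer(0))
  for (a in seq_len(cfg$n_animals)) {
    id <- sprintf("cow%02d", a)
    times <- cfg$start + cfg$fix_interval * seq_len(n_sched)
    rec <- stats::runif(n_sched) >= cfg$missed_fix_prob
    n_rec <- sum(rec)
    if (n_rec == 0L) {
      sched_tab <- rbind(sched_tab, data.frame(animal_id = id,
                                               scheduled = n_sched,
                                               recorded = 0L,
                                               missed = n_sched))
      next
    }
    if (cfg$autocorrelation <= 0) {
      drawn <- in_idx[sample.int(length(in_idx), n_rec, replace = TRUE,
                                 prob = p)]
    } else {
      drawn <- integer(n_rec)
      drawn[1L] <- in_idx[sample.int(length(in_idx), 1L, prob = p)]
      cx <- cells$x[in_idx]; cy <- cells$y[in_idx]
      for (i in seq_len(n_rec)[-1L]) {
        prev <- drawn[i - 1L]
        near <- (cx - cells$x[prev])^2 + (cy - cells$y[prev])^2 <=
          cfg$autocorrelation^2
        if (!any(near)) near <- rep(TRUE, length(in_idx))
        w <- p * near
        drawn[i] <- in_idx[sample.int(length(in_idx), 1L, prob = w)]
      }
    }
    true_x <- cells$x[drawn] + stats::runif(n_rec, -cs / 2, cs / 2)
    true_y <- cells$y[drawn] + stats::runif(n_rec, -cs / 2, cs / 2)
    ehpe_cm <- stats::rlnorm(n_rec, lp["meanlog"], lp["sdlog"])
    ehpe_m <- ehpe_cm / 100
    err_sd <- ehpe_m / sqrt(2)  # per-axis sd so RMS magnitude = EHPE
    x <- true_x + stats::rnorm(n_rec, 0, err_sd)
    y <- true_y + stats::rnorm(n_rec, 0, err_sd)
    artifact <- stats::runif(n_rec) < cfg$out_of_fence_prob
    if (any(artifact)) {
      nb <- dist_to_boundary(cbind(true_x[artifact], true_y[artifact]),
                             landscape$fence, nearest = TRUE)
      dir <- nb$point - cbind(true_x[artifact], true_y[artifact])
      nrm <- sqrt(rowSums(dir^2))
      nrm[nrm == 0] <- 1
      push <- stats::runif(sum(artifact), 5, 50)
      x[artifact] <- nb$point[, 1L] + dir[, 1L] / nrm * push
      y[artifact] <- nb$point[, 2L] + dir[, 2L] / nrm * push
    }
    per_animal[[a]] <- data.frame(
      animal_id = id, timestamp = times[rec], x = x, y = y,
      ehpe_cm = ehpe_cm, true_x = true_x, true_y = true_y, cell = drawn,
      artifact = artifact, stringsAsFactors = FALSE)
    sched_tab <- rbind(sched_tab, data.frame(animal_id = id,
                                             scheduled = n_sched,
                                             recorded = n_rec,
                                             missed = n_sched - n_rec))
  }
  all <- do.call(rbind, per_animal)
  if (is.null(all)) all <- data.frame(animal_id = character(0),
                                      timestamp = cfg$start[0],
                                      x = numeric(0), y = numeric(0),
                                      ehpe_cm = numeric(0))
  fixes <- all[, c("animal_id", "timestamp", "x", "y", "ehpe_cm")]
  rownames(fixes) <- NULL
  attr(fixes, "truth") <- all[, c("animal_id", "timestamp", "true_x",
                                  "true_y", "cell", "artifact")]
  attr(fixes, "schedule") <- sched_tab
  attr(fixes, "seed") <- cfg$seed
  fixes
}

#' Simulate per-plot fix counts directly from the count model
#'
#' Draws a multinomial allocation of `n_fixes` over plots with cell
#' probabilities proportional to exp(beta' x) evaluated on the plot
#' predictor table — the data-generating process assumed by the fitted RSPF.
#' Used for parameter-recovery and validation-calibration studies where the
#' plot, not the grid cell, is the observational unit.
#'
#' @param table plot predictor table (see [extract_predictors()]).
#' @param beta named coefficient vector resolved against table columns
#'   (trailing `2` squares the base column); NULL for uniform.
#' @param n_fixes total number of fixes to allocate.
#' @param seed optional seed.
#' @return integer vector of counts, one per plot row, summing to `n_fixes`.
#' @export
simulate_plot_counts <- function(table, beta = NULL, n_fixes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta) || length(beta) == 0L) {
    eta <- rep(0, nrow(table))
  } else {
    eta <- drop(resolve_terms(names(beta), table) %*% beta)
  }
  eta <- eta - max(eta)
  p <- exp(eta) / sum(exp(eta))
  drop(stats::rmultinom(1L, n_fixes, p))
}
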