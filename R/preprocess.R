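# GPS preprocessing: fix cleaning, fix-rate accounting, pairwise association
# screening, and the development/validation split.

#' Clean raw GPS fixes
#'
#' Applies, in order and per animal:
#' 1. edge-day removal: fixes on the first or last calendar day (UTC) of the
#'    animal's deployment window (collar placement/removal days);
#' 2. fence filter: fixes strictly outside the fence polygon;
#' 3. speed filter: the later fix of any consecutive pair implying a segment
#'    speed above `speed_max`, re-applied until no pair violates (so cleaning
#'    is idempotent);
#' 4. turn filter: fixes at the apex of a course change above `turn_max`
#'    degrees with both adjacent segment speeds above `speed_max / 2`, also
#'    to a fixed point.
#'
#' An optional EHPE threshold (off by default) removes fixes whose reported
#' horizontal error exceeds `ehpe_max_cm`.
#'
#' @param fixes data.frame with `animal_id`, `timestamp`, `x`, `y` (and
#'   optionally `ehpe_cm`).
#' @param fence closed fence polygon (vertex matrix).
#' @param deployment_windows optional data.frame `animal_id, start, end`;
#'   when NULL each animal's first/last fix timestamps are used.
#' @param speed_max maximum plausible speed, m/s (default 3, an upper bound
#'   for trotting cattle).
#' @param turn_max course-change threshold in degrees (default 170).
#' @param ehpe_max_cm optional EHPE cut-off in cm (default NULL = off).
#' @return cleaned data.frame, timestamps strictly increasing per animal,
#'   with attribute `removal_log`: counts removed per rule.
#' @export
clean_fixes <- function(fixes, fence, deployment_windows = NULL,
                        speed_max = 3, turn_max = 170, ehpe_max_cm = NULL) {
  stopifnot(all(c("animal_id", "timestamp", "x", "y") %in% names(fixes)))
  log <- c(edge_day = 0L, out_of_fence = 0L, speed = 0L, turn = 0L, ehpe = 0L)
  if (nrow(fixes) == 0L) {
    attr(fixes, "removal_log") <- log
    return(fixes)
  }
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]

  pieces <- lapply(split(fixes, fixes$animal_id), function(d) {
    id <- d$animal_id[1L]
    if (!is.null(deployment_windows)) {
      w <- deployment_windows[deployment_windows$animal_id == id, , drop = FALSE]
      d0 <- as.Date(w$start[1L], tz = "UTC"); d1 <- as.Date(w$end[1L], tz = "UTC")
    } else {
      d0 <- as.Date(min(d$timestamp), tz = "UTC")
      d1 <- as.Date(max(d$timestamp), tz = "UTC")
    }
    day <- as.Date(d$timestamp, tz = "UTC")
    edge <- day == d0 | day == d1
    log["edge_day"] <<- log["edge_day"] + sum(edge)
    d <- d[!edge, , drop = FALSE]
    if (nrow(d) == 0L) return(d)

    inside <- point_in_polygon(cbind(d$x, d$y), fence)
    log["out_of_fence"] <<- log["out_of_fence"] + sum(!inside)
    d <- d[inside, , drop = FALSE]

    if (!is.null(ehpe_max_cm) && "ehpe_cm" %in% names(d)) {
      bad <- d$ehpe_cm > ehpe_max_cm
      log["ehpe"] <<- log["ehpe"] + sum(bad)
      d <- d[!bad, , drop = FALSE]
    }

    # speed and turn filters to a joint fixed point (so cleaning is
    # idempotent: removing a turn apex can create a new too-fast pair)
    repeat {
    n_before_filters <- nrow(d)
    # speed filter: forward scan dropping any fix whose speed from the last
    # retained fix exceeds speed_max (the fixed point of remove-and-rescan)
    if (nrow(d) >= 2L) {
      tt <- as.numeric(d$timestamp); xx <- d$x; yy <- d$y
      keep <- rep(TRUE, nrow(d))
      last <- 1L
      for (i in 2L:nrow(d)) {
        dt <- max(tt[i] - tt[last], .Machine$double.eps)
        if (sqrt((xx[i] - xx[last])^2 + (yy[i] - yy[last])^2) / dt > speed_max) {
          keep[i] <- FALSE
        } else {
          last <- i
        }
      }
      log["speed"] <<- log["speed"] + sum(!keep)
      d <- d[keep, , drop = FALSE]
    }

    # turn filter to fixed point: remove apexes of near-reversals travelled
    # at speed (> turn_max course change, both adjacent speeds > speed_max/2)
    repeat {
      if (nrow(d) < 3L) break
      n <- nrow(d)
      dt <- diff(as.numeric(d$timestamp))
      dx <- diff(d$x); dy <- diff(d$y)
      sp <- sqrt(dx^2 + dy^2) / pmax(dt, .Machine$double.eps)
      h1x <- dx[-(n - 1L)]; h1y <- dy[-(n - 1L)]   # heading into apex
      h2x <- dx[-1L];       h2y <- dy[-1L]         # heading out of apex
      dot <- h1x * h2x + h1y * h2y
      nn <- sqrt(h1x^2 + h1y^2) * sqrt(h2x^2 + h2y^2)
      ang <- acos(pmin(1, pmax(-1, ifelse(nn > 0, dot / nn, 1)))) * 180 / pi
      bad <- which(ang > turn_max & sp[-(n - 1L)] > speed_max / 2 &
                     sp[-1L] > speed_max / 2)
      if (length(bad) == 0L) break
      # drop a non-adjacent subset per pass, then re-scan
      bad <- bad[c(TRUE, diff(bad) >= 2L)]
      log["turn"] <<- log["turn"] + length(bad)
      d <- d[-(bad + 1L), , drop = FALSE]
    }
    if (nrow(d) == n_before_filters) break
    }
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("all fixes removed by cleaning rules")
  attr(out, "removal_log") <- log
  out
}

#' Fix-rate accounting per deployment window
#'
#' Scheduled fixes are `floor(window_seconds / interval)`; the fix rate is
#' 100 * recorded / scheduled.
#'
#' @param fixes data.frame with `animal_id`, `timestamp`.
#' @param interval fix schedule interval in seconds (> 0).
#' @param windows data.frame `animal_id, start, end` and optionally
#'   `period`; when NULL, one window per animal spanning its fixes.
#' @return data.frame per (period, animal): scheduled, recorded, fix_rate
#'   (%), with attribute `summary`: per-period mean and s.d. across animals.
#' @export
compute_fix_rate <- function(fixes, interval, windows = NULL) {
  stopifnot(interval > 0)
  if (is.null(windows)) {
    sp <- split(fixes, fixes$animal_id)
    windows <- do.call(rbind, lapply(sp, function(d)
      data.frame(animal_id = d$animal_id[1L], start = min(d$timestamp),
                 end = max(d$timestamp))))
  }
  if (is.null(windows$period)) windows$period <- "all"
  secs <- as.numeric(difftime(windows$end, windows$start, units = "secs"))
  if (any(secs <= 0)) stop("zero-length deployment window")
  out <- windows
  out$scheduled <- floor(secs / interval)
  out$recorded <- mapply(function(id, s, e)
    sum(fixes$animal_id == id & fixes$timestamp >= s & fixes$timestamp <= e),
    windows$animal_id, windows$start, windows$end)
  out$fix_rate <- 100 * out$recorded / out$scheduled
  smry <- do.call(rbind, lapply(split(out, out$period), function(d)
    data.frame(period = d$period[1L], n_animals = nrow(d),
               fix_rate_mean = mean(d$fix_rate),
               fix_rate_sd = stats::sd(d$fix_rate))))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}

# mutual-nearest timestamp matching within a tolerance; symmetric in (ta, tb)
match_times <- function(ta, tb, tol) {
  ta <- as.numeric(ta); tb <- as.numeric(tb)
  oa <- order(ta); ob <- order(tb)
  sa <- ta[oa]; sb <- tb[ob]
  near_b <- function(v) {  # index into sb of nearest element per v
    j <- findInterval(v, sb)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(sb))
    ifelse(abs(v - sb[lo]) <= abs(sb[hi] - v), lo, hi)
  }
  jb <- near_b(sa)
  ja <- {
    j <- findInterval(sb, sa)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(sa))
    ifelse(abs(sb - sa[lo]) <= abs(sa[hi] - sb), lo, hi)
  }
  mutual <- which(ja[jb] == seq_along(sa) & abs(sa - sb[jb]) <= tol)
  cbind(a = oa[mutual], b = ob[jb[mutual]])
}

#' Pairwise spatiotemporal association between collared animals
#'
#' Matches fixes of each unordered animal pair at common times (mutual
#' nearest timestamps within `match_tolerance`) and computes the fraction of
#' matched times at which the animals were separated by more than
#' `dist_threshold`. A pair is non-associated when that fraction strictly
#' exceeds `frac_threshold` — the independence screen required before
#' pooling animals as sampling units.
#'
#' @param fixes data.frame with `animal_id`, `timestamp`, `x`, `y`.
#' @param dist_threshold separation distance in metres (default 25).
#' @param frac_threshold time fraction (default 0.75); both inequalities are
#'   strict.
#' @param match_tolerance timestamp matching tolerance in seconds (default
#'   90, half the 3-minute schedule).
#' @return data.frame per pair: `animal_a`, `animal_b`, `n_matched`,
#'   `fraction_time_apart`, `non_associated`, `indeterminate` (TRUE when no
#'   timestamps matched).
#' @export
assess_association <- function(fixes, dist_threshold = 25,
                               frac_threshold = 0.75, match_tolerance = 90) {
  ids <- sort(unique(fixes$animal_id))
  if (length(ids) < 2L) stop("need at least 2 animals")
  sp <- split(fixes, fixes$animal_id)
  combs <- utils::combn(ids, 2L)
  res <- lapply(seq_len(ncol(combs)), function(k) {
    a <- sp[[combs[1L, k]]]; b <- sp[[combs[2L, k]]]
    m <- match_times(a$timestamp, b$timestamp, match_tolerance)
    if (nrow(m) == 0L)
      return(data.frame(animal_a = combs[1L, k], animal_b = combs[2L, k],
                        n_matched = 0L, fraction_time_apart = NA_real_,
                        non_associated = NA, indeterminate = TRUE))
    d <- sqrt((a$x[m[, "a"]] - b$x[m[, "b"]])^2 +
              (a$y[m[, "a"]] - b$y[m[, "b"]])^2)
    fr <- mean(d > dist_threshold)
    data.frame(animal_a = combs[1L, k], animal_b = combs[2L, k],
               n_matched = nrow(m), fraction_time_apart = fr,
               non_associated = fr > frac_threshold, indeterminate = FALSE)
  })
  do.call(rbind, res)
}

#' Random development/validation split of fixes
#'
#' Pools all fixes and assigns `round(dev_fraction * n)` of them to the
#' development set; the rest form the validation set. Optionally stratified
#' by animal (the default pools animals before splitting, matching the
#' population-level model).
#'
#' @param fixes data.frame of cleaned fixes.
#' @param dev_fraction development share in (0, 1), default 0.75.
#' @param seed integer seed for reproducibility.
#' @param stratify_by_animal split within each animal separately.
#' @return list with `dev` and `val` data.frames (a disjoint, exhaustive
#'   partition of the input rows).
#' @export
split_dev_val <- function(fixes, dev_fraction = 0.75, seed = NULL,
                          stratify_by_animal = FALSE) {
  stopifnot(dev_fraction > 0, dev_fraction < 1)
  n <- nrow(fixes)
  if (n < 20L) stop("refusing to split fewer than 20 fixes")
  if (!is.null(seed)) set.seed(seed)
  if (stratify_by_animal) {
    idx <- unlist(lapply(split(seq_len(n), fixes$animal_id), function(ii)
      ii[sample.int(length(ii), round(dev_fraction * length(ii)))]))
  } else {
    idx <- sample.int(n, round(dev_fraction * n))
  }
  idx <- sort(idx)
  list(dev = fixes[idx, , drop = FALSE],
       val = fixes[setdiff(seq_len(n), idx), , drop = FALSE])
}
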