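# Circular sampling plots: random placement inside the fence and per-plot
# fix counting.

#' Randomly place circular sampling plots inside the fence
#'
#' Uniform rejection sampling of plot centroids over the fenced area.
#' Candidates strictly closer than `min_fence_dist` to the fence boundary
#' are rejected (a centroid exactly at the threshold is retained); when
#' `min_spacing > 0` a candidate closer than that to an accepted centroid is
#' also rejected. Plots are 50-m-diameter disks by default.
#'
#' @param fence closed fence polygon (vertex matrix).
#' @param n_target number of plots to place.
#' @param radius plot radius in metres (default 25).
#' @param min_fence_dist minimum centroid-to-fence distance in metres
#'   (default 13).
#' @param min_spacing minimum pairwise centroid spacing (default 0 =
#'   overlapping plots allowed).
#' @param seed integer seed.
#' @param max_attempts attempt budget before giving up.
#' @return data.frame `plot_id, x, y, radius` with exactly `n_target` rows.
#' @export
sample_plots <- function(fence, n_target, radius = 25, min_fence_dist = 13,
                         min_spacing = 0, seed = NULL,
                         max_attempts = 1000L * n_target) {
  stopifnot(n_target >= 1, radius > 0, min_fence_dist >= 0)
  if (!is.null(seed)) set.seed(seed)
  fence <- close_polygon(fence)
  xr <- range(fence[, 1L]); yr <- range(fence[, 2L])
  acc_x <- numeric(0); acc_y <- numeric(0)
  attempts <- 0L
  while (length(acc_x) < n_target) {
    if (attempts >= max_attempts)
      stop("attempt budget exhausted after ", attempts,
           " draws; region too small for ", n_target,
           " plots at the requested spacing")
    # draw candidates in batches for speed
    m <- min(1000L, max_attempts - attempts)
    attempts <- attempts + m
    cx <- stats::runif(m, xr[1L], xr[2L])
    cy <- stats::runif(m, yr[1L], yr[2L])
    ok <- point_in_polygon(cbind(cx, cy), fence)
    if (any(ok)) {
      d <- dist_to_boundary(cbind(cx[ok], cy[ok]), fence)
      keep <- d >= min_fence_dist  # strictly closer than the threshold is out
      cx <- cx[ok][keep]; cy <- cy[ok][keep]
      for (i in seq_along(cx)) {
        if (length(acc_x) >= n_target) break
        if (min_spacing > 0 && length(acc_x) > 0) {
          if (min(sqrt((acc_x - cx[i])^2 + (acc_y - cy[i])^2)) < min_spacing)
            next
        }
        acc_x <- c(acc_x, cx[i]); acc_y <- c(acc_y, cy[i])
      }
    }
  }
  data.frame(plot_id = seq_len(n_target), x = acc_x, y = acc_y,
             radius = radius)
}

#' Count GPS fixes within each plot
#'
#' A fix is counted in every plot whose centroid lies within the plot
#' radius (closed disk: distance <= radius). Plots may overlap, so a fix
#' can contribute to several plots and no deduplication is applied.
#'
#' @param fixes data.frame with `x`, `y` (cleaned fixes).
#' @param plots data.frame from [sample_plots()].
#' @return integer vector of counts, one per plot.
#' @export
count_fixes_in_plots <- function(fixes, plots) {
  n <- nrow(fixes)
  counts <- integer(nrow(plots))
  if (n == 0L) return(counts)
  chunk <- 20000L
  r2 <- plots$radius^2
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(fixes$x[s:e], plots$x, "-")
    dy <- outer(fixes$y[s:e], plots$y, "-")
    within <- sweep(dx^2 + dy^2, 2L, r2, "<=")
    counts <- counts + colSums(within)
  }
  as.integer(counts)
}
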