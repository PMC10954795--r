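# Synthetic landscape generator: DEM, cover map, fence and water point with the
# statistical structure of a fenced Mediterranean silvopastoral paddock.

#' Canonical cover class names
#'
#' Order fixes the integer codes used in cover grids: wood (deciduous oak
#' wood), shrub (shrub-encroached grassland), grasslands, rock, feedwater.
#' @export
cover_classes <- function() c("wood", "shrub", "grasslands", "rock", "feedwater")

# Smoothed Gaussian-ish random field: white noise + repeated 3x3 mean filter.
# `passes` controls the correlation length (~passes * cell_size).
smooth_field <- function(ny, nx, passes = 8L) {
  f <- matrix(stats::rnorm(ny * nx), ny, nx)
  pad_shift <- function(m, dr, dc) {
    # shift with edge replication
    ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
    ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
    m[ri, ci, drop = FALSE]
  }
  for (i in seq_len(passes)) {
    acc <- matrix(0, ny, nx)
    for (dr in -1:1) for (dc in -1:1) acc <- acc + pad_shift(f, dr, dc)
    f <- acc / 9
  }
  f
}

#' Cell centre coordinates of a landscape grid
#'
#' Row 1 is the northern edge of the grid (raster convention).
#'
#' @param landscape an `rspf_landscape`.
#' @return data.frame with cell (matrix index), row, col, x, y for every cell.
#' @export
grid_cells <- function(landscape) {
  ny <- nrow(landscape$dem); nx <- ncol(landscape$dem)
  cs <- landscape$cell_size
  col <- rep(seq_len(nx), each = ny)
  row <- rep(seq_len(ny), times = nx)
  data.frame(
    cell = seq_len(ny * nx),
    row = row, col = col,
    x = landscape$xmin + (col - 0.5) * cs,
    y = landscape$ymin + (ny - row + 0.5) * cs
  )
}

#' Generate a synthetic fenced landscape
#'
#' Builds a paddock with a rounded-rectangle fence of exactly the target
#' area, a smoothed random-field DEM rescaled to `elev_range`, a clumped
#' cover map whose class fractions match `cover_fractions` to within grid
#' rounding, and a single water point placed in the lowest-elevation quintile
#' of the paddock (water points sit low in the terrain). The feedwater cover
#' class is the patch of cells nearest the water point.
#'
#' @param target_area_ha fenced area in hectares (> 1).
#' @param cover_fractions named fractions for all five [cover_classes()];
#'   must sum to 1 within 0.001.
#' @param elev_range c(min, max) elevation in metres.
#' @param cell_size grid resolution in metres (default 10).
#' @param aspect_ratio fence width/height ratio.
#' @param smooth_passes smoothing passes for the random fields.
#' @param seed integer seed; identical seeds give bit-identical landscapes.
#' @return an object of class `rspf_landscape`: list with `dem` (matrix, row
#'   1 = north), `cover` (integer matrix, codes into [cover_classes()], NA
#'   outside the fence), `in_fence` (logical matrix), `fence` (closed vertex
#'   matrix), `water_point` (named x/y), `cell_size`, `xmin`, `ymin`,
#'   `crs_note`, `seed`.
#' @export
generate_landscape <- function(target_area_ha,
                               cover_fractions = c(wood = 0.558, shrub = 0.260,
                                                   grasslands = 0.069,
                                                   rock = 0.100,
                                                   feedwater = 0.013),
                               elev_range = c(660, 731),
                               cell_size = 10,
                               aspect_ratio = 1.4,
                               smooth_passes = 8L,
                               seed = NULL) {
  if (target_area_ha <= 1) stop("target_area_ha must exceed 1 ha")
  cls <- cover_classes()
  if (!all(cls %in% names(cover_fractions)))
    stop("cover_fractions must name all of: ", paste(cls, collapse = ", "))
  fr <- cover_fractions[cls]
  if (any(fr < 0)) stop("cover fractions must be non-negative")
  if (abs(sum(fr) - 1) > 0.001)
    stop("cover fractions must sum to 1 (got ", signif(sum(fr), 6), ")")
  if (length(elev_range) != 2L || diff(elev_range) < 0)
    stop("elev_range must be c(min, max)")
  if (!is.null(seed)) set.seed(seed)

  area_m2 <- target_area_ha * 1e4
  fence <- rounded_rect_polygon(area_m2, aspect = aspect_ratio)
  # one-cell margin around the fence bounding box
  fence[, 1L] <- fence[, 1L] + cell_size
  fence[, 2L] <- fence[, 2L] + cell_size
  xmin <- 0; ymin <- 0
  nx <- ceiling((max(fence[, 1L]) + cell_size) / cell_size)
  ny <- ceiling((max(fence[, 2L]) + cell_size) / cell_size)

  land <- list(dem = matrix(0, ny, nx), cover = matrix(NA_integer_, ny, nx),
               in_fence = matrix(FALSE, ny, nx), fence = fence,
               water_point = c(x = NA_real_, y = NA_real_),
               cell_size = cell_size, xmin = xmin, ymin = ymin,
               crs_note = "abstract projected metre grid (no geodesy)",
               seed = seed)
  class(land) <- "rspf_landscape"

  cells <- grid_cells(land)
  inside <- point_in_polygon(cbind(cells$x, cells$y), fence)
  land$in_fence[cbind(cells$row, cells$col)] <- inside
  in_idx <- cells$cell[inside]
  if (length(in_idx) == 0L) stop("no grid cells inside fence")

  # DEM: smoothed field rescaled (over the whole grid) to elev_range
  dem <- smooth_field(ny, nx, smooth_passes)
  rng <- range(dem)
  dem <- (dem - rng[1L]) / (rng[2L] - rng[1L]) * diff(elev_range) + elev_range[1L]
  land$dem <- dem

  # water point: random in-fence cell from the lowest-elevation quintile
  elev_in <- dem[in_idx]
  q20 <- stats::quantile(elev_in, 0.2, names = FALSE)
  low <- in_idx[elev_in <= q20]
  wcell <- low[sample.int(length(low), 1L)]
  land$water_point <- c(x = cells$x[wcell], y = cells$y[wcell])

  # cover: feedwater = cells nearest the water point; remaining classes by
  # greedy quota over independent smooth fields (clumped, near-exact shares)
  n_in <- length(in_idx)
  cov <- matrix(NA_integer_, ny, nx)
  quota <- round(fr * n_in)
  if (fr["feedwater"] > 0 && quota["feedwater"] == 0) quota["feedwater"] <- 1L
  unassigned <- in_idx
  if (quota["feedwater"] > 0) {
    d_w <- sqrt((cells$x[unassigned] - land$water_point["x"])^2 +
                (cells$y[unassigned] - land$water_point["y"])^2)
    take <- unassigned[order(d_w)][seq_len(min(quota["feedwater"], n_in))]
    cov[take] <- match("feedwater", cls)
    unassigned <- setdiff(unassigned, take)
  }
  others <- setdiff(cls, "feedwater")
  others <- others[order(-fr[others])]
  for (k in seq_along(others)) {
    cl <- others[k]
    if (k == length(others)) {
      take <- unassigned  # last class absorbs rounding remainder
    } else {
      fld <- smooth_field(ny, nx, smooth_passes)
      nk <- min(quota[cl], length(unassigned))
      take <- unassigned[order(-fld[unassigned])][seq_len(nk)]
    }
    cov[take] <- match(cl, cls)
    unassigned <- setdiff(unassigned, take)
  }
  land$cover <- cov
  land
}

#' @export
print.rspf_landscape <- function(x, ...) {
  cells <- sum(x$in_fence)
  cat("Synthetic fenced landscape\n")
  cat(sprintf("  grid: %d x %d cells @ %g m (%d in fence, %.1f ha)\n",
              nrow(x$dem), ncol(x$dem), x$cell_size, cells,
              cells * x$cell_size^2 / 1e4))
  cat(sprintf("  elevation: %.0f-%.0f m; water point at (%.0f, %.0f)\n",
              min(x$dem), max(x$dem), x$water_point["x"], x$water_point["y"]))
  fr <- cover_fractions_realized(x)
  cat("  cover: ", paste(sprintf("%s %.1f%%", names(fr), 100 * fr),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Realized cover fractions of a landscape
#'
#' @param landscape an `rspf_landscape`.
#' @return named vector of in-fence class fractions (sums to 1).
#' @export
cover_fractions_realized <- function(landscape) {
  tab <- tabulate(landscape$cover[landscape$in_fence],
                  nbins = length(cover_classes()))
  stats::setNames(tab / sum(tab), cover_classes())
}

#' Per-cell predictor values for the in-fence cells
#'
#' The cell-level analogue of the plot predictor table, used by the track
#' simulator and the prediction-raster renderer: elevation, slope, TRI, TPI,
#' aspect class, 0/1 cover indicators, and distances to the fence boundary
#' and the water point, evaluated at cell centres.
#'
#' @param landscape an `rspf_landscape`.
#' @param terrain optional precomputed [compute_terrain()] result.
#' @return data.frame, one row per in-fence cell (with `cell`, `x`, `y`).
#' @export
cell_predictors <- function(landscape, terrain = NULL) {
  if (is.null(terrain))
    terrain <- compute_terrain(landscape$dem, landscape$cell_size)
  cells <- grid_cells(landscape)
  keep <- which(landscape$in_fence)
  cells <- cells[cells$cell %in% keep, , drop = FALSE]
  idx <- cells$cell
  cls <- cover_classes()
  out <- data.frame(
    cell = idx, x = cells$x, y = cells$y,
    elevation = landscape$dem[idx],
    slope = terrain$slope[idx],
    TRI = terrain$tri[idx],
    TPI = terrain$tpi[idx],
    aspect = factor(c("N", "E", "S", "W")[terrain$aspect[idx]],
                    levels = c("N", "E", "S", "W"))
  )
  cov <- landscape$cover[idx]
  for (k in seq_along(cls)) out[[cls[k]]] <- as.numeric(cov == k)
  out$distfence <- dist_to_boundary(cbind(cells$x, cells$y), landscape$fence)
  out$distfeed <- as.numeric(sqrt((cells$x - landscape$water_point["x"])^2 +
                                  (cells$y - landscape$water_point["y"])^2))
  out
}

# Resolve model term names against a predictor data frame. A trailing "2"
# denotes the square of the base predictor (elevation2 = elevation^2).
# Returns a numeric matrix with one column per term.
resolve_terms <- function(terms, data) {
  if (length(terms) == 0L)
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0L))
  cols <- lapply(terms, function(tm) {
    if (tm %in% names(data)) {
      v <- data[[tm]]
      if (!is.numeric(v))
        stop("term '", tm, "' is not numeric; categorical terms are only ",
             "supported in model fitting, not in coefficient vectors")
      v
    } else if (grepl("2$", tm) && sub("2$", "", tm) %in% names(data)) {
      base <- data[[sub("2$", "", tm)]]
      if (!is.numeric(base)) stop("quadratic of non-numeric term '", tm, "'")
      base^2
    } else {
      stop("unresolvable predictor name: '", tm, "'")
    }
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- terms
  mat
}

#' True utilization distribution for known selection coefficients
#'
#' The discrete utilization distribution implied by a selection coefficient
#' vector: over in-fence cells, probability proportional to exp(beta' x).
#' This is the simulator's ground truth and the oracle against which fitted
#' predictions are compared.
#'
#' @param landscape an `rspf_landscape`.
#' @param true_beta named numeric vector of coefficients; names resolve
#'   against [cell_predictors()] columns (a trailing `2` squares the base
#'   predictor). `beta = NULL` or empty gives the uniform distribution.
#' @param terrain optional precomputed terrain grids.
#' @return matrix of probabilities (NA outside the fence) summing to 1 over
#'   in-fence cells.
#' @export
true_utilization <- function(landscape, true_beta = NULL, terrain = NULL) {
  pred <- cell_predictors(landscape, terrain)
  if (is.null(true_beta) || length(true_beta) == 0L) {
    eta <- rep(0, nrow(pred))
  } else {
    if (is.null(names(true_beta)) || any(names(true_beta) == ""))
      stop("true_beta must be a fully named vector")
    X <- resolve_terms(names(true_beta), pred)
    eta <- drop(X %*% true_beta)
  }
  eta <- eta - max(eta)  # overflow guard
  w <- exp(eta)
  p <- w / sum(w)
  out <- matrix(NA_real_, nrow(landscape$dem), ncol(landscape$dem))
  out[pred$cell] <- p
  out
}
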