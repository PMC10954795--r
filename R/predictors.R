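# Plot-level predictor extraction and the collinearity screen.

#' Extract predictor values for each plot
#'
#' For every plot disk (cells whose centres fall within the plot radius,
#' closed disk): means of elevation, slope, TRI and TPI; the modal aspect
#' quadrant (ties broken in N, E, S, W order; plots dominated by flat cells
#' are flagged); cover areas in square metres per class (cell count times
#' cell area); and centroid distances to the fence boundary (minimum over
#' boundary segments) and to the water point.
#'
#' @param plots data.frame from [sample_plots()].
#' @param landscape an `rspf_landscape`.
#' @param terrain optional precomputed [compute_terrain()] grids.
#' @param cover_as_percent report cover as percent of the disk cell area
#'   instead of square metres (default FALSE, matching the m2 convention).
#' @return data.frame with columns `plot_id, x, y, elevation, slope, aspect,
#'   TRI, TPI, wood, shrub, grasslands, feedwater, rock, distfence,
#'   distfeed, aspect_flat`.
#' @export
extract_predictors <- function(plots, landscape, terrain = NULL,
                               cover_as_percent = FALSE) {
  if (is.null(terrain))
    terrain <- compute_terrain(landscape$dem, landscape$cell_size)
  cells <- grid_cells(landscape)
  cell_area <- landscape$cell_size^2
  cls <- cover_classes()
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    d2 <- (cells$x - plots$x[i])^2 + (cells$y - plots$y[i])^2
    idx <- cells$cell[d2 <= plots$radius[i]^2]
    if (length(idx) == 0L)
      stop("plot ", plots$plot_id[i], " contains no cell centres")
    asp <- terrain$aspect[idx]
    modal <- which.max(tabulate(asp, nbins = 4L))
    cov <- landscape$cover[idx]
    areas <- tabulate(cov[!is.na(cov)], nbins = length(cls)) * cell_area
    if (cover_as_percent) areas <- 100 * areas / (length(idx) * cell_area)
    out <- data.frame(
      plot_id = plots$plot_id[i], x = plots$x[i], y = plots$y[i],
      elevation = mean(landscape$dem[idx]),
      slope = mean(terrain$slope[idx]),
      aspect = factor(c("N", "E", "S", "W")[modal],
                      levels = c("N", "E", "S", "W")),
      TRI = mean(terrain$tri[idx]),
      TPI = mean(terrain$tpi[idx]))
    for (k in seq_along(cls)) out[[cls[k]]] <- areas[k]
    out$aspect_flat <- mean(terrain$aspect_flat[idx]) > 0.5
    out
  })
  tab <- do.call(rbind, rows)
  tab$distfence <- dist_to_boundary(cbind(plots$x, plots$y), landscape$fence)
  tab$distfeed <- as.numeric(sqrt((plots$x - landscape$water_point["x"])^2 +
                                  (plots$y - landscape$water_point["y"])^2))
  ord <- c("plot_id", "x", "y", "elevation", "slope", "aspect", "TRI", "TPI",
           "wood", "shrub", "grasslands", "feedwater", "rock",
           "distfence", "distfeed", "aspect_flat")
  tab[, ord]
}

#' Screen predictors for pairwise collinearity
#'
#' Pearson correlations over plots; pairs with |r| strictly above the
#' threshold are flagged. Zero-variance predictors have undefined r and are
#' reported separately as degenerate.
#'
#' @param table plot predictor table.
#' @param predictors character vector of numeric predictor columns.
#' @param threshold flagging threshold on |r| (default 0.60, strict).
#' @return list with `r` (correlation matrix), `flagged` (data.frame
#'   `var_a, var_b, r`), and `degenerate` (zero-variance predictor names).
#' @export
screen_collinearity <- function(table, predictors, threshold = 0.60) {
  stopifnot(nrow(table) >= 3L)
  miss <- setdiff(predictors, names(table))
  if (length(miss)) stop("unknown predictors: ", paste(miss, collapse = ", "))
  X <- table[, predictors, drop = FALSE]
  if (!all(vapply(X, is.numeric, logical(1L))))
    stop("collinearity screen requires numeric predictors")
  sds <- vapply(X, stats::sd, numeric(1L))
  degenerate <- predictors[sds == 0]
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  flag <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  flagged <- data.frame(var_a = rownames(r)[flag[, 1L]],
                        var_b = colnames(r)[flag[, 2L]],
                        r = r[flag])
  flagged <- flagged[!is.na(flagged$r), , drop = FALSE]
  list(r = r, flagged = flagged, degenerate = degenerate)
}
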