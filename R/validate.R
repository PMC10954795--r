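# Hold-out validation, quartile use classification, class marginal means,
# marginal-effect curves and the prediction raster.

#' Binned Spearman validation of a fitted RSPF
#'
#' Plots are sorted by predicted probability of use (ties broken by plot
#' id) and partitioned into `n_classes` contiguous classes of near-equal
#' size (sizes differ by at most one; remainder plots go to the
#' lowest-ranked classes). Class rank 1 is the lowest predicted use. The
#' validation fix counts are summed per class and the statistic is the
#' Spearman rank correlation between class rank and the size-adjusted class
#' count (summed count divided by the number of plots in the class): counts
#' that increase with class rank signal successful prediction. The size
#' adjustment only matters when the plot count is not divisible by
#' `n_classes`; without it the one-plot size differences would bias the
#' statistic away from zero under uniform use.
#'
#' @param predicted per-plot predicted probabilities ([predict_use()]).
#' @param val_counts per-plot validation-set fix counts.
#' @param n_classes number of classes (default 20).
#' @param plot_ids optional plot ids for tie-breaking.
#' @return list with `rs` (NA with a note when all validation counts are
#'   zero) and `class_table` (data.frame `class, n_plots, val_sum,
#'   val_mean`).
#' @export
spearman_validation <- function(predicted, val_counts, n_classes = 20L,
                                plot_ids = seq_along(predicted)) {
  n <- length(predicted)
  stopifnot(length(val_counts) == n, n >= n_classes)
  ord <- order(predicted, plot_ids)
  sizes <- rep(floor(n / n_classes), n_classes)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cls <- rep(seq_len(n_classes), times = sizes)
  sums <- as.numeric(tapply(val_counts[ord], cls, sum))
  tab <- data.frame(class = seq_len(n_classes), n_plots = as.integer(sizes),
                    val_sum = sums, val_mean = sums / sizes)
  if (all(val_counts == 0)) {
    return(list(rs = NA_real_, class_table = tab,
                note = "all validation counts zero; rs undefined"))
  }
  rs <- suppressWarnings(stats::cor(seq_len(n_classes), tab$val_mean,
                                    method = "spearman"))
  list(rs = rs, class_table = tab)
}

#' Classify plots into quartile probability-of-use classes
#'
#' Rank-based quartiles of the predicted-use distribution: low, moderate,
#' high, very_high in ascending predicted use. Ties and remainder plots are
#' assigned to the lower class, so class sizes are within one of n/4 (194
#' plots give sizes 48 and 49). The classification depends only on the
#' ranking, so it is invariant to strictly monotone transforms of the
#' predictions.
#'
#' @param predicted per-plot predicted probabilities.
#' @param plot_ids optional ids for tie-breaking.
#' @return data.frame `plot_id, predicted, class` (ordered factor low <
#'   moderate < high < very_high), with attribute `boundaries` (upper
#'   predicted value per class).
#' @export
classify_quartiles <- function(predicted, plot_ids = seq_along(predicted)) {
  n <- length(predicted)
  if (n < 4L) stop("need at least 4 plots to form quartile classes")
  if (length(unique(predicted)) == 1L)
    warning("all predictions identical; classes assigned by plot order")
  labs <- c("low", "moderate", "high", "very_high")
  ord <- order(predicted, plot_ids)
  sizes <- rep(floor(n / 4), 4L)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cls_sorted <- rep(seq_len(4L), times = sizes)
  cls <- integer(n)
  cls[ord] <- cls_sorted
  out <- data.frame(plot_id = plot_ids, predicted = predicted,
                    class = factor(labs[cls], levels = labs, ordered = TRUE))
  attr(out, "boundaries") <- tapply(predicted[ord], cls_sorted, max)
  out
}

#' Estimated marginal means of predictors by use class
#'
#' For each predictor, fits a one-way linear model with class as a fixed
#' effect, reports the estimated marginal mean and pooled-variance standard
#' error per class, and summarizes pairwise class differences (Tukey-
#' adjusted by default, alpha = 0.05) as compact letters: classes sharing a
#' letter are not significantly different. Classes with a single plot are
#' excluded from the letter display and flagged.
#'
#' @param classes data.frame from [classify_quartiles()].
#' @param table plot predictor table (matched to `classes` by `plot_id`).
#' @param predictors columns to summarize (default distfeed, distfence,
#'   elevation).
#' @param adjust "tukey" (default), "bonferroni" or "none".
#' @return data.frame `class, predictor, emmean, se, n, letter`.
#' @export
class_emmeans <- function(classes, table,
                          predictors = c("distfeed", "distfence", "elevation"),
                          adjust = c("tukey", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  m <- merge(classes, table, by = "plot_id")
  m$class <- factor(as.character(m$class),
                    levels = levels(classes$class))  # unordered for contrasts
  tab_n <- table(m$class)
  small <- names(tab_n)[tab_n < 2L]
  res <- lapply(predictors, function(p) {
    d <- m[, c("class", p)]
    names(d)[2L] <- ".y"
    fit <- stats::lm(.y ~ class, data = d)
    em <- as.data.frame(emmeans::emmeans(fit, "class"))
    letters <- rep(NA_character_, nrow(em))
    use <- !(em$class %in% small)
    if (sum(use) >= 2L && stats::sd(d$.y) > 0) {
      glt <- multcomp::glht(fit, linfct = multcomp::mcp(class = "Tukey"))
      test <- switch(adjust,
                     tukey = multcomp::adjusted("single-step"),
                     bonferroni = multcomp::adjusted("bonferroni"),
                     none = multcomp::adjusted("none"))
      cl <- multcomp::cld(summary(glt, test = test))
      letters[match(names(cl$mcletters$Letters), em$class)] <-
        unname(cl$mcletters$Letters)
    } else if (stats::sd(d$.y) == 0) {
      letters[use] <- "a"  # identical values: one group
    }
    data.frame(class = em$class, predictor = p, emmean = em$emmean,
               se = em$SE, n = as.integer(tab_n[as.character(em$class)]),
               letter = letters)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (length(small))
    attr(out, "flagged_small_classes") <- small
  out
}

#' Marginal-effect curve of one predictor
#'
#' Predicted relative use along a grid of one predictor, holding all other
#' model terms at their development-set means (quadratic terms move with
#' their base predictor). When the model holds both the linear and
#' quadratic form, the turning point -b1 / (2 b2) is reported. Grid values
#' outside the observed predictor range are flagged as extrapolation.
#'
#' @param fit a converged `rspf_fit`.
#' @param variable base predictor name in the fit.
#' @param table development plot predictor table (for means and ranges).
#' @param grid numeric grid; default 100 points over the observed range.
#' @return data.frame `value, prediction` (prediction normalized to sum to
#'   1 over the grid); attributes `turning_point` (if quadratic) and
#'   `extrapolated` (logical vector).
#' @export
marginal_effects <- function(fit, variable, table, grid = NULL) {
  base_terms <- setdiff(fit$terms, "aspect")
  bases <- unique(sub("2$", "", base_terms))
  if (!(variable %in% bases))
    stop("'", variable, "' is not a predictor of this fit")
  obs <- range(table[[variable]])
  if (is.null(grid)) grid <- seq(obs[1L], obs[2L], length.out = 100L)
  nd <- table[rep(1L, length(grid)), , drop = FALSE]
  for (b in bases) nd[[b]] <- mean(table[[b]])
  if ("aspect" %in% fit$terms) {
    lv <- names(which.max(table(table$aspect)))
    nd$aspect <- factor(lv, levels = c("N", "E", "S", "W"))
  }
  nd[[variable]] <- grid
  pred <- predict_use(fit, nd)
  out <- data.frame(value = grid, prediction = pred)
  quad <- paste0(variable, "2")
  if (quad %in% fit$terms) {
    b1 <- fit$beta[variable]; b2 <- fit$beta[quad]
    attr(out, "turning_point") <- unname(-b1 / (2 * b2))
  }
  attr(out, "extrapolated") <- grid < obs[1L] | grid > obs[2L]
  if (any(attr(out, "extrapolated")))
    warning("grid extends outside the observed range of ", variable)
  out
}

#' Render the predicted probability-of-use raster
#'
#' Evaluates the fitted model on a grid of cells at the requested
#' resolution: each in-fence cell centre is treated like a plot centroid
#' (predictors over a disk of `plot_radius`), the normalized prediction is
#' the cell's relative probability of use, and a quartile class raster is
#' derived alongside.
#'
#' @param fit a converged `rspf_fit`.
#' @param landscape an `rspf_landscape`.
#' @param resolution output cell size in metres (default 25).
#' @param plot_radius predictor-extraction radius in metres (default 25,
#'   the plot radius the model was built on).
#' @param terrain optional precomputed terrain grids.
#' @return list with `prob` (matrix, NA outside the fence, in-fence values
#'   sum to 1), `class` (integer matrix 1..4, low to very_high), `xmin`,
#'   `ymin`, `cell_size`.
#' @export
render_use_map <- function(fit, landscape, resolution = 25, plot_radius = 25,
                           terrain = NULL) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  ext_x <- ncol(landscape$dem) * landscape$cell_size
  ext_y <- nrow(landscape$dem) * landscape$cell_size
  if (resolution > min(ext_x, ext_y))
    stop("resolution coarser than the landscape extent")
  nx <- floor(ext_x / resolution); ny <- floor(ext_y / resolution)
  col <- rep(seq_len(nx), each = ny)
  row <- rep(seq_len(ny), times = nx)
  cx <- landscape$xmin + (col - 0.5) * resolution
  cy <- landscape$ymin + (ny - row + 0.5) * resolution
  inside <- point_in_polygon(cbind(cx, cy), landscape$fence)
  prob <- matrix(NA_real_, ny, nx)
  clsm <- matrix(NA_integer_, ny, nx)
  if (any(inside)) {
    pseudo <- data.frame(plot_id = which(inside), x = cx[inside],
                         y = cy[inside], radius = plot_radius)
    tab <- extract_predictors(pseudo, landscape, terrain)
    p <- predict_use(fit, tab)
    prob[cbind(row[inside], col[inside])] <- p
    cl <- classify_quartiles(p)
    clsm[cbind(row[inside], col[inside])] <- as.integer(cl$class)
  }
  list(prob = prob, class = clsm, xmin = landscape$xmin,
       ymin = landscape$ymin, cell_size = resolution)
}
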