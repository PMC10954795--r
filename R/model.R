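# Count-based RSPF modelling: candidate enumeration, negative-binomial
# fitting with a log(total) offset, AIC ranking and bootstrap confidence
# intervals.
#
# The fitted model is ln E[l_i] = ln(total) + b0 + b1 X1 + ... + bp Xp with
# negative-binomial errors, so exp(linear predictor without offset) is the
# relative frequency of use of plot i (a discrete utilization distribution).

#' Canonical identifier of a model specification
#'
#' @param terms character vector of term names.
#' @return string id (terms sorted, joined by "+").
#' @export
spec_id <- function(terms) paste(sort(terms), collapse = "+")

#' Named final-model presets
#'
#' `final_full`: feedwater + elevation + elevation^2 + distfeed +
#' distfeed^2 + distfence + distfence^2 + TPI. `final_summer` is the same
#' model without the quadratic distance-to-feed term (in summer the
#' distance-to-water response is linear).
#'
#' @param name "final_full" or "final_summer".
#' @return character vector of terms.
#' @export
rspf_preset <- function(name = c("final_full", "final_summer")) {
  name <- match.arg(name)
  switch(name,
    final_full = c("feedwater", "elevation", "elevation2", "distfeed",
                   "distfeed2", "distfence", "distfence2", "TPI"),
    final_summer = c("feedwater", "elevation", "elevation2", "distfeed",
                     "distfence", "distfence2", "TPI"))
}

# drop a base predictor (and its quadratic) from a term vector
drop_base <- function(terms, base) setdiff(terms, c(base, paste0(base, "2")))

#' Enumerate the a priori candidate model set
#'
#' All subsets of 1..`max_base` base predictors; for each subset, one
#' variant per subset of its quadratic-eligible members with the squared
#' term added (a quadratic term always accompanies its linear form). Any
#' spec containing a flagged collinear pair is replaced by the two swap
#' variants in which one member (with its quadratic) is dropped; the result
#' is de-duplicated on the canonical id.
#'
#' @param predictors character vector of base predictor names.
#' @param quadratic_eligible predictors that may carry a squared term.
#' @param collinear_pairs optional data.frame with columns `var_a`, `var_b`
#'   (e.g. the `flagged` component of [screen_collinearity()]).
#' @param max_base maximum number of base predictors per model (default 5).
#' @return named list of term vectors, names = canonical ids.
#' @export
enumerate_candidates <- function(predictors,
                                 quadratic_eligible = c("elevation", "slope",
                                                        "distfeed",
                                                        "distfence"),
                                 collinear_pairs = NULL,
                                 max_base = 5L) {
  stopifnot(length(predictors) >= 1L)
  specs <- list()
  for (k in seq_len(min(max_base, length(predictors)))) {
    subs <- utils::combn(predictors, k, simplify = FALSE)
    for (base in subs) {
      qe <- intersect(base, quadratic_eligible)
      qsets <- list(character(0))
      if (length(qe) > 0L)
        qsets <- c(qsets, unlist(lapply(seq_along(qe), function(j)
          utils::combn(qe, j, simplify = FALSE)), recursive = FALSE))
      for (q in qsets)
        specs[[length(specs) + 1L]] <-
          if (length(q)) c(base, paste0(q, "2")) else base
    }
  }
  if (!is.null(collinear_pairs) && nrow(collinear_pairs) > 0L) {
    expand <- function(terms) {
      for (i in seq_len(nrow(collinear_pairs))) {
        a <- collinear_pairs$var_a[i]; b <- collinear_pairs$var_b[i]
        if (a %in% terms && b %in% terms)
          return(c(expand(drop_base(terms, a)), expand(drop_base(terms, b))))
      }
      list(terms)
    }
    specs <- unlist(lapply(specs, expand), recursive = FALSE)
    specs <- specs[vapply(specs, length, 1L) > 0L]
  }
  ids <- vapply(specs, spec_id, character(1L))
  specs <- specs[!duplicated(ids)]
  names(specs) <- ids[!duplicated(ids)]
  specs
}

# model design for a term vector: numeric columns (quadratics resolved) and
# the aspect factor when requested
nb_design <- function(terms, table) {
  num_terms <- setdiff(terms, "aspect")
  dd <- if (length(num_terms) > 0L)
    as.data.frame(resolve_terms(num_terms, table))
  else
    data.frame(row.names = seq_len(nrow(table)))
  if ("aspect" %in% terms)
    dd$aspect <- factor(table$aspect, levels = c("N", "E", "S", "W"))
  dd
}

#' Fit a negative-binomial RSPF model
#'
#' Maximum-likelihood negative-binomial regression (log link, dispersion
#' theta estimated jointly via [MASS::glm.nb()]) of plot counts on the
#' model terms, with the fixed offset ln(total) that converts counts to
#' relative frequencies. Numeric predictors are standardized internally for
#' a stable fit; reported coefficients and standard errors are
#' back-transformed to the original predictor scales. AIC counts the
#' intercept, every slope and theta.
#'
#' @param terms character vector of term names; a trailing `2` denotes the
#'   square of the base column, and `aspect` enters as a factor. Empty
#'   vector fits the intercept-only model.
#' @param table plot predictor table with a count column.
#' @param count_col name of the count column (default "dev_count").
#' @param total offset total (number of locations in the study area for the
#'   data set being fitted); defaults to the sum of the count column.
#' @return object of class `rspf_fit`: terms, id, beta, se, wald_p (on the
#'   original scales), theta, aic, loglik, converged, n_plots, total, and
#'   the underlying glm fit.
#' @export
fit_nb_rspf <- function(terms, table, count_col = "dev_count", total = NULL) {
  li <- table[[count_col]]
  if (is.null(li)) stop("count column '", count_col, "' not found")
  if (any(li < 0) || any(li != round(li))) stop("counts must be nonnegative integers")
  if (is.null(total)) total <- sum(li)
  if (total <= 0) stop("total must be positive")
  if (nrow(table) < length(terms) + 2L)
    stop("need at least terms + 2 plots to fit")

  dd <- nb_design(terms, table)
  num_cols <- names(dd)[vapply(dd, is.numeric, logical(1L))]
  ctr <- vapply(dd[num_cols], mean, numeric(1L))
  scl <- vapply(dd[num_cols], stats::sd, numeric(1L))
  scl[scl == 0] <- 1
  ddz <- dd
  for (j in num_cols) ddz[[j]] <- (dd[[j]] - ctr[j]) / scl[j]
  ddz$.li <- li
  ddz$.off <- rep(log(total), nrow(table))
  rhs <- if (ncol(dd) > 0L) paste(names(dd), collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".li ~", rhs, "+ offset(.off)"))

  n_warn <- 0L
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(fml, data = ddz),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)

  out <- list(terms = terms, id = spec_id(terms), count_col = count_col,
              total = total, n_plots = nrow(table),
              center = ctr, scale = scl, n_warnings = n_warn)
  class(out) <- "rspf_fit"
  if (inherits(fit, "error")) {
    out$converged <- FALSE
    out$diagnostics <- conditionMessage(fit)
    out$beta <- out$se <- out$wald_p <- NULL
    out$theta <- out$aic <- out$loglik <- NA_real_
    return(out)
  }

  b_std <- stats::coef(fit)
  if (any(is.na(b_std))) {
    out$converged <- FALSE
    out$diagnostics <- "aliased coefficients (degenerate or separated design)"
    out$theta <- out$aic <- out$loglik <- NA_real_
    return(out)
  }
  V_std <- stats::vcov(fit)
  cn <- names(b_std)
  # linear back-transform to original predictor scales
  A <- diag(length(cn))
  dimnames(A) <- list(cn, cn)
  for (j in num_cols) {
    A[j, j] <- 1 / scl[j]
    A["(Intercept)", j] <- -ctr[j] / scl[j]
  }
  beta <- drop(A %*% b_std)
  names(beta) <- cn
  V <- A %*% V_std %*% t(A)
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- cn

  out$glm <- fit
  out$beta <- beta
  out$se <- se
  out$wald_p <- 2 * stats::pnorm(-abs(beta / se))
  out$theta <- fit$theta
  out$loglik <- as.numeric(stats::logLik(fit))
  out$aic <- stats::AIC(fit)
  out$converged <- isTRUE(fit$converged)
  out
}

#' @export
print.rspf_fit <- function(x, ...) {
  cat("Negative-binomial RSPF fit:", if (length(x$terms)) x$id else
      "(intercept only)", "\n")
  if (!isTRUE(x$converged)) {
    cat("  NOT converged", if (!is.null(x$diagnostics))
        paste0(" (", x$diagnostics, ")"), "\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d plots, total = %d, theta = %.3g, AIC = %.1f\n",
              x$n_plots, x$total, x$theta, x$aic))
  print(data.frame(estimate = signif(x$beta, 4), se = signif(x$se, 3),
                   p = signif(x$wald_p, 3)))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Ascending AIC over converged fits; ties broken by fewer terms, then by
#' canonical id.
#'
#' @param fits list of `rspf_fit` objects.
#' @param k shortlist length (default 10).
#' @return data.frame `rank, id, n_terms, aic, theta, delta_aic`, at most
#'   `k` rows.
#' @export
rank_by_aic <- function(fits, k = 10L) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic),
               logical(1L))
  if (!any(ok)) stop("no converged fits to rank")
  fits <- fits[ok]
  df <- data.frame(
    id = vapply(fits, function(f) f$id, character(1L)),
    n_terms = vapply(fits, function(f) length(f$terms), integer(1L)),
    aic = vapply(fits, function(f) f$aic, numeric(1L)),
    theta = vapply(fits, function(f) f$theta, numeric(1L)),
    stringsAsFactors = FALSE)
  df <- df[order(df$aic, df$n_terms, df$id), , drop = FALSE]
  df <- utils::head(df, k)
  df$delta_aic <- df$aic - df$aic[1L]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "id", "n_terms", "aic", "delta_aic", "theta")]
}

#' Bootstrap percentile confidence intervals for RSPF coefficients
#'
#' Resamples plots (the model's observational unit) with replacement,
#' refits per replicate, and reports percentile intervals. A coefficient is
#' significant when its interval excludes zero. Replicates that fail to
#' converge are dropped and counted; above 20% failures the intervals are
#' flagged unreliable.
#'
#' @param fit a converged `rspf_fit`.
#' @param table the plot predictor table the fit used.
#' @param B replicates (default 1000).
#' @param level interval level (default 0.90).
#' @param seed integer seed.
#' @return data.frame per coefficient: `term, estimate, lower, upper,
#'   significant`; attributes `B`, `n_failed`, `unreliable`, `level`.
#' @export
bootstrap_cis <- function(fit, table, B = 1000L, level = 0.90, seed = NULL) {
  stopifnot(inherits(fit, "rspf_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge on the full data")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  draws <- matrix(NA_real_, B, length(fit$beta),
                  dimnames = list(NULL, names(fit$beta)))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rf <- fit_nb_rspf(fit$terms, table[idx, , drop = FALSE],
                      count_col = fit$count_col, total = fit$total)
    if (isTRUE(rf$converged) && length(rf$beta) == length(fit$beta)) {
      draws[b, ] <- rf$beta
    } else {
      failed <- failed + 1L
    }
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                    lower = qs[1L, ], upper = qs[2L, ])
  out$significant <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  attr(out, "B") <- B
  attr(out, "n_failed") <- failed
  attr(out, "unreliable") <- failed > 0.2 * B
  attr(out, "level") <- level
  out
}

#' Percent change in expected use per unit predictor increase
#'
#' The odds-ratio style transform of an NB log-link coefficient:
#' (exp(beta) - 1) * 100.
#'
#' @param beta coefficient value(s).
#' @return percent change, same length as `beta`.
#' @export
odds_ratio_percent <- function(beta) (exp(beta) - 1) * 100

# linear predictor (without offset) of a fit on new rows, original scales
linpred <- function(fit, table) {
  eta <- rep(unname(fit$beta["(Intercept)"]), nrow(table))
  num_terms <- setdiff(fit$terms, "aspect")
  if (length(num_terms) > 0L) {
    X <- resolve_terms(num_terms, table)
    eta <- eta + drop(X %*% fit$beta[num_terms])
  }
  if ("aspect" %in% fit$terms) {
    f <- factor(table$aspect, levels = c("N", "E", "S", "W"))
    for (lev in c("E", "S", "W")) {
      cf <- fit$beta[paste0("aspect", lev)]
      if (!is.na(cf)) eta <- eta + cf * (f == lev)
    }
  }
  eta
}

#' Predicted relative probability of use per plot
#'
#' exp(linear predictor without offset), renormalized to sum to 1 over the
#' supplied plots: the fitted discrete utilization distribution.
#'
#' @param fit a converged `rspf_fit`.
#' @param table plot predictor table containing all model terms.
#' @return numeric vector of probabilities summing to 1.
#' @export
predict_use <- function(fit, table) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  eta <- linpred(fit, table)
  eta <- eta - max(eta)
  w <- exp(eta)
  w / sum(w)
}
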