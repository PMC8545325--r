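#' Time-point-count guard for longitudinal statistics
#'
#' Longitudinal correlation and regression statistics overestimate on very
#' short series, so every operation in this module checks the series
#' length: fewer than three time points is an error, three or four yields a
#' warning (analysis proceeds), five or more is fine.
#'
#' @param T_ number of time points.
#' @return "error", "warn" or "ok".
#' @export
guard_time_points <- function(T_) {
  if (!(is.numeric(T_) && length(T_) == 1 && is.finite(T_))) {
    stop("T_ must be a single number")
  }
  if (T_ < 3) return("error")
  if (T_ < 5) return("warn")
  "ok"
}

# enforce the guard, emitting the documented error/warning
assert_time_points <- function(T_, where) {
  state <- guard_time_points(T_)
  if (state == "error") {
    stop(where, ": fewer than three time points detected; analysis aborted")
  }
  if (state == "warn") {
    warning(where, ": fewer than five time points detected; ",
            "statistics may be overestimated")
  }
  state
}

#' Construct a miRNA-mRNA pair series
#'
#' Two aligned value trajectories over the same ordered time points.
#'
#' @param mirna_label,mrna_label gene labels.
#' @param x miRNA value vector.
#' @param y mRNA value vector (same length).
#' @param time_points optional labels (defaults to seq_along(x)).
#' @return object of class `PairSeries`.
#' @export
pair_series <- function(mirna_label, mrna_label, x, y, time_points = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("pair series values must be finite")
  }
  if (guard_time_points(length(x)) == "error") {
    stop("pair_series: fewer than three time points detected; ",
         "analysis aborted")
  }
  tps <- time_points %||% as.character(seq_along(x))
  structure(list(mirna_label = mirna_label, mrna_label = mrna_label,
                 x = as.numeric(x), y = as.numeric(y), time_points = tps),
            class = "PairSeries")
}

#' Extract a pair series from a time-course table
#' @param de a `TimeCourseDE`.
#' @param mirna,mrna gene labels.
#' @param value "log2fc" or "avg_expression".
#' @param expression optional expression matrix.
#' @return a [pair_series()] object.
#' @export
pair_series_from_de <- function(de, mirna, mrna, value = "log2fc",
                                expression = NULL) {
  x <- value_matrix(de, mirna, "miRNA", value, expression)[1, ]
  y <- value_matrix(de, mrna, "mRNA", value, expression)[1, ]
  pair_series(mirna, mrna, x, y, de_time_points(de))
}

#' Sample cross-correlation of a miRNA-mRNA pair
#'
#' ccf(l) = sum_t (x_t - mean(x)) (y_{t+l} - mean(y)) / (T * sx * sy),
#' summed over the overlapping indices, with full-series means and
#' population (divisor-T) standard deviations — the classical sample-CCF
#' normalization. Under this constant ccf(0) equals the Pearson correlation
#' exactly. Sign convention: a positive lag means the mRNA series trails
#' (is shifted later than) the miRNA series.
#'
#' @param pair a `PairSeries`.
#' @param max_lag maximum |lag| (must be <= T - 2).
#' @return data.frame `lag`, `ccf` for lags -max_lag..max_lag.
#' @export
cross_correlation <- function(pair, max_lag = NULL) {
  x <- pair$x; y <- pair$y
  T_ <- length(x)
  assert_time_points(T_, "cross_correlation")
  max_lag <- max_lag %||% (T_ - 2)
  if (max_lag > T_ - 2) stop("max_lag must be <= T - 2")
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0) stop("zero-variance series; ccf undefined")
  xc <- x - mean(x); yc <- y - mean(y)
  lags <- seq(-max_lag, max_lag)
  vals <- vapply(lags, function(l) {
    t_idx <- seq(max(1, 1 - l), min(T_, T_ - l))
    sum(xc[t_idx] * yc[t_idx + l]) / (T_ * sx * sy)
  }, numeric(1))
  data.frame(lag = lags, ccf = vals)
}

#' Scaled spline trajectories of a pair
#'
#' Standardizes both series (mean 0, sd 1; sample sd) and interpolates each
#' through a natural cubic spline onto a uniform grid, for the classic
#' two-curve pair display. The correlation of the unscaled data is returned
#' rounded to 2 decimal places as the plot annotation.
#'
#' @param pair a `PairSeries`.
#' @param points number of grid samples (default 100).
#' @param out optional PNG path.
#' @return list with `grid`, `x_curve`, `y_curve`, `x_std`, `y_std`,
#'   `x_fun`/`y_fun` (the spline interpolants), `correlation` (full
#'   precision) and `annotation` (2-decimal string).
#' @export
scaled_spline_series <- function(pair, points = 100, out = NULL) {
  T_ <- length(pair$x)
  assert_time_points(T_, "scaled_spline_series")
  xs <- as.numeric(scale(pair$x))
  ys <- as.numeric(scale(pair$y))
  tidx <- seq_len(T_)
  fx <- splinefun(tidx, xs, method = "natural")
  fy <- splinefun(tidx, ys, method = "natural")
  grid <- seq(1, T_, length.out = points)
  rho <- cor(pair$x, pair$y)
  res <- list(grid = grid, x_curve = fx(grid), y_curve = fy(grid),
              x_std = xs, y_std = ys, x_fun = fx, y_fun = fy,
              correlation = rho,
              annotation = sprintf("%.2f", round(rho, 2)))
  if (!is.null(out)) {
    png(out, width = 640, height = 440)
    on.exit(dev.off())
    matplot(grid, cbind(res$x_curve, res$y_curve), type = "l", lty = 1,
            col = c("blue", "red"), xlab = "time index",
            ylab = "scaled value",
            main = paste0(pair$mirna_label, " / ", pair$mrna_label,
                          "  (cor = ", res$annotation, ")"))
    legend("topright", legend = c(pair$mirna_label, pair$mrna_label),
           col = c("blue", "red"), lty = 1, bty = "n")
  }
  res
}

#' Predict one gene's trajectory from its binding partners
#'
#' Ordinary least squares with intercept of a selected gene's trajectory on
#' any number of its predicted binding partners; reports the coefficient
#' table, R-squared, the overall F-test p-value and the fitted trajectory.
#'
#' @param response numeric response trajectory.
#' @param predictors named list (or data.frame) of predictor trajectories.
#' @param response_label label for reporting.
#' @return object of class `RegressionFit`.
#' @export
regress_multi <- function(response, predictors, response_label = "response") {
  T_ <- length(response)
  assert_time_points(T_, "regress_multi")
  pred <- as.data.frame(predictors)
  if (nrow(pred) != T_) stop("predictor length does not match response")
  p <- ncol(pred)
  if (p > T_ - 2) {
    stop("too many predictors (", p, ") for ", T_,
         " time points (need p <= T - 2)")
  }
  if (p > 1) {
    cm <- suppressWarnings(cor(pred))
    cm[is.na(cm)] <- 0  # constant predictors are caught by the rank check
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        if (abs(cm[i, j]) > 1 - 1e-10) {
          stop("collinear predictors: ", colnames(pred)[i], " and ",
               colnames(pred)[j])
        }
      }
    }
  }
  X <- cbind(1, as.matrix(pred))
  if (qr(X)$rank < ncol(X)) stop("collinear predictors: design is rank-deficient")
  dat <- data.frame(.response = response, pred, check.names = FALSE)
  fit <- lm(.response ~ ., data = dat)
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p_value <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  rss <- sum(fit$residuals^2)
  tss <- sum((response - mean(response))^2)
  if (rss < 1e-24 * max(tss, 1)) p_value <- 0  # numerically exact fit
  structure(list(response_label = response_label,
                 predictor_labels = colnames(pred),
                 coefficients = sm$coefficients,
                 r_squared = sm$r.squared,
                 p_value = p_value,
                 fitted_trajectory = unname(fit$fitted.values),
                 lm = fit),
            class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat("RegressionFit: ", x$response_label, " ~ ",
      paste(x$predictor_labels, collapse = " + "),
      sprintf("  (R^2 = %.3f, p = %.3g)\n", x$r_squared, x$p_value),
      sep = "")
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  OR = %.2f, 95%% CI [%.2f, %.2f]%s\n",
                round(x$odds_ratio, 2), round(x$ci95[1], 2),
                round(x$ci95[2], 2),
                if (isTRUE(x$exact_fit)) " (exact fit)" else ""))
  }
  invisible(x)
}

#' Pair regression with odds ratio and Wald 95% CI
#'
#' Single-predictor OLS of the mRNA trajectory on the miRNA trajectory.
#' The odds ratio is exp(slope) — an effect-size reading of the regression
#' coefficient for pair association — with Wald 95% confidence interval
#' exp(slope +- 1.96 * SE). A numerically exact fit has SE 0, so the CI
#' collapses onto the odds ratio; this is flagged `exact_fit`. Values are
#' held at full precision; rounding to 2 decimals happens only at display
#' time.
#'
#' @param pair a `PairSeries`.
#' @return a `RegressionFit` with `odds_ratio`, `ci95`, `slope`, `slope_se`
#'   and `exact_fit` fields added.
#' @export
pair_odds_ratio <- function(pair) {
  T_ <- length(pair$x)
  assert_time_points(T_, "pair_odds_ratio")
  if (sd(pair$x) == 0) stop("zero-variance miRNA trajectory; cannot regress")
  # the guard already ran here; silence its duplicate inside regress_multi
  fit <- suppressWarnings(
    regress_multi(pair$y, stats::setNames(list(pair$x), pair$mirna_label),
                  response_label = pair$mrna_label))
  slope <- fit$coefficients[2, "Estimate"]
  se <- fit$coefficients[2, "Std. Error"]
  exact <- !is.finite(se) || se < 1e-12
  if (exact) se <- 0
  fit$slope <- unname(slope)
  fit$slope_se <- unname(se)
  fit$odds_ratio <- exp(unname(slope))
  fit$ci95 <- exp(unname(slope) + c(-1, 1) * 1.96 * se)
  fit$exact_fit <- exact
  fit
}

#' Order interacting pairs by descending correlation
#'
#' Sorts all available pairs by decreasing correlation (ties broken by
#' (miRNA, mRNA) lexicographic order) and returns, with the order, a
#' per-pair trajectory matrix (miRNA then mRNA blocks of time-point
#' columns) for heatmap rendering.
#'
#' @param x an `InteractionMatrix`, or a filtered network (igraph) together
#'   with `de`.
#' @param de required when `x` is a network: the `TimeCourseDE` supplying
#'   trajectories.
#' @param value,expression trajectory source when `x` is a network.
#' @return list with `order` (data.frame `mirna`, `mrna`, `corr`) and
#'   `heatmap` (matrix, one row per pair).
#' @export
order_pairs_heatmap <- function(x, de = NULL, value = "log2fc",
                                expression = NULL) {
  if (inherits(x, "InteractionMatrix")) {
    idx <- which(x$available, arr.ind = TRUE)
    pairs <- data.frame(mirna = x$mirnas[idx[, 1]],
                        mrna = x$mrnas[idx[, 2]],
                        corr = x$corr[idx], stringsAsFactors = FALSE)
    X <- x$traj$mirna; Y <- x$traj$mrna
    tps <- x$time_points
  } else if (inherits(x, "igraph")) {
    if (is.null(de)) stop("a network input needs the DE table (de)")
    pairs <- network_edges(x)[, c("mirna", "mrna", "corr")]
    tps <- de_time_points(de)
    X <- value_matrix(de, unique(pairs$mirna), "miRNA", value, expression)
    Y <- value_matrix(de, unique(pairs$mrna), "mRNA", value, expression)
  } else {
    stop("x must be an InteractionMatrix or an igraph network")
  }
  if (!nrow(pairs)) {
    warning("no pairs to order")
    return(list(order = pairs, heatmap = matrix(numeric(0), 0, 0)))
  }
  pairs <- pairs[order(-pairs$corr, pairs$mirna, pairs$mrna), , drop = FALSE]
  rownames(pairs) <- NULL
  hm <- matrix(NA_real_, nrow(pairs), 2 * length(tps),
               dimnames = list(paste(pairs$mirna, pairs$mrna, sep = " | "),
                               c(paste0("miRNA_", tps),
                                 paste0("mRNA_", tps))))
  for (r in seq_len(nrow(pairs))) {
    hm[r, ] <- c(X[pairs$mirna[r], ], Y[pairs$mrna[r], ])
  }
  list(order = pairs, heatmap = hm)
}
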