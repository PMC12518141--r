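# Anisotropic correlation functions of the rejection field, 1/e correlation
# lengths, growth exponents, scaling collapse, and bootstrap confidence
# intervals.

#' Rejection-field correlation function along one axis
#'
#' C(dr) = < dn_perp(r) dn_perp(r + dr e_axis) > / < dn_perp^2 >, averaged
#' over all pairs of valid nodes; the field is not mean-subtracted, so a
#' uniform bias raises the large-lag plateau. Lags run up to half the domain
#' extent along the chosen axis. The parallel axis is x (the preferred/flow
#' axis), the perpendicular axis is y.
#'
#' @param rej a `rejection_field` (see [rejection_and_domains()]).
#' @param axis "parallel" or "perpendicular".
#' @param max_lag_frac largest lag as a fraction of the axis extent
#'   (default 0.5).
#' @return object of class `correlation_curve`: `lags_um`, `values`,
#'   `n_pairs`, `plateau` (mean of C over the largest-lag quartile), `axis`.
#' @export
correlation_function <- function(rej, axis = c("parallel", "perpendicular"),
                                 max_lag_frac = 0.5) {
  stopifnot(inherits(rej, "rejection_field"))
  axis <- match.arg(axis)
  dn <- rej$dn_perp
  valid <- rej$mask & is.finite(dn)
  n_axis <- if (axis == "parallel") ncol(dn) else nrow(dn)
  if (sum(valid) < 16 || n_axis < 16)
    stop("need at least 16 valid nodes along the chosen axis")
  dn0 <- ifelse(valid, dn, 0)
  norm_num <- sum(dn0^2); norm_den <- sum(valid)
  if (norm_num / norm_den < .Machine$double.eps)
    stop("all-zero rejection field: correlation normalization undefined")
  var0 <- norm_num / norm_den
  max_lag <- floor(n_axis * max_lag_frac)
  lags <- 0:max_lag
  vals <- numeric(length(lags)); npairs <- numeric(length(lags))
  for (s in lags) {
    if (axis == "parallel") {
      a <- dn0[, seq_len(ncol(dn) - s), drop = FALSE]
      b <- dn0[, seq_len(ncol(dn) - s) + s, drop = FALSE]
      va <- valid[, seq_len(ncol(dn) - s), drop = FALSE]
      vb <- valid[, seq_len(ncol(dn) - s) + s, drop = FALSE]
    } else {
      a <- dn0[seq_len(nrow(dn) - s), , drop = FALSE]
      b <- dn0[seq_len(nrow(dn) - s) + s, , drop = FALSE]
      va <- valid[seq_len(nrow(dn) - s), , drop = FALSE]
      vb <- valid[seq_len(nrow(dn) - s) + s, , drop = FALSE]
    }
    both <- va & vb
    npairs[s + 1] <- sum(both)
    vals[s + 1] <- if (npairs[s + 1]) sum(a * b * both) / npairs[s + 1] / var0 else NA_real_
  }
  qi <- lags >= stats::quantile(lags, 0.75)
  structure(list(lags_um = lags * rej$spacing, values = vals,
                 n_pairs = npairs, axis = axis,
                 plateau = mean(vals[qi], na.rm = TRUE),
                 spacing = rej$spacing, time = rej$time),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> axis %s, %d lags up to %.3g um, plateau %.3f\n",
              x$axis, length(x$lags_um), max(x$lags_um), x$plateau))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(x$lags_um, x$values, type = "l", xlab = "lag [um]",
                 ylab = "C", ...)
  graphics::abline(h = exp(-1), lty = 3)
  invisible(x)
}

#' 1/e correlation length of a correlation curve
#'
#' The first crossing of C below `level` (default 1/e), located by linear
#' interpolation between the bracketing lags. When the curve never crosses,
#' the length is unavailable and the long-range plateau is reported instead.
#'
#' @param curve a `correlation_curve`.
#' @param level crossing level (default `exp(-1)`).
#' @return list with `xi_um` (NA when unavailable), `available`, `plateau`.
#' @export
correlation_length <- function(curve, level = exp(-1)) {
  stopifnot(inherits(curve, "correlation_curve"))
  v <- curve$values; l <- curve$lags_um
  ok <- is.finite(v)
  v <- v[ok]; l <- l[ok]
  below <- which(v < level)
  below <- below[below > 1]
  if (!length(below))
    return(list(xi_um = NA_real_, available = FALSE, plateau = curve$plateau))
  i <- below[1]
  # linear interpolation between lag i-1 (C >= level) and lag i (C < level)
  x0 <- l[i - 1]; x1 <- l[i]; y0 <- v[i - 1]; y1 <- v[i]
  xi <- x0 + (level - y0) * (x1 - x0) / (y1 - y0)
  list(xi_um = xi, available = TRUE, plateau = curve$plateau)
}

#' Growth exponent of a correlation-length series
#'
#' Least-squares slope of log(xi) versus log(t) over a time window, with a
#' percentile bootstrap confidence interval over time points.
#'
#' @param times times (h or simulation units), > 0.
#' @param xi correlation lengths, > 0 where available (NA elsewhere).
#' @param window numeric length-2 time interval; defaults to the full range.
#' @param n_boot bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `slope`, `ci` (lower, upper), `n`.
#' @export
growth_exponent <- function(times, xi, window = range(times), n_boot = 1000,
                            level = 0.95, seed = 1L) {
  keep <- is.finite(xi) & is.finite(times) & times >= window[1] & times <= window[2]
  t <- times[keep]; x <- xi[keep]
  if (length(t) < 5) stop("need at least 5 available points in the window")
  if (any(t <= 0) || any(x <= 0)) stop("times and lengths must be positive")
  lt <- log(t); lx <- log(x)
  slope <- stats::cov(lt, lx) / stats::var(lt)
  bs <- bootstrap_ci(seq_along(t), n_boot = n_boot, level = level, seed = seed,
                     statistic = function(idx) {
                       if (stats::var(lt[idx]) == 0) return(NA_real_)
                       stats::cov(lt[idx], lx[idx]) / stats::var(lt[idx])
                     })
  list(slope = slope, ci = bs, n = length(t))
}

#' Scaling-collapse error of correlation curves
#'
#' Each curve is rescaled to C(dr / xi) and interpolated onto a common
#' rescaled-lag grid spanning the overlap of all curves; the collapse error
#' is the mean squared deviation of each curve from the pointwise mean curve.
#' A single curve has error 0 by convention.
#'
#' @param curves list of `correlation_curve` objects.
#' @param lengths corresponding correlation lengths (um); curves with NA
#'   length are dropped.
#' @param n_grid number of common rescaled-lag points (default 50).
#' @return scalar collapse error (lower is better).
#' @export
collapse_error <- function(curves, lengths, n_grid = 50) {
  ok <- is.finite(lengths) & lengths > 0
  curves <- curves[ok]; lengths <- lengths[ok]
  if (!length(curves)) stop("no curve has an available correlation length")
  if (length(curves) == 1) return(0)
  scaled <- Map(function(cu, xi) list(x = cu$lags_um / xi, y = cu$values),
                curves, lengths)
  xmax <- min(vapply(scaled, function(s) max(s$x), 0))
  grid <- seq(0, xmax, length.out = n_grid)
  ys <- vapply(scaled, function(s) stats::approx(s$x, s$y, xout = grid)$y,
               numeric(n_grid))
  mu <- rowMeans(ys)
  mean((ys - mu)^2)
}

#' Percentile bootstrap confidence interval
#'
#' Percentile bootstrap of the mean (or an arbitrary statistic) with
#' `n_boot` resamples; deterministic given `seed`. Resampling uses
#' `sample.int(n, n, replace = TRUE)` draws in sequence from a local RNG
#' stream, leaving the global RNG state untouched.
#'
#' @param values numeric vector (n >= 2), or an index vector when `statistic`
#'   is supplied.
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param statistic function applied to each resample (default `mean`).
#' @return named numeric c(lower, upper).
#' @export
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95, seed = 1L,
                         statistic = mean) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats <- vapply(seq_len(n_boot), function(b) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Operational phase boundaries from a defect-count series
#'
#' The ordering kinetics are split into stages at the extrema of the
#' moving-median-smoothed defect count: stage (i) initial ordering up to the
#' first local minimum, stage (ii) defect nucleation up to the subsequent
#' local maximum, stage (iii) final coarsening.
#'
#' @param times frame times.
#' @param defect_count defect counts per frame.
#' @param window moving-median window in frames (odd, default 5).
#' @return list with `t_min`, `t_max` (NA when the corresponding extremum
#'   does not exist) and the smoothed series.
#' @export
phase_boundaries <- function(times, defect_count, window = 5) {
  n <- length(defect_count)
  if (n < window) stop("series shorter than the smoothing window")
  sm <- stats::runmed(defect_count, k = window)
  i_min <- NA_integer_; i_max <- NA_integer_
  for (i in 2:(n - 1)) {
    if (is.na(i_min) && sm[i] <= sm[i - 1] && sm[i] < sm[i + 1]) {
      i_min <- i
    } else if (!is.na(i_min) && is.na(i_max) && sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]) {
      i_max <- i
    }
  }
  list(t_min = if (is.na(i_min)) NA_real_ else times[i_min],
       t_max = if (is.na(i_max)) NA_real_ else times[i_max],
       smoothed = sm)
}
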