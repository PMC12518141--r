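# Structure-tensor extraction of the nematic director field from grayscale
# images, plus director <-> Q conversions, local order and rejection/domain
# maps.

#' Construct an image frame
#'
#' A single grayscale frame with physical calibration, the input currency of
#' the orientation-extraction stage.
#'
#' @param intensity numeric matrix of pixel intensities (rows = y, cols = x).
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param time acquisition time in hours.
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(intensity, pixel_size, time = 0) {
  intensity <- as.matrix(intensity)
  if (length(intensity) == 0L) stop("intensity grid must be non-empty")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(intensity = intensity, pixel_size = pixel_size, time = time),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.3g um/px, t = %.3g h\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size, x$time))
  invisible(x)
}

#' Construct a director field
#'
#' Per-node nematic orientation with spacing, coherence and validity mask;
#' the common currency between the experiment-side and simulation-side
#' analyses. Angles are measured from the preferred (flow, x) axis and folded
#' into (-pi/2, pi/2].
#'
#' @param alpha matrix of angles in radians, in (-pi/2, pi/2].
#' @param spacing node spacing in micrometres.
#' @param coherence matrix of non-negative confidence values (eigenvalue
#'   difference of the structure tensor); defaults to 1 everywhere.
#' @param mask logical matrix of valid nodes; defaults to wherever alpha is
#'   finite.
#' @param time frame time in hours.
#' @return an object of class `director_field`.
#' @export
director_field <- function(alpha, spacing = 1, coherence = NULL, mask = NULL,
                           time = 0) {
  alpha <- as.matrix(alpha)
  if (is.null(coherence)) coherence <- matrix(1, nrow(alpha), ncol(alpha))
  if (is.null(mask)) mask <- is.finite(alpha)
  stopifnot(all(dim(coherence) == dim(alpha)), all(dim(mask) == dim(alpha)))
  if (any(coherence[mask] < 0, na.rm = TRUE)) stop("coherence must be >= 0")
  a <- alpha[mask]
  if (any(!is.finite(a))) stop("alpha must be defined wherever mask is TRUE")
  if (any(a <= -pi / 2 - 1e-12 | a > pi / 2 + 1e-12))
    stop("alpha must lie in (-pi/2, pi/2]")
  structure(list(alpha = alpha, spacing = spacing, coherence = coherence,
                 mask = mask, time = time),
            class = "director_field")
}

#' @export
print.director_field <- function(x, ...) {
  cat(sprintf(
    "<director_field> %d x %d nodes, spacing %.3g um, %.1f%% valid, t = %.3g h\n",
    nrow(x$alpha), ncol(x$alpha), x$spacing, 100 * mean(x$mask), x$time))
  invisible(x)
}

#' Plot a director field as short line segments
#'
#' @param x a `director_field`.
#' @param every draw every `every`-th node.
#' @param ... passed to [graphics::segments()].
#' @export
plot.director_field <- function(x, every = 4, ...) {
  idx_i <- seq(1, nrow(x$alpha), by = every)
  idx_j <- seq(1, ncol(x$alpha), by = every)
  g <- expand.grid(i = idx_i, j = idx_j)
  ok <- x$mask[cbind(g$i, g$j)]
  g <- g[ok, , drop = FALSE]
  a <- x$alpha[cbind(g$i, g$j)]
  xs <- (g$j - 1) * x$spacing; ys <- (g$i - 1) * x$spacing
  L <- 0.45 * every * x$spacing
  graphics::plot(NA, xlim = range(xs), ylim = rev(range(ys)), asp = 1,
                 xlab = "x [um]", ylab = "y [um]")
  graphics::segments(xs - L * cos(a), ys - L * sin(a),
                     xs + L * cos(a), ys + L * sin(a), ...)
  invisible(x)
}

#' Extract the nematic director field from an image
#'
#' Structure-tensor method: the image is smoothed with a Gaussian of
#' sigma = box/6, intensity gradients are taken by centred differences, the
#' tangent vector t = (Iy, -Ix) is formed, and the tensor t %o% t is averaged
#' over a box of side `box_size` around each output node. The director is the
#' dominant eigenvector of the averaged tensor; coherence is the eigenvalue
#' difference n1 - n2. Nodes whose averaging box leaves the image, or whose
#' coherence falls below `min_coherence_frac` of the frame median, are masked.
#'
#' @param frame an [image_frame()].
#' @param box_size box side in micrometres (default 130).
#' @param step node spacing in micrometres (default 5.2).
#' @param min_coherence_frac mask nodes with coherence below this fraction of
#'   the frame's median coherence (default 1e-3).
#' @return a [director_field()].
#' @export
extract_orientation <- function(frame, box_size = 130, step = 5.2,
                                min_coherence_frac = 1e-3) {
  stopifnot(inherits(frame, "image_frame"))
  px <- frame$pixel_size
  box_px <- max(1L, as.integer(round(box_size / px)))
  if (box_px < 3L) stop("box must span at least 3 pixels")
  if (step <= 0) stop("step must be positive")
  if (step > box_size) stop("step must not exceed box_size")
  step_px <- max(1L, as.integer(round(step / px)))

  img <- frame$intensity
  sigma <- box_px / 6
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))

  ix <- ddx_bounded(sm); iy <- ddy_bounded(sm)
  # tangent t = (Iy, -Ix): runs along intensity ridges
  txx <- iy * iy; txy <- -ix * iy; tyy <- ix * ix
  grad_ok <- is.finite(ix) & is.finite(iy)
  r <- box_px %/% 2L
  jxx <- box_mean_masked(txx, r, grad_ok)
  jxy <- box_mean_masked(txy, r, grad_ok)
  jyy <- box_mean_masked(tyy, r, grad_ok)

  nodes_i <- seq(1L, nrow(img), by = step_px)
  nodes_j <- seq(1L, ncol(img), by = step_px)
  Jxx <- jxx[nodes_i, nodes_j, drop = FALSE]
  Jxy <- jxy[nodes_i, nodes_j, drop = FALSE]
  Jyy <- jyy[nodes_i, nodes_j, drop = FALSE]

  alpha <- fold_half(0.5 * atan2(2 * Jxy, Jxx - Jyy))
  coherence <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)

  # box fully inside the image (one-pixel gradient ring included)
  in_i <- nodes_i - r >= 2L & nodes_i + r <= nrow(img) - 1L
  in_j <- nodes_j - r >= 2L & nodes_j + r <= ncol(img) - 1L
  inside <- outer(in_i, in_j, "&")
  mask <- inside & is.finite(alpha) & is.finite(coherence)
  med <- stats::median(coherence[mask])
  if (is.finite(med) && med > 0) {
    mask <- mask & coherence >= min_coherence_frac * med
  } else {
    mask[] <- FALSE  # gradient-free frame: no orientation information
  }
  alpha[!is.finite(alpha)] <- 0
  coherence[!is.finite(coherence)] <- 0
  director_field(alpha, spacing = step_px * px, coherence = coherence,
                 mask = mask, time = frame$time)
}

#' Convert a director field to a two-component Q field
#'
#' qxx = S cos(2 alpha), qxy = S sin(2 alpha) with uniform order magnitude S.
#'
#' @param field a [director_field()].
#' @param order scalar order magnitude S in [0, 1] (default 1).
#' @return an object of class `q_field` with matrices `qxx`, `qxy`, plus
#'   `spacing` and `mask`; masked nodes are NA.
#' @export
director_to_q <- function(field, order = 1) {
  stopifnot(inherits(field, "director_field"))
  if (!is.numeric(order) || length(order) != 1 || order < 0 || order > 1)
    stop("order must be a scalar in [0, 1]")
  qxx <- order * cos(2 * field$alpha)
  qxy <- order * sin(2 * field$alpha)
  qxx[!field$mask] <- NA_real_
  qxy[!field$mask] <- NA_real_
  structure(list(qxx = qxx, qxy = qxy, spacing = field$spacing,
                 mask = field$mask, time = field$time),
            class = "q_field")
}

#' Recover director angles from a two-component Q field
#'
#' Inverse of [director_to_q()] for positive order: alpha =
#' atan2(qxy, qxx) / 2, folded into (-pi/2, pi/2].
#'
#' @param q a `q_field`.
#' @return a [director_field()].
#' @export
q_to_director <- function(q) {
  stopifnot(inherits(q, "q_field"))
  alpha <- fold_half(0.5 * atan2(q$qxy, q$qxx))
  alpha[!q$mask] <- 0
  director_field(alpha, spacing = q$spacing, mask = q$mask, time = q$time)
}

#' Local nematic order parameter at evenly distributed sample points
#'
#' S_loc = sqrt(<cos 2a>^2 + <sin 2a>^2) with the average taken over a square
#' window around each sampled node; the mean over points is the global nematic
#' order in [0, 1]. Sample points form a uniform ceiling(sqrt(N)) x
#' ceiling(sqrt(N)) grid trimmed to N; with `jitter = TRUE` they are
#' perturbed by up to half a grid cell using `seed`.
#'
#' @param field a [director_field()].
#' @param window window side in micrometres (must be >= node spacing).
#' @param sample_points number of evenly distributed points N.
#' @param seed integer seed, used only when `jitter = TRUE`.
#' @param jitter randomize point positions within their grid cell.
#' @return list with `values` (S_loc at each point), `points` (node indices),
#'   and `mean` (global order).
#' @export
local_order_parameter <- function(field, window, sample_points = 1000,
                                  seed = NULL, jitter = FALSE) {
  stopifnot(inherits(field, "director_field"))
  if (window < field$spacing) stop("window must be at least the node spacing")
  if (sample_points < 1) stop("sample_points must be >= 1")
  w <- max(1L, as.integer(round(window / field$spacing)))
  r <- w %/% 2L
  c2 <- box_mean_masked(cos(2 * field$alpha), r, field$mask)
  s2 <- box_mean_masked(sin(2 * field$alpha), r, field$mask)
  sloc <- sqrt(c2^2 + s2^2)

  k <- ceiling(sqrt(sample_points))
  gi <- round(seq(1, nrow(sloc), length.out = k))
  gj <- round(seq(1, ncol(sloc), length.out = k))
  pts <- expand.grid(i = gi, j = gj)
  if (jitter) {
    if (!is.null(seed)) set.seed(seed)
    ci <- max(1, diff(gi)[1] %/% 2); cj <- max(1, diff(gj)[1] %/% 2)
    pts$i <- pmin(pmax(pts$i + sample.int(2 * ci + 1, nrow(pts), TRUE) - ci - 1, 1), nrow(sloc))
    pts$j <- pmin(pmax(pts$j + sample.int(2 * cj + 1, nrow(pts), TRUE) - cj - 1, 1), ncol(sloc))
  }
  pts <- pts[seq_len(min(sample_points, nrow(pts))), , drop = FALSE]
  vals <- sloc[cbind(pts$i, pts$j)]
  list(values = vals, points = pts, mean = mean(vals, na.rm = TRUE))
}

#' Rejection field and degenerate-domain map
#'
#' The rejection dn_perp = sin(alpha) is the signed perpendicular component of
#' the unit director chosen with non-negative component along the preferred
#' axis; its sign splits the monolayer into the two energy-degenerate domains.
#'
#' @param field a [director_field()].
#' @return object of class `rejection_field` with matrices `dn_perp`,
#'   `domain_sign` (NA outside the mask) and the area fractions
#'   `fraction_positive`, `fraction_negative` of valid nodes.
#' @export
rejection_and_domains <- function(field) {
  stopifnot(inherits(field, "director_field"))
  dn <- sin(field$alpha)
  dn[!field$mask] <- NA_real_
  ds <- sign(dn)
  nv <- sum(field$mask)
  structure(list(
    dn_perp = dn, domain_sign = ds, spacing = field$spacing,
    mask = field$mask, time = field$time,
    fraction_positive = if (nv) sum(ds > 0, na.rm = TRUE) / nv else NA_real_,
    fraction_negative = if (nv) sum(ds < 0, na.rm = TRUE) / nv else NA_real_),
    class = "rejection_field")
}
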