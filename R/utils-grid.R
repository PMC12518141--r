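# Grid helpers shared by the analysis and simulation modules.
#
# Matrix convention throughout the package: element [i, j] sits at row i
# (y, increasing downward) and column j (x, the flow axis, increasing
# rightward); physical coordinates are (j - 1) * spacing and (i - 1) * spacing
# in micrometres.

#' Fold angles into the half-open nematic interval (-pi/2, pi/2]
#'
#' Nematic orientations are defined modulo pi; this is the package's canonical
#' representation.
#'
#' @param a numeric vector/matrix of angles in radians.
#' @return angles folded into (-pi/2, pi/2], same shape as `a`.
#' @export
fold_half <- function(a) {
  b <- a %% pi
  out <- ifelse(b > pi / 2, b - pi, b)
  # b == 0 could come from a == pi etc.; 0 maps to 0 which is in range.
  if (is.matrix(a)) dim(out) <- dim(a)
  out
}

# Periodic shift of a matrix by (di, dj) (row, col); positive di moves
# content so that result[i, j] = m[i + di, j + dj] with wrapping.
shift_periodic <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- ((seq_len(n1) - 1 + di) %% n1) + 1
  j <- ((seq_len(n2) - 1 + dj) %% n2) + 1
  m[i, j, drop = FALSE]
}

# Centred differences on a periodic grid; spacing h defaults to 1 node.
ddx_periodic <- function(m, h = 1) (shift_periodic(m, 0, 1) - shift_periodic(m, 0, -1)) / (2 * h)
ddy_periodic <- function(m, h = 1) (shift_periodic(m, 1, 0) - shift_periodic(m, -1, 0)) / (2 * h)

laplacian_periodic <- function(m, h = 1) {
  (shift_periodic(m, 0, 1) + shift_periodic(m, 0, -1) +
     shift_periodic(m, 1, 0) + shift_periodic(m, -1, 0) - 4 * m) / h^2
}

# Centred differences on a bounded grid: NA on the one-node boundary ring.
ddx_bounded <- function(m, h = 1) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  if (ncol(m) >= 3) {
    j <- 2:(ncol(m) - 1)
    out[, j] <- (m[, j + 1] - m[, j - 1]) / (2 * h)
  }
  out
}
ddy_bounded <- function(m, h = 1) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  if (nrow(m) >= 3) {
    i <- 2:(nrow(m) - 1)
    out[i, ] <- (m[i + 1, ] - m[i - 1, ]) / (2 * h)
  }
  out
}

# Mean filter over a (2r+1)^2 box, mask-aware: entries where `valid` is FALSE
# contribute neither to the sum nor to the count. Uses cumulative sums, exact
# at boundaries (shrinking window).
box_mean_masked <- function(m, r, valid = NULL) {
  if (r < 0) stop("box radius must be >= 0")
  if (is.null(valid)) valid <- !is.na(m)
  mm <- ifelse(valid, m, 0)
  cnt <- matrix(as.numeric(valid), nrow(m), ncol(m))
  s <- box_sum(mm, r)
  n <- box_sum(cnt, r)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# Sum over a (2r+1)^2 box via 2D summed-area table (window clipped at edges).
box_sum <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  pad <- matrix(0, n1 + 1, n2 + 1)
  pad[-1, -1] <- sat
  i1 <- pmax(seq_len(n1) - r, 1); i2 <- pmin(seq_len(n1) + r, n1)
  j1 <- pmax(seq_len(n2) - r, 1); j2 <- pmin(seq_len(n2) + r, n2)
  pad[i2 + 1, j2 + 1, drop = FALSE] - pad[i1, j2 + 1, drop = FALSE] -
    pad[i2 + 1, j1, drop = FALSE] + pad[i1, j1, drop = FALSE]
}

# Bilinear interpolation of matrix values at fractional (row, col) positions
# (1-based). Positions must lie inside [1, nrow] x [1, ncol].
bilinear <- function(m, ri, ci) {
  shape <- dim(ri)
  ri <- as.vector(ri); ci <- as.vector(ci)
  i0 <- pmin(pmax(floor(ri), 1), nrow(m) - 1)
  j0 <- pmin(pmax(floor(ci), 1), ncol(m) - 1)
  fi <- ri - i0; fj <- ci - j0
  v00 <- m[cbind(i0, j0)];     v01 <- m[cbind(i0, j0 + 1)]
  v10 <- m[cbind(i0 + 1, j0)]; v11 <- m[cbind(i0 + 1, j0 + 1)]
  out <- v00 * (1 - fi) * (1 - fj) + v01 * (1 - fi) * fj +
    v10 * fi * (1 - fj) + v11 * fi * fj
  if (!is.null(shape)) dim(out) <- shape
  out
}
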