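# Seeded ground-truth generators: defect textures, bound defect pairs with
# domain-wall strings, director fields with prescribed anisotropic
# correlation lengths, and oriented cell-like texture images. Every analysis
# stage is testable against these without microscopy data.

#' Director texture with prescribed half-integer defects
#'
#' The standard defect ansatz: alpha(r) = alpha0 + sum_i k_i atan2(y - y_i,
#' x - x_i), folded into (-pi/2, pi/2]. Each core carries exactly the
#' requested winding when cores are well separated.
#'
#' @param defects data.frame with columns `x_um`, `y_um`, `charge`
#'   (half-integers).
#' @param n number of nodes per side (square grid), or c(ny, nx).
#' @param spacing node spacing in micrometres.
#' @param alpha0 background angle in radians.
#' @param periodic request a texture intended for periodic wrapping; requires
#'   the charges to sum to zero (a seam is topologically unavoidable
#'   otherwise).
#' @return a [director_field()].
#' @export
make_defect_texture <- function(defects, n = 128, spacing = 1, alpha0 = 0,
                                periodic = FALSE) {
  if (length(n) == 1) n <- c(n, n)
  if (!all(abs(defects$charge * 2 - round(defects$charge * 2)) < 1e-12))
    stop("charges must be half-integers")
  if (nrow(defects) >= 2) {
    d <- stats::dist(defects[, c("x_um", "y_um")])
    if (min(d) < 1e-9) stop("coincident defect cores")
  }
  if (periodic && abs(sum(defects$charge)) > 1e-12)
    stop("periodic texture requires zero net charge (seam unavoidable)")
  xs <- (seq_len(n[2]) - 1) * spacing
  ys <- (seq_len(n[1]) - 1) * spacing
  X <- matrix(xs, n[1], n[2], byrow = TRUE)
  Y <- matrix(ys, n[1], n[2])
  alpha <- matrix(alpha0, n[1], n[2])
  for (i in seq_len(nrow(defects))) {
    alpha <- alpha + defects$charge[i] *
      atan2(Y - defects$y_um[i], X - defects$x_um[i])
  }
  director_field(fold_half(alpha), spacing = spacing)
}

#' Bound defect pair joined by a domain wall of a chosen class
#'
#' A +1/2 / -1/2 pair separated by `separation` whose connecting wall is of
#' the requested class. For the perpendicular ("red") class the pair lies
#' along y with far-field director along the preferred axis; the director
#' between the cores passes through +-pi/2. For the parallel ("green") class
#' the same construction is rotated by pi/2 in director space so that the
#' inter-core director passes through 0 (the far field is then perpendicular
#' to the preferred axis: for an isolated pair, topology ties the inter-core
#' orientation to the far field, so both cannot be along the axis at once).
#' The generator asserts the class by running [string_maps()] on its own
#' output.
#'
#' @param separation core separation in node spacings (>= 6).
#' @param axis wall class: "perpendicular" (red) or "parallel" (green).
#' @param n grid nodes per side.
#' @param spacing node spacing in micrometres.
#' @return a [director_field()] with attribute `cores` (data.frame of the
#'   two core positions and charges).
#' @export
make_pair_with_string <- function(separation, axis = c("perpendicular", "parallel"),
                                  n = 128, spacing = 1) {
  axis <- match.arg(axis)
  if (separation < 6) stop("separation too small to resolve the wall")
  cx <- (n - 1) / 2 * spacing
  d2 <- separation / 2 * spacing
  cores <- data.frame(x_um = c(cx, cx), y_um = c(cx - d2, cx + d2),
                      charge = c(0.5, -0.5))
  alpha0 <- if (axis == "perpendicular") 0 else pi / 2
  field <- make_defect_texture(cores, n = n, spacing = spacing, alpha0 = alpha0)
  # self-check: the requested wall class must appear between the cores
  sm <- string_maps(dual_angle_maps(field))
  mid_i <- round(n / 2) + (-2:2)
  mid_j <- round((cx / spacing) + 1) + (-2:2)
  target <- if (axis == "perpendicular") sm$red_map else sm$green_map
  if (!any(target[mid_i, mid_j]))
    stop("generator self-check failed: requested wall class absent between cores")
  attr(field, "cores") <- cores
  field
}

#' Director field with prescribed anisotropic correlation lengths
#'
#' The rejection dn_perp is drawn as a stationary Gaussian random field with
#' a separable Gaussian correlation kernel exp(-(dx/xi_par)^2 - (dy/xi_perp)^2)
#' synthesized spectrally (circulant embedding), whose 1/e autocorrelation
#' lengths along the two axes equal (xi_par, xi_perp) by construction; the
#' generator verifies the realized lengths on its own output and recalibrates
#' by rescaling the kernel if the first draw misses by more than 5%.
#' The director is alpha = arcsin(clipped dn_perp).
#'
#' @param xi_par,xi_perp target 1/e correlation lengths in node spacings.
#' @param amplitude standard deviation of dn_perp before clipping, in (0, 1].
#' @param n grid nodes per side (>= 8 * max(xi_par, xi_perp)).
#' @param spacing node spacing in micrometres.
#' @param seed integer seed.
#' @param bias uniform offset added to dn_perp (raises the correlation
#'   plateau; default 0).
#' @return a [director_field()].
#' @export
make_correlated_rejection_field <- function(xi_par = 20, xi_perp = 5,
                                            amplitude = 0.3, n = 256,
                                            spacing = 1, seed = 1L, bias = 0) {
  if (xi_par <= 0 || xi_perp <= 0) stop("correlation lengths must be > 0")
  if (amplitude <= 0 || amplitude > 1) stop("amplitude must be in (0, 1]")
  if (n < 8 * max(xi_par, xi_perp))
    stop("grid too small for the requested correlation lengths")
  # calibration loop: the spectral kernel has the target correlation in
  # expectation; per-realization 1/e lengths fluctuate, so the kernel scale
  # is adjusted until the realized lengths sit within 5% of the targets
  lx <- xi_par; ly <- xi_perp
  for (iter in 1:4) {
    dn <- gaussian_field_2d(n, lx, ly, seed)
    got <- field_corr_lengths(dn)
    if (all(is.finite(got)) &&
        abs(got[1] - xi_par) <= 0.05 * xi_par &&
        abs(got[2] - xi_perp) <= 0.05 * xi_perp) break
    if (is.finite(got[1]) && got[1] > 0) lx <- lx * xi_par / got[1]
    if (is.finite(got[2]) && got[2] > 0) ly <- ly * xi_perp / got[2]
  }
  dn <- amplitude * dn + bias
  dn <- pmin(pmax(dn, -0.999), 0.999)
  dim(dn) <- c(n, n)
  director_field(asin(dn), spacing = spacing)
}

# Stationary unit-variance Gaussian field with correlation
# exp(-(dx/lx)^2 - (dy/ly)^2), by spectral synthesis on the periodic grid.
gaussian_field_2d <- function(n, lx, ly, seed) {
  dx <- c(0:(n %/% 2), -((n - 1) %/% 2):-1)
  RX <- matrix(dx, n, n, byrow = TRUE)
  RY <- matrix(dx, n, n)
  rho <- exp(-(RX / lx)^2 - (RY / ly)^2)
  S <- Re(stats::fft(rho))
  S[S < 0] <- 0  # clip tiny negative embedding eigenvalues
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  w <- matrix(stats::rnorm(n * n), n, n)
  f <- Re(stats::fft(sqrt(S) * stats::fft(w), inverse = TRUE)) / n^2
  f / sqrt(mean(f^2))
}

# 1/e autocorrelation lengths of a periodic field along x and y, via the
# FFT autocorrelation, with linear interpolation at the crossing.
field_corr_lengths <- function(f) {
  n <- nrow(f)
  ac <- Re(stats::fft(Mod(stats::fft(f))^2, inverse = TRUE))
  ac <- ac / ac[1, 1]
  cross <- function(v) {
    i <- which(v < exp(-1))
    i <- i[i > 1]
    if (!length(i)) return(NA_real_)
    i <- i[1]
    (i - 2) + (v[i - 1] - exp(-1)) / (v[i - 1] - v[i])
  }
  c(x = cross(ac[1, seq_len(n %/% 2)]), y = cross(ac[seq_len(n %/% 2), 1]))
}

#' Oriented cell-like texture image with known ground-truth director
#'
#' Mimics a phase-contrast image of elongated cells: seeded white noise is
#' filtered by a bank of oriented band-pass (Gabor) kernels whose carrier
#' runs perpendicular to the director and whose envelope is elongated along
#' it, and the filtered channels are blended per pixel according to the local
#' ground-truth orientation. The result is an intensity texture whose local
#' stripes run along the prescribed director; Gaussian sensor noise is added
#' on top.
#'
#' @param field ground-truth [director_field()] (node = pixel).
#' @param wavelength transverse stripe period in pixels (> 2).
#' @param elongation streak correlation length along the director, in pixels.
#' @param n_bins number of orientation channels in the filter bank.
#' @param contrast stripe contrast (standard deviation of the noise-free
#'   texture); the contrast-to-noise ratio is `contrast / noise_sd`.
#' @param noise_sd sensor-noise standard deviation.
#' @param pixel_size physical pixel size in micrometres.
#' @param seed integer seed.
#' @return an [image_frame()] with attribute `truth` = `field`.
#' @export
make_oriented_texture_image <- function(field, wavelength = 8, elongation = 48,
                                        n_bins = 48, contrast = 1,
                                        noise_sd = 0.05, pixel_size = 1,
                                        seed = 1L) {
  stopifnot(inherits(field, "director_field"))
  if (wavelength <= 2) stop("wavelength must exceed 2 pixels (Nyquist)")
  ny <- nrow(field$alpha); nx <- ncol(field$alpha)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  noise_h <- stats::fft(matrix(stats::rnorm(ny * nx), ny, nx))
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - 1) %/% 2):-1) / nx
  ky <- 2 * pi * c(0:(ny %/% 2), -((ny - 1) %/% 2):-1) / ny
  KX <- matrix(kx, ny, nx, byrow = TRUE); KY <- matrix(ky, ny, nx)
  k0 <- 2 * pi / wavelength; bw <- wavelength / 2
  img <- matrix(0, ny, nx); wtot <- matrix(0, ny, nx)
  bins <- -pi / 2 + (seq_len(n_bins) - 0.5) * pi / n_bins
  for (b in seq_len(n_bins)) {
    tb <- c(cos(bins[b]), sin(bins[b])); nb <- c(-tb[2], tb[1])
    u <- KX * tb[1] + KY * tb[2]   # along-director wavenumber
    v <- KX * nb[1] + KY * nb[2]   # transverse wavenumber
    G <- exp(-u^2 * elongation^2 / 2) *
      (exp(-(v - k0)^2 * bw^2 / 2) + exp(-(v + k0)^2 * bw^2 / 2))
    fb <- Re(stats::fft(noise_h * G, inverse = TRUE)) / (ny * nx)
    wb <- pmax(0, 1 - abs(fold_half(field$alpha - bins[b])) / (pi / n_bins))
    img <- img + wb * fb; wtot <- wtot + wb
  }
  img <- img / pmax(wtot, 1e-9)
  img <- contrast * img / stats::sd(img)
  img <- img + matrix(stats::rnorm(ny * nx, sd = noise_sd), ny, nx)
  out <- image_frame(img, pixel_size = pixel_size, time = field$time)
  attr(out, "truth") <- field
  out
}

#' Synthetic multi-frame image stack from a sequence of director fields
#'
#' @param fields list of [director_field()] objects (one per frame).
#' @param ... passed to [make_oriented_texture_image()].
#' @param seed base seed; frame f uses seed + f - 1.
#' @return list of [image_frame()] objects.
#' @export
make_texture_stack <- function(fields, ..., seed = 1L) {
  lapply(seq_along(fields), function(f)
    make_oriented_texture_image(fields[[f]], ..., seed = seed + f - 1L))
}
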