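# Beris-Edwards Q-tensor dynamics on a periodic 2D grid, coupled to
# incompressible momentum balance with active stress, friction, an external
# aligning field (with schedules) and an optional active torque.
#
# The order parameter is the full symmetric traceless 3x3 tensor (5 degrees
# of freedom) varying on a 2D grid, initialized in-plane. Momentum balance is
# solved pseudo-spectrally: in hydrodynamic mode the semi-implicit Stokes
# problem (gamma - eta lap) u = -grad p + div Pi with the incompressibility
# projection; in overdamped mode gamma u = -grad p + div Pi.

#' Simulation parameters
#'
#' Defaults are the model's standard operating point: Landau-de Gennes scale
#' A0 = 0.05 with nu = 2.55 (isotropic bulk in the absence of activity or
#' field), elastic constant K = 0.02, flow-aligning parameter xi = 0.9,
#' rotational mobility Gamma = 0.1, extensile activity zeta = 0.03, film
#' viscosity eta = 2/3, friction gamma_f = 0.1, and aligning-field strength
#' eps0 = 0.5 along x, which set the timescales tau_zeta = eta/zeta,
#' tau_n = 1/(Gamma A0) = 200 and tau_e = 1/(Gamma eps0) = 20.
#'
#' @param A0 Landau-de Gennes energy scale.
#' @param nu Landau-de Gennes shape parameter.
#' @param K Frank-Oseen elastic constant (one-constant).
#' @param xi_align flow-aligning parameter.
#' @param Gamma rotational mobility of Q.
#' @param zeta activity (extensile > 0).
#' @param eta film viscosity.
#' @param rho fluid density (inertia is neglected by both solvers).
#' @param gamma_f substrate friction coefficient.
#' @param eps0 aligning-field strength.
#' @param field_axis unit 2-vector of the preferred axis (default x).
#' @param field_schedule list: `list(type = "constant")`,
#'   `list(type = "switch_off", t_off = ...)` or
#'   `list(type = "ac", period = ...)` (50% duty on/off square wave).
#' @param omega,s active-torque magnitude and direction sign (|s| in {0, 1}).
#' @param nx,ny periodic grid size (>= 32 per side).
#' @param dt time step.
#' @param seed integer seed for the initial condition.
#' @param solver_mode "hydrodynamic" or "overdamped".
#' @param init_amplitude amplitude of the initial in-plane order.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(A0 = 0.05, nu = 2.55, K = 0.02, xi_align = 0.9,
                       Gamma = 0.1, zeta = 0.03, eta = 2 / 3, rho = 1,
                       gamma_f = 0.1, eps0 = 0.5, field_axis = c(1, 0),
                       field_schedule = list(type = "constant"),
                       omega = 0, s = 0, nx = 128, ny = 128, dt = 0.5,
                       seed = 1L, solver_mode = c("hydrodynamic", "overdamped"),
                       init_amplitude = 0.1) {
  solver_mode <- match.arg(solver_mode)
  if (any(c(A0, K, Gamma, eta, dt) <= 0)) stop("A0, K, Gamma, eta, dt must be > 0")
  if (!(abs(s) %in% c(0, 1))) stop("|s| must be 0 or 1")
  if (nx < 32 || ny < 32) stop("grid must be at least 32 per side")
  field_axis <- field_axis / sqrt(sum(field_axis^2))
  structure(list(A0 = A0, nu = nu, K = K, xi_align = xi_align, Gamma = Gamma,
                 zeta = zeta, eta = eta, rho = rho, gamma_f = gamma_f,
                 eps0 = eps0, field_axis = field_axis,
                 field_schedule = field_schedule, omega = omega, s = s,
                 nx = nx, ny = ny, dt = dt, seed = as.integer(seed),
                 solver_mode = solver_mode, init_amplitude = init_amplitude),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %dx%d, dt=%.3g, zeta=%.3g, eps0=%.3g (%s), Gamma=%.3g, %s\n",
    x$nx, x$ny, x$dt, x$zeta, x$eps0, x$field_schedule$type, x$Gamma,
    x$solver_mode))
  invisible(x)
}

# Instantaneous field strength under the configured schedule.
field_strength <- function(params, t) {
  sc <- params$field_schedule
  switch(sc$type,
         constant = params$eps0,
         switch_off = if (t < sc$t_off) params$eps0 else 0,
         ac = if (sin(2 * pi * t / sc$period) >= 0) params$eps0 else 0,
         stop("unknown field schedule: ", sc$type))
}

#' Analytic timescales of the model
#'
#' tau_zeta = eta / zeta (active), tau_n = 1 / (Gamma A0) (nematic
#' coarsening), tau_e = 1 / (Gamma eps0) (external field). A vanishing
#' denominator yields Inf.
#'
#' @param params a [sim_params()].
#' @return named numeric c(tau_zeta, tau_n, tau_e).
#' @export
timescales <- function(params) {
  safe_div <- function(a, b) if (b > 0) a / b else Inf
  c(tau_zeta = safe_div(params$eta, params$zeta),
    tau_n = safe_div(1, params$Gamma * params$A0),
    tau_e = safe_div(1, params$Gamma * params$eps0))
}

## ---- full 3x3 tensor-field helpers (each component is an ny x nx matrix) ----

m3_names <- c("xx", "xy", "xz", "yx", "yy", "yz", "zx", "zy", "zz")

m3_zero <- function(ny, nx) {
  z <- matrix(0, ny, nx)
  stats::setNames(rep(list(z), 9), m3_names)
}

# Build a full 3x3 field from the 5 independent components of a symmetric
# traceless tensor.
m3_from_q5 <- function(q) {
  list(xx = q$xx, xy = q$xy, xz = q$xz,
       yx = q$xy, yy = q$yy, yz = q$yz,
       zx = q$xz, zy = q$yz, zz = -(q$xx + q$yy))
}

m3_mult <- function(A, B) {
  out <- list()
  for (i in c("x", "y", "z")) for (j in c("x", "y", "z")) {
    out[[paste0(i, j)]] <-
      A[[paste0(i, "x")]] * B[[paste0("x", j)]] +
      A[[paste0(i, "y")]] * B[[paste0("y", j)]] +
      A[[paste0(i, "z")]] * B[[paste0("z", j)]]
  }
  out
}

m3_lin <- function(A, B, ca = 1, cb = 1) {
  stats::setNames(lapply(m3_names, function(n) ca * A[[n]] + cb * B[[n]]), m3_names)
}

m3_scale <- function(A, c) stats::setNames(lapply(A, function(m) c * m), m3_names)

m3_trace <- function(A) A$xx + A$yy + A$zz

# Frobenius double contraction A : B
m3_dot <- function(A, B) Reduce(`+`, lapply(m3_names, function(n) A[[n]] * B[[n]]))

# Extract the 5 independent components (assumes symmetry).
m3_to_q5 <- function(A) list(xx = A$xx, xy = A$xy, xz = A$xz, yy = A$yy, yz = A$yz)

# Remove the trace: A - (I/3) tr A.
m3_deviatoric <- function(A) {
  tr3 <- m3_trace(A) / 3
  A$xx <- A$xx - tr3; A$yy <- A$yy - tr3; A$zz <- A$zz - tr3
  A
}

## ---- state ----

#' Initialize a simulation state
#'
#' The initial condition is an in-plane uniaxial tensor
#' Q = a (n n^T - I/3) with i.i.d. uniform director angles per node and
#' amplitude `init_amplitude`, seeded from `params$seed`; velocity and
#' pressure start at zero.
#'
#' @param params a [sim_params()].
#' @return object of class `sim_state` with fields `Q` (5 component
#'   matrices), `u` (list x, y), `p`, `t` and spectral caches.
#' @export
sim_init <- function(params) {
  ny <- params$ny; nx <- params$nx
  set.seed(params$seed)
  th <- matrix(stats::runif(ny * nx, -pi / 2, pi / 2), ny, nx)
  a <- params$init_amplitude
  n1 <- cos(th); n2 <- sin(th)
  Q <- list(xx = a * (n1 * n1 - 1 / 3), xy = a * n1 * n2,
            xz = matrix(0, ny, nx), yy = a * (n2 * n2 - 1 / 3),
            yz = matrix(0, ny, nx))
  # spectral wavenumbers (unit lattice spacing); the Nyquist mode is zeroed
  # so that first-derivative operators stay odd under k -> -k and the
  # projected velocity remains exactly real (standard pseudo-spectral
  # convention for even grids)
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - 1) %/% 2):-1) / nx
  ky <- 2 * pi * c(0:(ny %/% 2), -((ny - 1) %/% 2):-1) / ny
  if (nx %% 2 == 0) kx[nx / 2 + 1] <- 0
  if (ny %% 2 == 0) ky[ny / 2 + 1] <- 0
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  structure(list(Q = Q, u = list(x = matrix(0, ny, nx), y = matrix(0, ny, nx)),
                 p = matrix(0, ny, nx), t = 0,
                 cache = list(KX = KX, KY = KY, K2 = KX^2 + KY^2)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %dx%d, t = %.4g, max|Q| = %.3g, max|u| = %.3g\n",
              nrow(x$Q$xx), ncol(x$Q$xx), x$t,
              max(abs(x$Q$xx), abs(x$Q$xy), abs(x$Q$yy)),
              max(abs(x$u$x), abs(x$u$y))))
  invisible(x)
}

#' Molecular field H
#'
#' H = -(dF/dQ - (I/3) tr dF/dQ) assembled from the analytic Landau-de
#' Gennes derivative A0[(1 - nu/3) Q - nu Q^2 + nu tr(Q^2) Q], the elastic
#' Laplacian term -K lap Q, and the aligning-field term -eps0 E with
#' E the outer product of the field axis with itself. Traceless and symmetric
#' by construction.
#'
#' @param state a `sim_state`.
#' @param params a [sim_params()].
#' @param eps0 instantaneous field strength (defaults to the schedule value
#'   at the state's time).
#' @return list of 5 component matrices (xx, xy, xz, yy, yz).
#' @export
molecular_field <- function(state, params,
                            eps0 = field_strength(params, state$t)) {
  Qf <- m3_from_q5(state$Q)
  Q2 <- m3_mult(Qf, Qf)
  trQ2 <- m3_trace(Q2)
  dbulk <- stats::setNames(lapply(m3_names, function(n) {
    params$A0 * ((1 - params$nu / 3) * Qf[[n]] - params$nu * Q2[[n]] +
                   params$nu * trQ2 * Qf[[n]])
  }), m3_names)
  lapQ <- lapply(state$Q, laplacian_periodic)
  dQ <- dbulk
  for (n in c("xx", "xy", "xz", "yy", "yz")) {
    dn <- -params$K * lapQ[[n]]
    dQ[[n]] <- dQ[[n]] + dn
    sym <- paste0(substr(n, 2, 2), substr(n, 1, 1))
    if (sym != n) dQ[[sym]] <- dQ[[sym]] + dn
  }
  dQ$zz <- dQ$zz - params$K * (-(lapQ$xx + lapQ$yy))
  e <- params$field_axis
  Exx <- e[1]^2; Exy <- e[1] * e[2]; Eyy <- e[2]^2
  dQ$xx <- dQ$xx - eps0 * Exx
  dQ$xy <- dQ$xy - eps0 * Exy
  dQ$yx <- dQ$yx - eps0 * Exy
  dQ$yy <- dQ$yy - eps0 * Eyy
  H <- m3_deviatoric(dQ)
  m3_to_q5(m3_scale(H, -1))
}

#' Co-rotation (generalized advection) term
#'
#' S = (xi D + Omega)(Q + I/3) + (Q + I/3)(xi D - Omega)
#'     - 2 xi (Q + I/3) tr(Q W), with W = grad u split into the strain rate D
#' and vorticity Omega. Traceless by construction.
#'
#' @param Q list of 5 component matrices.
#' @param gradu list with matrices `uxx = dux/dx`, `uxy = dux/dy`,
#'   `uyx = duy/dx`, `uyy = duy/dy`.
#' @param xi_align flow-aligning parameter.
#' @return list of 5 component matrices.
#' @export
corotation <- function(Q, gradu, xi_align) {
  ny <- nrow(Q$xx); nx <- ncol(Q$xx)
  z <- matrix(0, ny, nx)
  # W_ab = d u_a / d x_b
  W <- list(xx = gradu$uxx, xy = gradu$uxy, xz = z,
            yx = gradu$uyx, yy = gradu$uyy, yz = z,
            zx = z, zy = z, zz = z)
  D <- list(xx = W$xx, xy = 0.5 * (W$xy + W$yx), xz = z,
            yx = 0.5 * (W$xy + W$yx), yy = W$yy, yz = z,
            zx = z, zy = z, zz = z)
  Om <- list(xx = z, xy = 0.5 * (W$xy - W$yx), xz = z,
             yx = 0.5 * (W$yx - W$xy), yy = z, yz = z,
             zx = z, zy = z, zz = z)
  Qf <- m3_from_q5(Q)
  QI <- Qf; QI$xx <- QI$xx + 1 / 3; QI$yy <- QI$yy + 1 / 3; QI$zz <- QI$zz + 1 / 3
  A <- m3_lin(m3_scale(D, xi_align), Om)           # xi D + Omega
  B <- m3_lin(m3_scale(D, xi_align), Om, 1, -1)    # xi D - Omega
  trQW <- m3_dot(Qf, W)
  S <- m3_lin(m3_mult(A, QI), m3_mult(QI, B))
  for (n in m3_names) S[[n]] <- S[[n]] - 2 * xi_align * trQW * QI[[n]]
  m3_to_q5(S)
}

#' Active torque source term
#'
#' f_q = 2 omega s [-Qxy, Qxx; Qxx, Qxy] embedded in the in-plane block of
#' the Q evolution; models the spontaneous self-generated rotation of the
#' cells, which breaks mirror symmetry.
#'
#' @param Q list of 5 component matrices.
#' @param omega torque magnitude.
#' @param s direction sign (|s| in {0, 1}).
#' @return list of 5 component matrices.
#' @export
active_torque <- function(Q, omega, s) {
  if (!(abs(s) %in% c(0, 1))) stop("|s| must be 0 or 1")
  z <- matrix(0, nrow(Q$xx), ncol(Q$xx))
  c2 <- 2 * omega * s
  list(xx = -c2 * Q$xy, xy = c2 * Q$xx, xz = z, yy = c2 * Q$xy, yz = z)
}

#' Elastic plus active stress tensor
#'
#' Pi = 2 xi QI (Q : H) - xi H QI - xi QI H - K (grad Q : grad Q)
#'      + Q H - H Q - zeta Q, with QI = Q + I/3. The viscous part
#' 2 eta D is handled implicitly by the momentum solver and is not included
#' here.
#'
#' @param state a `sim_state`.
#' @param H molecular field (5 components), consistent with `state$Q`.
#' @param params a [sim_params()].
#' @return list with in-plane stress components `xx`, `xy`, `yx`, `yy`.
#' @export
stresses <- function(state, H, params) {
  Qf <- m3_from_q5(state$Q)
  Hf <- m3_from_q5(H)
  QI <- Qf; QI$xx <- QI$xx + 1 / 3; QI$yy <- QI$yy + 1 / 3; QI$zz <- QI$zz + 1 / 3
  xi <- params$xi_align
  QH <- m3_dot(Qf, Hf)
  P <- m3_lin(m3_mult(Hf, QI), m3_mult(QI, Hf))       # H QI + QI H
  P <- m3_scale(P, -xi)
  for (n in m3_names) P[[n]] <- P[[n]] + 2 * xi * QI[[n]] * QH
  anti <- m3_lin(m3_mult(Qf, Hf), m3_mult(Hf, Qf), 1, -1)  # Q H - H Q
  P <- m3_lin(P, anti)
  # Ericksen term -K (d_a Q : d_b Q), in-plane block only
  gx <- lapply(state$Q, ddx_periodic)
  gy <- lapply(state$Q, ddy_periodic)
  dot_grad <- function(ga, gb) {
    2 * (ga$xx * gb$xx + ga$xy * gb$xy + ga$xz * gb$xz + ga$yz * gb$yz +
           ga$yy * gb$yy + ga$xx * gb$yy)  # includes zz = -(xx+yy) and symmetry
  }
  exx <- dot_grad(gx, gx); exy <- dot_grad(gx, gy); eyy <- dot_grad(gy, gy)
  list(xx = P$xx - params$K * exx - params$zeta * Qf$xx,
       xy = P$xy - params$K * exy - params$zeta * Qf$xy,
       yx = P$yx - params$K * exy - params$zeta * Qf$xy,
       yy = P$yy - params$K * eyy - params$zeta * Qf$yy)
}

#' Active force density
#'
#' f = div(-zeta Q) by centred differences on the periodic grid; highest
#' along domain boundaries, where it drives the string dynamics.
#'
#' @param Q list of component matrices with at least `xx`, `xy`, `yy`
#'   (a simulation Q) or a `q_field` (then Qyy = -Qxx).
#' @param zeta activity.
#' @return list with matrices `fx`, `fy`.
#' @export
active_force_density <- function(Q, zeta) {
  if (inherits(Q, "q_field")) Q <- list(xx = Q$qxx, xy = Q$qxy, yy = -Q$qxx)
  fx <- -zeta * (ddx_periodic(Q$xx) + ddy_periodic(Q$xy))
  fy <- -zeta * (ddx_periodic(Q$xy) + ddy_periodic(Q$yy))
  list(fx = fx, fy = fy)
}

# Incompressible velocity from the force density f = div Pi, solved
# spectrally: u_hat = P(k) f_hat / (gamma + eta k^2) in hydrodynamic mode,
# u_hat = P(k) f_hat / gamma in overdamped mode, with P the transverse
# projector enforcing div u = 0. Returns u and the pressure field.
solve_velocity <- function(fx, fy, params, cache) {
  KX <- cache$KX; KY <- cache$KY; K2 <- cache$K2
  fxh <- stats::fft(fx); fyh <- stats::fft(fy)
  # projection: remove longitudinal part
  with_k <- K2 > 0
  kdotf <- KX * fxh + KY * fyh
  phat <- matrix(0i, nrow(fx), ncol(fx))
  phat[with_k] <- -1i * kdotf[with_k] / K2[with_k]
  uxh <- fxh; uyh <- fyh
  uxh[with_k] <- fxh[with_k] - KX[with_k] * kdotf[with_k] / K2[with_k]
  uyh[with_k] <- fyh[with_k] - KY[with_k] * kdotf[with_k] / K2[with_k]
  denom <- if (params$solver_mode == "hydrodynamic")
    params$gamma_f + params$eta * K2 else params$gamma_f + 0 * K2
  if (params$gamma_f <= 0) {
    denom[!with_k] <- Inf  # no mean-flow response without friction
    denom[denom == 0] <- Inf
  }
  uxh <- uxh / denom; uyh <- uyh / denom
  n <- length(fx)
  list(ux = Re(stats::fft(uxh, inverse = TRUE)) / n,
       uy = Re(stats::fft(uyh, inverse = TRUE)) / n,
       p = Re(stats::fft(phat, inverse = TRUE)) / n)
}

# Spectral divergence of the velocity field (diagnostic for the solver
# contract).
velocity_divergence <- function(state) {
  KX <- state$cache$KX; KY <- state$cache$KY
  uxh <- stats::fft(state$u$x); uyh <- stats::fft(state$u$y)
  d <- 1i * (KX * uxh + KY * uyh)
  Re(stats::fft(d, inverse = TRUE)) / length(uxh)
}

#' Advance the simulation by one step
#'
#' Q is advanced with explicit Euler for
#' (d_t + u . grad) Q = S + f_q + Gamma H; the velocity is re-solved from the
#' instantaneous stress divergence (Stokes/overdamped momentum balance with
#' friction and the incompressibility projection). Aborts with a diagnostic
#' when the field norm diverges.
#'
#' @param state a `sim_state`.
#' @param params a [sim_params()].
#' @return the advanced `sim_state`.
#' @export
sim_step <- function(state, params) {
  H <- molecular_field(state, params)
  Pi <- stresses(state, H, params)
  fx <- ddx_periodic(Pi$xx) + ddy_periodic(Pi$xy)
  fy <- ddx_periodic(Pi$yx) + ddy_periodic(Pi$yy)
  sol <- solve_velocity(fx, fy, params, state$cache)
  state$u$x <- sol$ux; state$u$y <- sol$uy; state$p <- sol$p
  gradu <- list(uxx = ddx_periodic(sol$ux), uxy = ddy_periodic(sol$ux),
                uyx = ddx_periodic(sol$uy), uyy = ddy_periodic(sol$uy))
  S <- corotation(state$Q, gradu, params$xi_align)
  fq <- active_torque(state$Q, params$omega, params$s)
  dt <- params$dt
  for (n in c("xx", "xy", "xz", "yy", "yz")) {
    adv <- sol$ux * ddx_periodic(state$Q[[n]]) + sol$uy * ddy_periodic(state$Q[[n]])
    state$Q[[n]] <- state$Q[[n]] +
      dt * (-adv + S[[n]] + fq[[n]] + params$Gamma * H[[n]])
  }
  mx <- max(abs(state$Q$xx), abs(state$Q$xy), abs(state$Q$yy))
  if (!is.finite(mx) || mx > 50)
    stop(sprintf("simulation unstable at t = %.4g (max|Q| = %.3g); reduce dt",
                 state$t, mx))
  state$t <- state$t + dt
  state
}

#' Total free energy of the state
#'
#' Sum over nodes of the Landau-de Gennes bulk density, the one-constant
#' elastic density (K/2) |grad Q|^2 and the field density -eps0 e . Q . e.
#' Non-increasing under passive relaxational dynamics.
#'
#' @param state a `sim_state`.
#' @param params a [sim_params()].
#' @param eps0 instantaneous field strength (defaults to schedule value).
#' @return scalar total free energy.
#' @export
free_energy <- function(state, params,
                        eps0 = field_strength(params, state$t)) {
  Qf <- m3_from_q5(state$Q)
  Q2 <- m3_mult(Qf, Qf)
  trQ2 <- m3_trace(Q2)
  trQ3 <- m3_trace(m3_mult(Q2, Qf))
  f_ldg <- params$A0 * (0.5 * (1 - params$nu / 3) * trQ2 -
                          (params$nu / 3) * trQ3 + (params$nu / 4) * trQ2^2)
  gx <- lapply(state$Q, ddx_periodic); gy <- lapply(state$Q, ddy_periodic)
  gsq <- function(g) 2 * (g$xx^2 + g$xy^2 + g$xz^2 + g$yz^2 + g$yy^2 + g$xx * g$yy)
  f_el <- 0.5 * params$K * (gsq(gx) + gsq(gy))
  e <- params$field_axis
  eQe <- e[1]^2 * Qf$xx + 2 * e[1] * e[2] * Qf$xy + e[2]^2 * Qf$yy
  f_field <- -eps0 * eQe
  sum(f_ldg + f_el + f_field)
}

#' Director field of a simulation state
#'
#' The in-plane director angle alpha = atan2(2 Qxy, Qxx - Qyy) / 2, folded
#' into (-pi/2, pi/2], on the simulation grid (unit node spacing).
#'
#' @param state a `sim_state`.
#' @param spacing physical node spacing to attach (default 1).
#' @return a [director_field()].
#' @export
sim_director <- function(state, spacing = 1) {
  alpha <- fold_half(0.5 * atan2(2 * state$Q$xy, state$Q$xx - state$Q$yy))
  s2d <- sqrt((state$Q$xx - state$Q$yy)^2 + 4 * state$Q$xy^2)
  director_field(alpha, spacing = spacing, coherence = s2d, time = state$t)
}

#' Run a simulation and record coarsening observables
#'
#' Integrates for `duration` time units, recording every `record_every` time
#' units: defect detections (charge density on the periodic grid with unit
#' order magnitude), the global nematic order (mean local order parameter),
#' and optionally correlation lengths of the rejection field along both axes.
#'
#' @param params a [sim_params()].
#' @param duration total simulated time.
#' @param record_every recording cadence in time units (>= dt).
#' @param correlations also record 1/e correlation lengths (slower).
#' @param keep_snapshots record full Q snapshots (memory heavy).
#' @param detect_method "winding" (default; topologically exact on the
#'   periodic simulation grid, see [detect_defects_winding()]) or "charge"
#'   (thresholded charge density, the image-side method).
#' @param detect_threshold,detect_subsample charge-density detection settings
#'   used when `detect_method = "charge"`.
#' @param order_window window of the local order parameter, in nodes.
#' @param progress print progress lines.
#' @return object of class `coarsening_series`: data.frame `series` (time,
#'   defect_count, global_order, xi_parallel, xi_perp), list `detections`
#'   per recorded frame, final state in `state`, and the parameters.
#' @export
run_experiment <- function(params, duration, record_every = 10,
                           correlations = FALSE, keep_snapshots = FALSE,
                           detect_method = c("winding", "charge"),
                           detect_threshold = 0.1, detect_subsample = 1,
                           order_window = 9, progress = FALSE) {
  detect_method <- match.arg(detect_method)
  if (record_every < params$dt) stop("recorder cadence must be >= dt")
  state <- sim_init(params)
  n_steps <- ceiling(duration / params$dt)
  rec_steps <- max(1L, round(record_every / params$dt))
  rows <- list(); dets <- list(); snaps <- list()
  record <- function(state) {
    dirf <- sim_director(state)
    frame_idx <- length(rows) + 1L
    det <- if (detect_method == "winding") {
      detect_defects_winding(dirf, frame = frame_idx)
    } else {
      cd <- charge_density(director_to_q(dirf, order = 1), periodic = TRUE)
      detect_defects(cd, threshold = detect_threshold,
                     subsample = detect_subsample,
                     min_separation = 3, frame = frame_idx)
    }
    lop <- local_order_parameter(dirf, window = order_window,
                                 sample_points = 400)
    xi_par <- NA_real_; xi_perp <- NA_real_
    if (correlations) {
      rej <- rejection_and_domains(dirf)
      xi_par <- tryCatch(
        correlation_length(correlation_function(rej, "parallel"))$xi_um,
        error = function(e) NA_real_)
      xi_perp <- tryCatch(
        correlation_length(correlation_function(rej, "perpendicular"))$xi_um,
        error = function(e) NA_real_)
    }
    rows[[frame_idx]] <<- data.frame(
      frame = frame_idx, time = state$t, defect_count = nrow(det),
      global_order = lop$mean,
      mean_amplitude = mean(sqrt((state$Q$xx - state$Q$yy)^2 +
                                   4 * state$Q$xy^2)),
      xi_parallel = xi_par, xi_perp = xi_perp)
    dets[[frame_idx]] <<- det
    if (keep_snapshots) snaps[[frame_idx]] <<- state$Q
    if (progress)
      message(sprintf("t = %8.1f  defects = %4d  order = %.3f",
                      state$t, nrow(det), lop$mean))
  }
  record(state)
  for (k in seq_len(n_steps)) {
    state <- sim_step(state, params)
    if (k %% rec_steps == 0 || k == n_steps) record(state)
  }
  structure(list(series = do.call(rbind, rows), detections = dets,
                 snapshots = snaps, state = state, params = params),
            class = "coarsening_series")
}

#' @export
print.coarsening_series <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "<coarsening_series> %d frames to t = %.4g; defects %d -> %d; order %.3f -> %.3f\n",
    nrow(s), max(s$time), s$defect_count[1], s$defect_count[nrow(s)],
    s$global_order[1], s$global_order[nrow(s)]))
  invisible(x)
}

#' @export
plot.coarsening_series <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mar = c(4, 4, 1, 4)); on.exit(graphics::par(op))
  graphics::plot(s$time, s$defect_count, type = "b", pch = 16,
                 xlab = "time", ylab = "defect count", ...)
  graphics::par(new = TRUE)
  graphics::plot(s$time, s$global_order, type = "l", col = "darkgreen",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4); graphics::mtext("global order", side = 4, line = 2.5)
  invisible(x)
}

#' Classify the dynamical regime of a coarsening series
#'
#' Operational taxonomy: `isotropic` when the final order is below `S_low`,
#' or -- for simulated series carrying a `mean_amplitude` column -- when the
#' final in-plane order magnitude |Q| falls below `A_low` (the direction
#' becomes ill-defined as Q collapses to the isotropic state);
#' `active_turbulence` when the final defect density exceeds `N_high_frac`
#' of the initial count while the order stays below `S_mid`;
#' `non_monotonic` when the moving-median-smoothed defect count has a local
#' minimum followed by a local maximum exceeding it by at least `rho_nm`
#' and the final order exceeds `S_high`; otherwise `monotonic`.
#'
#' @param series a `coarsening_series` (or its `series` data.frame).
#' @param S_low,S_mid,S_high,rho_nm,N_high_frac thresholds (defaults 0.1,
#'   0.3, 0.6, 1.5, 0.1).
#' @param A_low order-magnitude threshold for the isotropic label
#'   (default 0.1).
#' @param smooth_window moving-median window in frames (default 5).
#' @return object of class `regime_label`: list with `label` and the
#'   diagnostics used.
#' @export
classify_regime <- function(series, S_low = 0.1, S_mid = 0.3, S_high = 0.6,
                            rho_nm = 1.5, N_high_frac = 0.1, A_low = 0.1,
                            smooth_window = 5) {
  s <- if (inherits(series, "coarsening_series")) series$series else series
  if (nrow(s) < smooth_window + 2) stop("series too short to classify")
  sm <- stats::runmed(s$defect_count, k = smooth_window)
  final_order <- s$global_order[nrow(s)]
  final_amplitude <- if ("mean_amplitude" %in% names(s))
    s$mean_amplitude[nrow(s)] else NA_real_
  final_count <- sm[length(sm)]
  n0 <- max(sm[1], 1)
  # minimum-then-maximum structure of the smoothed count
  nm <- FALSE; t_min <- NA_real_; t_max <- NA_real_
  i_min <- NA_integer_
  for (i in 2:(length(sm) - 1)) {
    if (is.na(i_min)) {
      if (sm[i] <= sm[i - 1] && sm[i] < sm[i + 1]) i_min <- i
    } else if (sm[i] >= sm[i - 1] && sm[i] > sm[i + 1]) {
      if (sm[i] >= rho_nm * max(sm[i_min], 1)) {
        nm <- TRUE; t_min <- s$time[i_min]; t_max <- s$time[i]
        break
      }
    }
  }
  label <- if (final_order < S_low ||
               (is.finite(final_amplitude) && final_amplitude < A_low)) "isotropic"
  else if (final_count > N_high_frac * n0 && final_order < S_mid) "active_turbulence"
  else if (nm && final_order > S_high) "non_monotonic"
  else "monotonic"
  structure(list(label = label, final_order = final_order,
                 final_amplitude = final_amplitude,
                 final_count = final_count, initial_count = sm[1],
                 t_min = t_min, t_max = t_max,
                 thresholds = list(S_low = S_low, S_mid = S_mid,
                                   S_high = S_high, rho_nm = rho_nm,
                                   N_high_frac = N_high_frac)),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (final order %.3f, defects %d -> %.0f)\n",
              x$label, x$final_order, x$initial_count, x$final_count))
  invisible(x)
}

#' Maximum |trace Q| over the grid (conservation diagnostic)
#'
#' The 5-component representation stores Qzz = -(Qxx + Qyy), so the trace is
#' zero by construction; this verifies the stored components stay finite and
#' consistent.
#'
#' @param state a `sim_state`.
#' @return scalar max |tr Q|.
#' @export
trace_q_max <- function(state) {
  Qf <- m3_from_q5(state$Q)
  max(abs(m3_trace(Qf)))
}
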