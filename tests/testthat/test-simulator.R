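test_that("molecular field vanishes at the isotropic state and linearizes to -K k^2", {
  p <- sim_params(nx = 32, ny = 32, eps0 = 0, zeta = 0)
  st <- sim_init(p)
  for (nm in names(st$Q)) st$Q[[nm]][] <- 0
  H <- molecular_field(st, p)
  expect_true(all(vapply(H, function(m) max(abs(m)), 0) < 1e-14))
  # plane-wave perturbation about Q = 0 with a negligible bulk term:
  # H = -K k_eff^2 dQ cos(kx) with the centred-difference k_eff^2 = 2 - 2 cos k
  p2 <- sim_params(nx = 64, ny = 64, A0 = 1e-12, eps0 = 0, zeta = 0)
  st2 <- sim_init(p2)
  for (nm in names(st2$Q)) st2$Q[[nm]][] <- 0
  kx <- 2 * pi * 3 / 64
  wave <- 1e-3 * cos(kx * (matrix(0:63, 64, 64, byrow = TRUE)))
  st2$Q$xy <- wave
  H2 <- molecular_field(st2, p2)
  keff2 <- 2 - 2 * cos(kx)
  expect_equal(H2$xy, -p2$K * keff2 * wave, tolerance = 1e-6)
  expect_lt(max(abs(H2$xx)), 1e-12)
})

test_that("molecular field includes the aligning-field term -eps0 E (traceless part)", {
  p <- sim_params(nx = 32, ny = 32, eps0 = 0.5, zeta = 0)
  st <- sim_init(p)
  for (nm in names(st$Q)) st$Q[[nm]][] <- 0
  H <- molecular_field(st, p, eps0 = 0.5)
  # H = -(-eps0 E - I/3 tr(-eps0 E)) = eps0 (E - I/3)
  expect_equal(H$xx[1, 1], 0.5 * (1 - 1 / 3), tolerance = 1e-12)
  expect_equal(H$yy[1, 1], 0.5 * (0 - 1 / 3), tolerance = 1e-12)
  expect_equal(H$xy[1, 1], 0, tolerance = 1e-15)
})

test_that("co-rotation: rest fluid gives zero; pure rotation commutates; Q = 0 extension gives (2 xi/3) D", {
  n <- 16
  Q <- uniform_q5(n, 0.4, 0.3)
  z <- matrix(0, n, n)
  g0 <- list(uxx = z, uxy = z, uyx = z, uyy = z)
  S0 <- corotation(Q, g0, 0.9)
  expect_true(all(vapply(S0, function(m) max(abs(m)), 0) < 1e-15))
  # pure rotation with xi = 0: S = [Omega, Q], traceless
  a <- 0.2
  grot <- list(uxx = z, uxy = z + a, uyx = z - a, uyy = z)  # Omega_xy = a
  Sr <- corotation(Q, grot, 0)
  Om <- matrix(c(0, a, 0, -a, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  Qm <- matrix(c(Q$xx[1, 1], Q$xy[1, 1], 0,
                 Q$xy[1, 1], Q$yy[1, 1], 0,
                 0, 0, -Q$xx[1, 1] - Q$yy[1, 1]), 3, 3)
  comm <- Om %*% Qm - Qm %*% Om
  expect_equal(Sr$xx[1, 1], comm[1, 1], tolerance = 1e-12)
  expect_equal(Sr$xy[1, 1], comm[1, 2], tolerance = 1e-12)
  expect_equal(Sr$xx[1, 1] + Sr$yy[1, 1] - Q$xx[1, 1] * 0, comm[1, 1] + comm[2, 2],
               tolerance = 1e-12)
  # pure extension with Q = 0: S = (2 xi / 3) D
  Q0 <- uniform_q5(n, 0, 0)
  b <- 0.1
  gext <- list(uxx = z + b, uxy = z, uyx = z, uyy = z - b)
  Se <- corotation(Q0, gext, 0.9)
  expect_equal(Se$xx[1, 1], 2 * 0.9 / 3 * b, tolerance = 1e-12)
  expect_equal(Se$yy[1, 1], -2 * 0.9 / 3 * b, tolerance = 1e-12)
  expect_equal(Se$xy[1, 1], 0, tolerance = 1e-15)
})

test_that("stress: zero at rest, reduces to the active part for uniform equilibrium Q, and is linear in zeta", {
  p <- sim_params(nx = 32, ny = 32, zeta = 0.03, eps0 = 0)
  st <- sim_init(p)
  for (nm in names(st$Q)) st$Q[[nm]][] <- 0
  H <- molecular_field(st, p)
  Pi0 <- stresses(st, H, p)
  expect_true(all(vapply(Pi0, function(m) max(abs(m)), 0) < 1e-14))
  # uniform Q with H forced to zero: only -zeta Q remains
  st$Q <- uniform_q5(32, 0.3, 0.5)
  Hz <- lapply(st$Q, function(m) m * 0)
  Pi <- stresses(st, Hz, p)
  expect_equal(Pi$xx, -p$zeta * st$Q$xx, tolerance = 1e-12)
  expect_equal(Pi$xy, -p$zeta * st$Q$xy, tolerance = 1e-12)
  expect_equal(Pi$xy, Pi$yx, tolerance = 1e-14)
  # activity reversal flips the active stress exactly
  p2 <- p; p2$zeta <- -p$zeta
  Pi2 <- stresses(st, Hz, p2)
  expect_equal(Pi2$xx, -Pi$xx, tolerance = 1e-14)
})

test_that("active torque is the stated in-plane source and flips with s", {
  Q <- uniform_q5(8, 0.3, 0.4)
  f0 <- active_torque(Q, 0, 1)
  expect_true(all(vapply(f0, function(m) max(abs(m)), 0) == 0))
  fp <- active_torque(Q, 0.05, 1)
  fm <- active_torque(Q, 0.05, -1)
  expect_equal(fp$xx, -2 * 0.05 * Q$xy, tolerance = 1e-14)
  expect_equal(fp$xy, 2 * 0.05 * Q$xx, tolerance = 1e-14)
  expect_equal(fp$yy, 2 * 0.05 * Q$xy, tolerance = 1e-14)
  expect_equal(fm$xy, -fp$xy, tolerance = 1e-14)
  expect_error(active_torque(Q, 0.05, 2), "s")
  # with activity and field off, the torque drives a steady director drift
  # whose sign follows s
  drift <- function(s) {
    p <- sim_params(nx = 32, ny = 32, zeta = 0, eps0 = 0, omega = 0.05, s = s,
                    dt = 0.5)
    st <- sim_init(p)
    st$Q <- uniform_q5(32, 0.2, 0)
    for (k in 1:30) st <- sim_step(st, p)
    mean(sim_director(st)$alpha)
  }
  expect_gt(drift(1), 0.05)
  expect_lt(drift(-1), -0.05)
})

test_that("active force density concentrates on domain walls and is linear in zeta", {
  n <- 64
  z <- matrix(0, n, n)
  Qw <- uniform_q5(n, 0.5, 0)
  # smooth two-domain wall at column n/2 (director rotates across it)
  prof <- 0.4 * tanh((matrix(0:(n - 1), n, n, byrow = TRUE) - n / 2) / 3)
  Qw$xy <- prof
  expect_true(all(vapply(active_force_density(Qw, 0), function(m) max(abs(m)), 0) == 0))
  fu <- active_force_density(uniform_q5(n, 0.5, 0.7), 0.03)
  expect_lt(max(abs(fu$fx), abs(fu$fy)), 1e-14)
  f <- active_force_density(Qw, 0.03)
  mag <- sqrt(f$fx^2 + f$fy^2)
  peak_col <- which.max(apply(mag[, 5:(n - 5)], 2, max)) + 4
  expect_lte(abs(peak_col - (n / 2 + 1)), 2)
})

test_that("passive relaxation decreases the free energy and aligns with the field", {
  p <- sim_params(zeta = 0, nx = 48, ny = 48, dt = 0.5, seed = 3)
  st <- sim_init(p)
  Fs <- free_energy(st, p)
  for (k in 1:300) {
    st <- sim_step(st, p)
    if (k %% 30 == 0) Fs <- c(Fs, free_energy(st, p))
  }
  expect_true(all(diff(Fs) <= 1e-9))
  # steady state: director parallel to the field axis everywhere
  d <- sim_director(st)
  expect_lt(max(abs(d$alpha)), 1e-3)
})

test_that("conservation: trace, incompressibility and detected charge neutrality hold along active runs", {
  p <- sim_params(zeta = 0.1, eps0 = 0.01, nx = 48, ny = 48, dt = 0.5, seed = 4)
  st <- sim_init(p)
  for (k in 1:200) {
    st <- sim_step(st, p)
    if (k %% 50 == 0) {
      expect_lt(trace_q_max(st), 1e-10)
      dv <- nemakin:::velocity_divergence(st)
      umax <- max(abs(st$u$x), abs(st$u$y), 1e-12)
      expect_lt(max(abs(dv)) / umax, 1e-6)
      det <- detect_defects_winding(sim_director(st))
      expect_equal(sum(det$charge), 0)
    }
  }
})

test_that("passive coarsening is monotone across seeds", {
  for (seed in 1:3) {
    p <- sim_params(zeta = 0, eps0 = 0.05, nx = 48, ny = 48, dt = 1,
                    seed = seed)
    ex <- run_experiment(p, duration = 200, record_every = 25)
    counts <- ex$series$defect_count[-1]
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("timescales follow the stated formulas with infinite flags", {
  p <- sim_params()  # eta = 2/3, zeta = 0.03, Gamma = 0.1, A0 = 0.05, eps0 = 0.5
  ts <- timescales(p)
  expect_equal(unname(ts["tau_zeta"]), (2 / 3) / 0.03, tolerance = 1e-12)  # 22.2
  expect_equal(unname(ts["tau_n"]), 200, tolerance = 1e-12)
  expect_equal(unname(ts["tau_e"]), 20, tolerance = 1e-12)
  p0 <- sim_params(zeta = 0, eps0 = 0)
  ts0 <- timescales(p0)
  expect_identical(unname(ts0["tau_zeta"]), Inf)
  expect_identical(unname(ts0["tau_e"]), Inf)
})

test_that("field schedules modulate the aligning term", {
  p <- sim_params(field_schedule = list(type = "switch_off", t_off = 100))
  expect_equal(nemakin:::field_strength(p, 50), p$eps0)
  expect_equal(nemakin:::field_strength(p, 150), 0)
  pac <- sim_params(field_schedule = list(type = "ac", period = 10))
  expect_equal(nemakin:::field_strength(pac, 2), pac$eps0)
  expect_equal(nemakin:::field_strength(pac, 7), 0)
})

test_that("switching the field off after full alignment leaves the order nearly intact", {
  t_off <- 150
  p <- sim_params(zeta = 0.01, eps0 = 0.1, nx = 48, ny = 48, dt = 0.5, seed = 2,
                  field_schedule = list(type = "switch_off", t_off = t_off))
  ex <- run_experiment(p, duration = t_off + 0.5 * t_off, record_every = 15)
  s <- ex$series
  o_off <- s$global_order[which.min(abs(s$time - t_off))]
  o_end <- s$global_order[nrow(s)]
  expect_gt(o_off, 0.9)                       # aligned before switch-off
  expect_gt(o_end, o_off - 0.05 * o_off)      # decays by < 5% afterwards
})

test_that("a fast a.c. field reproduces the constant-field regime label", {
  base <- list(zeta = 0.03, eps0 = 0.2, nx = 48, ny = 48, dt = 0.5, seed = 2)
  pc <- do.call(sim_params, base)
  pa <- do.call(sim_params, c(base, list(field_schedule = list(type = "ac", period = 4))))
  rc <- classify_regime(run_experiment(pc, duration = 400, record_every = 40))
  ra <- classify_regime(run_experiment(pa, duration = 400, record_every = 40))
  expect_identical(rc$label, "monotonic")
  expect_identical(ra$label, rc$label)
})

test_that("regime taxonomy applies literally to a constructed series", {
  s <- data.frame(frame = 1:10, time = 1:10,
                  defect_count = c(40, 20, 10, 10, 18, 25, 25, 12, 5, 0),
                  global_order = seq(0.2, 0.95, length.out = 10),
                  mean_amplitude = rep(0.8, 10))
  r <- classify_regime(s, rho_nm = 1.5, smooth_window = 3)
  expect_identical(r$label, "non_monotonic")
  s2 <- s; s2$defect_count <- seq(40, 0, length.out = 10)
  expect_identical(classify_regime(s2, smooth_window = 3)$label, "monotonic")
  s3 <- s; s3$mean_amplitude <- rep(0.01, 10)
  expect_identical(classify_regime(s3, smooth_window = 3)$label, "isotropic")
  s4 <- s; s4$defect_count <- rep(40, 10); s4$global_order <- rep(0.2, 10)
  expect_identical(classify_regime(s4, smooth_window = 3)$label,
                   "active_turbulence")
})

test_that("simulation guards reject invalid parameters and detect blow-up", {
  expect_error(sim_params(dt = 0), "must be > 0")
  expect_error(sim_params(nx = 16), "at least 32")
  expect_error(sim_params(s = 0.5), "s")
  p <- sim_params(nx = 32, ny = 32, dt = 500)  # grossly unstable step
  st <- sim_init(p)
  expect_error({for (k in 1:50) st <- sim_step(st, p)}, "unstable")
})
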