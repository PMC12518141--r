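test_that("charge density vanishes on uniform and smooth defect-free textures", {
  f <- director_field(matrix(0.7, 32, 32))
  cd <- charge_density(director_to_q(f, 1))
  expect_lt(max(abs(cd$q), na.rm = TRUE), 1e-12)
  # smooth bend texture stays below the detection threshold
  n <- 64
  g <- grid_xy(n)
  fb <- director_field(0.2 * sin(2 * pi * g$X / n))
  cdb <- charge_density(director_to_q(fb, 1))
  expect_lt(max(abs(cdb$q), na.rm = TRUE), 0.1)
  expect_error(charge_density(director_to_q(director_field(matrix(0, 2, 2)), 1)),
               "too small")
})

test_that("charge density integrates to the winding number over a defect core", {
  n <- 129
  f <- make_defect_texture(data.frame(x_um = 64, y_um = 64, charge = 0.5),
                           n = n)
  w <- winding_number(f, c(64, 64), 20)
  expect_identical(as.numeric(w), 0.5)
  cd <- charge_density(director_to_q(f, 1))
  core <- abs(row(cd$q) - 65) <= 8 & abs(col(cd$q) - 65) <= 8
  expect_equal(sum(cd$q[core], na.rm = TRUE), 0.5, tolerance = 0.02)
  # single positive extremum at the core
  peak <- which(cd$q == max(cd$q, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(max(abs(peak - 65)), 2)
})

test_that("winding oracle returns +-1/2 on the standard defect ansatz and 0 on uniform fields", {
  for (k in c(0.5, -0.5)) {
    f <- director_field(analytic_defect_alpha(101, k, 50, 50))
    w <- winding_number(f, c(50, 50), 15)
    expect_identical(as.numeric(w), k)
    expect_lt(attr(w, "residual"), 0.01)
  }
  fu <- director_field(matrix(1.2, 64, 64))
  expect_identical(as.numeric(winding_number(fu, c(30, 30), 10)), 0)
  expect_error(winding_number(fu, c(30, 30), 40), "exits")
})

test_that("defect detection finds isolated cores with correct signs and positions", {
  n <- 160
  spec <- data.frame(x_um = c(40, 120), y_um = c(80, 80),
                     charge = c(0.5, -0.5))
  f <- make_defect_texture(spec, n = n)
  det <- detect_defects(charge_density(director_to_q(f, 1)),
                        subsample = 1, min_separation = 8)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_um), ]
  expect_equal(det$charge, c(0.5, -0.5))
  expect_lt(max(abs(det$x_um - spec$x_um)), 2)
  expect_lt(max(abs(det$y_um - spec$y_um)), 2)
  # uniform field: empty result
  fu <- director_field(matrix(0.3, 64, 64))
  expect_equal(nrow(detect_defects(charge_density(director_to_q(fu, 1)))), 0)
})

test_that("detection is neutral on four-defect textures and matches the winding oracle", {
  n <- 192
  spec <- data.frame(x_um = c(48, 96, 48, 144), y_um = c(48, 48, 144, 144),
                     charge = c(0.5, -0.5, -0.5, 0.5))
  f <- make_defect_texture(spec, n = n)
  det <- detect_defects(charge_density(director_to_q(f, 1)),
                        subsample = 1, min_separation = 8)
  expect_equal(nrow(det), 4)
  expect_equal(sum(det$charge), 0)
  for (i in seq_len(nrow(det))) {
    w <- winding_number(f, c(det$x_um[i], det$y_um[i]), 10)
    expect_equal(as.numeric(w), det$charge[i])
  }
})

test_that("detection depends only on director gradients (global rotation invariance)", {
  n <- 128
  spec <- data.frame(x_um = c(40, 90), y_um = c(64, 64), charge = c(0.5, -0.5))
  f <- make_defect_texture(spec, n = n)
  d1 <- detect_defects(charge_density(director_to_q(f, 1)),
                       subsample = 1, min_separation = 8)
  f2 <- director_field(fold_half(f$alpha + 0.61))
  d2 <- detect_defects(charge_density(director_to_q(f2, 1)),
                       subsample = 1, min_separation = 8)
  expect_equal(d1$x_um, d2$x_um, tolerance = 1e-6)
  expect_equal(d1$charge, d2$charge)
})

test_that("plaquette-winding detection is exact and neutral on periodic textures", {
  n <- 128
  spec <- data.frame(x_um = c(32.5, 96.5, 32.5, 96.5) - 0.25,
                     y_um = c(32.5, 32.5, 96.5, 96.5) - 0.25,
                     charge = c(0.5, -0.5, -0.5, 0.5))
  f <- make_defect_texture(spec, n = n, periodic = TRUE)
  det <- detect_defects_winding(f)
  expect_equal(sum(det$charge), 0)
  expect_equal(nrow(det), 4)
  for (i in seq_len(nrow(det))) {
    j <- which.min((spec$x_um - det$x_um[i])^2 + (spec$y_um - det$y_um[i])^2)
    expect_equal(det$charge[i], spec$charge[j])
    expect_lt(abs(det$x_um[i] - spec$x_um[j]), 1.5)
  }
})

test_that("trajectory linking follows moving defects and applies the persistence filter", {
  # two stationary defects over 20 frames
  det <- do.call(rbind, lapply(1:20, function(f)
    data.frame(x_um = c(10, 50), y_um = c(10, 50), charge = c(0.5, -0.5),
               frame = f)))
  tr <- link_trajectories(det, max_displacement = 5, min_duration = 4,
                          frame_interval_h = 1 / 3)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(unique(tr$duration_h), 20 / 3)
  # one defect moving 1 node per frame stays a single track
  mv <- do.call(rbind, lapply(1:15, function(f)
    data.frame(x_um = f * 1.0, y_um = 0, charge = 0.5, frame = f)))
  trm <- link_trajectories(mv, max_displacement = 3, min_duration = 0)
  expect_equal(length(unique(trm$track_id)), 1)
  # a 6-frame-lived pair at 20 min/frame fails the 4 h persistence filter
  sh <- do.call(rbind, lapply(1:6, function(f)
    data.frame(x_um = c(0, 9), y_um = c(0, 0), charge = c(0.5, -0.5),
               frame = f)))
  trs <- link_trajectories(sh, max_displacement = 5, min_duration = 4,
                           frame_interval_h = 1 / 3)
  expect_equal(nrow(trs), 0)
  # charge segregation: opposite charges never share a track
  mix <- rbind(data.frame(x_um = 0, y_um = 0, charge = 0.5, frame = 1),
               data.frame(x_um = 0.5, y_um = 0, charge = -0.5, frame = 2))
  trx <- link_trajectories(mix, max_displacement = 5, min_duration = 0)
  expect_equal(length(unique(trx$track_id)), 2)
})

test_that("kNN opposite-charge distances match a brute-force oracle and stay ordered", {
  # deterministic configuration
  det <- rbind(
    data.frame(x_um = 0, y_um = 0, charge = 0.5, frame = 1),
    data.frame(x_um = c(10, 20, 30, 40), y_um = 0, charge = -0.5, frame = 1))
  k <- knn_opposite_distances(det)
  q <- k$per_defect[k$per_defect$charge == 0.5, ]
  expect_equal(q$d_um, c(10, 20, 30, 40))
  # a lone opposite pair: d0 only, the rest flagged unavailable
  p2 <- data.frame(x_um = c(0, 0), y_um = c(0, 100),
                   charge = c(0.5, -0.5), frame = 1)
  k2 <- knn_opposite_distances(p2)
  expect_equal(k2$summary$mean_um[k2$summary$k == 0], 100)
  expect_true(all(is.na(k2$summary$mean_um[k2$summary$k > 0])))
  # random configuration against an exhaustive all-pairs oracle
  set.seed(21)
  rnd <- data.frame(x_um = runif(40, 0, 200), y_um = runif(40, 0, 200),
                    charge = rep(c(0.5, -0.5), each = 20), frame = 1)
  kr <- knn_opposite_distances(rnd)$per_defect
  for (i in seq_len(nrow(rnd))) {
    opp <- rnd[rnd$charge == -rnd$charge[i], ]
    dso <- sort(sqrt((opp$x_um - rnd$x_um[i])^2 + (opp$y_um - rnd$y_um[i])^2))
    got <- kr$d_um[kr$x_um == rnd$x_um[i] & kr$y_um == rnd$y_um[i]]
    expect_equal(got, dso[1:4])
    expect_true(all(diff(got) >= 0))
  }
})
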