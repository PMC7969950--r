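test_that("direction labels separate the high and low alpha-catenin regimes", {
  high <- default_traj(0.8, v_Y = 0.5, t_end = 2.5)
  low <- default_traj(0.1, v_Y = 0.5, t_end = 2.5)
  expect_equal(classify_direction(high, T = 2.5)$label, "decrease")
  expect_equal(classify_direction(low, T = 2.5)$label, "increase")

  # frozen Y equation: no sequestration, no accumulation
  p <- model_params(v_Y = 0.5)
  p$r1 <- 1e-300; p$r2 <- 1e-300  # numerically zero, constructor-positive
  traj <- integrate_model(p, initial_state(alpha_cat_init = 0.5),
                          t_end = 2.5, n_samples = 101L)
  expect_equal(classify_direction(traj, T = 2.5)$label, "unchanged")

  expect_error(classify_direction(low, T = 99), "outside trajectory span")
})

test_that("the flip boundary falls between the printed regime thresholds", {
  b <- find_flip_boundary(model_params(), initial_state(), v_Y = 0.5,
                          T = 2.5, tol = 1e-4)
  expect_equal(b$diagnostic, "ok")
  expect_gt(b$boundary, 0.3)
  expect_lt(b$boundary, 0.5)

  # bisection agrees with a brute-force fine-grid scan
  grid <- seq(0.25, 0.45, by = 1e-3)
  yT <- vapply(grid, function(a) {
    traj <- default_traj(a, v_Y = 0.5, t_end = 2.5, n_samples = 101L)
    traj$Y[101L]
  }, numeric(1))
  flip <- which(diff(sign(yT - 1)) < 0)[1L]
  scan_boundary <- (grid[flip] + grid[flip + 1L]) / 2
  expect_equal(b$boundary, scan_boundary, tolerance = 2e-3)
})

test_that("boundary search returns a diagnostic when no flip exists", {
  # without sequestration Y never falls below its start
  p <- model_params(v_Y = 0.5)
  p$r1 <- 1e-300
  b <- find_flip_boundary(p, initial_state(), T = 2.5)
  expect_true(is.na(b$boundary))
  expect_match(b$diagnostic, "no increase-to-decrease sign change")
})

test_that("direction flips across the located boundary", {
  b <- find_flip_boundary(model_params(), initial_state(), v_Y = 0.5,
                          T = 2.5)$boundary
  below <- default_traj(b - 0.01, v_Y = 0.5, t_end = 2.5)
  above <- default_traj(b + 0.01, v_Y = 0.5, t_end = 2.5)
  expect_equal(classify_direction(below, T = 2.5)$label, "increase")
  expect_equal(classify_direction(above, T = 2.5)$label, "decrease")
})

test_that("windowed correlations reproduce the biphasic low-alpha-cat signature", {
  traj <- default_traj(0.1, v_Y = 0.5, t_end = 10, n_samples = 400L)
  r <- windowed_correlation(traj)
  expect_lte(r$R_early, -0.5)
  expect_gte(r$R_late, 0.5)
  expect_equal(r$diagnostic, "ok")
  expect_equal(r$n_early + r$n_late, 401L)  # peak sample in both windows
  expect_true(abs(r$R_early) <= 1 && abs(r$R_late) <= 1)
})

test_that("correlation handles exact linear and degenerate windows", {
  traj <- default_traj(0.1, v_Y = 0.5, t_end = 10, n_samples = 100L)
  # perfect anti-correlation when Y is an affine decreasing map of A
  traj$Y <- 2 - traj$A
  r <- windowed_correlation(traj)
  expect_equal(r$R_early, -1)

  # constant Y: zero variance -> undefined-correlation error
  traj$Y <- rep(1, length(traj$Y))
  expect_error(windowed_correlation(traj), "zero variance")

  # monotone-decreasing Y: peak at t = 0, early window undefined
  high <- default_traj(0.9, v_Y = 0.5, t_end = 5, n_samples = 100L)
  rh <- windowed_correlation(high)
  expect_true(is.na(rh$R_early))
  expect_equal(rh$diagnostic, "no interior Y peak")
  expect_true(is.finite(rh$R_late))
})

test_that("co-moving monotone windows give near-perfect correlation", {
  # in the high-alpha-cat regime Y and A fall together over the whole window
  set.seed(5)
  for (i in 1:5) {
    alpha <- runif(1, 0.8, 1.2)
    v_Y <- runif(1, 0.3, 1.0)
    traj <- default_traj(alpha, v_Y, t_end = 2.5, n_samples = 150L)
    expect_true(all(diff(traj$Y) <= 1e-12))
    expect_gt(cor(traj$Y, traj$A), 0)
  }
})

test_that("the YAP peak time matches a finite-difference sign-change oracle", {
  high <- default_traj(0.9, v_Y = 0.5, t_end = 5, n_samples = 200L)
  expect_equal(yap_peak_time(high), 0)

  traj <- default_traj(0.1, v_Y = 0.5, t_end = 10, n_samples = 400L)
  tp <- yap_peak_time(traj)
  expect_gt(tp, 0)
  expect_lt(tp, 10)
  d <- diff(traj$Y)
  flip <- which(d[-1] < 0 & d[-length(d)] >= 0)[1L] + 1L
  expect_equal(tp, traj$times[flip], tolerance = 1e-9)

  # refinement: doubling the sampling moves the peak by at most one step
  fine <- default_traj(0.1, v_Y = 0.5, t_end = 10, n_samples = 800L)
  expect_lt(abs(yap_peak_time(fine) - tp), 10 / 399)
})

test_that("the flip boundary decreases with the evaluation horizon", {
  prof <- flip_boundary_profile(T_values = c(2, 2.5, 3), tol = 1e-3)
  expect_true(all(is.finite(prof$boundary)))
  expect_true(all(diff(prof$boundary) < 0))
})

test_that("initial YAP slope agrees with the rhs at t = 0", {
  set.seed(11)
  for (i in 1:6) {
    alpha <- runif(1, 0.05, 1.2)
    v_Y <- runif(1, 0.1, 1.0)
    traj <- default_traj(alpha, v_Y, t_end = 2, n_samples = 400L)
    d0 <- model_rhs(c(1, 1, alpha), traj$params, traj$scales)
    expected <- -1 * alpha + 1.2 * (1 - exp(-1)) * (1 - 1 / 4) * 1
    expect_equal(d0[["dY"]], expected, tolerance = 1e-12)
    if (abs(d0[["dY"]]) > 0.01) {
      expect_equal(sign(traj$Y[2L] - traj$Y[1L]), sign(d0[["dY"]]))
    }
  }
})
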