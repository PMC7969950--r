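test_that("rhs matches hand-substituted rates and limiting cases", {
  p <- model_params(v_Y = 0.5)
  s <- derived_scales(p, initial_state(alpha_cat_init = 0.1))

  d <- model_rhs(c(1, 1, 0.1), p, s)
  sat <- 1 - exp(-1)
  expect_equal(unname(d[1]), -0.1 - 0.5 * sat)
  expect_equal(unname(d[2]), -0.1 + 1.2 * sat * 0.75)
  expect_equal(unname(d[3]), 3 * 0.1 * 0.5 * sat * (1 - 0.1 / 0.3) * 0.1)

  # zero YAP/TAZ and zero alpha-catenin: only primary autophagy decay
  d0 <- model_rhs(c(1, 0, 0), p, s)
  expect_equal(unname(d0), c(-0.1, 0, 0))

  # extinguished autophagy: only sequestration acts on Y
  s2 <- derived_scales(p, initial_state(alpha_cat_init = 0.5))
  d2 <- model_rhs(c(0, 1, 0.5), p, s2)
  expect_equal(unname(d2[c(1, 3)]), c(0, 0))
  expect_equal(unname(d2[2]), -p$r1 * 0.5 * 1)
  expect_lt(d2[2], 0)
})

test_that("rhs rejects invalid states and degenerate scales", {
  p <- model_params()
  s <- derived_scales(p, initial_state(alpha_cat_init = 0.1))
  expect_error(model_rhs(c(NA, 1, 0.1), p, s), "invalid state")
  expect_error(model_rhs(c(1, 1), p, s), "invalid state")
  s0 <- derived_scales(p, initial_state(alpha_cat_init = 0))
  expect_error(model_rhs(c(1, 1, 0.2), p, s0), "degenerate scale")
})

test_that("parameter and state constructors validate their fields", {
  expect_error(model_params(c = -1), "positive")
  expect_error(model_params(r1 = 0), "positive")
  expect_error(initial_state(A_init = -0.1), "non-negative")
  expect_error(integrate_model(t_end = 0), "positive")
  expect_error(integrate_model(t_end = 5, n_samples = 1), "n_samples")
})

test_that("derived scales follow the initial state", {
  p <- model_params()
  s <- derived_scales(p, initial_state(Y_init = 2, alpha_cat_init = 0.4))
  expect_equal(s$v_C, 0.4)
  expect_equal(s$C_max, 1.2)
  expect_equal(s$Y_max, 8)
})

test_that("closed-form limits are reproduced", {
  # no feedback, no alpha-catenin: pure exponential autophagy decay
  traj <- integrate_model(model_params(v_Y = 0),
                          initial_state(alpha_cat_init = 0),
                          t_end = 10, n_samples = 21L)
  expect_equal(traj$A, exp(-0.1 * traj$times), tolerance = 1e-7)
  expect_equal(traj$A[21L], exp(-1), tolerance = 1e-7)
  expect_true(all(traj$C == 0))

  # extinguished autophagy, constant alpha-catenin: exponential Y decay
  traj2 <- integrate_model(model_params(),
                           initial_state(A_init = 0, alpha_cat_init = 0.5),
                           t_end = 6, n_samples = 25L)
  expect_equal(traj2$Y, exp(-0.5 * traj2$times), tolerance = 1e-7)
  expect_equal(traj2$C, rep(0.5, 25L), tolerance = 1e-9)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  # single reference scenario, fine oracle step
  tg <- seq(0, 3, by = 0.25)
  orc <- rk4_default(0.3, 0.5, tg, h = 1e-4)
  traj <- default_traj(0.3, 0.5, t_end = 3, n_samples = 13L)
  expect_equal(traj$Y, orc[, "Y"], tolerance = 1e-6)
  expect_lt(max(abs(traj$Y - orc[, "Y"])), 1e-6)

  # sup-norm agreement over random parameter/initial-state draws
  set.seed(101)
  tg10 <- seq(0, 10, by = 0.5)
  for (i in 1:10) {
    alpha <- runif(1, 0.05, 1.2)
    v_Y <- runif(1, 0.1, 1.0)
    A0 <- runif(1, 0.5, 2)
    Y0 <- runif(1, 0.5, 2)
    orc <- rk4_default(alpha, v_Y, tg10, h = 1e-3, A0 = A0, Y0 = Y0)
    traj <- default_traj(alpha, v_Y, t_end = 10, n_samples = 21L,
                         A_init = A0, Y_init = Y0)
    sup <- max(abs(cbind(traj$A, traj$Y, traj$C) - orc[, c("A", "Y", "C")]))
    expect_lt(sup, 1e-6)
  }
})

test_that("trajectories preserve positivity, monotonicity and ceilings", {
  set.seed(7)
  for (i in 1:12) {
    alpha <- runif(1, 0, 1.5)
    v_Y <- runif(1, 0.05, 1.2)
    Y0 <- runif(1, 0.2, 2)
    traj <- default_traj(alpha, v_Y, t_end = runif(1, 2, 15),
                         n_samples = 200L, Y_init = Y0)
    expect_true(all(traj$A >= 0) && all(traj$Y >= 0) && all(traj$C >= 0))
    expect_true(all(diff(traj$A) < 0))           # A strictly decreasing
    expect_true(all(diff(traj$C) >= -1e-9))      # C non-decreasing
    expect_true(all(traj$C <= traj$scales$C_max + 1e-9))
    expect_true(all(traj$Y <= traj$scales$Y_max + 1e-9))
  }
})

test_that("YAP/TAZ activity decays towards zero at long horizons", {
  for (alpha in c(0.1, 0.5, 1.0)) {
    traj <- default_traj(alpha, 0.5, t_end = 200, n_samples = 400L)
    expect_lt(traj$Y[400L], 1e-3)
    expect_lt(traj$Y[400L], traj$Y[200L])
  }
})

test_that("a zero initial alpha-catenin freezes the C equation", {
  traj <- default_traj(0, 0.5, t_end = 5, n_samples = 50L)
  expect_true(all(traj$C == 0))
  expect_true(all(is.finite(traj$Y)))
})

test_that("steady_state_check reports decay and terminal phase", {
  traj <- integrate_model(model_params(v_Y = 0),
                          initial_state(alpha_cat_init = 0),
                          t_end = 100, n_samples = 200L)
  chk <- steady_state_check(traj)
  expect_true(chk$A_decayed)
  expect_lt(chk$A_final, 1e-4)

  short <- default_traj(0.3, 0.5, t_end = 1, n_samples = 2L)
  expect_true(steady_state_check(short)$insufficient_samples)

  # low-alpha-cat run past the YAP peak: terminal phase is decreasing,
  # consistent with the sign of the rhs at the final sample
  traj2 <- default_traj(0.1, 0.5, t_end = 10, n_samples = 400L)
  chk2 <- steady_state_check(traj2)
  expect_false(chk2$insufficient_samples)
  expect_equal(chk2$terminal_dY, -1)
  n <- length(traj2$times)
  d_end <- model_rhs(c(traj2$A[n], traj2$Y[n], traj2$C[n]),
                     traj2$params, traj2$scales)
  expect_lt(d_end[["dY"]], 0)
})

test_that("trajectory writer round-trips values with full provenance", {
  traj <- default_traj(0.3, 0.5, t_end = 2, n_samples = 20L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_identical(names(back), c("t", "A", "Y", "C"))
  expect_equal(back$Y, traj$Y, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$params$v_Y, 0.5)
  expect_equal(side$init$alpha_cat_init, 0.3)
  expect_equal(side$scales$C_max, 0.9)
})
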