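# Independent oracles, written directly from the model definition and kept
# separate from the package's integration path.

# Hand-written right-hand side: plain transcription of the three equations,
# not a call into the package.
oracle_rhs <- function(y, cc, r1, r2, r3, v_Y, v_C, C_max, Y_max,
                       dA = 1, dY = 1, dC = 1) {
  A <- y[1]; Y <- y[2]; C <- y[3]
  c(-cc * A - v_Y * (1 - exp(-dA * Y)) * A,
    -r1 * Y * C + r2 * (1 - exp(-dY * A)) * (1 - Y / Y_max) * Y,
    if (C_max > 0) r3 * v_C * v_Y * (1 - exp(-dC * A)) * (1 - C / C_max) * C
    else 0)
}

# Classical fixed-step 4th-order Runge-Kutta. t_grid times must be integer
# multiples of h; returns a matrix with columns t, A, Y, C at the grid.
rk4_solve <- function(y0, t_grid, h, ...) {
  n_steps <- round(max(t_grid) / h)
  record_at <- round(t_grid / h)
  stopifnot(max(abs(record_at * h - t_grid)) < 1e-9)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 4L)
  colnames(out) <- c("t", "A", "Y", "C")
  y <- y0
  j <- 1L
  for (step in 0:n_steps) {
    if (j <= length(record_at) && step == record_at[j]) {
      out[j, ] <- c(step * h, y)
      j <- j + 1L
    }
    if (step == n_steps) break
    k1 <- oracle_rhs(y, ...)
    k2 <- oracle_rhs(y + h / 2 * k1, ...)
    k3 <- oracle_rhs(y + h / 2 * k2, ...)
    k4 <- oracle_rhs(y + h * k3, ...)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

# Convenience: oracle solve under default constants for a given initial
# alpha-catenin and feedback strength.
rk4_default <- function(alpha, v_Y, t_grid, h, A0 = 1, Y0 = 1) {
  rk4_solve(c(A0, Y0, alpha), t_grid, h,
            cc = 0.1, r1 = 1, r2 = 1.2, r3 = 3, v_Y = v_Y,
            v_C = alpha, C_max = 3 * alpha, Y_max = 4 * Y0)
}

default_traj <- function(alpha, v_Y = 0.5, t_end = 2.5, n_samples = 400L,
                         A_init = 1, Y_init = 1) {
  integrate_model(model_params(v_Y = v_Y),
                  initial_state(A_init = A_init, Y_init = Y_init,
                                alpha_cat_init = alpha),
                  t_end = t_end, n_samples = n_samples)
}
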