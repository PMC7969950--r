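#' Right-hand side of the three-ODE feedback loop
#'
#' Evaluates the instantaneous rates of change of autophagy \code{A},
#' YAP/TAZ activity \code{Y} and alpha-catenin \code{C}:
#' \deqn{dA/dt = -cA - v_Y (1 - e^{-\delta_A Y}) A}
#' \deqn{dY/dt = -r_1 Y C + r_2 (1 - e^{-\delta_Y A})(1 - Y/Y_{max}) Y}
#' \deqn{dC/dt = r_3 v_C v_Y (1 - e^{-\delta_C A})(1 - C/C_{max}) C}
#' The first equation combines the primary depletion of autophagy (the
#' inhibition being modelled) with the loss of YAP/TAZ-driven autophagosome
#' formation; the second balances alpha-catenin sequestration of YAP/TAZ
#' against its autophagy-dependent accumulation, saturating at
#' \code{Y_max}; the third accumulates alpha-catenin (an autophagy
#' substrate) towards its ceiling \code{C_max}. Protein synthesis is
#' neglected throughout.
#'
#' When \code{C(0) = 0} both \code{v_C} and \code{C_max} vanish and the
#' alpha-catenin equation is identically zero; \code{dC} is then returned as
#' 0 rather than evaluating the indeterminate \code{1 - C/C_max}.
#'
#' @param state Numeric vector \code{c(A, Y, C)} of non-negative finite
#'   levels.
#' @param params A \code{\link{model_params}} object.
#' @param scales A \code{\link{derived_scales}} object consistent with the
#'   run's initial state.
#'
#' @return Numeric vector \code{c(dA, dY, dC)}.
#' @export
#' @examples
#' p <- model_params(v_Y = 0.5)
#' s <- derived_scales(p, initial_state(alpha_cat_init = 0.1))
#' model_rhs(c(A = 1, Y = 1, C = 0.1), p, s)
model_rhs <- function(state, params, scales) {
  stopifnot(inherits(params, "catloop_params"),
            inherits(scales, "catloop_scales"))
  if (length(state) != 3L || !all(is.finite(state))) {
    stop("invalid state: expected three finite values (A, Y, C)", call. = FALSE)
  }
  A <- state[[1L]]; Y <- state[[2L]]; C <- state[[3L]]
  if (scales$C_max == 0 && C > 0) {
    stop("degenerate scale: C_max = 0 with non-zero C", call. = FALSE)
  }
  if (scales$Y_max == 0 && Y > 0) {
    stop("degenerate scale: Y_max = 0 with non-zero Y", call. = FALSE)
  }
  dA <- -params$c * A - params$v_Y * (1 - exp(-params$delta_A * Y)) * A
  dY <- if (scales$Y_max == 0) 0 else {
    -params$r1 * Y * C +
      params$r2 * (1 - exp(-params$delta_Y * A)) * (1 - Y / scales$Y_max) * Y
  }
  dC <- if (scales$C_max == 0) 0 else {
    params$r3 * scales$v_C * params$v_Y *
      (1 - exp(-params$delta_C * A)) * (1 - C / scales$C_max) * C
  }
  c(dA = dA, dY = dY, dC = dC)
}

#' Integrate the feedback-loop model
#'
#' Solves the three coupled ODEs with an adaptive Dormand--Prince
#' Runge--Kutta scheme (\code{deSolve} method \code{"ode45"},
#' \code{rtol = 1e-8}, \code{atol = 1e-10}) and returns the solution on an
#' equally spaced time grid, independent of the internal adaptive steps, so
#' that downstream correlation windows and horizon look-ups are well
#' defined. The saturation scales \code{v_C}, \code{C_max}, \code{Y_max}
#' are derived from this run's own initial state.
#'
#' @param params A \code{\link{model_params}} object.
#' @param init An \code{\link{initial_state}} object.
#' @param t_end End of the integration window (model-time units, > 0).
#' @param n_samples Number of equally spaced samples including t = 0
#'   (>= 2; default 400).
#' @param rtol,atol Integrator tolerances.
#'
#' @return A \code{catloop_trajectory}: list with \code{times}, \code{A},
#'   \code{Y}, \code{C} (equal-length numeric vectors) and provenance copies
#'   \code{params}, \code{init}, \code{scales}.
#' @export
#' @examples
#' traj <- integrate_model(model_params(v_Y = 0.5),
#'                         initial_state(alpha_cat_init = 0.3),
#'                         t_end = 3)
#' tail(traj$Y, 1)
integrate_model <- function(params = model_params(), init = initial_state(),
                            t_end, n_samples = 400L,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "catloop_params"), inherits(init, "catloop_init"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    stop("t_end must be a single positive number", call. = FALSE)
  }
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  scales <- derived_scales(params, init)
  times <- seq(0, t_end, length.out = n_samples)
  y0 <- c(A = init$A_init, Y = init$Y_init, C = init$alpha_cat_init)

  deriv <- function(t, y, parms) {
    list(model_rhs(y, params, scales))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < n_samples || !all(is.finite(sol))) {
    last_t <- if (nrow(sol) > 0) sol[nrow(sol), "time"] else NA_real_
    stop("integration failed; last valid time: ", format(last_t),
         call. = FALSE)
  }
  # Absorb sub-tolerance negative overshoot from the adaptive stepper; a
  # genuinely negative solution would signal a model/integrator defect.
  clamp <- function(v) {
    if (any(v < -1e2 * atol)) {
      stop("integration produced negative levels beyond tolerance",
           call. = FALSE)
    }
    pmax(v, 0)
  }
  structure(list(times = sol[, "time"],
                 A = clamp(sol[, "A"]),
                 Y = clamp(sol[, "Y"]),
                 C = clamp(sol[, "C"]),
                 params = params, init = init, scales = scales),
            class = "catloop_trajectory")
}

#' @export
print.catloop_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<catloop trajectory: %d samples on [0, %g]>\n",
              n, x$times[n]))
  cat(sprintf("  A: %.4g -> %.4g | Y: %.4g -> %.4g | C: %.4g -> %.4g\n",
              x$A[1], x$A[n], x$Y[1], x$Y[n], x$C[1], x$C[n]))
  invisible(x)
}

#' @export
as.data.frame.catloop_trajectory <- function(x, ...) {
  data.frame(t = x$times, A = x$A, Y = x$Y, C = x$C)
}

#' Check decay and terminal behaviour of a trajectory
#'
#' Reports whether autophagy has decayed below \code{eps} by the end of the
#' window and whether YAP/TAZ activity is in its terminal monotone phase
#' (all finite differences over the last \code{terminal_frac} of samples
#' share one sign). Used to validate horizon choices before running the
#' direction and correlation analyses.
#'
#' @param traj A \code{catloop_trajectory}.
#' @param eps Decay threshold on the final autophagy level.
#' @param terminal_frac Fraction of trailing samples defining the terminal
#'   window (at least 5 samples are required).
#'
#' @return List with \code{A_final}, \code{A_decayed}, \code{terminal_dY}
#'   (sign of the last finite difference of Y: -1, 0 or 1),
#'   \code{terminal_monotone} and \code{insufficient_samples}.
#' @export
steady_state_check <- function(traj, eps = 1e-4, terminal_frac = 0.1) {
  stopifnot(inherits(traj, "catloop_trajectory"))
  n <- length(traj$times)
  k <- max(5L, ceiling(terminal_frac * n))
  if (n < k + 1L) {
    return(list(A_final = traj$A[n], A_decayed = traj$A[n] < eps,
                terminal_dY = NA_real_, terminal_monotone = NA,
                insufficient_samples = TRUE))
  }
  dY <- diff(traj$Y[(n - k):n])
  list(A_final = traj$A[n],
       A_decayed = traj$A[n] < eps,
       terminal_dY = sign(dY[length(dY)]),
       terminal_monotone = all(dY <= 0) || all(dY >= 0),
       insufficient_samples = FALSE)
}

#' Write a trajectory to CSV with a JSON provenance sidecar
#'
#' Writes the time series as \code{t,A,Y,C} and, next to it, a
#' \code{<path>.json} sidecar recording the full parameter set, initial
#' state and derived scales so the run can be reproduced exactly.
#'
#' @param traj A \code{catloop_trajectory}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "catloop_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  side <- list(params = unclass(traj$params), init = unclass(traj$init),
               scales = unclass(traj$scales),
               package_version = as.character(utils::packageVersion("catloop")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
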