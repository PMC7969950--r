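#' Classify the direction of the YAP/TAZ response
#'
#' Compares YAP/TAZ activity at the evaluation horizon T with its initial
#' value: \code{"increase"} if \code{Y(T) > Y_init * (1 + tie_eps)},
#' \code{"decrease"} if \code{Y(T) < Y_init * (1 - tie_eps)}, else
#' \code{"unchanged"}. Y(T) is read from the trajectory's dense output grid
#' (nearest sample, at most half a grid step from T). The relative tie
#' tolerance defaults to 1e-6, far below integrator error visibility.
#'
#' With the reference parameterisation (v_Y = 0.5, horizon T = 2.5), high
#' initial alpha-catenin (> 0.5) yields a decrease and low initial
#' alpha-catenin (< 0.3) an increase — the two regimes observed across
#' cell lines with high (MCF10A-like) versus low (HepG2-like) basal
#' alpha-catenin.
#'
#' @param traj A \code{catloop_trajectory}.
#' @param T Evaluation horizon; must lie within the trajectory span.
#' @param tie_eps Relative tolerance for the "unchanged" band.
#'
#' @return List with \code{label}, \code{Y_T}, \code{Y_rel}
#'   (Y(T)/Y_init) and \code{T}.
#' @export
#' @examples
#' traj <- integrate_model(model_params(v_Y = 0.5),
#'                         initial_state(alpha_cat_init = 0.8), t_end = 2.5)
#' classify_direction(traj, T = 2.5)$label
classify_direction <- function(traj, T, tie_eps = 1e-6) {
  stopifnot(inherits(traj, "catloop_trajectory"))
  tspan <- range(traj$times)
  step <- traj$times[2L] - traj$times[1L]
  if (T < tspan[1L] - step / 2 || T > tspan[2L] + step / 2) {
    stop("horizon T = ", T, " outside trajectory span [",
         tspan[1L], ", ", tspan[2L], "]", call. = FALSE)
  }
  i <- which.min(abs(traj$times - T))
  y0 <- traj$init$Y_init
  yT <- traj$Y[i]
  label <- if (yT > y0 * (1 + tie_eps)) "increase"
           else if (yT < y0 * (1 - tie_eps)) "decrease"
           else "unchanged"
  list(label = label, Y_T = yT,
       Y_rel = if (y0 > 0) yT / y0 else NA_real_, T = traj$times[i])
}

#' Locate the alpha-catenin flip boundary by bisection
#'
#' Finds the initial alpha-catenin level at which the finite-horizon
#' YAP/TAZ response to autophagy inhibition switches from net increase to
#' net decrease: the root of \code{Y(T) - Y_init} as a function of
#' \code{alpha_cat_init}, bisected within \code{bracket}. Requires an
#' increase at the low end and a decrease at the high end; if no sign
#' change exists in the bracket, returns \code{NA} with a diagnostic rather
#' than raising an error. This is a finite-horizon classification boundary,
#' not a fixed-point bifurcation.
#'
#' @param params A \code{\link{model_params}} object; its \code{v_Y} (or the
#'   \code{v_Y} argument, if supplied) sets the feedback strength.
#' @param init Template \code{\link{initial_state}}; \code{alpha_cat_init}
#'   is overwritten by the bisection.
#' @param v_Y Optional override of the feedback strength.
#' @param T Evaluation horizon.
#' @param bracket Length-2 search interval for alpha_cat_init.
#' @param tol Absolute tolerance on the boundary location.
#' @param n_samples Samples per trial integration.
#'
#' @return List with \code{boundary} (NA if no sign change), \code{g_low},
#'   \code{g_high} (endpoint values of Y(T) - Y_init), \code{iterations}
#'   and \code{diagnostic}.
#' @export
#' @examples
#' find_flip_boundary(model_params(), initial_state(), v_Y = 0.5, T = 2.5)
find_flip_boundary <- function(params = model_params(),
                               init = initial_state(), v_Y = NULL,
                               T = 2.5, bracket = c(0.05, 1.0),
                               tol = 1e-4, n_samples = 101L) {
  stopifnot(inherits(params, "catloop_params"), inherits(init, "catloop_init"))
  if (!is.null(v_Y)) params$v_Y <- v_Y
  g <- function(alpha) {
    ii <- init; ii$alpha_cat_init <- alpha
    traj <- integrate_model(params, ii, t_end = T, n_samples = n_samples)
    traj$Y[length(traj$Y)] - init$Y_init
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  g_lo <- g(lo); g_hi <- g(hi)
  if (!(g_lo > 0 && g_hi < 0)) {
    return(list(boundary = NA_real_, g_low = g_lo, g_high = g_hi,
                iterations = 0L,
                diagnostic = paste0(
                  "no increase-to-decrease sign change in bracket [",
                  lo, ", ", hi, "]: endpoint responses ",
                  sprintf("%.3g, %.3g", g_lo, g_hi))))
  }
  iter <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  list(boundary = (lo + hi) / 2, g_low = g_lo, g_high = g_hi,
       iterations = iter, diagnostic = "ok")
}

#' Flip-boundary sensitivity to the evaluation horizon
#'
#' Diagnostic table of the flip boundary across candidate horizons, for
#' assessing how strongly a direction analysis depends on the choice of T.
#' The boundary decreases as the horizon grows (longer inhibition gives
#' alpha-catenin more time to accumulate, so less initial alpha-catenin
#' suffices to turn the response downward).
#'
#' @param params A \code{\link{model_params}} object.
#' @param init Template \code{\link{initial_state}}.
#' @param T_values Horizons to profile.
#' @param ... Passed to \code{\link{find_flip_boundary}}.
#'
#' @return Data frame with columns \code{T} and \code{boundary} (NA where
#'   no flip exists in the bracket).
#' @export
flip_boundary_profile <- function(params = model_params(),
                                  init = initial_state(),
                                  T_values = seq(1.5, 4, by = 0.5), ...) {
  data.frame(T = T_values,
             boundary = vapply(T_values, function(T) {
               find_flip_boundary(params, init, T = T, ...)$boundary
             }, numeric(1)))
}

#' Time of maximal YAP/TAZ activity
#'
#' Returns the sample time at which Y attains its maximum, ties broken
#' toward the earliest sample. In the low-alpha-catenin regime this is the
#' changepoint at which accumulated alpha-catenin starts to dominate and
#' YAP/TAZ turns from rising to falling.
#'
#' @param traj A \code{catloop_trajectory}.
#' @return The peak time (numeric scalar).
#' @export
yap_peak_time <- function(traj) {
  stopifnot(inherits(traj, "catloop_trajectory"))
  traj$times[which.max(traj$Y)]
}

#' Windowed Pearson correlation between YAP/TAZ and autophagy
#'
#' Splits the sample grid at the time of maximum Y (both windows include
#' the peak sample) and computes the Pearson correlation between the
#' sampled Y and A values within each window. In the low-alpha-catenin
#' inhibition scenario Y first rises while A falls (strongly negative
#' early-window correlation) and then falls together with A once
#' alpha-catenin sequestration dominates (positive late-window
#' correlation).
#'
#' A window with zero variance in Y or A raises an undefined-correlation
#' error. If the Y maximum sits at either end of the grid there is no
#' interior peak: the degenerate window's correlation is reported as NA
#' with a diagnostic and the other window is still computed.
#'
#' @param traj A \code{catloop_trajectory} with at least 10 samples per
#'   window for a fully defined result.
#' @param min_window Minimum samples per window before a window is
#'   considered defined.
#'
#' @return List with \code{R_early}, \code{R_late}, \code{t_peak},
#'   \code{n_early}, \code{n_late} and \code{diagnostic}.
#' @export
#' @examples
#' traj <- integrate_model(model_params(v_Y = 0.5),
#'                         initial_state(alpha_cat_init = 0.1), t_end = 10)
#' windowed_correlation(traj)[c("R_early", "R_late")]
windowed_correlation <- function(traj, min_window = 10L) {
  stopifnot(inherits(traj, "catloop_trajectory"))
  n <- length(traj$times)
  ip <- which.max(traj$Y)
  win_cor <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    if (stats::sd(traj$Y[idx]) == 0 || stats::sd(traj$A[idx]) == 0) {
      stop("undefined correlation: zero variance within window",
           call. = FALSE)
    }
    stats::cor(traj$Y[idx], traj$A[idx])
  }
  early <- seq_len(ip)
  late <- ip:n
  diag <- "ok"
  if (ip == 1L || ip == n) diag <- "no interior Y peak"
  else if (length(early) < min_window || length(late) < min_window) {
    diag <- "fewer samples than min_window in one window"
  }
  list(R_early = if (ip == 1L) NA_real_ else win_cor(early),
       R_late = if (ip == n) NA_real_ else win_cor(late),
       t_peak = traj$times[ip],
       n_early = length(early), n_late = length(late),
       diagnostic = diag)
}
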