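#' Model parameters for the autophagy--alpha-catenin--YAP/TAZ loop
#'
#' Rate constants, saturation scales and feedback strength of the three-ODE
#' model. Defaults are the reference parameterisation of the loop:
#' \code{c = 0.1}, \code{r1 = 1.0}, \code{r2 = 1.2}, \code{r3 = 3.0},
#' \code{k = 1.0}, \code{k_C = 3.0}, \code{k_Y = 4.0} and all saturation
#' exponents equal to 1. The feedback strength \code{v_Y} (how strongly
#' YAP/TAZ activity sustains autophagy) defaults to the reference value 0.5
#' used throughout the direction and boundary analyses; it is the first of
#' the two swept quantities of the response-surface analysis.
#'
#' @param c Primary autophagy depletion rate (genetic or chemical
#'   inhibition), per model-time unit.
#' @param r1 YAP/TAZ sequestration rate by alpha-catenin.
#' @param r2 YAP/TAZ accumulation rate.
#' @param r3 alpha-catenin accumulation rate.
#' @param k Scale factor for the alpha-catenin accumulation coefficient
#'   \code{v_C = k * C(0)}.
#' @param k_C Scale factor for the alpha-catenin ceiling
#'   \code{C_max = k_C * C(0)}.
#' @param k_Y Scale factor for the YAP/TAZ activity ceiling
#'   \code{Y_max = k_Y * Y(0)}.
#' @param delta_A,delta_Y,delta_C Saturation exponents of the
#'   \code{1 - exp(-delta * x)} terms.
#' @param v_Y Feedback-loop strength: YAP/TAZ influence over autophagy.
#'
#' @return An object of class \code{catloop_params} (a named list).
#' @export
#' @examples
#' p <- model_params()
#' p$v_Y
model_params <- function(c = 0.1, r1 = 1.0, r2 = 1.2, r3 = 3.0,
                         k = 1.0, k_C = 3.0, k_Y = 4.0,
                         delta_A = 1.0, delta_Y = 1.0, delta_C = 1.0,
                         v_Y = 0.5) {
  p <- list(c = c, r1 = r1, r2 = r2, r3 = r3, k = k, k_C = k_C, k_Y = k_Y,
            delta_A = delta_A, delta_Y = delta_Y, delta_C = delta_C, v_Y = v_Y)
  for (nm in names(p)) {
    v <- p[[nm]]
    # v_Y = 0 (no feedback) is a meaningful limiting case; all other
    # constants must be strictly positive
    lo_ok <- if (nm == "v_Y") v >= 0 else v > 0
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || !lo_ok) {
      stop("model parameter '", nm, "' must be a single finite positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "catloop_params")
}

#' Initial state of the loop
#'
#' Dimensionless initial levels: autophagy \code{A(0)}, YAP/TAZ activity
#' \code{Y(0)} and alpha-catenin \code{C(0)} (written "alpha-cat" in the
#' response-surface analyses). \code{A_init = Y_init = 1} is the reference
#' state at the onset of autophagy inhibition; \code{alpha_cat_init = 1}
#' corresponds to a high-alpha-catenin (MCF10A-like) reference line, against
#' which other lines' basal levels are expressed as relative ratios.
#'
#' @param A_init Initial autophagy level.
#' @param Y_init Initial YAP/TAZ activity.
#' @param alpha_cat_init Initial alpha-catenin level \code{C(0)}.
#'
#' @return An object of class \code{catloop_init} (a named list).
#' @export
initial_state <- function(A_init = 1.0, Y_init = 1.0, alpha_cat_init = 1.0) {
  s <- list(A_init = A_init, Y_init = Y_init, alpha_cat_init = alpha_cat_init)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("initial state field '", nm, "' must be a single finite ",
           "non-negative number", call. = FALSE)
    }
  }
  structure(s, class = "catloop_init")
}

#' Derived saturation scales
#'
#' Quantities defined from the initial state rather than free constants:
#' the alpha-catenin accumulation coefficient \code{v_C = k * C(0)}, the
#' alpha-catenin ceiling \code{C_max = k_C * C(0)} and the YAP/TAZ activity
#' ceiling \code{Y_max = k_Y * Y(0)}. They are recomputed from each run's
#' own initial state, including for every cell of a parameter sweep.
#'
#' @param params A \code{\link{model_params}} object.
#' @param init An \code{\link{initial_state}} object.
#'
#' @return An object of class \code{catloop_scales} with fields \code{v_C},
#'   \code{C_max}, \code{Y_max}.
#' @export
#' @examples
#' derived_scales(model_params(), initial_state(alpha_cat_init = 0.3))
derived_scales <- function(params, init) {
  stopifnot(inherits(params, "catloop_params"), inherits(init, "catloop_init"))
  structure(list(v_C = params$k * init$alpha_cat_init,
                 C_max = params$k_C * init$alpha_cat_init,
                 Y_max = params$k_Y * init$Y_init),
            class = "catloop_scales")
}

#' @export
print.catloop_params <- function(x, ...) {
  cat("<catloop model parameters>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.catloop_init <- function(x, ...) {
  cat("<catloop initial state>\n")
  print(unlist(x))
  invisible(x)
}
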