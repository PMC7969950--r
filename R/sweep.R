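#' Specify a two-axis parameter sweep
#'
#' Defines the grid for a response-surface run. The default grid is the
#' reference sweep of feedback strength \code{v_Y} and initial
#' alpha-catenin, each over the 10 values 0.1, 0.2, ..., 1.0 (endpoints
#' included). Initial-state axes (\code{A_init}, \code{Y_init}) sweep
#' 0.1 to 2.0 by default when selected. Axis names must be one of
#' \code{"v_Y"}, \code{"alpha_cat_init"}, \code{"A_init"}, \code{"Y_init"}.
#'
#' @param axis1,axis2 Axis names.
#' @param axis1_values,axis2_values Strictly increasing positive values;
#'   defaults depend on the axis name as described above.
#' @param params Fixed \code{\link{model_params}} for non-swept parameters.
#' @param init Fixed \code{\link{initial_state}} for non-swept state fields.
#' @param t_end Evaluation horizon T at which the surface is read out.
#' @param n_samples Samples per trajectory.
#'
#' @return A \code{catloop_sweep_spec}.
#' @export
sweep_spec <- function(axis1 = "v_Y", axis2 = "alpha_cat_init",
                       axis1_values = default_axis_values(axis1),
                       axis2_values = default_axis_values(axis2),
                       params = model_params(), init = initial_state(),
                       t_end = 2.5, n_samples = 201L) {
  ok_axes <- c("v_Y", "alpha_cat_init", "A_init", "Y_init")
  if (!(axis1 %in% ok_axes) || !(axis2 %in% ok_axes) || axis1 == axis2) {
    stop("axes must be two distinct names among: ",
         paste(ok_axes, collapse = ", "), call. = FALSE)
  }
  for (v in list(axis1_values, axis2_values)) {
    if (!is.numeric(v) || length(v) < 1L || any(v <= 0) ||
        is.unsorted(v, strictly = TRUE)) {
      stop("axis values must be strictly increasing and positive",
           call. = FALSE)
    }
  }
  structure(list(axis1 = axis1, axis1_values = axis1_values,
                 axis2 = axis2, axis2_values = axis2_values,
                 params = params, init = init,
                 t_end = t_end, n_samples = as.integer(n_samples)),
            class = "catloop_sweep_spec")
}

#' Default axis values for a sweep
#'
#' 0.1 to 1.0 in 10 steps for \code{v_Y} and \code{alpha_cat_init};
#' 0.1 to 2.0 in 20 steps for \code{A_init} and \code{Y_init}.
#'
#' @param axis Axis name.
#' @return Numeric vector of axis values.
#' @export
default_axis_values <- function(axis) {
  switch(axis,
         v_Y = seq(0.1, 1.0, by = 0.1),
         alpha_cat_init = seq(0.1, 1.0, by = 0.1),
         A_init = seq(0.1, 2.0, by = 0.1),
         Y_init = seq(0.1, 2.0, by = 0.1),
         stop("unknown axis: ", axis, call. = FALSE))
}

set_axis <- function(params, init, axis, value) {
  if (axis == "v_Y") params$v_Y <- value else init[[axis]] <- value
  list(params = params, init = init)
}

#' Run a parameter sweep and build the response surface
#'
#' Integrates one trajectory per grid cell, with the non-swept parameters
#' shared across all cells and the saturation scales (\code{v_C},
#' \code{C_max}, \code{Y_max}) re-derived per cell from that cell's own
#' initial state. Each cell records the terminal levels at the horizon T
#' and the direction of the YAP/TAZ response (see
#' \code{\link{classify_direction}}).
#'
#' @param spec A \code{\link{sweep_spec}}.
#' @param tie_eps Relative tolerance for the "unchanged" direction label.
#'
#' @return A data frame of class \code{catloop_surface} with one row per
#'   cell and columns \code{axis1}, \code{axis2}, \code{A_T}, \code{Y_T},
#'   \code{Y_rel} (Y(T)/Y_init), \code{C_T}, \code{C_rel} (C(T)/C(0), NA
#'   when C(0) = 0) and \code{direction}. The spec is attached as attribute
#'   \code{"spec"}.
#' @export
#' @examples
#' surf <- run_sweep(sweep_spec(axis1_values = c(0.3, 0.5),
#'                              axis2_values = c(0.1, 0.8)))
#' surf[, c("axis1", "axis2", "Y_rel", "direction")]
run_sweep <- function(spec, tie_eps = 1e-6) {
  stopifnot(inherits(spec, "catloop_sweep_spec"))
  grid <- expand.grid(axis1 = spec$axis1_values, axis2 = spec$axis2_values,
                      KEEP.OUT.ATTRS = FALSE)
  # axis1 varies fastest; reorder so axis1 is the outer (slow) index
  grid <- grid[order(grid$axis1, grid$axis2), , drop = FALSE]
  rownames(grid) <- NULL
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pi0 <- set_axis(spec$params, spec$init, spec$axis1, grid$axis1[i])
    pi <- set_axis(pi0$params, pi0$init, spec$axis2, grid$axis2[i])
    traj <- tryCatch(
      integrate_model(pi$params, pi$init, t_end = spec$t_end,
                      n_samples = spec$n_samples),
      error = function(e) {
        stop(sprintf("sweep cell (%s=%g, %s=%g) failed: %s",
                     spec$axis1, grid$axis1[i], spec$axis2, grid$axis2[i],
                     conditionMessage(e)), call. = FALSE)
      })
    n <- length(traj$times)
    c0 <- pi$init$alpha_cat_init
    dir <- classify_direction(traj, T = spec$t_end, tie_eps = tie_eps)
    data.frame(axis1 = grid$axis1[i], axis2 = grid$axis2[i],
               A_T = traj$A[n], Y_T = traj$Y[n],
               Y_rel = traj$Y[n] / pi$init$Y_init,
               C_T = traj$C[n],
               C_rel = if (c0 > 0) traj$C[n] / c0 else NA_real_,
               direction = dir$label)
  })
  surf <- do.call(rbind, rows)
  attr(surf, "spec") <- spec
  class(surf) <- c("catloop_surface", "data.frame")
  surf
}

#' Alpha-catenin accumulation across a response surface
#'
#' Per-cell fold change \code{C(T)/C(0)} and absolute increase
#' \code{C(T) - C(0)}, the quantities behind the model prediction that
#' lines with lower basal alpha-catenin accumulate less alpha-catenin upon
#' autophagy inhibition. Cells with \code{C(0) = 0} are reported with an
#' undefined (NA) fold change.
#'
#' @param surface A \code{catloop_surface} whose spec swept
#'   \code{alpha_cat_init} on one axis (otherwise \code{C(0)} is the fixed
#'   initial value for every cell).
#'
#' @return Data frame with \code{axis1}, \code{axis2}, \code{C_0},
#'   \code{C_T}, \code{fold_change}, \code{abs_increase}.
#' @export
relative_accumulation <- function(surface) {
  stopifnot(inherits(surface, "catloop_surface"))
  spec <- attr(surface, "spec")
  c0 <- if (spec$axis1 == "alpha_cat_init") surface$axis1
        else if (spec$axis2 == "alpha_cat_init") surface$axis2
        else rep(spec$init$alpha_cat_init, nrow(surface))
  data.frame(axis1 = surface$axis1, axis2 = surface$axis2,
             C_0 = c0, C_T = surface$C_T,
             fold_change = ifelse(c0 > 0, surface$C_T / c0, NA_real_),
             abs_increase = surface$C_T - c0)
}

#' Write a response surface to long-format CSV
#'
#' Columns \code{axis1,axis2,A_T,Y_T,Y_rel,C_T,C_rel,direction}, plus a
#' JSON sidecar with the resolved sweep specification.
#'
#' @param surface A \code{catloop_surface}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "catloop_surface"))
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                   quote = FALSE)
  spec <- attr(surface, "spec")
  side <- list(axis1 = spec$axis1, axis1_values = spec$axis1_values,
               axis2 = spec$axis2, axis2_values = spec$axis2_values,
               params = unclass(spec$params), init = unclass(spec$init),
               t_end = spec$t_end, n_samples = spec$n_samples,
               package_version = as.character(utils::packageVersion("catloop")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
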