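#' Replicate noise model for synthetic readouts
#'
#' Multiplicative lognormal noise for densitometry and luciferase
#' replicates: a readout with centre m is drawn as
#' \code{m * exp(rnorm(1, 0, sdlog))} with \code{sdlog} chosen so the
#' distribution's coefficient of variation equals \code{cv}
#' (\code{sdlog = sqrt(log(1 + cv^2))}). The centre is the distribution's
#' median, so geometric-mean estimators are unbiased for it on the log
#' scale. \code{cv = 0} degenerates to noiseless readouts.
#'
#' @param cv Coefficient of variation (>= 0; default 0.2, a typical
#'   replicate spread for densitometry/luciferase ratios).
#' @param n_replicates Replicates per line and condition (3--6 in the
#'   emulated designs; default 4).
#' @param seed Integer seed for reproducible panels (NULL leaves the RNG
#'   state untouched).
#'
#' @return A \code{catloop_noise} object.
#' @export
noise_model <- function(cv = 0.2, n_replicates = 4L, seed = NULL) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0) {
    stop("cv must be a single non-negative number", call. = FALSE)
  }
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(family = "lognormal", cv = cv,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "catloop_noise")
}

draw_replicates <- function(centre, noise) {
  if (noise$cv == 0) return(rep(centre, noise$n_replicates))
  sdlog <- sqrt(log(1 + noise$cv^2))
  centre * exp(stats::rnorm(noise$n_replicates, 0, sdlog))
}

#' Generate a synthetic multi-cell-line panel
#'
#' Emulates the measurement design used to read the loop out in cells:
#' per-line basal CTNNA1 densitometry ratios relative to a high-alpha-
#' catenin reference line (pinned at 1.0, "MCF10A_like"), CTNNA1 after
#' autophagy knockdown, and TEAD luciferase activity (a firefly/renilla
#' proxy for YAP/TAZ activity) under each condition — all centred on the
#' forward model and perturbed with multiplicative lognormal replicate
#' noise. High-regime lines draw their true basal alpha-catenin from
#' [0.5, 1.2] and low-regime lines from [0.05, 0.3], mirroring the two
#' observed classes of basal CTNNA1 ratios.
#'
#' Conditions: \code{"baseline"} (readouts centred on the initial state),
#' \code{"knockdown"} (the model's primary autophagy inhibition, read out
#' at horizon \code{T_kd}) and \code{"induction"} (autophagy induction
#' represented as an elevated initial autophagy level
#' \code{induction_A_init}, read out at \code{T_induction}).
#'
#' @param n_lines_per_regime Cell lines per regime (>= 1). The first
#'   high-regime line is the reference with true alpha_cat_init = 1.
#' @param noise A \code{\link{noise_model}}; its seed (if non-NULL) makes
#'   the whole panel reproducible.
#' @param params Shared \code{\link{model_params}}; its \code{v_Y} is the
#'   true feedback strength of every line.
#' @param horizons Named numeric vector \code{c(T_kd =, T_induction =)}.
#' @param induction_A_init Initial autophagy level representing induction.
#'
#' @return A data frame of class \code{catloop_panel} with columns
#'   \code{line}, \code{regime}, \code{condition}, \code{replicate},
#'   \code{readout_type} (\code{"CTNNA1"} or \code{"TEAD"}) and
#'   \code{value}; ground truth and generation metadata are attached as
#'   attributes \code{"ground_truth"} and \code{"meta"}.
#' @export
#' @examples
#' panel <- generate_panel(n_lines_per_regime = 2,
#'                         noise = noise_model(cv = 0.2, seed = 1))
#' head(panel)
generate_panel <- function(n_lines_per_regime = 10L,
                           noise = noise_model(),
                           params = model_params(),
                           horizons = c(T_kd = 2.5, T_induction = 2.5),
                           induction_A_init = 2.0) {
  stopifnot(inherits(noise, "catloop_noise"),
            inherits(params, "catloop_params"))
  if (n_lines_per_regime < 1L) stop("need >= 1 line per regime", call. = FALSE)
  if (!all(c("T_kd", "T_induction") %in% names(horizons))) {
    stop("horizons must name T_kd and T_induction", call. = FALSE)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)

  n <- n_lines_per_regime
  alpha_high <- c(1.0, if (n > 1L) stats::runif(n - 1L, 0.5, 1.2))
  alpha_low <- stats::runif(n, 0.05, 0.3)
  lines <- data.frame(
    line = c("MCF10A_like",
             if (n > 1L) paste0("high_", seq_len(n)[-1L]),
             paste0("low_", seq_len(n))),
    regime = rep(c("high", "low"), each = n),
    alpha_cat_init = c(alpha_high, alpha_low),
    v_Y = params$v_Y,
    stringsAsFactors = FALSE)

  one_line <- function(j) {
    alpha <- lines$alpha_cat_init[j]
    kd <- integrate_model(params, initial_state(alpha_cat_init = alpha),
                          t_end = horizons[["T_kd"]], n_samples = 101L)
    ind <- integrate_model(params,
                           initial_state(A_init = induction_A_init,
                                         alpha_cat_init = alpha),
                           t_end = horizons[["T_induction"]],
                           n_samples = 101L)
    m <- length(kd$times)
    centres <- data.frame(
      condition = rep(c("baseline", "knockdown", "induction"), each = 2L),
      readout_type = rep(c("CTNNA1", "TEAD"), 3L),
      centre = c(alpha, 1.0,
                 kd$C[m], kd$Y[m],
                 ind$C[length(ind$times)], ind$Y[length(ind$times)]))
    do.call(rbind, lapply(seq_len(nrow(centres)), function(r) {
      data.frame(line = lines$line[j], regime = lines$regime[j],
                 condition = centres$condition[r],
                 replicate = seq_len(noise$n_replicates),
                 readout_type = centres$readout_type[r],
                 value = draw_replicates(centres$centre[r], noise),
                 stringsAsFactors = FALSE)
    }))
  }
  panel <- do.call(rbind, lapply(seq_len(nrow(lines)), one_line))
  rownames(panel) <- NULL
  attr(panel, "ground_truth") <- lines
  attr(panel, "meta") <- list(noise = unclass(noise),
                              params = unclass(params),
                              horizons = as.list(horizons),
                              induction_A_init = induction_A_init)
  class(panel) <- c("catloop_panel", "data.frame")
  panel
}

#' Summarise a synthetic panel per line and condition
#'
#' Mean, standard deviation, standard error of the mean and replicate
#' count per line, condition and readout type; the s.d. is reported as NA
#' for a single replicate.
#'
#' @param panel A \code{catloop_panel}.
#' @return A data frame with one row per (line, condition, readout_type).
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "catloop_panel"))
  key <- interaction(panel$line, panel$condition, panel$readout_type,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(panel, key), function(g) {
    n <- nrow(g)
    s <- if (n > 1L) stats::sd(g$value) else NA_real_
    data.frame(line = g$line[1L], condition = g$condition[1L],
               readout_type = g$readout_type[1L],
               n = n, mean = mean(g$value), sd = s,
               sem = if (n > 1L) s / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$line, out$condition, out$readout_type), , drop = FALSE]
}

#' Write a panel to tidy CSV with a ground-truth sidecar
#'
#' Columns \code{line,regime,condition,replicate,readout_type,value};
#' the JSON sidecar \code{<path>.json} records the true per-line
#' parameters and the noise/model configuration.
#'
#' @param panel A \code{catloop_panel}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "catloop_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  side <- list(ground_truth = attr(panel, "ground_truth"),
               meta = attr(panel, "meta"),
               package_version = as.character(utils::packageVersion("catloop")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a panel written by \code{\link{write_panel}}
#'
#' Restores the tidy readout table and, when the JSON sidecar is present,
#' the ground-truth and metadata attributes.
#'
#' @param path CSV path.
#' @return A \code{catloop_panel}.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(panel, "ground_truth") <- side$ground_truth
    attr(panel, "meta") <- side$meta
  }
  class(panel) <- c("catloop_panel", "data.frame")
  panel
}
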