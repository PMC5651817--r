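#' Simulate gLV dynamics
#'
#' Integrates the gLV system on a fixed time grid with an adaptive
#' stiff-capable solver (deSolve's `lsoda`). Trajectories started from
#' nonnegative states are nonnegative analytically; tiny negative excursions
#' from floating-point noise (magnitude below `clip_tol`) are clipped to
#' zero. States exceeding `overflow` in magnitude abort the integration with
#' an error naming the failure time — divergent parameterizations are
#' expected while sampling candidate interaction matrices.
#'
#' @param model A [community_model()].
#' @param y0 Nonnegative initial abundance vector.
#' @param times Strictly increasing numeric time grid.
#' @param atol,rtol Absolute and relative solver tolerances.
#' @param clip_tol Negative components smaller in magnitude than this are
#'   clipped to 0; larger negative excursions raise an error.
#' @param overflow Abort threshold on `max(abs(y))`.
#' @return A `glv_trajectory`: list with `times` and a `length(times) x n`
#'   `states` matrix (columns named by taxa).
#' @export
simulate_glv <- function(model, y0, times, atol = 1e-9, rtol = 1e-7,
                         clip_tol = 1e-10, overflow = 1e6) {
  y0 <- check_state(y0, model, "y0")
  if (any(y0 < 0)) stop("y0 must be nonnegative")
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least two points")
  }
  r <- unname(model$r)
  A <- unname(model$A)
  deriv <- function(t, y, parms) {
    if (max(abs(y)) > overflow) {
      stop(sprintf("gLV integration overflow (|y| > %g) at time %g",
                   overflow, t), call. = FALSE)
    }
    list(y * (r + A %*% y))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (nrow(states) < length(times) || anyNA(states)) {
    stop(sprintf("gLV integration failed near time %g",
                 sol[nrow(sol), 1]))
  }
  if (max(abs(states)) > overflow) {
    bad <- which(apply(abs(states), 1, max) > overflow)[1]
    stop(sprintf("gLV integration overflow (|y| > %g) at time %g",
                 overflow, times[bad]))
  }
  neg <- states < 0
  if (any(states[neg] < -clip_tol)) {
    worst <- min(states)
    stop(sprintf("trajectory went negative (min %g) beyond clip tolerance %g",
                 worst, clip_tol))
  }
  states[neg] <- 0
  colnames(states) <- model$taxa
  structure(list(times = times, states = states, taxa = model$taxa),
            class = "glv_trajectory")
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat(sprintf("gLV trajectory: %d taxa, %d time points on [%g, %g]\n",
              ncol(x$states), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Write a trajectory to TSV (time column + one column per taxon)
#' @param traj A `glv_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_tsv()]
#' @param path Input file path.
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  states <- as.matrix(df[, -1, drop = FALSE])
  structure(list(times = df$time, states = states,
                 taxa = colnames(states)),
            class = "glv_trajectory")
}
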