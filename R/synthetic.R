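# Synthetic bacterial-growth data: Euler-Maruyama integration of the
# stochastic generalized-logistic (Richards) equation
#   dN = r N [1 - (N/K)^nu] dt + sigma N dW
# subsampled to a measurement grid, with additive Gaussian measurement noise.
# This is the generator behind the package's worked example and most tests.

# Vectorized over replicates: one Euler-Maruyama path per column-free vector
# entry.  Negative excursions are clipped to a small positive floor (counted).
em_growth_paths <- function(n_rep, r, n0, K, nu, sigma, t_max, em_dt,
                            floor = 1e-12) {
  n_steps <- round(t_max / em_dt)
  N <- rep(n0, n_rep)
  sq_dt <- sqrt(em_dt)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n_rep)
  out[1L, ] <- N
  n_floored <- 0L
  for (s in seq_len(n_steps)) {
    drift <- r * N * (1 - (N / K)^nu)
    N <- N + drift * em_dt + sigma * N * sq_dt * stats::rnorm(n_rep)
    low <- N < floor
    if (any(low)) {
      n_floored <- n_floored + sum(low)
      N[low] <- floor
    }
    out[s + 1L, ] <- N
  }
  attr(out, "times") <- seq(0, by = em_dt, length.out = n_steps + 1L)
  attr(out, "n_floored") <- n_floored
  out
}

#' Simulate stochastic growth curves
#'
#' Generates one dataset per `(r, n0)` pair by Euler-Maruyama integration of
#' `dN = r N [1 - (N/K)^nu] dt + sigma N dW` from `N(0) = n0`, subsampled to
#' `n_points` equispaced measurement times on `[0, t_max]`, plus additive
#' Gaussian measurement noise.  The defaults are the worked example shipped
#' with the package: six curves (growth rate 0.2 for the first triplet, 0.1
#' for the second, initial values 0.01/0.02/0.1 within each triplet) around a
#' shared carrying capacity `K = 10` with growth curvature `nu = 0.5`,
#' multiplicative noise `sigma = 0.01`, and measurement noise SD 0.1.
#'
#' Each curve draws from its own random substream derived from `seed`, so
#' adding a curve never perturbs earlier curves.  If any path dips below a
#' small positive floor it is clipped there and the count is reported as a
#' message.
#'
#' @param r Growth rates, one per curve.
#' @param n0 Initial values, one per curve (recycled against `r`).
#' @param K Carrying capacity.
#' @param nu Growth curvature.
#' @param sigma Multiplicative (Langevin) noise amplitude.
#' @param measurement_sd Additive Gaussian measurement noise SD.
#' @param t_max Time horizon.
#' @param n_points Number of equispaced measurement times (including 0).
#' @param em_dt Euler-Maruyama step; must not exceed a tenth of the
#'   measurement spacing.
#' @param seed Integer seed (required for reproducibility).
#' @param names Optional dataset names; default `curve_1`, `curve_2`, ...
#' @return A list of [xy_dataset()] objects, one per curve.
#' @examples
#' curves <- simulate_growth_curves(seed = 1)
#' length(curves) # 6
#' @export
simulate_growth_curves <- function(r = rep(c(0.2, 0.1), each = 3),
                                   n0 = rep(c(0.01, 0.02, 0.1), times = 2),
                                   K = 10, nu = 0.5, sigma = 0.01,
                                   measurement_sd = 0.1,
                                   t_max = 100, n_points = 101L,
                                   em_dt = 0.01, seed = NULL,
                                   names = NULL) {
  n_curves <- max(length(r), length(n0))
  r <- rep_len(r, n_curves)
  n0 <- rep_len(n0, n_curves)
  if (any(c(r, n0, K, nu) <= 0) || sigma < 0 || measurement_sd < 0 ||
    t_max <= 0 || n_points < 2L || em_dt <= 0) {
    stop("invalid generator configuration", call. = FALSE)
  }
  meas_dt <- t_max / (n_points - 1L)
  if (em_dt > meas_dt / 10) {
    stop(sprintf(
      "em_dt = %g too coarse: must be <= %g (a tenth of the measurement spacing)",
      em_dt, meas_dt / 10
    ), call. = FALSE)
  }
  if (is.null(seed)) {
    stop("'seed' is required for a reproducible simulation", call. = FALSE)
  }
  if (is.null(names)) names <- sprintf("curve_%d", seq_len(n_curves))
  set.seed(seed)
  curve_seeds <- sample.int(.Machine$integer.max, n_curves)

  t_meas <- seq(0, t_max, length.out = n_points)
  out <- vector("list", n_curves)
  total_floored <- 0L
  for (i in seq_len(n_curves)) {
    set.seed(curve_seeds[i])
    path <- em_growth_paths(
      1L, r[i], n0[i], K, nu, sigma, t_max, em_dt
    )
    total_floored <- total_floored + attr(path, "n_floored")
    idx <- round(t_meas / em_dt) + 1L
    y <- path[idx, 1L] + stats::rnorm(n_points, 0, measurement_sd)
    out[[i]] <- xy_dataset(t_meas, y, name = names[i])
  }
  if (total_floored > 0L) {
    message(sprintf(
      "simulate_growth_curves: clipped %d negative excursion(s) to the floor",
      total_floored
    ))
  }
  out
}

#' Noiseless fixture dataset from a model
#'
#' Evaluates a model exactly at the given abscissae and packages the outputs
#' as observations, for exact-recovery tests and cross-model checks.
#'
#' @param model An `sf_model`.
#' @param parameters Named natural-scale parameter values.
#' @param times Abscissae.
#' @param name Dataset name.
#' @return An [xy_dataset()].
#' @export
noiseless_dataset <- function(model, parameters, times, name = "noiseless") {
  pred <- model_predict(model, unlist(as.list(parameters)), times,
    gradient = FALSE
  )$pred
  xy_dataset(times, pred, name = name)
}
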