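# The global objective is the unweighted sum of squared residuals pooled over
# every dataset in the topology.  The optimizer works on the hidden
# (unconstrained) vector; gradients reach it analytically via the chain
#   d SSE / d hidden = (d SSE / d prediction) (d prediction / d natural)
#                      (d natural / d hidden)
# where d prediction / d natural is symbolic for expression models and comes
# from forward sensitivities for ODE models.

model_predict <- function(model, args, x, gradient = FALSE,
                          rtol = 1e-6, atol = 1e-9) {
  args <- unlist(as.list(args))
  for (p in names(model$parameters)) {
    # constants declared on the model need not be supplied by the caller
    if (!p %in% names(args) &&
      model$parameters[[p]]$bound$kind == "constant") {
      args[p] <- model$parameters[[p]]$bound$value
    }
  }
  if (model$kind == "expression") {
    values <- c(stats::setNames(list(x), model$independent), as.list(args))
    pred <- eval_expr(model$body, values)
    if (length(pred) == 1L) pred <- rep(pred, length(x))
    if (!gradient) {
      return(list(pred = pred))
    }
    g <- grad_expr(model$body, values, wrt = names(model$parameters))
    if (nrow(g) == 1L && length(x) > 1L) {
      g <- matrix(g,
        nrow = length(x), ncol = ncol(g), byrow = TRUE,
        dimnames = list(NULL, colnames(g))
      )
    }
    list(pred = pred, grad = g)
  } else {
    sol <- solve_ode_sensitivities(model, args, x, rtol = rtol, atol = atol)
    list(pred = sol$outputs, grad = sol$output_gradients)
  }
}

#' Global objective and analytic gradient
#'
#' Evaluates the pooled sum of squared residuals over every dataset of the
#' topology at a hidden-scale parameter vector, together with its exact
#' gradient.  Evaluation failures (ODE integration breakdown, expression
#' domain errors) do not propagate: the objective returns a large finite
#' penalty `1e12 + ||hidden - reference||^2` (gradient of the distance term
#' only) so the optimizer's line search is steered back, and a warning is
#' logged.
#'
#' @param topology An `sf_topology`.
#' @param hidden Numeric hidden-scale vector in packing order.
#' @param gradient If `FALSE`, skip gradient computation.
#' @param reference Hidden vector used by the failure penalty (defaults to
#'   zero).
#' @param rtol,atol ODE integrator tolerances.
#' @return List with `value` (scalar SSE) and `gradient` (vector, or `NULL`).
#' @export
objective_and_gradient <- function(topology, hidden, gradient = TRUE,
                                   reference = NULL,
                                   rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(topology, "sf_topology"))
  if (is.null(reference)) reference <- numeric(length(hidden))
  args_by_ds <- tryCatch(
    unpack_parameters(topology, hidden),
    error = function(e) NULL
  )
  penalty <- function(msg) {
    warning(sprintf("objective evaluation penalized: %s", msg),
      call. = FALSE
    )
    d <- hidden - reference
    list(
      value = 1e12 + sum(d^2),
      gradient = if (gradient) 2 * d else NULL
    )
  }
  if (is.null(args_by_ds)) {
    return(penalty("parameter unpacking failed"))
  }
  sse <- 0
  grads <- list()
  for (ds in names(topology$datasets)) {
    dat <- topology$datasets[[ds]]
    mod <- topology$models[[topology$bindings[[ds]]]]
    res <- tryCatch(
      model_predict(mod, args_by_ds[[ds]], dat$x,
        gradient = gradient,
        rtol = rtol, atol = atol
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(penalty(conditionMessage(res)))
    }
    r <- res$pred - dat$y
    sse <- sse + sum(r^2)
    if (gradient) {
      grads[[ds]] <- stats::setNames(
        as.numeric(2 * crossprod(res$grad, r)), colnames(res$grad)
      )
    }
  }
  list(
    value = sse,
    gradient = if (gradient) {
      accumulate_gradient(topology, grads, hidden)
    } else {
      NULL
    }
  )
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of
#' `observed`.  For the pooled (global) value of a simultaneous fit, pass the
#' concatenated observations and predictions of all datasets: the pooled mean
#' is then used.  Returns `NA` when the observations are constant
#' (`SS_tot = 0`).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Scalar `R^2` (at most 1; equal to 1 only for a perfect fit).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

default_control <- function(control) {
  utils::modifyList(
    list(
      maxit = 1000L, # L-BFGS iteration cap
      pgtol = 1e-8, # L-BFGS projected-gradient tolerance
      lmm = 10L, # L-BFGS memory
      factr = 10, # L-BFGS relative f tolerance factor
      nm_maxit = 10000L, # Nelder-Mead iterations per restart
      nm_reltol = 1e-12,
      nm_restarts = 100L, # restart NM from its incumbent until stable
      rtol = 1e-6, # ODE tolerances during fitting
      atol = 1e-9
    ),
    control
  )
}

#' Simultaneous (global) curve fit
#'
#' Minimizes the pooled sum of squared residuals of a [fit_topology()] over
#' its packed free-parameter vector.  Bounds are enforced by the smooth
#' transforms attached to each free parameter, so the optimizer runs
#' unconstrained; with `method = "lbfgs"` (the default) it uses analytic
#' gradients (symbolic for expression models, forward ODE sensitivities for
#' ODE models).  `method = "neldermead"` is a gradient-free fallback for
#' models whose derivatives are uninformative (restarted from its own
#' incumbent until the objective stabilizes); it typically needs far more
#' function evaluations.
#'
#' @param topology An `sf_topology`.
#' @param guesses Named natural-scale initial guesses (by identity id or bare
#'   parameter name); see [initial_hidden()].  Guesses must lie strictly
#'   inside their bounds.
#' @param method `"lbfgs"` or `"neldermead"`.
#' @param control List of optimizer settings overriding the defaults:
#'   `maxit`, `pgtol`, `lmm`, `factr` (L-BFGS); `nm_maxit`, `nm_reltol`,
#'   `nm_restarts` (Nelder-Mead); `rtol`, `atol` (ODE tolerances).
#' @return An object of class `simulfit`: estimates on the natural scale,
#'   per-dataset predictions and residuals, the objective (total SSE), global
#'   and per-dataset R-squared, and an optimizer report.  Supported methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`, `deviance`.
#' @examples
#' m <- expression_model("line", "a*x + b", c("a", "b"))
#' d <- xy_dataset(0:5, 2 * (0:5) + 1, "d")
#' fit <- simulfit(fit_topology(d, m))
#' coef(fit)
#' @export
simulfit <- function(topology, guesses = list(),
                     method = c("lbfgs", "neldermead"),
                     control = list()) {
  stopifnot(inherits(topology, "sf_topology"))
  method <- match.arg(method)
  ctl <- default_control(control)
  hidden0 <- initial_hidden(topology, guesses) # errors name the parameter
  nfree <- length(hidden0)

  n_fev <- 0L
  n_gev <- 0L
  last <- new.env(parent = emptyenv())
  evaluate <- function(h, gradient) {
    if (!is.null(last$h) && identical(h, last$h) &&
      (!gradient || !is.null(last$res$gradient))) {
      return(last$res)
    }
    res <- objective_and_gradient(topology, h,
      gradient = gradient,
      reference = unname(hidden0), rtol = ctl$rtol, atol = ctl$atol
    )
    last$h <- h
    last$res <- res
    res
  }
  fn <- function(h) {
    n_fev <<- n_fev + 1L
    evaluate(h, gradient = (method == "lbfgs"))$value
  }
  gr <- function(h) {
    n_gev <<- n_gev + 1L
    evaluate(h, gradient = TRUE)$gradient
  }

  if (nfree == 0L) {
    # all parameters constant: fitting is a no-op evaluation
    opt <- list(
      par = unname(hidden0), value = fn(unname(hidden0)),
      counts = c(`function` = 1L, gradient = 0L),
      convergence = 0L, message = "no free parameters"
    )
    iterations <- 0L
  } else if (method == "lbfgs") {
    opt <- stats::optim(unname(hidden0), fn, gr,
      method = "L-BFGS-B",
      control = list(
        maxit = ctl$maxit, pgtol = ctl$pgtol,
        lmm = ctl$lmm, factr = ctl$factr
      )
    )
    iterations <- unname(opt$counts["function"])
  } else {
    par <- unname(hidden0)
    best <- fn(par)
    total_counts <- c(`function` = 1L, gradient = 0L)
    opt <- NULL
    for (i in seq_len(max(1L, ctl$nm_restarts))) {
      o <- stats::optim(par, fn,
        method = "Nelder-Mead",
        control = list(maxit = ctl$nm_maxit, reltol = ctl$nm_reltol)
      )
      total_counts <- total_counts + o$counts[c("function", "gradient")]
      improved <- best - o$value
      par <- o$par
      best <- o$value
      opt <- o
      if (is.finite(improved) && improved <= abs(best) * 1e-10) break
    }
    total_counts["gradient"] <- 0L
    opt$counts <- total_counts
    opt$par <- par
    opt$value <- best
    iterations <- unname(total_counts["function"])
  }

  hidden <- stats::setNames(opt$par, names(hidden0))
  final <- objective_and_gradient(topology, unname(hidden),
    gradient = TRUE,
    reference = unname(hidden0), rtol = ctl$rtol, atol = ctl$atol
  )
  grad_norm <- if (nfree > 0L) max(abs(final$gradient)) else 0

  args_by_ds <- unpack_parameters(topology, unname(hidden))
  predictions <- list()
  residuals <- list()
  r2_per <- numeric(0)
  all_y <- numeric(0)
  all_p <- numeric(0)
  for (ds in names(topology$datasets)) {
    dat <- topology$datasets[[ds]]
    mod <- topology$models[[topology$bindings[[ds]]]]
    pred <- model_predict(mod, args_by_ds[[ds]], dat$x,
      gradient = FALSE,
      rtol = ctl$rtol, atol = ctl$atol
    )$pred
    predictions[[ds]] <- pred
    residuals[[ds]] <- dat$y - pred
    r2_per[ds] <- r_squared(dat$y, pred)
    all_y <- c(all_y, dat$y)
    all_p <- c(all_p, pred)
  }

  structure(
    list(
      estimates = natural_estimates(topology, unname(hidden)),
      hidden = hidden,
      objective = final$value,
      predictions = predictions,
      residuals = residuals,
      r_squared_global = r_squared(all_y, all_p),
      r_squared_per_dataset = r2_per,
      optimizer = list(
        method = method,
        iterations = iterations,
        n_function_evaluations = n_fev,
        n_gradient_evaluations = n_gev,
        convergence = opt$convergence,
        converged = opt$convergence == 0L,
        gradient_norm = grad_norm,
        message = if (is.null(opt$message)) "" else opt$message
      ),
      config_echo = list(
        guesses = guesses, method = method, control = ctl,
        initial_hidden = hidden0
      ),
      topology = topology,
      call = match.call()
    ),
    class = "simulfit"
  )
}
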