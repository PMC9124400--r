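# ODE models are solved together with their forward sensitivity equations
#   dy/dt = f(y, theta, t)
#   dS/dt = (df/dy) S + df/dtheta,   S(t0) = d y0 / d theta
# so that output gradients are analytic at solver accuracy.  The Jacobians
# df/dy and df/dtheta are symbolic derivatives of the right-hand-side trees.
# Events are located by bisection on a cubic-Hermite dense representation of
# the trajectory.

ode_workspace <- function(model) {
  ws <- model$cache$ws
  if (!is.null(ws)) {
    return(ws)
  }
  states <- model$states
  params <- names(model$parameters)
  n <- length(states)
  p <- length(params)
  f_exprs <- lapply(model$body, `[[`, "expr")
  J_exprs <- vector("list", n * n) # column-major [i + (j-1)*n]
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      J_exprs[[i + (j - 1L) * n]] <- deriv_tree(model$body[[i]], states[j])
    }
  }
  B_exprs <- vector("list", n * p)
  for (k in seq_len(p)) {
    for (i in seq_len(n)) {
      B_exprs[[i + (k - 1L) * n]] <- deriv_tree(model$body[[i]], params[k])
    }
  }
  ws <- list(
    n = n, p = p, states = states, params = params,
    f = f_exprs, J = J_exprs, B = B_exprs
  )
  model$cache$ws <- ws
  ws
}

eval_all <- function(exprs, env) {
  vapply(exprs, function(e) {
    if (is.numeric(e)) as.numeric(e) else eval(e, env)
  }, numeric(1))
}

make_rhs_env <- function(model, parameters) {
  env <- new.env(parent = sf_math_env())
  for (k in names(parameters)) assign(k, parameters[[k]], envir = env)
  env
}

initial_state <- function(model, parameters) {
  vapply(model$states, function(s) {
    v <- model$init[[s]]
    if (is.character(v)) parameters[[v]] else as.numeric(v)
  }, numeric(1))
}

initial_sensitivity <- function(model) {
  # indicator where the initial state IS the parameter, zero elsewhere
  params <- names(model$parameters)
  S0 <- matrix(0, length(model$states), length(params),
    dimnames = list(model$states, params)
  )
  for (i in seq_along(model$states)) {
    v <- model$init[[model$states[i]]]
    if (is.character(v)) S0[i, v] <- 1
  }
  S0
}

# cubic Hermite interpolation of the state between two solver output rows
hermite_state <- function(t, t0, t1, y0, y1, f0, f1) {
  h <- t1 - t0
  s <- (t - t0) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y0 + h10 * h * f0 + h01 * y1 + h11 * h * f1
}

#' Solve an ODE model with forward sensitivities
#'
#' Integrates the model together with the sensitivity system
#' `dS/dt = (df/dy) S + df/dtheta` (Jacobians taken symbolically from the
#' right-hand-side trees) and reports states, sensitivities, model outputs,
#' and analytic output gradients exactly at the requested times.  The first
#' requested time is taken as the initial time.  Event conditions are scanned
#' on a refined grid and located by bisection on a cubic-Hermite dense
#' representation to a time tolerance of `1e-9 * (range of times)`; terminal
#' events stop the trajectory, later times reporting the event-time value.
#'
#' @param model An [ode_model()].
#' @param parameters Named natural-scale values covering the model's
#'   parameter list.
#' @param times Numeric vector of requested times, sorted ascending.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `sf_sens`: list with `times`, `states`
#'   (time x state), `sensitivities` (time x state x parameter), `outputs`,
#'   `output_gradients` (time x parameter), and `events` (per event: `time`,
#'   `state`, `sens`).
#' @examples
#' m <- ode_model("decay",
#'   states = "y", rhs = "-k*y", init = list(y = 1),
#'   parameters = "k"
#' )
#' s <- solve_ode_sensitivities(m, c(k = 0.5), times = c(0, 1, 2))
#' s$outputs # exp(-0.5 * t)
#' @export
solve_ode_sensitivities <- function(model, parameters, times,
                                    rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "sf_model"), model$kind == "ode")
  parameters <- unlist(as.list(parameters))
  missing <- setdiff(names(model$parameters), names(parameters))
  if (length(missing) > 0L) {
    stop(sprintf(
      "missing parameter value(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("'times' must be sorted ascending", call. = FALSE)
  }
  ws <- ode_workspace(model)
  n <- ws$n
  p <- ws$p
  env <- make_rhs_env(model, parameters)
  indep <- model$independent

  eval_field <- function(t, y) {
    assign(indep, t, envir = env)
    for (i in seq_len(n)) assign(ws$states[i], y[i], envir = env)
    eval_all(ws$f, env)
  }
  integration_error <- function(msg) {
    stop(structure(
      class = c("sf_integration_error", "error", "condition"),
      list(
        message = sprintf(
          "%s (model '%s', parameters: %s)", msg, model$name,
          paste(sprintf("%s=%g", names(parameters), parameters),
            collapse = ", "
          )
        ),
        call = NULL, parameters = parameters
      )
    ))
  }
  rhs <- function(t, Y, parms) {
    assign(indep, t, envir = env)
    for (i in seq_len(n)) assign(ws$states[i], Y[i], envir = env)
    f <- eval_all(ws$f, env)
    if (!all(is.finite(f))) {
      integration_error(sprintf(
        "non-finite right-hand side at %s = %g", indep, t
      ))
    }
    J <- matrix(eval_all(ws$J, env), n, n)
    B <- matrix(eval_all(ws$B, env), n, p)
    S <- matrix(Y[-seq_len(n)], n, p)
    list(c(f, J %*% S + B))
  }

  y0 <- initial_state(model, parameters)
  S0 <- initial_sensitivity(model)
  t0 <- times[1L]
  t_end <- times[length(times)]

  # solver grid: requested times refined for event scanning / interpolation
  utimes <- sort(unique(times))
  grid <- utimes
  if (length(model$events) > 0L && t_end > t0) {
    grid <- sort(unique(c(grid, seq(t0, t_end, length.out = 257L))))
  }

  if (t_end > t0) {
    sol <- suppressWarnings(deSolve::lsoda(
      y = c(y0, as.vector(S0)), times = grid, func = rhs,
      parms = NULL, rtol = rtol, atol = atol
    ))
    if (attr(sol, "istate")[1L] < 0L || nrow(sol) < length(grid) ||
      anyNA(sol)) {
      integration_error("ODE integration failed")
    }
    Ymat <- unname(sol[, -1L, drop = FALSE])
  } else {
    Ymat <- matrix(rep(c(y0, as.vector(S0)), length(grid)),
      nrow = length(grid), byrow = TRUE
    )
  }
  states_g <- Ymat[, seq_len(n), drop = FALSE]
  sens_g <- Ymat[, -seq_len(n), drop = FALSE]

  events <- detect_events(
    model, parameters, grid, states_g, sens_g, eval_field, env
  )

  # truncate at the earliest terminal event
  term <- Filter(function(e) e$terminal, events)
  t_cut <- if (length(term) > 0L) {
    min(vapply(term, `[[`, numeric(1), "time"))
  } else {
    Inf
  }

  # rows at the originally requested times
  row_of <- match(pmin(times, t_cut), grid)
  frozen <- times > t_cut
  if (any(frozen)) {
    ev_t <- t_cut
    ev <- term[[which.min(vapply(term, `[[`, numeric(1), "time"))]]
    states_out <- states_g[row_of, , drop = FALSE]
    sens_out <- sens_g[row_of, , drop = FALSE]
    states_out[frozen, ] <- rep(ev$state, each = sum(frozen))
    sens_out[frozen, ] <- rep(as.vector(ev$sens), each = sum(frozen))
    t_eval <- ifelse(frozen, ev_t, times)
  } else {
    # requested times are all on the solver grid by construction
    states_out <- states_g[row_of, , drop = FALSE]
    sens_out <- sens_g[row_of, , drop = FALSE]
    t_eval <- times
  }
  dimnames(states_out) <- list(NULL, ws$states)
  sens_arr <- array(sens_out,
    dim = c(length(times), n, p),
    dimnames = list(NULL, ws$states, ws$params)
  )

  out <- apply_output_transform(
    model, parameters, t_eval, states_out, sens_arr, events
  )

  structure(
    list(
      times = times, states = states_out, sensitivities = sens_arr,
      outputs = out$outputs, output_gradients = out$output_gradients,
      events = events
    ),
    class = "sf_sens"
  )
}

# Scan event conditions over the solver grid and bisect each first crossing
# in its stated direction.  The sensitivity snapshot is S interpolated at the
# located time (the implicit dependence of the event time itself on the
# parameters is not included; see the package vignette).
detect_events <- function(model, parameters, grid, states_g, sens_g,
                          eval_field, env) {
  if (length(model$events) == 0L) {
    return(list())
  }
  n <- length(model$states)
  p <- length(parameters)
  indep <- model$independent
  t0 <- grid[1L]
  t_end <- grid[length(grid)]
  tol <- 1e-9 * max(t_end - t0, .Machine$double.eps)

  cond_at <- function(tree, t, y) {
    assign(indep, t, envir = env)
    for (i in seq_len(n)) assign(model$states[i], y[i], envir = env)
    eval(tree$expr, env)
  }
  state_at_row <- function(r) states_g[r, ]
  found <- list()
  for (e_i in seq_along(model$events)) {
    ev <- model$events[[e_i]]
    tree <- model$event_trees[[e_i]]
    g <- vapply(seq_along(grid), function(r) {
      cond_at(tree, grid[r], state_at_row(r))
    }, numeric(1))
    dir_ok <- function(lo, hi) {
      switch(ev$direction,
        rising = lo < 0 && hi > 0,
        falling = lo > 0 && hi < 0,
        any = sign(lo) != sign(hi) && lo != 0
      )
    }
    rec <- NULL
    if (g[1L] == 0) {
      # condition zero at the start, moving in the stated direction
      gdot <- if (length(grid) > 1L) {
        (g[2L] - g[1L]) / (grid[2L] - grid[1L])
      } else {
        0
      }
      moving <- switch(ev$direction,
        rising = gdot > 0, falling = gdot < 0, any = gdot != 0
      )
      if (moving) {
        rec <- list(
          time = t0,
          state = stats::setNames(state_at_row(1L), model$states),
          sens = matrix(sens_g[1L, ], n, p,
            dimnames = list(model$states, names(parameters))
          )
        )
      }
    }
    if (is.null(rec)) {
      for (r in seq_len(length(grid) - 1L)) {
        if (!dir_ok(g[r], g[r + 1L]) && g[r + 1L] != 0) next
        if (g[r + 1L] == 0 &&
          !(r + 1L < length(grid) && dir_ok(g[r], g[r + 2L]))) {
          next
        }
        # bisect on the Hermite dense output
        ta <- grid[r]
        tb <- grid[r + 1L]
        ya <- state_at_row(r)
        yb <- state_at_row(r + 1L)
        fa <- eval_field(ta, ya)
        fb <- eval_field(tb, yb)
        glo <- g[r]
        while (tb - ta > tol) {
          tm <- (ta + tb) / 2
          ym <- hermite_state(
            tm, grid[r], grid[r + 1L],
            state_at_row(r), state_at_row(r + 1L), fa, fb
          )
          gm <- cond_at(tree, tm, ym)
          if (sign(gm) == sign(glo) && gm != 0) {
            ta <- tm
            glo <- gm
          } else {
            tb <- tm
          }
        }
        tstar <- (ta + tb) / 2
        ystar <- hermite_state(
          tstar, grid[r], grid[r + 1L],
          state_at_row(r), state_at_row(r + 1L), fa, fb
        )
        w <- (tstar - grid[r]) / (grid[r + 1L] - grid[r])
        sstar <- (1 - w) * sens_g[r, ] + w * sens_g[r + 1L, ]
        rec <- list(
          time = tstar,
          state = stats::setNames(ystar, model$states),
          sens = matrix(sstar, n, p,
            dimnames = list(model$states, names(parameters))
          )
        )
        break
      }
    }
    if (!is.null(rec)) {
      rec$terminal <- ev$terminal
      found[[ev$name]] <- rec
    }
  }
  found
}

# Compose the output transform (default: the selected state) with the chain
# rule over state sensitivities, explicit parameter dependence, and event
# snapshots.
apply_output_transform <- function(model, parameters, t_eval, states_out,
                                   sens_arr, events) {
  nT <- nrow(states_out)
  n <- length(model$states)
  p <- length(parameters)
  pnames <- names(parameters)
  if (is.null(model$output_tree)) {
    idx <- model$output_state
    return(list(
      outputs = states_out[, idx],
      output_gradients = matrix(sens_arr[, idx, ],
        nrow = nT, ncol = p,
        dimnames = list(NULL, pnames)
      )
    ))
  }
  tree <- model$output_tree
  ev_syms <- intersect(tree$used, event_symbols(
    names(model$events), model$states
  ))
  ev_vals <- list()
  ev_sens <- list()
  for (sym in ev_syms) {
    body <- sub("^ev\\.", "", sym)
    hit <- NULL
    for (en in names(model$events)) {
      if (body == en && n == 1L) {
        hit <- list(event = en, state = model$states[1L])
      } else if (startsWith(body, paste0(en, "."))) {
        st <- sub(paste0("^", en, "\\."), "", body)
        if (st %in% model$states) hit <- list(event = en, state = st)
      }
      if (!is.null(hit)) break
    }
    if (is.null(events[[hit$event]])) {
      stop(sprintf(
        "output transform of '%s' references event '%s', which did not occur",
        model$name, hit$event
      ), call. = FALSE)
    }
    rec <- events[[hit$event]]
    ev_vals[[sym]] <- unname(rec$state[hit$state])
    ev_sens[[sym]] <- rec$sens[hit$state, ]
  }
  values <- c(
    stats::setNames(list(t_eval), model$independent),
    lapply(stats::setNames(seq_len(n), model$states), function(i) {
      states_out[, i]
    }),
    as.list(parameters),
    ev_vals
  )
  outputs <- eval_expr(tree, values)
  if (length(outputs) == 1L) outputs <- rep(outputs, nT)
  partials <- grad_expr(tree, values,
    wrt = intersect(tree$used, c(model$states, pnames, ev_syms))
  )
  grads <- matrix(0, nT, p, dimnames = list(NULL, pnames))
  for (k in seq_len(p)) {
    acc <- numeric(nT)
    for (i in seq_len(n)) {
      s <- model$states[i]
      if (s %in% colnames(partials)) {
        acc <- acc + partials[, s] * sens_arr[, i, k]
      }
    }
    if (pnames[k] %in% colnames(partials)) {
      acc <- acc + partials[, pnames[k]]
    }
    for (sym in ev_syms) {
      if (sym %in% colnames(partials)) {
        acc <- acc + partials[, sym] * ev_sens[[sym]][k]
      }
    }
    grads[, k] <- acc
  }
  list(outputs = outputs, output_gradients = grads)
}

#' @export
print.sf_sens <- function(x, ...) {
  cat(sprintf(
    "<sf_sens> %d time(s), %d state(s), %d parameter(s)",
    length(x$times), ncol(x$states), dim(x$sensitivities)[3L]
  ))
  if (length(x$events) > 0L) {
    cat(sprintf(
      "; events: %s",
      paste(sprintf(
        "%s@%g", names(x$events),
        vapply(x$events, `[[`, numeric(1), "time")
      ), collapse = ", ")
    ))
  }
  cat("\n")
  invisible(x)
}
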