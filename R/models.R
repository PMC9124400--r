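# Fit-model definitions: closed-form expression models and ODE-defined
# models, with annotated parameter lists.  Bound annotations follow the
# R(lo, hi) / C(value) convention: R(0, inf) is the positive-only default,
# R(-inf, inf) is unbounded, R(0, 1) an interval, C(10) a fixed constant.

#' Parameter bound annotation
#'
#' Parses a bound annotation string.  Accepted forms: `"R(lo, hi)"` with
#' `inf`/`-inf` for open ends (`R(0, inf)` means positive, `R(-inf, inf)`
#' unbounded), `"C(value)"` for a constant excluded from fitting, and the
#' keywords `"positive"` / `"unbounded"`.
#'
#' @param s A single annotation string.
#' @return A bound object: list with `kind` (one of `"unbounded"`,
#'   `"positive"`, `"lower"`, `"upper"`, `"interval"`, `"constant"`) and,
#'   as applicable, `lo`, `hi`, `value`.
#' @export
parse_bound <- function(s) {
  if (is.numeric(s)) {
    return(list(kind = "constant", value = as.numeric(s)))
  }
  stopifnot(is.character(s), length(s) == 1L)
  s0 <- gsub("[[:space:]]", "", s)
  if (tolower(s0) == "positive") {
    return(list(kind = "positive", lo = 0, hi = Inf))
  }
  if (tolower(s0) == "unbounded") {
    return(list(kind = "unbounded", lo = -Inf, hi = Inf))
  }
  m <- regmatches(s0, regexec("^C\\((-?[0-9.eE+-]+)\\)$", s0))[[1L]]
  if (length(m) == 2L) {
    v <- suppressWarnings(as.numeric(m[2L]))
    if (is.na(v)) stop(sprintf("bad constant annotation '%s'", s),
      call. = FALSE)
    return(list(kind = "constant", value = v))
  }
  m <- regmatches(s0, regexec("^R\\(([^,]+),([^,]+)\\)$", s0))[[1L]]
  if (length(m) == 3L) {
    ends <- vapply(m[2:3], function(tok) {
      tok <- tolower(tok)
      if (tok == "inf") return(Inf)
      if (tok == "-inf") return(-Inf)
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v)) stop(sprintf("bad range annotation '%s'", s),
        call. = FALSE)
      v
    }, numeric(1), USE.NAMES = FALSE)
    lo <- ends[1L]
    hi <- ends[2L]
    if (lo >= hi) stop(sprintf("range annotation '%s' needs lo < hi", s),
      call. = FALSE)
    kind <- if (is.infinite(lo) && is.infinite(hi)) {
      "unbounded"
    } else if (lo == 0 && is.infinite(hi)) {
      "positive"
    } else if (is.infinite(hi)) {
      "lower"
    } else if (is.infinite(lo)) {
      "upper"
    } else {
      "interval"
    }
    return(list(kind = kind, lo = lo, hi = hi))
  }
  stop(sprintf("cannot parse bound annotation '%s'", s), call. = FALSE)
}

format_bound <- function(bound) {
  switch(bound$kind,
    unbounded = "R(-inf, inf)",
    positive = "R(0, inf)",
    lower = sprintf("R(%g, inf)", bound$lo),
    upper = sprintf("R(-inf, %g)", bound$hi),
    interval = sprintf("R(%g, %g)", bound$lo, bound$hi),
    constant = sprintf("C(%g)", bound$value)
  )
}

#' Parameter specification
#'
#' @param name Parameter name (a valid symbol).
#' @param bound A bound object from [parse_bound()], an annotation string, or
#'   a number (shorthand for a constant).  Default is positive-only, the
#'   package-wide default for unannotated parameters.
#' @param guess Default initial guess on the natural scale (ignored for
#'   constants).  When omitted it is placed at a sensible interior point of
#'   the bound: 1 for unbounded/positive, the midpoint for an interval,
#'   one unit inside a half-open range.
#' @return An object of class `sf_param`.
#' @export
param_spec <- function(name, bound = "R(0, inf)", guess = NULL) {
  if (!is.list(bound)) bound <- parse_bound(bound)
  if (is.null(guess)) {
    guess <- switch(bound$kind,
      unbounded = 1,
      positive = 1,
      lower = bound$lo + 1,
      upper = bound$hi - 1,
      interval = (bound$lo + bound$hi) / 2,
      constant = NA_real_
    )
  }
  if (bound$kind != "constant") {
    ok <- switch(bound$kind,
      unbounded = TRUE,
      positive = guess > 0,
      lower = guess > bound$lo,
      upper = guess < bound$hi,
      interval = guess > bound$lo && guess < bound$hi
    )
    if (!ok) {
      stop(sprintf(
        "default guess %g for '%s' is not inside its bound %s",
        guess, name, format_bound(bound)
      ), call. = FALSE)
    }
  }
  structure(list(name = name, bound = bound, guess = guess),
    class = "sf_param"
  )
}

# Normalise the many accepted declaration shapes into a named list of
# sf_param:  c("K", "r");  list(K = 5, r = "R(0, 1)");
# list(K = list(bound = "C(10)"), r = param_spec("r")).
as_param_list <- function(parameters) {
  if (is.null(parameters) || length(parameters) == 0L) {
    return(list())
  }
  if (is.character(parameters)) {
    parameters <- stats::setNames(
      rep(list(NULL), length(parameters)),
      parameters
    )
  }
  nms <- names(parameters)
  if (is.null(nms) || any(nms == "")) {
    stop("parameter declarations must be named (or a character vector)",
      call. = FALSE
    )
  }
  if (anyDuplicated(nms)) {
    stop(sprintf(
      "duplicate parameter name(s): %s",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ), call. = FALSE)
  }
  out <- vector("list", length(nms))
  names(out) <- nms
  for (nm in nms) {
    d <- parameters[[nm]]
    out[[nm]] <- if (is.null(d)) {
      param_spec(nm)
    } else if (inherits(d, "sf_param")) {
      d$name <- nm
      d
    } else if (is.numeric(d)) {
      # bare number = default guess (positive bound), matching the
      # "defaults as default arguments" convention
      param_spec(nm, guess = as.numeric(d))
    } else if (is.character(d)) {
      param_spec(nm, bound = d)
    } else if (is.list(d)) {
      b <- if (!is.null(d$bound)) d$bound else "R(0, inf)"
      g <- if (!is.null(d$guess)) as.numeric(d$guess) else NULL
      param_spec(nm, bound = if (is.list(b)) b else parse_bound(b),
        guess = g)
    } else {
      stop(sprintf("cannot interpret declaration of parameter '%s'", nm),
        call. = FALSE
      )
    }
  }
  out
}

free_param_names <- function(model) {
  keep <- vapply(model$parameters, function(p) p$bound$kind != "constant",
    logical(1)
  )
  names(model$parameters)[keep]
}

#' Number of free parameters of a model
#'
#' Declared parameters minus those annotated as constants.
#'
#' @param model An `sf_model`.
#' @return Integer count.
#' @rdname n_free_parameters
#' @export
n_free_parameters.sf_model <- function(model) {
  length(free_param_names(model))
}

#' Define a closed-form expression model
#'
#' The model body is a single expression in the independent variable and the
#' declared parameters.  Parameters without an annotation default to
#' positive-only with initial guess 1.
#'
#' @param name Model name.
#' @param body A string with the model expression (see [parse_model_expr()]
#'   for the accepted language).
#' @param parameters Parameter declarations: a character vector of names, or a
#'   named list whose elements are default guesses (numbers), bound annotation
#'   strings such as `"R(0, 1)"` or `"C(10)"`, `list(bound =, guess =)`
#'   pairs, or [param_spec()] objects.
#' @param independent Name of the independent variable (default `"x"`).
#' @return An object of class `sf_model` with `kind = "expression"`.
#' @examples
#' m <- expression_model(
#'   "growth",
#'   "K*(1 - (1 - (K/n0)**nu)*exp(-r*nu*x))**(-1/nu)",
#'   parameters = c("K", "n0", "nu", "r")
#' )
#' m
#' @export
expression_model <- function(name, body, parameters, independent = "x") {
  params <- as_param_list(parameters)
  if (independent %in% names(params)) {
    stop(sprintf(
      "independent variable '%s' also declared as a parameter", independent
    ), call. = FALSE)
  }
  tree <- parse_model_expr(body, c(independent, names(params)))
  structure(
    list(
      name = name, kind = "expression", independent = independent,
      parameters = params, body = tree
    ),
    class = "sf_model"
  )
}

#' Event specification for an ODE model
#'
#' An event fires at the first time its condition expression (over the
#' independent variable, states, and parameters) crosses zero in the stated
#' direction.  The state snapshot at the crossing is exposed to the model's
#' output transform under the symbols `ev.<name>` (single-state models) and
#' `ev.<name>.<state>`.
#'
#' @param name Event name.
#' @param condition Condition expression source (string).
#' @param direction `"rising"` (condition increasing through 0), `"falling"`,
#'   or `"any"`.
#' @param terminal If `TRUE`, integration stops at the event and later
#'   requested times report the event-time value (constant extrapolation).
#' @return An object of class `sf_event`.
#' @export
event_spec <- function(name, condition,
                       direction = c("rising", "falling", "any"),
                       terminal = FALSE) {
  structure(
    list(
      name = name, condition = condition,
      direction = match.arg(direction), terminal = isTRUE(terminal)
    ),
    class = "sf_event"
  )
}

event_symbols <- function(event_names, state_names) {
  if (length(event_names) == 0L) return(character(0))
  syms <- as.vector(outer(
    paste0("ev.", event_names), state_names,
    function(e, s) paste(e, s, sep = ".")
  ))
  if (length(state_names) == 1L) {
    syms <- c(paste0("ev.", event_names), syms)
  }
  syms
}

#' Define an ODE model
#'
#' The fit function is the solution of an initial value problem.  Each state
#' has one right-hand-side expression over the independent variable, the
#' states, and the parameters.  Initial conditions may be literals or
#' parameter names; a parameter used as an initial condition is fitted like
#' any other (so an initial population size is itself estimable).  Systems
#' with several states express higher-order ODEs in first-order form.
#'
#' @inheritParams expression_model
#' @param states Character vector of state names.
#' @param rhs Character vector of right-hand-side expressions, one per state.
#' @param init Named list/vector mapping every state to a literal number or to
#'   the name of a declared parameter.
#' @param output Which quantity the model predicts: `NULL` (single-state
#'   models: that state), a state name, or an expression string over the
#'   independent variable, states, parameters, and event values
#'   (`ev.<event>` symbols).
#' @param events List of [event_spec()] objects.
#' @param independent Name of the independent variable (default `"t"`).
#' @return An object of class `sf_model` with `kind = "ode"`.
#' @examples
#' m <- ode_model(
#'   "growth_ode",
#'   states = "N", rhs = "r*N*(1 - (N/K)**nu)",
#'   init = list(N = "n0"),
#'   parameters = c("r", "K", "nu", "n0")
#' )
#' @export
ode_model <- function(name, states, rhs, init, parameters,
                      output = NULL, events = list(), independent = "t") {
  params <- as_param_list(parameters)
  states <- as.character(states)
  if (length(rhs) != length(states)) {
    stop("need exactly one rhs expression per state", call. = FALSE)
  }
  if (any(states %in% names(params))) {
    stop("state names must not collide with parameter names", call. = FALSE)
  }
  syms <- c(independent, states, names(params))
  trees <- lapply(rhs, parse_model_expr, symbols = syms)
  init <- as.list(init)
  missing_init <- setdiff(states, names(init))
  if (length(missing_init) > 0L) {
    stop(sprintf(
      "missing initial condition for state(s): %s",
      paste(missing_init, collapse = ", ")
    ), call. = FALSE)
  }
  for (s in states) {
    v <- init[[s]]
    if (is.character(v)) {
      if (!v %in% names(params)) {
        stop(sprintf(
          "initial condition of '%s' references unknown parameter '%s'",
          s, v
        ), call. = FALSE)
      }
    } else if (!is.numeric(v)) {
      stop(sprintf("initial condition of '%s' must be a number or parameter name", s),
        call. = FALSE
      )
    }
  }
  if (!is.null(events) && length(events) > 0L) {
    stopifnot(all(vapply(events, inherits, logical(1), "sf_event")))
    ev_trees <- lapply(events, function(e) {
      parse_model_expr(e$condition, syms)
    })
    names(events) <- vapply(events, `[[`, character(1), "name")
  } else {
    events <- list()
    ev_trees <- list()
  }
  out_tree <- NULL
  out_state <- NULL
  if (is.null(output)) {
    if (length(states) != 1L) {
      stop("multi-state models need an explicit 'output'", call. = FALSE)
    }
    out_state <- 1L
  } else if (is.character(output) && length(output) == 1L &&
    output %in% states) {
    out_state <- match(output, states)
  } else if (is.character(output) && length(output) == 1L) {
    out_tree <- parse_model_expr(
      output,
      c(syms, event_symbols(names(events), states))
    )
  } else {
    stop("'output' must be NULL, a state name, or an expression string",
      call. = FALSE
    )
  }
  structure(
    list(
      name = name, kind = "ode", independent = independent,
      parameters = params, body = trees, states = states, init = init,
      output_state = out_state, output_tree = out_tree,
      events = events, event_trees = ev_trees,
      cache = new.env(parent = emptyenv())
    ),
    class = "sf_model"
  )
}

#' @export
print.sf_model <- function(x, ...) {
  cat(sprintf("<sf_model> %s (%s)\n", x$name, x$kind))
  if (x$kind == "expression") {
    cat("  ", x$independent, " -> ", x$body$source, "\n", sep = "")
  } else {
    for (i in seq_along(x$states)) {
      cat(sprintf(
        "  d%s/d%s = %s\n", x$states[i], x$independent,
        x$body[[i]]$source
      ))
    }
  }
  for (p in x$parameters) {
    cat(sprintf("  %-10s %s", p$name, format_bound(p$bound)))
    if (p$bound$kind != "constant") cat(sprintf("  guess = %g", p$guess))
    cat("\n")
  }
  invisible(x)
}
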