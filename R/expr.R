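# Expression trees for model bodies: a small arithmetic language parsed with
# R's own parser, then restricted to a whitelist of operators and functions.
# Gradients are exact, via symbolic differentiation over the whitelisted AST.

.SF_BINARY <- c("+", "-", "*", "/", "^")
.SF_UNARY <- c("-", "+")
.SF_FUNCS <- c("exp", "log", "sqrt", "sin", "cos", "tan", "abs")

sf_domain_error <- function(msg) {
  stop(structure(
    class = c("sf_domain_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluation environment with domain-checked math.  Non-positive log/sqrt and
# ill-defined powers are hard errors (fail fast), not silent NaNs; 0^0 = 1.
.sf_pow <- function(a, b) {
  zz <- a == 0 & b == 0
  if (any(a == 0 & b < 0)) {
    sf_domain_error("0 raised to a negative power")
  }
  if (any(a < 0 & b != round(b))) {
    sf_domain_error("negative base raised to a non-integer power")
  }
  out <- a^b
  if (any(zz)) out[zz] <- 1
  out
}

.sf_log <- function(x) {
  if (any(x <= 0)) sf_domain_error("log of a non-positive value")
  log(x)
}

.sf_sqrt <- function(x) {
  if (any(x < 0)) sf_domain_error("sqrt of a negative value")
  sqrt(x)
}

# sign with sign(0) = 0: the subgradient chosen for d|x|/dx at 0
.sf_sign <- function(x) sign(x)

.sf_math_env_cache <- new.env(parent = emptyenv())

sf_math_env <- function() {
  if (!is.null(.sf_math_env_cache$env)) {
    return(.sf_math_env_cache$env)
  }
  e <- new.env(parent = baseenv())
  e$`^` <- .sf_pow
  e$log <- .sf_log
  e$sqrt <- .sf_sqrt
  e$.sf_sign <- .sf_sign
  .sf_math_env_cache$env <- e
  e
}

walk_expr <- function(e, source) {
  # returns the set of symbols referenced; errors on anything outside the
  # whitelist
  if (is.numeric(e) || is.integer(e)) {
    return(character(0))
  }
  if (is.symbol(e)) {
    return(as.character(e))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    args <- as.list(e)[-1L]
    if (op == "(") {
      return(walk_expr(args[[1L]], source))
    }
    if (length(args) == 2L && op %in% .SF_BINARY) {
      return(union(
        walk_expr(args[[1L]], source),
        walk_expr(args[[2L]], source)
      ))
    }
    if (length(args) == 1L && op %in% .SF_UNARY) {
      return(walk_expr(args[[1L]], source))
    }
    if (length(args) == 1L && op %in% .SF_FUNCS) {
      return(walk_expr(args[[1L]], source))
    }
    if (op %in% .SF_FUNCS) {
      stop(sprintf(
        "function '%s' takes exactly one argument in '%s'",
        op, source
      ), call. = FALSE)
    }
    stop(sprintf(
      "unsupported operator or function '%s' in '%s' (allowed: %s)",
      op, source, paste(c(.SF_BINARY, .SF_FUNCS), collapse = " ")
    ), call. = FALSE)
  }
  stop(sprintf("unsupported construct in expression '%s'", source),
    call. = FALSE
  )
}

#' Parse a model expression
#'
#' Parses the body of a fit model written in a small arithmetic expression
#' language: the operators `+ - * / **` (or `^`), unary minus, and the
#' functions `exp`, `log`, `sqrt`, `sin`, `cos`, `tan`, `abs`.  Every
#' identifier must appear in `symbols`; anything else is rejected with a
#' message naming the offending identifier and its position in the source.
#'
#' @param source A single string containing one expression.
#' @param symbols Character vector of declared symbol names (by convention the
#'   independent variable first, then parameters, then any ODE state names).
#' @return An object of class `sf_expr`: the parsed tree, the declared
#'   `variables`, the subset actually `used`, and the original `source`.
#' @examples
#' tr <- parse_model_expr("K/(1 + exp(-r*x))", c("x", "K", "r"))
#' eval_expr(tr, list(x = 0, K = 10, r = 1))
#' @export
parse_model_expr <- function(source, symbols) {
  if (!is.character(source) || length(source) != 1L || is.na(source)) {
    stop("'source' must be a single string", call. = FALSE)
  }
  symbols <- as.character(symbols)
  exprs <- tryCatch(
    parse(text = source, keep.source = FALSE),
    error = function(e) {
      stop(sprintf(
        "syntax error in '%s': %s", source,
        conditionMessage(e)
      ), call. = FALSE)
    }
  )
  if (length(exprs) != 1L) {
    stop(sprintf("'%s' must contain exactly one expression", source),
      call. = FALSE
    )
  }
  e <- exprs[[1L]]
  used <- walk_expr(e, source)
  unknown <- setdiff(used, symbols)
  if (length(unknown) > 0L) {
    pos <- regexpr(unknown[1L], source, fixed = TRUE)
    stop(sprintf(
      "undeclared symbol '%s' at position %d in '%s' (declared: %s)",
      unknown[1L], as.integer(pos), source,
      paste(symbols, collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(
      expr = e,
      variables = symbols,
      used = symbols[symbols %in% used],
      source = source,
      cache = new.env(parent = emptyenv())
    ),
    class = "sf_expr"
  )
}

#' @export
print.sf_expr <- function(x, ...) {
  cat("<sf_expr> ", x$source, "\n", sep = "")
  cat("  variables: ", paste(x$variables, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a parsed expression
#'
#' Values may be scalars or equal-length vectors (evaluation is then
#' elementwise).  Domain violations (`log`/`sqrt` outside their domain,
#' `0^negative`, negative base to a fractional power) and non-finite results
#' raise errors rather than propagating `NaN`.
#'
#' @param tree An `sf_expr` from [parse_model_expr()].
#' @param values Named list or numeric vector covering every symbol the tree
#'   uses.
#' @return Numeric vector of evaluated values.
#' @export
eval_expr <- function(tree, values) {
  stopifnot(inherits(tree, "sf_expr"))
  values <- as.list(values)
  missing <- setdiff(tree$used, names(values))
  if (length(missing) > 0L) {
    stop(sprintf(
      "missing value(s) for symbol(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  env <- list2env(values, parent = sf_math_env())
  v <- eval(tree$expr, env)
  if (!all(is.finite(v))) {
    sf_domain_error(sprintf(
      "non-finite value when evaluating '%s'", tree$source
    ))
  }
  v
}

# ---- symbolic differentiation over the whitelisted AST -----------------------

is_num <- function(e) is.numeric(e) && length(e) == 1L
is_zero <- function(e) is_num(e) && e == 0
is_one <- function(e) is_num(e) && e == 1

mk_add <- function(a, b) {
  if (is_zero(a)) return(b)
  if (is_zero(b)) return(a)
  if (is_num(a) && is_num(b)) return(a + b)
  call("+", a, b)
}

mk_sub <- function(a, b) {
  if (is_zero(b)) return(a)
  if (is_num(a) && is_num(b)) return(a - b)
  if (is_zero(a)) return(mk_neg(b))
  call("-", a, b)
}

mk_neg <- function(a) {
  if (is_num(a)) return(-a)
  call("-", a)
}

mk_mul <- function(a, b) {
  if (is_zero(a) || is_zero(b)) return(0)
  if (is_one(a)) return(b)
  if (is_one(b)) return(a)
  if (is_num(a) && is_num(b)) return(a * b)
  call("*", a, b)
}

mk_div <- function(a, b) {
  if (is_zero(a)) return(0)
  if (is_one(b)) return(a)
  if (is_num(a) && is_num(b)) return(a / b)
  call("/", a, b)
}

mk_pow <- function(a, b) {
  if (is_one(b)) return(a)
  if (is_zero(b)) return(1)
  call("^", a, b)
}

sf_deriv <- function(e, var) {
  if (is.numeric(e)) {
    return(0)
  }
  if (is.symbol(e)) {
    return(if (as.character(e) == var) 1 else 0)
  }
  op <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  if (op == "(") {
    return(sf_deriv(args[[1L]], var))
  }
  if (length(args) == 1L && op %in% c("-", "+")) {
    d <- sf_deriv(args[[1L]], var)
    return(if (op == "-") mk_neg(d) else d)
  }
  u <- args[[1L]]
  du <- sf_deriv(u, var)
  switch(op,
    "+" = mk_add(du, sf_deriv(args[[2L]], var)),
    "-" = mk_sub(du, sf_deriv(args[[2L]], var)),
    "*" = {
      v <- args[[2L]]
      mk_add(mk_mul(du, v), mk_mul(u, sf_deriv(v, var)))
    },
    "/" = {
      v <- args[[2L]]
      dv <- sf_deriv(v, var)
      # d(u/v) = du/v - u*dv/v^2
      mk_sub(mk_div(du, v), mk_div(mk_mul(u, dv), mk_pow(v, 2)))
    },
    "^" = {
      v <- args[[2L]]
      dv <- sf_deriv(v, var)
      if (is_zero(dv)) {
        # exponent constant wrt var: v*u^(v-1)*du
        mk_mul(mk_mul(v, mk_pow(u, mk_sub(v, 1))), du)
      } else if (is_zero(du)) {
        # base constant wrt var: u^v*log(u)*dv
        mk_mul(mk_mul(mk_pow(u, v), call("log", u)), dv)
      } else {
        # general: u^v * (dv*log(u) + v*du/u)
        mk_mul(
          mk_pow(u, v),
          mk_add(
            mk_mul(dv, call("log", u)),
            mk_div(mk_mul(v, du), u)
          )
        )
      }
    },
    "exp" = mk_mul(e, du),
    "log" = mk_div(du, u),
    "sqrt" = mk_div(du, mk_mul(2, call("sqrt", u))),
    "sin" = mk_mul(call("cos", u), du),
    "cos" = mk_neg(mk_mul(call("sin", u), du)),
    "tan" = mk_div(du, mk_pow(call("cos", u), 2)),
    "abs" = mk_mul(call(".sf_sign", u), du),
    stop(sprintf("cannot differentiate '%s'", op), call. = FALSE)
  )
}

deriv_tree <- function(tree, var) {
  key <- paste0("d_", var)
  d <- tree$cache[[key]]
  if (is.null(d)) {
    d <- sf_deriv(tree$expr, var)
    assign(key, d, envir = tree$cache)
  }
  d
}

#' Exact gradient of a parsed expression
#'
#' Partial derivatives are obtained by symbolic differentiation of the tree
#' (cached per symbol) and evaluated at `values`.  Derivatives are exact up to
#' floating point; `d|x|/dx` at 0 is defined as 0.
#'
#' @inheritParams eval_expr
#' @param wrt Character vector of symbols to differentiate with respect to;
#'   defaults to all declared variables.
#' @return A numeric matrix with one row per evaluation point (the common
#'   length of the vectors in `values`) and one named column per symbol in
#'   `wrt`.
#' @examples
#' tr <- parse_model_expr("x**2", "x")
#' grad_expr(tr, list(x = 3)) # 6
#' @export
grad_expr <- function(tree, values, wrt = tree$variables) {
  stopifnot(inherits(tree, "sf_expr"))
  values <- as.list(values)
  missing <- setdiff(tree$used, names(values))
  if (length(missing) > 0L) {
    stop(sprintf(
      "missing value(s) for symbol(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  n <- max(1L, vapply(values, length, 1L))
  env <- list2env(values, parent = sf_math_env())
  out <- matrix(0, nrow = n, ncol = length(wrt),
    dimnames = list(NULL, wrt))
  for (s in wrt) {
    d <- deriv_tree(tree, s)
    v <- eval(d, env)
    if (!all(is.finite(v))) {
      sf_domain_error(sprintf(
        "non-finite derivative d/d%s of '%s'", s, tree$source
      ))
    }
    out[, s] <- v
  }
  out
}
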