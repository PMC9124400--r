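# Smooth bound-enforcing reparameterizations.  The optimizer always works on
# an unconstrained "hidden" vector; each bounded natural-scale parameter b is
# tied to a hidden variable b~ through a strictly increasing map:
#   positivity / (lo, Inf):  b = lo + exp(b~)
#   (-Inf, hi):              b = hi - exp(-b~)
#   (lo, hi):                b = lo + (hi - lo) * logistic(b~)
# so gradients chain through an always-positive jacobian factor and the
# objective never sees a boundary discontinuity.

#' Parameter transform specification
#'
#' @param kind `"identity"`, `"exponential"` (one finite end), or
#'   `"sigmoidal"` (two finite ends).
#' @param lo,hi Bound ends; use `-Inf`/`Inf` for open ends.
#' @return An object of class `sf_transform`.
#' @seealso [transform_forward()], [transform_inverse()],
#'   [transform_jacobian()]
#' @export
par_transform <- function(kind = c("identity", "exponential", "sigmoidal"),
                          lo = -Inf, hi = Inf) {
  kind <- match.arg(kind)
  if (kind == "sigmoidal") {
    if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
      stop("sigmoidal transform needs finite lo < hi", call. = FALSE)
    }
  }
  if (kind == "exponential") {
    if (is.finite(lo) == is.finite(hi)) {
      stop("exponential transform needs exactly one finite end",
        call. = FALSE
      )
    }
  }
  structure(list(kind = kind, lo = lo, hi = hi), class = "sf_transform")
}

# L-BFGS line searches can probe extreme hidden values; clamp before exp
.sf_clamp <- function(x) pmin(pmax(x, -700), 700)

#' Hidden-to-natural transform
#'
#' Maps an unconstrained hidden value into the interior of the bound.  All
#' three kinds are strictly increasing; the exponential branch clamps the
#' hidden value to \[-700, 700\] before exponentiation so overflow cannot
#' occur.
#'
#' @param spec An `sf_transform`.
#' @param hidden Numeric vector of hidden-scale values.
#' @return Natural-scale values, strictly inside the bound.
#' @export
transform_forward <- function(spec, hidden) {
  switch(spec$kind,
    identity = hidden,
    exponential = {
      if (is.finite(spec$lo)) {
        spec$lo + exp(.sf_clamp(hidden))
      } else {
        spec$hi - exp(.sf_clamp(-hidden))
      }
    },
    sigmoidal = spec$lo + (spec$hi - spec$lo) * stats::plogis(hidden)
  )
}

#' Natural-to-hidden transform
#'
#' Inverse of [transform_forward()]; defined only for natural values strictly
#' inside the bound.
#'
#' @inheritParams transform_forward
#' @param natural Numeric vector of natural-scale values.
#' @param name Parameter name used in the error message when `natural` sits on
#'   or outside the bound.
#' @return Hidden-scale values with `transform_forward(spec, out) == natural`
#'   to relative error below 1e-12.
#' @export
transform_inverse <- function(spec, natural, name = "parameter") {
  bad <- switch(spec$kind,
    identity = rep(FALSE, length(natural)),
    exponential = if (is.finite(spec$lo)) {
      natural <= spec$lo
    } else {
      natural >= spec$hi
    },
    sigmoidal = natural <= spec$lo | natural >= spec$hi
  )
  if (any(bad)) {
    stop(sprintf(
      "'%s' = %g is on or outside its bound %s",
      name, natural[which(bad)[1L]], format_transform(spec)
    ), call. = FALSE)
  }
  switch(spec$kind,
    identity = natural,
    exponential = if (is.finite(spec$lo)) {
      log(natural - spec$lo)
    } else {
      -log(spec$hi - natural)
    },
    sigmoidal = stats::qlogis((natural - spec$lo) / (spec$hi - spec$lo))
  )
}

#' Transform jacobian factor
#'
#' `d(natural)/d(hidden)` at the given hidden value, used to chain objective
#' gradients from the natural scale onto the hidden vector.  Strictly positive
#' for the exponential and sigmoidal kinds, identically 1 for identity.
#'
#' @inheritParams transform_forward
#' @return Numeric vector of derivative factors.
#' @export
transform_jacobian <- function(spec, hidden) {
  switch(spec$kind,
    identity = rep(1, length(hidden)),
    exponential = if (is.finite(spec$lo)) {
      exp(.sf_clamp(hidden))
    } else {
      exp(.sf_clamp(-hidden))
    },
    sigmoidal = (spec$hi - spec$lo) * stats::dlogis(hidden)
  )
}

format_transform <- function(spec) {
  switch(spec$kind,
    identity = "(-inf, inf)",
    exponential = sprintf("(%s, %s)", format(spec$lo), format(spec$hi)),
    sigmoidal = sprintf("(%g, %g)", spec$lo, spec$hi)
  )
}

#' @export
print.sf_transform <- function(x, ...) {
  cat("<sf_transform> ", x$kind, " ", format_transform(x), "\n", sep = "")
  invisible(x)
}

# Map a parameter bound (see param_spec) to its transform; constants have none.
bound_transform <- function(bound) {
  switch(bound$kind,
    unbounded = par_transform("identity"),
    positive = par_transform("exponential", lo = 0),
    lower = par_transform("exponential", lo = bound$lo),
    upper = par_transform("exponential", hi = bound$hi),
    interval = par_transform("sigmoidal", lo = bound$lo, hi = bound$hi),
    constant = stop("constant parameters have no transform", call. = FALSE)
  )
}
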