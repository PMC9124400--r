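# The shipped worked example: six stochastic growth curves fitted
# simultaneously by the generalized-logistic (Richards) model
#   N(t) = K [1 - (1 - (K/n0)^nu) exp(-r nu t)]^(-1/nu)
# with carrying capacity K and curvature nu shared across all curves, the
# initial value n0 free per curve, and the growth rate r either tied to two
# detached parameters (one per triplet of curves), shared across all curves,
# or free per curve.

#' The generalized-logistic growth model
#'
#' Closed-form Richards growth curve with parameters `K` (carrying capacity),
#' `n0` (initial value), `nu` (growth curvature; `nu = 1` is the standard
#' logistic), and `r` (growth rate), all positive.  Initial guesses are set
#' to magnitudes typical of microbial growth-curve data (`K = 5`,
#' `n0 = 0.05`, `nu = 1`, `r = 0.3`).
#'
#' @return An [expression_model()].
#' @export
growth_model <- function() {
  expression_model(
    "growth",
    "K*(1 - (1 - (K/n0)**nu)*exp(-r*nu*x))**(-1/nu)",
    parameters = list(K = 5, n0 = 0.05, nu = 1, r = 0.3)
  )
}

#' The growth model as an ODE
#'
#' The same generalized-logistic model defined through its differential form
#' `dN/dt = r N (1 - (N/K)^nu)` with `N(0) = n0` as a fittable parameter.
#'
#' @return An [ode_model()].
#' @export
growth_ode_model <- function() {
  ode_model(
    "growth_ode",
    states = "N",
    rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"),
    parameters = list(r = 0.3, K = 5, nu = 1, n0 = 0.05)
  )
}

#' Worked-example fit topology
#'
#' Binds six growth curves to the [growth_model()] with `K` and `nu` shared
#' across all curves, `n0` free per curve, and the growth rate `r` in one of
#' three sharing arrangements:
#' \describe{
#'   \item{`"detached"`}{`r` tied to detached parameters `rA` (first half of
#'     the curves) and `rB` (second half): 10 free parameters for 6 curves.}
#'   \item{`"shared"`}{`r` a single model parameter: 9 free parameters.}
#'   \item{`"independent"`}{all four parameters free per curve: 24 free
#'     parameters, equivalent to six separate fits.}
#' }
#'
#' @param datasets List of datasets, typically from
#'   [simulate_growth_curves()]; an even count is required for `"detached"`.
#' @param sharing Sharing arrangement for `r`.
#' @param model Model to bind (defaults to [growth_model()]; use
#'   [growth_ode_model()] for the ODE route).
#' @return An `sf_topology`.
#' @export
growth_example_topology <- function(datasets,
                                    sharing = c(
                                      "detached", "shared",
                                      "independent"
                                    ),
                                    model = growth_model()) {
  sharing <- match.arg(sharing)
  ds_names <- vapply(datasets, `[[`, character(1), "name")
  roles <- switch(sharing,
    detached = {
      k <- length(ds_names)
      if (k %% 2L != 0L) {
        stop("'detached' sharing needs an even number of datasets",
          call. = FALSE
        )
      }
      half <- k %/% 2L
      list(
        K = "model", nu = "model", n0 = "data",
        r = stats::setNames(
          rep(c("rA", "rB"), each = half), ds_names
        )
      )
    },
    shared = list(K = "model", nu = "model", n0 = "data", r = "model"),
    independent = list()
  )
  fit_topology(datasets, model, roles = roles)
}
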