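# S3 methods for fitted simulfit objects.

#' @export
print.simulfit <- function(x, digits = max(4L, getOption("digits") - 3L),
                           ...) {
  cat("Simultaneous fit\n")
  cat(sprintf(
    "  %d dataset(s), %d free parameter(s), method %s (%s)\n",
    length(x$topology$datasets), n_free_parameters(x$topology),
    x$optimizer$method,
    if (x$optimizer$converged) "converged" else "not converged"
  ))
  cat(sprintf(
    "  objective (SSE): %s   global R-squared: %s\n",
    format(x$objective, digits = digits),
    format(x$r_squared_global, digits = digits)
  ))
  cat("\nCoefficients:\n")
  print(signif(x$estimates, digits))
  invisible(x)
}

#' @export
coef.simulfit <- function(object, ...) object$estimates

#' @export
deviance.simulfit <- function(object, ...) object$objective

#' @export
fitted.simulfit <- function(object, ...) object$predictions

#' @export
residuals.simulfit <- function(object, ...) object$residuals

#' @export
summary.simulfit <- function(object, ...) {
  idt <- object$topology$identities
  tab <- data.frame(
    id = idt$id, estimate = unname(object$estimates),
    type = idt$type, model = idt$model, dataset = idt$dataset,
    param = idt$param, bound = idt$bound,
    stringsAsFactors = FALSE
  )
  npts <- sum(vapply(
    object$topology$datasets,
    function(d) length(d$x), integer(1)
  ))
  structure(
    list(
      coefficients = tab,
      objective = object$objective,
      r_squared_global = object$r_squared_global,
      r_squared_per_dataset = object$r_squared_per_dataset,
      n_points = npts,
      n_free = nrow(idt),
      optimizer = object$optimizer,
      residual_sd = sqrt(object$objective / max(1L, npts - nrow(idt)))
    ),
    class = "summary.simulfit"
  )
}

#' @export
print.summary.simulfit <- function(x, digits = max(
                                     4L,
                                     getOption("digits") - 3L
                                   ), ...) {
  cat("Simultaneous fit summary\n\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "\nObjective (SSE) %s on %d points, %d free parameters\n",
    format(x$objective, digits = digits), x$n_points, x$n_free
  ))
  cat(sprintf(
    "Residual standard deviation: %s\n",
    format(x$residual_sd, digits = digits)
  ))
  cat(sprintf(
    "Global R-squared: %s\n",
    format(x$r_squared_global, digits = digits)
  ))
  cat("Per-dataset R-squared:\n")
  print(signif(x$r_squared_per_dataset, digits))
  cat(sprintf(
    "Optimizer: %s, %d function / %d gradient evaluations, |grad| = %s\n",
    x$optimizer$method, x$optimizer$n_function_evaluations,
    x$optimizer$n_gradient_evaluations,
    format(x$optimizer$gradient_norm, digits = 3)
  ))
  invisible(x)
}

#' Predictions from a simultaneous fit
#'
#' @param object A `simulfit` object.
#' @param newdata Optional abscissae at which to predict: a numeric vector
#'   (used for every dataset) or a named list of vectors per dataset.
#'   Defaults to each dataset's own abscissae.
#' @param ... Unused.
#' @return Named list of prediction vectors, one per dataset.
#' @export
predict.simulfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$predictions)
  }
  top <- object$topology
  args_by_ds <- unpack_parameters(top, unname(object$hidden))
  ctl <- object$config_echo$control
  out <- list()
  for (ds in names(top$datasets)) {
    x <- if (is.list(newdata)) newdata[[ds]] else newdata
    if (is.null(x)) next
    mod <- top$models[[top$bindings[[ds]]]]
    out[[ds]] <- model_predict(mod, args_by_ds[[ds]], sort(as.numeric(x)),
      gradient = FALSE, rtol = ctl$rtol, atol = ctl$atol
    )$pred
  }
  out
}

#' Plot data and fitted curves
#'
#' One panel per dataset: observations as points, the fitted model evaluated
#' on a fine grid as a line.
#'
#' @param x A `simulfit` object.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.simulfit <- function(x, n_grid = 200L, ...) {
  top <- x$topology
  k <- length(top$datasets)
  mfrow <- c(ceiling(k / ceiling(sqrt(k))), ceiling(sqrt(k)))
  op <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ds in names(top$datasets)) {
    dat <- top$datasets[[ds]]
    xs <- seq(min(dat$x), max(dat$x), length.out = n_grid)
    ys <- predict(x, stats::setNames(list(xs), ds))[[ds]]
    graphics::plot(dat$x, dat$y,
      xlab = "x", ylab = "y",
      main = sprintf(
        "%s (R² = %.3f)", ds,
        x$r_squared_per_dataset[[ds]]
      ), ...
    )
    graphics::lines(xs, ys, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate responses from a fitted model
#'
#' Parametric resampling: fitted predictions plus Gaussian noise with the
#' residual standard deviation of the fit.
#'
#' @param object A `simulfit` object.
#' @param nsim Number of simulated replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of length `nsim`; each element is a named list of simulated
#'   response vectors per dataset.
#' @export
simulate.simulfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- summary(object)$residual_sd
  lapply(seq_len(nsim), function(i) {
    lapply(object$predictions, function(p) p + stats::rnorm(length(p), 0, sd))
  })
}
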