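# The fit topology binds datasets to models and assigns every
# (dataset, parameter) slot one of four sharing roles:
#   model   - one value shared by every dataset bound to the model
#   data    - an independent value per dataset (the default)
#   detached - tied to a named free parameter; any slot in any model may tie
#              to the same name, giving arbitrary sharing patterns
#   constant - fixed, excluded from fitting
# Free parameters are packed into one flat hidden-scale vector in a
# deterministic order: model-shared identities sorted by (model, parameter),
# then detached names lexicographically, then per-dataset slots by
# (dataset order, parameter name).

#' Number of free parameters
#'
#' @param x An `sf_model` or `sf_topology`.
#' @return Integer count of free (non-constant) parameters; for a topology
#'   this is the length of the packed optimizer vector.
#' @export
n_free_parameters <- function(x) UseMethod("n_free_parameters")

#' @export
n_free_parameters.sf_topology <- function(x) nrow(x$identities)

role_of <- function(spec, dataset) {
  # spec: the roles[[param]] entry; dataset: dataset name
  if (is.null(spec)) {
    return(list(type = "data"))
  }
  if ((is.list(spec) || length(spec) > 1L ||
    !is.null(names(spec))) && !is.null(names(spec))) {
    spec <- if (dataset %in% names(spec)) spec[[dataset]] else NULL
    if (is.null(spec)) {
      return(list(type = "data"))
    }
  }
  if (is.numeric(spec)) {
    return(list(type = "constant", value = as.numeric(spec)))
  }
  if (is.character(spec) && length(spec) == 1L) {
    s <- spec
    if (s %in% c("model", "shared")) {
      return(list(type = "model"))
    }
    if (s %in% c("data", "per_dataset", "independent")) {
      return(list(type = "data"))
    }
    b <- tryCatch(parse_bound(s), error = function(e) NULL)
    if (!is.null(b) && b$kind == "constant") {
      return(list(type = "constant", value = b$value))
    }
    return(list(type = "detached", name = s))
  }
  stop("cannot interpret a parameter role specification", call. = FALSE)
}

bounds_equal <- function(a, b) {
  a$kind == b$kind &&
    isTRUE(all.equal(c(a$lo, a$hi), c(b$lo, b$hi)))
}

#' Build a fit topology
#'
#' @param datasets A list of [xy_dataset()] objects (or a single one).
#' @param models A single [expression_model()]/[ode_model()] or a named list
#'   of models.  A single model is bound to every dataset automatically.
#' @param roles Named list, one entry per model parameter name.  Each entry is
#'   either a single role applied to all datasets or a named vector/list of
#'   per-dataset roles.  A role is `"model"` (shared across the model's
#'   datasets), `"data"` (independent per dataset, the default), a number or
#'   `"C(value)"` (constant), or any other string, which names a detached
#'   parameter.
#' @param detached Optional named list overriding the bound/guess of detached
#'   parameters: `list(rA = list(bound = "R(0, inf)", guess = 0.3))`.  By
#'   default a detached parameter inherits bound and guess from the first
#'   parameter slot tied to it.
#' @param bindings Named character vector `dataset -> model name`; required
#'   only when more than one model is supplied.
#' @return An object of class `sf_topology`.
#' @examples
#' m <- expression_model("line", "a*x + b", c("a", "b"))
#' d1 <- xy_dataset(0:3, c(1, 3, 5, 7), "d1")
#' d2 <- xy_dataset(0:3, c(2, 4, 6, 8), "d2")
#' top <- fit_topology(list(d1, d2), m, roles = list(a = "model"))
#' n_free_parameters(top) # one shared slope + two intercepts
#' @export
fit_topology <- function(datasets, models, roles = list(),
                         detached = list(), bindings = NULL) {
  if (inherits(datasets, "sf_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, logical(1), "sf_dataset")))
  names(datasets) <- vapply(datasets, `[[`, character(1), "name")
  if (anyDuplicated(names(datasets))) {
    stop("dataset names must be unique", call. = FALSE)
  }
  if (inherits(models, "sf_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "sf_model")))
  names(models) <- vapply(models, `[[`, character(1), "name")

  if (is.null(bindings)) {
    if (length(models) != 1L) {
      stop("'bindings' is required when more than one model is given",
        call. = FALSE
      )
    }
    bindings <- stats::setNames(
      rep(names(models), length(datasets)), names(datasets)
    )
  } else {
    bindings <- unlist(bindings)
    missing_ds <- setdiff(names(datasets), names(bindings))
    if (length(missing_ds) > 0L) {
      stop(sprintf(
        "no model bound to dataset(s): %s",
        paste(missing_ds, collapse = ", ")
      ), call. = FALSE)
    }
    bad <- setdiff(unique(bindings[names(datasets)]), names(models))
    if (length(bad) > 0L) {
      stop(sprintf(
        "dataset bound to unknown model(s): %s",
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    bindings <- bindings[names(datasets)]
  }

  # resolve every (dataset, parameter) slot
  slots <- list()
  detached_registry <- list()
  detached_warned <- character(0)
  model_shared <- list() # key "model|param" -> list(model, param)
  for (ds in names(datasets)) {
    mod <- models[[bindings[[ds]]]]
    slots[[ds]] <- list()
    for (p in names(mod$parameters)) {
      spec <- mod$parameters[[p]]
      if (spec$bound$kind == "constant") {
        slots[[ds]][[p]] <- list(type = "constant", value = spec$bound$value)
        next
      }
      role <- role_of(roles[[p]], ds)
      if (role$type == "model") {
        key <- paste(mod$name, p, sep = "|")
        model_shared[[key]] <- list(model = mod$name, param = p)
        slots[[ds]][[p]] <- list(type = "model", key = key)
      } else if (role$type == "detached") {
        nm <- role$name
        if (is.null(detached_registry[[nm]])) {
          ov <- detached[[nm]]
          detached_registry[[nm]] <- list(
            bound = if (!is.null(ov$bound)) {
              if (is.list(ov$bound)) ov$bound else parse_bound(ov$bound)
            } else {
              spec$bound
            },
            guess = if (!is.null(ov$guess)) {
              as.numeric(ov$guess)
            } else {
              spec$guess
            }
          )
        } else if (!bounds_equal(detached_registry[[nm]]$bound, spec$bound) &&
          !nm %in% detached_warned) {
          detached_warned <- c(detached_warned, nm)
          warning(sprintf(
            "detached parameter '%s' tied to slots with differing bounds; keeping %s",
            nm, format_bound(detached_registry[[nm]]$bound)
          ), call. = FALSE)
        }
        slots[[ds]][[p]] <- list(type = "detached", name = nm)
      } else if (role$type == "constant") {
        slots[[ds]][[p]] <- list(type = "constant", value = role$value)
      } else {
        slots[[ds]][[p]] <- list(type = "data")
      }
    }
  }
  unknown_roles <- setdiff(
    names(roles),
    unlist(lapply(names(models), function(m) names(models[[m]]$parameters)))
  )
  if (length(unknown_roles) > 0L) {
    stop(sprintf(
      "role(s) given for unknown parameter(s): %s",
      paste(unknown_roles, collapse = ", ")
    ), call. = FALSE)
  }

  # deterministic packing order
  ids <- list()
  add_identity <- function(id, type, model, dataset, param, bound, guess) {
    ids[[length(ids) + 1L]] <<- data.frame(
      id = id, type = type, model = model, dataset = dataset,
      param = param, bound = format_bound(bound), guess = guess,
      stringsAsFactors = FALSE
    )
  }
  for (key in sort(names(model_shared))) {
    ms <- model_shared[[key]]
    spec <- models[[ms$model]]$parameters[[ms$param]]
    add_identity(
      paste(ms$model, ms$param, sep = ":"), "model",
      ms$model, NA_character_, ms$param, spec$bound, spec$guess
    )
  }
  for (nm in sort(names(detached_registry))) {
    reg <- detached_registry[[nm]]
    add_identity(
      nm, "detached", NA_character_, NA_character_, NA_character_,
      reg$bound, reg$guess
    )
  }
  for (ds in names(datasets)) {
    mod <- models[[bindings[[ds]]]]
    for (p in sort(names(mod$parameters))) {
      if (identical(slots[[ds]][[p]]$type, "data")) {
        spec <- mod$parameters[[p]]
        add_identity(
          paste(ds, p, sep = ":"), "data", mod$name, ds, p,
          spec$bound, spec$guess
        )
      }
    }
  }
  identities <- if (length(ids) > 0L) {
    do.call(rbind, ids)
  } else {
    data.frame(
      id = character(0), type = character(0), model = character(0),
      dataset = character(0), param = character(0), bound = character(0),
      guess = numeric(0), stringsAsFactors = FALSE
    )
  }
  transforms <- lapply(seq_len(nrow(identities)), function(i) {
    bound_transform(parse_bound(identities$bound[i]))
  })

  structure(
    list(
      datasets = datasets, models = models, bindings = bindings,
      slots = slots, detached_registry = detached_registry,
      identities = identities, transforms = transforms
    ),
    class = "sf_topology"
  )
}

# id of the free identity a slot resolves to, or NA for constants
slot_id <- function(topology, ds, p) {
  s <- topology$slots[[ds]][[p]]
  switch(s$type,
    model = {
      ms <- strsplit(s$key, "|", fixed = TRUE)[[1L]]
      paste(ms[1L], ms[2L], sep = ":")
    },
    detached = s$name,
    data = paste(ds, p, sep = ":"),
    constant = NA_character_
  )
}

#' Free-parameter table of a topology
#'
#' One row per entry of the packed optimizer vector, in packing order.
#'
#' @param topology An `sf_topology`.
#' @return A data frame with columns `id`, `type`, `model`, `dataset`,
#'   `param`, `bound`, `guess`.
#' @export
free_parameters <- function(topology) {
  stopifnot(inherits(topology, "sf_topology"))
  topology$identities
}

#' Initial hidden-scale vector
#'
#' Turns natural-scale initial guesses into the unconstrained hidden vector
#' the optimizer starts from.  Guesses are taken from `guesses` (matched first
#' by full identity id such as `"curve_1:n0"` or `"rA"`, then by bare
#' parameter name, which then applies to every identity of that parameter),
#' falling back to each parameter's declared default.
#'
#' @param topology An `sf_topology`.
#' @param guesses Named list/vector of natural-scale values.
#' @return Named numeric hidden-scale vector in packing order.
#' @export
initial_hidden <- function(topology, guesses = list()) {
  idt <- topology$identities
  guesses <- as.list(guesses)
  unknown <- setdiff(names(guesses), c(idt$id, idt$param))
  if (length(unknown) > 0L) {
    stop(sprintf(
      "guess(es) for unknown identity: %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  hidden <- numeric(nrow(idt))
  for (i in seq_len(nrow(idt))) {
    g <- idt$guess[i]
    if (!is.na(idt$param[i]) && idt$param[i] %in% names(guesses)) {
      g <- as.numeric(guesses[[idt$param[i]]])
    }
    if (idt$id[i] %in% names(guesses)) {
      g <- as.numeric(guesses[[idt$id[i]]])
    }
    hidden[i] <- transform_inverse(topology$transforms[[i]], g, idt$id[i])
  }
  stats::setNames(hidden, idt$id)
}

#' Natural-scale estimates from a hidden vector
#'
#' @param topology An `sf_topology`.
#' @param hidden Numeric vector in packing order.
#' @return Named numeric vector of natural-scale values, one per free
#'   identity.
#' @export
natural_estimates <- function(topology, hidden) {
  idt <- topology$identities
  if (length(hidden) != nrow(idt)) {
    stop(sprintf(
      "hidden vector has length %d, topology has %d free parameters",
      length(hidden), nrow(idt)
    ), call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(idt)), function(i) {
    transform_forward(topology$transforms[[i]], hidden[i])
  }, numeric(1))
  stats::setNames(vals, idt$id)
}

#' Unpack a hidden vector into per-dataset argument maps
#'
#' Applies the transforms and distributes shared values, yielding for every
#' dataset the complete natural-scale parameter map its model needs
#' (constants included).
#'
#' @inheritParams natural_estimates
#' @return Named list (one element per dataset) of named numeric parameter
#'   vectors.
#' @export
unpack_parameters <- function(topology, hidden) {
  nat <- natural_estimates(topology, hidden)
  out <- list()
  for (ds in names(topology$datasets)) {
    mod <- topology$models[[topology$bindings[[ds]]]]
    args <- numeric(length(mod$parameters))
    names(args) <- names(mod$parameters)
    for (p in names(mod$parameters)) {
      s <- topology$slots[[ds]][[p]]
      args[[p]] <- if (s$type == "constant") {
        s$value
      } else {
        nat[[slot_id(topology, ds, p)]]
      }
    }
    out[[ds]] <- args
  }
  out
}

#' Accumulate per-dataset gradients onto the hidden vector
#'
#' Each packed entry receives the sum of the objective's partial derivatives
#' with respect to the natural value over every slot sharing that identity,
#' multiplied by the transform's jacobian factor at the current hidden value.
#' Constant slots contribute nothing.
#'
#' @inheritParams natural_estimates
#' @param dataset_gradients Named list (per dataset) of named numeric vectors:
#'   the partial derivative of the objective with respect to each natural
#'   model parameter for that dataset.
#' @return Numeric gradient with respect to the hidden vector, in packing
#'   order.
#' @export
accumulate_gradient <- function(topology, dataset_gradients, hidden) {
  idt <- topology$identities
  g <- stats::setNames(numeric(nrow(idt)), idt$id)
  for (ds in names(topology$datasets)) {
    dg <- dataset_gradients[[ds]]
    if (is.null(dg)) next
    mod <- topology$models[[topology$bindings[[ds]]]]
    for (p in names(mod$parameters)) {
      id <- slot_id(topology, ds, p)
      if (!is.na(id) && p %in% names(dg)) {
        g[[id]] <- g[[id]] + dg[[p]]
      }
    }
  }
  jac <- vapply(seq_len(nrow(idt)), function(i) {
    transform_jacobian(topology$transforms[[i]], hidden[i])
  }, numeric(1))
  unname(g) * jac
}

#' @export
print.sf_topology <- function(x, ...) {
  cat(sprintf(
    "<sf_topology> %d dataset(s), %d model(s), %d free parameter(s)\n",
    length(x$datasets), length(x$models), n_free_parameters(x)
  ))
  idt <- x$identities
  if (nrow(idt) > 0L) {
    for (ty in c("model", "detached", "data")) {
      sel <- idt$id[idt$type == ty]
      if (length(sel) > 0L) {
        cat(sprintf(
          "  %-8s (%d): %s\n", ty, length(sel),
          paste(sel, collapse = ", ")
        ))
      }
    }
  }
  invisible(x)
}
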