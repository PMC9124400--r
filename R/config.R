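# YAML fit configuration: the headless description of a complete fit —
# models, data files, topology, guesses, optimizer settings — mirroring the
# four-step workflow (define models, import data, set the topology, run).

config_stop <- function(path, field, msg) {
  stop(sprintf("%s: %s: %s", path, field, msg), call. = FALSE)
}

model_from_block <- function(block, cfg_path, i) {
  where <- sprintf("models[%d]", i)
  if (is.null(block$name)) config_stop(cfg_path, where, "missing 'name'")
  kind <- if (is.null(block$kind)) "expression" else block$kind
  params <- if (is.null(block$parameters)) {
    config_stop(cfg_path, where, "missing 'parameters'")
  } else {
    block$parameters
  }
  if (kind == "expression") {
    if (is.null(block$body)) config_stop(cfg_path, where, "missing 'body'")
    expression_model(
      block$name, block$body, params,
      independent = if (is.null(block$independent)) "x" else block$independent
    )
  } else if (kind == "ode") {
    for (f in c("states", "rhs", "init")) {
      if (is.null(block[[f]])) {
        config_stop(cfg_path, where, sprintf("missing '%s'", f))
      }
    }
    events <- lapply(block$events, function(e) {
      event_spec(
        e$name, e$condition,
        direction = if (is.null(e$direction)) "any" else e$direction,
        terminal = isTRUE(e$terminal)
      )
    })
    ode_model(
      block$name,
      states = unlist(block$states), rhs = unlist(block$rhs),
      init = block$init, parameters = params,
      output = block$output, events = events,
      independent = if (is.null(block$independent)) "t" else block$independent
    )
  } else {
    config_stop(cfg_path, where, sprintf("unknown kind '%s'", kind))
  }
}

#' Load a fit configuration
#'
#' Reads and validates a YAML fit configuration, loads the referenced data
#' files (paths resolved relative to the configuration file), and builds the
#' fit topology.  Defaulting rules: parameter roles default to per-dataset,
#' bounds to positive, the optimizer method to `"lbfgs"`.
#'
#' @param path Path to the YAML file.
#' @return An object of class `sf_config`: list with `topology`, `guesses`,
#'   `method`, `control`, `seed`, `output_dir`, `path`, and `raw` (the parsed
#'   YAML).
#' @export
load_fit_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  if (is.null(raw$models) || length(raw$models) == 0L) {
    config_stop(path, "models", "at least one model is required")
  }
  models <- lapply(seq_along(raw$models), function(i) {
    model_from_block(raw$models[[i]], path, i)
  })
  if (is.null(raw$data) || length(raw$data) == 0L) {
    config_stop(path, "data", "at least one dataset is required")
  }
  datasets <- lapply(seq_along(raw$data), function(i) {
    blk <- raw$data[[i]]
    if (is.null(blk$file)) {
      config_stop(path, sprintf("data[%d]", i), "missing 'file'")
    }
    fp <- blk$file
    if (!file.exists(fp)) fp <- file.path(base_dir, blk$file)
    if (!file.exists(fp)) {
      config_stop(
        path, sprintf("data[%d].file", i),
        sprintf("file not found: %s", blk$file)
      )
    }
    read_xy_table(fp, name = blk$name)
  })
  topo_blk <- if (is.null(raw$topology)) list() else raw$topology
  topology <- fit_topology(
    datasets, models,
    roles = if (is.null(topo_blk$roles)) list() else topo_blk$roles,
    detached = if (is.null(topo_blk$detached)) list() else topo_blk$detached,
    bindings = topo_blk$bindings
  )
  guesses <- if (is.null(raw$guesses)) list() else raw$guesses
  unknown <- setdiff(
    names(guesses),
    c(topology$identities$id, topology$identities$param)
  )
  if (length(unknown) > 0L) {
    config_stop(
      path, "guesses",
      sprintf("unknown identity: %s", paste(unknown, collapse = ", "))
    )
  }
  opt <- if (is.null(raw$optimizer)) list() else raw$optimizer
  method <- if (is.null(opt$method)) "lbfgs" else opt$method
  if (!method %in% c("lbfgs", "neldermead")) {
    config_stop(path, "optimizer.method", sprintf("unknown '%s'", method))
  }
  control <- list()
  if (!is.null(opt$max_iterations)) {
    control$maxit <- as.integer(opt$max_iterations)
  }
  for (f in c("pgtol", "rtol", "atol", "nm_restarts")) {
    if (!is.null(opt[[f]])) control[[f]] <- opt[[f]]
  }
  structure(
    list(
      topology = topology,
      guesses = guesses,
      method = method,
      control = control,
      seed = if (is.null(raw$seed)) 0L else as.integer(raw$seed),
      output_dir = if (is.null(raw$output_dir)) {
        file.path(base_dir, "results")
      } else if (dirname(raw$output_dir) == "." &&
        !startsWith(raw$output_dir, "/")) {
        file.path(base_dir, raw$output_dir)
      } else {
        raw$output_dir
      },
      path = path,
      raw = raw
    ),
    class = "sf_config"
  )
}

#' Write a fit configuration back to YAML
#'
#' Serializes the raw configuration list; `load_fit_config()` of the written
#' file reproduces a structurally identical configuration.
#'
#' @param raw A configuration list (as in the `raw` field of an `sf_config`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fit_config <- function(raw, path) {
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write fit results to a directory
#'
#' Writes a parameter report (`parameters.csv`: one row per free parameter
#' with identity, estimate, role, bound), one prediction file per dataset
#' (`<name>_fit.csv`: x, y, fit, residual), a machine-readable
#' `manifest.json` with the convergence report and the list of output files,
#' and a human-readable `run.log`.  An existing non-empty directory is never
#' silently overwritten.
#'
#' @param fit A `simulfit` object.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @param seed Seed echoed into the manifest.
#' @return The manifest, invisibly.
#' @export
write_fit_results <- function(fit, dir, force = FALSE, seed = NULL) {
  stopifnot(inherits(fit, "simulfit"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop(sprintf(
      "output directory '%s' is not empty; use force = TRUE to overwrite",
      dir
    ), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  idt <- fit$topology$identities
  par_tab <- data.frame(
    id = idt$id, value = unname(fit$estimates), role = idt$type,
    bound = idt$bound, model = idt$model, dataset = idt$dataset,
    param = idt$param, stringsAsFactors = FALSE
  )
  pf <- file.path(dir, "parameters.csv")
  utils::write.csv(par_tab, pf, row.names = FALSE)
  files <- c(files, pf)

  for (ds in names(fit$topology$datasets)) {
    dat <- fit$topology$datasets[[ds]]
    df <- data.frame(
      x = dat$x, y = dat$y, fit = fit$predictions[[ds]],
      residual = fit$residuals[[ds]]
    )
    f <- file.path(dir, sprintf("%s_fit.csv", ds))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    files = basename(files),
    objective = fit$objective,
    r_squared_global = fit$r_squared_global,
    r_squared_per_dataset = as.list(fit$r_squared_per_dataset),
    n_free_parameters = nrow(idt),
    optimizer = fit$optimizer[c(
      "method", "iterations", "n_function_evaluations",
      "n_gradient_evaluations", "converged", "gradient_norm"
    )],
    seed = seed
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  files <- c(files, mf)

  lf <- file.path(dir, "run.log")
  lines <- c(
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf(
      "%d dataset(s), %d free parameter(s)",
      length(fit$topology$datasets), nrow(idt)
    ),
    sprintf(
      "method %s: %d function / %d gradient evaluations, converged: %s",
      fit$optimizer$method, fit$optimizer$n_function_evaluations,
      fit$optimizer$n_gradient_evaluations, fit$optimizer$converged
    ),
    sprintf("objective (SSE): %.10g", fit$objective),
    sprintf("global R-squared: %.6f", fit$r_squared_global),
    "estimates:",
    sprintf("  %-20s %.8g", names(fit$estimates), fit$estimates)
  )
  writeLines(lines, lf)
  invisible(manifest)
}

# Raw configuration list for the shipped worked example (detached sharing),
# with data files expected next to the configuration.
growth_example_config_raw <- function(seed, n_curves = 6L) {
  ds_names <- sprintf("curve_%d", seq_len(n_curves))
  half <- n_curves %/% 2L
  list(
    version = 1L,
    seed = as.integer(seed),
    models = list(list(
      name = "growth",
      kind = "expression",
      independent = "x",
      parameters = list(
        K = list(bound = "R(0, inf)", guess = 5),
        n0 = list(bound = "R(0, inf)", guess = 0.05),
        nu = list(bound = "R(0, inf)", guess = 1),
        r = list(bound = "R(0, inf)", guess = 0.3)
      ),
      body = "K*(1 - (1 - (K/n0)**nu)*exp(-r*nu*x))**(-1/nu)"
    )),
    data = lapply(ds_names, function(nm) {
      list(name = nm, file = paste0(nm, ".csv"))
    }),
    topology = list(
      roles = list(
        K = "model", nu = "model", n0 = "data",
        r = as.list(stats::setNames(
          rep(c("rA", "rB"), each = half), ds_names
        ))
      )
    ),
    optimizer = list(method = "lbfgs", max_iterations = 1000L),
    output_dir = "results"
  )
}

#' Write the worked-example fixture set
#'
#' Simulates the six stochastic growth curves of the shipped example
#' (see [simulate_growth_curves()]), writes them as two-column CSV files, and
#' writes a ready-made fit configuration with the detached-`r` topology.
#'
#' @param dir Output directory.
#' @param seed Integer seed for the simulation.
#' @param force Overwrite an existing non-empty directory.
#' @return Path to the written configuration file, invisibly.
#' @export
write_growth_example <- function(dir, seed = 0L, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop(sprintf(
      "output directory '%s' is not empty; use force = TRUE to overwrite",
      dir
    ), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- simulate_growth_curves(seed = seed)
  for (d in curves) {
    write_xy_table(d, file.path(dir, paste0(d$name, ".csv")))
  }
  cfg <- file.path(dir, "config.yaml")
  write_fit_config(growth_example_config_raw(seed, length(curves)), cfg)
  invisible(cfg)
}
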