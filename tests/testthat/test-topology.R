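# Sharing roles, the packed parameter vector, and gradient accumulation.

example_topology <- function(curves = NULL, sharing = "detached") {
  if (is.null(curves)) curves <- make_growth_curves(1)
  growth_example_topology(curves, sharing)
}

test_that("the worked-example topology has 10 free parameters, 6 from n0", {
  top <- example_topology()
  expect_equal(n_free_parameters(top), 10L)
  idt <- free_parameters(top)
  expect_equal(sum(idt$type == "data" & idt$param == "n0"), 6L)
  expect_equal(sum(idt$type == "detached"), 2L)
  expect_setequal(idt$id[idt$type == "detached"], c("rA", "rB"))
  expect_equal(sum(idt$type == "model"), 2L)
})

test_that("alternative sharing arrangements count correctly", {
  curves <- make_growth_curves(1)
  expect_equal(
    n_free_parameters(example_topology(curves, "shared")), 9L
  )
  expect_equal(
    n_free_parameters(example_topology(curves, "independent")), 24L
  )
  # single dataset, all roles per-dataset: an ordinary single-curve fit
  single <- fit_topology(curves[[1]], growth_model())
  expect_equal(n_free_parameters(single), 4L)
})

test_that("an all-constant topology has zero free parameters and fits as a no-op", {
  d <- xy_dataset(0:5, rep(2, 6), "flat")
  m <- expression_model("const", "a", parameters = list(a = "C(2)"))
  top <- fit_topology(d, m)
  expect_equal(n_free_parameters(top), 0L)
  fit <- simulfit(top)
  expect_equal(fit$objective, 0)
  expect_equal(fit$predictions$flat, rep(2, 6))
})

test_that("shared identities distribute one value; constants pass through", {
  curves <- make_growth_curves(1)
  m <- expression_model(
    "growth", "K*(1 - (1 - (K/n0)**nu)*exp(-r*nu*x))**(-1/nu)",
    parameters = list(K = "C(10)", n0 = 0.05, nu = 1, r = 0.3)
  )
  top <- growth_example_topology(curves, "detached", model = m)
  h <- initial_hidden(top)
  args <- unpack_parameters(top, h)
  expect_equal(unname(vapply(args, `[[`, numeric(1), "K")), rep(10, 6))

  # changing the rA entry changes r in exactly the first three argument maps
  h2 <- h
  h2[["rA"]] <- h2[["rA"]] + 0.1
  args2 <- unpack_parameters(top, h2)
  changed <- vapply(
    names(args),
    function(ds) args2[[ds]][["r"]] != args[[ds]][["r"]], logical(1)
  )
  expect_equal(unname(changed), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("pack/unpack round-trips natural guesses to 1e-12", {
  top <- example_topology()
  guesses <- list(
    "growth:K" = 12.5, "growth:nu" = 0.7, rA = 0.21, rB = 0.09,
    n0 = 0.033
  )
  h <- initial_hidden(top, guesses)
  nat <- natural_estimates(top, h)
  expect_equal(nat[["growth:K"]], 12.5, tolerance = 1e-12)
  expect_equal(nat[["rA"]], 0.21, tolerance = 1e-12)
  expect_equal(nat[["curve_3:n0"]], 0.033, tolerance = 1e-12)
})

test_that("gradient accumulation sums shared slots through the chain rule", {
  # constant model y = a on k datasets with an identity transform:
  # d SSE / d a over all datasets is the sum of per-dataset contributions
  m <- expression_model("const", "a",
    parameters = list(a = list(bound = "R(-inf, inf)", guess = 0))
  )
  k <- 4L
  ds <- lapply(seq_len(k), function(i) {
    xy_dataset(1:3, rep(i, 3), sprintf("d%d", i))
  })
  top <- fit_topology(ds, m, roles = list(a = "model"))
  g_each <- lapply(stats::setNames(seq_len(k), sprintf("d%d", seq_len(k))),
    function(i) c(a = 2.5)
  )
  acc <- accumulate_gradient(top, g_each, hidden = 0)
  expect_equal(acc, k * 2.5)
  # constants contribute nothing
  m2 <- expression_model("c2", "a + b",
    parameters = list(
      a = list(bound = "R(-inf, inf)", guess = 0),
      b = "C(1)"
    )
  )
  top2 <- fit_topology(ds[[1]], m2, roles = list(a = "model"))
  acc2 <- accumulate_gradient(top2, list(d1 = c(a = 1, b = 99)), hidden = 0)
  expect_equal(acc2, 1)
})

test_that("the assembled objective gradient matches finite differences", {
  top <- example_topology()
  set.seed(5)
  err <- check_gradient(top, n_points = 3)
  expect_lt(err, 1e-4)
})

test_that("dataset order does not change the objective or the estimates", {
  curves <- make_growth_curves(2)
  top1 <- growth_example_topology(curves, "detached")
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L) # within-triplet permutation
  top2 <- growth_example_topology(curves[perm], "detached")
  g <- list(
    "growth:K" = 8, "growth:nu" = 0.6, rA = 0.25, rB = 0.12, n0 = 0.02
  )
  o1 <- objective_and_gradient(top1, unname(initial_hidden(top1, g)),
    gradient = FALSE
  )$value
  o2 <- objective_and_gradient(top2, unname(initial_hidden(top2, g)),
    gradient = FALSE
  )$value
  expect_equal(o1, o2, tolerance = 1e-12)
  f1 <- simulfit(top1)
  f2 <- simulfit(top2)
  common <- names(f1$estimates)
  expect_equal(f1$estimates[common], f2$estimates[common], tolerance = 1e-4)
})

test_that("detached parameters subsume the other sharing roles", {
  curves <- make_growth_curves(3)[1:3]
  m <- growth_model()
  at <- list(K = 9, nu = 0.45, r = 0.18, n0 = 0.02)

  # one detached name shared by all datasets == model-shared
  top_m <- fit_topology(curves, m, roles = list(K = "model"))
  top_d <- fit_topology(curves, m, roles = list(K = "Kshared"))
  o_m <- objective_and_gradient(
    top_m, unname(initial_hidden(top_m, at)),
    gradient = FALSE
  )$value
  o_d <- objective_and_gradient(
    top_d,
    unname(initial_hidden(
      top_d, c(at[names(at) != "K"], Kshared = at$K)
    )),
    gradient = FALSE
  )$value
  expect_equal(o_m, o_d, tolerance = 1e-10)

  # one detached name per (dataset, parameter) == per-dataset
  nm <- vapply(curves, `[[`, character(1), "name")
  top_p <- fit_topology(curves, m)
  top_e <- fit_topology(curves, m,
    roles = list(r = stats::setNames(paste0("r_", nm), nm))
  )
  r_each <- stats::setNames(
    as.list(rep(at$r, length(nm))), paste0("r_", nm)
  )
  o_p <- objective_and_gradient(
    top_p, unname(initial_hidden(top_p, at)),
    gradient = FALSE
  )$value
  o_e <- objective_and_gradient(
    top_e,
    unname(initial_hidden(top_e, c(at[names(at) != "r"], r_each))),
    gradient = FALSE
  )$value
  expect_equal(o_p, o_e, tolerance = 1e-10)
})

test_that("topology validation catches dangling references", {
  curves <- make_growth_curves(1)[1:2]
  expect_error(
    fit_topology(curves, growth_model(),
      bindings = c(curve_1 = "nope", curve_2 = "growth")
    ),
    "unknown model"
  )
  expect_error(
    fit_topology(curves, growth_model(), roles = list(zz = "model")),
    "unknown parameter"
  )
  # detached name reused under incompatible bounds: warn, registry wins
  m2 <- expression_model("f", "a*x + b",
    parameters = list(a = "R(0, inf)", b = "R(0, 1)")
  )
  expect_warning(
    fit_topology(curves, m2, roles = list(a = "sh", b = "sh")),
    "differing bounds"
  )
})
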