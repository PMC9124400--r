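# Expression parsing, evaluation, and exact differentiation.

test_that("parsing records referenced symbols and rejects bad input", {
  tr <- parse_model_expr(
    "K*(1-(1-(K/n0)**nu)*exp(-r*nu*x))**(-1/nu)",
    c("x", "K", "n0", "nu", "r")
  )
  expect_setequal(tr$used, c("x", "K", "n0", "nu", "r"))

  # identity and an unused independent variable are both legal
  expect_equal(parse_model_expr("x", "x")$used, "x")
  tr2 <- parse_model_expr(
    "K*(1-(N/K)**nu)*r*N", c("t", "N", "r", "K", "nu")
  )
  expect_false("t" %in% tr2$used)

  expect_error(parse_model_expr("x +* 2", "x"), "syntax error")
  expect_error(
    parse_model_expr("x + qq", "x"),
    "undeclared symbol 'qq' at position 5"
  )
  expect_error(parse_model_expr("foo(x)", "x"), "unsupported")
  expect_error(parse_model_expr("x > 1", "x"), "unsupported")
})

test_that("parsing is deterministic", {
  src <- "a*exp(-b*x) + c"
  t1 <- parse_model_expr(src, c("x", "a", "b", "c"))
  t2 <- parse_model_expr(src, c("x", "a", "b", "c"))
  expect_identical(t1$expr, t2$expr)
})

test_that("evaluation matches the growth curve's closed-form structure", {
  tr <- parse_model_expr(
    "K*(1-(1-(K/n0)**nu)*exp(-r*nu*x))**(-1/nu)",
    c("x", "K", "n0", "nu", "r")
  )
  # N(0) = n0 for arbitrary positive parameters
  set.seed(11)
  for (i in 1:10) {
    p <- list(
      x = 0, K = runif(1, 1, 50), n0 = runif(1, 0.001, 1),
      nu = runif(1, 0.2, 2), r = runif(1, 0.05, 1)
    )
    expect_equal(eval_expr(tr, p), p$n0, tolerance = 1e-12)
  }
  # at r*nu*t >> 1 the exponential term vanishes and N -> K
  expect_equal(
    eval_expr(tr, list(x = 1e4, K = 10, n0 = 0.01, nu = 0.5, r = 0.2)),
    10,
    tolerance = 1e-9
  )
  # frozen value from an independent 60-digit evaluation of the same formula
  expect_equal(
    eval_expr(tr, list(x = 25, K = 10, n0 = 0.01, nu = 0.5, r = 0.2)),
    0.80998675363996285,
    tolerance = 1e-14
  )
})

test_that("evaluation fails fast on domain violations and missing symbols", {
  expect_error(
    eval_expr(parse_model_expr("log(x)", "x"), list(x = -1)),
    class = "sf_domain_error"
  )
  expect_error(
    eval_expr(parse_model_expr("sqrt(x)", "x"), list(x = -4)),
    class = "sf_domain_error"
  )
  expect_error(
    eval_expr(parse_model_expr("x**(-1)", "x"), list(x = 0)),
    class = "sf_domain_error"
  )
  expect_equal(eval_expr(parse_model_expr("x**0", "x"), list(x = 0)), 1)
  expect_error(
    eval_expr(parse_model_expr("a + b", c("a", "b")), list(a = 1)),
    "missing value"
  )
})

test_that("a tree with no variables is constant", {
  tr <- parse_model_expr("2*exp(1) + 3", character(0))
  expect_equal(eval_expr(tr, list()), 2 * exp(1) + 3)
})

test_that("simple derivatives are exact", {
  expect_equal(
    unname(grad_expr(parse_model_expr("x**2", "x"), list(x = 3))[1, "x"]), 6
  )
  expect_equal(
    unname(grad_expr(parse_model_expr("exp(x)", "x"), list(x = 0))[1, "x"]), 1
  )
  # subgradient convention at the kink of |x|
  expect_equal(
    unname(grad_expr(parse_model_expr("abs(x)", "x"), list(x = 0))[1, "x"]), 0
  )
  expect_equal(
    unname(grad_expr(parse_model_expr("abs(x)", "x"), list(x = -2))[1, "x"]), -1
  )
})

test_that("growth-curve partials match central finite differences", {
  tr <- parse_model_expr(
    "K*(1-(1-(K/n0)**nu)*exp(-r*nu*x))**(-1/nu)",
    c("x", "K", "n0", "nu", "r")
  )
  at <- list(x = 25, K = 10, n0 = 0.01, nu = 0.5, r = 0.2)
  g <- grad_expr(tr, at, wrt = c("K", "n0", "nu", "r"))
  for (p in c("K", "n0", "nu", "r")) {
    h <- 1e-6 * abs(at[[p]])
    up <- at
    dn <- at
    up[[p]] <- up[[p]] + h
    dn[[p]] <- dn[[p]] - h
    fd <- (eval_expr(tr, up) - eval_expr(tr, dn)) / (2 * h)
    expect_equal(unname(g[1, p]), fd, tolerance = 1e-5)
  }
})

test_that("every operator's derivative matches finite differences", {
  cases <- list(
    list(src = "a + b*a", syms = c("a", "b")),
    list(src = "a - b/a", syms = c("a", "b")),
    list(src = "a*b*a", syms = c("a", "b")),
    list(src = "a/(b + 2)", syms = c("a", "b")),
    list(src = "a**b", syms = c("a", "b")),
    list(src = "-a + (-b)", syms = c("a", "b")),
    list(src = "exp(a*b)", syms = c("a", "b")),
    list(src = "log(a + b)", syms = c("a", "b")),
    list(src = "sqrt(a*b)", syms = c("a", "b")),
    list(src = "sin(a) * cos(b)", syms = c("a", "b")),
    list(src = "tan(a/4)", syms = c("a", "b")),
    list(src = "abs(a - b)", syms = c("a", "b")),
    list(src = "exp(-a)*sqrt(b)/(1 + a**2)", syms = c("a", "b"))
  )
  set.seed(42)
  n_checked <- 0L
  while (n_checked < 100L) {
    cs <- cases[[sample.int(length(cases), 1)]]
    tr <- parse_model_expr(cs$src, cs$syms)
    # away from domain boundaries and the |.| kink
    at <- list(a = runif(1, 0.3, 3), b = runif(1, 0.3, 3))
    if (grepl("abs", cs$src) && abs(at$a - at$b) < 0.05) next
    g <- grad_expr(tr, at)
    for (s in cs$syms) {
      h <- 1e-6
      up <- at
      dn <- at
      up[[s]] <- up[[s]] + h
      dn[[s]] <- dn[[s]] - h
      fd <- (eval_expr(tr, up) - eval_expr(tr, dn)) / (2 * h)
      expect_equal(unname(g[1, s]), fd, tolerance = 1e-5)
    }
    n_checked <- n_checked + 1L
  }
})

test_that("evaluation and gradients vectorize over the abscissa", {
  tr <- parse_model_expr("a*exp(-b*x)", c("x", "a", "b"))
  x <- c(0, 1, 2, 5)
  v <- eval_expr(tr, list(x = x, a = 2, b = 0.5))
  expect_equal(v, 2 * exp(-0.5 * x))
  g <- grad_expr(tr, list(x = x, a = 2, b = 0.5), wrt = c("a", "b"))
  expect_equal(dim(g), c(4L, 2L))
  expect_equal(g[, "a"], exp(-0.5 * x))
  expect_equal(g[, "b"], -2 * x * exp(-0.5 * x))
})
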