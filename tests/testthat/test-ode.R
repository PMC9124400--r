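# Forward sensitivities, event location, and output transforms.

logistic_ode <- function() {
  ode_model("growth_ode",
    states = "N", rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"), parameters = c("r", "K", "nu", "n0")
  )
}

test_that("linear decay has closed-form states and sensitivities", {
  m <- ode_model("decay",
    states = "y", rhs = "-k*y", init = list(y = 1),
    parameters = "k"
  )
  s <- solve_ode_sensitivities(m, c(k = 0.5), times = c(0, 1, 2))
  expect_equal(s$outputs[3], exp(-1), tolerance = 1e-6)
  expect_equal(unname(s$output_gradients[3, "k"]), -2 * exp(-1),
    tolerance = 1e-6
  )
  # sensitivity at t = 0 is zero for a literal initial condition
  expect_equal(unname(s$output_gradients[1, "k"]), 0)
})

test_that("a parameter used as initial condition has unit sensitivity", {
  m <- ode_model("const",
    states = "y", rhs = "0*t", init = list(y = "c"),
    parameters = "c"
  )
  s <- solve_ode_sensitivities(m, c(c = 3), times = c(0, 5, 10))
  expect_equal(s$outputs, rep(3, 3), tolerance = 1e-8)
  expect_equal(unname(s$output_gradients[, "c"]), rep(1, 3),
    tolerance = 1e-8
  )
})

test_that("logistic sensitivities match finite differences over random draws", {
  m <- logistic_ode()
  set.seed(31)
  tt <- seq(0, 100, length.out = 9)
  for (i in 1:20) {
    K <- runif(1, 5, 15)
    pars <- c(
      r = runif(1, 0.05, 1), K = K, nu = runif(1, 0.2, 2),
      n0 = K / 10^runif(1, log10(2), 3)
    )
    s <- solve_ode_sensitivities(m, pars, tt) # rtol 1e-6, atol 1e-9
    for (p in names(pars)) {
      # step large enough that the oracle's own solver error cancels
      h <- 1e-4 * pars[[p]]
      up <- pars
      dn <- pars
      up[p] <- up[p] + h
      dn[p] <- dn[p] - h
      fd <- (solve_ode_sensitivities(m, up, tt,
        rtol = 1e-10,
        atol = 1e-12
      )$outputs -
        solve_ode_sensitivities(m, dn, tt,
          rtol = 1e-10,
          atol = 1e-12
        )$outputs) / (2 * h)
      # relative to each component, floored at 1% of the largest one
      scale <- pmax(abs(fd), 1e-2 * max(abs(fd)))
      expect_lt(max(abs(s$output_gradients[, p] - fd) / scale), 1e-4)
    }
  }
})

test_that("halving the tolerances changes outputs by less than the coarser one", {
  m <- logistic_ode()
  pars <- c(r = 0.2, K = 10, nu = 0.5, n0 = 0.01)
  tt <- seq(0, 100, length.out = 21)
  a <- solve_ode_sensitivities(m, pars, tt, rtol = 1e-6, atol = 1e-9)$outputs
  b <- solve_ode_sensitivities(m, pars, tt, rtol = 5e-7, atol = 5e-10)$outputs
  expect_lt(max(abs(a - b) / pmax(abs(a), 1)), 1e-6)
})

test_that("autonomous dynamics are time-translation invariant", {
  m <- logistic_ode()
  pars <- c(r = 0.2, K = 10, nu = 0.5, n0 = 0.01)
  t1 <- seq(0, 40, length.out = 11)
  s1 <- solve_ode_sensitivities(m, pars, t1)
  s2 <- solve_ode_sensitivities(m, pars, t1 + 17)
  expect_equal(s2$outputs, s1$outputs, tolerance = 1e-7)
})

test_that("event crossing times match the logistic closed form", {
  m <- ode_model("g",
    states = "N", rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"), parameters = c("r", "K", "nu", "n0"),
    events = list(event_spec("half", "N - K/2", "rising"))
  )
  pars <- c(r = 0.2, K = 10, nu = 1, n0 = 0.01)
  s <- solve_ode_sensitivities(m, pars, seq(0, 100, 1))
  # nu = 1: N(t) = K / (1 + (K/n0 - 1) exp(-r t)) crosses K/2 at
  # t* = log(K/n0 - 1)/r
  tstar <- log(10 / 0.01 - 1) / 0.2
  expect_equal(s$events$half$time, tstar, tolerance = 1e-6)
  expect_equal(unname(s$events$half$state["N"]), 5, tolerance = 1e-5)
})

test_that("events without a crossing are absent; boundary events fire at t0", {
  m_no <- ode_model("g",
    states = "N", rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"), parameters = c("r", "K", "nu", "n0"),
    events = list(event_spec("never", "N - 2*K", "rising"))
  )
  pars <- c(r = 0.2, K = 10, nu = 1, n0 = 0.01)
  s <- solve_ode_sensitivities(m_no, pars, seq(0, 50, 1))
  expect_length(s$events, 0)

  # condition exactly zero at the start and moving in the stated direction
  m_t0 <- ode_model("g",
    states = "N", rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"), parameters = c("r", "K", "nu", "n0"),
    events = list(event_spec("start", "N - n0", "rising"))
  )
  s0 <- solve_ode_sensitivities(m_t0, pars, seq(0, 10, 1))
  expect_equal(s0$events$start$time, 0)
})

test_that("a terminal event freezes later outputs at the event value", {
  m <- ode_model("g",
    states = "N", rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"), parameters = c("r", "K", "nu", "n0"),
    events = list(event_spec("stop", "N - K/2", "rising", terminal = TRUE))
  )
  pars <- c(r = 0.2, K = 10, nu = 1, n0 = 0.01)
  tt <- seq(0, 100, 5)
  s <- solve_ode_sensitivities(m, pars, tt)
  after <- tt > s$events$stop$time
  expect_true(any(after))
  expect_equal(unname(s$outputs[after]),
    rep(unname(s$events$stop$state["N"]), sum(after)),
    tolerance = 1e-8
  )
})

test_that("output transforms compose gradients through states and events", {
  # normalization by the carrying capacity: N/K -> 1 at large t
  m <- ode_model("g",
    states = "N", rhs = "r*N*(1 - (N/K)**nu)",
    init = list(N = "n0"), parameters = c("r", "K", "nu", "n0"),
    output = "N/K"
  )
  pars <- c(r = 0.5, K = 10, nu = 1, n0 = 0.1)
  tt <- c(0, 10, 60)
  s <- solve_ode_sensitivities(m, pars, tt)
  expect_equal(s$outputs[3], 1, tolerance = 1e-4)
  for (p in names(pars)) {
    h <- 1e-6 * pars[[p]]
    up <- pars
    dn <- pars
    up[p] <- up[p] + h
    dn[p] <- dn[p] - h
    fd <- (solve_ode_sensitivities(m, up, tt,
      rtol = 1e-10, atol = 1e-12
    )$outputs -
      solve_ode_sensitivities(m, dn, tt,
        rtol = 1e-10, atol = 1e-12
      )$outputs) / (2 * h)
    expect_equal(unname(s$output_gradients[, p]), unname(fd),
      tolerance = 1e-4
    )
  }
})

test_that("integration failure raises a typed error carrying the parameters", {
  m <- ode_model("blowup",
    states = "y", rhs = "a*y**2", init = list(y = "y0"),
    parameters = c("a", "y0")
  )
  expect_error(
    solve_ode_sensitivities(m, c(a = 1, y0 = 1), times = seq(0, 10, 0.5)),
    class = "sf_integration_error"
  )
})
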