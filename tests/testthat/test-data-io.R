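# File input, the YAML configuration, and the command-line interface.

test_that("csv and tsv inputs parse identically, with header auto-detection", {
  fc <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0.01", "1,0.02"), fc)
  dc <- read_xy_table(fc)
  expect_equal(dc$x, c(0, 1))
  expect_equal(dc$y, c(0.01, 0.02))

  ft <- tempfile(fileext = ".tsv")
  writeLines(c("x\ty", "0\t0.01", "1\t0.02"), ft)
  dt <- read_xy_table(ft)
  expect_equal(dt$x, dc$x)
  expect_equal(dt$y, dc$y)

  # headerless files work too
  fh <- tempfile(fileext = ".csv")
  writeLines(c("0,0.01", "1,0.02"), fh)
  expect_equal(read_xy_table(fh)$y, c(0.01, 0.02))
  unlink(c(fc, ft, fh))
})

test_that("non-finite rows are dropped with a count; x is sorted ascending", {
  f <- tempfile(fileext = ".csv")
  rows <- sprintf("%d,%g", 0:100, (0:100) / 10)
  rows[51] <- "50,NaN"
  writeLines(c("x,y", rev(rows)), f) # reversed order on disk
  expect_message(d <- read_xy_table(f), "dropped 1 non-finite row")
  expect_length(d$x, 100L)
  expect_false(is.unsorted(d$x))
  unlink(f)
})

test_that("degenerate files are rejected", {
  f1 <- tempfile(fileext = ".csv")
  writeLines(c("x", "1", "2"), f1)
  expect_error(read_xy_table(f1), "fewer than two columns")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "a,b"), f2)
  expect_error(read_xy_table(f2), "no usable rows")
  expect_error(read_xy_table(tempfile()), "not found")
  unlink(c(f1, f2))
})

test_that("the shipped example configuration builds the 10-parameter topology", {
  td <- tempfile()
  cfg_path <- suppressMessages(write_growth_example(td, seed = 3))
  cfg <- load_fit_config(cfg_path)
  expect_equal(n_free_parameters(cfg$topology), 10L)
  expect_equal(cfg$method, "lbfgs")
  expect_equal(cfg$seed, 3L)
  # round-trip: serialize and re-read, structurally identical
  p2 <- file.path(td, "copy.yaml")
  write_fit_config(cfg$raw, p2)
  cfg2 <- load_fit_config(p2)
  expect_equal(cfg2$raw, cfg$raw)
  expect_equal(
    free_parameters(cfg2$topology), free_parameters(cfg$topology)
  )
  unlink(td, recursive = TRUE)
})

test_that("a minimal configuration defaults to an all-per-dataset fit", {
  td <- tempfile()
  dir.create(td)
  writeLines(c("x,y", "0,1", "1,3", "2,5"), file.path(td, "d.csv"))
  writeLines(c(
    "models:",
    "  - name: line",
    "    body: a*x + b",
    "    parameters:",
    "      a: {bound: 'R(-inf, inf)'}",
    "      b: {bound: 'R(-inf, inf)'}",
    "data:",
    "  - {name: d, file: d.csv}"
  ), file.path(td, "cfg.yaml"))
  cfg <- load_fit_config(file.path(td, "cfg.yaml"))
  expect_equal(n_free_parameters(cfg$topology), 2L)
  expect_setequal(free_parameters(cfg$topology)$type, "data")
  unlink(td, recursive = TRUE)
})

test_that("configuration errors carry field paths and file names", {
  td <- tempfile()
  dir.create(td)
  writeLines(c(
    "models:",
    "  - name: line",
    "    body: a*x",
    "    parameters: {a: }",
    "data:",
    "  - {name: d, file: nope.csv}"
  ), file.path(td, "cfg.yaml"))
  expect_error(
    load_fit_config(file.path(td, "cfg.yaml")),
    "nope.csv"
  )
  writeLines(c(
    "data:",
    "  - {name: d, file: d.csv}"
  ), file.path(td, "nomodel.yaml"))
  expect_error(
    load_fit_config(file.path(td, "nomodel.yaml")),
    "models"
  )
  unlink(td, recursive = TRUE)
})

test_that("the cli runs the full simulate / fit / check-grad workflow", {
  td <- tempfile()
  expect_output(
    st <- suppressMessages(
      run_cli(c("simulate", "growth", "--seed", "1", "--out", td))
    ),
    "worked example"
  )
  expect_equal(st, 0L)
  cfg <- file.path(td, "config.yaml")
  expect_true(file.exists(cfg))

  expect_output(st <- run_cli(c("fit", cfg)), "R-squared")
  expect_equal(st, 0L)
  par_tab <- utils::read.csv(file.path(td, "results", "parameters.csv"))
  expect_equal(nrow(par_tab), 10L)
  expect_true(file.exists(file.path(td, "results", "manifest.json")))

  # an existing results directory is never silently overwritten
  expect_message(st2 <- run_cli(c("fit", cfg)), "force")
  expect_equal(st2, 1L)
  expect_output(st3 <- run_cli(c("fit", cfg, "--force")), "R-squared")
  expect_equal(st3, 0L)

  expect_output(
    st4 <- run_cli(c("check-grad", cfg, "--points", "2")),
    "relative gradient error"
  )
  expect_equal(st4, 0L)
  unlink(td, recursive = TRUE)
})

test_that("the cli reports bad guesses and unknown commands as failures", {
  td <- tempfile()
  suppressMessages(suppressWarnings(
    utils::capture.output(
      run_cli(c("simulate", "growth", "--seed", "1", "--out", td))
    )
  ))
  cfg_raw <- yaml::read_yaml(file.path(td, "config.yaml"))
  cfg_raw$guesses <- list(K = -4) # outside the positive bound
  bad <- file.path(td, "bad.yaml")
  yaml::write_yaml(cfg_raw, bad)
  expect_message(st <- run_cli(c("fit", bad)), "growth:K")
  expect_equal(st, 1L)
  expect_message(st2 <- run_cli("frobnicate"), "unknown command")
  expect_equal(st2, 1L)
  unlink(td, recursive = TRUE)
})
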