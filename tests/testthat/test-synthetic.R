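test_that("identical seeds give byte-identical panels", {
  cfg <- generator_config(n_tu = 10, years = 2000:2004, noise_cv = 0.05, seed = 99)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p1, f1); write_panel(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different panel
  p3 <- generate_panel(generator_config(n_tu = 10, years = 2000:2004,
                                        noise_cv = 0.05, seed = 100))
  expect_false(identical(p1$population, p3$population))
})

test_that("noiseless panels satisfy the flow identities each year", {
  panel <- generate_panel(generator_config(n_tu = 12, years = 2000:2003))
  for (yr in 2000:2003) {
    expect_lt(max(flow_identity_gap(panel, yr)), 1e-12)
  }
})

test_that("default share law puts about 16% on the top unit of 33", {
  panel <- generate_panel(generator_config())
  p <- observed_shares(panel, 2000)$p
  expect_lt(abs(max(p) - 0.16), 0.02)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("per-capita rates stay within their configured ranges", {
  rr <- list(alpha = c(0.02, 0.05), epsilon = c(500, 1500), w = c(30, 60))
  panel <- generate_panel(generator_config(n_tu = 20, years = 2000:2002,
                                           rate_ranges = rr, seed = 3))
  alpha <- panel$students / panel$population
  epsilon <- panel$electricity_kwh / panel$population
  w <- panel$water_m3 / panel$population
  expect_true(all(alpha > rr$alpha[1] * 0.999 & alpha < rr$alpha[2] * 1.001))
  expect_true(all(epsilon >= rr$epsilon[1] & epsilon <= rr$epsilon[2]))
  expect_true(all(w >= rr$w[1] & w <= rr$w[2]))
})

test_that("no trends and no noise give identical years", {
  panel <- generate_panel(generator_config(n_tu = 8, years = 2000:2003,
                                           growth_mean = 0, growth_sd = 0))
  y0 <- dplyr::filter(panel, year == 2000)
  for (yr in 2001:2003) {
    yk <- dplyr::filter(panel, year == yr)
    expect_equal(yk$population, y0$population)
    expect_equal(yk$students, y0$students)
  }
})

test_that("planted panels carry their own maximum-entropy truth", {
  pl <- generate_planted_panel(generator_config(n_tu = 12, years = 2000:2004), m_max = 4)
  for (yr in 2000:2004) {
    truth <- dplyr::filter(pl$truth, year == yr)
    obs <- observed_shares(pl$panel, yr)
    # emitted populations realize the planted shares exactly
    expect_equal(obs$p, truth$p_true, tolerance = 1e-12)
    # the truth satisfies its planted moment targets
    tk <- dplyr::filter(pl$targets, year == yr)
    cs <- constraint_set(t(vapply(tk$m, function(m) (1:12)^m, numeric(12))), tk$C)
    expect_lt(max(abs(constraint_residuals(truth$p_true, cs)) / pmax(1, abs(tk$C))), 1e-9)
  }
  # targets drift exactly linearly across years
  for (mo in 1:4) {
    series <- dplyr::filter(pl$targets, m == mo)
    expect_lt(max(abs(diff(diff(series$C)))), 1e-9 * max(abs(series$C)))
  }
})

test_that("a natural-restriction-only planted panel is uniform every year", {
  pl <- generate_planted_panel(generator_config(n_tu = 6, years = 2000:2002), m_max = 0)
  expect_true(all(abs(pl$truth$p_true - 1 / 6) < 1e-12))
  expect_equal(nrow(pl$targets), 0)
})

test_that("planted truth sidecar JSON holds per-year shares and targets", {
  pl <- generate_planted_panel(generator_config(n_tu = 5, years = 2000:2001), m_max = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_planted_truth(pl, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$m_max, 2)
  expect_equal(x$p_true[["2000"]],
               dplyr::filter(pl$truth, year == 2000)$p_true, tolerance = 1e-12)
  expect_equal(x$targets[["2001"]],
               dplyr::filter(pl$targets, year == 2001)$C, tolerance = 1e-12)
})
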