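test_that("macro-state aggregates match the worked two-unit example", {
  ms <- macro_state(two_tu_panel())
  expect_equal(ms$B, 100)
  expect_equal(ms$U, 4)
  expect_equal(ms$A, 0.04)
  expect_equal(ms$u_bar, 2.5)      # (9 + 1) / 4
  expect_equal(ms$E, 1.6)
  expect_equal(ms$W, 0.4)
})

test_that("student flow restriction reproduces the worked example and is satisfied by true shares", {
  cs <- flow_constraint(two_tu_panel(), "students", 2000)
  expect_equal(drop(cs$G), c(0.18, 0.02))
  expect_equal(cs$C, 0.1)
  expect_equal(constraint_residuals(c(0.5, 0.5), cs), 0, tolerance = 1e-15)
})

test_that("observed shares satisfy every flow restriction identically on self-consistent panels", {
  for (seed in 1:5) {
    panel <- random_panel(n = 10, seed = seed)
    gaps <- flow_identity_gap(panel, 2000)
    expect_lt(max(gaps), 1e-12)
  }
})

test_that("flow targets equal the direct summation oracle sum(total^2)/B", {
  panel <- random_panel(n = 8, seed = 42)
  B <- sum(panel$population)
  for (v in c("students", "electricity", "water")) {
    col <- switch(v, students = "students", electricity = "electricity_kwh",
                  water = "water_m3")
    cs <- flow_constraint(panel, v, 2000)
    expect_equal(cs$C, sum(panel[[col]]^2) / B, tolerance = 1e-12)
  }
})

test_that("self-weighted means dominate simple means (Cauchy-Schwarz)", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      panel <- random_panel(n = 12, seed = rep + 100)
      ms <- macro_state(panel)
      n <- 12
      expect_gte(ms$u_bar, ms$U / n - 1e-9)
      expect_gte(ms$ce_bar, ms$CE / n - 1e-9)
      expect_gte(ms$cw_bar, ms$CW / n - 1e-9)
    }
  })
  # equality iff all equal
  eq <- tibble::tibble(
    year = 2000, tu_id = c("a", "b", "c"), population = c(10, 10, 10),
    students = c(2, 2, 2), electricity_kwh = c(5, 5, 5), water_m3 = c(1, 1, 1)
  )
  ms <- macro_state(eq)
  expect_equal(ms$u_bar, ms$U / 3)
})

test_that("moment restrictions carry the reference distribution's raw index moments", {
  cs <- moment_constraints(c(0.5, 0.3, 0.2), m_max = 2)
  expect_equal(cs$C, c(1.7, 3.5))
  expect_equal(cs$G[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(cs$G[2, ], c(1, 4, 9), ignore_attr = TRUE)
  expect_equal(moment_constraints(rep(1 / 3, 3), 1)$C, 2)
  expect_error(moment_constraints(c(0.5, 0.5), 2), "m_max")
  expect_error(moment_constraints(c(0.7, 0.2), 1), "distribution")
})

test_that("moment targets always lie strictly inside the attainable range", {
  withr::with_seed(4, {
    for (rep in 1:10) {
      n <- sample(4:20, 1)
      p <- exp(rnorm(n)); p <- p / sum(p)
      cs <- moment_constraints(p, min(6, n - 1))
      expect_no_error(maxentpop:::check_feasibility(cs))
    }
  })
})

test_that("assemble_model concatenates flows and moments with the natural restriction implicit", {
  panel <- random_panel(n = 33, seed = 8)
  ord <- make_ordering(panel, "descending")
  p_ref <- observed_shares(panel, 2000, ord)$p
  cs <- assemble_model(panel, 2000, m_max = 10, p_ref = p_ref, ordering = ord)
  expect_equal(nrow(cs$G), 13)   # 3 flows + 10 moments
  expect_equal(ncol(cs$G), 33)
  # empty selection: natural restriction only -> uniform
  cs0 <- assemble_model(panel, 2000, flows = character(0), m_max = 0, ordering = ord)
  expect_equal(nrow(cs0$G), 0)
  s <- solve_maxent(cs0, n = 33)
  expect_equal(s$p, rep(1 / 33, 33))
  # exceeding N - 1 rows
  small <- random_panel(n = 4, seed = 8)
  ps <- observed_shares(small, 2000)$p
  expect_error(assemble_model(small, 2000, m_max = 3, p_ref = ps), "N - 1")
})

test_that("integrated constraint set is solvable and flow rows are consistent with moments", {
  panel <- random_panel(n = 33, seed = 12)
  ord <- make_ordering(panel, "descending")
  p_ref <- observed_shares(panel, 2000, ord)$p
  cs <- assemble_model(panel, 2000, m_max = 6, p_ref = p_ref, ordering = ord)
  s <- solve_maxent(cs)
  expect_true(s$converged)
  expect_lte(max(abs(s$residuals)), 1e-10)
})

test_that("panel validation rejects structural defects with row-numbered messages", {
  p <- two_tu_panel()
  expect_error(validate_panel(dplyr::select(p, -"students")), "missing column")
  bad <- p; bad$population[2] <- -5
  expect_error(validate_panel(bad), "row 2")
  expect_error(validate_panel(dplyr::bind_rows(p, p[1, ])), "duplicate")
  gap <- dplyr::bind_rows(p, dplyr::mutate(p[1, ], year = 2001))
  expect_error(validate_panel(gap), "same territorial units")
})
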