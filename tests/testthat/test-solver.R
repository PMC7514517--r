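test_that("unconstrained problem gives the uniform distribution with entropy ln N", {
  s <- solve_maxent(constraint_set(matrix(0, 0, 33), numeric(0)), n = 33)
  expect_equal(s$p, rep(1 / 33, 33), tolerance = 1e-14)
  expect_equal(s$entropy, log(33), tolerance = 1e-12)
  expect_true(s$converged)
  expect_identical(s$iterations, 0L)
})

test_that("a symmetric mean constraint keeps the distribution uniform with a zero multiplier", {
  cs <- constraint_set(matrix(1:5, 1), C = 3)
  s <- solve_maxent(cs)
  expect_equal(s$p, rep(0.2, 5), tolerance = 1e-10)
  expect_equal(s$lambda, 0, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("single mean-of-index constraint matches the 1-D bisection oracle", {
  g <- 1:4
  oracle <- bisect_single_constraint(g, 1.75)
  s <- solve_maxent(constraint_set(matrix(g, 1), 1.75))
  expect_lt(max(abs(s$p - oracle$p)), 1e-8)
  expect_equal(s$lambda, oracle$lambda, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("solutions have exponential form, bounded entropy, and residuals within tolerance", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      r <- sample(1:3, 1)
      cs <- random_feasible_set(n, r)
      s <- solve_maxent(cs)
      expect_true(s$converged)
      # exponential form in the original rows
      p_form <- exp(-s$lambda0 - drop(s$lambda %*% cs$G))
      expect_lt(max(abs(s$p - p_form)), 1e-10)
      expect_true(all(s$p > 0))
      expect_equal(sum(s$p), 1, tolerance = 1e-12)
      expect_gte(s$entropy, 0)
      expect_lte(s$entropy, log(n) + 1e-12)
      expect_lte(max(abs(s$residuals)), 1e-10)
    }
  })
})

test_that("solver agrees with brute-force and generic-optimizer oracles", {
  # brute force on the 2-simplex, one constraint
  withr::with_seed(11, {
    g <- c(0.2, 1.4, 2.9)
    p_ref <- c(0.5, 0.3, 0.2)
    C <- sum(g * p_ref)
    s <- solve_maxent(constraint_set(matrix(g, 1), C))
    bf <- brute_force_simplex3(g, C)
    expect_lt(max(abs(s$p - bf)), 1e-3)  # grid-limited accuracy
    po <- penalty_oracle(matrix(g, 1), C, z0 = log(p_ref))
    expect_lt(max(abs(s$p - po)), 1e-6)
  })
})

test_that("nested constraint sets have monotonically non-increasing entropy", {
  withr::with_seed(3, {
    n <- 8
    p <- exp(rnorm(n)); p <- p / sum(p)
    G <- matrix(runif(3 * n), 3, n)
    C <- drop(G %*% p)
    h <- vapply(0:3, function(r) {
      cs <- constraint_set(G[seq_len(r), , drop = FALSE], C[seq_len(r)])
      solve_maxent(cs, n = n)$entropy
    }, numeric(1))
    expect_true(all(diff(h) <= 1e-10))
  })
})

test_that("N-1 index moments reproduce any strictly positive distribution", {
  withr::with_seed(5, {
    for (n in 5:8) {
      p_star <- exp(rnorm(n)); p_star <- p_star / sum(p_star)
      cs <- moment_constraints(p_star, m_max = n - 1)
      s <- solve_maxent(cs)
      expect_lt(max(abs(s$p - p_star)), 1e-8)
    }
  })
})

test_that("rescaling a row and its target leaves the solution unchanged", {
  withr::with_seed(9, {
    cs <- random_feasible_set(6, 2)
    s1 <- solve_maxent(cs)
    cs2 <- constraint_set(cs$G * c(1000, 0.003), cs$C * c(1000, 0.003))
    s2 <- solve_maxent(cs2)
    expect_lt(max(abs(s1$p - s2$p)), 1e-10)
  })
})

test_that("degenerate and infeasible constraint sets are rejected with informative errors", {
  g <- 1:4
  # duplicated rows -> conditioning error
  cs_dup <- constraint_set(rbind(g, g), c(2.0, 2.0))
  expect_error(solve_maxent(cs_dup), class = "maxentpop_conditioning")
  # target outside the attainable range -> feasibility error before iterating
  expect_error(solve_maxent(constraint_set(matrix(g, 1), 4.5)),
               class = "maxentpop_infeasible")
  expect_error(solve_maxent(constraint_set(matrix(g, 1), 1.0)),
               class = "maxentpop_infeasible")
  # constant row must match its constant
  expect_error(solve_maxent(constraint_set(matrix(2, 1, 4), 3)),
               class = "maxentpop_infeasible")
  # too many rows for N units
  expect_error(constraint_set(matrix(0, 0, 3), numeric(0)) |>
                 c(moment_constraints(c(.4, .3, .3), 2),
                   constraint_set(matrix(c(1, 0, 0), 1), 0.4)) |>
                 solve_maxent(),
               "N - 1")
  # identically zero row
  expect_error(constraint_set(matrix(0, 1, 4), 0), "identically zero")
})

test_that("shannon_entropy follows the convention 0 log 0 = 0 and rejects invalid input", {
  expect_equal(shannon_entropy(rep(1 / 33, 33)), log(33))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_error(shannon_entropy(c(0.7, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("constraint_residuals reports raw violations and checks dimensions", {
  cs <- constraint_set(matrix(1:4, 1), 2.5)
  expect_equal(constraint_residuals(rep(0.25, 4), cs), 0)
  expect_equal(constraint_residuals(c(1, 0, 0, 0), cs), -1.5)
  expect_error(constraint_residuals(c(0.5, 0.5), cs), "length")
})

test_that("solutions round-trip through JSON", {
  cs <- constraint_set(matrix(1:4, 1), 1.75)
  s <- solve_maxent(cs)
  path <- withr::local_tempfile(fileext = ".json")
  write_solution(s, path)
  s2 <- read_solution(path)
  expect_equal(s2$p, s$p, tolerance = 1e-14)
  expect_equal(s2$lambda, s$lambda, tolerance = 1e-14)
  expect_equal(s2$entropy, s$entropy, tolerance = 1e-14)
  expect_true(s2$converged)
})

test_that("constraint sets round-trip through CSV", {
  cs <- c(constraint_set(matrix(rnorm(8), 2, 4), c(0.1, 0.2), c("u", "v")),
          moment_constraints(c(0.4, 0.3, 0.2, 0.1), 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_constraints(cs, path)
  cs2 <- read_constraints(path)
  expect_equal(cs2$G, cs$G, ignore_attr = TRUE)
  expect_equal(cs2$C, cs$C)
  expect_equal(cs2$labels, cs$labels)
})
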