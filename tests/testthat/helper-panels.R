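# Small panels built in code for unit tests.

# The two-unit worked example: populations 50/50, students 3/1 so that
# alpha = (0.06, 0.02), U = 4, A = 0.04, u_bar = 2.5, C = 0.1.
two_tu_panel <- function(year = 2000) {
  tibble::tibble(
    year = year, tu_id = c("a", "b"), population = c(50, 50),
    students = c(3, 1), electricity_kwh = c(100, 60), water_m3 = c(10, 30)
  )
}

# Random self-consistent panel: arbitrary positive totals per unit.
random_panel <- function(n = 6, years = 2000, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(years, function(y) {
      b <- stats::runif(n, 1e4, 1e6)
      tibble::tibble(
        year = y, tu_id = sprintf("TU%02d", seq_len(n)),
        population = b,
        students = round(stats::runif(n, 0.005, 0.08) * b),
        electricity_kwh = stats::runif(n, 100, 4000) * b,
        water_m3 = stats::runif(n, 10, 200) * b
      )
    }))
  })
}

# Relative violation of every flow row by the observed shares.
flow_identity_gap <- function(panel, year) {
  p <- observed_shares(panel, year)$p
  vapply(c("students", "electricity", "water"), function(v) {
    cs <- flow_constraint(panel, v, year)
    abs(constraint_residuals(p, cs)) / max(1, abs(cs$C))
  }, numeric(1))
}
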