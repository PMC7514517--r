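#' Build one flow-variable restriction
#'
#' Each socio-ecological flow variable — students (information),
#' electricity (energy), water (matter) — contributes one linear
#' restriction on the population shares. Writing \eqn{u_i} for the TU
#' total of the variable and \eqn{\alpha_i = u_i / b_i} for its
#' per-capita rate, the restriction is
#' \deqn{\sum_i p_i u_i \alpha_i = \bar{u} A,}
#' with \eqn{\bar{u} = \sum_i u_i^2 / U} the self-weighted departmental
#' mean and \eqn{A = U / B} the national per-capita rate (and the exact
#' analogues for electricity and water). On a self-consistent panel the
#' observed shares \eqn{p_i = b_i / B} satisfy this identity exactly,
#' since both sides equal \eqn{\sum_i u_i^2 / B}.
#'
#' @param panel a territorial panel (see [validate_panel()]).
#' @param variable one of `"students"`, `"electricity"`, `"water"`.
#' @param year the model year.
#' @param ordering optional [make_ordering()]; determines the column
#'   (index) order of the returned row.
#' @return A single-row [constraint_set()].
#' @examples
#' panel <- tibble::tibble(
#'   year = 2000, tu_id = c("a", "b"), population = c(50, 50),
#'   students = c(3, 1), electricity_kwh = c(100, 60), water_m3 = c(10, 30)
#' )
#' flow_constraint(panel, "students", 2000) # g = (0.18, 0.02), C = 0.1
#' @export
flow_constraint <- function(panel, variable = c("students", "electricity", "water"),
                            year, ordering = NULL) {
  variable <- arg_match(variable)
  panel <- validate_panel(panel)
  df <- year_slice(panel, year, ordering)
  col <- switch(variable, students = "students",
                electricity = "electricity_kwh", water = "water_m3")
  total <- df[[col]]
  national <- sum(total)
  if (national <= 0) {
    abort(sprintf("national %s total is zero in %d; cannot build a flow restriction.",
                  variable, year))
  }
  rate <- total / df$population
  B <- sum(df$population)
  g <- total * rate
  C <- (sum(total^2) / national) * (national / B)   # self-weighted mean x national rate
  constraint_set(matrix(g, nrow = 1), C, paste0(variable, "_", year))
}

#' Build non-centered index-moment restrictions
#'
#' The m-th restriction fixes the m-th raw moment of the TU index under
#' a reference distribution: \eqn{\sum_i i^m p_i = C_m} with
#' \eqn{C_m = \sum_i i^m p^{ref}_i}. The reference distribution is
#' typically the previous year's observed shares (population inertia —
#' people tend to stay where they are), expressed in the same frozen
#' ordering used for the model.
#'
#' @param p_ref numeric vector of reference shares, in index order.
#' @param m_max highest moment order; must satisfy
#'   `1 <= m_max <= length(p_ref) - 1`.
#' @param label_prefix prefix for the row labels.
#' @return A [constraint_set()] with rows \eqn{g_{m,i} = i^m},
#'   \eqn{m = 1, \dots, m_{max}}.
#' @examples
#' moment_constraints(c(0.5, 0.3, 0.2), m_max = 2)$C # 1.7, 3.5
#' @export
moment_constraints <- function(p_ref, m_max, label_prefix = "moment") {
  p_ref <- as.numeric(p_ref)
  n <- length(p_ref)
  if (n < 2) abort("`p_ref` needs at least 2 entries.")
  if (any(p_ref < 0) || abs(sum(p_ref) - 1) > 1e-8) {
    abort("`p_ref` must be a valid distribution (non-negative, summing to 1).")
  }
  if (m_max < 1 || m_max > n - 1) {
    abort(sprintf("`m_max` must be in [1, %d], got %d.", n - 1, m_max))
  }
  idx <- seq_len(n)
  G <- t(vapply(seq_len(m_max), function(m) idx^m, numeric(n)))
  C <- drop(G %*% p_ref)
  constraint_set(G, C, paste0(label_prefix, "_", seq_len(m_max)))
}

#' Assemble the integrated model's constraint set for one year
#'
#' Concatenates the selected flow-variable rows and index-moment rows
#' into a single constraint set (the natural restriction
#' \eqn{\sum p_i = 1} is handled implicitly by the solver and never
#' appears as a row). With all three flows and ten moments on 33 units
#' this is the 13-row integrated configuration.
#'
#' @param panel a territorial panel.
#' @param year the model year.
#' @param flows character subset of
#'   `c("students", "electricity", "water")`; may be empty.
#' @param m_max number of moment rows (0 for none).
#' @param p_ref reference shares for the moments, in the ordering's
#'   index order; required when `m_max > 0`.
#' @param ordering a [make_ordering()] result (required; fixes the
#'   index assignment for all rows).
#' @return A [constraint_set()].
#' @export
assemble_model <- function(panel, year, flows = c("students", "electricity", "water"),
                           m_max = 10, p_ref = NULL, ordering = NULL) {
  if (length(flows)) flows <- match.arg(flows, c("students", "electricity", "water"),
                                        several.ok = TRUE)
  panel <- validate_panel(panel)
  n <- length(unique(panel$tu_id))
  total_rows <- length(flows) + m_max
  if (total_rows > n - 1) {
    abort(sprintf("%d constraint rows on %d units exceeds the identifiable maximum N - 1 = %d.",
                  total_rows, n, n - 1))
  }
  parts <- list()
  for (v in flows) {
    parts[[length(parts) + 1L]] <- flow_constraint(panel, v, year, ordering)
  }
  if (m_max > 0) {
    if (is.null(p_ref)) abort("`p_ref` is required when moment rows are requested.")
    parts[[length(parts) + 1L]] <- moment_constraints(p_ref, m_max)
  }
  if (!length(parts)) {
    return(constraint_set(matrix(0, 0, n), numeric(0)))
  }
  do.call(c, parts)
}
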