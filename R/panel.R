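#' Validate a territorial panel
#'
#' A territorial panel is a tidy table with one row per territorial unit
#' (TU) and year, holding the observed population and the three flow
#' variables: higher-education students (information), electricity
#' consumption in kWh (energy), and water demand in m^3 (matter).
#' Required columns: `year`, `tu_id`, `population`, `students`,
#' `electricity_kwh`, `water_m3`; an optional `tu_name` is carried
#' through. Per-capita rates (`alpha`, `epsilon`, `w`) are always
#' derived from these columns, never stored, so a panel is
#' self-consistent by construction.
#'
#' @param panel a data frame.
#' @return The panel as a tibble, rows sorted by `(year, tu_id)`, with
#'   an error if any structural rule is violated.
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) abort("`panel` must be a data frame.")
  need <- c("year", "tu_id", "population", "students", "electricity_kwh", "water_m3")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    abort(sprintf("panel is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  panel <- as_tibble(panel)
  panel$tu_id <- as.character(panel$tu_id)
  num <- setdiff(need, "tu_id")
  for (col in num) {
    if (!is.numeric(panel[[col]])) {
      abort(sprintf("panel column `%s` must be numeric.", col))
    }
    bad <- which(!is.finite(panel[[col]]))
    if (length(bad)) {
      abort(sprintf("panel column `%s` has non-finite values (first at row %d).", col, bad[1]))
    }
  }
  bad <- which(panel$population <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive population at row %d (tu_id %s, year %d).",
                  bad[1], panel$tu_id[bad[1]], panel$year[bad[1]]))
  }
  for (col in c("students", "electricity_kwh", "water_m3")) {
    bad <- which(panel[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("negative `%s` at row %d.", col, bad[1]))
    }
  }
  dup <- duplicated(panel[c("year", "tu_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate (year, tu_id) = (%d, %s) at row %d.",
                  panel$year[i], panel$tu_id[i], i))
  }
  # every year must cover the same TU set
  tus_by_year <- split(panel$tu_id, panel$year)
  ref <- sort(tus_by_year[[1]])
  for (y in names(tus_by_year)) {
    if (!identical(sort(tus_by_year[[y]]), ref)) {
      abort(sprintf("year %s does not cover the same territorial units as the first year.", y))
    }
  }
  arrange(panel, .data$year, .data$tu_id)
}

# single-year slice with derived per-capita rates, arranged by an ordering
year_slice <- function(panel, year, ordering = NULL) {
  df <- filter(panel, .data$year == !!year)
  if (!nrow(df)) abort(sprintf("panel has no rows for year %d.", year))
  df <- mutate(
    df,
    alpha = .data$students / .data$population,
    epsilon = .data$electricity_kwh / .data$population,
    w = .data$water_m3 / .data$population
  )
  if (!is.null(ordering)) {
    miss <- setdiff(df$tu_id, ordering$tu_id)
    if (length(miss)) abort(sprintf("ordering lacks tu_id(s): %s.", paste(miss, collapse = ", ")))
    df <- left_join(df, ordering, by = "tu_id")
    df <- arrange(df, .data$index)
  } else {
    df <- mutate(arrange(df, .data$tu_id), index = dplyr::row_number())
  }
  df
}

#' National macro-state aggregates by year
#'
#' Aggregates a panel into the national macro-state for each year: total
#' population `B`, total students `U`, total electricity `CE` (kWh),
#' total water `CW` (m^3), the national per-capita rates `A = U/B`,
#' `E = CE/B`, `W = CW/B`, and the self-weighted departmental means
#' `u_bar = sum(u_i^2)/U`, `ce_bar = sum(ce_i^2)/CE`,
#' `cw_bar = sum(cw_i^2)/CW` — the mean of each variable under its own
#' weighting factor (\eqn{q_i = u_i / U} and analogues), which is what
#' "average per department" means when departments are weighted by their
#' share of the national total. By the Cauchy–Schwarz inequality each
#' self-weighted mean is at least the simple mean of its variable.
#'
#' @param panel a territorial panel (see [validate_panel()]).
#' @return A tibble with one row per year and columns `year`, `B`, `U`,
#'   `CE`, `CW`, `A`, `E`, `W`, `u_bar`, `ce_bar`, `cw_bar`.
#' @examples
#' panel <- tibble::tibble(
#'   year = 2000, tu_id = c("a", "b"), population = c(50, 50),
#'   students = c(3, 1), electricity_kwh = c(100, 60), water_m3 = c(10, 30)
#' )
#' macro_state(panel)
#' @export
macro_state <- function(panel) {
  panel <- validate_panel(panel)
  out <- summarise(
    group_by(panel, .data$year),
    B = sum(.data$population),
    U = sum(.data$students),
    CE = sum(.data$electricity_kwh),
    CW = sum(.data$water_m3),
    u_bar = if (.data$U > 0) sum(.data$students^2) / .data$U else 0,
    ce_bar = if (.data$CE > 0) sum(.data$electricity_kwh^2) / .data$CE else 0,
    cw_bar = if (.data$CW > 0) sum(.data$water_m3^2) / .data$CW else 0,
    .groups = "drop"
  )
  mutate(out, A = .data$U / .data$B, E = .data$CE / .data$B, W = .data$CW / .data$B) %>%
    select("year", "B", "U", "CE", "CW", "A", "E", "W", "u_bar", "ce_bar", "cw_bar")
}

#' Observed population shares for one year
#'
#' \eqn{p_i = b_i / B}, arranged by the given ordering (or by `tu_id`).
#'
#' @param panel a territorial panel.
#' @param year the year to extract.
#' @param ordering optional [make_ordering()] result.
#' @return A tibble with columns `tu_id`, `index`, `p`.
#' @export
observed_shares <- function(panel, year, ordering = NULL) {
  df <- year_slice(validate_panel(panel), year, ordering)
  tibble(tu_id = df$tu_id, index = df$index, p = df$population / sum(df$population))
}
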