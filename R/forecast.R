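#' Fit linear trends to the calibration moment targets
#'
#' Each index-moment target series \eqn{C_m(t)} over the calibration
#' years is summarized by an ordinary least-squares line
#' \eqn{C_m = slope \times year + intercept}, with the Pearson
#' correlation recorded as a goodness-of-trend diagnostic. A constant
#' series has an undefined correlation; it is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param calibration a [calibrate()] result (or a tibble with columns
#'   `year`, `m`, `C`).
#' @return A tibble of class `moment_regressions` with columns `m`,
#'   `slope`, `intercept`, `correlation`, `degenerate`.
#' @export
fit_moment_regressions <- function(calibration) {
  series <- if (inherits(calibration, "maxent_calibration")) {
    filter(calibration$targets, .data$type == "moment")
  } else {
    as_tibble(calibration)
  }
  if (!all(c("year", "m", "C") %in% names(series))) {
    abort("need moment target series with columns `year`, `m`, `C`.")
  }
  if (length(unique(series$year)) < 2) {
    abort("need at least 2 distinct years to fit moment trends (a two-point series gives the exact interpolating line; three or more are recommended).")
  }
  out <- series %>%
    group_by(.data$m) %>%
    summarise(fit = list(line_fit(.data$year, .data$C)), .groups = "drop") %>%
    tidyr::unnest_wider("fit")
  structure(arrange(out, .data$m), class = c("moment_regressions", class(out)))
}

line_fit <- function(x, y) {
  fit <- lm(y ~ x)
  degenerate <- sd(y) == 0
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    correlation = if (degenerate) 0 else cor(x, y),
    degenerate = degenerate
  )
}

#' Evaluate fitted moment trends at given years
#'
#' @param regressions a [fit_moment_regressions()] result.
#' @param years integer vector.
#' @return A tibble `year`, `m`, `C` of predicted targets.
#' @export
predict_moments <- function(regressions, years) {
  tidyr::crossing(year = as.integer(years), m = regressions$m) %>%
    left_join(select(regressions, "m", "slope", "intercept"), by = "m") %>%
    mutate(C = .data$slope * .data$year + .data$intercept) %>%
    select("year", "m", "C")
}

# Per-TU OLS extrapolation of a panel column over the calibration years.
# Non-positive extrapolations are clamped to the last observed value.
extrapolate_totals <- function(panel, cal_years, fore_years) {
  cols <- c("population", "students", "electricity_kwh", "water_m3")
  base <- filter(panel, .data$year %in% cal_years)
  last_year <- max(cal_years)
  warnings <- list()
  per_tu <- split(base, base$tu_id)
  rows <- lapply(per_tu, function(df) {
    df <- arrange(df, .data$year)
    fits <- lapply(cols, function(col) lm(df[[col]] ~ df$year))
    names(fits) <- cols
    last <- filter(df, .data$year == last_year)
    out <- lapply(fore_years, function(yr) {
      vals <- vapply(cols, function(col) {
        cf <- coef(fits[[col]])
        unname(cf[1] + cf[2] * yr)
      }, numeric(1))
      for (col in cols) {
        if (vals[[col]] <= 0) {
          warnings[[length(warnings) + 1L]] <<- sprintf(
            "%s of %s extrapolated to %.3g in %d; clamped to the last observed value.",
            col, df$tu_id[1], vals[[col]], yr)
          vals[[col]] <- last[[col]]
        }
      }
      tibble(year = yr, tu_id = df$tu_id[1], tu_name = df$tu_name[1] %||% df$tu_id[1],
             population = vals[["population"]], students = vals[["students"]],
             electricity_kwh = vals[["electricity_kwh"]], water_m3 = vals[["water_m3"]])
    })
    bind_rows(out)
  })
  list(panel = bind_rows(rows), warnings = unlist(warnings) %||% character(0))
}

#' Forecast the population distribution beyond the calibration window
#'
#' Replays the verification procedure: per-unit flow totals are
#' extrapolated to each forecast year by per-unit least-squares lines
#' over the calibration years; per-capita rates are held constant at
#' their last calibration-year values; index-moment targets come from
#' the fitted moment trend lines; the national macro-state is
#' recomputed from the extrapolated totals. Each forecast year is then
#' solved like a calibration year. When the panel also contains
#' observed data for a forecast year, the estimate is scored against
#' it; otherwise the error fields are left missing.
#'
#' @param panel the territorial panel used for calibration (observed
#'   forecast-year rows, if present, are used only for scoring).
#' @param calibration a [calibrate()] result on the same panel.
#' @param years integer vector of forecast years (after the calibration
#'   window).
#' @return An object of class `maxent_forecast`, shaped like a
#'   [calibrate()] result, with additional elements `regressions` (the
#'   fitted [fit_moment_regressions()]) and `warnings` (clamped
#'   extrapolations).
#' @export
forecast <- function(panel, calibration, years) {
  stopifnot(inherits(calibration, "maxent_calibration"))
  panel <- validate_panel(panel)
  years <- as.integer(years)
  if (min(years) <= max(calibration$years)) {
    abort("forecast years must follow the calibration window.")
  }
  config <- calibration$config
  ordering <- calibration$ordering
  cal_years <- calibration$years

  regressions <- if (config$m_max > 0) fit_moment_regressions(calibration)
  ex <- extrapolate_totals(panel, cal_years, years)
  fpanel <- ex$panel

  # rates frozen at the last calibration year
  last <- year_slice(panel, max(cal_years), ordering)
  rates <- select(last, "tu_id", "alpha", "epsilon", "w")

  have_truth <- intersect(years, unique(panel$year))
  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    fy <- left_join(year_slice(fpanel, yr, ordering) %>%
                      select(-"alpha", -"epsilon", -"w"),
                    rates, by = "tu_id") %>% arrange(.data$index)
    fit <- tryCatch(
      {
        cs <- forecast_constraints(fy, config, regressions, yr)
        sol <- solve_maxent(cs, n = nrow(fy), tol = config$tol,
                            max_iter = config$max_iter)
        list(sol = sol, cs = cs, error = NA_character_)
      },
      error = function(e) list(sol = NULL, cs = NULL, error = conditionMessage(e))
    )
    p_true <- if (yr %in% have_truth) observed_shares(panel, yr, ordering)$p
    if (is.null(fit$sol)) {
      res[[k]] <- tibble(
        year = yr, rmse = NA_real_, mean_rel_err_pct = NA_real_,
        entropy = NA_real_, iterations = NA_integer_, converged = FALSE,
        message = fit$error, p_est = list(NULL), p_true = list(p_true),
        per_tu_rel_err_pct = list(NULL), solution = list(NULL)
      )
      next
    }
    err <- if (!is.null(p_true)) share_errors(fit$sol$p, p_true)
    res[[k]] <- tibble(
      year = yr,
      rmse = err$rmse %||% NA_real_,
      mean_rel_err_pct = err$mean_rel_err_pct %||% NA_real_,
      entropy = fit$sol$entropy, iterations = fit$sol$iterations,
      converged = fit$sol$converged, message = NA_character_,
      p_est = list(fit$sol$p), p_true = list(p_true),
      per_tu_rel_err_pct = list(err$per_tu_rel_err_pct %||% NULL),
      solution = list(fit$sol)
    )
  }
  structure(
    list(results = bind_rows(res), regressions = regressions,
         ordering = ordering, config = config, years = years,
         warnings = ex$warnings),
    class = "maxent_forecast"
  )
}

# Constraint set for one forecast year from extrapolated totals, frozen
# rates and regression-predicted moment targets.
forecast_constraints <- function(fy, config, regressions, yr) {
  n <- nrow(fy)
  parts <- list()
  var_cols <- list(
    students = c(total = "students", rate = "alpha"),
    electricity = c(total = "electricity_kwh", rate = "epsilon"),
    water = c(total = "water_m3", rate = "w")
  )
  B <- sum(fy$population)
  for (v in config$flows) {
    total <- fy[[var_cols[[v]][["total"]]]]
    rate <- fy[[var_cols[[v]][["rate"]]]]
    national <- sum(total)
    if (national <= 0) abort(sprintf("extrapolated national %s total is zero in %d.", v, yr))
    g <- total * rate
    C <- (sum(total^2) / national) * (national / B)
    parts[[length(parts) + 1L]] <- constraint_set(matrix(g, 1), C, paste0(v, "_", yr))
  }
  if (config$m_max > 0) {
    Cm <- predict_moments(regressions, yr)$C
    idx <- seq_len(n)
    G <- t(vapply(seq_len(config$m_max), function(m) idx^m, numeric(n)))
    parts[[length(parts) + 1L]] <- constraint_set(G, Cm, paste0("moment_", seq_len(config$m_max)))
  }
  if (!length(parts)) return(constraint_set(matrix(0, 0, n), numeric(0)))
  do.call(c, parts)
}

#' @export
print.maxent_forecast <- function(x, ...) {
  cat(sprintf(
    "<maxent_forecast: %d year(s) %d-%d>\n",
    length(x$years), min(x$years), max(x$years)
  ))
  ok <- x$results$converged & !is.na(x$results$mean_rel_err_pct)
  if (any(ok)) {
    cat(sprintf("  mean relative error %.3f%% over %d scored year(s)\n",
                mean(x$results$mean_rel_err_pct[ok]), sum(ok)))
  }
  if (length(x$warnings)) cat(sprintf("  %d extrapolation warning(s)\n", length(x$warnings)))
  invisible(x)
}

#' @rdname forecast
#' @param x a `maxent_forecast`.
#' @param ... unused.
#' @export
tidy.maxent_forecast <- function(x, ...) tidy.maxent_calibration(x, ...)

#' @rdname forecast
#' @export
glance.maxent_forecast <- function(x, ...) {
  ok <- x$results$converged & !is.na(x$results$mean_rel_err_pct)
  tibble(
    n_years = nrow(x$results),
    n_converged = sum(x$results$converged),
    n_scored = sum(ok),
    mean_rmse = if (any(ok)) mean(x$results$rmse[ok]) else NA_real_,
    mean_rel_err_pct = if (any(ok)) mean(x$results$mean_rel_err_pct[ok]) else NA_real_
  )
}

#' Reconstruct flow-variable totals from estimated shares
#'
#' Given estimated shares and a year's observed per-capita rates, the
#' implied per-unit totals are \eqn{\hat{u}_i = p_i B \alpha_i} (and
#' analogues for electricity and water) — the control plots of the
#' integrated model.
#'
#' @param p_est numeric vector of estimated shares, in the ordering's
#'   index order.
#' @param panel a territorial panel.
#' @param year the year whose rates and national population to use.
#' @param ordering optional [make_ordering()] result.
#' @return A tibble `tu_id`, `index`, `students_hat`,
#'   `electricity_kwh_hat`, `water_m3_hat`.
#' @export
reconstruct_flows <- function(p_est, panel, year, ordering = NULL) {
  df <- year_slice(validate_panel(panel), year, ordering)
  if (length(p_est) != nrow(df)) {
    abort(sprintf("`p_est` has length %d but the panel has %d units.",
                  length(p_est), nrow(df)))
  }
  B <- sum(df$population)
  tibble(
    tu_id = df$tu_id, index = df$index,
    students_hat = p_est * B * df$alpha,
    electricity_kwh_hat = p_est * B * df$epsilon,
    water_m3_hat = p_est * B * df$w
  )
}
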