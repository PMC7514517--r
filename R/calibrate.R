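#' Model configuration for calibration and forecasting
#'
#' Collects the modelling choices that define one experiment: which
#' flow-variable restrictions enter the constraint set, how many
#' index-moment restrictions, the territorial reordering scheme, where
#' the moment targets come from, and solver settings.
#'
#' @param flows character subset of
#'   `c("students", "electricity", "water")` (all three by default);
#'   use `character(0)` for a natural-restriction-only or moments-only
#'   model.
#' @param m_max number of index-moment restrictions (default 10, the
#'   configuration found optimal in combination with the three flows).
#' @param ordering reordering scheme passed to [make_ordering()]
#'   (default `"descending"`).
#' @param moment_ref `"previous"` (default): moment targets are the raw
#'   index moments of the previous year's observed shares — population
#'   inertia; `"current"`: targets from the modelled year's own
#'   observed shares.
#' @param tol,max_iter solver settings, see [solve_maxent()].
#' @return A list of class `model_config`.
#' @export
model_config <- function(flows = c("students", "electricity", "water"),
                         m_max = 10,
                         ordering = c("descending", "bell", "original"),
                         moment_ref = c("previous", "current"),
                         tol = 1e-10, max_iter = 200L) {
  if (length(flows)) {
    flows <- match.arg(flows, c("students", "electricity", "water"), several.ok = TRUE)
  } else {
    flows <- character(0)
  }
  structure(
    list(
      flows = flows, m_max = as.integer(m_max),
      ordering = arg_match(ordering), moment_ref = arg_match(moment_ref),
      tol = tol, max_iter = as.integer(max_iter)
    ),
    class = "model_config"
  )
}

share_errors <- function(p_est, p_true) {
  rel <- 100 * abs(p_est - p_true) / p_true
  list(
    rmse = sqrt(mean((p_est - p_true)^2)),
    mean_rel_err_pct = mean(rel),
    per_tu_rel_err_pct = rel
  )
}

#' Calibrate the maximum-entropy model over a window of years
#'
#' For each year in `years`, builds the configured constraint set from
#' that year's macro-state (flow restrictions) and from the reference
#' distribution's index moments, solves the maximum-entropy problem,
#' and scores the estimated shares against the observed ones. The
#' territorial ordering is frozen at the first calibration year and
#' reused throughout, so the moment target series are comparable across
#' years (a prerequisite for the trend regressions used in
#' forecasting). An infeasible or non-convergent year is recorded with
#' its error message and does not abort the window.
#'
#' @param panel a territorial panel (see [validate_panel()]); must
#'   cover every year of the window, plus the year before it when
#'   `moment_ref = "previous"`.
#' @param years integer vector of calibration years.
#' @param config a [model_config()].
#' @param ordering optional pre-built [make_ordering()] result,
#'   overriding `config$ordering`.
#' @return An object of class `maxent_calibration`: list with
#'   `results` (a tibble with one row per year: errors, diagnostics and
#'   list-columns `p_est`, `p_true`, `per_tu_rel_err_pct`, `solution`),
#'   `targets` (tibble of every constraint target by year, the moment
#'   series feeding [fit_moment_regressions()]), `ordering`, `config`
#'   and `years`.
#' @examples
#' panel <- generate_panel(generator_config(n_tu = 8, years = 2000:2006))
#' cal <- calibrate(panel, 2001:2006, model_config(m_max = 4))
#' glance(cal)
#' @export
calibrate <- function(panel, years, config = model_config(), ordering = NULL) {
  panel <- validate_panel(panel)
  years <- as.integer(years)
  if (!length(years)) abort("`years` is empty.")
  have <- unique(panel$year)
  need <- years
  if (config$m_max > 0 && config$moment_ref == "previous") need <- c(min(years) - 1L, need)
  missing <- setdiff(need, have)
  if (length(missing)) {
    abort(sprintf("panel lacks required year(s): %s.", paste(missing, collapse = ", ")))
  }
  if (is.null(ordering)) {
    ordering <- make_ordering(panel, config$ordering, reference_year = years[1])
  }

  res <- vector("list", length(years))
  tgt <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    obs <- observed_shares(panel, yr, ordering)
    p_ref <- if (config$m_max > 0) {
      ref_year <- if (config$moment_ref == "previous") yr - 1L else yr
      observed_shares(panel, ref_year, ordering)$p
    }
    fit <- tryCatch(
      {
        cs <- assemble_model(panel, yr, flows = config$flows,
                             m_max = config$m_max, p_ref = p_ref,
                             ordering = ordering)
        sol <- solve_maxent(cs, n = nrow(obs), tol = config$tol,
                            max_iter = config$max_iter)
        list(cs = cs, sol = sol, error = NA_character_)
      },
      error = function(e) list(cs = NULL, sol = NULL, error = conditionMessage(e))
    )
    if (is.null(fit$sol)) {
      res[[k]] <- tibble(
        year = yr, rmse = NA_real_, mean_rel_err_pct = NA_real_,
        entropy = NA_real_, iterations = NA_integer_, converged = FALSE,
        message = fit$error,
        p_est = list(NULL), p_true = list(obs$p),
        per_tu_rel_err_pct = list(NULL), solution = list(NULL)
      )
      next
    }
    err <- share_errors(fit$sol$p, obs$p)
    res[[k]] <- tibble(
      year = yr, rmse = err$rmse, mean_rel_err_pct = err$mean_rel_err_pct,
      entropy = fit$sol$entropy, iterations = fit$sol$iterations,
      converged = fit$sol$converged, message = NA_character_,
      p_est = list(fit$sol$p), p_true = list(obs$p),
      per_tu_rel_err_pct = list(err$per_tu_rel_err_pct),
      solution = list(fit$sol)
    )
    if (!is.null(fit$cs) && nrow(fit$cs$G)) {
      tgt[[k]] <- tibble(year = yr, label = fit$cs$labels, C = fit$cs$C)
    }
  }
  targets <- bind_rows(tgt)
  if (nrow(targets)) {
    targets <- mutate(
      targets,
      type = ifelse(grepl("^moment_", .data$label), "moment", "flow"),
      m = ifelse(.data$type == "moment",
                 suppressWarnings(as.integer(sub("^moment_", "", .data$label))),
                 NA_integer_)
    )
  }
  structure(
    list(results = bind_rows(res), targets = targets,
         ordering = ordering, config = config, years = years),
    class = "maxent_calibration"
  )
}

#' @export
print.maxent_calibration <- function(x, ...) {
  cat(sprintf(
    "<maxent_calibration: %d year(s) %d-%d, flows = {%s}, m_max = %d, %s ordering>\n",
    length(x$years), min(x$years), max(x$years),
    paste(x$config$flows, collapse = ", "), x$config$m_max,
    attr(x$ordering, "scheme")
  ))
  ok <- x$results$converged
  cat(sprintf(
    "  mean relative error %.3f%%, mean RMSE %.3g over %d converged year(s)\n",
    mean(x$results$mean_rel_err_pct[ok]), mean(x$results$rmse[ok]), sum(ok)
  ))
  invisible(x)
}

#' @rdname calibrate
#' @param x a `maxent_calibration`.
#' @param ... unused.
#' @export
tidy.maxent_calibration <- function(x, ...) {
  select(x$results, "year", "rmse", "mean_rel_err_pct", "entropy",
         "iterations", "converged")
}

#' @rdname calibrate
#' @export
glance.maxent_calibration <- function(x, ...) {
  ok <- x$results$converged
  tibble(
    n_years = nrow(x$results),
    n_converged = sum(ok),
    mean_rmse = mean(x$results$rmse[ok]),
    mean_rel_err_pct = mean(x$results$mean_rel_err_pct[ok]),
    max_rel_err_pct = if (any(ok)) max(x$results$mean_rel_err_pct[ok]) else NA_real_,
    m_max = x$config$m_max,
    n_flows = length(x$config$flows),
    ordering = attr(x$ordering, "scheme")
  )
}

#' Unnest per-unit estimated and observed shares
#'
#' @param x a `maxent_calibration` or `maxent_forecast`.
#' @return A tibble with one row per year and territorial unit:
#'   `year`, `tu_id`, `index`, `p_est`, `p_true` (when available) and
#'   `rel_err_pct`.
#' @export
share_table <- function(x) {
  stopifnot(inherits(x, c("maxent_calibration", "maxent_forecast")))
  ord <- x$ordering
  rows <- lapply(seq_len(nrow(x$results)), function(k) {
    r <- x$results[k, ]
    if (is.null(r$p_est[[1]])) return(NULL)
    out <- tibble(
      year = r$year, tu_id = ord$tu_id, index = ord$index,
      p_est = r$p_est[[1]]
    )
    if (!is.null(r$p_true[[1]])) {
      out$p_true <- r$p_true[[1]]
      out$rel_err_pct <- 100 * abs(out$p_est - out$p_true) / out$p_true
    }
    out
  })
  bind_rows(rows)
}
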