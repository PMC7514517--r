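#' Summarise estimation errors of a calibration or forecast
#'
#' Produces the standard error report: per-year RMSE and mean relative
#' error, the window averages, and a per-unit error profile averaged
#' over years. The profile makes the characteristic failure mode
#' visible — thinly populated units at the tail of the ordering carry
#' much larger relative errors than the big ones.
#'
#' @param ... one or more [calibrate()] / [forecast()] results (a
#'   label is taken from the class of each).
#' @return A list of class `maxent_error_report` with tibbles
#'   `by_year`, `window` and `by_tu`.
#' @export
error_report <- function(...) {
  runs <- list(...)
  if (!length(runs)) {
    return(structure(list(by_year = tibble(), window = tibble(), by_tu = tibble()),
                     class = "maxent_error_report"))
  }
  labels <- vapply(runs, function(r) {
    if (inherits(r, "maxent_forecast")) "forecast" else "calibration"
  }, character(1))
  by_year <- bind_rows(lapply(seq_along(runs), function(i) {
    mutate(tidy(runs[[i]]), phase = labels[i], .before = 1)
  }))
  window <- by_year %>%
    filter(!is.na(.data$mean_rel_err_pct)) %>%
    group_by(.data$phase) %>%
    summarise(
      n_years = n(),
      mean_rmse = mean(.data$rmse),
      max_rel_err_pct = max(.data$mean_rel_err_pct),
      mean_rel_err_pct = mean(.data$mean_rel_err_pct),
      .groups = "drop"
    ) %>%
    select("phase", "n_years", "mean_rmse", "mean_rel_err_pct", "max_rel_err_pct")
  by_tu <- bind_rows(lapply(seq_along(runs), function(i) {
    st <- share_table(runs[[i]])
    if (!nrow(st) || is.null(st$rel_err_pct)) return(NULL)
    st %>%
      filter(!is.na(.data$rel_err_pct)) %>%
      group_by(.data$tu_id, .data$index) %>%
      summarise(
        mean_share = mean(.data$p_true),
        mean_rel_err_pct = mean(.data$rel_err_pct),
        .groups = "drop"
      ) %>%
      mutate(phase = labels[i], .before = 1) %>%
      arrange(.data$index)
  }))
  structure(list(by_year = by_year, window = window, by_tu = by_tu),
            class = "maxent_error_report")
}

#' @export
print.maxent_error_report <- function(x, ...) {
  cat("<maxent_error_report>\n")
  if (nrow(x$window)) {
    cat("Window averages:\n")
    print(x$window, ...)
  }
  if (nrow(x$by_tu)) {
    worst <- head(arrange(x$by_tu, dplyr::desc(.data$mean_rel_err_pct)), 3)
    cat(sprintf(
      "Worst units by mean relative error: %s\n",
      paste(sprintf("%s (%.1f%%)", worst$tu_id, worst$mean_rel_err_pct), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Write an error report as CSV files
#'
#' @param report a [error_report()] result.
#' @param dir output directory (created if needed).
#' @export
write_error_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$by_year, file.path(dir, "errors_by_year.csv"))
  readr::write_csv(report$window, file.path(dir, "errors_window.csv"))
  readr::write_csv(report$by_tu, file.path(dir, "errors_by_tu.csv"))
  invisible(dir)
}

#' Plot estimation error against the year
#'
#' @param object a `maxent_calibration` or `maxent_forecast`.
#' @param metric `"mean_rel_err_pct"` (default) or `"rmse"`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.maxent_calibration <- function(object, metric = c("mean_rel_err_pct", "rmse"), ...) {
  metric <- arg_match(metric)
  df <- tidy(object)
  lab <- if (metric == "rmse") "RMSE of shares" else "mean relative error (%)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data[[metric]])) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::labs(x = "year", y = lab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.maxent_calibration
#' @export
autoplot.maxent_forecast <- autoplot.maxent_calibration

#' Plot estimated against observed shares
#'
#' Observed shares as bars and modelled shares as points and lines, by
#' territorial index, one facet per year.
#'
#' @param x a `maxent_calibration` or `maxent_forecast`.
#' @param years optional subset of years to show.
#' @return A ggplot.
#' @export
plot_shares <- function(x, years = NULL) {
  st <- share_table(x)
  if (!is.null(years)) st <- filter(st, .data$year %in% years)
  if (!nrow(st)) abort("nothing to plot.")
  gg <- ggplot2::ggplot(st, ggplot2::aes(x = .data$index))
  if (!is.null(st$p_true)) {
    gg <- gg + ggplot2::geom_col(ggplot2::aes(y = .data$p_true),
                                 fill = "steelblue", alpha = 0.6)
  }
  gg +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_est), color = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_est), color = "firebrick", size = 0.8) +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = "territorial index", y = "population share") +
    ggplot2::theme_minimal()
}

#' Plot the per-unit error profile
#'
#' @param x a `maxent_calibration` or `maxent_forecast`.
#' @return A ggplot of mean relative error by territorial index.
#' @export
plot_error_profile <- function(x) {
  rep <- error_report(x)
  if (!nrow(rep$by_tu)) abort("no scored years to profile.")
  ggplot2::ggplot(rep$by_tu, ggplot2::aes(x = .data$index, y = .data$mean_rel_err_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "territorial index", y = "mean relative error (%)") +
    ggplot2::theme_minimal()
}
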