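#' Read or write a territorial panel CSV
#'
#' The panel dialect has one row per unit and year with columns `year`,
#' `tu_id`, `tu_name` (optional), `population`, `students`,
#' `electricity_kwh`, `water_m3`. Reading validates the panel
#' structurally (see [validate_panel()]) and rejects malformed numerics
#' rather than coercing them.
#'
#' @param path file path.
#' @return `read_panel()` returns a validated panel tibble.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(tu_id = readr::col_character(),
                                                .default = readr::col_guess()))
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(sprintf("panel CSV has %d parsing problem(s); first at row %d: expected %s.",
                  nrow(prob), prob$row[1], prob$expected[1]))
  }
  validate_panel(df)
}

#' @rdname read_panel
#' @param panel a territorial panel.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(validate_panel(panel), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' One YAML file drives a full experiment: `paths` (panel, output
#' directory), `model` (flows, m_max, ordering, moment_ref), `solver`
#' (tol, max_iter), `windows` (calibration and forecast year ranges as
#' `[first, last]`), and an optional `generator` section mirroring
#' [generator_config()].
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `paths`, `model`
#'   (a [model_config()]), `windows` and `generator` (a
#'   [generator_config()] or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  model_raw <- raw$model %||% list()
  solver_raw <- raw$solver %||% list()
  model <- model_config(
    flows = model_raw$flows %||% c("students", "electricity", "water"),
    m_max = model_raw$m_max %||% 10,
    ordering = model_raw$ordering %||% "descending",
    moment_ref = model_raw$moment_ref %||% "previous",
    tol = solver_raw$tol %||% 1e-10,
    max_iter = solver_raw$max_iter %||% 200L
  )
  windows <- list()
  expand <- function(w) if (is.null(w)) NULL else seq(as.integer(w[1]), as.integer(w[2]))
  windows$calibration <- expand(raw$windows$calibration)
  windows$forecast <- expand(raw$windows$forecast)
  if (!is.null(windows$calibration) && !is.null(windows$forecast) &&
      min(windows$forecast) <= max(windows$calibration)) {
    abort("forecast window must start after the calibration window ends.")
  }
  generator <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    args <- list(
      n_tu = g$n_tu %||% 33,
      years = if (!is.null(g$years)) seq(as.integer(g$years[1]), as.integer(g$years[2])) else 2000:2015,
      share_law = g$share_law %||% "zipf",
      zipf_exponent = g$zipf_exponent %||% 0.744,
      base_population = g$base_population %||% 4e7,
      growth_mean = g$growth_mean %||% 0.012,
      growth_sd = g$growth_sd %||% 0.008,
      noise_cv = g$noise_cv %||% 0,
      seed = g$seed %||% 1L
    )
    if (!is.null(g$rate_ranges)) {
      args$rate_ranges <- list(
        alpha = as.numeric(g$rate_ranges$alpha),
        epsilon = as.numeric(g$rate_ranges$epsilon),
        w = as.numeric(g$rate_ranges$w)
      )
    }
    generator <- do.call(generator_config, args)
  }
  structure(
    list(paths = raw$paths %||% list(), model = model,
         windows = windows, generator = generator,
         planted = raw$planted %||% NULL),
    class = "run_config"
  )
}
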