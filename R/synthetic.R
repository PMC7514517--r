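#' Configuration for the synthetic panel generator
#'
#' Describes a synthetic country of `n_tu` territorial units observed
#' over `years`. Defaults emulate the study setting the package targets:
#' 33 units whose population shares follow a heavy-tailed rank law with
#' the dominant unit holding about 16% of the national population (and
#' the smallest about 1%), per-capita rates for students, electricity
#' and water drawn once per unit from realistic ranges, per-unit
#' population totals following exactly linear yearly trends, and
#' optional multiplicative log-normal noise on all totals.
#'
#' @param n_tu number of territorial units (default 33).
#' @param years integer vector of consecutive years (default 2000:2015,
#'   an 11-year calibration window plus a 5-year verification window).
#' @param share_law `"zipf"` (normalized power law over ranks) or
#'   `"dirichlet"`.
#' @param zipf_exponent rank-law exponent; the default 0.744 puts a
#'   share of 0.16 on the top unit when `n_tu = 33`.
#' @param dirichlet_concentration concentration for the Dirichlet law.
#' @param base_population national population in the first year
#'   (default 4e7 inhabitants).
#' @param growth_mean,growth_sd mean and spread of the per-unit linear
#'   population growth rate, as a fraction of the first-year population
#'   per year (defaults 0.012 and 0.008: units grow about 1.2%/year,
#'   some faster, a few shrinking).
#' @param rate_ranges list with elements `alpha` (students/inhabitant),
#'   `epsilon` (kWh/inhabitant) and `w` (m^3/inhabitant), each a
#'   `c(min, max)` range for the uniform draw of per-unit rates.
#' @param noise_cv coefficient of variation of multiplicative
#'   log-normal noise applied to every total (default 0 = noiseless).
#' @param seed integer RNG seed; identical seeds give identical panels.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_tu = 33, years = 2000:2015,
                             share_law = c("zipf", "dirichlet"),
                             zipf_exponent = 0.744,
                             dirichlet_concentration = 1,
                             base_population = 4e7,
                             growth_mean = 0.012, growth_sd = 0.008,
                             rate_ranges = list(alpha = c(0.01, 0.06),
                                                epsilon = c(300, 3000),
                                                w = c(20, 120)),
                             noise_cv = 0, seed = 1L) {
  share_law <- arg_match(share_law)
  if (n_tu < 2) abort("`n_tu` must be at least 2.")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  for (nm in c("alpha", "epsilon", "w")) {
    r <- rate_ranges[[nm]]
    if (is.null(r) || length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      abort(sprintf("`rate_ranges$%s` must be a positive c(min, max) range.", nm))
    }
  }
  structure(
    list(
      n_tu = as.integer(n_tu), years = as.integer(years),
      share_law = share_law, zipf_exponent = zipf_exponent,
      dirichlet_concentration = dirichlet_concentration,
      base_population = base_population,
      growth_mean = growth_mean, growth_sd = growth_sd,
      rate_ranges = rate_ranges, noise_cv = noise_cv,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

base_shares <- function(config) {
  n <- config$n_tu
  if (config$share_law == "zipf") {
    p <- seq_len(n)^(-config$zipf_exponent)
  } else {
    p <- sort(stats::rgamma(n, shape = config$dirichlet_concentration), decreasing = TRUE)
  }
  p / sum(p)
}

#' Generate a synthetic territorial panel
#'
#' Draws first-year unit populations from the configured share law,
#' gives each unit a linear population trend and fixed per-capita rates
#' for the three flow variables, and builds the flow totals as
#' `rate x population` (students rounded to whole persons). With
#' `noise_cv = 0` every total is an exactly linear function of the year.
#' Multiplicative log-normal noise, when requested, is applied to each
#' total independently; shares stay on the simplex because they are
#' always recomputed as `population / sum(population)`.
#'
#' @param config a [generator_config()].
#' @return A territorial panel tibble (see [validate_panel()]) with
#'   columns `year`, `tu_id`, `tu_name`, `population`, `students`,
#'   `electricity_kwh`, `water_m3`.
#' @examples
#' panel <- generate_panel(generator_config(n_tu = 5, years = 2000:2002))
#' panel
#' @export
generate_panel <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) abort("`config` must be a `generator_config`.")
  withr::with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(config) {
  n <- config$n_tu
  years <- config$years
  p0 <- base_shares(config)
  b0 <- p0 * config$base_population
  slopes <- b0 * stats::rnorm(n, config$growth_mean, config$growth_sd)
  rr <- config$rate_ranges
  alpha <- stats::runif(n, rr$alpha[1], rr$alpha[2])
  epsilon <- stats::runif(n, rr$epsilon[1], rr$epsilon[2])
  w <- stats::runif(n, rr$w[1], rr$w[2])
  tu_id <- sprintf("TU%02d", seq_len(n))

  rows <- lapply(seq_along(years), function(k) {
    t <- years[k] - years[1]
    b <- pmax(b0 + slopes * t, b0 * 0.05)
    u <- alpha * b
    ce <- epsilon * b
    cw <- w * b
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      noise <- function(x) x * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      b <- noise(b); u <- noise(u); ce <- noise(ce); cw <- noise(cw)
    }
    tibble(
      year = years[k], tu_id = tu_id, tu_name = paste("Unit", tu_id),
      population = b, students = round(u), electricity_kwh = ce, water_m3 = cw
    )
  })
  validate_panel(bind_rows(rows))
}

#' Generate a panel whose true shares are a known maximum-entropy
#' solution
#'
#' Builds a "planted-truth" panel: for every year the true population
#' shares are, by construction, exactly the maximum-entropy solution of
#' `m_max` index-moment restrictions whose targets follow exactly
#' linear yearly trends. The targets interpolate between the moment
#' vectors of two feasible anchor distributions (the configured rank
#' law at two exponents), so every intermediate target vector is
#' feasible. Flow totals are rebuilt from the planted shares with fixed
#' per-unit rates, so the three flow restrictions are satisfied by the
#' truth identically; adding them to the moment rows therefore leaves
#' the maximum-entropy solution — the truth itself — unchanged, which is
#' what makes end-to-end recovery exact. Recovery requires calibrating
#' with `moment_ref = "current"` (targets recomputed from the observed
#' year) and the identity ordering the panel is emitted in (its units
#' are labelled in descending first-year size, so the `descending`
#' scheme reproduces it).
#'
#' @param config a [generator_config()].
#' @param m_max number of planted moment restrictions (default 5);
#'   `m_max = 0` plants the natural restriction only, so every year's
#'   truth is the uniform distribution.
#' @param drift relative increase of the rank-law exponent from the
#'   first to the last year (default 0.12), which makes every moment
#'   target drift linearly.
#' @return A list of class `planted_panel`: `panel` (tibble), `truth`
#'   (tibble `year`, `tu_id`, `index`, `p_true`), `targets` (tibble
#'   `year`, `m`, `C`), `m_max`, and `config`.
#' @export
generate_planted_panel <- function(config = generator_config(), m_max = 5,
                                   drift = 0.12) {
  if (!inherits(config, "generator_config")) abort("`config` must be a `generator_config`.")
  if (m_max < 0 || m_max > config$n_tu - 1) abort("`m_max` out of range.")
  withr::with_seed(config$seed, generate_planted_impl(config, m_max, drift))
}

generate_planted_impl <- function(config, m_max, drift) {
  n <- config$n_tu
  years <- config$years
  idx <- seq_len(n)
  zshare <- function(s) { p <- idx^(-s); p / sum(p) }
  pA <- zshare(config$zipf_exponent)
  pB <- zshare(config$zipf_exponent * (1 + drift))
  Gm <- if (m_max > 0) t(vapply(seq_len(m_max), function(m) idx^m, numeric(n))) else matrix(0, 0, n)
  CA <- drop(Gm %*% pA)
  CB <- drop(Gm %*% pB)

  rr <- config$rate_ranges
  alpha <- stats::runif(n, rr$alpha[1], rr$alpha[2])
  epsilon <- stats::runif(n, rr$epsilon[1], rr$epsilon[2])
  w <- stats::runif(n, rr$w[1], rr$w[2])
  tu_id <- sprintf("TU%02d", idx)

  span <- max(length(years) - 1L, 1L)
  rows <- list(); truths <- list(); targets <- list()
  for (k in seq_along(years)) {
    theta <- (k - 1) / span
    Ck <- (1 - theta) * CA + theta * CB
    p <- if (m_max > 0) {
      solve_maxent(
        constraint_set(Gm, Ck, paste0("moment_", seq_len(m_max))),
        tol = 1e-12, max_iter = 300, must_converge = FALSE
      )$p
    } else {
      rep(1 / n, n)
    }
    B <- config$base_population * (1 + config$growth_mean * (k - 1))
    b <- p * B
    rows[[k]] <- tibble(
      year = years[k], tu_id = tu_id, tu_name = paste("Unit", tu_id),
      population = b, students = round(alpha * b),
      electricity_kwh = epsilon * b, water_m3 = w * b
    )
    truths[[k]] <- tibble(year = years[k], tu_id = tu_id, index = idx, p_true = p)
    targets[[k]] <- tibble(year = years[k], m = seq_len(m_max), C = Ck)
  }
  structure(
    list(
      panel = validate_panel(bind_rows(rows)),
      truth = bind_rows(truths),
      targets = bind_rows(targets),
      m_max = m_max, config = config
    ),
    class = "planted_panel"
  )
}

#' @export
print.planted_panel <- function(x, ...) {
  cat(sprintf(
    "<planted_panel: %d units x %d years, %d planted moment restriction(s)>\n",
    x$config$n_tu, length(x$config$years), x$m_max
  ))
  invisible(x)
}

#' Write the planted truth as a sidecar JSON
#'
#' @param planted a `planted_panel`.
#' @param path file path.
#' @export
write_planted_truth <- function(planted, path) {
  truth_by_year <- split(planted$truth$p_true, planted$truth$year)
  targets_by_year <- split(planted$targets$C, planted$targets$year)
  jsonlite::write_json(
    list(m_max = planted$m_max, p_true = truth_by_year, targets = targets_by_year),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
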