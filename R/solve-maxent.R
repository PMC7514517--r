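#' Solve the discrete maximum-entropy problem
#'
#' Finds the distribution \eqn{p} over \eqn{N} territorial units that
#' maximizes Shannon entropy \eqn{H(p) = -\sum_i p_i \ln p_i} subject to
#' the implicit normalization \eqn{\sum_i p_i = 1} and the linear
#' restrictions \eqn{\sum_i p_i g_r(i) = C_r} held in `constraints`.
#' The unique maximizer has the exponential form
#' \eqn{p_i = \exp(-\lambda_0 - \sum_r \lambda_r g_r(i))}, and is found
#' by minimizing the convex Lagrangian dual
#' \eqn{\ln Z(\lambda) + \sum_r \lambda_r C_r} with Newton's method and a
#' backtracking line search, starting from \eqn{\lambda = 0} (the uniform
#' distribution). Constraint rows are rescaled to unit maximum absolute
#' value, then centered and orthonormalized internally before iterating;
#' both transformations leave the solution unchanged (the constant parts
#' are absorbed by \eqn{\lambda_0}) but keep the dual Hessian well
#' conditioned even for high-order index-moment rows.
#'
#' @param constraints a [constraint_set()]; an empty set gives the
#'   uniform distribution.
#' @param n number of territorial units; required only when
#'   `constraints` has no rows, otherwise taken from the constraint
#'   matrix.
#' @param tol convergence tolerance on the maximum over rows of
#'   \eqn{|residual_r| / \max(1, |C_r|)}, with rows and targets on their
#'   unit-rescaled scale. Default `1e-10`.
#' @param max_iter maximum Newton iterations (default 200).
#' @param init optional numeric vector of initial multipliers on the
#'   original row scale (default all zero).
#' @param must_converge if `TRUE` (default), failure to reach `tol`
#'   raises an error naming the worst-violated constraint; if `FALSE`
#'   the best iterate is returned with `converged = FALSE`.
#'
#' @return An object of class `maxent_solution`: list with elements
#'   `p` (the distribution), `lambda` (multipliers on the original row
#'   scale), `lambda0` (normalization multiplier \eqn{\ln Z}),
#'   `entropy` (nats), `residuals` (per-row violations on the rescaled
#'   row scale), `iterations`, `converged`, and `labels`.
#'
#' @examples
#' # no constraints: uniform over 33 units, entropy ln 33
#' s <- solve_maxent(constraint_set(matrix(0, 0, 33), numeric(0)), n = 33)
#' s$entropy - log(33)
#'
#' # mean-of-index constraint pulls mass toward low indices
#' cs <- constraint_set(matrix(1:4, 1), C = 1.75)
#' solve_maxent(cs)$p
#' @export
solve_maxent <- function(constraints, n = NULL, tol = 1e-10, max_iter = 200L,
                         init = NULL, must_converge = TRUE) {
  if (!inherits(constraints, "constraint_set")) {
    abort("`constraints` must be a `constraint_set`.")
  }
  R <- nrow(constraints$G)
  N <- if (R || ncol(constraints$G)) ncol(constraints$G) else n
  if (is.null(N) || N < 2) abort("need at least 2 territorial units (supply `n` for an empty set).")
  if (R > N - 1) {
    abort(sprintf(
      "%d constraints on %d units: at most N - 1 = %d rows are identifiable (normalization consumes one degree of freedom).",
      R, N, N - 1
    ))
  }

  if (R == 0L) {
    p <- rep(1 / N, N)
    return(new_maxent_solution(
      p = p, lambda = numeric(0), lambda0 = log(N),
      residuals = numeric(0), iterations = 0L, converged = TRUE,
      labels = character(0)
    ))
  }

  check_feasibility(constraints)

  Gs <- constraints$G / constraints$scale
  Cs <- constraints$C / constraints$scale

  # centered + orthonormalized working basis (QR of the transposed rows)
  X <- t(Gs)
  mu <- colMeans(X)
  dec <- qr(sweep(X, 2L, mu))
  if (dec$rank < R) {
    abort(paste0(
      "constraint rows are linearly dependent (after removing the constant ",
      "direction); drop duplicated or collinear rows."
    ), class = "maxentpop_conditioning")
  }
  Qm <- qr.Q(dec)            # N x R, orthonormal columns
  Rm <- qr.R(dec)
  Ct <- drop(backsolve(Rm, Cs - mu, transpose = TRUE))
  Gt <- t(Qm)                # R x N working rows

  lam <- if (is.null(init)) rep(0, R) else drop(Rm %*% (as.numeric(init) * constraints$scale))
  if (length(lam) != R) abort("`init` must supply one multiplier per constraint row.")

  dual <- function(l) {
    e <- -drop(l %*% Gt)
    m <- max(e)
    log(sum(exp(e - m))) + m + sum(l * Ct)
  }
  p_of <- function(l) {
    e <- -drop(l %*% Gt)
    e <- e - max(e)
    p <- exp(e)
    p / sum(p)
  }
  rel_resid <- function(p) {
    (drop(Gs %*% p) - Cs) / pmax(1, abs(Cs))
  }

  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    p <- p_of(lam)
    if (max(abs(rel_resid(p))) <= tol) { converged <- TRUE; break }
    gbar <- drop(Gt %*% p)
    grad <- Ct - gbar                       # gradient of the dual in lam
    Gc <- sweep(Gt, 1L, gbar)
    H <- Gc %*% (p * t(Gc))                 # dual Hessian = covariance of rows
    step <- tryCatch(
      solve(H + diag(1e-13, R), grad),
      error = function(e) abort(
        "dual Hessian is numerically singular; constraints may be degenerate.",
        class = "maxentpop_conditioning"
      )
    )
    f0 <- dual(lam)
    slope <- sum(grad * step)
    if (slope <= 1e-14 * max(1, abs(f0))) {
      # within floating noise of the optimum: take the full Newton step
      lam <- lam - step
      next
    }
    t_ <- 1
    while (t_ >= 1e-12 && dual(lam - t_ * step) > f0 - 1e-4 * t_ * slope) {
      t_ <- t_ / 2
    }
    lam <- lam - t_ * step
  }
  p <- p_of(lam)
  res <- drop(Gs %*% p) - Cs
  if (max(abs(rel_resid(p))) <= tol) converged <- TRUE
  if (!converged && must_converge) {
    worst <- which.max(abs(rel_resid(p)))
    abort(sprintf(
      "maximum-entropy solver did not converge in %d iterations; worst-violated constraint: '%s' (relative residual %.3g).",
      max_iter, constraints$labels[worst], max(abs(rel_resid(p)))
    ), class = "maxentpop_nonconvergence")
  }

  lambda <- drop(backsolve(Rm, lam)) / constraints$scale
  lambda0 <- {
    e <- -drop(lambda %*% constraints$G)
    m <- max(e)
    log(sum(exp(e - m))) + m
  }
  new_maxent_solution(
    p = p, lambda = lambda, lambda0 = lambda0,
    residuals = res, iterations = iterations, converged = converged,
    labels = constraints$labels
  )
}

new_maxent_solution <- function(p, lambda, lambda0, residuals, iterations,
                                converged, labels) {
  structure(
    list(
      p = as.numeric(p), tu_index = seq_along(p),
      lambda = as.numeric(lambda), lambda0 = lambda0,
      entropy = shannon_entropy(p),
      residuals = as.numeric(residuals),
      iterations = as.integer(iterations), converged = isTRUE(converged),
      labels = labels
    ),
    class = "maxent_solution"
  )
}

#' @export
print.maxent_solution <- function(x, ...) {
  cat(sprintf(
    "<maxent_solution: N = %d, R = %d, entropy = %.6f nats, %s in %d iteration(s)>\n",
    length(x$p), length(x$lambda), x$entropy,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  if (length(x$residuals)) {
    cat(sprintf("  max |residual| = %.3g\n", max(abs(x$residuals))))
  }
  invisible(x)
}

#' Shannon entropy of a discrete distribution
#'
#' \eqn{H(p) = -\sum_i p_i \ln p_i} in nats; zero entries contribute
#' zero by the usual convention \eqn{0 \ln 0 = 0}.
#'
#' @param p numeric vector of shares: non-negative, summing to 1.
#' @return entropy in nats, a value in \eqn{[0, \ln N]}.
#' @examples
#' shannon_entropy(rep(1 / 33, 33)) # = log(33)
#' shannon_entropy(c(0.5, 0.25, 0.25))
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) abort("shares must be non-negative.")
  if (abs(sum(p) - 1) > 1e-8) abort("shares must sum to 1.")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Constraint violations of a distribution
#'
#' Returns \eqn{\sum_i p_i g_r(i) - C_r} for every row of a constraint
#' set, in the row's original units. (A `maxent_solution` instead
#' carries residuals on the unit-rescaled row scale, where the
#' convergence tolerance applies uniformly across heterogeneous rows.)
#'
#' @param p numeric vector of shares.
#' @param constraints a [constraint_set()].
#' @return numeric vector of residuals, one per constraint row.
#' @export
constraint_residuals <- function(p, constraints) {
  if (!inherits(constraints, "constraint_set")) {
    abort("`constraints` must be a `constraint_set`.")
  }
  if (nrow(constraints$G) && length(p) != ncol(constraints$G)) {
    abort(sprintf(
      "`p` has length %d but constraints cover %d units.",
      length(p), ncol(constraints$G)
    ))
  }
  if (!nrow(constraints$G)) return(numeric(0))
  drop(constraints$G %*% p) - constraints$C
}

#' @rdname solve_maxent
#' @param x a `maxent_solution`.
#' @param ... unused.
#' @export
tidy.maxent_solution <- function(x, ...) {
  tibble(tu_index = x$tu_index, p = x$p)
}

#' @rdname solve_maxent
#' @export
glance.maxent_solution <- function(x, ...) {
  tibble(
    n_units = length(x$p),
    n_constraints = length(x$lambda),
    entropy = x$entropy,
    max_abs_residual = if (length(x$residuals)) max(abs(x$residuals)) else 0,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Write or read a maximum-entropy solution as JSON
#'
#' @param solution a `maxent_solution`.
#' @param path file path.
#' @return `read_solution()` returns a `maxent_solution`;
#'   `write_solution()` returns `path` invisibly.
#' @export
write_solution <- function(solution, path) {
  jsonlite::write_json(
    list(
      p = solution$p, lambda = solution$lambda, lambda0 = solution$lambda0,
      entropy = solution$entropy, residuals = solution$residuals,
      iterations = solution$iterations, converged = solution$converged,
      labels = solution$labels
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_maxent_solution(
    p = x$p, lambda = x$lambda %||% numeric(0), lambda0 = x$lambda0,
    residuals = x$residuals %||% numeric(0), iterations = x$iterations,
    converged = x$converged, labels = x$labels %||% character(0)
  )
}
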