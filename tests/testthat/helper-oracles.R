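# Independent oracles for the maximum-entropy solver. These never call
# the package's dual Newton path.

# 1-D bisection on the geometric family p_i ∝ exp(-lambda * g_i) for a
# single mean constraint sum(g * p) = C.
bisect_single_constraint <- function(g, C, lo = -200, hi = 200, iters = 200) {
  mean_of <- function(lambda) {
    e <- -lambda * g
    z <- exp(e - max(e))
    sum(g * z) / sum(z)
  }
  # mean_of is decreasing in lambda
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mean_of(mid) > C) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  e <- -lambda * g
  p <- exp(e - max(e))
  list(p = p / sum(p), lambda = lambda)
}

# Generic augmented-Lagrangian maximizer of entropy subject to G p = C,
# parameterized by softmax so the simplex constraint is built in.
# Analytic gradient; multiplier updates avoid the stiffness of a pure
# penalty ladder.
penalty_oracle <- function(G, C, mu = 1e4, outer = 60, z0 = NULL) {
  G <- rbind(G)
  n <- ncol(G)
  scale <- apply(abs(G), 1, max)
  Gs <- G / scale
  Cs <- C / scale
  z <- z0 %||% rep(0, n)
  nu <- rep(0, nrow(Gs))
  softmax <- function(z) { z <- z - max(z); p <- exp(z); p / sum(p) }
  for (k in seq_len(outer)) {
    obj <- function(z) {
      p <- softmax(z)
      r <- drop(Gs %*% p) - Cs
      sum(p[p > 0] * log(p[p > 0])) + sum(nu * r) + mu * sum(r^2)
    }
    grad <- function(z) {
      p <- softmax(z)
      r <- drop(Gs %*% p) - Cs
      dp <- (log(pmax(p, 1e-300)) + 1) + drop((nu + 2 * mu * r) %*% Gs)
      p * (dp - sum(p * dp))          # softmax jacobian applied
    }
    fit <- stats::optim(z, obj, grad, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    z <- fit$par
    r <- drop(Gs %*% softmax(z)) - Cs
    nu <- nu + 2 * mu * r
    if (max(abs(r)) < 1e-12) break
  }
  softmax(z)
}

# Brute-force entropy maximizer over a grid on the 2-simplex for N = 3,
# one constraint, with local refinement.
brute_force_simplex3 <- function(g, C, steps = 400, rounds = 4) {
  lo1 <- 0; hi1 <- 1; lo2 <- 0; hi2 <- 1
  best <- c(1 / 3, 1 / 3, 1 / 3); bestH <- -Inf
  tol_feas <- (max(g) - min(g)) * 2e-3
  for (round in seq_len(rounds)) {
    p1s <- seq(lo1, hi1, length.out = steps)
    p2s <- seq(lo2, hi2, length.out = steps)
    for (p1 in p1s) {
      # for fixed p1 the constraint is linear in p2: solve directly
      # g1 p1 + g2 p2 + g3 (1 - p1 - p2) = C
      if (abs(g[2] - g[3]) > 1e-12) {
        p2 <- (C - g[3] - p1 * (g[1] - g[3])) / (g[2] - g[3])
        p3 <- 1 - p1 - p2
        if (p2 >= 0 && p3 >= 0) {
          p <- c(p1, p2, p3)
          H <- -sum(p[p > 0] * log(p[p > 0]))
          if (H > bestH) { bestH <- H; best <- p }
        }
      }
    }
    w1 <- (hi1 - lo1) / steps * 4
    lo1 <- max(0, best[1] - w1); hi1 <- min(1, best[1] + w1)
  }
  best
}

# Random feasible constraint set: targets are expectations under a
# random strictly positive distribution, so feasibility is guaranteed.
# The generating distribution is attached for warm-starting oracles (it
# is a feasible interior point, not the solution).
random_feasible_set <- function(n, r) {
  G <- matrix(stats::runif(r * n, -1, 1), r, n)
  p <- exp(stats::rnorm(n)); p <- p / sum(p)
  cs <- constraint_set(G, drop(G %*% p))
  attr(cs, "generator_p") <- p
  cs
}
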