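# Independent numerical oracles, deliberately on different algorithmic
# routes than the package solvers.

# Fused lasso objective
fl_objective <- function(y, x, lambda0, lambda1) {
  0.5 * sum((y - x)^2) + lambda0 * sum(abs(x)) + lambda1 * sum(abs(diff(x)))
}

# Transformed (convex fused lasso) objective
cf_objective_r <- function(y, x, lambda0, lambda1, a0, a1) {
  f <- function(t, a) if (a < 1e-10) t else (1 - exp(-a * t)) / a
  0.5 * sum((y - x)^2) + lambda0 * sum(f(abs(x), a0)) +
    lambda1 * sum(f(abs(diff(x)), a1))
}

# Oracle 1: fused lasso by accelerated projected gradient (FISTA) on the
# box-constrained dual max_{|u|<=l0,|v|<=l1} 0.5||y||^2 - 0.5||y-u-D'v||^2,
# with the duality gap as a certificate of the reported optimum.
fl_oracle <- function(y, lambda0, lambda1, gap_tol = 1e-10,
                      max_iter = 200000) {
  n <- length(y)
  u <- z_u <- rep(0, n)
  v <- z_v <- rep(0, max(n - 1, 0))
  tk <- 1
  L <- 9  # ||[I; D]||^2 <= (1 + 2)^2
  clip <- function(w, b) pmin(b, pmax(-b, w))
  gap <- Inf
  x <- y
  for (it in seq_len(max_iter)) {
    dtv <- if (n > 1) c(0, z_v) - c(z_v, 0) else 0
    x <- y - z_u - dtv
    u_new <- clip(z_u + x / L, lambda0)
    v_new <- if (n > 1) clip(z_v + diff(x) / L, lambda1) else z_v
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z_u <- u_new + (tk - 1) / t_new * (u_new - u)
    z_v <- v_new + (tk - 1) / t_new * (v_new - v)
    u <- u_new; v <- v_new; tk <- t_new
    if (it %% 50 == 0) {
      dtv <- if (n > 1) c(0, v) - c(v, 0) else 0
      x <- y - u - dtv
      primal <- fl_objective(y, x, lambda0, lambda1)
      gap <- primal - (0.5 * sum(y^2) - 0.5 * sum(x^2))
      if (gap <= gap_tol) break
    }
  }
  dtv <- if (n > 1) c(0, v) - c(v, 0) else 0
  x <- y - u - dtv
  list(x = x, objective = fl_objective(y, x, lambda0, lambda1), gap = gap)
}

# Oracle 2: convex fused lasso by graduated-smoothing L-BFGS-B over R^n.
# |t| is smoothed as sqrt(t^2 + eps^2) - eps with eps decreasing across
# warm-started stages; independent of the majorize-minimize route.
cf_oracle <- function(y, lambda0, lambda1, a0, a1,
                      eps_stages = c(1e-2, 1e-4, 1e-6, 1e-9)) {
  n <- length(y)
  fs <- function(t, a, eps) {
    s <- sqrt(t^2 + eps^2) - eps
    if (a < 1e-10) s else (1 - exp(-a * s)) / a
  }
  dfs <- function(t, a, eps) {
    s <- sqrt(t^2 + eps^2) - eps
    fp <- if (a < 1e-10) 1 else exp(-a * s)
    fp * t / sqrt(t^2 + eps^2)
  }
  x <- y
  for (eps in eps_stages) {
    obj <- function(x) {
      0.5 * sum((y - x)^2) + lambda0 * sum(fs(x, a0, eps)) +
        lambda1 * sum(fs(diff(x), a1, eps))
    }
    grad <- function(x) {
      g <- x - y + lambda0 * dfs(x, a0, eps)
      if (n > 1) {
        dd <- lambda1 * dfs(diff(x), a1, eps)
        g <- g + c(0, dd) - c(dd, 0)
      }
      g
    }
    res <- stats::optim(x, obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 10))
    x <- res$par
  }
  list(x = x, objective = cf_objective_r(y, x, lambda0, lambda1, a0, a1))
}
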