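test_that("convexity gate reproduces the printed inequality with boundary", {
  expect_true(check_convexity(solver_config(lambda0 = 1, lambda1 = 1,
                                            a0 = 0, a1 = 0)))
  # boundary equality: 1 - 2*0.5 - 0 = 0 is accepted
  expect_true(check_convexity(0.5, 0, 2, 0))
  # 1 - 0 - 4*1*0.5 < 0 rejected
  expect_false(check_convexity(0, 0.5, 0, 1))
  expect_error(convex_fused_fit(rnorm(5),
                                solver_config(lambda0 = 0.1, lambda1 = 0.3,
                                              a0 = 1, a1 = 1)),
               "convexity")
})

test_that("fused lasso solves degenerate cases exactly", {
  # constant signal with no sparsity penalty stays put for any fusion weight
  f <- fused_lasso_fit(rep(2.5, 8), 0, 13)
  expect_equal(f$x_hat, rep(2.5, 8))
  expect_equal(nrow(f$segments), 1)

  # strong sparsity penalty shrinks everything to zero
  f2 <- fused_lasso_fit(c(0.3, -0.2, 0.25), 5, 0.01)
  expect_equal(f2$x_hat, rep(0, 3), tolerance = 1e-9)

  expect_error(fused_lasso_fit(c(1, NaN), 0.1, 0.1), "finite")
})

test_that("fused lasso matches the projected-gradient dual oracle", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(2:30, 1)
    y <- rnorm(n, sd = sample(c(0.5, 1, 3), 1))
    l0 <- runif(1, 0, 0.6)
    l1 <- runif(1, 0, 1.5)
    fit <- fused_lasso_fit(y, l0, l1)
    ora <- fl_oracle(y, l0, l1)
    expect_lt(abs(fit$objective - ora$objective), 1e-6)
    # minimizer property: no worse than trivial candidates
    expect_lte(fit$objective, fl_objective(y, y, l0, l1) + 1e-12)
    expect_lte(fit$objective, fl_objective(y, rep(0, n), l0, l1) + 1e-12)
  }
})

test_that("the stated structured instance matches the convex oracle", {
  y <- c(0, 0, -3, -3, 0, 0)
  fit <- fused_lasso_fit(y, 0.1, 0.5)
  ora <- fl_oracle(y, 0.1, 0.5)
  expect_lt(abs(fit$objective - ora$objective), 1e-6)
  expect_equal(fit$x_hat[3], fit$x_hat[4], tolerance = 1e-8)
})

test_that("extreme fusion drives the fit to the soft-thresholded mean", {
  set.seed(7)
  for (k in 1:5) {
    y <- rnorm(12)
    f <- fused_lasso_fit(y, 0, 1e4)
    expect_equal(f$x_hat, rep(mean(y), 12), tolerance = 1e-6)
  }
})

test_that("convex fused fit matches dense numeric minimization", {
  set.seed(202)
  for (k in 1:20) {
    n <- sample(2:30, 1)
    y <- rnorm(n, sd = sample(c(0.5, 2), 1))
    repeat {
      l0 <- runif(1, 0, 0.5); l1 <- runif(1, 0, 1)
      a0 <- runif(1, 0, 1); a1 <- runif(1, 0, 0.5)
      if (1 - a0 * l0 - 4 * a1 * l1 >= 0.05) break
    }
    cfg <- solver_config(l0, l1, a0, a1)
    fit <- convex_fused_fit(y, cfg)
    ora <- cf_oracle(y, l0, l1, a0, a1)
    expect_lt(abs(fit$objective - ora$objective), 1e-5)
  }
})

test_that("zero input yields the zero fit with zero objective", {
  fit <- convex_fused_fit(rep(0, 6), solver_config(0.1, 0.3, 0.5, 0.2))
  expect_equal(fit$x_hat, rep(0, 6))
  expect_equal(fit$objective, 0)
})

test_that("vanishing curvature reduces the convex fit to the fused lasso", {
  set.seed(303)
  for (k in 1:8) {
    y <- rnorm(sample(3:25, 1))
    l0 <- runif(1, 0, 0.4); l1 <- runif(1, 0, 1)
    cfg <- solver_config(l0, l1, a0 = 1e-8, a1 = 1e-8)
    cf <- convex_fused_fit(y, cfg)
    fl <- fused_lasso_fit(y, l0, l1)
    expect_lt(abs(cf$objective - fl$objective), 1e-6)
  }
})

test_that("majorize-minimize objective never increases across iterations", {
  set.seed(404)
  for (k in 1:20) {
    y <- rnorm(sample(5:40, 1), sd = 2)
    repeat {
      l0 <- runif(1, 0, 0.5); l1 <- runif(1, 0, 2)
      a0 <- runif(1, 0, 1); a1 <- runif(1, 0, 0.3)
      if (1 - a0 * l0 - 4 * a1 * l1 >= 0) break
    }
    fit <- convex_fused_fit(y, solver_config(l0, l1, a0, a1))
    expect_true(all(diff(fit$trace) <= 1e-10))
  }
})

test_that("penalty curvature and difference-operator bounds justify the gate", {
  # f(t, a) = (1 - exp(-a t))/a has second derivative -a*exp(-a t) >= -a
  a <- 0.7
  f <- function(t) (1 - exp(-a * t)) / a
  t <- seq(0.05, 5, by = 0.05)
  h <- 1e-4
  second <- (f(t + h) - 2 * f(t) + f(t - h)) / h^2
  expect_true(all(second >= -a - 1e-5))
  # squared spectral norm of the first-difference operator is < 4
  for (n in c(5, 12, 30)) {
    D <- diff(diag(n))
    expect_lt(max(eigen(t(D) %*% D, symmetric = TRUE,
                        only.values = TRUE)$values), 4)
  }
})

test_that("the fit object reports its own objective and segment partition", {
  set.seed(17)
  y <- c(rnorm(10), rnorm(10, -3), rnorm(10))
  fit <- convex_fused_fit(y, solver_config(0.05, 1, 0.5, 0.1),
                          positions = seq(3, by = 14, length.out = 30),
                          gene = "KIF18A")
  expect_equal(fit$objective,
               cf_objective_r(y, fit$x_hat, 0.05, 1, 0.5, 0.1),
               tolerance = 1e-8)
  td <- tidy(fit)
  # segments partition the index range
  expect_equal(td$start_idx[1], 1L)
  expect_equal(td$end_idx[nrow(td)], 30L)
  if (nrow(td) > 1) {
    expect_equal(td$start_idx[-1], head(td$end_idx, -1) + 1L)
  }
  gl <- glance(fit)
  expect_equal(gl$gene, "KIF18A")
  expect_equal(gl$n_segments, nrow(td))
  expect_true(gl$converged)
})

test_that("region calling compares fits against the global average", {
  mk_fit <- function(gene, x_hat, cut_aa) {
    f <- fused_lasso_fit(x_hat, 0, 0, gene = gene)
    f$cut_aa <- cut_aa
    f
  }
  # one gene dips to -3 over aa 10-30; another flat at 0
  aa <- seq(2, 60, by = 2)
  x1 <- ifelse(aa >= 10 & aa <= 30, -3, 0)
  fits <- list(A = mk_fit("A", x1, aa), B = mk_fit("B", rep(0, 30), aa))
  r <- call_regions(fits, tau = 1)
  expect_equal(nrow(r), 1)
  expect_equal(r$gene, "A")
  expect_equal(r$aa_start, 10)
  expect_equal(r$aa_end, 30)
  expect_equal(r$score, -3)

  # all fits at the global mean -> nothing called
  flat <- list(A = mk_fit("A", rep(-2, 10), 1:10),
               B = mk_fit("B", rep(-2, 10), 1:10))
  expect_equal(nrow(call_regions(flat, tau = 1)), 0)

  # two qualifying runs separated by one passing guide stay separate
  x2 <- c(-3, -3, 0, -3, -3)
  fits2 <- list(A = mk_fit("A", x2, c(10, 12, 14, 16, 18)),
                B = mk_fit("B", rep(0, 45), seq_len(45)))
  r2 <- call_regions(fits2, tau = 1)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$aa_start, c(10, 16))

  # the margin scales with the NTC score SD when supplied
  r3 <- call_regions(fits2, tau = 1, ntc_sd = 0.5)
  expect_equal(attr(r3, "threshold"), attr(r3, "global_mean") - 0.5)
})

test_that("penalty selection balances fit and segment count", {
  grid <- tidyr::expand_grid(lambda0 = c(0.01, 0.1),
                             lambda1 = c(0.05, 0.5, 2),
                             a0 = 0.1, a1 = 0.05)
  # noiseless two-step signal: selection recovers exactly 3 segments
  y <- c(rep(0, 15), rep(-3, 15), rep(0, 15))
  cfg <- lambda_select(y, grid)
  fit <- convex_fused_fit(y, cfg)
  expect_equal(nrow(fit$segments), 3)

  # pure noise selects a single-segment (maximally smooth) fit
  set.seed(55)
  hits <- vapply(1:10, function(i) {
    y <- rnorm(40, sd = 0.3)
    cfg <- lambda_select(y, grid)
    nrow(convex_fused_fit(y, cfg)$segments)
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.9)

  # a single-row grid returns that configuration
  one <- lambda_select(rnorm(10), grid[3, ])
  expect_equal(one$lambda1, grid$lambda1[3])
  expect_error(lambda_select(rnorm(10), grid[0, ]), "empty grid")
})
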