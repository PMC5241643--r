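# Geometric-mean scaling and its exactness/equivalence contracts.

test_that("identity matrix needs no scaling", {
  sc <- compute_scales(list(m = 3, n = 3, i = 1:3, j = 1:3, x = rep(1, 3)))
  expect_equal(sc$row_scales, rep(1, 3))
  expect_equal(sc$col_scales, rep(1, 3))
  expect_equal(sc$achieved_spread, 1)
})

test_that("diagonal extremes are equilibrated to unit entries", {
  sc <- compute_scales(list(m = 2, n = 2, i = 1:2, j = 1:2, x = c(1e6, 1e-6)),
                       round_pow2 = FALSE)
  scaled <- c(1e6, 1e-6) / (sc$row_scales * sc$col_scales)
  expect_equal(scaled, c(1, 1), tolerance = 1e-12)
})

test_that("pass recurrence matches an independent reimplementation", {
  set.seed(1)
  m <- 4; n <- 4
  e <- matrix(runif(m * n, -8, 8), m, n)   # log10-uniform in [1e-8, 1e8]
  x <- 10^e
  tr <- list(m = m, n = n, i = rep(1:m, n), j = rep(1:n, each = m),
             x = as.vector(x))
  sc <- compute_scales(tr, max_passes = 1, round_pow2 = FALSE)
  # straightforward dense recomputation of one row pass then one col pass
  la <- log2(abs(x))
  lr <- apply(la, 1, function(v) (max(v) + min(v)) / 2)
  la1 <- sweep(la, 1, lr)
  lc <- apply(la1, 2, function(v) (max(v) + min(v)) / 2)
  la2 <- sweep(la1, 2, lc)
  expect_equal(log2(sc$row_scales), lr, tolerance = 1e-12)
  expect_equal(log2(sc$col_scales), lc, tolerance = 1e-12)
  expect_equal(sc$achieved_spread, 2^(max(la2) - min(la2)), tolerance = 1e-9)
  expect_lt(sc$achieved_spread, sc$unscaled_spread)
})

test_that("spread never increases with additional passes", {
  set.seed(7)
  gen <- generate_multiscale_lp(synthetic_spec(m = 20, n = 30, seed = 7))
  spreads <- vapply(1:6, function(k)
    compute_scales(gen$problem, max_passes = k, round_pow2 = FALSE,
                   stop_ratio = 0)$achieved_spread, 0)
  expect_true(all(diff(spreads) <= 1e-9 * spreads[-length(spreads)]))
})

test_that("scaling preserves the optimal objective exactly (power-of-two)", {
  for (s in c(21, 22)) {
    p <- generate_dense_small_lp(s, m = 3, n = 4)
    or <- lp_vertex_oracle(p)
    if (or$status != "optimal") next
    r_scaled <- primal_simplex(p, double_opts(scale = TRUE))
    expect_lt(abs(r_scaled$objective - or$objective), 1e-9)
  }
  # multiscale instance: scaled solve equals unscaled quad certificate
  gen <- generate_multiscale_lp(synthetic_spec(m = 20, n = 30, seed = 5))
  a <- primal_simplex(gen$problem, quad_opts(scale = TRUE))
  b <- primal_simplex(gen$problem, quad_opts(scale = FALSE))
  expect_lt(hi_lo_diff(a$objective, a$objective_lo, b$objective, b$objective_lo),
            1e-20 * (1 + abs(a$objective)))
})

test_that("apply/unscale round trip is the identity", {
  gen <- generate_multiscale_lp(synthetic_spec(m = 15, n = 20, seed = 9))
  form <- to_computational_form(gen$problem)
  sc <- compute_scales(gen$problem)
  sf <- apply_scaling(form, sc)
  x <- c(gen$v0, rep(1, form$m)); y <- runif(form$m)
  colsc <- c(sc$col_scales, 1 / sc$row_scales)
  back <- unscale_solution(x * colsc, y * sc$row_scales, sc)
  expect_identical(back$x, x)   # powers of two: bitwise identity
  expect_identical(back$y, y)
  expect_error(apply_scaling(form, list(row_scales = rep(-1, form$m),
                                        col_scales = sc$col_scales)),
               "positive")
})

test_that("unscaling can inflate Pinf on ill-scaled data (why Q2 exists)", {
  # iid 1e+-8 entries: no row/column structure for scaling to remove
  set.seed(3)
  m <- 12; n <- 16; k <- 4
  ti <- rep(1:m, each = k)
  tj <- as.vector(vapply(1:m, function(i) sample.int(n, k), integer(k)))
  x <- 2^sample(c(-27, 27), m * k, replace = TRUE) *
    sample(c(-1, 1), m * k, replace = TRUE)
  v0 <- 2^sample(-5:5, n, replace = TRUE)
  act <- dqqlp:::cpp_matvec_qd(m, ti - 1L, tj - 1L, x, v0, rep(0, n))
  p <- lp_problem(i = ti, j = tj, x = x, m = m, n = n, row_sense = "E",
                  rhs = act$hi, rhs_lo = act$lo, c_obj = round(rnorm(n), 2),
                  lower = rep(0, n), upper = 2^(pmax(
                    ceiling(log2(v0)), 0) + 3))
  d <- primal_simplex(p, double_opts(scale = TRUE))
  # the scaled solve satisfied its own tolerance, yet on the original data
  # the unscaled point violates the nominal delta1 = 1e-7 -- the inflation
  # that motivates the final unscaled quad step, which removes it
  expect_identical(d$status, "optimal")
  expect_gt(d$pinf, 1e-7)
  q2 <- primal_simplex(p, default_options("Q2"))
  expect_lte(q2$pinf, 1e-15 * (1 + max(abs(q2$v))))
})
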