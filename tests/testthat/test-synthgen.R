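# Synthetic generators: determinism, exact planted feasibility, coverage.

test_that("identical spec and seed give bit-identical instances", {
  a <- generate_multiscale_lp(synthetic_spec(seed = 42))
  b <- generate_multiscale_lp(synthetic_spec(seed = 42))
  expect_identical(write_mps(a$problem, dialect = "free"),
                   write_mps(b$problem, dialect = "free"))
  expect_identical(a$v0, b$v0)
  c1 <- generate_multiscale_lp(synthetic_spec(seed = 43))
  expect_false(identical(a$problem$S$x, c1$problem$S$x))
})

test_that("planted points satisfy every row exactly at high precision", {
  for (s in c(7, 8)) {
    gen <- generate_multiscale_lp(synthetic_spec(m = 60, n = 80,
                                                 coefficient_decades = 12,
                                                 flux_decades = 18, seed = s))
    st <- problem_stats(gen$problem)
    expect_gte(st$max_abs / st$min_abs, 1e12)
    expect_lte(planted_residual(gen), 1e-40)
    p <- gen$problem
    expect_true(all(gen$v0 >= p$lower & gen$v0 <= p$upper))
  }
  # steady-state variant: b = 0 with balancing columns, still exact
  gs <- generate_multiscale_lp(synthetic_spec(m = 20, n = 30, seed = 3,
                                              steady_state = TRUE))
  expect_true(all(gs$problem$rhs == 0))
  expect_lte(planted_residual(gs), 1e-40)
})

test_that("flux magnitudes span the requested decades", {
  gen <- generate_multiscale_lp(synthetic_spec(seed = 5))
  v <- gen$v0[gen$v0 > 0]
  expect_gte(log10(max(v) / min(v)), 17.5)
  expect_lte(min(v), 1e-9)   # transcription-scale values
  expect_gte(max(v), 1e7)    # metabolic-scale values
})

test_that("well-scaled instances certify in step D alone", {
  gen <- generate_multiscale_lp(synthetic_spec(m = 5, n = 8,
                                               coefficient_decades = 0,
                                               flux_decades = 0, seed = 1))
  r <- primal_simplex(gen$problem, default_options("D"))
  expect_identical(r$status, "optimal")
  expect_lte(r$pinf, 1e-7 * (1 + max(abs(r$v))))
})

test_that("ME-like models couple tiny expression fluxes to metabolic fluxes", {
  gen <- generate_me_like_model(synthetic_spec(m = 30, n = 50, seed = 31))
  expect_gt(nrow(gen$coupling), 0)
  p <- gen$problem
  ncpl <- sum(grepl("^CPL_", p$row_names))
  expect_equal(ncpl, nrow(gen$coupling))
  # planted point satisfies the coupling rows strictly
  for (k in seq_len(nrow(gen$coupling))) {
    i <- gen$coupling$i[k]; j <- gen$coupling$j[k]
    cmax <- gen$mu / gen$coupling$k_eff[k]
    expect_lt(gen$v0[i], cmax * gen$v0[j])
  }
  expect_lte(planted_residual(gen), 1e-40)
  # zero expression block reduces to the metabolic multiscale core
  g0 <- generate_me_like_model(synthetic_spec(m = 30, n = 50, seed = 31))
  expect_identical(g0$problem$S$x, gen$problem$S$x)
})

test_that("degeneracy level controls the optimal basics on bounds", {
  dg <- generate_degenerate_lp(5, 0.3)
  r <- primal_simplex(dg$problem, quad_opts())
  expect_identical(r$status, "optimal")
  expect_equal(r$objective, dg$optimal_objective, tolerance = 1e-20)
  form <- to_computational_form(dg$problem)
  bas <- r$basis$basic
  on_bound <- abs(r$v[bas] - form$lower[bas]) < 1e-25 |
    abs(r$v[bas] - form$upper[bas]) < 1e-25
  expect_gte(mean(on_bound), 0.3)
  # level 0 instances solve without degenerate pivots from the planted basis
  dg0 <- generate_degenerate_lp(6, 0)
  r0 <- primal_simplex(dg0$problem, quad_opts())
  expect_equal(r0$objective, dg0$optimal_objective, tolerance = 1e-20)
})

test_that("infeasible family carries a valid margin certificate", {
  for (s in c(3, 9)) {
    inf <- generate_infeasible_lp(synthetic_spec(m = 25, n = 35, seed = s))
    expect_gt(inf$certificate$margin, 0)
    rep <- run_dqq(inf$problem)
    expect_identical(rep$status, "infeasible")
  }
})
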