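# Revised primal simplex: oracle agreement, degeneracy handling,
# infeasibility certification, duality.

test_that("trivial equality LP solves to its known optimum", {
  r <- primal_simplex(toy_equality_lp(), double_opts())
  expect_identical(r$status, "optimal")
  expect_equal(r$objective, -1)
  expect_equal(sum(r$v[1:2]), 1, tolerance = 1e-12)
})

test_that("random boxed LPs match the enumeration oracle in both precisions", {
  for (s in 1:25) {
    p <- generate_dense_small_lp(s)
    or <- lp_vertex_oracle(p)
    rd <- primal_simplex(p, double_opts(scale = FALSE))
    rq <- primal_simplex(p, quad_opts())
    if (or$status == "infeasible") {
      expect_identical(rd$status, "infeasible")
      expect_identical(rq$status, "infeasible")
    } else {
      expect_identical(rd$status, "optimal")
      expect_lt(abs(rd$objective - or$objective), 1e-9)
      expect_lt(hi_lo_diff(rq$objective, rq$objective_lo,
                           or$objective, or$objective_lo), 1e-25)
    }
  }
})

test_that("solutions agree with an independent LP solver", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  script <- '
import sys, json
from scipy.optimize import linprog
d = json.load(sys.stdin)
out = []
for pb in d:
    res = linprog(c=pb["c"], A_eq=pb.get("Aeq"), b_eq=pb.get("beq"),
                  A_ub=pb.get("Aub"), b_ub=pb.get("bub"),
                  bounds=list(zip(pb["lo"], pb["hi"])), method="highs")
    out.append({"status": int(res.status), "obj": res.fun if res.success else None})
print(json.dumps(out))
'
  probs <- list(); mine <- list()
  for (s in 1:8) {
    p <- generate_dense_small_lp(s + 400)
    A <- as.matrix(lp_matrix(p))
    eq <- p$row_sense == "E"
    le <- p$row_sense == "L"; ge <- p$row_sense == "G"
    Aub <- rbind(A[le, , drop = FALSE], -A[ge, , drop = FALSE])
    bub <- c(p$rhs[le], -p$rhs[ge])
    probs[[s]] <- list(c = p$c_obj,
                       Aeq = if (any(eq)) A[eq, , drop = FALSE],
                       beq = if (any(eq)) p$rhs[eq],
                       Aub = if (nrow(Aub)) Aub, bub = if (length(bub)) bub,
                       lo = p$lower, hi = p$upper)
    mine[[s]] <- primal_simplex(p, double_opts())
  }
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  res <- system2("python", sf, input = jsonlite::toJSON(probs, digits = NA,
                                                        auto_unbox = TRUE,
                                                        null = "null"),
                 stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(res, collapse = ""),
                            simplifyDataFrame = FALSE)
  for (s in seq_along(ref)) {
    if (ref[[s]]$status == 2) expect_identical(mine[[s]]$status, "infeasible")
    else if (ref[[s]]$status == 0)
      expect_equal(mine[[s]]$objective, ref[[s]]$obj, tolerance = 1e-7)
  }
})

test_that("EXPAND terminates on a cycling-prone degenerate LP; the classic rule stalls", {
  dg <- generate_degenerate_lp(3, 0.8)
  re <- primal_simplex(dg$problem, double_opts())
  expect_identical(re$status, "optimal")
  expect_equal(re$objective, dg$optimal_objective, tolerance = 1e-9)
  rc <- primal_simplex(dg$problem,
                       solver_options(precision = "double", scale = FALSE,
                                      expand = FALSE, iteration_limit = 300))
  expect_true(rc$status != "optimal" ||
                abs(rc$objective - dg$optimal_objective) > 1e-9)
})

test_that("degenerate steps are counted and feasibility drift stays bounded", {
  dg <- generate_degenerate_lp(11, 0.5)
  r <- primal_simplex(dg$problem, double_opts())
  expect_identical(r$status, "optimal")
  expect_gt(r$degenerate_iterations, 0)
  expect_lte(r$pinf, 1e-7 * (1 + max(abs(r$v))))
  expect_equal(r$objective, dg$optimal_objective, tolerance = 1e-9)
})

test_that("compute_infeasibilities matches hand values and solver reports", {
  p <- one_var_lp()
  r <- primal_simplex(p, double_opts())
  expect_equal(r$v[1], 2)
  expect_equal(r$pinf, 0)
  expect_equal(r$dinf, 0)
  # perturb the primal beyond a bound: Pinf is exactly the overshoot
  v <- r$v; v[1] <- 3 + 1e-6
  ci <- compute_infeasibilities(p, v, r$y, r$basis)
  expect_equal(ci$pinf, 1e-6)
  # independent recomputation on a toy optimum
  p2 <- generate_dense_small_lp(5)
  r2 <- primal_simplex(p2, double_opts())
  if (r2$status == "optimal") {
    A <- as.matrix(lp_matrix(p2))
    act <- as.vector(A %*% r2$v[1:p2$n])
    ri <- dqqlp:::row_intervals(p2)
    pinf_ref <- max(0, ri$rlo - act, act - ri$rhi,
                    p2$lower - r2$v[1:p2$n], r2$v[1:p2$n] - p2$upper)
    expect_equal(r2$pinf, pinf_ref, tolerance = 1e-12)
    z <- p2$c_obj - as.vector(t(A) %*% r2$y)
    st <- r2$basis$vstat[1:p2$n]
    dviol <- ifelse(st == 1, pmax(0, -z), ifelse(st == 2, pmax(0, z), abs(z)))
    dviol_slack <- ifelse(r2$basis$vstat[p2$n + 1:p2$m] == 1,
                          pmax(0, -r2$y),
                          ifelse(r2$basis$vstat[p2$n + 1:p2$m] == 2,
                                 pmax(0, r2$y), abs(r2$y)))
    expect_equal(r2$dinf, max(dviol, dviol_slack), tolerance = 1e-10)
  }
})

test_that("weak duality holds at reported optima", {
  for (s in c(31, 33, 35)) {
    gen <- generate_multiscale_lp(synthetic_spec(m = 20, n = 30, seed = s))
    r <- primal_simplex(gen$problem, quad_opts(scale = TRUE))
    expect_identical(r$status, "optimal")
    # in the slack form A x = 0, c'v = z'x over the full vector (the slack
    # reduced cost being y_i), with z_B = 0 at an exact optimum
    dual_obj <- sum(r$z * r$v)
    gap <- abs(r$objective - dual_obj)
    expect_lt(gap, 1e-6 * (1 + abs(r$objective)))
  }
})

test_that("unbounded problems are detected with certificate status", {
  p <- lp_problem(i = 1, j = 1, x = 1, m = 1, n = 2, row_sense = "L",
                  rhs = 5, c_obj = c(0, -1), lower = c(0, 0),
                  upper = c(Inf, Inf))
  r <- primal_simplex(p, double_opts())
  expect_identical(r$status, "unbounded")
})

test_that("iteration limit returns the best iterate with its status", {
  gen <- generate_multiscale_lp(synthetic_spec(m = 30, n = 40, seed = 2))
  r <- primal_simplex(gen$problem,
                      solver_options(precision = "double", iteration_limit = 5))
  expect_identical(r$status, "iteration_limit")
  expect_equal(r$iterations, 5)
})
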