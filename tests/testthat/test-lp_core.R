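# Problem container, computational form, MPS I/O.

test_that("lp_problem validates dimensions, duplicates and bounds", {
  expect_error(lp_problem(i = 1, j = 3, x = 1, m = 2, n = 2, row_sense = "E",
                          rhs = c(0, 0), c_obj = c(0, 0)),
               "column index")
  expect_error(lp_problem(i = c(1, 1), j = c(1, 1), x = c(1, 2), m = 1, n = 1,
                          row_sense = "E", rhs = 0, c_obj = 0),
               "duplicate")
  expect_error(lp_problem(i = 1, j = 1, x = 1, m = 1, n = 1, row_sense = "E",
                          rhs = 0, c_obj = 0, lower = 2, upper = 1),
               "lower > upper")
})

test_that("computational form encodes senses in slack bounds", {
  p <- lp_problem(i = c(1, 2, 3, 4), j = c(1, 1, 1, 1), x = c(1, 1, 1, 1),
                  m = 4, n = 1, row_sense = c("E", "L", "G", "R"),
                  rhs = c(1, 2, 3, 4), range = c(NA, NA, NA, 2),
                  c_obj = 1)
  f <- to_computational_form(p)
  sl <- 1 + seq_len(4)
  expect_equal(f$lower[sl], c(1, -Inf, 3, 4))
  expect_equal(f$upper[sl], c(1, 2, Inf, 6))
  # slack coefficient -1, one per row
  expect_equal(f$ntot, 5)
  expect_equal(sum(f$ax == -1), 4)
})

test_that("computational form preserves the optimum (vertex oracle)", {
  for (s in c(11, 12, 13)) {
    p <- generate_dense_small_lp(s, m = 3, n = 4)
    or <- lp_vertex_oracle(p)
    r <- primal_simplex(p, double_opts())
    expect_identical(r$status, or$status)
    if (or$status == "optimal")
      expect_lt(abs(r$objective - or$objective), 1e-9)
  }
})

test_that("maximization is solved by negation and reported in original sense", {
  p <- lp_problem(i = c(1, 1), j = c(1, 2), x = c(1, 1), m = 1, n = 2,
                  row_sense = "L", rhs = 5, c_obj = c(2, 3),
                  upper = c(4, 4), sense = "max")
  r <- primal_simplex(p, double_opts())
  expect_equal(r$objective, 2 * 1 + 3 * 4, tolerance = 1e-9) # v=(1,4)
})

test_that("problem_stats reports dimensions and magnitude spread", {
  p <- toy_equality_lp()
  st <- problem_stats(p)
  expect_equal(st$m, 1); expect_equal(st$n, 2); expect_equal(st$nnz, 2)
  gen <- generate_multiscale_lp(synthetic_spec(seed = 3))
  st2 <- problem_stats(gen$problem)
  expect_gte(st2$max_abs / st2$min_abs, 1e12)
  expect_gte(st2$coefficient_decades, 12)
})

test_that("MPS semantics: defaults, duplicate summing, objective constant", {
  txt <- c("NAME          T1",
           "ROWS",
           " N  COST",
           " E  R1",
           " L  R2",
           "COLUMNS",
           "    X         R1        1.0",
           "    X         R2        2.0",
           "    X         R2        3.0",     # duplicate: summed
           "    X         COST      1.5",
           "RHS",
           "    RHS       R1        1.0",
           "    RHS       COST      4.0",     # objective constant (negated)
           "ENDATA")
  p <- read_mps(text = txt)
  expect_equal(p$m, 2); expect_equal(p$n, 1)
  expect_equal(p$lower, 0); expect_equal(p$upper, Inf)  # default bounds
  expect_equal(sort(p$S$x), c(1, 5))
  expect_equal(p$obj_constant, -4)
  expect_equal(p$c_obj, 1.5)
})

test_that("MPS errors name the offending line", {
  bad_row <- c("NAME", "ROWS", " N OBJ", " E R1", "COLUMNS",
               "    X   NOSUCH   1.0", "ENDATA")
  expect_error(read_mps(text = bad_row), "unknown row name 'NOSUCH'")
  bad_num <- c("NAME", "ROWS", " N OBJ", " E R1", "COLUMNS",
               "    X   R1   1.0.0", "ENDATA")
  expect_error(read_mps(text = bad_num), "malformed numeric")
  no_end <- c("NAME", "ROWS", " N OBJ", " E R1", "COLUMNS",
              "    X   R1   2.0")
  expect_warning(p <- read_mps(text = no_end), "ENDATA")
  expect_equal(p$S$x, 2)
})

test_that("RANGES make an E row two-sided (classical convention)", {
  txt <- c("NAME", "ROWS", " N OBJ", " E R1", "COLUMNS",
           "    X   R1   1.0", "    X   OBJ  1.0",
           "RHS", "    RHS  R1  2.0",
           "RANGES", "    RNG  R1  3.0", "ENDATA")
  p <- read_mps(text = txt)
  expect_equal(p$row_sense, "R")
  ri <- dqqlp:::row_intervals(p)
  expect_equal(c(ri$rlo, ri$rhi), c(2, 5))
  # negative range on an E row extends downward
  txt[11] <- "    RNG  R1  -3.0"
  p2 <- read_mps(text = txt)
  ri2 <- dqqlp:::row_intervals(p2)
  expect_equal(c(ri2$rlo, ri2$rhi), c(-1, 2))
})

test_that("fixed-dialect round trip is stable at field resolution", {
  p <- lp_problem(i = c(1, 1, 2), j = c(1, 2, 1), x = c(1, 8.0e+05, 1e-10),
                  m = 2, n = 2, row_sense = c("E", "G"), rhs = c(1, 0),
                  c_obj = c(-1, 2), lower = c(0, 1e-10), upper = c(10, Inf),
                  sense = "max", row_names = c("R1", "R2"),
                  col_names = c("X", "Y"))
  q <- read_mps(text = write_mps(p, dialect = "fixed"))
  expect_equal(q$S$x[order(q$S$j, q$S$i)], p$S$x[order(p$S$j, p$S$i)])
  expect_equal(q$lower, p$lower)   # 1e-10 survives exactly
  expect_equal(q$sense, "max")
  # second emit identical to first (fixed point of the round trip)
  expect_identical(write_mps(q, dialect = "fixed"),
                   write_mps(read_mps(text = write_mps(q, dialect = "fixed")),
                             dialect = "fixed"))
})

test_that("free-dialect round trip reproduces doubles exactly", {
  gen <- generate_multiscale_lp(synthetic_spec(m = 10, n = 12, seed = 2))
  p <- gen$problem
  q <- read_mps(text = write_mps(p, dialect = "free"), dialect = "free")
  o1 <- order(p$S$j, p$S$i); o2 <- order(q$S$j, q$S$i)
  expect_identical(q$S$x[o2], p$S$x[o1])
  expect_identical(q$lower, p$lower)
  expect_identical(q$upper, p$upper)
  expect_identical(q$rhs, p$rhs)
})

test_that("quad parse path captures digits beyond double", {
  txt <- c("NAME", "ROWS", " N OBJ", " E R1", "COLUMNS",
           "    X   R1   1.00000000000000000001", "    X   OBJ  1.0",
           "RHS", "    RHS  R1  1.0", "ENDATA")
  p <- read_mps(text = txt, precision = "quad")
  expect_identical(p$S$x, 1)
  expect_gt(abs(p$S$x_lo), 0)
  expect_equal(p$S$x_lo, 1e-20, tolerance = 1e-3)
})

test_that("the shipped toy FBA model parses and solves to its known optimum", {
  f <- system.file("extdata", "toy_fba.mps", package = "dqqlp")
  p <- read_mps(f, dialect = "fixed")
  expect_equal(p$m, 2); expect_equal(p$n, 4)
  expect_identical(p$sense, "max")
  rep <- run_dqq(p)
  # uptake 10 split as 8 direct + 2 bypass (yield 0.5): biomass 8 + 1 = 9
  expect_equal(rep$objective, 9)
  expect_identical(rep$status, "optimal")
})

test_that("fixed-dialect writer rejects name collisions after truncation", {
  p <- lp_problem(i = c(1, 1), j = c(1, 2), x = c(1, 1), m = 1, n = 2,
                  row_sense = "E", rhs = 1, c_obj = c(1, 1),
                  col_names = c("LONGNAME_A", "LONGNAME_B"))
  expect_error(write_mps(p, dialect = "fixed"), "collision")
})
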