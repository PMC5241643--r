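# Sparse LU of the basis: factorization accuracy, dependent-column
# detection, repair, refined solves, and Bartels-Golub updates.

random_sparse_basis <- function(m, seed, cond_boost = 0) {
  set.seed(seed)
  B <- diag(m) * 2^sample(-1:1, m, replace = TRUE)
  nnz_extra <- 2 * m
  B[cbind(sample.int(m, nnz_extra, TRUE), sample.int(m, nnz_extra, TRUE))] <-
    round(rnorm(nnz_extra), 3)
  if (cond_boost > 0) B[1, ] <- B[1, ] * 10^cond_boost
  B
}

test_that("identity basis factorizes trivially", {
  f <- factorize_basis(diag(5))
  expect_equal(nrow(f$dependents), 0)
  expect_equal(f$reconstruction_error, 0)
})

test_that("a duplicated column is reported as one dependent position", {
  B <- random_sparse_basis(6, 1)
  B[, 4] <- B[, 2]
  f <- factorize_basis(B)
  expect_equal(nrow(f$dependents), 1)
  f2 <- factorize_basis(B, precision = "quad")
  expect_equal(nrow(f2$dependents), 1)
})

test_that("reconstruction error respects the precision of the context", {
  B <- random_sparse_basis(8, 7, cond_boost = 3)
  fd <- factorize_basis(B, lu_factor_tol = 1.9)
  expect_equal(nrow(fd$dependents), 0)
  expect_lte(fd$reconstruction_error, 1e-12 * fd$matrix_norm)
  fq <- factorize_basis(B, lu_factor_tol = 1.9, precision = "quad")
  expect_lte(fq$reconstruction_error, 1e-30 * fq$matrix_norm)
})

test_that("repair_basis substitutes slack unit columns soundly", {
  m <- 5; n <- 4
  # basis: structurals 1..4 plus slack of row 5; make column 2 dependent on 1
  vstat <- c(rep(0L, 4), rep(1L, 0), c(1L, 1L, 1L, 1L, 0L))
  bs <- basis_state(vstat, m)
  dep <- data.frame(position = 2, row = 3)
  rb <- repair_basis(bs, dep, n_struct = n)
  expect_equal(sum(rb$vstat == 0L), m)
  expect_equal(rb$vstat[n + 3], 0L)      # slack of row 3 now basic
  expect_equal(rb$vstat[bs$basic[2]], 1L) # displaced variable nonbasic
  # no dependents: identity operation
  expect_identical(repair_basis(bs, dep[0, ], n_struct = n)$vstat, bs$vstat)
  # doubly-deficient: two replacements
  rb2 <- repair_basis(bs, data.frame(position = c(1, 2), row = c(1, 1)),
                      n_struct = n)
  expect_equal(sum(rb2$vstat == 0L), m)
  expect_equal(sum(rb2$vstat[n + 1:m] == 0L), 3) # two extra slacks basic
})

test_that("solves with B and B' meet the residual contract", {
  expect_equal(solve_with_basis(diag(4), c(1, 2, 3, 4))$x, c(1, 2, 3, 4))
  expect_equal(solve_with_basis(diag(4), c(1, 2, 3, 4), transpose = TRUE)$x,
               c(1, 2, 3, 4))
  for (s in 1:5) {
    m <- 5 + 3 * s
    B <- random_sparse_basis(m, 100 + s)
    e <- rep(1, m)
    rhs <- as.vector(B %*% e)
    sol <- solve_with_basis(B, rhs, refine = 1)
    expect_lt(max(abs(sol$x - e)), 1e-11 * (1 + max(abs(e))))
    expect_lt(sol$residual_inf, 1e-13 * (1 + max(abs(rhs))))
    solt <- solve_with_basis(B, rhs, transpose = TRUE, refine = 1)
    expect_lt(solt$residual_inf, 1e-13 * (1 + max(abs(rhs))))
    # dense high-precision oracle agreement
    oracle <- dqqlp:::cpp_dense_solve_qd(B, rhs)
    expect_lt(max(abs(sol$x - oracle$x)), 1e-10 * (1 + max(abs(oracle$x))))
    solq <- solve_with_basis(B, rhs, refine = 1, precision = "quad")
    expect_lt(max(abs((solq$x - oracle$x) + (solq$x_lo - oracle$x_lo))),
              1e-25 * (1 + max(abs(oracle$x))))
  }
})

test_that("one refinement pass shrinks the error of an ill-conditioned solve", {
  m <- 6
  H <- outer(1:m, 1:m, function(i, j) 1 / (i + j - 1))  # Hilbert-like
  rhs <- rowSums(H)
  oracle <- dqqlp:::cpp_dense_solve_qd(H, rhs)
  err <- function(ref) {
    s <- solve_with_basis(H, rhs, refine = ref)
    max(abs((s$x - oracle$x) + (s$x_lo - oracle$x_lo)))
  }
  e0 <- err(0); e1 <- err(1)
  expect_true(e1 <= e0 / 10 || e1 < 1e-18)
})

test_that("updated factors agree with fresh factorization across m replacements", {
  m <- 5
  B <- random_sparse_basis(m, 42)
  set.seed(43)
  cols <- matrix(round(rnorm(m * m), 3), m, m) + 3 * diag(m)
  rhs <- rnorm(m)
  res <- update_basis_columns(B, positions = 1:m, new_cols = cols, rhs = rhs)
  expect_lt(res$max_solve_deviation, 1e-10)
  resq <- update_basis_columns(B, positions = 1:m, new_cols = cols, rhs = rhs,
                               precision = "quad")
  expect_lt(resq$max_solve_deviation, 1e-25)
})

test_that("replacing a column with itself leaves solves unchanged", {
  B <- random_sparse_basis(6, 5)
  res <- update_basis_columns(B, positions = 3, new_cols = B[, 3, drop = FALSE],
                              rhs = rnorm(6))
  expect_equal(res$signals, 0)
  expect_lt(res$max_solve_deviation, 1e-12)
})

test_that("a forced tiny update pivot raises the singularity signal", {
  B <- diag(4)
  newcol <- c(1, 0, 0, 0)   # duplicate of column 1 -> singular update
  res <- update_basis_columns(B, positions = 2,
                              new_cols = matrix(newcol, 4, 1), rhs = rep(1, 4))
  expect_equal(res$signals, 2)
})
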