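# User-facing wrappers over the precision-generic sparse LU kernel:
# factorization with dependent-column detection, solves with B and B', and
# the Bartels-Golub column-update driver.  These expose the linear-algebra
# contracts (reconstruction accuracy, repair soundness, update/refactor
# equivalence) independently of the simplex loop.

.as_triplet_square <- function(B) {
  if (is.matrix(B)) {
    idx <- which(B != 0, arr.ind = TRUE)
    list(m = nrow(B), i = idx[, 1], j = idx[, 2], x = B[idx])
  } else if (is.list(B)) {
    list(m = B$m, i = B$i, j = B$j, x = B$x)
  } else stop("B must be a dense matrix or triplet list(m, i, j, x)")
}

#' Factorize a basis matrix
#'
#' Sparse LU with Markowitz-style threshold partial pivoting: a pivot is
#' admissible when \code{|pivot| >= colmax / lu_factor_tol}; among
#' admissible candidates the sparsest row wins.  Columns whose best pivot
#' falls below \code{eps^(2/3)} relative to the column norm are reported as
#' dependent (a singularity report, not an error -- the caller repairs).
#'
#' @param B square matrix (dense or triplet \code{list(m,i,j,x)})
#' @param lu_factor_tol threshold pivoting tolerance (>= 1)
#' @param precision "double" or "quad"
#' @return list: \code{dependents} (data frame of position/row),
#'   \code{reconstruction_error} (max abs deviation of L*U from B),
#'   \code{matrix_norm}
#' @export
factorize_basis <- function(B, lu_factor_tol = 1.9,
                            precision = c("double", "quad")) {
  precision <- match.arg(precision)
  tr <- .as_triplet_square(B)
  res <- cpp_lu_factor_check(tr$m, tr$i - 1L, tr$j - 1L, tr$x,
                             lu_factor_tol, precision)
  list(dependents = data.frame(position = res$dependent_positions,
                               row = res$dependent_rows),
       reconstruction_error = res$reconstruction_error,
       matrix_norm = res$matrix_norm)
}

#' Solve with the basis matrix or its transpose
#'
#' \code{B x = rhs} (or \code{B'y = rhs}) via the sparse LU factors, with
#' optional Wilkinson iterative refinement: the residual is computed in
#' compensated high precision and a correction is solved with the existing
#' factors.
#'
#' @param B square matrix or triplet list
#' @param rhs right-hand side
#' @param transpose solve with \code{B'} instead of \code{B}
#' @param refine number of refinement passes (0, 1 or 2)
#' @param lu_factor_tol pivot threshold
#' @param precision "double" or "quad"
#' @return list: solution \code{x} (+ \code{x_lo}), \code{residual_inf}
#'   and its log10
#' @export
solve_with_basis <- function(B, rhs, transpose = FALSE, refine = 1L,
                             lu_factor_tol = 1.9,
                             precision = c("double", "quad")) {
  precision <- match.arg(precision)
  tr <- .as_triplet_square(B)
  stopifnot(length(rhs) == tr$m)
  cpp_basis_solve(tr$m, tr$i - 1L, tr$j - 1L, tr$x, as.double(rhs),
                  transpose, as.integer(refine), lu_factor_tol, precision)
}

#' Sequential column updates of a factorized basis
#'
#' Starting from \code{B}, replaces columns one at a time (Bartels-Golub
#' spike elimination with threshold interchanges), solving \code{Bx = rhs}
#' after each update both through the updated factors and through a fresh
#' factorization.  Returns the per-update signals (0 ok, 1 refactorize,
#' 2 singular) and the largest relative deviation between the two solve
#' routes.
#'
#' @param B initial square matrix (dense or triplet list)
#' @param positions column positions replaced (1-based, in order)
#' @param new_cols matrix whose k-th column replaces position k
#' @param rhs right-hand side for the solve checks
#' @param lu_factor_tol,lu_update_tol pivot thresholds
#' @param precision "double" or "quad"
#' @return list with \code{signals} and \code{max_solve_deviation}
#' @export
update_basis_columns <- function(B, positions, new_cols, rhs,
                                 lu_factor_tol = 1.9, lu_update_tol = 10,
                                 precision = c("double", "quad")) {
  precision <- match.arg(precision)
  tr <- .as_triplet_square(B)
  new_cols <- as.matrix(new_cols)
  stopifnot(nrow(new_cols) == tr$m, ncol(new_cols) == length(positions))
  cpp_lu_update_driver(tr$m, tr$i - 1L, tr$j - 1L, tr$x,
                       as.integer(positions) - 1L, new_cols,
                       as.double(rhs), lu_factor_tol, lu_update_tol,
                       precision)
}
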