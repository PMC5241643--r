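#' Construct a linear optimization problem
#'
#' The single exchange container used by every module: a sparse constraint
#' matrix over reaction fluxes (or generic decision variables), per-row
#' senses, right-hand sides, optional ranges, an objective and bounds.
#' Flux-balance problems are the special case \code{Sv = 0} with
#' \code{row_sense = "E"} and \code{rhs = 0}.
#'
#' Matrix data may carry a low-order correction (\code{x_lo}, \code{rhs_lo})
#' holding digits beyond double precision; the quad solver adds the
#' correction exactly, so problem data are not limited to 16 digits.
#'
#' @param i,j,x triplet form of the m x n constraint matrix (1-based indices)
#' @param m,n dimensions
#' @param row_sense character vector: "E" (equality), "L" (<=), "G" (>=),
#'   or "R" (range: activity in \code{[rhs, rhs + range]})
#' @param rhs right-hand side per row
#' @param c_obj objective coefficients per column
#' @param lower,upper column bounds; \code{-Inf}/\code{Inf} allowed
#' @param sense "min" or "max"
#' @param range range width per row (only used for "R" rows)
#' @param x_lo,rhs_lo optional low-order parts of \code{x} and \code{rhs}
#' @param obj_constant constant added to the objective
#' @param row_names,col_names identifiers (defaults R1..Rm / C1..Cn)
#' @param name problem name
#' @return an object of class \code{lp_problem}
#' @export
lp_problem <- function(i, j, x, m, n, row_sense, rhs, c_obj,
                       lower = rep(0, n), upper = rep(Inf, n),
                       sense = "min", range = rep(NA_real_, m),
                       x_lo = rep(0, length(x)), rhs_lo = rep(0, m),
                       obj_constant = 0,
                       row_names = paste0("R", seq_len(m)),
                       col_names = paste0("C", seq_len(n)),
                       name = "LP") {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j), length(j) == length(x),
            length(x_lo) == length(x))
  if (length(x)) {  # drop explicit zeros
    keep <- x != 0 | x_lo != 0
    i <- i[keep]; j <- j[keep]; x <- x[keep]; x_lo <- x_lo[keep]
  }
  if (length(x) > 0) {
    if (min(i) < 1L || max(i) > m) stop("row index out of bounds")
    if (min(j) < 1L || max(j) > n) stop("column index out of bounds")
    if (anyDuplicated(i + (j - 1) * as.double(m)))
      stop("duplicate (row, col) entries in sparse matrix")
  }
  row_sense <- match.arg(toupper(row_sense), c("E", "L", "G", "R"),
                         several.ok = TRUE)
  if (length(row_sense) == 1L) row_sense <- rep(row_sense, m)
  stopifnot(length(row_sense) == m, length(rhs) == m, length(c_obj) == n,
            length(lower) == n, length(upper) == n)
  sense <- match.arg(sense, c("min", "max"))
  bad <- which(lower > upper)
  if (length(bad))
    stop("lower > upper for column(s): ", paste(col_names[bad], collapse = ", "))
  structure(list(
    m = as.integer(m), n = as.integer(n),
    S = list(i = i, j = j, x = as.double(x), x_lo = as.double(x_lo)),
    row_sense = row_sense, rhs = as.double(rhs), rhs_lo = as.double(rhs_lo),
    range = as.double(range), c_obj = as.double(c_obj),
    obj_constant = as.double(obj_constant),
    lower = as.double(lower), upper = as.double(upper),
    row_names = row_names, col_names = col_names,
    sense = sense, name = name
  ), class = "lp_problem")
}

#' @export
print.lp_problem <- function(x, ...) {
  st <- problem_stats(x)
  cat(sprintf("lp_problem '%s': %d rows, %d cols, %d nonzeros (%s)\n",
              x$name, x$m, x$n, st$nnz, x$sense))
  if (st$nnz > 0)
    cat(sprintf("  |S_ij| in [%.2e, %.2e]\n", st$min_abs, st$max_abs))
  invisible(x)
}

#' Constraint matrix of a problem as a sparse Matrix object
#' @param p an \code{lp_problem}
#' @return a \code{\link[Matrix]{sparseMatrix}} (low-order parts dropped)
#' @export
lp_matrix <- function(p) {
  Matrix::sparseMatrix(i = p$S$i, j = p$S$j, x = p$S$x, dims = c(p$m, p$n))
}

# per-row activity intervals [rlo, rhi] (with low-order parts) from senses
row_intervals <- function(p) {
  rlo <- rep(-Inf, p$m); rhi <- rep(Inf, p$m)
  rlo_lo <- rhi_lo <- rep(0, p$m)
  for (s in c("E", "L", "G", "R")) {
    idx <- which(p$row_sense == s)
    if (!length(idx)) next
    if (s == "E") {
      rlo[idx] <- rhi[idx] <- p$rhs[idx]
      rlo_lo[idx] <- rhi_lo[idx] <- p$rhs_lo[idx]
    } else if (s == "L") {
      rhi[idx] <- p$rhs[idx]; rhi_lo[idx] <- p$rhs_lo[idx]
    } else if (s == "G") {
      rlo[idx] <- p$rhs[idx]; rlo_lo[idx] <- p$rhs_lo[idx]
    } else {
      rng <- p$range[idx]
      if (any(is.na(rng))) stop("R rows must carry a range width")
      rlo[idx] <- p$rhs[idx]; rlo_lo[idx] <- p$rhs_lo[idx]
      rhi[idx] <- p$rhs[idx] + abs(rng); rhi_lo[idx] <- p$rhs_lo[idx]
    }
  }
  list(rlo = rlo, rhi = rhi, rlo_lo = rlo_lo, rhi_lo = rhi_lo)
}

#' Convert a problem to computational standard form
#'
#' Appends one slack column per row (coefficient -1) so that every
#' constraint becomes \code{A x = 0} with all sense and range information
#' carried in the slack bounds (the slack equals the row activity).
#' Maximization is converted to minimization by negating the objective;
#' the sign is recorded so results can be reported on the original scale.
#'
#' @param p an \code{lp_problem}
#' @return an object of class \code{lp_standard_form}
#' @export
to_computational_form <- function(p) {
  stopifnot(inherits(p, "lp_problem"))
  bad <- which(p$lower > p$upper)
  if (length(bad))
    stop("infeasible bounds (lower > upper) for column(s): ",
         paste(p$col_names[bad], collapse = ", "))
  ri <- row_intervals(p)
  m <- p$m; n <- p$n; ntot <- n + m
  i0 <- c(p$S$i, seq_len(m)) - 1L
  j0 <- c(p$S$j, n + seq_len(m)) - 1L
  x  <- c(p$S$x, rep(-1, m))
  xl <- c(p$S$x_lo, rep(0, m))
  ord <- order(j0, i0)
  i0 <- i0[ord]; j0 <- j0[ord]; x <- x[ord]; xl <- xl[ord]
  ap <- c(0L, cumsum(tabulate(j0 + 1L, nbins = ntot)))
  obj_sign <- if (p$sense == "max") -1 else 1
  structure(list(
    m = m, n_struct = n, ntot = ntot,
    ap = as.integer(ap), ai = as.integer(i0), ax = x, ax_lo = xl,
    c = c(obj_sign * p$c_obj, rep(0, m)),
    lower = c(p$lower, ri$rlo), upper = c(p$upper, ri$rhi),
    lower_lo = c(rep(0, n), ri$rlo_lo), upper_lo = c(rep(0, n), ri$rhi_lo),
    obj_sign = obj_sign, obj_constant = p$obj_constant,
    problem = p
  ), class = "lp_standard_form")
}

#' Summary statistics of a problem
#'
#' Reports the dimensions, nonzero count and the magnitude ranges of the
#' structural matrix entries, bounds and right-hand sides -- the quantities
#' used to characterize multiscale instances.
#'
#' @param p an \code{lp_problem}
#' @return a list with \code{m}, \code{n}, \code{nnz}, \code{max_abs},
#'   \code{min_abs}, \code{coefficient_decades}, and bound/rhs ranges
#' @export
problem_stats <- function(p) {
  stopifnot(inherits(p, "lp_problem"))
  ax <- abs(p$S$x[p$S$x != 0])
  fin_b <- abs(c(p$lower, p$upper))
  fin_b <- fin_b[is.finite(fin_b) & fin_b != 0]
  fin_r <- abs(p$rhs[p$rhs != 0])
  res <- list(
    m = p$m, n = p$n, nnz = length(ax),
    max_abs = if (length(ax)) max(ax) else 0,
    min_abs = if (length(ax)) min(ax) else 0,
    coefficient_decades = if (length(ax)) log10(max(ax) / min(ax)) else 0,
    bound_range = if (length(fin_b)) range(fin_b) else c(0, 0),
    rhs_range = if (length(fin_r)) range(fin_r) else c(0, 0)
  )
  class(res) <- "lp_problem_stats"
  res
}

#' @export
print.lp_problem_stats <- function(x, ...) {
  cat(sprintf("m=%d n=%d nnz=%d max|S_ij|=%.4g min|S_ij|=%.4g (%.1f decades)\n",
              x$m, x$n, x$nnz, x$max_abs, x$min_abs, x$coefficient_decades))
  invisible(x)
}
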