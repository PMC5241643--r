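# Exhaustive basic-solution enumeration: an independent optimum oracle for
# small instances (m + n up to ~12).  Enumerates every basis of the slack
# computational form crossed with every nonbasic bound assignment, keeps
# the feasible basic solutions, and (optionally) re-solves the candidate
# vertices in compensated high precision so the reported objective is
# accurate far beyond double rounding.  Deliberately shares no code with
# the simplex engine's factorization or pivoting paths.

#' Exhaustive vertex-enumeration LP oracle
#'
#' @param p an \code{lp_problem} with finite variable bounds (slacks from
#'   inequality rows may be one-sided)
#' @param feas_tol feasibility tolerance for accepting a basic solution
#' @param refine re-solve near-optimal vertices in high precision
#' @return list: \code{status} ("optimal" or "infeasible"),
#'   \code{objective} (+ \code{objective_lo}), \code{v} (an optimal
#'   vertex, structurals then slacks)
#' @export
lp_vertex_oracle <- function(p, feas_tol = 1e-7, refine = TRUE) {
  form <- to_computational_form(p)
  m <- form$m; N <- form$ntot
  if (choose(N, m) > 20000) stop("problem too large for the enumeration oracle")
  A <- matrix(0, m, N)
  jj <- rep(seq_len(N), diff(form$ap))
  A[cbind(form$ai + 1L, jj)] <- form$ax
  l <- form$lower; u <- form$upper
  cvec <- form$c
  tolv <- function(b) feas_tol * (1 + ifelse(is.finite(b), abs(b), 0))
  best <- Inf; best_x <- NULL; cands <- list()
  bases <- utils::combn(N, m)
  for (kb in seq_len(ncol(bases))) {
    Bset <- bases[, kb]
    AB <- A[, Bset, drop = FALSE]
    ok <- tryCatch({ qr(AB)$rank == m }, error = function(e) FALSE)
    if (!ok) next
    Nset <- setdiff(seq_len(N), Bset)
    opts <- lapply(Nset, function(j) {
      o <- c()
      if (is.finite(l[j])) o <- c(o, l[j])
      if (is.finite(u[j]) && u[j] != l[j]) o <- c(o, u[j])
      if (!length(o)) o <- 0  # free nonbasic rests at zero
      o
    })
    combos <- as.matrix(expand.grid(opts, KEEP.OUT.ATTRS = FALSE))
    if (!nrow(combos)) combos <- matrix(0, 1, 0)
    RHS <- -A[, Nset, drop = FALSE] %*% t(combos)
    XB <- tryCatch(solve(AB, RHS), error = function(e) NULL)
    if (is.null(XB)) next
    XB <- matrix(XB, nrow = m)
    for (cc in seq_len(ncol(XB))) {
      xb <- XB[, cc]
      if (any(xb < l[Bset] - tolv(l[Bset])) ||
          any(xb > u[Bset] + tolv(u[Bset]))) next
      x <- numeric(N)
      x[Bset] <- xb
      x[Nset] <- combos[cc, ]
      obj <- sum(cvec * x)
      if (obj < best) best <- obj
      cands[[length(cands) + 1L]] <- list(obj = obj, Bset = Bset,
                                          xN = x[Nset], Nset = Nset, x = x)
    }
  }
  if (!length(cands))
    return(list(status = "infeasible", objective = NA_real_,
                objective_lo = NA_real_, v = NULL))
  keep <- Filter(function(cd) cd$obj <= best + 1e-6 * (1 + abs(best)), cands)
  if (!refine) {
    w <- which.min(vapply(keep, `[[`, 0, "obj"))
    cd <- keep[[w]]
    return(list(status = "optimal", objective = cd$obj, objective_lo = 0,
                v = cd$x))
  }
  # high-precision re-solve of each candidate vertex
  bh <- Inf; bl <- 0; bx <- NULL
  for (cd in keep) {
    AB <- A[, cd$Bset, drop = FALSE]
    rhs <- as.vector(-A[, cd$Nset, drop = FALSE] %*% cd$xN)
    sol <- cpp_dense_solve_qd(AB, rhs)
    xh <- numeric(N); xl <- numeric(N)
    xh[cd$Bset] <- sol$x; xl[cd$Bset] <- sol$x_lo
    xh[cd$Nset] <- cd$xN
    dot <- cpp_matvec_qd(1L, rep(0L, N), 0:(N - 1L), cvec, xh, xl)
    if (dot$hi < bh || (dot$hi == bh && dot$lo < bl)) {
      bh <- dot$hi; bl <- dot$lo; bx <- xh
    }
  }
  list(status = "optimal",
       objective = form$obj_sign * bh + form$obj_constant,
       objective_lo = form$obj_sign * bl,
       v = bx)
}
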