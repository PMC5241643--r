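# ME/FBA formulation layer: flux-coupling constraints, coefficient lifting,
# stoichiometric-consistency screening, flux variability analysis, and
# growth-rate bisection.

#' Append flux-coupling constraints
#'
#' A coupling \code{c_min <= v_i / v_j <= c_max} between two nonnegative
#' fluxes becomes the linear pair \code{v_i - c_max v_j <= 0} and
#' \code{-v_i + c_min v_j <= 0} (the second is omitted when
#' \code{c_min = 0}).  With a mu-dependence \code{(i, j, k_eff)} the upper
#' coefficient is \code{c_max = mu / k_eff}, the standard form of
#' growth-rate-dependent coupling between catalytic usage and synthesis.
#'
#' @param p an \code{lp_problem}
#' @param pairs data frame with columns \code{i}, \code{j}, and either
#'   \code{c_min}/\code{c_max} or \code{k_eff}
#' @param mu growth rate used for rows given via \code{k_eff}
#' @return the extended \code{lp_problem}
#' @export
add_coupling_constraints <- function(p, pairs, mu = 1) {
  stopifnot(inherits(p, "lp_problem"), is.data.frame(pairs))
  if (!NROW(pairs)) return(p)
  if (!"c_max" %in% names(pairs)) pairs$c_max <- NA_real_
  if (!"c_min" %in% names(pairs)) pairs$c_min <- 0
  if ("k_eff" %in% names(pairs)) {
    use <- !is.na(pairs$k_eff)
    if (any(pairs$k_eff[use] <= 0)) stop("k_eff must be finite positive")
    pairs$c_max[use] <- mu / pairs$k_eff[use]
  }
  if (any(is.na(pairs$c_max))) stop("each pair needs c_max or k_eff")
  if (any(pairs$c_min < 0) || any(pairs$c_max < pairs$c_min))
    stop("coupling requires 0 <= c_min <= c_max")
  bad <- p$lower[pairs$i] < 0 | p$lower[pairs$j] < 0
  if (any(bad))
    stop("coupled fluxes must be nonnegative (ratio coupling presumes v >= 0): ",
         paste(unique(p$col_names[c(pairs$i[bad], pairs$j[bad])]), collapse = ", "))
  new_i <- integer(); new_j <- integer(); new_x <- double()
  names_new <- character()
  row <- p$m
  for (k in seq_len(NROW(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    row <- row + 1L
    new_i <- c(new_i, row, row); new_j <- c(new_j, i, j)
    new_x <- c(new_x, 1, -pairs$c_max[k])
    names_new <- c(names_new, sprintf("CPL_%s_%s_U", p$col_names[i], p$col_names[j]))
    if (pairs$c_min[k] > 0) {
      row <- row + 1L
      new_i <- c(new_i, row, row); new_j <- c(new_j, i, j)
      new_x <- c(new_x, -1, pairs$c_min[k])
      names_new <- c(names_new, sprintf("CPL_%s_%s_L", p$col_names[i], p$col_names[j]))
    }
  }
  n_new <- row - p$m
  lp_problem(i = c(p$S$i, new_i), j = c(p$S$j, new_j),
             x = c(p$S$x, new_x), x_lo = c(p$S$x_lo, rep(0, length(new_x))),
             m = row, n = p$n,
             row_sense = c(p$row_sense, rep("L", n_new)),
             rhs = c(p$rhs, rep(0, n_new)),
             rhs_lo = c(p$rhs_lo, rep(0, n_new)),
             range = c(p$range, rep(NA_real_, n_new)),
             c_obj = p$c_obj, lower = p$lower, upper = p$upper,
             sense = p$sense, obj_constant = p$obj_constant,
             row_names = c(p$row_names, names_new), col_names = p$col_names,
             name = p$name)
}

#' Lift large matrix coefficients
#'
#' Reduces the largest entries by introducing auxiliary variables and
#' equality rows: an entry \code{K = S_ij} with \code{|K| > tau} is split
#' into a balanced power-of-two factorization \code{K = K1 * K2}
#' (\code{K1 = 2^round(log2|K|/2)}), the auxiliary row \code{K1 v_j - w = 0}
#' is added, and the entry is replaced by \code{sign(K) K2} on \code{w}.
#' Because the split is exact in binary floating point, the optimal
#' objective is provably unchanged.  Applied recursively until no entry
#' exceeds \code{tau}.
#'
#' @param p an \code{lp_problem}
#' @param tau magnitude threshold (> 1)
#' @return the lifted \code{lp_problem}
#' @export
lift_large_coefficients <- function(p, tau) {
  stopifnot(inherits(p, "lp_problem"))
  if (tau < 1) stop("tau must be >= 1")
  repeat {
    big <- which(abs(p$S$x) > tau)
    if (!length(big)) return(p)
    i <- p$S$i; j <- p$S$j; x <- p$S$x; x_lo <- p$S$x_lo
    m <- p$m; n <- p$n
    add_i <- integer(); add_j <- integer(); add_x <- double()
    row_names <- p$row_names; col_names <- p$col_names
    for (k in big) {
      K <- x[k]; sgn <- sign(K)
      K1 <- 2^round(log2(abs(K)) / 2)
      K2 <- abs(K) / K1   # exact: division by a power of two
      n <- n + 1L; m <- m + 1L
      col_names <- c(col_names, sprintf("LFT%d", n))
      row_names <- c(row_names, sprintf("LFTR%d", m))
      # auxiliary row: K1 * v_j - w = 0
      add_i <- c(add_i, m, m); add_j <- c(add_j, j[k], n)
      add_x <- c(add_x, K1, -1)
      # original entry now sign * K2 on w
      j[k] <- n; x[k] <- sgn * K2; x_lo[k] <- 0
    }
    n_newc <- n - p$n; n_newr <- m - p$m
    p <- lp_problem(i = c(i, add_i), j = c(j, add_j), x = c(x, add_x),
                    x_lo = c(x_lo, rep(0, length(add_x))),
                    m = m, n = n,
                    row_sense = c(p$row_sense, rep("E", n_newr)),
                    rhs = c(p$rhs, rep(0, n_newr)),
                    rhs_lo = c(p$rhs_lo, rep(0, n_newr)),
                    range = c(p$range, rep(NA_real_, n_newr)),
                    c_obj = c(p$c_obj, rep(0, n_newc)),
                    lower = c(p$lower, rep(-Inf, n_newc)),
                    upper = c(p$upper, rep(Inf, n_newc)),
                    sense = p$sense, obj_constant = p$obj_constant,
                    row_names = row_names, col_names = col_names,
                    name = p$name)
  }
}

#' Stoichiometric consistency screening
#'
#' A network is stoichiometrically consistent when strictly positive
#' molecular masses \code{l} with \code{S'l = 0} exist.  The cardinality
#' problem is approximated by the linear relaxation: maximize
#' \code{sum(z)} subject to \code{S'l = 0}, \code{z <= l},
#' \code{0 <= z <= alpha}, \code{0 <= l <= beta}, solved with the DQQ
#' backend; rows whose optimal \code{l_i} falls below \code{alpha} are
#' flagged as inconsistency candidates.
#'
#' @param S an \code{lp_problem} (its matrix is used) or triplet list with
#'   \code{m}, \code{n}, \code{i}, \code{j}, \code{x}
#' @param alpha smallest mass considered nonzero (default 1e-4)
#' @param beta largest mass allowed (default 1e4)
#' @return list: \code{masses} (l per row), \code{flagged} (row indices),
#'   \code{all_flagged} (TRUE when only l = 0 is feasible), the DQQ report
#' @export
consistency_check <- function(S, alpha = 1e-4, beta = 1e4) {
  stopifnot(alpha > 0, beta > alpha)
  tr <- if (inherits(S, "lp_problem"))
          list(m = S$m, n = S$n, i = S$S$i, j = S$S$j, x = S$S$x)
        else S
  mS <- tr$m; nS <- tr$n
  # variables: l (mS), z (mS); rows: S'l = 0 (nS), z - l <= 0 (mS)
  i <- c(tr$j, seq_len(mS) + nS, seq_len(mS) + nS)
  j <- c(tr$i, seq_len(mS) + mS, seq_len(mS))
  x <- c(tr$x, rep(1, mS), rep(-1, mS))
  prob <- lp_problem(i = i, j = j, x = x, m = nS + mS, n = 2L * mS,
                     row_sense = c(rep("E", nS), rep("L", mS)),
                     rhs = rep(0, nS + mS),
                     c_obj = c(rep(0, mS), rep(1, mS)),
                     lower = rep(0, 2 * mS),
                     upper = c(rep(beta, mS), rep(alpha, mS)),
                     sense = "max", name = "consistency")
  rep <- run_dqq(prob)
  masses <- rep$v[seq_len(mS)]
  flagged <- which(masses < alpha * (1 - 1e-9))
  list(masses = masses, flagged = flagged,
       all_flagged = length(flagged) == mS, report = rep)
}

#' Flux variability analysis
#'
#' After an optimal solve with objective value \code{Z0}, each requested
#' flux is minimized and maximized subject to the original constraints
#' plus the near-optimality row (for maximization problems
#' \code{c'v >= gamma Z0} when \code{Z0 >= 0}, \code{c'v >= Z0/gamma}
#' otherwise; mirrored for minimization), so the restriction always
#' contains the incumbent optimum.  Consecutive solves warm-start from the
#' previous optimal basis.
#'
#' @param p an \code{lp_problem} with a nonzero objective
#' @param gamma fraction of the optimal objective retained, in (0, 1]
#' @param indices flux indices to analyze (default all structurals)
#' @param warm warm-start consecutive solves (default TRUE)
#' @param opts solver options for the subproblems (default quad, scaled)
#' @param sol optional \code{simplex_result}/\code{dqq_report} for \code{p}
#'   (solved if missing)
#' @return object of class \code{fva_result}: data frame with per-flux
#'   \code{min}/\code{max} and statuses, plus \code{gamma}, \code{Z0}
#' @export
flux_variability <- function(p, gamma = 0.99, indices = seq_len(p$n),
                             warm = TRUE, opts = NULL, sol = NULL) {
  stopifnot(inherits(p, "lp_problem"), gamma > 0, gamma <= 1)
  if (is.null(opts))
    opts <- solver_options(precision = "quad", scale = TRUE,
                           feasibility_tol = 1e-15, optimality_tol = 1e-15,
                           lu_factor_tol = 10, lu_update_tol = 10)
  if (is.null(sol)) sol <- run_dqq(p)
  if (sol$status != "optimal") stop("FVA requires an optimal base solution")
  Z0 <- sol$objective
  has_obj <- any(p$c_obj != 0)
  q <- p
  if (has_obj) {
    bound <- if (p$sense == "max") {
      if (Z0 >= 0) gamma * Z0 else Z0 / gamma
    } else {
      if (Z0 >= 0) Z0 / gamma else gamma * Z0
    }
    nz <- which(p$c_obj != 0)
    q <- lp_problem(i = c(p$S$i, rep(p$m + 1L, length(nz))),
                    j = c(p$S$j, nz),
                    x = c(p$S$x, p$c_obj[nz]),
                    x_lo = c(p$S$x_lo, rep(0, length(nz))),
                    m = p$m + 1L, n = p$n,
                    row_sense = c(p$row_sense,
                                  if (p$sense == "max") "G" else "L"),
                    rhs = c(p$rhs, bound - p$obj_constant),
                    rhs_lo = c(p$rhs_lo, 0),
                    range = c(p$range, NA_real_),
                    c_obj = p$c_obj, lower = p$lower, upper = p$upper,
                    sense = p$sense, obj_constant = p$obj_constant,
                    row_names = c(p$row_names, "FVA_OBJ"),
                    col_names = p$col_names, name = p$name)
  }
  start <- NULL
  out <- data.frame(index = indices, min = NA_real_, max = NA_real_,
                    status_min = "", status_max = "",
                    stringsAsFactors = FALSE)
  for (r in seq_along(indices)) {
    jx <- indices[r]
    for (dirn in c("min", "max")) {
      qj <- q
      qj$c_obj <- rep(0, q$n); qj$c_obj[jx] <- 1
      qj$obj_constant <- 0
      qj$sense <- dirn
      res <- primal_simplex(qj, opts, start = start)
      if (res$status == "infeasible")
        stop("FVA gamma-row renders the problem infeasible (inconsistent Z0)")
      if (res$status %in% c("optimal", "unbounded") && warm)
        start <- res$basis
      val <- if (res$status == "unbounded")
               (if (dirn == "min") -Inf else Inf) else res$objective
      out[[dirn]][r] <- val
      out[[paste0("status_", dirn)]][r] <- res$status
    }
  }
  structure(list(ranges = out, gamma = gamma, Z0 = Z0),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat(sprintf("FVA at gamma = %g (Z0 = %.8g):\n", x$gamma, x$Z0))
  print(x$ranges)
  invisible(x)
}

#' Growth-rate feasibility boundary by bisection
#'
#' For a family of linear problems parameterized by the growth rate mu
#' (coupling constraints with \code{c_max = mu/k_eff} become linear at
#' fixed mu), locates the feasibility boundary mu* by bisection, assuming
#' feasibility is monotone in mu.  Either orientation is accepted:
#' feasible-below/infeasible-above returns the largest feasible mu;
#' the mirrored case returns the smallest feasible mu.  Each feasibility
#' test is a quad phase-1 solve warm-started from the previous test's
#' basis.
#'
#' @param builder function(mu) returning an \code{lp_problem} (constant
#'   dimensions across mu)
#' @param mu_lo,mu_hi bracketing interval endpoints
#' @param tol_mu interval tolerance
#' @param opts solver options for the feasibility solves
#' @return list: \code{mu_star}, \code{feasible_at} (last feasible mu
#'   tested), \code{n_solves}, \code{orientation}
#' @export
max_growth_bisection <- function(builder, mu_lo, mu_hi, tol_mu = 1e-6,
                                 opts = NULL) {
  stopifnot(mu_lo < mu_hi, tol_mu > 0)
  if (is.null(opts))
    opts <- solver_options(precision = "quad", scale = TRUE,
                           feasibility_tol = 1e-15, optimality_tol = 1e-15,
                           lu_factor_tol = 10, lu_update_tol = 10)
  start <- NULL
  nsolve <- 0L
  feas <- function(mu) {
    q <- builder(mu)
    q$c_obj <- rep(0, q$n)   # pure feasibility (phase 1)
    res <- primal_simplex(q, opts, start = start)
    nsolve <<- nsolve + 1L
    if (res$status == "optimal") start <<- res$basis
    res$status == "optimal"
  }
  flo <- feas(mu_lo); fhi <- feas(mu_hi)
  if (flo == fhi)
    stop("bisection requires opposite feasibility at the endpoints; ",
         "adjust [mu_lo, mu_hi]")
  orientation <- if (flo) "decreasing" else "increasing"
  lo <- mu_lo; hi <- mu_hi
  while (hi - lo > tol_mu) {
    mid <- (lo + hi) / 2
    fm <- feas(mid)
    keep_lo <- if (orientation == "decreasing") fm else !fm
    if (keep_lo) lo <- mid else hi <- mid
  }
  mu_star <- if (orientation == "decreasing") lo else hi
  list(mu_star = mu_star,
       feasible_at = if (orientation == "decreasing") lo else hi,
       n_solves = nsolve, orientation = orientation,
       interval = c(lo, hi))
}
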