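# Revised primal simplex front-end: options, warm starts, certification.

#' Solver options
#'
#' Runtime options of one simplex run: arithmetic precision, scaling,
#' feasibility/optimality tolerances (delta1, delta2), the EXPAND
#' anti-degeneracy frequency, LU factor/update tolerances, limits.
#' Tolerances are interpreted relative with the \code{(1 + |.|)} convention.
#'
#' @param precision "double" (~16 digits) or "quad" (~34 digits)
#' @param scale scale the problem before solving (geometric-mean)
#' @param feasibility_tol primal tolerance delta1
#' @param optimality_tol dual tolerance delta2
#' @param expand_frequency EXPAND reset frequency (iterations)
#' @param lu_factor_tol,lu_update_tol threshold-pivoting tolerances (>= 1)
#' @param iteration_limit simplex iteration limit
#' @param refactor_frequency basis refactorization interval (default 100)
#' @param refine_passes Wilkinson refinement passes on each basis solve
#' @param expand EXPAND anti-degeneracy on/off (off reproduces the classic
#'   textbook ratio test; used to demonstrate stalling/cycling)
#' @param pricing only "dantzig" is implemented; the flag is reserved
#' @return an object of class \code{solver_options}
#' @export
solver_options <- function(precision = c("double", "quad"), scale = TRUE,
                           feasibility_tol = 1e-7, optimality_tol = 1e-7,
                           expand_frequency = 100000L,
                           lu_factor_tol = 1.9, lu_update_tol = 1.9,
                           iteration_limit = 100000L,
                           refactor_frequency = 100L, refine_passes = 1L,
                           expand = TRUE, pricing = "dantzig") {
  precision <- match.arg(precision)
  stopifnot(feasibility_tol > 0, optimality_tol > 0, expand_frequency >= 1,
            lu_factor_tol >= 1, lu_update_tol >= 1)
  structure(list(precision = precision, scale = scale,
                 feas_tol = feasibility_tol, opt_tol = optimality_tol,
                 expand_frequency = as.integer(expand_frequency),
                 lu_factor_tol = lu_factor_tol, lu_update_tol = lu_update_tol,
                 iteration_limit = as.integer(iteration_limit),
                 refactor_frequency = as.integer(refactor_frequency),
                 refine_passes = as.integer(refine_passes),
                 expand = isTRUE(expand), pricing = pricing),
            class = "solver_options")
}

.status_names <- c("optimal", "infeasible", "unbounded", "iteration_limit",
                   "numeric_error")

#' Basis state constructor
#'
#' Statuses per variable (structurals then slacks): 0 basic, 1 nonbasic at
#' lower bound, 2 nonbasic at upper bound, 3 nonbasic free.
#'
#' @param vstat integer status vector of length n + m
#' @param m number of rows (basic variables)
#' @return object of class \code{basis_state}
#' @export
basis_state <- function(vstat, m) {
  vstat <- as.integer(vstat)
  if (sum(vstat == 0L) != m)
    stop("a basis must have exactly m basic variables")
  structure(list(vstat = vstat, m = as.integer(m),
                 basic = which(vstat == 0L)),
            class = "basis_state")
}

#' Repair a basis by substituting slack unit columns
#'
#' Each dependent basic column is replaced by the slack of its row (the
#' displaced variable becomes nonbasic); if that slack is already basic,
#' another row's nonbasic slack is used.  Mirrors the repair the solver
#' performs internally when the factorization reports near-singularity.
#'
#' @param basis a \code{basis_state}
#' @param dependents data frame with \code{position} (basis position) and
#'   \code{row} (1-based row of the failing pivot)
#' @param n_struct number of structural columns
#' @return repaired \code{basis_state}
#' @export
repair_basis <- function(basis, dependents, n_struct) {
  vstat <- basis$vstat
  m <- basis$m
  if (NROW(dependents) == 0) return(basis)
  basic <- which(vstat == 0L)
  used <- rep(FALSE, m)
  for (k in seq_len(NROW(dependents))) {
    pos <- dependents$position[k]
    row <- dependents$row[k]
    sl <- n_struct + row
    if (vstat[sl] != 0L && !used[row]) {
      target <- sl; used[row] <- TRUE
    } else {
      free_rows <- which(vstat[n_struct + seq_len(m)] != 0L & !used)
      if (!length(free_rows))
        stop("fatal rank error: no nonbasic slack available for repair")
      target <- n_struct + free_rows[1]; used[free_rows[1]] <- TRUE
    }
    old <- basic[pos]
    vstat[old] <- 1L       # nonbasic (caller chooses exact bound on reload)
    vstat[target] <- 0L
  }
  basis_state(vstat, m)
}

# low-level cpp call on a (possibly scaled) standard form
.simplex_core <- function(form, opts, start = NULL) {
  warm <- if (!is.null(start)) as.integer(start$vstat) else NULL
  cpp_simplex(form$m, form$ntot, form$n_struct, form$ap, form$ai,
              form$ax, form$ax_lo, form$c,
              form$lower, form$lower_lo, form$upper, form$upper_lo,
              list(feas_tol = opts$feas_tol, opt_tol = opts$opt_tol,
                   lu_factor_tol = opts$lu_factor_tol,
                   lu_update_tol = opts$lu_update_tol,
                   expand_frequency = opts$expand_frequency,
                   iteration_limit = opts$iteration_limit,
                   refactor_frequency = opts$refactor_frequency,
                   refine_passes = opts$refine_passes,
                   expand = opts$expand),
              warm, opts$precision)
}

#' Revised primal simplex
#'
#' Solves an \code{lp_problem} (or prepared \code{lp_standard_form}) by the
#' revised primal simplex method (phases 1 and 2) in the requested
#' precision, with EXPAND anti-degeneracy, optional geometric-mean scaling,
#' and warm starts from a \code{basis_state}.  On return, Pinf and Dinf are
#' certified on the ORIGINAL unscaled data in compensated high precision.
#'
#' @param p an \code{lp_problem} or \code{lp_standard_form}
#' @param opts a \code{solver_options}
#' @param start optional \code{basis_state} warm start
#' @return object of class \code{simplex_result}: \code{status}, primal
#'   values \code{v} (structurals then slacks), duals \code{y}, reduced
#'   costs \code{z}, \code{objective} (original sense), iteration counts,
#'   certified \code{pinf}/\code{dinf} with log10 displays, and the final
#'   \code{basis}
#' @export
primal_simplex <- function(p, opts = solver_options(), start = NULL) {
  form <- if (inherits(p, "lp_standard_form")) p else to_computational_form(p)
  prob <- form$problem
  sc <- NULL
  sf <- form
  if (isTRUE(opts$scale) && any(prob$S$x != 0)) {
    sc <- compute_scales(prob, round_pow2 = TRUE)
    sf <- apply_scaling(form, sc)
  }
  res <- .simplex_core(sf, opts, start)
  x <- res$x; x_lo <- res$x_lo; y <- res$y; y_lo <- res$y_lo
  if (!is.null(sc)) {
    colsc <- c(sc$col_scales, 1 / sc$row_scales)
    x <- x / colsc; x_lo <- x_lo / colsc
    y <- y / sc$row_scales; y_lo <- y_lo / sc$row_scales
  }
  basis <- basis_state(res$vstat, form$m)
  cert <- compute_infeasibilities(prob, x, y, basis,
                                  x_lo = x_lo, y_lo = y_lo,
                                  internal_sense = TRUE)
  obj_min <- cert$objective
  objective <- form$obj_sign * obj_min + form$obj_constant
  structure(list(
    status = .status_names[res$status + 1L],
    v = x, v_lo = x_lo,
    y = form$obj_sign * y, y_lo = form$obj_sign * y_lo,
    z = form$obj_sign * cert$z, z_lo = form$obj_sign * cert$z_lo,
    objective = objective,
    objective_lo = form$obj_sign * cert$objective_lo,
    objective_solver = form$obj_sign * res$objective + form$obj_constant,
    iterations = res$iterations,
    degenerate_iterations = res$degenerate_iterations,
    phase1_iterations = res$phase1_iterations,
    pinf = cert$pinf, dinf = cert$dinf,
    pinf_log10 = cert$pinf_log10, dinf_log10 = cert$dinf_log10,
    pinf_scaled = res$pinf, dinf_scaled = res$dinf,
    basis = basis,
    n_singular = res$n_singular, n_repair = res$n_repair,
    opts = opts
  ), class = "simplex_result")
}

#' @export
print.simplex_result <- function(x, ...) {
  cat(sprintf("simplex (%s%s): %s, obj = %.12g, itns = %d (degen %d)\n",
              x$opts$precision, if (x$opts$scale) ", scaled" else "",
              x$status, x$objective, x$iterations, x$degenerate_iterations))
  cat(sprintf("  Pinf = %.3g (log10 %s)   Dinf = %.3g (log10 %s)\n",
              x$pinf, .log10_cell(x$pinf_log10),
              x$dinf, .log10_cell(x$dinf_log10)))
  invisible(x)
}

.log10_cell <- function(l10) {
  if (!is.finite(l10)) "—" else sprintf("%+d", as.integer(floor(l10)))
}

#' Maximum primal and dual infeasibilities of a candidate point
#'
#' Computed on the original (unscaled) problem data in compensated
#' high-precision arithmetic (~68 decimal digits).  Pinf is the largest
#' violation of row activities beyond their sense and of variable bounds;
#' Dinf is the largest reduced-cost sign violation given each variable's
#' basis status (nonbasic at lower: \code{max(0, -z_j)}; at upper:
#' \code{max(0, z_j)}; basic or free: \code{|z_j|}).  Slacks are included
#' (the slack reduced cost is \code{y_i}).
#'
#' @param p an \code{lp_problem}
#' @param v primal values, structurals then slacks (length n + m), in the
#'   minimized orientation used by the solver
#' @param y duals per row
#' @param basis a \code{basis_state} (statuses decide the sign conditions)
#' @param v_lo,x_lo,y_lo optional low-order parts
#' @param internal_sense if TRUE, \code{y} is already in minimized
#'   orientation (internal use); otherwise a "max" problem's duals are
#'   negated before the check
#' @return list with \code{pinf}, \code{dinf}, their log10 displays, the
#'   objective \code{c'v} (minimized orientation) and reduced costs
#' @export
compute_infeasibilities <- function(p, v, y, basis, v_lo = NULL, y_lo = NULL,
                                    x_lo = NULL, internal_sense = FALSE) {
  stopifnot(inherits(p, "lp_problem"))
  if (is.null(v_lo)) v_lo <- if (!is.null(x_lo)) x_lo else rep(0, length(v))
  if (is.null(y_lo)) y_lo <- rep(0, length(y))
  obj_sign <- if (p$sense == "max") -1 else 1
  if (!internal_sense && obj_sign < 0) { y <- -y; y_lo <- -y_lo }
  ri <- row_intervals(p)
  vstat <- if (inherits(basis, "basis_state")) basis$vstat else as.integer(basis)
  cmin <- obj_sign * p$c_obj
  res <- cpp_infeasibilities(p$m, p$n, p$S$i - 1L, p$S$j - 1L, p$S$x, p$S$x_lo,
                             ri$rlo, ri$rlo_lo, ri$rhi, ri$rhi_lo,
                             p$lower, p$upper, cmin,
                             v[seq_len(p$n)], v_lo[seq_len(p$n)],
                             y, y_lo, vstat)
  res
}
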