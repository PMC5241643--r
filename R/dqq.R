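# The three-step DQQ driver: Double scaled -> Quad scaled (warm start) ->
# Quad unscaled (warm start), each step with its own runtime options, and
# report tables giving per-step objective, iterations, Pinf and Dinf.

#' Default runtime options of each DQQ step
#'
#' Step D: double precision, scaling on, delta1 = delta2 = 1e-7, EXPAND
#' frequency 100000, LU factor/update tolerances 1.9/1.9.  Step Q1: quad,
#' scaling on, delta = 1e-15, LU tolerances 10.0/10.0.  Step Q2: quad, no
#' scaling, delta = 1e-15, LU tolerances 5.0/5.0.
#'
#' @param step "D", "Q1" or "Q2"
#' @return a \code{solver_options}
#' @export
default_options <- function(step = c("D", "Q1", "Q2")) {
  step <- match.arg(step)
  switch(step,
    D  = solver_options(precision = "double", scale = TRUE,
                        feasibility_tol = 1e-7, optimality_tol = 1e-7,
                        expand_frequency = 100000L,
                        lu_factor_tol = 1.9, lu_update_tol = 1.9),
    Q1 = solver_options(precision = "quad", scale = TRUE,
                        feasibility_tol = 1e-15, optimality_tol = 1e-15,
                        expand_frequency = 100000L,
                        lu_factor_tol = 10.0, lu_update_tol = 10.0),
    Q2 = solver_options(precision = "quad", scale = FALSE,
                        feasibility_tol = 1e-15, optimality_tol = 1e-15,
                        expand_frequency = 100000L,
                        lu_factor_tol = 5.0, lu_update_tol = 5.0))
}

#' Run the DQQ procedure
#'
#' Step D applies the double-precision solver with scaling (optionally
#' under an iteration limit).  Its final basis warm-starts the quad solver
#' with scaling (Q1; statuses carried over verbatim, basic values
#' recomputed in quad).  Q1's basis warm-starts the quad solver on the
#' unscaled data (Q2), which certifies the 1e-15 tolerances on the original
#' problem.  An infeasibility claim by step D is re-verified in quad before
#' being reported.
#'
#' @param p an \code{lp_problem}
#' @param d_options,q1_options,q2_options per-step option overrides
#' @param d_iteration_limit iteration limit for step D (default
#'   \code{5 * (m + n)})
#' @return object of class \code{dqq_report}: per-step reports, final
#'   solution at quad precision, certified Pinf/Dinf, and notes
#' @export
run_dqq <- function(p, d_options = default_options("D"),
                    q1_options = default_options("Q1"),
                    q2_options = default_options("Q2"),
                    d_iteration_limit = NULL) {
  stopifnot(inherits(p, "lp_problem"))
  if (is.null(d_iteration_limit)) d_iteration_limit <- 5L * (p$m + p$n)
  d_options$iteration_limit <- as.integer(d_iteration_limit)
  notes <- character()
  t0 <- proc.time()[3]
  resD <- primal_simplex(p, d_options)
  tD <- proc.time()[3] - t0
  if (resD$status == "iteration_limit")
    notes <- c(notes, sprintf("step D hit its iteration limit (%d); Q1 continues from its basis",
                              d_iteration_limit))
  startQ1 <- resD$basis
  if (resD$status == "numeric_error") {
    notes <- c(notes, "step D failed numerically; Q1 cold-starts from the slack basis")
    startQ1 <- NULL
  }
  t0 <- proc.time()[3]
  resQ1 <- primal_simplex(p, q1_options, start = startQ1)
  tQ1 <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  resQ2 <- primal_simplex(p, q2_options, start = resQ1$basis)
  tQ2 <- proc.time()[3] - t0
  if (resQ2$status == "infeasible")
    notes <- c(notes, "infeasibility certified in quad precision")
  dobj <- resD$objective; qobj <- resQ2$objective
  if (is.finite(dobj) && is.finite(qobj) && resD$status == "optimal" &&
      resQ2$status == "optimal") {
    rel <- abs(dobj - qobj) / max(1, abs(qobj))
    if (rel > 1e-4)
      notes <- c(notes,
                 sprintf("step D and Q2 objectives disagree in leading digits (%.10g vs %.10g): double arithmetic was insufficient for this instance",
                         dobj, qobj))
  }
  steps <- list(D = resD, Q1 = resQ1, Q2 = resQ2)
  times <- c(D = tD, Q1 = tQ1, Q2 = tQ2)
  structure(list(steps = steps, wall_time = times, notes = notes,
                 problem_stats = problem_stats(p),
                 status = resQ2$status,
                 objective = resQ2$objective,
                 objective_lo = resQ2$objective_lo,
                 v = resQ2$v, v_lo = resQ2$v_lo,
                 y = resQ2$y, y_lo = resQ2$y_lo,
                 z = resQ2$z, z_lo = resQ2$z_lo,
                 pinf = resQ2$pinf, dinf = resQ2$dinf,
                 pinf_log10 = resQ2$pinf_log10,
                 dinf_log10 = resQ2$dinf_log10,
                 basis = resQ2$basis),
            class = "dqq_report")
}

#' @export
print.dqq_report <- function(x, ...) {
  cat(sprintf("DQQ procedure: %s, final objective %.12g\n",
              x$status, x$objective))
  print(dqq_table(x))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Per-step summary table of a DQQ run
#'
#' Three rows (D, Q1, Q2) with iterations, wall time, objective and the
#' certified Pinf/Dinf rendered as log10 cells ("—" for exact zero),
#' the layout used for reporting multiscale benchmark runs.
#'
#' @param rep a \code{dqq_report}
#' @return a data frame
#' @export
dqq_table <- function(rep) {
  stopifnot(inherits(rep, "dqq_report"))
  data.frame(
    step = c("D", "Q1", "Q2"),
    itns = vapply(rep$steps, function(s) s$iterations, 0L),
    time = round(unname(rep$wall_time), 2),
    objective = vapply(rep$steps, function(s) s$objective, 0),
    Pinf = vapply(rep$steps, function(s) .log10_cell(s$pinf_log10), ""),
    Dinf = vapply(rep$steps, function(s) .log10_cell(s$dinf_log10), ""),
    row.names = NULL
  )
}

#' Certify a candidate solution
#'
#' Recomputes Pinf and Dinf on the original data in compensated
#' high-precision arithmetic and renders the log10 table cells
#' ("—" for an exact zero, otherwise the signed integer floor of log10).
#'
#' @param p an \code{lp_problem}
#' @param v primal values (structurals then slacks)
#' @param y row duals
#' @param basis a \code{basis_state}
#' @param v_lo,y_lo optional low-order parts
#' @return list with \code{pinf}, \code{dinf}, log10 values and rendered
#'   cells
#' @export
certify <- function(p, v, y, basis, v_lo = NULL, y_lo = NULL) {
  res <- compute_infeasibilities(p, v, y, basis, v_lo = v_lo, y_lo = y_lo)
  list(pinf = res$pinf, dinf = res$dinf,
       pinf_log10 = res$pinf_log10, dinf_log10 = res$dinf_log10,
       pinf_cell = .log10_cell(res$pinf_log10),
       dinf_cell = .log10_cell(res$dinf_log10))
}
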