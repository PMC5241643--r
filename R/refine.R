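# The zoom strategy: residuals of an approximate LP solution are computed
# in elevated (compensated ~68-digit) precision, a residual-scaled
# "zoomed in" problem of order 1 is solved with an ordinary fixed-precision
# solver, and the correction is accumulated in high precision.  Repeated
# rounds contract max(Pinf, Dinf) geometrically until the residual
# context's precision floor.

#' Residuals of a candidate point in elevated precision
#'
#' \code{r = b - A x} and \code{d = c - A'y} evaluated in compensated
#' high-precision arithmetic (roughly four times double precision), the
#' quantities whose cancellation a working-precision evaluation cannot
#' resolve.  For the slack computational form \code{b = 0}.
#'
#' @param form an \code{lp_standard_form}
#' @param x primal values (length n + m), hi part
#' @param y duals per row (minimized orientation)
#' @param x_lo,y_lo optional low-order parts
#' @return list with \code{r}, \code{r_lo}, \code{d}, \code{d_lo}
#' @export
compute_residuals <- function(form, x, y, x_lo = NULL, y_lo = NULL) {
  stopifnot(inherits(form, "lp_standard_form"))
  if (is.null(x_lo)) x_lo <- rep(0, length(x))
  if (is.null(y_lo)) y_lo <- rep(0, length(y))
  jj <- rep(seq_len(form$ntot), diff(form$ap)) - 1L
  cpp_residuals_qd(form$m, form$ntot, form$ai, jj, form$ax, form$ax_lo,
                   rep(0, form$m), rep(0, form$m), form$c,
                   x, x_lo, y, y_lo)
}

# power-of-two sigma = 1 / max residual norm (exact to scale by)
.zoom_sigma <- function(r, d, basic, floor_val = 1e-280) {
  base <- max(abs(r), abs(d[basic]), floor_val)
  2^(-ceiling(log2(base)))
}

#' One zoom round
#'
#' Builds the zoomed problem: minimize \code{d1' xhat} subject to
#' \code{A xhat = sigma r1}, \code{sigma (l - x1) <= xhat <= sigma (u - x1)},
#' with \code{sigma = 1/max(||r1||_inf, ||d1||_basic_inf)} rounded to a
#' power of two, solves it warm-started from the incumbent basis with the
#' supplied fixed-precision options, and returns the corrected point
#' \code{x = x1 + xhat/sigma}, \code{y = y1 + yhat/sigma} accumulated in
#' high precision.
#'
#' @param form an \code{lp_standard_form} of the original problem
#' @param x,y incumbent point (hi parts; minimized orientation)
#' @param basis incumbent \code{basis_state} over the n+m form variables
#' @param opts inner solver options (default double, unscaled)
#' @param x_lo,y_lo low-order parts of the incumbent
#' @return list: corrected \code{x}, \code{x_lo}, \code{y}, \code{y_lo},
#'   \code{sigma}, updated \code{basis}, inner solver \code{status}
#' @export
zoom_round <- function(form, x, y, basis, opts = NULL,
                       x_lo = NULL, y_lo = NULL) {
  stopifnot(inherits(form, "lp_standard_form"))
  if (is.null(opts))
    opts <- solver_options(precision = "double", scale = FALSE,
                           feasibility_tol = 1e-9, optimality_tol = 1e-9)
  if (is.null(x_lo)) x_lo <- rep(0, length(x))
  if (is.null(y_lo)) y_lo <- rep(0, length(y))
  res <- compute_residuals(form, x, y, x_lo, y_lo)
  N <- form$ntot; m <- form$m
  sigma <- .zoom_sigma(c(res$r, res$r_lo), res$d, basis$basic)
  if (max(abs(res$r)) == 0 && max(abs(res$d[basis$basic])) == 0) {
    return(list(x = x, x_lo = x_lo, y = y, y_lo = y_lo, sigma = Inf,
                basis = basis, status = "converged", iterations = 0L))
  }
  # zoomed bounds sigma * (l - x1), sigma * (u - x1) in high precision
  lo_d <- cpp_sub_qd(form$lower, form$lower_lo, x, x_lo)
  hi_d <- cpp_sub_qd(form$upper, form$upper_lo, x, x_lo)
  zl <- ifelse(is.finite(form$lower), sigma * lo_d$hi, -Inf)
  zu <- ifelse(is.finite(form$upper), sigma * hi_d$hi, Inf)
  swap <- zl > zu  # guard against rounding inversion at tight bounds
  if (any(swap)) { tmp <- zl[swap]; zl[swap] <- zu[swap]; zu[swap] <- tmp }
  # triplets of A (structurals + original slacks become plain columns)
  jj <- rep(seq_len(N), diff(form$ap))
  # objective sigma * d1 so that the dual of the zoomed problem is the
  # sigma-scaled dual correction (duals and primal corrections then share
  # the same 1/sigma unzoom)
  zp <- lp_problem(i = form$ai + 1L, j = jj, x = form$ax, x_lo = form$ax_lo,
                   m = m, n = N, row_sense = "E",
                   rhs = sigma * res$r, rhs_lo = sigma * res$r_lo,
                   c_obj = sigma * res$d, lower = zl, upper = zu,
                   sense = "min", name = "zoom")
  zf <- to_computational_form(zp)
  # warm start: incumbent statuses; the zoomed form's own slacks nonbasic
  vst <- c(basis$vstat, rep(1L, m))
  inner <- .simplex_core(zf, opts, basis_state(vst, m))
  if (inner$status == 1L) {  # zoomed problem infeasible: inconsistent start
    inner <- .simplex_core(zf, opts, NULL)
    if (inner$status == 1L)
      stop("zoomed problem infeasible even from a cold start")
  }
  xc <- cpp_axpy_qd(x, x_lo, inner$x[seq_len(N)], inner$x_lo[seq_len(N)],
                    1 / sigma)
  yc <- cpp_axpy_qd(y, y_lo, inner$y, inner$y_lo, 1 / sigma)
  # map the zoomed basis back to the original form's variables
  vst_new <- inner$vstat[seq_len(N)]
  deficit <- which(inner$vstat[N + seq_len(m)] == 0L)
  for (i in deficit) {
    sl <- form$n_struct + i
    if (vst_new[sl] != 0L) vst_new[sl] <- 0L
    else {
      nb <- which(vst_new != 0L)[1]
      vst_new[nb] <- 0L
    }
  }
  list(x = xc$hi, x_lo = xc$lo, y = yc$hi, y_lo = yc$lo, sigma = sigma,
       basis = basis_state(vst_new, m), status = .status_names[inner$status + 1L],
       iterations = inner$iterations)
}

#' Iterated zoom refinement
#'
#' Runs zoom rounds from an initial solve until
#' \code{max(Pinf, Dinf) <= target_tol * (1 + max(|x|, |y|))} or
#' \code{rounds_max}; stops early (flagging stagnation) when a round fails
#' to decrease the trace.
#'
#' @param p an \code{lp_problem}
#' @param start optional \code{simplex_result} for the initial point (a
#'   double solve with \code{inner_opts} is performed if missing)
#' @param inner_opts options of the fixed-precision inner solver
#' @param rounds_max maximum zoom rounds (default 6)
#' @param target_tol requested relative accuracy (default 1e-30)
#' @return object of class \code{zoom_state}: corrected solution (hi/lo),
#'   per-round \code{trace} of max(Pinf, Dinf), \code{sigmas},
#'   \code{rounds}, \code{converged}, \code{stagnated}
#' @export
zoom_refine <- function(p, start = NULL, inner_opts = NULL, rounds_max = 6,
                        target_tol = 1e-30) {
  stopifnot(inherits(p, "lp_problem"))
  if (is.null(inner_opts))
    inner_opts <- solver_options(precision = "double", scale = FALSE,
                                 feasibility_tol = 1e-9, optimality_tol = 1e-9)
  form <- to_computational_form(p)
  if (is.null(start)) start <- primal_simplex(p, inner_opts)
  if (!start$status %in% c("optimal", "iteration_limit"))
    stop("zoom refinement needs a (near-)optimal starting point; solver status: ",
         start$status)
  obj_sign <- form$obj_sign
  x <- start$v; x_lo <- start$v_lo
  y <- obj_sign * start$y; y_lo <- obj_sign * start$y_lo
  basis <- start$basis
  measure <- function(x, x_lo, y, y_lo, basis) {
    cert <- compute_infeasibilities(p, x, y, basis, v_lo = x_lo, y_lo = y_lo,
                                    internal_sense = TRUE)
    max(cert$pinf, cert$dinf)
  }
  trace <- measure(x, x_lo, y, y_lo, basis)
  sigmas <- numeric()
  stagnated <- FALSE
  rounds <- 0L
  scale_ref <- 1 + max(abs(x), abs(y))
  while (rounds < rounds_max && trace[length(trace)] > target_tol * scale_ref) {
    zr <- zoom_round(form, x, y, basis, inner_opts, x_lo, y_lo)
    if (identical(zr$status, "converged")) break
    val <- measure(zr$x, zr$x_lo, zr$y, zr$y_lo, zr$basis)
    rounds <- rounds + 1L
    sigmas <- c(sigmas, zr$sigma)
    if (val >= trace[length(trace)]) {
      stagnated <- TRUE
      trace <- c(trace, val)
      if (val < trace[length(trace) - 1L]) {
        x <- zr$x; x_lo <- zr$x_lo; y <- zr$y; y_lo <- zr$y_lo; basis <- zr$basis
      }
      break
    }
    x <- zr$x; x_lo <- zr$x_lo; y <- zr$y; y_lo <- zr$y_lo; basis <- zr$basis
    trace <- c(trace, val)
  }
  structure(list(x = x, x_lo = x_lo, y = obj_sign * y, y_lo = obj_sign * y_lo,
                 basis = basis, trace = trace, sigmas = sigmas,
                 rounds = rounds,
                 converged = trace[length(trace)] <= target_tol * scale_ref,
                 stagnated = stagnated),
            class = "zoom_state")
}

#' @export
print.zoom_state <- function(x, ...) {
  cat(sprintf("zoom refinement: %d rounds, %s\n", x$rounds,
              if (x$converged) "converged" else
                if (x$stagnated) "stagnated" else "round limit"))
  cat("max(Pinf,Dinf) trace:", sprintf("%.3g", x$trace), "\n")
  invisible(x)
}
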