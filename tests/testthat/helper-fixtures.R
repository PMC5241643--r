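# Shared fixtures: small problems built in code.

# min -v1 - v2  s.t.  v1 + v2 = 1,  0 <= v <= 1   (optimum -1)
toy_equality_lp <- function() {
  lp_problem(i = c(1, 1), j = c(1, 2), x = c(1, 1), m = 1, n = 2,
             row_sense = "E", rhs = 1, c_obj = c(-1, -1),
             lower = c(0, 0), upper = c(1, 1))
}

# 1-variable LP min v, v in [2, 3] (optimum v = 2, all residuals zero)
one_var_lp <- function() {
  lp_problem(i = 1, j = 1, x = 1, m = 1, n = 1, row_sense = "L", rhs = 10,
             c_obj = 1, lower = 2, upper = 3)
}

quad_opts <- function(scale = FALSE)
  solver_options(precision = "quad", scale = scale,
                 feasibility_tol = 1e-15, optimality_tol = 1e-15,
                 lu_factor_tol = 10, lu_update_tol = 10)

double_opts <- function(scale = FALSE)
  solver_options(precision = "double", scale = scale)

# qd-accurate absolute difference of two (hi, lo) scalars
hi_lo_diff <- function(ah, al, bh, bl) abs((ah - bh) + (al - bl))

# objective of a full-length point on a computational form, in high precision
form_objective <- function(form, x, x_lo = NULL) {
  if (is.null(x_lo)) x_lo <- rep(0, length(x))
  dot <- dqqlp:::cpp_matvec_qd(1L, rep(0L, form$ntot), 0:(form$ntot - 1L),
                               form$c, x, x_lo)
  c(hi = dot$hi, lo = dot$lo)
}

# planted-point row-interval violations of a generated instance, in high
# precision (inequality rows count only their overshoot)
planted_residual <- function(gen) {
  p <- gen$problem
  act <- dqqlp:::cpp_matvec_qd(p$m, p$S$i - 1L, p$S$j - 1L, p$S$x,
                               gen$v0, gen$v0_lo)
  ri <- dqqlp:::row_intervals(p)
  lo_viol <- ifelse(is.finite(ri$rlo),
                    (ri$rlo - act$hi) + (ri$rlo_lo - act$lo), -Inf)
  hi_viol <- ifelse(is.finite(ri$rhi),
                    (act$hi - ri$rhi) + (act$lo - ri$rhi_lo), -Inf)
  max(pmax(lo_viol, hi_viol, 0))
}
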