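# Deterministic, seeded generation of multiscale LPs and ME-like coupled
# models with planted feasible points.
#
# Exactness design: matrix entries and planted fluxes are signed powers of
# two with bounded per-row exponent span (row support <= 16, coefficient
# exponents spanning ~40 bits, flux exponents ~60 bits), so every row
# activity S v0 is exactly representable in a hi/lo double pair.  The
# right-hand side carries the low-order part in rhs_lo, making the planted
# point feasible EXACTLY -- its residual at ~68-digit precision is zero.

#' Synthetic instance specification
#'
#' Defaults emulate the multiscale regime of genome-scale ME models:
#' data values spanning many orders of magnitude (12 decades of
#' coefficients) and biochemically meaningful solution values from 1e-10
#' up to 1e8 (18 decades), with effective rate constants around 2.34e5.
#'
#' @param m,n dimensions
#' @param density target fraction of nonzeros per row (row support is
#'   capped at 16 to keep planted activities exactly representable)
#' @param coefficient_decades span of log10 |S_ij|
#' @param flux_decades span of log10 of planted flux magnitudes
#' @param coupling_fraction fraction of columns coupled in ME-like models
#' @param k_eff_mean central effective rate constant (1/h)
#' @param steady_state add one balancing column per row so that b = 0
#' @param seed RNG seed; same spec + seed gives bit-identical problems
#' @return object of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(m = 60, n = 80, density = 0.08,
                           coefficient_decades = 12, flux_decades = 18,
                           coupling_fraction = 0.15, k_eff_mean = 2.34e5,
                           steady_state = FALSE, seed = 1) {
  stopifnot(m >= 2, n >= 4, density > 0, coefficient_decades >= 0,
            flux_decades >= 0, k_eff_mean > 0)
  structure(list(m = as.integer(m), n = as.integer(n), density = density,
                 coefficient_decades = coefficient_decades,
                 flux_decades = flux_decades,
                 coupling_fraction = coupling_fraction,
                 k_eff_mean = k_eff_mean,
                 steady_state = isTRUE(steady_state),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Exponent design (bits): entry exponents decompose as
#   e_ij = rho_i + gamma_j + eta_ij     (row scale + column scale + jitter)
# and planted flux exponents as
#   f_j = -gamma_j + phi_j + centre     (anti-correlated with column scale)
# so magnitudes are row/column structured -- the regime geometric-mean
# scaling is designed for and the structure real ME models have -- while
# per-row activity terms e_ij + f_j = rho_i + eta_ij + phi_j + centre span
# only a few dozen bits and sums stay exactly representable in hi/lo pairs.
.exp_design <- function(coefficient_decades, flux_decades) {
  cspan <- round(coefficient_decades * log2(10))
  fspan <- round(flux_decades * log2(10))
  rho_span <- 2L; eta_span <- 4L
  gspan <- max(0L, cspan - rho_span - eta_span)
  phi_span <- max(0L, fspan - gspan)
  ghalf <- floor(gspan / 2); phalf <- floor(phi_span / 2)
  list(rho = c(-1L, 1L), eta = c(-2L, 2L),
       gamma = c(-ghalf, gspan - ghalf),
       phi = c(-phalf, phi_span - phalf),
       centre = -4L)
}

#' Generate a multiscale LP with a planted feasible point
#'
#' Sparse matrix with log-uniform magnitudes (signed powers of two) and a
#' planted flux vector v0 that satisfies \code{S v0 = b} exactly (the
#' low-order half of b is stored in \code{rhs_lo}).  Bounds enclose v0
#' with slack; the objective is random.  With \code{steady_state = TRUE} a
#' balancing column per row makes \code{b = 0}.
#'
#' @param spec a \code{synthetic_spec}
#' @return list: \code{problem}, planted \code{v0} (+ \code{v0_lo}),
#'   \code{spec}
#' @export
generate_multiscale_lp <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$m; n <- spec$n
  k_row <- max(2L, min(16L, as.integer(round(spec$density * n))))
  dz <- .exp_design(spec$coefficient_decades, spec$flux_decades)
  rho <- sample(dz$rho[1]:dz$rho[2], m, replace = TRUE)
  gamma <- sample(dz$gamma[1]:dz$gamma[2], n, replace = TRUE)
  phi <- sample(dz$phi[1]:dz$phi[2], n, replace = TRUE)
  # realize the extreme coefficient and flux magnitudes
  rho[1] <- dz$rho[1]; rho[min(2L, m)] <- dz$rho[2]
  gamma[1] <- dz$gamma[1]; phi[1] <- dz$phi[2]
  gamma[n] <- dz$gamma[2]; phi[n] <- dz$phi[1]
  ti <- integer(); tj <- integer(); teta <- integer()
  for (i in seq_len(m)) {
    cols <- sample.int(n, k_row)
    if (i == 1L && !(1L %in% cols)) cols[1] <- 1L
    if (i == min(2L, m) && !(n %in% cols)) cols[1] <- n
    ti <- c(ti, rep(i, k_row)); tj <- c(tj, cols)
    teta <- c(teta, sample(dz$eta[1]:dz$eta[2], k_row, replace = TRUE))
  }
  teta[ti == 1L & tj == 1L] <- dz$eta[1]
  teta[ti == min(2L, m) & tj == n] <- dz$eta[2]
  te <- rho[ti] + gamma[tj] + teta
  sgn <- sample(c(-1, 1), length(te), replace = TRUE)
  x <- sgn * 2^te
  f <- -gamma + phi + dz$centre
  v0 <- 2^f
  lower <- rep(0, n)
  upper <- 2^(f + 3)
  c_obj <- round(stats::rnorm(n), 3)
  act <- cpp_matvec_qd(m, ti - 1L, tj - 1L, x, v0, rep(0, n))
  v0_lo <- rep(0, n)
  if (spec$steady_state) {
    # balancing column per row: g_i = 2^ceil(log2|s_i|), planted t_i = -s_i/g_i
    g <- ifelse(act$hi == 0, 1, 2^ceiling(log2(abs(act$hi) + abs(act$lo))))
    ti <- c(ti, seq_len(m)); tj <- c(tj, n + seq_len(m)); x <- c(x, g)
    tvals <- -act$hi / g; tvals_lo <- -act$lo / g  # exact: g powers of two
    v0 <- c(v0, tvals); v0_lo <- c(v0_lo, tvals_lo)
    lower <- c(lower, rep(-2, m)); upper <- c(upper, rep(2, m))
    c_obj <- c(c_obj, rep(0, m))
    n <- n + m
    rhs <- rep(0, m); rhs_lo <- rep(0, m)
  } else {
    rhs <- act$hi; rhs_lo <- act$lo
  }
  prob <- lp_problem(i = ti, j = tj, x = x, m = m, n = n,
                     row_sense = "E", rhs = rhs, rhs_lo = rhs_lo,
                     c_obj = c_obj, lower = lower, upper = upper,
                     sense = "min",
                     name = sprintf("multiscale_s%d", spec$seed))
  list(problem = prob, v0 = v0, v0_lo = v0_lo, spec = spec)
}

#' Generate an ME-like coupled model
#'
#' Block structure emulating integrated metabolism/expression models: a
#' metabolic block with O(1) stoichiometry and O(1) planted fluxes, an
#' expression block whose macromolecule rows carry large coefficients
#' (molecular compositions) balanced by tiny synthesis fluxes (down to
#' ~1e-10) and O(1) dilution fluxes, and coupling rows tying expression
#' usage to catalyzed metabolic fluxes with \code{c_max = mu/k_eff},
#' \code{k_eff} drawn around 2.34e5.  The planted growth state satisfies
#' all rows exactly and all coupling rows strictly.
#'
#' @param spec a \code{synthetic_spec}
#' @param mu growth rate of the coupling rows (default 1)
#' @return list: \code{problem} (coupling rows included), \code{coupling}
#'   (pairs data frame), \code{v0}, \code{v0_lo}, \code{mu}, \code{spec}
#' @export
generate_me_like_model <- function(spec, mu = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  m1 <- max(2L, as.integer(round(spec$m * 0.6)))   # metabolite rows
  m2 <- max(1L, spec$m - m1)                       # macromolecule rows
  n1 <- max(3L, as.integer(round(spec$n * 0.6)))   # metabolic fluxes
  n_syn <- m2                                      # one synthesis flux each
  n_dil <- m2                                      # one dilution flux each
  ebits <- min(round(spec$coefficient_decades * log2(10)), 40)
  # metabolic block: small integer stoichiometry
  k_row <- max(2L, min(6L, as.integer(round(spec$density * n1 * 2))))
  ti <- integer(); tj <- integer(); tx <- double()
  for (i in seq_len(m1)) {
    cols <- sample.int(n1, k_row)
    ti <- c(ti, rep(i, k_row)); tj <- c(tj, cols)
    tx <- c(tx, sample(c(-2, -1, 1, 2), k_row, replace = TRUE))
  }
  f_met <- sample(-3:3, n1, replace = TRUE)
  v_met <- 2^f_met
  # expression block: row m1+r balances  2^e_r * v_syn_r - v_dil_r = 0
  e_syn <- sample(seq(max(4, ebits - 10), ebits), m2, replace = TRUE)
  f_syn <- sample(-34:-24, m2, replace = TRUE)
  j_syn <- n1 + seq_len(m2)
  j_dil <- n1 + m2 + seq_len(m2)
  ti <- c(ti, m1 + seq_len(m2), m1 + seq_len(m2))
  tj <- c(tj, j_syn, j_dil)
  tx <- c(tx, 2^e_syn, rep(-1, m2))
  # synthesis also consumes metabolites (tiny contributions to metabolic rows)
  for (r in seq_len(m2)) {
    row <- sample.int(m1, 1)
    ti <- c(ti, row); tj <- c(tj, j_syn[r])
    tx <- c(tx, -sample(c(1, 2, 4), 1))
  }
  v_syn <- 2^f_syn
  v_dil <- 2^(e_syn + f_syn)     # exact product of powers of two
  n <- n1 + 2L * m2
  v0 <- c(v_met, v_syn, v_dil)
  lower <- rep(0, n)
  upper <- c(2^(f_met + 3), 2^(f_syn + 3), 2^(e_syn + f_syn + 3))
  act <- cpp_matvec_qd(m1 + m2, ti - 1L, tj - 1L, tx, v0, rep(0, n))
  c_obj <- rep(0, n); c_obj[n1] <- 1    # maximize a biomass-like flux
  prob <- lp_problem(i = ti, j = tj, x = tx, m = m1 + m2, n = n,
                     row_sense = "E", rhs = act$hi, rhs_lo = act$lo,
                     c_obj = c_obj, lower = lower, upper = upper,
                     sense = "max",
                     name = sprintf("melike_s%d", spec$seed))
  # coupling: expression usage (tiny synthesis flux) bounded by mu/k_eff
  # times the catalyzed metabolic flux
  n_cpl <- max(1L, as.integer(round(spec$coupling_fraction * n1)))
  k_eff <- spec$k_eff_mean * 2^sample(-2:2, n_cpl, replace = TRUE)
  pairs <- data.frame(i = sample(j_syn, n_cpl, replace = TRUE),
                      j = sample.int(n1, n_cpl), k_eff = k_eff)
  ok <- v0[pairs$i] <= (mu / pairs$k_eff) * v0[pairs$j] / 2
  if (!any(ok)) { pairs$k_eff[1] <- mu * v0[pairs$j[1]] / (4 * v0[pairs$i[1]]); ok[1] <- TRUE }
  pairs <- pairs[ok, , drop = FALSE]
  prob <- add_coupling_constraints(prob, pairs, mu = mu)
  list(problem = prob, coupling = pairs, v0 = v0,
       v0_lo = rep(0, length(v0)), mu = mu, spec = spec)
}

#' Generate a degenerate LP
#'
#' Constructs instances whose optimal bases have the requested fraction of
#' basic variables sitting exactly on bounds.  For moderate levels the
#' instance is a random integer problem with a known unique optimum whose
#' basic values contain the stated fraction of zeros.  For
#' \code{level >= 0.75} the instance embeds the classic 3x7 cycling-prone
#' degenerate core (plus inert padding rows at bound), on which the
#' textbook ratio test cycles while the EXPAND step floor terminates.
#'
#' @param seed RNG seed
#' @param degeneracy_level fraction in [0, 1] of optimal basic variables
#'   on a bound
#' @return list: \code{problem}, \code{optimal_objective} (exact),
#'   \code{level}, \code{cycling_prone}
#' @export
generate_degenerate_lp <- function(seed, degeneracy_level = 0.3) {
  stopifnot(degeneracy_level >= 0, degeneracy_level <= 1)
  set.seed(seed)
  if (degeneracy_level >= 0.75) {
    # classic cycling-prone degenerate core
    ncore <- 4L; mcore <- 3L
    i <- c(1, 1, 1, 1, 2, 2, 2, 2, 3)
    j <- c(1, 2, 3, 4, 1, 2, 3, 4, 3)
    x <- c(0.25, -60, -0.04, 9, 0.5, -90, -0.02, 3, 1)
    cc <- c(-0.75, 150, -0.02, 6)
    npad <- min(ceiling(mcore * degeneracy_level / (1 - degeneracy_level)), 40L)
    for (r in seq_len(npad)) {
      i <- c(i, mcore + r); j <- c(j, ncore + r); x <- c(x, 1)
    }
    prob <- lp_problem(i = i, j = j, x = x, m = mcore + npad, n = ncore + npad,
                       row_sense = c("L", "L", "L", rep("E", npad)),
                       rhs = c(0, 0, 1, rep(0, npad)),
                       c_obj = c(cc, rep(0, npad)),
                       lower = rep(0, ncore + npad),
                       upper = c(rep(Inf, ncore), rep(1, npad)),
                       sense = "min",
                       name = sprintf("degen_cyc_s%d", seed))
    return(list(problem = prob, optimal_objective = -0.05,
                level = degeneracy_level, cycling_prone = TRUE))
  }
  m <- 8L; k <- 6L
  nzero <- as.integer(ceiling(degeneracy_level * m))
  b <- sample(1:9, m, replace = TRUE)
  if (nzero > 0) b[sample.int(m, nzero)] <- 0
  G <- matrix(sample(-3:3, m * k, replace = TRUE), m, k)
  yv <- sample(-3:3, m, replace = TRUE)
  s <- sample(1:3, k, replace = TRUE)
  cc <- c(yv, as.vector(t(G) %*% yv) + s)
  i <- c(seq_len(m), rep(seq_len(m), k))
  j <- c(seq_len(m), rep(m + seq_len(k), each = m))
  x <- c(rep(1, m), as.vector(G))
  keep <- x != 0
  prob <- lp_problem(i = i[keep], j = j[keep], x = x[keep], m = m, n = m + k,
                     row_sense = "E", rhs = b, c_obj = cc,
                     lower = rep(0, m + k),
                     upper = rep(10 * max(b, 1), m + k),
                     sense = "min", name = sprintf("degen_s%d", seed))
  list(problem = prob, optimal_objective = sum(b * yv),
       level = degeneracy_level, cycling_prone = FALSE)
}

#' Generate an infeasible-by-construction LP
#'
#' Starts from a multiscale instance with a planted feasible point, then
#' tightens the upper bounds on one equality row's support so far that the
#' row's maximum attainable activity falls short of its right-hand side by
#' a recorded margin -- a certificate of infeasibility carried with the
#' instance.
#'
#' @param spec a \code{synthetic_spec}
#' @return list: \code{problem}, \code{certificate} (row, margin),
#'   \code{spec}
#' @export
generate_infeasible_lp <- function(spec) {
  gen <- generate_multiscale_lp(spec)
  p <- gen$problem
  cand <- which(p$rhs != 0)
  if (!length(cand)) stop("no nonzero right-hand side to violate")
  i0 <- cand[which.max(abs(p$rhs[cand]))]
  b <- p$rhs[i0]
  on_row <- which(p$S$i == i0)
  sel <- if (b > 0) on_row[p$S$x[on_row] > 0] else on_row[p$S$x[on_row] < 0]
  if (!length(sel)) {
    # attainable activity has the wrong sign already; any support works
    sel <- on_row
  }
  kk <- length(sel)
  for (t in sel) {
    jx <- p$S$j[t]
    cap <- abs(b) / (4 * kk * abs(p$S$x[t]))
    p$upper[jx] <- min(p$upper[jx], 2^floor(log2(cap)))
  }
  # interval-arithmetic maximum/minimum of the row activity over the box
  xs <- p$S$x[on_row]; js <- p$S$j[on_row]
  amax <- sum(pmax(xs * p$lower[js], xs * p$upper[js]))
  amin <- sum(pmin(xs * p$lower[js], xs * p$upper[js]))
  margin <- if (b > 0) b - amax else amin - b
  if (margin <= 0) stop("failed to construct an infeasibility certificate")
  p$name <- sprintf("infeasible_s%d", spec$seed)
  list(problem = p, certificate = list(row = i0, margin = margin),
       spec = spec)
}

#' Generate a small dense integer LP (oracle family)
#'
#' Random boxed LPs small enough for exhaustive basic-solution
#' enumeration: integer entries in {-2..2}, mixed row senses, integer
#' right-hand sides and objectives, bounds [0, 3].  Always bounded; may be
#' infeasible.  Used to cross-check the simplex against
#' \code{\link{lp_vertex_oracle}}.
#'
#' @param seed RNG seed
#' @param m,n dimensions (default 4 x 6, so m + n = 10)
#' @return an \code{lp_problem}
#' @export
generate_dense_small_lp <- function(seed, m = 4, n = 6) {
  set.seed(seed)
  A <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
  idx <- which(A != 0, arr.ind = TRUE)
  if (!nrow(idx)) { A[1, 1] <- 1; idx <- cbind(1, 1) }
  lp_problem(i = idx[, 1], j = idx[, 2], x = A[idx], m = m, n = n,
             row_sense = sample(c("E", "L", "G"), m, replace = TRUE,
                                prob = c(0.3, 0.4, 0.3)),
             rhs = sample(-3:3, m, replace = TRUE),
             c_obj = sample(-3:3, n, replace = TRUE),
             lower = rep(0, n), upper = rep(3, n),
             sense = "min", name = sprintf("dense_s%d", seed))
}

#' Planted-threshold growth builder
#'
#' A minimal mu-parameterized family for exercising the growth bisection:
#' \code{v <= (mu/k_eff) w}, \code{w <= cap}, demand \code{v >= demand}.
#' The feasibility boundary is \code{mu* = k_eff * demand / cap}.
#'
#' @param k_eff effective rate constant
#' @param demand required flux
#' @param cap capacity of the coupled flux
#' @return list: \code{builder} (function of mu), exact \code{mu_star}
#' @export
planted_growth_builder <- function(k_eff = 2, demand = 0.5, cap = 1) {
  builder <- function(mu) {
    lp_problem(i = c(1, 1), j = c(1, 2), x = c(1, -mu / k_eff),
               m = 1, n = 2, row_sense = "L", rhs = 0,
               c_obj = c(0, 0), lower = c(demand, 0), upper = c(Inf, cap),
               sense = "min", name = "growth")
  }
  list(builder = builder, mu_star = k_eff * demand / cap)
}
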