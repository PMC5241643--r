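# Geometric-mean row/column scaling, applied before solving and reversed
# afterward.  Scales are rounded to powers of two so that applying and
# unapplying them is exact in any binary floating-point precision; this is
# why the scaled problem's data (and Q2's unscaled data) carry no rounding
# from the scaling itself.

#' Compute geometric-mean scale vectors
#'
#' Each pass sets every row scale to the geometric mean of the extreme
#' absolute entries in that row, then every column scale likewise.  Passes
#' stop when the spread (max/min scaled \code{|S_ij|}) shrinks by a factor
#' of less than \code{stop_ratio} between passes, or after
#' \code{max_passes}.
#'
#' @param S an \code{lp_problem} or a triplet list with \code{i}, \code{j},
#'   \code{x} and dimensions \code{m}, \code{n}
#' @param max_passes maximum number of row/column sweeps (default 10)
#' @param round_pow2 round final scales to the nearest power of two
#'   (default TRUE; keeps scaling exact)
#' @param stop_ratio pass-termination factor (default 0.9)
#' @return an object of class \code{scale_vectors}: positive
#'   \code{row_scales}, \code{col_scales}, \code{pass_count},
#'   \code{achieved_spread}
#' @export
compute_scales <- function(S, max_passes = 10, round_pow2 = TRUE,
                           stop_ratio = 0.9) {
  if (inherits(S, "lp_problem")) {
    tr <- list(i = S$S$i, j = S$S$j, x = S$S$x, m = S$m, n = S$n)
  } else tr <- S
  keep <- tr$x != 0
  i <- tr$i[keep]; j <- tr$j[keep]; a <- abs(tr$x[keep])
  if (!length(a)) stop("matrix has no nonzero entries to scale")
  lr <- rep(0, tr$m); lc <- rep(0, tr$n)  # log2 scales
  la <- log2(a)
  spread0 <- max(la) - min(la)
  spread_prev <- spread0
  passes <- 0L
  for (p in seq_len(max_passes)) {
    v <- la - lr[i] - lc[j]
    mx <- tapply(v, i, max); mn <- tapply(v, i, min)
    lr[as.integer(names(mx))] <- lr[as.integer(names(mx))] + (mx + mn) / 2
    v <- la - lr[i] - lc[j]
    mx <- tapply(v, j, max); mn <- tapply(v, j, min)
    lc[as.integer(names(mx))] <- lc[as.integer(names(mx))] + (mx + mn) / 2
    v <- la - lr[i] - lc[j]
    spread <- max(v) - min(v)
    passes <- p
    if (spread > spread_prev * stop_ratio && p > 1) break
    spread_prev <- spread
  }
  if (round_pow2) { lr <- round(lr); lc <- round(lc) }
  v <- la - lr[i] - lc[j]
  structure(list(row_scales = 2^lr, col_scales = 2^lc,
                 pass_count = passes,
                 achieved_spread = 2^(max(v) - min(v)),
                 unscaled_spread = 2^spread0),
            class = "scale_vectors")
}

#' Apply scale vectors to a computational form
#'
#' Transforms \code{A <- R^-1 A C^-1} with bounds, objective and slack
#' bounds transformed consistently (scaled variable \code{x_hat_j = c_j
#' x_j}; slack column scales are \code{1/r_i} so slack coefficients stay
#' -1).  Objective values of the scaled and original problems are equal.
#'
#' @param form an \code{lp_standard_form}
#' @param sc a \code{scale_vectors}
#' @return the scaled \code{lp_standard_form} (with \code{scales} attached)
#' @export
apply_scaling <- function(form, sc) {
  stopifnot(inherits(form, "lp_standard_form"))
  r <- sc$row_scales; cs <- sc$col_scales
  if (any(!is.finite(r)) || any(r <= 0) || any(!is.finite(cs)) || any(cs <= 0))
    stop("scale factors must be strictly positive and finite")
  m <- form$m; n <- form$n_struct
  if (length(r) != m || length(cs) != n) stop("scale vector dimensions mismatch")
  colsc <- c(cs, 1 / r)             # slack column scale = 1/r_i
  f <- form
  jj <- rep(seq_len(form$ntot), diff(form$ap))
  ii <- form$ai + 1L
  fac <- 1 / (r[ii] * colsc[jj])
  f$ax <- form$ax * fac
  f$ax_lo <- form$ax_lo * fac
  f$c <- form$c / colsc
  f$lower <- form$lower * colsc
  f$upper <- form$upper * colsc
  f$lower_lo <- form$lower_lo * colsc
  f$upper_lo <- form$upper_lo * colsc
  f$scales <- sc
  f
}

#' Undo scaling on a solution
#'
#' Exact inverse of \code{\link{apply_scaling}} on primal and dual values:
#' \code{x_j = x_hat_j / c_j}, \code{y_i = r_i^-1 y_hat_i} ... i.e. duals
#' divide by the row scale so that \code{z = c - S'y} is preserved.  Note
#' the documented hazard: unscaling an approximately-feasible solution can
#' inflate Pinf/Dinf measured on the original data -- the reason the final
#' DQQ step re-solves without scaling.
#'
#' @param x_scaled,y_scaled solution of the scaled problem (full-length
#'   primal including slacks; duals per row)
#' @param sc the \code{scale_vectors} used
#' @return list with unscaled \code{x}, \code{y}
#' @export
unscale_solution <- function(x_scaled, y_scaled, sc) {
  n <- length(sc$col_scales); m <- length(sc$row_scales)
  colsc <- c(sc$col_scales, 1 / sc$row_scales)
  stopifnot(length(x_scaled) == n + m, length(y_scaled) == m)
  list(x = x_scaled / colsc, y = y_scaled / sc$row_scales)
}
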