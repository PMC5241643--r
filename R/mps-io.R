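# MPS reading and writing: the fixed 12-character-field dialect of the
# classical mathematical-programming systems, and a free-format dialect
# (whitespace-separated tokens, same section grammar).

# fixed-format field positions (1-based, inclusive)
.mps_fields <- list(c(2, 3), c(5, 12), c(15, 22), c(25, 36), c(40, 47), c(50, 61))

.mps_split_fixed <- function(line) {
  out <- character(6)
  nc <- nchar(line)
  for (k in seq_along(.mps_fields)) {
    f <- .mps_fields[[k]]
    if (nc >= f[1]) out[k] <- trimws(substr(line, f[1], min(f[2], nc)))
  }
  out[nzchar(out)]
}

.mps_num <- function(tok, lineno) {
  v <- suppressWarnings(as.numeric(gsub("[dD]", "E", tok)))
  if (any(is.na(v)))
    stop(sprintf("malformed numeric field '%s' at line %d",
                 tok[which(is.na(v))[1]], lineno))
  v
}

#' Read an MPS file
#'
#' Parses the NAME/ROWS/COLUMNS/RHS/RANGES/BOUNDS/ENDATA sections in either
#' the fixed 12-character-field dialect or a free (whitespace-separated)
#' dialect.  Columns absent from BOUNDS get the default bounds
#' \code{[0, Inf)}; duplicate COLUMNS entries for one (row, column) pair are
#' summed; RANGES follow the classical convention (a range on an E row makes
#' it two-sided).  Bounds at or beyond 1e30 in magnitude are treated as
#' absent (infinite).
#'
#' With \code{precision = "quad"} numeric fields are additionally parsed
#' into 34-digit precision and the digits beyond double are stored as
#' low-order corrections, so quad solves are not limited by a double parse.
#'
#' @param file path to an MPS file, or a character vector of lines via
#'   \code{text}
#' @param dialect "fixed", "free", or "auto" (token-based; accepts both)
#' @param precision "double" or "quad"
#' @param text optional character vector of lines (overrides \code{file})
#' @return an \code{lp_problem}
#' @export
read_mps <- function(file, dialect = c("auto", "fixed", "free"),
                     precision = c("double", "quad"), text = NULL) {
  dialect <- match.arg(dialect)
  precision <- match.arg(precision)
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  lines <- sub("\r$", "", lines)
  section <- ""
  objname <- NULL
  probname <- "LP"
  maximize <- FALSE
  rows <- list(); rowid <- new.env(parent = emptyenv())
  cols <- list(); colid <- new.env(parent = emptyenv())
  ent_i <- integer(); ent_j <- integer(); ent_v <- character()
  rhs_i <- integer(); rhs_v <- character()
  rng_i <- integer(); rng_v <- character()
  bnd <- list()
  obj_const_tok <- NULL
  saw_endata <- FALSE
  free_row_warned <- FALSE

  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (!nzchar(trimws(raw)) || substr(raw, 1, 1) == "*") next
    if (!grepl("^[ \t]", raw)) { # section header
      toks <- strsplit(trimws(raw), "[ \t]+")[[1]]
      section <- toupper(toks[1])
      if (section == "NAME" && length(toks) > 1) probname <- toks[2]
      if (section == "ENDATA") { saw_endata <- TRUE; break }
      if (section == "OBJSENSE" && length(toks) > 1)
        maximize <- toupper(toks[2]) %in% c("MAX", "MAXIMIZE")
      next
    }
    toks <- if (dialect == "fixed") .mps_split_fixed(raw)
            else strsplit(trimws(raw), "[ \t]+")[[1]]
    if (!length(toks)) next
    if (section == "OBJSENSE") {
      maximize <- toupper(toks[1]) %in% c("MAX", "MAXIMIZE")
    } else if (section == "ROWS") {
      type <- toupper(toks[1]); rname <- toks[2]
      if (type == "N") {
        if (is.null(objname)) objname <- rname
        else if (!free_row_warned) {
          warning("additional N (free) rows ignored: ", rname)
          free_row_warned <- TRUE
        }
      } else if (type %in% c("E", "L", "G")) {
        rows[[length(rows) + 1L]] <- list(name = rname, sense = type)
        assign(rname, length(rows), envir = rowid)
      } else stop(sprintf("unknown row type '%s' at line %d", type, ln))
    } else if (section == "COLUMNS") {
      cname <- toks[1]
      if (grepl("MARKER", toupper(paste(toks, collapse = " "))))
        stop("MILP MARKER sections are not supported")
      if (!exists(cname, envir = colid, inherits = FALSE)) {
        cols[[length(cols) + 1L]] <- cname
        assign(cname, length(cols), envir = colid)
      }
      jc <- get(cname, envir = colid)
      pairs <- toks[-1]
      if (length(pairs) %% 2 != 0)
        stop(sprintf("odd row/value field count in COLUMNS at line %d", ln))
      for (k in seq(1, length(pairs), by = 2)) {
        rname <- pairs[k]; vtok <- pairs[k + 1]
        .mps_num(vtok, ln)
        if (!is.null(objname) && rname == objname) {
          ent_i <- c(ent_i, 0L); ent_j <- c(ent_j, jc); ent_v <- c(ent_v, vtok)
        } else {
          if (!exists(rname, envir = rowid, inherits = FALSE))
            stop(sprintf("unknown row name '%s' in COLUMNS at line %d", rname, ln))
          ent_i <- c(ent_i, get(rname, envir = rowid))
          ent_j <- c(ent_j, jc); ent_v <- c(ent_v, vtok)
        }
      }
    } else if (section == "RHS") {
      pairs <- toks[-1]
      if (length(pairs) %% 2 != 0)
        stop(sprintf("odd row/value field count in RHS at line %d", ln))
      for (k in seq(1, length(pairs), by = 2)) {
        rname <- pairs[k]; vtok <- pairs[k + 1]
        .mps_num(vtok, ln)
        if (!is.null(objname) && rname == objname) {
          obj_const_tok <- vtok
        } else {
          if (!exists(rname, envir = rowid, inherits = FALSE))
            stop(sprintf("unknown row name '%s' in RHS at line %d", rname, ln))
          rhs_i <- c(rhs_i, get(rname, envir = rowid)); rhs_v <- c(rhs_v, vtok)
        }
      }
    } else if (section == "RANGES") {
      pairs <- toks[-1]
      for (k in seq(1, length(pairs), by = 2)) {
        rname <- pairs[k]; vtok <- pairs[k + 1]
        .mps_num(vtok, ln)
        if (!exists(rname, envir = rowid, inherits = FALSE))
          stop(sprintf("unknown row name '%s' in RANGES at line %d", rname, ln))
        rng_i <- c(rng_i, get(rname, envir = rowid)); rng_v <- c(rng_v, vtok)
      }
    } else if (section == "BOUNDS") {
      btype <- toupper(toks[1]); cname <- toks[3]
      vtok <- if (length(toks) >= 4) toks[4] else NA_character_
      if (!exists(cname, envir = colid, inherits = FALSE))
        stop(sprintf("unknown column name '%s' in BOUNDS at line %d", cname, ln))
      bnd[[length(bnd) + 1L]] <- list(type = btype,
                                      j = get(cname, envir = colid), v = vtok,
                                      line = ln)
    }
  }
  if (!saw_endata) warning("missing ENDATA; accepting file as-is")

  m <- length(rows); n <- length(cols)
  row_names <- vapply(rows, `[[`, "", "name")
  senses <- vapply(rows, `[[`, "", "sense")
  col_names <- unlist(cols)
  if (n == 0) stop("MPS file defines no columns")

  parse_vals <- function(tok) {
    hi <- .mps_num(tok, 0L)
    lo <- rep(0, length(tok))
    if (precision == "quad" && length(tok)) {
      q <- cpp_parse_quad(gsub("[dD]", "E", tok))
      hi <- q$hi; lo <- q$lo
    }
    list(hi = hi, lo = lo)
  }

  # objective and structural entries (duplicates summed)
  isobj <- ent_i == 0L
  ev <- parse_vals(ent_v)
  c_obj <- rep(0, n)
  if (any(isobj)) {
    agg <- rowsum(ev$hi[isobj], ent_j[isobj])
    c_obj[as.integer(rownames(agg))] <- agg[, 1]
  }
  si <- ent_i[!isobj]; sj <- ent_j[!isobj]
  sx <- ev$hi[!isobj]; sxlo <- ev$lo[!isobj]
  if (length(si)) {
    key <- paste(si, sj)
    if (anyDuplicated(key)) {
      f <- factor(key, levels = unique(key))
      si <- si[!duplicated(key)]; sj <- sj[!duplicated(key)]
      sx <- as.vector(rowsum(sx, f))
      sxlo <- as.vector(rowsum(sxlo, f))
    }
  }

  rhs <- rep(0, m); rhs_lo <- rep(0, m)
  if (length(rhs_i)) {
    rv <- parse_vals(rhs_v)
    rhs[rhs_i] <- rv$hi; rhs_lo[rhs_i] <- rv$lo
  }
  obj_constant <- if (!is.null(obj_const_tok)) -.mps_num(obj_const_tok, 0L) else 0

  range <- rep(NA_real_, m)
  sense_out <- senses
  if (length(rng_i)) {
    rv <- .mps_num(rng_v, 0L)
    for (k in seq_along(rng_i)) {
      i <- rng_i[k]; r <- rv[k]
      b <- rhs[i]
      # classical convention -> normalized interval [rhs', rhs' + width]
      if (senses[i] == "E") {
        if (r >= 0) { rhs[i] <- b; range[i] <- r }
        else { rhs[i] <- b + r; range[i] <- -r }
      } else if (senses[i] == "L") {
        rhs[i] <- b - abs(r); range[i] <- abs(r)
      } else {
        rhs[i] <- b; range[i] <- abs(r)
      }
      sense_out[i] <- "R"
    }
  }

  lower <- rep(0, n); upper <- rep(Inf, n)
  INFTH <- 1e30
  for (b in bnd) {
    v <- if (!is.na(b$v)) .mps_num(b$v, b$line) else NA_real_
    j <- b$j
    switch(b$type,
      UP = { upper[j] <- if (!is.na(v) && abs(v) < INFTH) v else Inf },
      LO = { lower[j] <- if (!is.na(v) && abs(v) < INFTH) v else -Inf },
      FX = { lower[j] <- v; upper[j] <- v },
      FR = { lower[j] <- -Inf; upper[j] <- Inf },
      MI = { lower[j] <- -Inf },
      PL = { upper[j] <- Inf },
      stop(sprintf("unsupported bound type '%s' at line %d", b$type, b$line))
    )
  }

  lp_problem(i = si, j = sj, x = sx, x_lo = sxlo, m = m, n = n,
             row_sense = sense_out, rhs = rhs, rhs_lo = rhs_lo,
             range = range, c_obj = c_obj, lower = lower, upper = upper,
             sense = if (maximize) "max" else "min",
             obj_constant = obj_constant,
             row_names = row_names, col_names = col_names, name = probname)
}

# widest decimal representation fitting the 12-character fixed field
.mps_fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in 15:1) {
      s <- sprintf("%.*G", d, v)
      if (nchar(s) <= 12) return(s)
    }
    sprintf("%.1G", v)
  }, "")
}

#' Write a problem in MPS format
#'
#' The fixed dialect prints values with the maximum number of digits that
#' fit the 12-character numeric field (so a re-parse reproduces the problem
#' up to field resolution); the free dialect prints full double precision
#' and round-trips doubles exactly.
#'
#' @param p an \code{lp_problem}
#' @param file output path; if \code{NULL} the lines are returned invisibly
#' @param dialect "fixed" or "free"
#' @return character vector of lines, invisibly
#' @export
write_mps <- function(p, file = NULL, dialect = c("fixed", "free")) {
  dialect <- match.arg(dialect)
  rn <- p$row_names; cn <- p$col_names
  if (dialect == "fixed") {
    rn <- substr(rn, 1, 8); cn <- substr(cn, 1, 8)
    dup <- c(rn[duplicated(rn)], cn[duplicated(cn)])
    if (length(dup))
      stop("name collision after 8-character truncation: ",
           paste(unique(dup), collapse = ", "))
    fmt <- .mps_fmt_num
    dat <- function(f1, f2, f3, f4 = "", f5 = "")
      sprintf(" %-2s %-8s  %-8s  %-12s   %-8s  %-12s", f1, f2, f3, f4, f5, "")
  } else {
    fmt <- function(x) sprintf("%.17G", x)
    dat <- function(f1, f2, f3, f4 = "", f5 = "")
      paste("", f1, f2, f3, f4, f5)  # leading blank: data line, not header
  }
  out <- c(sprintf("NAME          %s", p$name))
  if (p$sense == "max") out <- c(out, "OBJSENSE", "    MAX")
  out <- c(out, "ROWS", sprintf(" %-2s %s", "N", "OBJ"))
  mps_sense <- ifelse(p$row_sense == "R",
                      "G", p$row_sense) # R rows emitted as G + RANGES
  out <- c(out, sprintf(" %-2s %s", mps_sense, rn))
  out <- c(out, "COLUMNS")
  ord <- order(p$S$j, p$S$i)
  si <- p$S$i[ord]; sj <- p$S$j[ord]; sx <- p$S$x[ord]
  for (j in seq_len(p$n)) {   # all entries of one column grouped together
    sel <- which(sj == j)
    if (p$c_obj[j] != 0 || !length(sel))  # empty columns registered via OBJ
      out <- c(out, dat("", cn[j], "OBJ", fmt(p$c_obj[j])))
    if (length(sel))
      out <- c(out, sprintf(" %-2s %-8s  %-8s  %-12s", "", cn[j],
                            rn[si[sel]], fmt(sx[sel])))
  }
  out <- c(out, "RHS")
  nz <- which(p$rhs != 0)
  if (length(nz))
    out <- c(out, sprintf(" %-2s %-8s  %-8s  %-12s", "", "RHS", rn[nz], fmt(p$rhs[nz])))
  if (p$obj_constant != 0)
    out <- c(out, sprintf(" %-2s %-8s  %-8s  %-12s", "", "RHS", "OBJ",
                          fmt(-p$obj_constant)))
  rr <- which(p$row_sense == "R")
  if (length(rr)) {
    out <- c(out, "RANGES",
             sprintf(" %-2s %-8s  %-8s  %-12s", "", "RNG", rn[rr],
                     fmt(p$range[rr])))
  }
  out <- c(out, "BOUNDS")
  for (j in seq_len(p$n)) {
    l <- p$lower[j]; u <- p$upper[j]
    if (l == u) {
      out <- c(out, sprintf(" %-2s %-8s  %-8s  %-12s", "FX", "BND", cn[j], fmt(l)))
    } else {
      if (is.infinite(l) && is.infinite(u)) {
        out <- c(out, sprintf(" %-2s %-8s  %-8s", "FR", "BND", cn[j]))
        next
      }
      if (is.infinite(l))
        out <- c(out, sprintf(" %-2s %-8s  %-8s", "MI", "BND", cn[j]))
      else if (l != 0)
        out <- c(out, sprintf(" %-2s %-8s  %-8s  %-12s", "LO", "BND", cn[j], fmt(l)))
      if (is.finite(u))
        out <- c(out, sprintf(" %-2s %-8s  %-8s  %-12s", "UP", "BND", cn[j], fmt(u)))
    }
  }
  out <- c(out, "ENDATA")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
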