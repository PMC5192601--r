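# Exact rational arithmetic on double-backed integers.
#
# Rationals are stored as parallel numeric vectors/matrices of numerators and
# denominators, always fully reduced with positive denominators.  All values
# stay exact as long as |numerator| and |denominator| remain below 2^53; every
# operation checks this and aborts rather than silently losing exactness.

.RQ_MAX <- 2^53

rq_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(t != 0, t, a)
  }
  ifelse(a == 0, 1, a)
}

rq_check <- function(n, d) {
  if (any(!is.finite(n)) || any(!is.finite(d)))
    stop("rational overflow: non-finite value", call. = FALSE)
  if (any(abs(n) >= .RQ_MAX) || any(abs(d) >= .RQ_MAX))
    stop("rational overflow: magnitude exceeds 2^53, exactness lost",
         call. = FALSE)
  invisible(NULL)
}

#' Construct a reduced rational vector
#'
#' @param n integer-valued numerators.
#' @param d integer-valued denominators (recycled).
#' @return list with components `n` and `d`, reduced, `d > 0`.
#' @keywords internal
rq <- function(n, d = 1) {
  if (length(d) == 1L) d <- rep(d, length(n))
  if (any(d == 0)) stop("zero denominator", call. = FALSE)
  if (any(n != round(n)) || any(d != round(d)))
    stop("rational parts must be integer-valued", call. = FALSE)
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- rq_gcd(n, d)
  n <- n / g; d <- d / g
  rq_check(n, d)
  list(n = n, d = d)
}

.rq_recycle <- function(a, b) {
  la <- length(a$n); lb <- length(b$n)
  if (la == lb) return(list(a = a, b = b))
  if (la == 1L) a <- list(n = rep(a$n, lb), d = rep(a$d, lb))
  else if (lb == 1L) b <- list(n = rep(b$n, la), d = rep(b$d, la))
  else stop("incompatible rational vector lengths", call. = FALSE)
  list(a = a, b = b)
}

rq_add <- function(a, b) {
  r <- .rq_recycle(a, b); a <- r$a; b <- r$b
  # use gcd of denominators to keep intermediates small
  g <- rq_gcd(a$d, b$d)
  da <- a$d / g
  db <- b$d / g
  n <- a$n * db + b$n * da
  d <- da * b$d
  rq_check(n, d)
  rq(n, d)
}

rq_sub <- function(a, b) rq_add(a, list(n = -b$n, d = b$d))

rq_mul <- function(a, b) {
  r <- .rq_recycle(a, b); a <- r$a; b <- r$b
  g1 <- rq_gcd(a$n, b$d)
  g2 <- rq_gcd(b$n, a$d)
  n <- (a$n / g1) * (b$n / g2)
  d <- (a$d / g2) * (b$d / g1)
  rq_check(n, d)
  rq(n, d)
}

rq_div <- function(a, b) {
  if (any(b$n == 0)) stop("division by zero rational", call. = FALSE)
  rq_mul(a, list(n = b$d, d = b$n))
}

rq_neg <- function(a) list(n = -a$n, d = a$d)

rq_eq <- function(a, b) a$n * b$d == b$n * a$d

rq_is_zero <- function(a) a$n == 0

rq_as_numeric <- function(a) a$n / a$d

rq_scalar <- function(n, d = 1) rq(n, d)

#' Exact rational from a decimal string
#'
#' Parses strings such as `"0.25"`, `"-3"`, `"1/3"`, `"5e-2"` into exact
#' rationals (decimal notation is interpreted as an exact base-10 fraction).
#' @keywords internal
rq_parse <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([+-]?[0-9]+)\\s*/\\s*([0-9]+)$", text))[[1]]
  if (length(m) == 3L)
    return(rq(as.numeric(m[2]), as.numeric(m[3])))
  m <- regmatches(
    text,
    regexec("^([+-]?)([0-9]*)(?:\\.([0-9]*))?(?:[eE]([+-]?[0-9]+))?$", text)
  )[[1]]
  if (length(m) == 0L || (m[3] == "" && m[4] == ""))
    stop(sprintf("cannot parse '%s' as a rational number", text),
         call. = FALSE)
  sign <- if (m[2] == "-") -1 else 1
  intpart <- if (m[3] == "") 0 else as.numeric(m[3])
  fracdigits <- m[4]
  ex <- if (m[5] == "") 0 else as.numeric(m[5])
  n <- intpart
  d <- 1
  if (fracdigits != "") {
    d <- 10^nchar(fracdigits)
    n <- intpart * d + as.numeric(fracdigits)
  }
  if (ex > 0) n <- n * 10^ex
  if (ex < 0) d <- d * 10^(-ex)
  rq(sign * n, d)
}

#' Format rationals as strings such as "3", "-1/2"
#' @keywords internal
rq_format <- function(a) {
  ifelse(a$d == 1, sprintf("%.0f", a$n), sprintf("%.0f/%.0f", a$n, a$d))
}

#' Best rational approximation of a double (continued fractions)
#'
#' Used when importing floating-point data (e.g. foreign SBML stoichiometry).
#' @keywords internal
rq_from_double <- function(x, tol = 1e-9, max_den = 1e6) {
  out_n <- numeric(length(x)); out_d <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    if (!is.finite(xi)) stop("cannot rationalise non-finite value")
    h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1; b <- xi
    repeat {
      a <- floor(b)
      h2 <- a * h1 + h0; k2 <- a * k1 + k0
      if (k2 > max_den) break
      h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
      if (abs(xi - h1 / k1) < tol * max(1, abs(xi))) break
      if (b == a) break
      b <- 1 / (b - a)
    }
    out_n[i] <- h1; out_d[i] <- k1
  }
  rq(out_n, out_d)
}

# ---- rational matrices ----------------------------------------------------

rq_mat <- function(n, d = NULL) {
  if (is.null(d)) d <- array(1, dim(n))
  stopifnot(all(dim(n) == dim(d)))
  v <- rq(as.numeric(n), as.numeric(d))
  list(n = array(v$n, dim(n), dimnames = dimnames(n)),
       d = array(v$d, dim(n), dimnames = dimnames(n)))
}

rq_mat_from_numeric <- function(m) {
  if (any(m != round(m))) stop("matrix not integer-valued")
  rq_mat(m)
}

rq_mat_as_numeric <- function(M) M$n / M$d

rq_mat_dim <- function(M) dim(M$n)

rq_row <- function(M, i) list(n = M$n[i, , drop = TRUE], d = M$d[i, , drop = TRUE])

rq_mat_t <- function(M) list(n = t(M$n), d = t(M$d))

# row <- row + s * other  (s scalar rational, rows as rq vectors)
rq_axpy <- function(row, s, other) {
  prod <- rq_mul(other, list(n = rep(s$n, length(other$n)),
                             d = rep(s$d, length(other$n))))
  rq_add(row, prod)
}

#' Reduced row echelon form of a rational matrix
#'
#' @return list(mat = rref matrix (rq), pivots = pivot column indices,
#'   rank = integer, ops = row operation log unused)
#' @keywords internal
rq_rref <- function(M) {
  dims <- rq_mat_dim(M)
  nr <- dims[1]; nc <- dims[2]
  N <- M$n; D <- M$d
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(nc)) {
    if (r > nr) break
    # choose pivot: nonzero entry in rows r..nr with smallest magnitude
    cand <- which(N[r:nr, col] != 0) + r - 1L
    if (length(cand) == 0L) next
    mag <- abs(N[cand, col] / D[cand, col])
    p <- cand[which.min(abs(log(mag))) ]
    if (p != r) {
      tmp <- N[r, ]; N[r, ] <- N[p, ]; N[p, ] <- tmp
      tmp <- D[r, ]; D[r, ] <- D[p, ]; D[p, ] <- tmp
    }
    # scale pivot row to 1
    pn <- N[r, col]; pd <- D[r, col]
    row <- rq_mul(list(n = N[r, ], d = D[r, ]), rq_scalar(pd, pn))
    N[r, ] <- row$n; D[r, ] <- row$d
    # eliminate in all other rows
    other <- which(N[, col] != 0)
    other <- setdiff(other, r)
    for (i in other) {
      s <- rq_scalar(-N[i, col], D[i, col])
      newrow <- rq_axpy(list(n = N[i, ], d = D[i, ]), s,
                        list(n = N[r, ], d = D[r, ]))
      N[i, ] <- newrow$n; D[i, ] <- newrow$d
    }
    pivots <- c(pivots, col)
    r <- r + 1L
  }
  list(mat = list(n = N, d = D), pivots = pivots, rank = length(pivots))
}

#' Exact rational right-nullspace basis
#'
#' Returns a matrix (columns = basis vectors) with integer entries scaled to
#' smallest magnitude (entries divided by their gcd, times lcm of
#' denominators).
#' @keywords internal
rq_nullspace <- function(M) {
  dims <- rq_mat_dim(M)
  nc <- dims[2]
  if (dims[1] == 0L) {
    basis <- diag(1, nc)
    return(basis)
  }
  rr <- rq_rref(M)
  piv <- rr$pivots
  free <- setdiff(seq_len(nc), piv)
  if (length(free) == 0L) return(matrix(0, nc, 0))
  N <- rr$mat$n; D <- rr$mat$d
  out <- matrix(0, nc, length(free))
  for (j in seq_along(free)) {
    fc <- free[j]
    vn <- numeric(nc); vd <- rep(1, nc)
    vn[fc] <- 1
    if (length(piv) > 0) {
      vn[piv] <- -N[seq_along(piv), fc]
      vd[piv] <- D[seq_along(piv), fc]
    }
    out[, j] <- rq_integerise(list(n = vn, d = vd))
  }
  out
}

# scale a rational vector to coprime integers (keeps sign pattern)
rq_integerise <- function(v) {
  d <- v$d
  l <- 1
  for (di in unique(d)) {
    l <- l / rq_gcd(l, di) * di
    if (l >= .RQ_MAX) stop("rational overflow while integerising")
  }
  ints <- v$n * (l / v$d)
  rq_check(ints, 1)
  nz <- ints[ints != 0]
  if (length(nz) == 0) return(ints)
  g <- Reduce(rq_gcd, abs(nz))
  ints / g
}

# Clear denominators along rows or columns (margin 1 = rows, 2 = cols).
# Row scaling preserves the right nullspace, column scaling the left one.
rq_mat_integerise <- function(M, margin = 1L) {
  N <- M$n; D <- M$d
  dims <- dim(N)
  if (margin == 1L) {
    for (i in seq_len(dims[1])) {
      l <- 1
      for (di in unique(D[i, ])) {
        l <- l / rq_gcd(l, di) * di
        if (l >= .RQ_MAX) stop("rational overflow while scaling")
      }
      N[i, ] <- N[i, ] * (l / D[i, ]); D[i, ] <- 1
      nz <- abs(N[i, N[i, ] != 0])
      if (length(nz)) {
        g <- Reduce(rq_gcd, nz)
        N[i, ] <- N[i, ] / g
      }
    }
  } else {
    for (j in seq_len(dims[2])) {
      l <- 1
      for (di in unique(D[, j])) {
        l <- l / rq_gcd(l, di) * di
        if (l >= .RQ_MAX) stop("rational overflow while scaling")
      }
      N[, j] <- N[, j] * (l / D[, j]); D[, j] <- 1
      nz <- abs(N[N[, j] != 0, j])
      if (length(nz)) {
        g <- Reduce(rq_gcd, nz)
        N[, j] <- N[, j] / g
      }
    }
  }
  rq_check(N, 1)
  list(n = N, d = D)
}

#' Exact matrix-vector product S v with integer inputs; returns rationals
#' @keywords internal
rq_matvec_int <- function(M, v) {
  # M rational matrix, v integer vector -> rq vector of length nrow
  dims <- rq_mat_dim(M)
  out_n <- numeric(dims[1]); out_d <- rep(1, dims[1])
  for (i in seq_len(dims[1])) {
    acc <- rq_scalar(0)
    nz <- which(M$n[i, ] != 0 & v != 0)
    for (j in nz) {
      term <- rq_mul(rq_scalar(M$n[i, j], M$d[i, j]), rq_scalar(v[j]))
      acc <- rq_add(acc, term)
    }
    out_n[i] <- acc$n; out_d[i] <- acc$d
  }
  list(n = out_n, d = out_d)
}
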