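# Independent brute-force oracles.  These deliberately avoid the package's
# double-description and LP code paths: EFMs by support enumeration over a
# floating-point nullspace, LP optima by vertex enumeration with base-R
# linear algebra.

# numeric nullspace via SVD (the oracle may use floats; candidate supports
# are validated by exact substitution afterwards)
.num_nullspace <- function(A, tol = 1e-9) {
  if (nrow(A) == 0L) return(diag(1, ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  keep <- c(sv$d, rep(0, ncol(A) - length(sv$d))) < tol * max(sv$d, 1)
  sv$v[, keep, drop = FALSE]
}

# all elementary flux modes by enumeration over column supports
oracle_efms <- function(net) {
  sm <- stoich_matrix(net)
  S <- sm$S$n / sm$S$d
  n <- ncol(S)
  stopifnot(n <= 14)
  rev <- sm$reversible
  modes <- list()
  for (mask in seq_len(2^n - 1L)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    B <- .num_nullspace(S[, supp, drop = FALSE])
    if (ncol(B) != 1L) next
    v <- B[, 1]
    if (any(abs(v) < 1e-9)) next        # support not exact -> smaller support
    full <- numeric(n); full[supp] <- v
    # orient: irreversible components must be non-negative
    if (any(full < -1e-9 & !rev)) full <- -full
    if (any(full < -1e-9 & !rev)) next
    # canonical sign: first nonzero positive
    if (full[supp[1]] < 0) {
      if (any(rev[supp]) && all(rev[supp] | full > -1e-9)) full <- -full
    }
    if (full[supp[1]] < 0) next
    full <- full / min(abs(full[supp]))
    modes[[length(modes) + 1L]] <- list(supp = supp, v = full)
  }
  # keep support-minimal only, deduplicate
  keep <- rep(TRUE, length(modes))
  for (i in seq_along(modes)) for (j in seq_along(modes)) {
    if (i == j || !keep[i] || !keep[j]) next
    if (all(modes[[j]]$supp %in% modes[[i]]$supp) &&
        length(modes[[j]]$supp) < length(modes[[i]]$supp)) keep[i] <- FALSE
  }
  modes <- modes[keep]
  seen <- character(0); out <- list()
  for (m in modes) {
    key <- paste(m$supp, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    v <- m$v
    names(v) <- sm$transformers
    out[[length(out) + 1L]] <- v[abs(v) > 1e-9]
  }
  out
}

# LP optimum by vertex enumeration for problems whose only constraints are
# the steady-state equalities and variable bounds (as built by gen_lp)
oracle_lp_optimum <- function(net, scenario) {
  lp <- plantflux:::build_lp(net, scenario)
  stopifnot(length(lp$sense) == lp$n_species_rows)  # bounds only
  S <- matrix(0, lp$n_species_rows, lp$ncol)
  for (k in seq_along(lp$rows$i)) S[lp$rows$i[k], lp$rows$j[k]] <- lp$rows$x[k]
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  n <- lp$ncol
  m <- qr(S)$rank
  free <- n - m
  bounds <- rbind(data.frame(j = seq_len(n), val = lp$lb),
                  data.frame(j = seq_len(n), val = lp$ub))
  bounds <- bounds[is.finite(bounds$val), ]
  if (free == 0L) combos <- list(integer(0)) else {
    stopifnot(nrow(bounds) >= free)
    combos <- utils::combn(seq_len(nrow(bounds)), free, simplify = FALSE)
  }
  best <- -Inf; best_v <- NULL
  cvec <- numeric(n)
  for (id in names(scenario$objective))
    cvec[match(id, lp$ids)] <- scenario$objective[[id]]
  for (cb in combos) {
    A <- S; b <- rep(0, nrow(S))
    for (q in cb) {
      row <- numeric(n); row[bounds$j[q]] <- 1
      A <- rbind(A, row); b <- c(b, bounds$val[q])
    }
    v <- tryCatch(qr.solve(A, b, tol = 1e-12), error = function(e) NULL)
    if (is.null(v)) next
    if (any(v < lp$lb - 1e-8) || any(v > lp$ub + 1e-8)) next
    if (max(abs(S %*% v)) > 1e-8) next
    z <- sum(cvec * v)
    if (z > best + 1e-12) { best <- z; best_v <- v }
  }
  list(optimum = best, vertex = stats::setNames(best_v, lp$ids))
}
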