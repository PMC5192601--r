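# Stoichiometric-matrix topology: degrees of freedom, nullspace, conserved
# moieties (left-kernel extreme rays), dead ends, internal parallel routes,
# small-scale elementary flux modes.  All kernel computations are exact
# (integer/rational); the counts they produce must not depend on a floating
# rank tolerance.

#' Stoichiometric matrix of a network
#'
#' Rows are balanced species (network order), columns transformers (network
#' order); unbalanced species contribute no steady-state row.
#'
#' @param net a `pf_network`.
#' @return object of class `stoich_matrix`: `S` (rational matrix as n/d
#'   pair), `species`, `transformers`, `exchange` (logical per column),
#'   `reversible` (logical per column).
#' @export
stoich_matrix <- function(net) {
  sp_ids <- names(net$species)[vapply(net$species, function(s) s$balanced, TRUE)]
  tr_ids <- names(net$transformers)
  N <- matrix(0, length(sp_ids), length(tr_ids),
              dimnames = list(sp_ids, tr_ids))
  D <- matrix(1, length(sp_ids), length(tr_ids),
              dimnames = list(sp_ids, tr_ids))
  for (j in seq_along(tr_ids)) {
    tr <- net$transformers[[j]]
    for (k in seq_along(tr$stoich$ids)) {
      sid <- tr$stoich$ids[k]
      if (sid %in% sp_ids) {
        N[sid, j] <- tr$stoich$n[k]
        D[sid, j] <- tr$stoich$d[k]
      }
    }
  }
  structure(list(S = list(n = N, d = D), species = sp_ids,
                 transformers = tr_ids,
                 exchange = vapply(tr_ids, function(id) is_exchange(net, id), TRUE),
                 reversible = vapply(net$transformers, `[[`, TRUE, "reversible")),
            class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat(sprintf("<stoich_matrix> %d species x %d transformers (%d exchange)\n",
              length(x$species), length(x$transformers), sum(x$exchange)))
  invisible(x)
}

#' Degrees of freedom of the flux space
#'
#' `total` = columns - rank(S); `inner` = dimension of the internal cycle
#' space (null vectors vanishing on exchange columns), i.e. the number of
#' independent parallel routes; `outer = total - inner`.
#'
#' @param sm a `stoich_matrix` (or network).
#' @param exchange optional logical override of the exchange columns.
#' @export
degrees_of_freedom <- function(sm, exchange = NULL) {
  if (inherits(sm, "pf_network")) sm <- stoich_matrix(sm)
  if (is.null(exchange)) exchange <- sm$exchange
  nc <- length(sm$transformers)
  rk <- if (length(sm$species) == 0L) 0L else
    rq_rref(rq_mat_integerise(sm$S, 1L))$rank
  total <- nc - rk
  internal <- which(!exchange)
  if (length(internal) == 0L) {
    inner <- 0L
  } else {
    Sint <- list(n = sm$S$n[, internal, drop = FALSE],
                 d = sm$S$d[, internal, drop = FALSE])
    rki <- if (length(sm$species) == 0L) 0L else
      rq_rref(rq_mat_integerise(Sint, 1L))$rank
    inner <- length(internal) - rki
  }
  list(total = total, inner = inner, outer = total - inner)
}

#' Exact integer basis of the right nullspace of S
#'
#' @param sm a `stoich_matrix` (or network).
#' @return integer matrix, one basis vector per column, rows named by
#'   transformer id; dimension equals the total degrees of freedom.
#' @export
nullspace_basis <- function(sm) {
  if (inherits(sm, "pf_network")) sm <- stoich_matrix(sm)
  B <- rq_nullspace(rq_mat_integerise(sm$S, 1L))
  rownames(B) <- sm$transformers
  B
}

#' Internal parallel routes and cycles
#'
#' Basis of the internal-cycle space: flux vectors with `S v = 0` that are
#' zero on every exchange column (no net consumption or production of any
#' external species).
#'
#' @param sm a `stoich_matrix` (or network).
#' @return object of class `route_set`: list of named integer vectors over
#'   the participating transformers.
#' @export
parallel_routes <- function(sm) {
  if (inherits(sm, "pf_network")) sm <- stoich_matrix(sm)
  internal <- which(!sm$exchange)
  routes <- list()
  if (length(internal)) {
    Sint <- rq_mat_integerise(
      list(n = sm$S$n[, internal, drop = FALSE],
           d = sm$S$d[, internal, drop = FALSE]), 1L)
    B <- rq_nullspace(Sint)
    for (j in seq_len(ncol(B))) {
      v <- B[, j]
      names(v) <- sm$transformers[internal]
      routes[[j]] <- v[v != 0]
    }
  }
  structure(list(routes = routes, n = length(routes)), class = "route_set")
}

#' @export
print.route_set <- function(x, ...) {
  cat(sprintf("<route_set> %d internal parallel route(s)/cycle(s)\n", x$n))
  for (i in seq_len(x$n)) {
    r <- x$routes[[i]]
    cat(sprintf("  [%d] %s\n", i,
                paste(sprintf("%+d %s", r, names(r)), collapse = "  ")))
  }
  invisible(x)
}

#' Dead-end species
#'
#' Balanced species that can only be produced or only consumed across all
#' transformers (a species touched by a reversible transformer can be moved
#' both ways and is therefore not a dead end through that transformer).
#'
#' @param net a `pf_network`.
#' @return character vector of species ids.
#' @export
dead_ends <- function(net) {
  prod <- cons <- stats::setNames(logical(length(net$species)),
                                  names(net$species))
  for (tr in net$transformers) {
    for (k in seq_along(tr$stoich$ids)) {
      sid <- tr$stoich$ids[k]
      pos <- tr$stoich$n[k] > 0
      if (pos || tr$reversible) prod[sid] <- TRUE
      if (!pos || tr$reversible) cons[sid] <- TRUE
    }
  }
  bal <- vapply(net$species, function(s) s$balanced, TRUE)
  names(which(bal & (!prod | !cons)))
}

# ---- double description ---------------------------------------------------

# Extreme rays of the pointed cone {x in R^d : A x >= 0}, A integer with full
# column rank d.  Incremental double description with combinatorial adjacency
# test; exact integer arithmetic throughout.
dd_extreme_rays <- function(A, max_rays = 10000L) {
  d <- ncol(A)
  if (d == 0L) return(matrix(0, 0, 0))
  m <- nrow(A)
  Aq <- rq_mat_from_numeric(A)
  # find d independent rows for initialisation
  rr <- rq_rref(rq_mat_t(Aq))   # rref of A^T: pivot columns = independent rows
  rows0 <- rr$pivots
  if (length(rows0) < d)
    stop("constraint matrix does not define a pointed cone", call. = FALSE)
  A0 <- A[rows0, , drop = FALSE]
  # rays of {x : A0 x >= 0} are the columns of A0^{-1} (up to scaling)
  aug <- rq_rref(rq_mat_from_numeric(cbind(A0, diag(1, d))))
  stopifnot(identical(aug$pivots, seq_len(d)))
  rays <- matrix(0, d, d)
  for (i in seq_len(d)) {
    rays[, i] <- rq_integerise(list(n = aug$mat$n[, d + i],
                                    d = aug$mat$d[, d + i]))
  }
  if (ncol(rays) > max_rays)
    stop(sprintf("extreme-ray enumeration exceeded limit of %d rays",
                 max_rays), call. = FALSE)
  processed <- rows0
  remaining <- setdiff(seq_len(m), rows0)
  for (row in remaining) {
    a <- A[row, ]
    val <- as.numeric(rays_dot(a, rays))
    pos <- which(val > 0); neg <- which(val < 0); zer <- which(val == 0)
    if (length(neg) == 0L) { processed <- c(processed, row); next }
    keep <- rays[, c(pos, zer), drop = FALSE]
    new <- list()
    if (length(pos)) {
      # zero sets w.r.t. processed rows, for adjacency testing
      Zs <- lapply(seq_len(ncol(rays)), function(j)
        processed[rays_dot_rows(A[processed, , drop = FALSE], rays[, j]) == 0])
      for (p in pos) for (q in neg) {
        zi <- intersect(Zs[[p]], Zs[[q]])
        if (length(zi) < d - 2L) next
        adjacent <- TRUE
        for (k in seq_len(ncol(rays))) {
          if (k == p || k == q) next
          if (all(zi %in% Zs[[k]])) { adjacent <- FALSE; break }
        }
        if (!adjacent) next
        comb <- val[p] * rays[, q] - val[q] * rays[, p]
        comb <- comb / Reduce(rq_gcd, abs(comb[comb != 0]))
        rq_check(comb, 1)
        new[[length(new) + 1L]] <- comb
      }
    }
    rays <- cbind(keep, if (length(new)) do.call(cbind, new))
    if (is.null(dim(rays))) rays <- matrix(rays, nrow = d)
    if (ncol(rays) > max_rays)
      stop(sprintf("extreme-ray enumeration exceeded limit of %d rays",
                   max_rays), call. = FALSE)
    # deduplicate
    if (ncol(rays) > 1L) {
      key <- apply(rays, 2, paste, collapse = ",")
      rays <- rays[, !duplicated(key), drop = FALSE]
    }
    processed <- c(processed, row)
  }
  rays
}

rays_dot <- function(a, rays) as.numeric(crossprod(a, rays))
rays_dot_rows <- function(Arows, ray) as.numeric(Arows %*% ray)

#' Conserved moieties: non-negative left-kernel extreme rays
#'
#' Computes the generators (extreme rays) of the cone
#' `{w >= 0 : w' S = 0}` by double description over a basis of the left
#' kernel of S, canonicalised to the smallest integer weights.  Each moiety
#' is a weighted species set whose total amount is invariant under every
#' transformer.
#'
#' @param sm a `stoich_matrix` (or network).
#' @param max_rays resource guard; exceeded enumeration raises an error
#'   rather than truncating silently.
#' @return object of class `moiety_set`: list of named positive integer
#'   weight vectors with heuristic labels.
#' @export
conserved_moieties <- function(sm, max_rays = 10000L) {
  if (inherits(sm, "pf_network")) sm <- stoich_matrix(sm)
  St <- rq_mat_integerise(rq_mat_t(sm$S), 1L)  # rows = transformers
  K <- rq_nullspace(St)          # species x d basis of left kernel
  if (ncol(K) == 0L)
    return(structure(list(moieties = list(), n = 0L), class = "moiety_set"))
  rays <- dd_extreme_rays(K, max_rays = max_rays)
  moieties <- list()
  for (j in seq_len(ncol(rays))) {
    w <- as.numeric(K %*% rays[, j])
    stopifnot(all(w >= 0))
    w <- w / Reduce(rq_gcd, abs(w[w != 0]))
    names(w) <- sm$species
    w <- w[w != 0]
    moieties[[length(moieties) + 1L]] <- w
  }
  # canonical order: by support size then first member id
  ord <- order(vapply(moieties, length, 0L),
               vapply(moieties, function(w) names(w)[1], ""))
  moieties <- moieties[ord]
  labels <- vapply(moieties, function(w)
    paste(names(w), collapse = "/"), "")
  structure(list(moieties = stats::setNames(moieties, labels),
                 n = length(moieties)), class = "moiety_set")
}

#' @export
print.moiety_set <- function(x, ...) {
  cat(sprintf("<moiety_set> %d conserved moiet%s\n", x$n,
              if (x$n == 1) "y" else "ies"))
  for (i in seq_len(x$n)) {
    w <- x$moieties[[i]]
    cat(sprintf("  [%d] %s\n", i,
                paste(sprintf("%s x%d", names(w), w), collapse = " + ")))
  }
  invisible(x)
}

#' Elementary flux modes (small networks)
#'
#' Support-minimal steady-state flux patterns honouring irreversibility,
#' computed by double description after splitting reversible transformers,
#' then re-merged (a reversible mode is reported once, sign fixed so that
#' its lexicographically first participating transformer is positive).
#'
#' @param net a `pf_network` or `stoich_matrix`.
#' @param max_modes resource guard on the enumeration.
#' @return list of named numeric flux vectors (integer entries).
#' @export
elementary_modes <- function(net, max_modes = 5000L) {
  sm <- if (inherits(net, "pf_network")) stoich_matrix(net) else net
  nrx <- length(sm$transformers)
  rev <- sm$reversible
  # split: columns = [all forward, reverse copies of reversible]
  Nn <- cbind(sm$S$n, -sm$S$n[, rev, drop = FALSE])
  Dd <- cbind(sm$S$d, sm$S$d[, rev, drop = FALSE])
  split_ids <- c(sm$transformers, paste0(sm$transformers[rev], "!rev"))
  K <- rq_nullspace(rq_mat_integerise(list(n = Nn, d = Dd), 1L))
  if (ncol(K) == 0L) return(list())
  rays <- dd_extreme_rays(K, max_rays = max_modes)
  modes <- list()
  seen <- character(0)
  for (j in seq_len(ncol(rays))) {
    v_split <- as.numeric(K %*% rays[, j])
    v <- v_split[seq_len(nrx)]
    if (any(rev)) v[rev] <- v[rev] - v_split[nrx + seq_len(sum(rev))]
    if (all(v == 0)) next   # forward/backward futile pair of one reversible
    names(v) <- sm$transformers
    supp <- which(v != 0)
    if (v[supp[1]] < 0) v <- -v
    if (any(v < 0 & !rev)) next
    v <- v / Reduce(rq_gcd, abs(v[v != 0]))
    key <- paste(sprintf("%s:%g", names(v)[v != 0], v[v != 0]), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    modes[[length(modes) + 1L]] <- v[v != 0]
  }
  # enforce support minimality across merged modes
  supps <- lapply(modes, names)
  keep <- rep(TRUE, length(modes))
  for (i in seq_along(modes)) for (k in seq_along(modes)) {
    if (i != k && keep[i] && keep[k] &&
        all(supps[[k]] %in% supps[[i]]) &&
        length(supps[[k]]) < length(supps[[i]])) keep[i] <- FALSE
  }
  if (length(modes) > max_modes)
    stop(sprintf("elementary mode count exceeds max_modes = %d", max_modes),
         call. = FALSE)
  modes[keep]
}
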