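# Elemental formulas with exact rational counts and integer charge.

.PERIODIC <- c(
  H = 1.008, He = 4.0026, Li = 6.94, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.99, Mg = 24.305, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971,
  Mo = 95.95, I = 126.9
)

.is_abstract_element <- function(sym) grepl("^E[0-9]+$", sym)

#' Elemental formula with rational counts
#'
#' Construct an elemental formula from a named vector of counts.  Counts may
#' be integers or strings holding exact decimals/fractions (`"1.592"`,
#' `"5/3"`); they are stored as exact rationals.
#'
#' @param elements named vector (names = element symbols from the periodic
#'   table, or abstract symbols `E1`, `E2`, ... used by synthetic fixtures).
#' @param charge integer net charge in elementary units.
#' @return object of class `elemental_formula` with fields `n`, `d`
#'   (numerator/denominator per element) and `charge`.
#' @export
make_formula <- function(elements = numeric(0), charge = 0L) {
  chg <- if (is.character(charge)) rq_parse(charge) else
    rq_scalar(round(charge * 1e6), 1e6)
  if (length(elements) == 0L)
    return(structure(list(n = numeric(0), d = numeric(0), charge = chg),
                     class = "elemental_formula"))
  syms <- names(elements)
  if (is.null(syms) || any(syms == ""))
    stop("element counts must be named", call. = FALSE)
  bad <- syms[!(syms %in% names(.PERIODIC)) & !.is_abstract_element(syms)]
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.character(elements)) {
    parsed <- lapply(elements, rq_parse)
    v <- list(n = vapply(parsed, `[[`, 0, "n"),
              d = vapply(parsed, `[[`, 0, "d"))
  } else {
    if (any(elements != round(elements)))
      stop("numeric counts must be integers; pass strings for fractions",
           call. = FALSE)
    v <- rq(as.numeric(elements))
  }
  if (any(v$n < 0)) stop("element counts must be non-negative", call. = FALSE)
  keep <- v$n != 0
  structure(list(n = stats::setNames(v$n[keep], syms[keep]),
                 d = stats::setNames(v$d[keep], syms[keep]),
                 charge = chg),
            class = "elemental_formula")
}

#' Parse a Hill-style formula string
#'
#' Subscripts may be integers, exact decimals (`O0.834`) or fractions
#' (`H5/3`).  An empty string gives the massless formula (used for electron
#' and redox-carrier bookkeeping species).
#'
#' @param text formula string, e.g. `"C12H22O11"`.
#' @param charge integer charge.
#' @return an `elemental_formula`.
#' @examples
#' parse_formula("C12H22O11", 0)
#' parse_formula("CH1.592O0.834N0.144P0.033", 0)
#' @export
parse_formula <- function(text, charge = 0L) {
  text <- trimws(text)
  if (text == "" || text == ".")
    return(make_formula(charge = charge))
  chg <- if (is.character(charge)) rq_parse(charge) else
    rq_scalar(round(charge * 1e6), 1e6)
  pat <- "([A-Z][a-z]?[0-9]*(?:(?<=E[0-9])[0-9]*)?)"
  # tokenise: element symbol followed by optional subscript
  tok_pat <- "(E[0-9]+|[A-Z][a-z]?)((?:[0-9]+/[0-9]+)|(?:[0-9]*\\.?[0-9]*))"
  pos <- 1L
  n <- numeric(0); d <- numeric(0); syms <- character(0)
  while (pos <= nchar(text)) {
    rest <- substring(text, pos)
    m <- regexec(paste0("^", tok_pat), rest, perl = TRUE)[[1]]
    if (m[1] == -1)
      stop(sprintf("malformed formula near '%s' in \"%s\"", rest, text),
           call. = FALSE)
    len <- attr(m, "match.length")[1]
    sym <- regmatches(rest, regexec(paste0("^", tok_pat), rest, perl = TRUE))[[1]][2]
    sub <- regmatches(rest, regexec(paste0("^", tok_pat), rest, perl = TRUE))[[1]][3]
    if (!(sym %in% names(.PERIODIC)) && !.is_abstract_element(sym))
      stop(sprintf("unknown element symbol '%s' in \"%s\"", sym, text),
           call. = FALSE)
    cnt <- if (sub == "") rq_scalar(1) else rq_parse(sub)
    i <- match(sym, syms)
    if (is.na(i)) {
      syms <- c(syms, sym); n <- c(n, cnt$n); d <- c(d, cnt$d)
    } else {
      s <- rq_add(rq_scalar(n[i], d[i]), cnt)
      n[i] <- s$n; d[i] <- s$d
    }
    pos <- pos + len
  }
  keep <- n != 0
  structure(list(n = stats::setNames(n[keep], syms[keep]),
                 d = stats::setNames(d[keep], syms[keep]),
                 charge = chg),
            class = "elemental_formula")
}

#' Format an elemental formula as a Hill-style string
#' @param f an `elemental_formula`.
#' @export
format_formula <- function(f) {
  if (length(f$n) == 0L) return("")
  syms <- names(f$n)
  ord <- if ("C" %in% syms) {
    c("C", "H"[("H" %in% syms)], sort(setdiff(syms, c("C", "H"))))
  } else sort(syms)
  ord <- ord[ord %in% syms]
  paste0(vapply(ord, function(s) {
    i <- match(s, syms)
    if (f$n[i] == 1 && f$d[i] == 1) return(s)
    if (f$d[i] == 1) return(sprintf("%s%.0f", s, f$n[i]))
    sprintf("%s%.0f/%.0f", s, f$n[i], f$d[i])
  }, ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(sprintf("<formula> %s  charge %s\n",
              if (length(x$n)) format_formula(x) else "(massless)",
              rq_format(x$charge)))
  invisible(x)
}

#' Molar mass of a formula in g/mol
#' @param f an `elemental_formula`.
#' @export
formula_mass <- function(f) {
  if (length(f$n) == 0L) return(0)
  if (any(.is_abstract_element(names(f$n))))
    stop("abstract elements have no mass", call. = FALSE)
  sum(.PERIODIC[names(f$n)] * f$n / f$d)
}

# Weighted sum of formulas: coefs = rq vector, formulas = list.
# Returns list(elements = rq named, charge = rq scalar).
formula_weighted_sum <- function(coefs, formulas) {
  acc_n <- numeric(0); acc_d <- numeric(0); syms <- character(0)
  chg <- rq_scalar(0)
  for (k in seq_along(formulas)) {
    cf <- rq_scalar(coefs$n[k], coefs$d[k])
    f <- formulas[[k]]
    chg <- rq_add(chg, rq_mul(cf, f$charge))
    for (j in seq_along(f$n)) {
      term <- rq_mul(cf, rq_scalar(f$n[j], f$d[j]))
      sym <- names(f$n)[j]
      i <- match(sym, syms)
      if (is.na(i)) {
        syms <- c(syms, sym); acc_n <- c(acc_n, term$n); acc_d <- c(acc_d, term$d)
      } else {
        s <- rq_add(rq_scalar(acc_n[i], acc_d[i]), term)
        acc_n[i] <- s$n; acc_d[i] <- s$d
      }
    }
  }
  keep <- acc_n != 0
  list(elements = list(n = stats::setNames(acc_n[keep], syms[keep]),
                       d = stats::setNames(acc_d[keep], syms[keep])),
       charge = chg)
}
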