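# Exact arbitrary-precision integer arithmetic.
#
# Counting formulas for spinal network classes produce values well beyond
# 2^53 (double precision), so all counts are carried as exact integers in a
# small sign-and-magnitude representation: base-1e6 digit vectors stored
# little-endian in a double vector (every digit and every carry stays far
# below 2^53). Only the operations the counting module needs are provided:
# add, subtract, multiply, small powers, factorials, binomials, comparison,
# and *exact* division by small integers. Division by factorials or powers
# of two is routed through prime factorisation so that every intermediate
# division step is exact.

.BIG_BASE <- 1e6

#' Exact arbitrary-precision integers
#'
#' Create a `bigint`, an exact integer of unbounded size. Accepts doubles
#' that represent integers exactly (|x| < 2^53), integers, decimal strings
#' (optionally signed), or an existing `bigint`.
#'
#' @param x value to convert.
#' @return An object of class `bigint`.
#' @examples
#' as_bigint("123456789012345678901234567890") + 1
#' big_factorial(30)
#' @export
as_bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    s <- trimws(x)
    neg <- startsWith(s, "-")
    if (neg || startsWith(s, "+")) s <- substring(s, 2L)
    if (!nzchar(s) || grepl("[^0-9]", s)) stop("not a decimal integer string: ", x)
    s <- sub("^0+(?=.)", "", s, perl = TRUE)
    nd <- ceiling(nchar(s) / 6)
    pad <- strrep("0", nd * 6 - nchar(s))
    s <- paste0(pad, s)
    chunks <- substring(s, seq(1L, nd * 6 - 5L, by = 6L), seq(6L, nd * 6, by = 6L))
    d <- rev(as.numeric(chunks))
    return(.big_norm(d, if (neg) -1L else 1L))
  }
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L, !is.na(x))
    if (x != trunc(x) || abs(x) >= 2^53)
      stop("numeric value is not an exactly representable integer: ", x)
    sign <- if (x < 0) -1L else 1L
    x <- abs(x)
    d <- numeric(0)
    repeat {
      d <- c(d, x %% .BIG_BASE)
      x <- (x - x %% .BIG_BASE) / .BIG_BASE
      if (x == 0) break
    }
    return(.big_norm(d, sign))
  }
  stop("cannot convert to bigint: class ", paste(class(x), collapse = "/"))
}

.big_norm <- function(d, sign) {
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  if (length(d) == 0L) d <- 0
  if (length(d) == 1L && d[1L] == 0) sign <- 0L
  structure(list(sign = as.integer(sign), d = d), class = "bigint")
}

.big_is_zero <- function(x) x$sign == 0L

# magnitude compare: -1, 0, 1
.ucmp <- function(a, b) {
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

.uadd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a))); b <- c(b, numeric(n - length(b)))
  d <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    d[i] <- d[i] + carry
    carry <- if (d[i] >= .BIG_BASE) 1 else 0
    if (carry) d[i] <- d[i] - .BIG_BASE
  }
  if (carry) d <- c(d, 1)
  d
}

# requires magnitude(a) >= magnitude(b)
.usub <- function(a, b) {
  n <- length(a)
  b <- c(b, numeric(n - length(b)))
  d <- a - b
  for (i in seq_len(n)) {
    if (d[i] < 0) {
      d[i] <- d[i] + .BIG_BASE
      d[i + 1L] <- d[i + 1L] - 1
    }
  }
  d
}

.umul <- function(a, b) {
  if ((length(a) == 1L && a[1L] == 0) || (length(b) == 1L && b[1L] == 0)) return(0)
  n <- length(a) + length(b)
  d <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    seg <- a[i] * b
    idx <- (i - 1L) + seq_along(b)
    d[idx] <- d[idx] + seg
    # renormalise eagerly so partial sums stay < 2^53
    carry <- 0
    for (j in idx[1L]:n) {
      v <- d[j] + carry
      carry <- floor(v / .BIG_BASE)
      d[j] <- v - carry * .BIG_BASE
      if (carry == 0 && j >= idx[length(idx)]) break
    }
  }
  d
}

.big_signed <- function(asign, ad, bsign, bd) {
  if (asign == 0L) return(.big_norm(bd, bsign))
  if (bsign == 0L) return(.big_norm(ad, asign))
  if (asign == bsign) return(.big_norm(.uadd(ad, bd), asign))
  cmp <- .ucmp(ad, bd)
  if (cmp == 0L) return(.big_norm(0, 0L))
  if (cmp > 0L) .big_norm(.usub(ad, bd), asign) else .big_norm(.usub(bd, ad), bsign)
}

#' @export
Ops.bigint <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*", "==", "!=", "<", "<=", ">", ">=")) {
    a <- as_bigint(e1)
    if (missing(e2)) {
      if (.Generic == "-") return(.big_norm(a$d, -a$sign))
      if (.Generic == "+") return(a)
      stop("unsupported unary operator for bigint: ", .Generic)
    }
    b <- as_bigint(e2)
    switch(.Generic,
      "+" = .big_signed(a$sign, a$d, b$sign, b$d),
      "-" = .big_signed(a$sign, a$d, -b$sign, b$d),
      "*" = {
        s <- a$sign * b$sign
        if (s == 0L) .big_norm(0, 0L) else .big_norm(.umul(a$d, b$d), s)
      },
      {
        cmp <- if (a$sign != b$sign) {
          if (a$sign < b$sign) -1L else 1L
        } else if (a$sign >= 0L) .ucmp(a$d, b$d) else -.ucmp(a$d, b$d)
        switch(.Generic,
          "==" = cmp == 0L, "!=" = cmp != 0L,
          "<"  = cmp < 0L,  "<=" = cmp <= 0L,
          ">"  = cmp > 0L,  ">=" = cmp >= 0L)
      })
  } else if (.Generic == "^") {
    big_pow(e1, e2)
  } else {
    stop("operator not defined for bigint: ", .Generic)
  }
}

#' @export
format.bigint <- function(x, ...) {
  d <- rev(x$d)
  s <- paste0(formatC(d[1L], format = "d"),
              paste(formatC(d[-1L], width = 6, flag = "0", format = "d"),
                    collapse = ""))
  if (x$sign < 0L) s <- paste0("-", s)
  s
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.double.bigint <- function(x, ...) {
  v <- sum(x$d * .BIG_BASE^(seq_along(x$d) - 1))
  if (v >= 2^53) warning("bigint exceeds 2^53; as.numeric is inexact")
  v * x$sign
}

#' @rdname as_bigint
#' @export
is_bigint <- function(x) inherits(x, "bigint")

#' Exact power, factorial and binomial coefficient
#'
#' `big_pow(base, e)` raises an integer to a non-negative integer power;
#' `big_factorial(n)` is `n!` (memoised); `big_binom(n, k)` is the binomial
#' coefficient, computed by the multiplicative formula whose intermediate
#' divisions are always exact. All return [as_bigint()] values.
#'
#' @param base,e,n,k scalar integers (`base` may be a `bigint`).
#' @export
big_pow <- function(base, e) {
  e <- as.integer(e)
  stopifnot(e >= 0L)
  r <- as_bigint(1)
  b <- as_bigint(base)
  while (e > 0L) {
    if (e %% 2L == 1L) r <- r * b
    b <- b * b
    e <- e %/% 2L
  }
  r
}

.big_cache <- new.env(parent = emptyenv())

#' @rdname big_pow
#' @export
big_factorial <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  key <- paste0("fact", n)
  if (!is.null(.big_cache[[key]])) return(.big_cache[[key]])
  r <- as_bigint(1)
  if (n >= 2L) for (i in 2:n) r <- r * as_bigint(i)
  .big_cache[[key]] <- r
  r
}

#' @rdname big_pow
#' @export
big_binom <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || k > n) return(as_bigint(0))
  k <- min(k, n - k)
  r <- as_bigint(1)
  if (k > 0L) for (i in seq_len(k)) {
    r <- big_div_small(r * as_bigint(n - k + i), i)  # exact at every step
  }
  r
}

#' Exact division of a bigint by a small integer
#'
#' Divides by `s` (0 < s < 1e6) and errors unless the division is exact.
#' Used internally wherever a counting formula divides by a factorial or a
#' power of two: such divisors are decomposed into prime powers first
#' ([big_div_factorial()], [big_div_pow2()]) so each step is exact.
#'
#' @param x a `bigint` (or value convertible to one).
#' @param s small positive integer divisor.
#' @export
big_div_small <- function(x, s) {
  x <- as_bigint(x)
  s <- as.numeric(s)
  stopifnot(s >= 1, s < .BIG_BASE, s == trunc(s))
  if (s == 1) return(x)
  d <- x$d
  q <- numeric(length(d))
  r <- 0
  for (i in rev(seq_along(d))) {
    cur <- r * .BIG_BASE + d[i]
    q[i] <- (cur - cur %% s) / s
    r <- cur %% s
  }
  if (r != 0) stop("non-exact division of bigint by ", s)
  .big_norm(q, x$sign)
}

.legendre <- function(n, p) {
  e <- 0L; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

.primes_upto <- function(n) {
  if (n < 2L) return(integer(0))
  which(vapply(seq_len(n), function(i)
    i >= 2L && all(i %% seq_len(max(1L, floor(sqrt(i)))) [-1L] != 0L), logical(1)))
}

#' @rdname big_div_small
#' @param k factorial divisor: divides `x` exactly by `k!`.
#' @export
big_div_factorial <- function(x, k) {
  x <- as_bigint(x)
  k <- as.integer(k)
  stopifnot(k >= 0L)
  if (k < 2L) return(x)
  for (p in .primes_upto(k)) {
    e <- .legendre(k, p)
    for (i in seq_len(e)) x <- big_div_small(x, p)
  }
  x
}

#' @rdname big_div_small
#' @param t power-of-two divisor: divides `x` exactly by `2^t`.
#' @export
big_div_pow2 <- function(x, t) {
  x <- as_bigint(x)
  t <- as.integer(t)
  stopifnot(t >= 0L)
  for (i in seq_len(t)) x <- big_div_small(x, 2)
  x
}
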