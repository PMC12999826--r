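# Exact counting formulas and recursions for spinal network classes.
#
# Every function returns an exact bigint. Parameters outside a class's
# domain return 0 (k < 0, n = 0, k >= n for tree-child) rather than
# raising, so table generation is total; the n = 1 column of the
# leaf-labelled binary classes is 1 for k = 0 and otherwise handled by the
# shape counts (no cherry correction applies to a single leaf).
#
# Wherever a closed form has two printed shapes, both are evaluated and
# compared; a mismatch raises an internal consistency error rather than
# silently picking one.

#' Count spinal networks by leaves and cover size
#'
#' The class of all spinal networks (degenerate and non-binary allowed, no
#' parallel arcs) on `n` leaves whose cover has `c` sets has cardinality
#' `2^binom(c-1, 2) * (c^n - (c-1)^n)`, with the binomial set to 0 for
#' `c <= 2`. The power term counts assignments of leaves to sets (first
#' set non-empty), the power of two the optional repeats of each non-leaf
#' label in later sets.
#'
#' @param n leaves (>= 1).
#' @param c cover size = number of non-leaf vertices including the root
#'   (>= 1).
#' @return A `bigint`.
#' @examples
#' count_spinal(4, 5)  # 23616
#' @export
count_spinal <- function(n, c) {
  n <- as.integer(n); c <- as.integer(c)
  if (n < 1L || c < 1L) return(as_bigint(0))
  ex <- if (c <= 2L) 0L else choose(c - 1L, 2L)
  big_pow(2, ex) * (big_pow(c, n) - big_pow(c - 1L, n))
}

#' Count binary spinal tree-child shapes (Bessel numbers)
#'
#' The shapes of binary spinal tree-child networks on `n` leaves with `k`
#' reticulations are counted by the Bessel number
#' `(n-1+k)! / (2^k (n-1-k)! k!)`: partitions of `{1..n-1+k}` into `k`
#' doubletons and `n-1-k` singletons. Zero when `k > n-1`; the n = 1
#' column is 1 for k = 0 and 0 otherwise.
#'
#' @param n leaves.
#' @param k reticulations.
#' @return A `bigint`.
#' @export
bessel_shapes <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L || k > n - 1L) return(as_bigint(0))
  # (n-1+k)!/(2^k (n-1-k)! k!) = C(n-1+k, 2k) * (2k-1)!!, division-free
  r <- big_binom(n - 1L + k, 2L * k)
  if (k > 0L) for (j in seq_len(k)) r <- r * as_bigint(2L * j - 1L)
  r
}

#' Count binary spinal tree-child networks
#'
#' Two equivalent forms are evaluated and must agree: the shape count
#' expanded by leaf labellings, `n! B(n-1,k) - (n!/2) B(n-2,k)` (the
#' subtraction corrects for the interchangeable cherry leaves of shapes
#' obtained by re-cherrying), and the closed form
#' `n! (n-2+k)! (n-1+3k) / (2^(k+1) k! (n-1-k)!)`.
#' Zero for `k >= n`; the single-leaf tree gives 1 at `k = 0`.
#'
#' @param n leaves.
#' @param k reticulations.
#' @return A `bigint`.
#' @examples
#' count_stc(4, 2)  # 324
#' @export
count_stc <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L || k >= n) return(as_bigint(0))
  if (n == 1L) return(as_bigint(if (k == 0L) 1 else 0))
  via_shapes <- shapes_to_networks(bessel_shapes(n, k), bessel_shapes(n - 1L, k), n)
  if (k == 0L) {
    # the closed form reduces to n!/2, the caterpillar-tree count
    closed <- big_div_pow2(big_factorial(n), 1L)
  } else {
    # closed form: n! * C(n-2+k, k) * [(n-2)!/(n-1-k)!] * (n-1+3k) / 2^(k+1)
    num <- big_factorial(n) * big_binom(n - 2L + k, k) * as_bigint(n - 1L + 3L * k)
    if (k >= 2L) for (t in (n - k):(n - 2L)) num <- num * as_bigint(t)
    closed <- big_div_pow2(num, k + 1L)
  }
  if (!(closed == via_shapes))
    stop("internal consistency error: tree-child closed form disagrees with shape expansion at n=",
         n, ", k=", k)
  closed
}

#' Totals over all reticulation numbers
#'
#' `count_stc_total(n)` sums the binary spinal tree-child networks over
#' `k = 0..n-1`; `count_stcs_total(n)` sums the shape (Bessel) counts, the
#' partial sums of Bessel numbers.
#'
#' @param n leaves.
#' @return A `bigint`.
#' @examples
#' count_stc_total(4)  # 804
#' @export
count_stc_total <- function(n) {
  n <- as.integer(n)
  tot <- as_bigint(0)
  for (k in 0:max(0L, n - 1L)) tot <- tot + count_stc(n, k)
  tot
}

#' @rdname count_stc_total
#' @export
count_stcs_total <- function(n) {
  n <- as.integer(n)
  tot <- as_bigint(0)
  for (k in 0:max(0L, n - 1L)) tot <- tot + bessel_shapes(n, k)
  tot
}

#' Stirling numbers (exact)
#'
#' `stirling2(n, k)` counts partitions of an n-set into k non-empty parts;
#' it is computed both by the standard triangular recurrence and by the
#' inclusion-exclusion closed form `sum_j (-1)^(k-j) C(k,j) j^n / k!`, and
#' the two must agree. `stirling1_unsigned(n, k)` counts permutations of n
#' elements with k cycles, by the recurrence
#' `s(n,k) = s(n-1,k-1) + (n-1) s(n-1,k)`.
#'
#' @param n,k non-negative integers.
#' @return A `bigint`.
#' @export
stirling2 <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  rec <- .stirling2_rec(n, k)
  if (n >= 0L && k >= 0L && n <= 40L) {     # closed form cross-check
    acc <- as_bigint(0)
    for (j in 0:k) {
      term <- big_binom(k, j) * big_pow(j, n)
      acc <- if ((k - j) %% 2L == 0L) acc + term else acc - term
    }
    cf <- big_div_factorial(acc, k)
    if (!(cf == rec))
      stop("internal consistency error: Stirling-2 closed form disagrees at n=",
           n, ", k=", k)
  }
  rec
}

.stirling2_rec <- function(n, k) {
  if (k < 0L || n < 0L) return(as_bigint(0))
  if (n == 0L && k == 0L) return(as_bigint(1))
  if (n == 0L || k == 0L) return(as_bigint(0))
  key <- paste0("s2.", n, ".", k)
  if (!is.null(.big_cache[[key]])) return(.big_cache[[key]])
  r <- .stirling2_rec(n - 1L, k - 1L) + as_bigint(k) * .stirling2_rec(n - 1L, k)
  .big_cache[[key]] <- r
  r
}

#' @rdname stirling2
#' @export
stirling1_unsigned <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || n < 0L) return(as_bigint(0))
  if (n == 0L && k == 0L) return(as_bigint(1))
  if (n == 0L || k == 0L) return(as_bigint(0))
  key <- paste0("s1.", n, ".", k)
  if (!is.null(.big_cache[[key]])) return(.big_cache[[key]])
  r <- stirling1_unsigned(n - 1L, k - 1L) +
    as_bigint(n - 1L) * stirling1_unsigned(n - 1L, k)
  .big_cache[[key]] <- r
  r
}

#' Count binary spinal stack-free networks
#'
#' Shape count `S2(n-1+k, n-1)` (set partitions into n-1 parts) expanded by
#' leaf labellings: `n! S2(n-1+k, n-1) - (n!/2) S2(n-2+k, n-2)`. A second,
#' algebraically reduced closed form
#' `n (n-1)^(n-1+k) - (n!/2) sum_j (-1)^(n-j) (n-1+j) j^(n-2+k) / ((n-1-j)! j!)`
#' is evaluated alongside and must agree.
#'
#' @param n leaves.
#' @param k reticulations.
#' @return A `bigint`.
#' @examples
#' count_ssf(4, 2)  # 516
#' @export
count_ssf <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L) return(as_bigint(0))
  if (n == 1L) return(as_bigint(if (k == 0L) 1 else 0))
  main <- shapes_to_networks(.stirling2_rec(n - 1L + k, n - 1L),
                             .stirling2_rec(n - 2L + k, n - 2L), n)
  # reduced closed form; (n!/2) * term_j has integer core
  # n!/((n-1-j)! j!) = n * C(n-1, j)
  acc <- as_bigint(0)
  for (j in 0:(n - 2L)) {
    core <- as_bigint(n) * big_binom(n - 1L, j) *
      as_bigint(n - 1L + j) * big_pow(j, n - 2L + k)
    acc <- if ((n - j) %% 2L == 0L) acc + core else acc - core
  }
  closed <- as_bigint(n) * big_pow(n - 1L, n - 1L + k) - big_div_pow2(acc, 1L)
  if (!(closed == main))
    stop("internal consistency error: stack-free closed form disagrees at n=",
         n, ", k=", k)
  main
}

#' Count binary spinal fully tree-sibling networks
#'
#' Shape count `|S1(n-1+k, n-1)|` (permutations with n-1 cycles) expanded
#' by leaf labellings: `n! |S1(n-1+k, n-1)| - (n!/2) |S1(n-2+k, n-2)|`.
#'
#' @param n leaves.
#' @param k reticulations.
#' @return A `bigint`.
#' @examples
#' count_fts(4, 2)  # 708
#' @export
count_fts <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L) return(as_bigint(0))
  if (n == 1L) return(as_bigint(if (k == 0L) 1 else 0))
  shapes_to_networks(stirling1_unsigned(n - 1L + k, n - 1L),
                     stirling1_unsigned(n - 2L + k, n - 2L), n)
}

#' Count binary spinal networks with parallel arcs permitted
#'
#' Shapes are sets of k disjoint pairs drawn from the `n-1+2k` spine
#' positions (each pair is a reticulation and its non-spinal parent), i.e.
#' `(n-1+2k)! / (2^k (n-1)! k!)` shapes. Both printed forms of the network
#' count are evaluated and must agree:
#' `n! (shapes(n,k) - shapes(n-1,k)/2)` and
#' `n (n-1+4k) (n-2+2k)! / (2^(k+1) k!)`.
#'
#' @param n leaves.
#' @param k reticulations.
#' @return A `bigint`.
#' @examples
#' count_bsp(4, 2)  # 1980
#' @export
count_bsp <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L) return(as_bigint(0))
  if (n == 1L && k == 0L) return(as_bigint(1))
  # direct closed form
  num <- as_bigint(n) * as_bigint(n - 1L + 4L * k) * big_factorial(n - 2L + 2L * k)
  closed <- big_div_factorial(big_div_pow2(num, k + 1L), k)
  if (n >= 2L) {
    via_shapes <- shapes_to_networks(bsp_shapes(n, k), bsp_shapes(n - 1L, k), n)
    if (!(closed == via_shapes))
      stop("internal consistency error: parallel-arc closed form disagrees at n=",
           n, ", k=", k)
  } else {
    # single leaf: no cherry correction; the count is the shape count
    if (!(closed == bsp_shapes(1L, k)))
      stop("internal consistency error: parallel-arc closed form disagrees at n=1, k=", k)
  }
  closed
}

#' @rdname count_bsp
#' @export
bsp_shapes <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L) return(as_bigint(0))
  # (n-1+2k)!/(2^k (n-1)! k!) = C(n-1+2k, 2k) * (2k-1)!!
  r <- big_binom(n - 1L + 2L * k, 2L * k)
  if (k > 0L) for (j in seq_len(k)) r <- r * as_bigint(2L * j - 1L)
  r
}

#' Count binary spinal shapes and networks without parallel arcs
#'
#' `count_bss_shapes(n, k)` evaluates the shape recursion
#' `BSS(n,k) = BSS(n-1,k) + (n+2k-3) BSS(n,k-1) + n BSS(n+1,k-2)`
#' (memoised; base cases `BSS(n,0) = 1` for `n >= 1`, zero for `k < 0` or
#' `n = 0`), classifying shapes by what the spine vertex nearest the root
#' does: it sees a leaf, a subdivided spine arc, or a reticulation whose
#' removal would create a parallel arc. `count_bs(n, k)` expands shapes to
#' leaf-labelled networks: `n! BSS(n,k) - (n!/2) BSS(n-1,k)`.
#'
#' @param n leaves.
#' @param k reticulations.
#' @return A `bigint`.
#' @examples
#' count_bss_shapes(2, 2)  # 6
#' count_bs(2, 2)          # 11
#' @export
count_bss_shapes <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0L || n < 1L) return(as_bigint(0))
  if (k == 0L) return(as_bigint(1))
  key <- paste0("bss.", n, ".", k)
  if (!is.null(.big_cache[[key]])) return(.big_cache[[key]])
  r <- count_bss_shapes(n - 1L, k) +
    as_bigint(max(0L, n + 2L * k - 3L)) * count_bss_shapes(n, k - 1L) +
    as_bigint(n) * count_bss_shapes(n + 1L, k - 2L)
  .big_cache[[key]] <- r
  r
}

#' @rdname count_bss_shapes
#' @export
count_bs <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 1L || k < 0L) return(as_bigint(0))
  shapes_to_networks(count_bss_shapes(n, k), count_bss_shapes(n - 1L, k), n)
}

#' Expand shape counts to leaf-labelled network counts
#'
#' For a class of binary spinal networks closed under leaf permutation,
#' cherry reduction and re-cherrying, the number of leaf-labelled networks
#' on n leaves is `n! * shapes(n,k) - (n!/2) * shapes(n-1,k)`: every shape
#' admits n! labellings except that shapes with a cherry (in bijection with
#' the (n-1)-leaf shapes, by cherry reduction) have their two cherry
#' labellings identified. Computed as `(n! * (2*shapes - shapes_prev)) / 2`
#' so the division is exact for every n (for n = 1 the previous-shape count
#' is necessarily 0).
#'
#' @param shapes_nk shape count at (n, k) (`bigint` or number).
#' @param shapes_prev shape count at (n-1, k).
#' @param n leaves.
#' @return A `bigint`.
#' @examples
#' shapes_to_networks(15, 3, 4)  # 324
#' @export
shapes_to_networks <- function(shapes_nk, shapes_prev, n) {
  n <- as.integer(n)
  shapes_nk <- as_bigint(shapes_nk)
  shapes_prev <- as_bigint(shapes_prev)
  if (n == 1L && !.big_is_zero(shapes_prev))
    stop("shapes_prev must be 0 when n = 1 (there is no 0-leaf shape)")
  big_div_pow2(big_factorial(n) * (as_bigint(2) * shapes_nk - shapes_prev), 1L)
}
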