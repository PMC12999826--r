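# Exhaustive generators and seeded uniform samplers.
#
# The enumerators are deliberately independent of the closed-form counts:
# enumerate_lrp backtracks over letters under the rule set,
# enumerate_spinal_covers realises the constructive argument behind the
# spinal counting formula (assign leaves to sets, then choose repeats), and
# brute_force_covers filters raw set systems through the expanding
# definition with no knowledge of either. Agreement between the three
# routes and the formulas is the package's central oracle suite.

.check_guard <- function(predicted, guard) {
  if (!is.null(guard) && as_bigint(predicted) > as_bigint(trunc(guard)))
    stop("predicted output size ", format(as_bigint(predicted)),
         " exceeds the enumeration guard (", guard,
         "); raise `guard` explicitly if you mean it")
  invisible(TRUE)
}

#' Exhaustively enumerate LRP sequences of a class
#'
#' Backtracking generator over the letter alphabet: at each step the next
#' letter is one of `L` (while any of the `n-1` remain), the next unplaced
#' reticulation `R_{r+1}` (rule R1 makes any other R index invalid), or
#' `P_i` for an opened, unclosed reticulation `i`; candidate letters are
#' filtered by the class rules against the previous letter. Sequences are
#' emitted in lexicographic letter order with `L < P1 < ... < R1 < ...`.
#'
#' @param n leaves (>= 1).
#' @param k reticulations (>= 0).
#' @param spec a [class_spec()] or class name (default `"BS"`).
#' @param guard refuse tasks whose predicted size exceeds this (default
#'   1e6); `NULL` disables.
#' @return List of `lrp_sequence` objects.
#' @examples
#' length(enumerate_lrp(4, 2, "STC"))  # 15 tree-child shapes
#' @export
enumerate_lrp <- function(n, k, spec = "BS", guard = 1e6) {
  if (is.character(spec)) spec <- class_spec(spec)
  n <- as.integer(n); k <- as.integer(k)
  stopifnot(n >= 1L, k >= 0L)
  predicted <- switch(spec$name,
    STC = bessel_shapes(n, k),
    SSF = .stirling2_rec(n - 1L + k, n - 1L),
    FTS = stirling1_unsigned(n - 1L + k, n - 1L),
    BS  = count_bss_shapes(n, k),
    BSP = bsp_shapes(n, k))
  .check_guard(predicted, guard)
  rules <- spec$rules
  out <- vector("list", as.numeric(predicted))
  cnt <- 0L
  total_len <- n - 1L + 2L * k

  recurse <- function(acc, l_left, r_placed, p_done) {
    if (length(acc) == total_len) {
      cnt <<- cnt + 1L
      out[[cnt]] <<- new_lrp(acc)
      return(invisible(NULL))
    }
    prev <- if (length(acc) > 0L) acc[length(acc)] else ""
    prev_is_r <- startsWith(prev, "R")
    # candidates in lexicographic letter order
    cands <- character(0)
    if (l_left > 0L) cands <- c(cands, "L")
    open_p <- which(!p_done[seq_len(r_placed)])
    if (length(open_p) > 0L) cands <- c(cands, paste0("P", open_p))
    if (r_placed < k) cands <- c(cands, paste0("R", r_placed + 1L))
    for (lt in cands) {
      if (prev_is_r) {
        if ("R4a" %in% rules && lt != "L") next
        if ("R4b" %in% rules && startsWith(lt, "R")) next
        if ("R4c" %in% rules && startsWith(lt, "P")) next
        if ("R3" %in% rules && lt == paste0("P", sub("R", "", prev))) next
      }
      if (lt == "L") recurse(c(acc, lt), l_left - 1L, r_placed, p_done)
      else if (startsWith(lt, "R")) recurse(c(acc, lt), l_left, r_placed + 1L, p_done)
      else {
        pd <- p_done; pd[as.integer(sub("P", "", lt))] <- TRUE
        recurse(c(acc, lt), l_left, r_placed, pd)
      }
    }
  }
  recurse(character(0), n - 1L, 0L, rep(FALSE, k))
  out[seq_len(cnt)]
}

#' Constructively enumerate spinal covers
#'
#' Realises the construction behind the spinal count: every spinal cover
#' on `n` leaves with `c` sets arises once from (i) an assignment of the
#' leaves `1..n` to the sets `C_1..C_c` with `C_1` non-empty (`C_1` gets
#' only leaves), and (ii) for each non-leaf label `n+i-1` (held by `C_i`),
#' an arbitrary subset of the later sets `C_{i+1}..C_c` receiving a repeat.
#'
#' @param n leaves (>= 1).
#' @param c cover size (>= 1).
#' @param guard see [enumerate_lrp()].
#' @return List of `expanding_cover` objects (labelling order).
#' @examples
#' length(enumerate_spinal_covers(2, 2))  # 3
#' @export
enumerate_spinal_covers <- function(n, c, guard = 1e6) {
  n <- as.integer(n); c <- as.integer(c)
  stopifnot(n >= 1L, c >= 1L)
  .check_guard(count_spinal(n, c), guard)
  out <- list()

  # all leaf assignments: vector a in {1..c}^n with 1 used at least once
  assign_rec <- function(a) {
    if (length(a) == n) {
      if (!any(a == 1L)) return(invisible(NULL))
      repeats_rec(a, 2L, vector("list", c))
      return(invisible(NULL))
    }
    for (s in seq_len(c)) assign_rec(c(a, s))
  }
  # choose, for each i = 2..c, which later sets repeat the element n+i-1
  repeats_rec <- function(a, i, extra) {
    if (i > c) {
      sets <- lapply(seq_len(c), function(s) {
        members <- which(a == s)                       # leaves
        if (s >= 2L) members <- c(members, n + s - 1L) # spinal element
        sort(unique(c(members, extra[[s]])))
      })
      out[[length(out) + 1L]] <<- expanding_cover(sets, reorder = FALSE)
      return(invisible(NULL))
    }
    later <- if (i < c) (i + 1L):c else integer(0)
    subsets <- .all_subsets(later)
    for (sub in subsets) {
      e2 <- extra
      for (s in sub) e2[[s]] <- c(e2[[s]], n + i - 1L)
      repeats_rec(a, i + 1L, e2)
    }
  }
  assign_rec(integer(0))
  out
}

.all_subsets <- function(x) {
  if (length(x) == 0L) return(list(integer(0)))
  subs <- list(integer(0))
  for (e in x) subs <- c(subs, lapply(subs, function(s) c(s, e)))
  subs
}

#' Brute-force enumeration of expanding covers
#'
#' The independent oracle: enumerates *all* collections of `c` distinct
#' non-empty subsets of `{1..m}` (as bitmasks, in strictly increasing mask
#' order, which refines the order by maximum element) and keeps those
#' passing the expanding definition — optionally tightened to spinal. The
#' only pruning applied is the expanding condition itself (the i-th mask
#' must fit inside `{1..n+i-1}`) and the once-only rule for leaf elements;
#' nothing is shared with the constructive generator.
#'
#' @param m ground-set size (guarded at <= 9).
#' @param c number of sets.
#' @param spinal if `TRUE`, keep only spinal covers.
#' @return List of `expanding_cover` objects.
#' @export
brute_force_covers <- function(m, c, spinal = FALSE) {
  m <- as.integer(m); c <- as.integer(c)
  stopifnot(m >= 1L, c >= 1L, c <= m)
  if (m > 9L) stop("brute force is guarded at m <= 9")
  n <- m - c + 1L
  leaf_mask <- if (n > 0L) bitwShiftL(1L, n) - 1L else 0L
  full <- bitwShiftL(1L, m) - 1L
  out <- list()
  recurse <- function(i, prev_mask, leaf_used, union_mask, chosen) {
    if (i > c) {
      if (union_mask == full) {
        sets <- lapply(chosen, .mask_to_set)
        cov <- expanding_cover(sets, reorder = FALSE, strict = FALSE)
        cov <- reorder_labelling(cov)
        if (!spinal || is_spinal_cover(cov)) out[[length(out) + 1L]] <<- cov
      }
      return(invisible(NULL))
    }
    limit <- bitwShiftL(1L, min(m, n + i - 1L)) - 1L
    if (prev_mask + 1L > limit) return(invisible(NULL))
    for (msk in (prev_mask + 1L):limit) {
      lm <- bitwAnd(msk, leaf_mask)
      if (bitwAnd(lm, leaf_used) != 0L) next          # a leaf appears twice
      recurse(i + 1L, msk, bitwOr(leaf_used, lm),
              bitwOr(union_mask, msk), c(chosen, msk))
    }
    invisible(NULL)
  }
  recurse(1L, 0L, 0L, 0L, integer(0))
  out
}

.mask_to_set <- function(msk) {
  which(bitwAnd(msk, bitwShiftL(1L, seq_len(31L) - 1L)) != 0L)
}

#' Enumerate leaf-labelled networks of a class
#'
#' Decodes every LRP sequence of the class and expands each shape to its
#' distinct leaf labellings: `n!` when the shape is cherry-free, `n!/2`
#' when it has a cherry (the two cherry leaves are interchangeable, so
#' labellings with the smaller label on the spine leaf are kept).
#'
#' @param spec [class_spec()] or name.
#' @param n,k leaves/reticulations.
#' @param guard see [enumerate_lrp()].
#' @return List of `phylo_network` objects.
#' @examples
#' length(enumerate_networks("BS", 2, 2))  # 11
#' @export
enumerate_networks <- function(spec, n, k, guard = 1e6) {
  if (is.character(spec)) spec <- class_spec(spec)
  n <- as.integer(n); k <- as.integer(k)
  allow_par <- spec$name == "BSP"
  shapes <- enumerate_lrp(n, k, spec, guard = guard)
  nets <- list()
  perms <- .all_permutations(n)
  for (seq in shapes) {
    shape <- decode_lrp(seq, allow_parallel = allow_par)
    has_cherry <- length(seq) > 0L && seq[1L] == "L"
    for (p in perms) {
      # p maps canonical leaf label -> new label; canonical cherry pair is
      # leaves 1 (spine leaf) and 2 (first L-leaf)
      if (has_cherry && p[1L] > p[2L]) next
      nets[[length(nets) + 1L]] <- .relabel_leaves(shape, p)
    }
  }
  nets
}

.all_permutations <- function(n) {
  if (n == 0L) return(list())
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

.relabel_leaves <- function(net, p) {
  arcs <- net$arcs
  is_leaf <- arcs[, "child"] %in% net$leaves
  arcs[is_leaf, "child"] <- paste0("leaf", p[as.integer(arcs[is_leaf, "child"])])
  arcs[, "child"] <- sub("^leaf", "", arcs[, "child"])
  phylo_network(arcs, allow_parallel = net$allow_parallel)
}
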