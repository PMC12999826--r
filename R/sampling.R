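# Seeded uniform samplers over leaf-labelled networks of a class.
#
# A shape is drawn uniformly from the class's bijection target family
# (partitions into singletons/doubletons for tree-child, set partitions
# for stack-free, permutations by cycle count for fully tree-sibling,
# disjoint position pairs for the parallel-arc class, rejection from the
# latter for the no-parallel-arc class); a uniform leaf labelling is then
# attached, and draws of cherry-bearing shapes are accepted with
# probability 1/2 after canonicalising the cherry pair. The acceptance
# step exactly compensates for the two interchangeable cherry labellings,
# so the output is uniform over the class's leaf-labelled networks.

# uniform partition of s elements into d doubletons + (s-2d) singletons:
# the smallest remaining element is a singleton with probability (s-2d)/s,
# otherwise it pairs with a uniformly chosen partner
.sample_pairing <- function(elements, d) {
  parts <- list()
  while (length(elements) > 0L) {
    s <- length(elements)
    if (d > 0L && stats::runif(1) < 2 * d / s) {
      j <- if (s > 2L) sample(elements[-1L], 1L) else elements[2L]
      parts[[length(parts) + 1L]] <- c(elements[1L], j)
      elements <- setdiff(elements, c(elements[1L], j))
      d <- d - 1L
    } else {
      parts[[length(parts) + 1L]] <- elements[1L]
      elements <- elements[-1L]
    }
  }
  parts
}

# uniform set partition of 1..N into exactly p parts, by the recurrence
# S2(N,p) = S2(N-1,p-1) + p*S2(N-1,p)
.sample_set_partition <- function(N, p) {
  if (N == 0L) return(list())
  w_alone <- as.numeric(.stirling2_rec(N - 1L, p - 1L))
  w_join <- p * as.numeric(.stirling2_rec(N - 1L, p))
  if (stats::runif(1) < w_alone / (w_alone + w_join)) {
    parts <- .sample_set_partition(N - 1L, p - 1L)
    parts[[length(parts) + 1L]] <- N
  } else {
    parts <- .sample_set_partition(N - 1L, p)
    j <- sample.int(length(parts), 1L)
    parts[[j]] <- c(parts[[j]], N)
  }
  parts
}

# uniform permutation of 1..N with exactly p cycles, by the recurrence
# c(N,p) = c(N-1,p-1) + (N-1)*c(N-1,p)
.sample_perm_with_cycles <- function(N, p) {
  if (N == 0L) return(integer(0))
  w_fix <- as.numeric(stirling1_unsigned(N - 1L, p - 1L))
  w_ins <- (N - 1) * as.numeric(stirling1_unsigned(N - 1L, p))
  if (stats::runif(1) < w_fix / (w_fix + w_ins)) {
    perm <- c(.sample_perm_with_cycles(N - 1L, p - 1L), N)
  } else {
    perm <- c(.sample_perm_with_cycles(N - 1L, p), N)
    j <- sample.int(N - 1L, 1L)       # insert N into the cycle after j
    perm[N] <- perm[j]
    perm[j] <- N
  }
  perm
}

.sample_shape_lrp <- function(spec, n, k) {
  N <- n - 1L + k
  switch(spec$name,
    STC = bessel_partition_to_lrp(.sample_pairing(seq_len(N), k)),
    SSF = set_partition_to_lrp(.sample_set_partition(N, n - 1L)),
    FTS = permutation_to_lrp(.sample_perm_with_cycles(N, n - 1L)),
    BSP = .pairs_to_lrp(.sample_pairing(seq_len(n - 1L + 2L * k), k)),
    BS = {
      repeat {
        parts <- .sample_pairing(seq_len(n - 1L + 2L * k), k)
        pairs <- parts[lengths(parts) == 2L]
        adjacent <- any(vapply(pairs, function(p) abs(diff(sort(p))) == 1L, logical(1)))
        if (!adjacent) break
      }
      .pairs_to_lrp(parts)
    },
    stop("unknown class: ", spec$name))
}

# k disjoint position pairs on the spine -> letters: pair minimum is the
# reticulation, pair maximum its parent, unpaired positions are L-vertices
.pairs_to_lrp <- function(parts) {
  pairs <- lapply(parts[lengths(parts) == 2L], sort)
  N <- length(unlist(parts))
  letters <- rep("L", N)
  pairs <- pairs[order(vapply(pairs, min, numeric(1)))]
  for (i in seq_along(pairs)) {
    letters[pairs[[i]][1L]] <- paste0("R", i)
    letters[pairs[[i]][2L]] <- paste0("P", i)
  }
  new_lrp(letters)
}

#' Draw uniform random networks from a class
#'
#' `sample_network()` returns one leaf-labelled network drawn uniformly
#' from the class at `(n, k)`; `sample_networks()` returns a list of
#' independent draws under one seed. Identical seeds give identical
#' output.
#'
#' @param spec [class_spec()] or class name (`"STC"`, `"SSF"`, `"FTS"`,
#'   `"BS"`, `"BSP"`).
#' @param n,k leaves / reticulations; the class must be non-empty there.
#' @param seed integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @param size number of draws.
#' @return A `phylo_network`, or a list of them.
#' @examples
#' net <- sample_network("STC", 4, 2, seed = 1)
#' classify_network(net)[["tree_child"]]
#' @export
sample_network <- function(spec, n, k, seed = NULL) {
  sample_networks(spec, n, k, size = 1L, seed = seed)[[1L]]
}

#' @rdname sample_network
#' @export
sample_networks <- function(spec, n, k, size = 1L, seed = NULL) {
  if (is.character(spec)) spec <- class_spec(spec)
  n <- as.integer(n); k <- as.integer(k)
  total <- switch(spec$name,
    STC = count_stc(n, k), SSF = count_ssf(n, k), FTS = count_fts(n, k),
    BS = count_bs(n, k), BSP = count_bsp(n, k))
  if (.big_is_zero(total))
    stop("class ", spec$name, " is empty at n = ", n, ", k = ", k)
  if (!is.null(seed)) set.seed(as.integer(seed))
  allow_par <- spec$name == "BSP"
  out <- vector("list", size)
  for (t in seq_len(size)) {
    repeat {
      lrp <- .sample_shape_lrp(spec, n, k)
      p <- sample.int(n)
      has_cherry <- length(lrp) > 0L && lrp[1L] == "L"
      if (has_cherry) {
        if (p[1L] > p[2L]) p[c(1L, 2L)] <- p[c(2L, 1L)]   # canonical cherry order
        if (stats::runif(1) < 0.5) next                   # duplicate correction
      }
      shape <- decode_lrp(lrp, allow_parallel = allow_par)
      out[[t]] <- .relabel_leaves(shape, p)
      break
    }
  }
  out
}
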