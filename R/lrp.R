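# LRP sequences: the canonical word encoding of binary spinal shapes.
#
# Walking the spine from the leaf end to the root, every non-leaf vertex
# carries exactly one arc that is not on the spinal path. The vertex is an
# L-vertex when that arc leads to a leaf, the i-th reticulation along the
# spine (R_i) when the arc arrives from a later spine vertex, and the
# non-spinal parent of reticulation i (P_i) when the arc leaves to an
# earlier spine vertex. A shape on n leaves with k reticulations becomes a
# word of n-1 L's plus one R_i and one P_i per reticulation, length n+2k-1.
# Structural rules: (R1) R_j comes after R_i for j > i; (R2) P_i comes
# after R_i; (R3) P_i never immediately follows R_i (that would be a
# parallel arc). Class rules: (R4a) every R_i is immediately followed by L
# (tree-child); (R4b) no R_i is immediately followed by an R_j
# (stack-free); (R4c) no R_i is immediately followed by a P_j (fully
# tree-sibling).

#' LRP sequences
#'
#' `new_lrp()` builds an `lrp_sequence` from a character vector of letters
#' (`"L"`, `"R1"`, `"P1"`, ...); `parse_lrp()` reads the comma-separated
#' text form `"R1,L,P1,R2,L,P2,L"`. Structural well-formedness (letter
#' counts; exactly one `R_i`/`P_i` per `i = 1..k`) is enforced; the order
#' rules are checked separately by [check_rules()].
#'
#' @param letters character vector of letters.
#' @param text comma-separated letters.
#' @return An `lrp_sequence` with attributes `n` (leaves, `= #L + 1`) and
#'   `k` (reticulations).
#' @export
new_lrp <- function(letters) {
  letters <- as.character(letters)
  if (!all(grepl("^(L|[RP][0-9]+)$", letters)))
    stop("invalid LRP letters: ", paste(setdiff(letters, "L"), collapse = ","))
  r_idx <- sort(as.integer(sub("^R", "", letters[startsWith(letters, "R")])))
  p_idx <- sort(as.integer(sub("^P", "", letters[startsWith(letters, "P")])))
  k <- length(r_idx)
  if (!identical(r_idx, seq_len(k)) || !identical(p_idx, seq_len(k)))
    stop("LRP sequence must contain exactly one R_i and one P_i for i = 1..k")
  structure(letters, n = sum(letters == "L") + 1L, k = k, class = "lrp_sequence")
}

#' @rdname new_lrp
#' @export
parse_lrp <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(new_lrp(character(0)))
  new_lrp(trimws(strsplit(text, ",", fixed = TRUE)[[1]]))
}

#' @export
format.lrp_sequence <- function(x, ...) paste(unclass(x), collapse = ",")

#' @export
print.lrp_sequence <- function(x, ...) {
  cat("LRP sequence (n = ", attr(x, "n"), ", k = ", attr(x, "k"), "): ",
      format(x), "\n", sep = "")
  invisible(x)
}

#' Network class rule sets
#'
#' Binds a class name to the subset of LRP rules its sequences must obey:
#' `BSP` (binary spinal, parallel arcs permitted) needs R1-R2 only; `BS`
#' (binary spinal, no parallel arcs) adds R3; `SSF` (stack-free) adds R4b;
#' `FTS` (fully tree-sibling) adds R4c; `STC` (tree-child) obeys all six
#' (R4a implies R4b and R4c).
#'
#' @param name one of `"STC"`, `"SSF"`, `"FTS"`, `"BS"`, `"BSP"`
#'   (case-insensitive).
#' @return A list with `name` and `rules` (character vector).
#' @export
class_spec <- function(name) {
  name <- toupper(name)
  rules <- switch(name,
    BSP = c("R1", "R2"),
    BS  = c("R1", "R2", "R3"),
    SSF = c("R1", "R2", "R3", "R4b"),
    FTS = c("R1", "R2", "R3", "R4c"),
    STC = c("R1", "R2", "R3", "R4a", "R4b", "R4c"),
    stop("unknown class: ", name, " (expected STC, SSF, FTS, BS or BSP)"))
  structure(list(name = name, rules = rules), class = "lrp_class_spec")
}

.lrp_positions <- function(seq) {
  letters <- as.character(seq)
  k <- attr(seq, "k")
  rpos <- ppos <- integer(k)
  for (i in seq_len(k)) {
    rpos[i] <- which(letters == paste0("R", i))
    ppos[i] <- which(letters == paste0("P", i))
  }
  list(letters = letters, k = k, rpos = rpos, ppos = ppos)
}

#' Check LRP rules
#'
#' Evaluates each rule of a [class_spec()] on a sequence, reporting every
#' violation (not just the first).
#'
#' @param seq an `lrp_sequence` (or its text form).
#' @param spec a [class_spec()] or class name.
#' @return A list with `per_rule` (named logical), `violations` (character
#'   vector) and `member` (`TRUE` iff all rules of the spec pass).
#' @examples
#' check_rules("L,R1,R2,P1,P2", "BS")$member   # TRUE
#' check_rules("L,R1,P1,R2,P2", "BS")$member   # FALSE: R3 fails twice
#' @export
check_rules <- function(seq, spec = class_spec("BS")) {
  if (is.character(seq) && length(seq) == 1L) seq <- parse_lrp(seq)
  if (is.character(spec)) spec <- class_spec(spec)
  z <- .lrp_positions(seq)
  viol <- character(0)
  per_rule <- c(R1 = TRUE, R2 = TRUE, R3 = TRUE, R4a = TRUE, R4b = TRUE, R4c = TRUE)
  if (z$k > 1L) for (i in seq_len(z$k - 1L)) {
    if (z$rpos[i + 1L] < z$rpos[i]) {
      per_rule["R1"] <- FALSE
      viol <- c(viol, paste0("R1: R", i + 1L, " appears before R", i))
    }
  }
  for (i in seq_len(z$k)) {
    if (z$ppos[i] < z$rpos[i]) {
      per_rule["R2"] <- FALSE
      viol <- c(viol, paste0("R2: P", i, " appears before R", i))
    }
    if (z$ppos[i] == z$rpos[i] + 1L) {
      per_rule["R3"] <- FALSE
      viol <- c(viol, paste0("R3: P", i, " immediately follows R", i))
    }
  }
  nxt <- c(z$letters[-1L], NA)
  for (i in seq_len(z$k)) {
    after <- nxt[z$rpos[i]]
    if (is.na(after) || after != "L") {
      per_rule["R4a"] <- FALSE
      viol <- c(viol, paste0("R4a: R", i, " is not immediately followed by L"))
    }
    if (!is.na(after) && startsWith(after, "R")) {
      per_rule["R4b"] <- FALSE
      viol <- c(viol, paste0("R4b: R", i, " is immediately followed by ", after))
    }
    if (!is.na(after) && startsWith(after, "P")) {
      per_rule["R4c"] <- FALSE
      viol <- c(viol, paste0("R4c: R", i, " is immediately followed by ", after))
    }
  }
  list(per_rule = per_rule,
       violations = viol,
       member = all(per_rule[spec$rules]))
}

# ---- encode / decode -------------------------------------------------------

#' Encode a binary spinal shape as an LRP sequence
#'
#' Walks the spine from the leaf end to the root and assigns each non-leaf
#' vertex its letter: `L` when its non-spinal arc reaches a leaf, `R_i` for
#' the i-th reticulation met along the spine, `P_i` for the vertex whose
#' non-spinal arc feeds reticulation i. The encoding is canonical: it does
#' not depend on which admissible leaf starts the spine, and shape
#' isomorphism of binary spinal networks is equality of LRP sequences.
#'
#' @param shape a binary spinal `phylo_network` (parallel arcs allowed if
#'   the network carries them; R3 then fails).
#' @return An `lrp_sequence`.
#' @export
encode_lrp <- function(shape) {
  stopifnot(inherits(shape, "phylo_network"))
  if (shape$n == 1L && length(shape$vertices) == 2L)
    return(new_lrp(character(0)))     # single-leaf tree: empty word
  sp <- find_spine(shape)
  if (identical(sp, "NOT_SPINAL")) stop("shape is not spinal")
  spine <- sp$vertices            # leaf, v1, ..., root
  body <- spine[-1L]              # non-leaf spine vertices, leaf end first
  t <- length(body)
  pos_of <- stats::setNames(seq_len(t), body)

  # arc multiset minus the spinal-path arcs leaves one arc per spine vertex
  akey <- paste(shape$arcs[, "parent"], shape$arcs[, "child"], sep = "\r")
  spine_keys <- paste(body, c(spine[1L], body[-t]), sep = "\r")
  use <- rep(TRUE, length(akey))
  for (kk in spine_keys) {
    hit <- which(use & akey == kk)
    if (length(hit) == 0L) stop("internal error: spinal arc missing")
    use[hit[1L]] <- FALSE
  }
  rest <- shape$arcs[use, , drop = FALSE]

  letters <- character(t)
  ret_order <- integer(0)               # spine positions that are reticulations
  nonspinal <- vector("list", t)
  for (j in seq_len(t)) {
    v <- body[j]
    outs <- which(rest[, "parent"] == v)
    ins <- which(rest[, "child"] == v)
    if (length(outs) + length(ins) != 1L)
      stop("shape is not binary: vertex ", v, " has ",
           length(outs) + length(ins), " non-spinal arcs")
    if (length(ins) == 1L) {
      letters[j] <- "R"                 # extra incoming arc: reticulation
      nonspinal[[j]] <- rest[ins, "parent"]
      ret_order <- c(ret_order, j)
    } else {
      w <- rest[outs, "child"]
      if (w %in% shape$leaves) {
        letters[j] <- "L"
      } else {
        letters[j] <- "P"
        nonspinal[[j]] <- w
      }
    }
  }
  for (i in seq_along(ret_order)) letters[ret_order[i]] <- paste0("R", i)
  for (j in which(letters == "P")) {
    target <- pos_of[[nonspinal[[j]]]]
    letters[j] <- paste0("P", match(target, ret_order))
  }
  new_lrp(letters)
}

#' Decode an LRP sequence into a binary spinal shape
#'
#' Builds the spine of `n+2k-1` non-leaf vertices from the leaf end up,
#' attaches the spine leaf and one leaf per `L`, and adds the non-spinal
#' arc from each `P_i` vertex down to its reticulation `R_i`. Leaves are
#' labelled canonically in spine order (the spine leaf is 1). Rules R1-R2
#' must hold; an R3 violation encodes a parallel arc and is admitted only
#' with `allow_parallel = TRUE`.
#'
#' @param seq an `lrp_sequence` or its text form.
#' @param allow_parallel admit parallel arcs (R3 violations).
#' @return A `phylo_network`.
#' @examples
#' net <- decode_lrp("R1,L,P1,R2,L,P2,L")
#' classify_network(net)[["tree_child"]]
#' @export
decode_lrp <- function(seq, allow_parallel = FALSE) {
  if (is.character(seq) && length(seq) == 1L) seq <- parse_lrp(seq)
  chk <- check_rules(seq, class_spec(if (allow_parallel) "BSP" else "BS"))
  if (!chk$member)
    stop("sequence violates rules: ", paste(chk$violations, collapse = "; "))
  z <- .lrp_positions(seq)
  t <- length(z$letters)
  if (t == 0L) return(phylo_network(rbind(c("s1", "1"))))   # single-leaf tree
  body <- paste0("s", seq_len(t))
  arcs <- NULL
  # spinal path: s_{j+1} -> s_j, and the spine leaf under s1
  if (t > 1L) arcs <- cbind(body[2:t], body[1:(t - 1L)])
  leaf_ct <- 1L
  arcs <- rbind(arcs, c(body[1L], "1"))
  for (j in seq_len(t)) {
    if (z$letters[j] == "L") {
      leaf_ct <- leaf_ct + 1L
      arcs <- rbind(arcs, c(body[j], as.character(leaf_ct)))
    }
  }
  for (i in seq_len(z$k)) {
    arcs <- rbind(arcs, c(body[z$ppos[i]], body[z$rpos[i]]))
  }
  phylo_network(arcs, allow_parallel = allow_parallel)
}

# ---- bijections to partition / permutation families -----------------------

# split an STC sequence into blocks R_iL | L | P_i; returns per-block info
.stc_blocks <- function(seq) {
  z <- .lrp_positions(seq)
  blocks <- list()
  j <- 1L
  while (j <= length(z$letters)) {
    lt <- z$letters[j]
    if (startsWith(lt, "R")) {
      if (j == length(z$letters) || z$letters[j + 1L] != "L")
        stop("sequence is not tree-child valid (R not followed by L)")
      blocks[[length(blocks) + 1L]] <- list(type = "RL", i = as.integer(sub("R", "", lt)))
      j <- j + 2L
    } else if (lt == "L") {
      blocks[[length(blocks) + 1L]] <- list(type = "L")
      j <- j + 1L
    } else {
      blocks[[length(blocks) + 1L]] <- list(type = "P", i = as.integer(sub("P", "", lt)))
      j <- j + 1L
    }
  }
  blocks
}

#' Bijection with partitions into singletons and doubletons
#'
#' A tree-child-valid LRP sequence splits into blocks `R_iL`, `L`, `P_i`
#' occupying positions `1..n-1+k` left to right. Pairing the block position
#' of each `R_iL` with that of its `P_i` gives k doubletons; lone `L`
#' blocks give singletons: a partition of `{1..n-1+k}` with exactly k
#' parts of size 2 (the family counted by Bessel numbers).
#' `bessel_partition_to_lrp()` inverts: each doubleton places `R_iL` at its
#' minimum and `P_i` at its maximum (doubletons indexed by ascending
#' minimum), singletons place `L`.
#'
#' @param seq a tree-child-valid `lrp_sequence` (or text).
#' @param partition list of integer vectors (or text `"12|34|5"`, single
#'   digits per element).
#' @return A partition (list of sorted integer vectors, ordered by
#'   minimum) with attribute `text`, or an `lrp_sequence`.
#' @examples
#' attr(lrp_to_bessel_partition("R1,L,P1,R2,L,P2,L"), "text")  # "12|34|5"
#' @export
lrp_to_bessel_partition <- function(seq) {
  if (is.character(seq) && length(seq) == 1L) seq <- parse_lrp(seq)
  chk <- check_rules(seq, class_spec("STC"))
  if (!chk$member)
    stop("sequence is not tree-child valid: ", paste(chk$violations, collapse = "; "))
  blocks <- .stc_blocks(seq)
  k <- attr(seq, "k")
  rl_pos <- p_pos <- integer(k)
  parts <- list()
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    if (bl$type == "RL") rl_pos[bl$i] <- b
    else if (bl$type == "P") p_pos[bl$i] <- b
    else parts[[length(parts) + 1L]] <- b
  }
  for (i in seq_len(k)) parts[[length(parts) + 1L]] <- c(rl_pos[i], p_pos[i])
  .partition_canonical(parts)
}

.partition_canonical <- function(parts) {
  parts <- lapply(parts, function(p) sort(as.integer(p)))
  parts <- parts[order(vapply(parts, min, integer(1)))]
  attr(parts, "text") <- paste(vapply(parts, function(p) paste(p, collapse = ""),
                                      character(1)), collapse = "|")
  parts
}

.parse_partition <- function(text) {
  parts <- strsplit(trimws(text), "|", fixed = TRUE)[[1]]
  lapply(parts, function(p) as.integer(strsplit(p, "")[[1]]))
}

#' @rdname lrp_to_bessel_partition
#' @export
bessel_partition_to_lrp <- function(partition) {
  if (is.character(partition)) partition <- .parse_partition(partition)
  parts <- lapply(partition, function(p) sort(as.integer(p)))
  sizes <- lengths(parts)
  if (!all(sizes %in% c(1L, 2L)))
    stop("parts must have size 1 or 2")
  npos <- length(unlist(parts))
  if (!setequal(unlist(parts), seq_len(npos)))
    stop("parts must partition 1..", npos)
  doubles <- parts[sizes == 2L]
  doubles <- doubles[order(vapply(doubles, min, integer(1)))]
  slot <- vector("list", npos)
  for (p in parts[sizes == 1L]) slot[[p]] <- "L"
  for (i in seq_along(doubles)) {
    slot[[doubles[[i]][1L]]] <- c(paste0("R", i), "L")
    slot[[doubles[[i]][2L]]] <- paste0("P", i)
  }
  new_lrp(unlist(slot))
}

# split an SSF sequence into blocks R_iL | R_iP_j | L | P_i
.ssf_blocks <- function(seq) {
  z <- .lrp_positions(seq)
  blocks <- list()
  j <- 1L
  while (j <= length(z$letters)) {
    lt <- z$letters[j]
    if (startsWith(lt, "R")) {
      if (j == length(z$letters)) stop("sequence is not stack-free valid")
      nxt <- z$letters[j + 1L]
      if (nxt == "L") {
        blocks[[length(blocks) + 1L]] <-
          list(type = "RL", i = as.integer(sub("R", "", lt)))
      } else if (startsWith(nxt, "P")) {
        blocks[[length(blocks) + 1L]] <-
          list(type = "RP", i = as.integer(sub("R", "", lt)),
               p = as.integer(sub("P", "", nxt)))
      } else {
        stop("sequence is not stack-free valid (R followed by R)")
      }
      j <- j + 2L
    } else if (lt == "L") {
      blocks[[length(blocks) + 1L]] <- list(type = "L")
      j <- j + 1L
    } else {
      blocks[[length(blocks) + 1L]] <- list(type = "P", i = as.integer(sub("P", "", lt)))
      j <- j + 1L
    }
  }
  blocks
}

#' Bijection with set partitions into n-1 parts
#'
#' A stack-free-valid LRP sequence splits into blocks `R_iL`, `R_iP_j`,
#' `L`, `P_i`. Relating the block position of each `R_iL` with the
#' position holding the matching `P_i` (lone or inside `R_jP_i`) and
#' closing transitively partitions `{1..n-1+k}` into exactly `n-1` parts.
#' The inverse reads each part in ascending order: minimum holds `R L`,
#' middle elements hold `R P`, the maximum holds the closing `P`;
#' reticulation indices are assigned by position order of the `R`s.
#'
#' @param seq a stack-free-valid `lrp_sequence` (or text).
#' @param partition list of integer vectors or text (`"124|3"`).
#' @return A partition with attribute `text`, or an `lrp_sequence`.
#' @examples
#' attr(lrp_to_set_partition("R1,L,R2,P1,L,P2"), "text")  # "124|3"
#' @export
lrp_to_set_partition <- function(seq) {
  if (is.character(seq) && length(seq) == 1L) seq <- parse_lrp(seq)
  chk <- check_rules(seq, class_spec("SSF"))
  if (!chk$member)
    stop("sequence is not stack-free valid: ", paste(chk$violations, collapse = "; "))
  blocks <- .ssf_blocks(seq)
  nb <- length(blocks)
  parent <- seq_len(nb)                      # union-find
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union <- function(a, b) { parent[find(a)] <<- find(b) }
  rl_at <- integer(0)                        # reticulation i -> block of R_iL / R_i...
  pos_of_p <- integer(0)                     # reticulation i -> block holding P_i
  for (b in seq_len(nb)) {
    bl <- blocks[[b]]
    if (bl$type %in% c("RL", "RP")) rl_at[bl$i] <- b
    if (bl$type == "RP") pos_of_p[bl$p] <- b
    if (bl$type == "P") pos_of_p[bl$i] <- b
  }
  # the block holding each R_i is related to the block holding its P_i;
  # transitive closure gives the partition
  for (i in seq_along(rl_at)) union(rl_at[i], pos_of_p[i])
  groups <- split(seq_len(nb), vapply(seq_len(nb), find, integer(1)))
  .partition_canonical(unname(groups))
}

#' @rdname lrp_to_bessel_partition
#' @export
set_partition_to_lrp <- function(partition) {
  if (is.character(partition)) partition <- .parse_partition(partition)
  parts <- lapply(partition, function(p) sort(as.integer(p)))
  npos <- length(unlist(parts))
  if (!setequal(unlist(parts), seq_len(npos)))
    stop("parts must partition 1..", npos)
  # which positions hold an R (every part element except its maximum)
  r_positions <- sort(unlist(lapply(parts, function(p) p[-length(p)])))
  r_index_at <- stats::setNames(seq_along(r_positions), r_positions)
  slot <- vector("list", npos)
  for (p in parts) {
    if (length(p) == 1L) { slot[[p]] <- "L"; next }
    for (t in seq_len(length(p) - 1L)) {
      pos <- p[t]
      ri <- r_index_at[[as.character(pos)]]
      if (t == 1L) {
        slot[[pos]] <- c(paste0("R", ri), "L")
      } else {
        prev_ri <- r_index_at[[as.character(p[t - 1L])]]
        slot[[pos]] <- c(paste0("R", ri), paste0("P", prev_ri))
      }
    }
    last_ri <- r_index_at[[as.character(p[length(p) - 1L])]]
    slot[[p[length(p)]]] <- paste0("P", last_ri)
  }
  new_lrp(unlist(slot))
}

# split an FTS sequence into blocks R_i..R_hL | L | P_i
.fts_blocks <- function(seq) {
  z <- .lrp_positions(seq)
  blocks <- list()
  j <- 1L
  while (j <= length(z$letters)) {
    lt <- z$letters[j]
    if (startsWith(lt, "R")) {
      run <- integer(0)
      while (startsWith(z$letters[j], "R")) {
        run <- c(run, as.integer(sub("R", "", z$letters[j])))
        j <- j + 1L
        if (j > length(z$letters)) stop("sequence is not fully-tree-sibling valid")
      }
      if (z$letters[j] != "L") stop("sequence is not fully-tree-sibling valid (R run not closed by L)")
      blocks[[length(blocks) + 1L]] <- list(type = "RunL", is = run)
      j <- j + 1L
    } else if (lt == "L") {
      blocks[[length(blocks) + 1L]] <- list(type = "L")
      j <- j + 1L
    } else {
      blocks[[length(blocks) + 1L]] <- list(type = "P", i = as.integer(sub("P", "", lt)))
      j <- j + 1L
    }
  }
  blocks
}

#' Bijection with permutations having n-1 cycles
#'
#' A fully-tree-sibling-valid LRP sequence splits into blocks
#' `R_i...R_hL`, `L`, `P_i`. Each lone `L` becomes a fixed point of its
#' block position; each run block at position `p` with parents `P_i..P_h`
#' at positions `q_i..q_h` becomes the cycle `(p q_i ... q_h)`. The result
#' is a permutation of `{1..n-1+k}` with exactly `n-1` cycles. The inverse
#' rotates each cycle to start at its minimum (which is always the run
#' block) and reads the structure back.
#'
#' @param seq a fully-tree-sibling-valid `lrp_sequence` (or text).
#' @param perm integer vector `perm[i] = image of i`, or cycle text
#'   `"(143)(2)"`.
#' @return An integer permutation vector with attribute `text` (cycle
#'   notation, cycles ordered by minimum, fixed points included), or an
#'   `lrp_sequence`.
#' @examples
#' attr(lrp_to_permutation("R1,R2,L,L,P2,P1"), "text")  # "(143)(2)"
#' @export
lrp_to_permutation <- function(seq) {
  if (is.character(seq) && length(seq) == 1L) seq <- parse_lrp(seq)
  chk <- check_rules(seq, class_spec("FTS"))
  if (!chk$member)
    stop("sequence is not fully-tree-sibling valid: ",
         paste(chk$violations, collapse = "; "))
  blocks <- .fts_blocks(seq)
  nb <- length(blocks)
  p_at <- integer(0)
  for (b in seq_len(nb)) {
    bl <- blocks[[b]]
    if (bl$type == "P") p_at[bl$i] <- b
  }
  perm <- seq_len(nb)
  for (b in seq_len(nb)) {
    bl <- blocks[[b]]
    if (bl$type == "RunL") {
      cyc <- c(b, p_at[bl$is])         # indices ascending along the run
      for (t in seq_along(cyc)) {
        perm[cyc[t]] <- cyc[if (t == length(cyc)) 1L else t + 1L]
      }
    }
  }
  attr(perm, "text") <- .cycle_text(perm)
  perm
}

.cycle_text <- function(perm) {
  n <- length(perm)
  seen <- rep(FALSE, n)
  out <- character(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    cyc <- s; seen[s] <- TRUE
    v <- perm[s]
    while (v != s) { cyc <- c(cyc, v); seen[v] <- TRUE; v <- perm[v] }
    out <- c(out, paste0("(", paste(cyc, collapse = ""), ")"))
  }
  paste(out, collapse = "")
}

.parse_cycles <- function(text) {
  text <- gsub(" ", "", text)
  if (!grepl("^(\\([0-9]+\\))+$", text)) stop("malformed cycle notation: ", text)
  cycs <- regmatches(text, gregexpr("\\(([0-9]+)\\)", text))[[1]]
  cycs <- lapply(cycs, function(s) as.integer(strsplit(gsub("[()]", "", s), "")[[1]]))
  n <- max(unlist(cycs))
  perm <- seq_len(n)
  for (cyc in cycs) {
    for (t in seq_along(cyc)) perm[cyc[t]] <- cyc[if (t == length(cyc)) 1L else t + 1L]
  }
  perm
}

#' @rdname lrp_to_permutation
#' @export
permutation_to_lrp <- function(perm) {
  if (is.character(perm)) perm <- .parse_cycles(perm)
  perm <- as.integer(perm)
  n <- length(perm)
  if (!setequal(perm, seq_len(n))) stop("not a permutation of 1..", n)
  seen <- rep(FALSE, n)
  cycles <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    cyc <- s; seen[s] <- TRUE
    v <- perm[s]
    while (v != s) { cyc <- c(cyc, v); seen[v] <- TRUE; v <- perm[v] }
    m <- which.min(cyc)
    cycles[[length(cycles) + 1L]] <- c(cyc[m:length(cyc)], cyc[seq_len(m - 1L)])
  }
  # positions holding R's: run-block positions repeated once per parent
  slot <- vector("list", n)
  run_blocks <- cycles[lengths(cycles) > 1L]
  # global R index = order of R position... each run block at position p has
  # h = len-1 reticulations, all at block p; index by p then run order
  run_blocks <- run_blocks[order(vapply(run_blocks, function(c) c[1L], integer(1)))]
  next_index <- 1L
  for (cyc in cycles[lengths(cycles) == 1L]) slot[[cyc[1L]]] <- "L"
  for (cyc in run_blocks) {
    h <- length(cyc) - 1L
    idx <- next_index:(next_index + h - 1L)
    next_index <- next_index + h
    slot[[cyc[1L]]] <- c(paste0("R", idx), "L")
    for (t in seq_len(h)) slot[[cyc[1L + t]]] <- paste0("P", idx[t])
  }
  new_lrp(unlist(slot))
}
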