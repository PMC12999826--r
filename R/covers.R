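# Expanding covers: the set-system encoding of labellable networks.
#
# A cover of [m] is a collection of subsets whose union is {1..m}. With
# n = m - |C| + 1 it is *expanding* when (i) no element of {1..n} (a leaf
# label) appears in more than one set, and (ii) for every i the cover
# contains at least i subsets of {1..n+i-1}. Expanding covers are in
# bijection with labellable networks: the i-th set in labelling order is the
# children-label set of the vertex labelled n+i (the root's set comes last).

#' Construct an expanding cover
#'
#' Builds an `expanding_cover` from a list of integer sets, reordering them
#' into labelling order (see [reorder_labelling()]) unless asked not to.
#' The object stores the sets plus the derived quantities `m` (ground-set
#' size = number of non-root vertices), `c` (number of sets = number of
#' non-leaf vertices including the root) and `n = m - c + 1` (leaf count).
#'
#' @param sets list of integer vectors, each a non-empty set of positive
#'   integers; duplicated elements within one set are an error.
#' @param reorder if `TRUE` (default), recover the labelling order; if
#'   `FALSE`, trust the given order.
#' @param strict if `TRUE` (default), reject repeated leaf elements (no
#'   element of `{1..n}` may appear in two sets); `strict = FALSE` admits
#'   arbitrary set systems so that [validate_expanding()] can report their
#'   violations.
#' @return An object of class `expanding_cover` with fields `sets`, `m`,
#'   `c`, `n`. Full validity is *not* enforced here; use
#'   [validate_expanding()].
#' @seealso [parse_cover()], [validate_expanding()], [cover_to_network()]
#' @export
expanding_cover <- function(sets, reorder = TRUE, strict = TRUE) {
  if (length(sets) == 0L) stop("empty cover: a network needs a root and at least one leaf")
  sets <- lapply(sets, function(s) {
    s <- as.integer(s)
    if (length(s) == 0L) stop("empty set in cover")
    if (any(s < 1L)) stop("cover elements must be positive integers")
    if (anyDuplicated(s)) stop("duplicate element within one set: {", paste(s, collapse = ","), "}")
    sort(s)
  })
  keys <- vapply(sets, function(s) paste(s, collapse = ","), character(1))
  if (anyDuplicated(keys)) stop("cover contains two equal sets; labelling would be ambiguous")
  m <- max(unlist(sets))
  cc <- length(sets)
  n <- m - cc + 1L
  cov <- structure(list(sets = sets, m = m, c = cc, n = n), class = "expanding_cover")
  if (strict && n >= 1L) {
    mult <- .cover_mult(cov)
    bad <- which(mult[seq_len(min(n, m))] > 1L)
    if (length(bad) > 0L)
      stop("leaf element ", bad[1L], " appears more than once in the cover")
  }
  if (reorder && cc > 1L) cov <- reorder_labelling(cov) else cov
}

#' Parse and serialise covers
#'
#' `parse_cover()` reads one cover from its text form: either the semicolon
#' dialect `"{2,3};{1,5};{5}"` (sets semicolon-separated, elements
#' comma-separated) or a JSON array-of-arrays `"[[2,3],[1,5],[5]]"`.
#' `format()` writes the canonical semicolon dialect, sets in labelling
#' order, elements ascending.
#'
#' @param text a single cover string.
#' @param reorder,strict passed on to [expanding_cover()].
#' @return `parse_cover()` returns an `expanding_cover`.
#' @examples
#' cov <- parse_cover("{2,3};{1,5};{5};{4,7};{5,6};{5,7,9};{8,10}")
#' cov$n  # 4 leaves
#' format(cov)
#' @export
parse_cover <- function(text, reorder = TRUE, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (startsWith(s, "[")) {
    sets <- jsonlite::fromJSON(s, simplifyVector = FALSE)
    sets <- lapply(sets, function(x) as.integer(unlist(x)))
    return(expanding_cover(sets, reorder = reorder, strict = strict))
  }
  if (!grepl("^\\{[0-9, ]+\\}(;\\{[0-9, ]+\\})*$", s))
    stop("malformed cover text: ", text)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  sets <- lapply(parts, function(p) {
    p <- gsub("[{} ]", "", p)
    as.integer(strsplit(p, ",", fixed = TRUE)[[1]])
  })
  expanding_cover(sets, reorder = reorder, strict = strict)
}

#' @rdname parse_cover
#' @param x an `expanding_cover`.
#' @param ... unused.
#' @export
format.expanding_cover <- function(x, ...) {
  paste(vapply(x$sets, function(s) paste0("{", paste(s, collapse = ","), "}"),
               character(1)), collapse = ";")
}

#' @export
print.expanding_cover <- function(x, ...) {
  cat("Expanding cover: ", format(x), "\n", sep = "")
  cat("  m = ", x$m, " (non-root vertices),  |C| = ", x$c,
      " (non-leaf vertices),  n = ", x$n, " (leaves)\n", sep = "")
  invisible(x)
}

#' @export
as.character.expanding_cover <- function(x, ...) format(x)

#' Read/write cover files
#'
#' One cover per line in the semicolon dialect; blank lines and `#` comments
#' are skipped.
#'
#' @param path file path.
#' @param covers list of `expanding_cover` objects.
#' @return `read_covers()`: a list of `expanding_cover`.
#' @export
read_covers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_cover)
}

#' @rdname read_covers
#' @export
write_covers <- function(covers, path) {
  writeLines(vapply(covers, format, character(1)), path)
  invisible(path)
}

# multiplicity of every element 1..m across the cover
.cover_mult <- function(cov) {
  tabulate(unlist(cov$sets), nbins = cov$m)
}

#' Validate the expanding-cover conditions
#'
#' Checks both defining conditions of an expanding cover: no leaf element
#' (of `{1..n}`) appears more than once, and for every `i` the cover has at
#' least `i` subsets of `{1..n+i-1}`. Violations are reported, not thrown.
#'
#' @param cov an `expanding_cover` (or cover text, parsed on the fly).
#' @return A list with `is_expanding` (flag), `n`, `m`, and `violations`, a
#'   character vector describing every violated condition (empty if valid).
#' @examples
#' validate_expanding(parse_cover("{2,3};{1,5};{5};{4,7};{5,6};{5,7,9};{8,10}"))$is_expanding
#' @export
validate_expanding <- function(cov) {
  if (is.character(cov)) cov <- parse_cover(cov, reorder = FALSE, strict = FALSE)
  if (!inherits(cov, "expanding_cover")) cov <- expanding_cover(cov, reorder = FALSE, strict = FALSE)
  viol <- character(0)
  mult <- .cover_mult(cov)
  if (any(mult == 0L))
    viol <- c(viol, paste0("element ", which(mult == 0L)[1L],
                           " missing: sets do not cover {1..", cov$m, "}"))
  rep_leaves <- which(mult[seq_len(max(0L, cov$n))] > 1L)
  if (cov$n >= 1L && length(rep_leaves) > 0L)
    viol <- c(viol, paste0("leaf element ", rep_leaves, " appears ",
                           mult[rep_leaves], " times"))
  maxes <- sort(vapply(cov$sets, max, integer(1)))
  for (i in seq_len(cov$c)) {
    if (maxes[i] > cov$n + i - 1L) {
      viol <- c(viol, paste0("fewer than ", i, " subsets of {1..", cov$n + i - 1L, "}"))
    }
  }
  list(is_expanding = length(viol) == 0L, n = cov$n, m = cov$m, violations = viol)
}

#' Recover the labelling order of a cover
#'
#' The labelling order is the order in which the labelling algorithm labels
#' the owning vertices. It is recovered directly from the sets: at step `i`
#' the candidate sets are the unused sets all of whose elements are already
#' labelled (i.e. at most `n+i-1`), and the lexicographically least
#' candidate becomes `C_i`; the remaining set (the root's children) comes
#' last. For a spinal cover this reduces to: `C_1` is the all-leaf set and
#' `C_i` is the unique set with maximum `n+i-1`.
#'
#' @param cov an `expanding_cover` (possibly in arbitrary order) or a list
#'   of integer sets.
#' @return The cover with `sets` in labelling order.
#' @export
reorder_labelling <- function(cov) {
  if (!inherits(cov, "expanding_cover")) cov <- expanding_cover(cov, reorder = FALSE)
  if (cov$c == 1L) return(cov)
  sets <- cov$sets
  n <- cov$n
  used <- rep(FALSE, length(sets))
  ord <- integer(0)
  for (i in seq_len(cov$c)) {
    cand <- which(!used & vapply(sets, max, integer(1)) <= n + i - 1L)
    if (length(cand) == 0L)
      stop("cannot recover labelling order: cover is not expanding")
    best <- cand[1L]
    if (length(cand) > 1L) {
      for (j in cand[-1L]) if (.lex_less(sets[[j]], sets[[best]])) best <- j
    }
    ord <- c(ord, best)
    used[best] <- TRUE
  }
  cov$sets <- sets[ord]
  cov
}

# lexicographic order on integer sets, read as ascending sequences with a
# proper prefix ordered first ({1,5} < {5}; {1} < {1,5}); returns TRUE on
# equality, which callers exclude separately
.lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) <= length(b)
}

#' Cover-level class predicates
#'
#' Characterisations of network classes evaluated directly on the expanding
#' cover (sets indexed in labelling order, `C_1..C_c`):
#' * `is_spinal_cover()`: the network is spinal iff for every `i` the cover
#'   has *exactly* `i` subsets of `{1..n+i-1}` (the expanding condition
#'   tightened from "at least" to "exactly").
#' * `is_tree_child_cover()`: tree-child iff every set contains an element
#'   whose total multiplicity across the cover is 1.
#' * `is_nondegenerate_cover()`: non-degenerate iff for every position `i`
#'   (except the root's, whose putative label `n+c` does not exist),
#'   `|C_i| > 1` implies `n+i` appears at most once and `|C_i| = 1` implies
#'   `n+i` appears more than once.
#' * `is_binary_cover()`: binary iff every set has size 1 or 2, the root's
#'   set has size exactly 2 (its out-degree must be 2) and, with the root
#'   exempt from the multiplicity clauses, `|C_i| = 2` implies `n+i`
#'   appears exactly once and `|C_i| = 1` implies `n+i` appears exactly
#'   twice.
#'
#' @param cov an `expanding_cover` in labelling order (or cover text).
#' @return A logical flag.
#' @export
is_spinal_cover <- function(cov) {
  if (is.character(cov)) cov <- parse_cover(cov)
  v <- validate_expanding(cov)
  if (!v$is_expanding)
    stop("cover is not expanding: ", paste(v$violations, collapse = "; "))
  maxes <- vapply(cov$sets, max, integer(1))
  counts <- vapply(seq_len(cov$c), function(i) sum(maxes <= cov$n + i - 1L), integer(1))
  all(counts == seq_len(cov$c))
}

#' @rdname is_spinal_cover
#' @export
is_tree_child_cover <- function(cov) {
  if (is.character(cov)) cov <- parse_cover(cov)
  mult <- .cover_mult(cov)
  all(vapply(cov$sets, function(s) any(mult[s] == 1L), logical(1)))
}

#' @rdname is_spinal_cover
#' @export
is_nondegenerate_cover <- function(cov) {
  if (is.character(cov)) cov <- parse_cover(cov)
  mult <- .cover_mult(cov)
  n <- cov$n
  for (i in seq_len(cov$c - 1L)) {       # the root's set imposes no condition
    mi <- mult[n + i]
    if (length(cov$sets[[i]]) > 1L && mi > 1L) return(FALSE)
    if (length(cov$sets[[i]]) == 1L && mi <= 1L) return(FALSE)
  }
  TRUE
}

#' @rdname is_spinal_cover
#' @export
is_binary_cover <- function(cov) {
  if (is.character(cov)) cov <- parse_cover(cov)
  sizes <- lengths(cov$sets)
  if (any(sizes > 2L)) return(FALSE)
  if (sizes[cov$c] != 2L) return(FALSE)   # the root must have out-degree 2
  mult <- .cover_mult(cov)
  n <- cov$n
  for (i in seq_len(cov$c - 1L)) {       # root's set exempt: label n+c does not exist
    mi <- mult[n + i]
    if (sizes[i] == 2L && mi != 1L) return(FALSE)
    if (sizes[i] == 1L && mi != 2L) return(FALSE)
  }
  TRUE
}

#' Category tags for binary spinal tree-child covers
#'
#' For the cover of a binary spinal tree-child network, every set beyond the
#' first falls into exactly one of three categories:
#' 1. the singleton `C_i = {n+i-1}` together with its successor `C_{i+1}`
#'    (which contains `n+i` and a leaf) — both members of the pair are
#'    tagged 1;
#' 2. `C_i` contains `n+i-1` and a leaf and is not the second set of a
#'    category-1 pair;
#' 3. `C_i` contains `n+i-1` uniquely together with a repeated earlier
#'    element `n+j` whose own set `C_j` is a singleton.
#' The number of category-1 pairs always equals the number of category-3
#' sets (each pair hosts one reticulation whose second parent is the
#' matching category-3 vertex).
#'
#' @param cov cover of a binary spinal tree-child network, labelling order.
#' @return Integer vector of tags, one per set. The first set is `NA` when
#'   it is a cherry (two leaves, an L-vertex, outside the categories) and
#'   `1` when it is a leaf singleton, in which case the lowest spine vertex
#'   is a reticulation opening a category-1 pair.
#' @export
stc_categories <- function(cov) {
  if (is.character(cov)) cov <- parse_cover(cov)
  if (!is_spinal_cover(cov) || !is_binary_cover(cov) || !is_tree_child_cover(cov))
    stop("cover is not the cover of a binary spinal tree-child network")
  n <- cov$n
  tags <- rep(NA_integer_, cov$c)
  # C_1 is the children-set of the lowest spine vertex: a leaf pair (cherry,
  # an L-vertex, outside the categories) or a leaf singleton, in which case
  # that vertex is a reticulation and C_1 opens a category-1 pair
  if (length(cov$sets[[1L]]) == 1L) tags[1L] <- 1L
  for (i in seq(2L, length.out = cov$c - 1L)) {
    s <- cov$sets[[i]]
    if (length(s) == 1L) {
      tags[i] <- 1L                                     # first of a pair
    } else if (length(cov$sets[[i - 1L]]) == 1L) {
      tags[i] <- 1L                                     # second of a pair
    } else if (setdiff(s, n + i - 1L) <= n) {
      tags[i] <- 2L
    } else {
      tags[i] <- 3L
    }
  }
  tags
}
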