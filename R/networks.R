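# Rooted phylogenetic networks as directed acyclic multigraphs.
#
# A network has one in-degree-0 vertex (the root), n out-degree-0 vertices
# of in-degree 1 (the leaves, labelled "1".."n"), and internal vertices of
# arbitrary in/out-degree >= 1. Arcs are stored as an ordered multiset of
# (parent, child) pairs; parallel arcs are admitted only when the
# allow_parallel flag is on. Throughout, "internal vertices" means non-root
# non-leaf vertices; the root is tracked separately (a binary network on n
# leaves with k reticulations has n+2k-2 internal vertices, and its spine
# has n+2k-1 non-leaf vertices once the root is included).

#' Construct a phylogenetic network
#'
#' @param arcs two-column character matrix (or data.frame) of
#'   `(parent, child)` arcs. Leaves are the vertices with no outgoing arc
#'   and must be named `"1".."n"`.
#' @param allow_parallel admit repeated `(parent, child)` arcs (needed only
#'   for the binary-spinal-with-parallel-arcs class).
#' @return An object of class `phylo_network` with fields `vertices`,
#'   `arcs`, `root`, `leaves`, `n`, `allow_parallel`.
#' @examples
#' cherry <- phylo_network(rbind(c("r", "1"), c("r", "2")))
#' network_height(cherry)  # 1
#' @export
phylo_network <- function(arcs, allow_parallel = FALSE) {
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2L) stop("arcs must have two columns (parent, child)")
  mode(arcs) <- "character"
  colnames(arcs) <- c("parent", "child")
  vertices <- unique(c(arcs))
  if (!allow_parallel && anyDuplicated(paste(arcs[, 1L], arcs[, 2L], sep = "\r")))
    stop("parallel arcs present but allow_parallel = FALSE")
  net <- structure(list(vertices = vertices, arcs = arcs,
                        allow_parallel = allow_parallel),
                   class = "phylo_network")
  indeg <- .in_degree(net)
  outdeg <- .out_degree(net)
  roots <- vertices[indeg == 0L]
  if (length(roots) != 1L) stop("network must have exactly one in-degree-0 vertex")
  leaves <- vertices[outdeg == 0L]
  if (any(indeg[match(leaves, vertices)] != 1L))
    stop("leaves must have in-degree 1")
  if (!setequal(leaves, as.character(seq_along(leaves))))
    stop("leaves must be labelled 1..n; got: ", paste(sort(leaves), collapse = ","))
  if (.has_cycle(net)) stop("arcs contain a directed cycle")
  net$root <- roots
  net$leaves <- as.character(seq_along(leaves))
  net$n <- length(leaves)
  net
}

.in_degree <- function(net) {
  tab <- table(factor(net$arcs[, "child"], levels = net$vertices))
  as.integer(tab)
}

.out_degree <- function(net) {
  tab <- table(factor(net$arcs[, "parent"], levels = net$vertices))
  as.integer(tab)
}

.children <- function(net, v) net$arcs[net$arcs[, "parent"] == v, "child"]
.parents  <- function(net, v) net$arcs[net$arcs[, "child"] == v, "parent"]

.has_cycle <- function(net) {
  deg <- .in_degree(net)
  names(deg) <- net$vertices
  queue <- net$vertices[deg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in .children(net, v)) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(net$vertices)
}

#' @export
print.phylo_network <- function(x, ...) {
  cat("Phylogenetic network: ", length(x$vertices), " vertices, ",
      nrow(x$arcs), " arcs, ", x$n, " leaves",
      if (x$allow_parallel) " (parallel arcs allowed)", "\n", sep = "")
  invisible(x)
}

#' Read/write a network as a directed edge list
#'
#' Tab-separated `parent<TAB>child` lines; `#` comments skipped.
#'
#' @param path file path.
#' @param net a `phylo_network`.
#' @param allow_parallel passed to [phylo_network()].
#' @export
read_edgelist <- function(path, allow_parallel = FALSE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("edge list lines must be parent<TAB>child")
  phylo_network(do.call(rbind, parts), allow_parallel = allow_parallel)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(net, path) {
  writeLines(paste(net$arcs[, "parent"], net$arcs[, "child"], sep = "\t"), path)
  invisible(path)
}

# ---- labelling algorithm ---------------------------------------------------

#' Label the internal vertices of a network
#'
#' Runs the deterministic labelling algorithm: leaves carry labels `1..n`;
#' repeatedly, among the unlabelled non-root internal vertices whose
#' children are all labelled, the vertex whose children-label set is least
#' under the lexicographic set order (`A < B` if `A` is a subset of `B` or
#' the minimum of the symmetric difference lies in `A`) receives the next
#' label `n+1, n+2, ...`. The network is *labellable* when this choice is
#' unique at every step; two candidate vertices with identical children
#' sets make the network non-labellable.
#'
#' @param net a `phylo_network`.
#' @return A list with `status` (`"ok"` or `"not_labellable"`) and, when ok,
#'   `labels` (named integer vector mapping vertex id to label; leaves map
#'   to themselves, the root is excluded).
#' @export
label_vertices <- function(net) {
  stopifnot(inherits(net, "phylo_network"))
  n <- net$n
  labels <- stats::setNames(rep(NA_integer_, length(net$vertices)), net$vertices)
  labels[net$leaves] <- seq_len(n)
  todo <- setdiff(net$vertices, c(net$leaves, net$root))
  i <- 0L
  while (length(todo) > 0L) {
    child_sets <- lapply(todo, function(v) {
      ch <- labels[.children(net, v)]
      if (anyNA(ch)) NULL else sort(unique(as.integer(ch)))
    })
    cand <- which(!vapply(child_sets, is.null, logical(1)))
    if (length(cand) == 0L) return(list(status = "not_labellable"))
    best <- cand[1L]
    for (j in cand[-1L]) {
      if (.lex_less(child_sets[[j]], child_sets[[best]])) best <- j
    }
    # the minimum must be attained by a unique vertex
    for (j in cand) {
      if (j != best && identical(child_sets[[j]], child_sets[[best]]))
        return(list(status = "not_labellable"))
    }
    i <- i + 1L
    labels[todo[best]] <- n + i
    todo <- todo[-best]
  }
  list(status = "ok", labels = labels[!is.na(labels)])
}

#' Convert between networks and expanding covers
#'
#' `network_to_cover()` labels the network and returns the expanding cover
#' whose i-th set (labelling order) is the children-label set of the vertex
#' labelled `n+i`, with the root's children-set last. `cover_to_network()`
#' rebuilds the network: leaves `1..n`, internal vertices `n+1..m`, a root,
#' and an arc from the owner of each set to each of its members. The two
#' maps are mutually inverse.
#'
#' @param net a labellable `phylo_network`.
#' @param cov an `expanding_cover` in labelling order (or cover text).
#' @param allow_parallel passed to [phylo_network()] on reconstruction.
#' @return A cover, or a network.
#' @examples
#' cov <- parse_cover("{1,2}")
#' net <- cover_to_network(cov)     # the two-leaf cherry
#' format(network_to_cover(net))
#' @export
network_to_cover <- function(net) {
  lab <- label_vertices(net)
  if (lab$status != "ok") stop("network is not labellable")
  labels <- lab$labels
  n <- net$n
  owners <- names(sort(labels[labels > n]))
  sets <- lapply(c(owners, net$root), function(v)
    sort(unique(as.integer(labels[.children(net, v)]))))
  expanding_cover(sets, reorder = FALSE)
}

#' @rdname network_to_cover
#' @export
cover_to_network <- function(cov, allow_parallel = FALSE) {
  if (is.character(cov)) cov <- parse_cover(cov)
  v <- validate_expanding(cov)
  if (!v$is_expanding)
    stop("cover is not expanding: ", paste(v$violations, collapse = "; "))
  n <- cov$n
  arcs <- NULL
  for (i in seq_len(cov$c)) {
    owner <- if (i == cov$c) "rho" else as.character(n + i)
    arcs <- rbind(arcs, cbind(owner, as.character(cov$sets[[i]])))
  }
  phylo_network(arcs, allow_parallel = allow_parallel)
}

# ---- spine, height, classification ----------------------------------------

#' Find the spine of a network
#'
#' A spine is a sequence of vertices from a leaf to the root, following
#' arcs in reverse, that passes through every non-leaf vertex. It exists
#' iff the non-leaf vertices form a directed path (equivalently, their
#' induced subgraph has a unique topological order with consecutive arcs).
#' When the lowest spine vertex has two leaf children either leaf can start
#' the spine; the canonical choice is the smaller label.
#'
#' @param net a `phylo_network`.
#' @return A list of class `network_spine` with `vertices` (leaf first,
#'   root last) and `start_leaf_choices` (integer labels of the admissible
#'   starting leaves), or the string `"NOT_SPINAL"` if no spine exists.
#' @export
find_spine <- function(net) {
  nonleaf <- setdiff(net$vertices, net$leaves)
  # topological order of the induced subgraph on non-leaf vertices
  sub <- net$arcs[net$arcs[, "parent"] %in% nonleaf & net$arcs[, "child"] %in% nonleaf, ,
                  drop = FALSE]
  indeg <- stats::setNames(rep(0L, length(nonleaf)), nonleaf)
  tabs <- table(sub[, "child"])
  indeg[names(tabs)] <- as.integer(tabs)
  ord <- character(0)
  avail <- names(indeg)[indeg == 0L]
  work <- indeg
  while (length(avail) > 0L) {
    if (length(avail) > 1L) return("NOT_SPINAL")   # order not unique: no chain
    v <- avail[1L]
    ord <- c(ord, v)
    avail <- character(0)
    for (w in sub[sub[, "parent"] == v, "child"]) {
      work[w] <- work[w] - 1L
      if (work[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(ord) < length(nonleaf)) return("NOT_SPINAL")
  # consecutive vertices must be joined by an arc
  if (length(ord) > 1L) {
    for (i in seq_len(length(ord) - 1L)) {
      if (!any(net$arcs[, "parent"] == ord[i] & net$arcs[, "child"] == ord[i + 1L]))
        return("NOT_SPINAL")
    }
  }
  lowest <- ord[length(ord)]
  leaf_children <- intersect(.children(net, lowest), net$leaves)
  if (length(leaf_children) == 0L) return("NOT_SPINAL")
  starts <- sort(as.integer(unique(leaf_children)))
  structure(list(vertices = c(as.character(starts[1L]), rev(ord)),
                 start_leaf_choices = starts),
            class = "network_spine")
}

#' @export
print.network_spine <- function(x, ...) {
  cat("Spine (leaf -> root): ", paste(x$vertices, collapse = " -> "), "\n",
      "admissible starting leaves: ", paste(x$start_leaf_choices, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Height of a network
#'
#' The number of arcs in the longest directed path. Among networks with a
#' fixed number of non-leaf vertices the spinal ones are exactly those of
#' maximal height (the path must then traverse every non-leaf vertex before
#' reaching a leaf).
#'
#' @param net a `phylo_network`.
#' @return Non-negative integer.
#' @export
network_height <- function(net) {
  # longest path by DP over reverse topological order
  depth <- stats::setNames(rep(0L, length(net$vertices)), net$vertices)
  indeg <- stats::setNames(.in_degree(net), net$vertices)
  queue <- net$vertices[indeg == 0L]
  work <- indeg
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in .children(net, v)) {
      depth[w] <- max(depth[w], depth[v] + 1L)
      work[w] <- work[w] - 1L
      if (work[w] == 0L) queue <- c(queue, w)
    }
  }
  max(depth)
}

#' Classify a network
#'
#' Evaluates the graph-level class predicates:
#' * `binary`: internal vertices have total degree 3 and the root has
#'   out-degree 2 (a one-vertex-root network is not binary);
#' * `nondegenerate`: no vertex has in- and out-degree both 1, or both > 1;
#' * `spinal`: a spine exists ([find_spine()]);
#' * `tree_child`: every non-leaf vertex has at least one child of
#'   in-degree < 2 (a tree-vertex child);
#' * `stack_free`: every child of a reticulation (in-degree >= 2) is a tree
#'   vertex;
#' * `fully_tree_sibling`: every sibling of a reticulation is a tree vertex;
#' * `has_parallel_arcs`: some `(parent, child)` pair is repeated.
#'
#' On labellable networks these agree with the cover-level predicates
#' ([is_binary_cover()] and friends).
#'
#' @param net a `phylo_network`.
#' @return Named logical vector.
#' @export
classify_network <- function(net) {
  indeg <- stats::setNames(.in_degree(net), net$vertices)
  outdeg <- stats::setNames(.out_degree(net), net$vertices)
  internal <- setdiff(net$vertices, c(net$leaves, net$root))
  retic <- net$vertices[indeg >= 2L]
  is_tree_vertex <- indeg < 2L

  binary <- outdeg[net$root] == 2L &&
    all(indeg[internal] + outdeg[internal] == 3L)
  nondegen <- !any((indeg == 1L & outdeg == 1L) | (indeg > 1L & outdeg > 1L))
  spinal <- !identical(find_spine(net), "NOT_SPINAL")
  tree_child <- all(vapply(setdiff(net$vertices, net$leaves), function(v)
    any(is_tree_vertex[.children(net, v)]), logical(1)))
  stack_free <- length(retic) == 0L ||
    all(vapply(retic, function(v) {
      ch <- .children(net, v)
      length(ch) == 0L || all(is_tree_vertex[ch])
    }, logical(1)))
  fts <- length(retic) == 0L ||
    all(vapply(retic, function(v) {
      # siblings with multiplicity: under a parallel arc a vertex is its own
      # sibling (the parent's child multiset holds it twice)
      sibs <- unlist(lapply(unique(.parents(net, v)), function(p) {
        ch <- .children(net, p)
        ch[-match(v, ch)]
      }))
      length(sibs) == 0L || all(is_tree_vertex[sibs])
    }, logical(1)))
  parallel <- anyDuplicated(paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\r")) > 0L

  c(binary = unname(binary), nondegenerate = nondegen, spinal = spinal,
    tree_child = tree_child, stack_free = stack_free,
    fully_tree_sibling = fts, has_parallel_arcs = parallel)
}

# ---- cherry operations on binary spinal shapes ----------------------------

#' Cherry reduction and re-cherrying of binary spinal shapes
#'
#' In a binary spinal shape the only possible cherry sits on the internal
#' vertex furthest from the root, so cherry reduction (delete one cherry
#' leaf and its parent, reconnecting the grandparent to the surviving leaf)
#' and re-cherrying (subdivide the lowest leaf arc and attach a fresh leaf)
#' are mutually inverse. Both are implemented on the shape's LRP encoding:
#' a shape has a cherry iff its LRP sequence starts with `L`, reduction
#' drops that letter, re-cherrying prepends it. The two-leaf tree reduces
#' to the single-leaf tree.
#'
#' @param shape a binary spinal `phylo_network` (leaf labels are treated as
#'   interchangeable; the result carries canonical labels).
#' @return A `phylo_network` of the reduced/expanded shape.
#' @export
cherry_reduce <- function(shape) {
  seq <- encode_lrp(shape)
  if (length(seq) == 0L) stop("cannot cherry-reduce the single-leaf tree")
  if (seq[1L] != "L")
    stop("shape has no cherry: the lowest spine vertex has no second leaf child")
  decode_lrp(new_lrp(seq[-1L]), allow_parallel = shape$allow_parallel)
}

#' @rdname cherry_reduce
#' @export
recherry <- function(shape) {
  seq <- encode_lrp(shape)
  decode_lrp(new_lrp(c("L", as.character(seq))),
             allow_parallel = shape$allow_parallel)
}
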