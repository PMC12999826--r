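# Extended Newick (eNewick) serialisation.
#
# Reticulate networks cannot be written as plain Newick; the eNewick
# convention splits each reticulation vertex across several occurrences
# sharing a #H<i> tag. One occurrence (the first reached in the traversal
# here) carries the vertex's subtree; the others are bare "#H<i>"
# references. Leaves are printed as their integer labels. Parallel arcs
# appear as a repeated reference under the same parent.

#' Write a network as an extended Newick string
#'
#' Reticulation vertices (in-degree >= 2) receive tags `#H1..#Hk` in spine
#' order when the network is spinal (otherwise in labelling-friendly
#' traversal order); the first occurrence carries the subtree, later ones
#' are bare references. Terminated with `;`.
#'
#' @param net a `phylo_network`.
#' @return A single string.
#' @examples
#' to_enewick(cover_to_network("{1,2}"))  # "(1,2);"
#' @export
to_enewick <- function(net) {
  stopifnot(inherits(net, "phylo_network"))
  indeg <- stats::setNames(.in_degree(net), net$vertices)
  retic <- net$vertices[indeg >= 2L]
  # stable tag order: spine order when spinal, else vertex order
  sp <- find_spine(net)
  if (!identical(sp, "NOT_SPINAL")) {
    ord <- sp$vertices
    retic <- retic[order(match(retic, ord))]
  }
  tag <- stats::setNames(seq_along(retic), retic)
  expanded <- stats::setNames(rep(FALSE, length(retic)), retic)

  emit <- function(v) {
    is_r <- v %in% retic
    if (is_r && expanded[[v]]) return(paste0("#H", tag[[v]]))
    if (is_r) expanded[[v]] <<- TRUE
    ch <- .children(net, v)
    body <- if (length(ch) == 0L) v
            else paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")")
    if (is_r) paste0(body, "#H", tag[[v]]) else body
  }
  paste0(emit(net$root), ";")
}

#' Parse an extended Newick string
#'
#' Inverse of [to_enewick()] up to isomorphism: occurrences sharing a
#' `#H` tag are merged into one reticulation vertex; at most one occurrence
#' may carry a subtree.
#'
#' @param text eNewick string (trailing `;` optional).
#' @param allow_parallel passed to [phylo_network()].
#' @return A `phylo_network`.
#' @export
from_enewick <- function(text, allow_parallel = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(sub(";\\s*$", "", trimws(text)))
  if (!nzchar(s)) stop("empty eNewick string")
  pos <- 1L
  nstr <- nchar(s)
  counter <- 0L
  arcs <- NULL
  tag_node <- character(0)     # tag -> internal node id
  tag_expanded <- logical(0)

  peek <- function() if (pos <= nstr) substring(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L

  new_node <- function() {
    counter <<- counter + 1L
    paste0("x", counter)
  }
  # returns node id
  parse_node <- function() {
    children <- NULL
    if (peek() == "(") {
      advance()
      children <- c(children, parse_node())
      while (peek() == ",") { advance(); children <- c(children, parse_node()) }
      if (peek() != ")") stop("malformed eNewick: expected ')' at position ", pos)
      advance()
    }
    # optional label and/or #H tag
    start <- pos
    while (pos <= nstr && !peek() %in% c("(", ")", ",", ";")) advance()
    label <- substring(s, start, pos - 1L)
    tagm <- regmatches(label, regexec("^([^#]*)#H([0-9]+)$", label))[[1]]
    tagid <- NA_character_
    if (length(tagm) == 3L) { label <- tagm[2L]; tagid <- tagm[3L] }
    if (!is.na(tagid)) {
      if (is.na(match(tagid, names(tag_node)))) {
        tag_node[tagid] <<- new_node()
        tag_expanded[tagid] <<- FALSE
      }
      id <- tag_node[[tagid]]
      if (!is.null(children)) {
        if (tag_expanded[[tagid]])
          stop("eNewick tag #H", tagid, " carries a subtree more than once")
        tag_expanded[tagid] <<- TRUE
      }
    } else if (is.null(children)) {
      if (!nzchar(label)) stop("malformed eNewick: unlabelled leaf at position ", pos)
      id <- label                     # a leaf: keep its printed label
    } else {
      id <- new_node()
    }
    for (ch in children) arcs <<- rbind(arcs, c(id, ch))
    id
  }
  root <- parse_node()
  if (pos <= nstr) stop("malformed eNewick: trailing characters at position ", pos)
  phylo_network(arcs, allow_parallel = allow_parallel)
}
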