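#' Taxonomy tree
#'
#' A rooted taxonomy over integer node ids. The root is its own parent.
#' Validation enforces a single root, existing parents and acyclicity.
#'
#' @param nodes data.frame with columns `id`, `parent`, `rank`, `name`.
#' @return A `taxonomy` object (list with `nodes` and `root`).
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent", "rank", "name") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  root <- nodes$id[nodes$id == nodes$parent]
  if (length(root) != 1L) stop("taxonomy must have exactly one root (parent == id)")
  if (!all(nodes$parent %in% nodes$id)) stop("every parent must be a node")
  tax <- structure(list(nodes = nodes, root = root), class = "taxonomy")
  # acyclicity: walking to the root must terminate for every node
  for (id in nodes$id) tax_ancestors(tax, id)
  tax
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("taxonomy: %d nodes, root=%d, ranks: %s\n", nrow(x$nodes),
              x$root, paste(unique(x$nodes$rank), collapse = " > ")))
  invisible(x)
}

# Path from a node up to the root, node first, root last.
tax_ancestors <- function(tax, id) {
  idx <- match(id, tax$nodes$id)
  if (is.na(idx)) stop("unknown node id: ", id)
  path <- integer(0)
  steps <- 0L
  while (TRUE) {
    path <- c(path, tax$nodes$id[idx])
    p <- tax$nodes$parent[idx]
    if (p == tax$nodes$id[idx]) break
    idx <- match(p, tax$nodes$id)
    steps <- steps + 1L
    if (steps > nrow(tax$nodes)) stop("cycle detected in taxonomy")
  }
  path
}

#' Lowest common ancestor of a set of taxonomy nodes
#'
#' @param tax a [taxonomy()].
#' @param ids integer vector of node ids (length >= 1).
#' @return The id of the deepest node ancestral to (or equal to) all `ids`.
#' @export
tax_lca <- function(tax, ids) {
  ids <- unique(ids)
  if (length(ids) == 0L) stop("tax_lca needs at least one node")
  common <- tax_ancestors(tax, ids[1L])
  for (id in ids[-1L]) {
    common <- common[common %in% tax_ancestors(tax, id)]
  }
  common[1L]
}

# ids of nodes with no children
tax_leaves <- function(tax) {
  setdiff(tax$nodes$id, tax$nodes$parent[tax$nodes$parent != tax$nodes$id])
}

# all node ids in the clade rooted at id (id included)
tax_clade <- function(tax, id) {
  out <- id
  frontier <- id
  repeat {
    kids <- tax$nodes$id[tax$nodes$parent %in% frontier &
                           !(tax$nodes$id %in% frontier)]
    kids <- setdiff(kids, out)
    if (length(kids) == 0L) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# nodes ordered so every child precedes its parent (for bottom-up sums)
tax_bottom_up <- function(tax) {
  depth <- vapply(tax$nodes$id, function(i) length(tax_ancestors(tax, i)),
                  integer(1))
  tax$nodes$id[order(-depth, tax$nodes$id)]
}
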