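#' Neuron trees and SWC input/output
#'
#' A `neuron_tree` holds one rooted tree of SWC sample points: a data frame
#' `nodes` with columns `id`, `type`, `x`, `y`, `z`, `radius`, `parent`
#' (coordinates and radius in microns, `parent = -1` for the root) and the
#' integer `root_id`. Radius and type codes are carried through unchanged by
#' every operation; the geometry used for mapping is the piecewise linear
#' curve through the node positions.
#'
#' @param nodes data frame with the seven SWC columns.
#' @return An object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes))) stop("nodes must have columns ", paste(req, collapse = ", "))
  nodes <- nodes[, req]
  if (anyDuplicated(nodes$id)) stop("duplicate node id(s): ",
                                    paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(nodes$radius < 0)) stop("radius must be non-negative")
  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) != 1L) stop("a neuron_tree must have exactly one root")
  known <- c(-1L, nodes$id)
  bad <- setdiff(nodes$parent, known)
  if (length(bad)) stop("dangling parent id(s): ", paste(bad, collapse = ", "))
  structure(list(nodes = nodes, root_id = roots), class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree: %d nodes, root id %d>\n", nrow(x$nodes), x$root_id))
  invisible(x)
}

#' Read neuron traces from an SWC file
#'
#' Parses the 7-column whitespace-delimited SWC dialect: `#`-prefixed
#' comment lines, fields `id type x y z radius parent`, arbitrary 1-based
#' ids. Multiple `parent = -1` rows yield a forest: one `neuron_tree` per
#' root, with file order preserved within each tree.
#'
#' @param path path to an SWC file.
#' @return A list of `neuron_tree` objects.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no data lines in ", path)
  parts <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 7L))
    stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                 keep[which(nf != 7L)[1L]], nf[nf != 7L][1L]))
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop(sprintf("malformed SWC line %d: non-numeric field", keep[bad]))
  }
  nodes <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L], parent = as.integer(m[, 7L]))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  known <- c(-1L, nodes$id)
  bad <- setdiff(nodes$parent, known)
  if (length(bad)) stop("dangling parent id(s): ", paste(bad, collapse = ", "))
  # assign each node to its root by walking parent links (also detects cycles)
  parent_of <- setNames(nodes$parent, nodes$id)
  root_cache <- new.env(hash = TRUE)
  find_root <- function(id) {
    chain <- integer(0)
    cur <- id
    repeat {
      key <- as.character(cur)
      hit <- root_cache[[key]]
      if (!is.null(hit)) { root <- hit; break }
      chain <- c(chain, cur)
      if (length(chain) > length(parent_of)) stop("cycle detected in parent links")
      p <- parent_of[[key]]
      if (p == -1L) { root <- cur; break }
      cur <- p
    }
    for (cid in chain) root_cache[[as.character(cid)]] <- root
    root
  }
  roots <- vapply(nodes$id, find_root, integer(1))
  lapply(unique(roots), function(r) neuron_tree(nodes[roots == r, , drop = FALSE]))
}

#' Write neuron trees to an SWC file
#'
#' Emits the standard 7-column format. With `renumber = TRUE`, ids are
#' relabeled consecutively from 1 in topological order (parents before
#' children), numbering continuing across the trees of a forest; otherwise
#' original ids are kept. Type codes and radii are copied through unchanged.
#'
#' @param trees a `neuron_tree` or list of them.
#' @param path output path.
#' @param renumber logical; relabel ids consecutively from 1.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(trees, path, renumber = FALSE) {
  if (inherits(trees, "neuron_tree")) trees <- list(trees)
  lines <- character(0)
  offset <- 0L
  for (tree in trees) {
    nodes <- tree$nodes
    nodes <- topo_sort_nodes(nodes, tree$root_id)
    if (renumber) {
      remap <- setNames(seq_len(nrow(nodes)) + offset, nodes$id)
      nodes$id <- as.integer(remap[as.character(nodes$id)])
      nodes$parent <- ifelse(nodes$parent == -1L, -1L,
                             as.integer(remap[as.character(nodes$parent)]))
      offset <- offset + nrow(nodes)
    }
    lines <- c(lines, sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                              nodes$id, nodes$type, nodes$x, nodes$y,
                              nodes$z, nodes$radius, nodes$parent))
  }
  writeLines(lines, path)
  invisible(path)
}

# order nodes so every parent precedes its children (stable w.r.t. input order)
topo_sort_nodes <- function(nodes, root_id) {
  children <- split(nodes$id, nodes$parent)
  order_ids <- integer(nrow(nodes))
  stack <- root_id
  k <- 0L
  while (length(stack)) {
    cur <- stack[1L]; stack <- stack[-1L]
    k <- k + 1L
    order_ids[k] <- cur
    kids <- children[[as.character(cur)]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  nodes[match(order_ids, nodes$id), , drop = FALSE]
}

#' Decompose a neuron tree into non-branching branches
#'
#' Recursively removes the root-to-leaf path of maximal arc length until the
#' tree is reduced to non-bifurcating branches. Each remaining subtree is
#' decomposed with its attachment node (the junction knot) duplicated as the
#' first knot of the child branch, so every branch is a standalone curve and
#' the branch segments partition the tree's edge set. Ties in path length
#' are broken toward the leaf with the smallest node id.
#'
#' @param tree a `neuron_tree`.
#' @return A list of `polyline_branch` (empty for a single-node tree), each
#'   carrying `source_ids` of the originating nodes.
#' @export
decompose_to_branches <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  nodes <- tree$nodes
  if (nrow(nodes) < 2L) return(list())
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(pos) <- nodes$id
  children <- lapply(split(nodes$id, nodes$parent), sort)
  edge_len <- function(a, b) sqrt(sum((pos[as.character(a), ] - pos[as.character(b), ])^2))

  # longest root-to-leaf path within the subtree rooted at `root`, restricted
  # to `allowed` children of the root (NULL = all); ties -> smallest leaf id
  longest_path <- function(root, allowed = NULL) {
    best_len <- -1; best_leaf <- NA_integer_
    dist <- new.env(hash = TRUE)
    prev <- new.env(hash = TRUE)
    dist[[as.character(root)]] <- 0
    first <- children[[as.character(root)]]
    if (!is.null(allowed)) first <- intersect(first, allowed)
    stack <- first
    for (id in stack) prev[[as.character(id)]] <- root
    while (length(stack)) {
      cur <- stack[1L]; stack <- stack[-1L]
      p <- prev[[as.character(cur)]]
      d <- dist[[as.character(p)]] + edge_len(p, cur)
      dist[[as.character(cur)]] <- d
      kids <- children[[as.character(cur)]]
      if (is.null(kids)) {
        if (d > best_len + 1e-12 ||
            (abs(d - best_len) <= 1e-12 && cur < best_leaf)) {
          best_len <- d; best_leaf <- cur
        }
      } else {
        for (k in kids) prev[[as.character(k)]] <- cur
        stack <- c(kids, stack)
      }
    }
    if (is.na(best_leaf)) return(root)  # root itself is a leaf in this subtree
    path <- best_leaf
    while (path[1L] != root) path <- c(prev[[as.character(path[1L])]], path)
    path
  }

  branches <- list()
  recurse <- function(root, allowed) {
    path <- longest_path(root, allowed)
    if (length(path) >= 2L)
      branches[[length(branches) + 1L]] <<-
        arc_length_parameterize(pos[as.character(path), , drop = FALSE],
                                source_ids = path)
    on_path <- as.character(path)
    for (i in seq_along(path)) {
      kids <- children[[on_path[i]]]
      if (i == 1L && !is.null(allowed)) kids <- intersect(kids, allowed)
      for (k in setdiff(kids, path)) recurse(path[i], k)
    }
  }
  recurse(tree$root_id, NULL)
  branches
}

#' Assemble an unbranched neuron tree from knot positions
#'
#' Convenience constructor for a chain-topology `neuron_tree` (one branch,
#' no bifurcations), used when writing synthetic curves to SWC.
#'
#' @param knots `n x 3` matrix of positions, microns.
#' @param type SWC type code for every node.
#' @param radius radius for every node, microns.
#' @return A `neuron_tree` with ids `1..n` and parent links forming a chain.
#' @export
chain_tree <- function(knots, type = 0L, radius = 1) {
  knots <- as_points(knots)
  n <- nrow(knots)
  neuron_tree(data.frame(id = seq_len(n), type = as.integer(type),
                         x = knots[, 1L], y = knots[, 2L], z = knots[, 3L],
                         radius = radius,
                         parent = c(-1L, seq_len(n - 1L))))
}
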