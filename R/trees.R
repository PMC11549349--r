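# Unrooted-tree kernel used by the parsimony engine. Trees are held as an
# adjacency structure ("utree") during search — tips are nodes 1..n_tip
# (in the matrix's taxon order), internal nodes have higher ids and degree
# 3 — and bridged to ape's "phylo" for I/O, consensus and display.

utree_new <- function(n_tip, labels, adj) {
  structure(list(n_tip = n_tip, labels = labels, adj = adj),
            class = "utree")
}

# smallest unrooted tree: three tips around one internal node
utree_star3 <- function(tips, n_tip, labels) {
  adj <- vector("list", n_tip + 1L)
  ctr <- n_tip + 1L
  adj[[ctr]] <- tips
  for (t in tips) adj[[t]] <- ctr
  utree_new(n_tip, labels, adj)
}

# edges as a 2-column matrix (u < v), deterministic order
utree_edges <- function(tr) {
  out <- NULL
  for (u in seq_along(tr$adj)) {
    nb <- tr$adj[[u]]
    if (is.null(nb)) next
    v <- nb[nb > u]
    if (length(v)) out <- rbind(out, cbind(u, sort(v)))
  }
  out
}

# insert `tip` on edge (u, v): subdivide with a fresh internal node
utree_insert <- function(tr, tip, u, v) {
  w <- length(tr$adj) + 1L
  tr$adj[[u]] <- c(setdiff(tr$adj[[u]], v), w)
  tr$adj[[v]] <- c(setdiff(tr$adj[[v]], u), w)
  tr$adj[[w]] <- c(u, v, tip)
  tr$adj[[tip]] <- w
  tr
}

# compact internal ids (after deletions) so adj has no NULL holes
utree_compact <- function(tr) {
  ids <- which(!vapply(tr$adj, is.null, TRUE))
  internals <- ids[ids > tr$n_tip]
  map <- integer(length(tr$adj))
  map[seq_len(tr$n_tip)] <- seq_len(tr$n_tip)
  map[internals] <- tr$n_tip + seq_along(internals)
  adj <- vector("list", tr$n_tip + length(internals))
  for (u in ids) adj[[map[u]]] <- map[tr$adj[[u]]]
  utree_new(tr$n_tip, tr$labels, adj)
}

# postorder node sequence from a root (an internal node), with parents
utree_postorder <- function(tr, root = tr$n_tip + 1L) {
  n <- length(tr$adj)
  parent <- integer(n)
  order <- integer(0)
  stack <- root; parent[root] <- 0L
  visit <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, u)
    for (v in tr$adj[[u]]) if (v != parent[u]) {
      parent[v] <- u
      stack <- c(stack, v)
    }
  }
  list(order = rev(visit), parent = parent)
}

# bipartitions as canonical label-based signatures: for each internal
# edge, the tip-label set on the side away from the lexicographically
# smallest label, sorted and comma-joined — comparable across trees
# regardless of taxon input order
utree_splits <- function(tr) {
  po <- utree_postorder(tr)
  n <- length(tr$adj)
  ref <- which(tr$labels == min(tr$labels))[1]
  below <- vector("list", n)
  for (u in po$order) {
    below[[u]] <- if (u <= tr$n_tip) u
                  else sort(unlist(lapply(
                    tr$adj[[u]][tr$adj[[u]] != po$parent[u]],
                    function(v) below[[v]])))
  }
  sigs <- character(0)
  for (u in seq_along(tr$adj)) {
    if (u <= tr$n_tip || u == po$order[length(po$order)]) next
    s <- below[[u]]
    if (length(s) < 2L || length(s) > tr$n_tip - 2L) next
    if (ref %in% s) s <- setdiff(seq_len(tr$n_tip), s)
    sigs <- c(sigs, paste(sort(tr$labels[s]), collapse = ","))
  }
  sort(unique(sigs))
}

# canonical whole-tree signature for deduplication
utree_signature <- function(tr) paste(utree_splits(tr), collapse = "|")

# Newick text for a utree (arbitrary trifurcating root at an internal node)
utree_newick <- function(tr) {
  root <- if (tr$n_tip <= 2L) 1L else tr$n_tip + 1L
  po <- utree_postorder(tr, root)
  build <- function(u, parent) {
    kids <- tr$adj[[u]][tr$adj[[u]] != parent]
    if (u <= tr$n_tip && !length(kids)) return(tr$labels[u])
    inner <- paste(vapply(kids, build, "", parent = u), collapse = ",")
    paste0("(", inner, ")")
  }
  paste0(build(root, 0L), ";")
}

#' Convert an internal search tree to ape's phylo
#' @param tr internal `utree` object.
#' @return an unrooted `phylo`.
#' @keywords internal
utree_to_phylo <- function(tr) {
  ape::read.tree(text = utree_newick(tr))
}

# phylo -> utree (tip order taken from `labels`)
phylo_to_utree <- function(phy, labels) {
  phy <- ape::unroot(phy)
  n_tip <- length(labels)
  idx <- match(phy$tip.label, labels)
  if (anyNA(idx)) stop_validation("tree tips do not match matrix taxa")
  n_node <- phy$Nnode
  adj <- vector("list", n_tip + n_node)
  map <- c(idx, n_tip + seq_len(n_node))
  for (e in seq_len(nrow(phy$edge))) {
    u <- map[phy$edge[e, 1]]; v <- map[phy$edge[e, 2]]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  utree_new(n_tip, labels, adj)
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick parser/writer so the rest of the
#' toolkit has a single entry point. Writing an unrooted tree uses ape's
#' trifurcating-root convention; `outgroup` requests display rooting with
#' the outgroup as sister to everything else. Node labels (e.g. consensus
#' clade frequencies) survive the round trip.
#'
#' @param tree a `phylo`.
#' @param path file path; for `write_newick`, `NULL` returns the text.
#' @param outgroup optional tip label for display rooting.
#' @return `read_newick`: a `phylo`. `write_newick`: the path (or text),
#'   invisibly.
#' @export
write_newick <- function(tree, path = NULL, outgroup = NULL) {
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (length(path) == 1L && file.exists(path)) ape::read.tree(path)
  else ape::read.tree(text = path)
}

# all unrooted binary topologies on the matrix's taxa (stepwise addition);
# (2n-5)!! trees — usable as an exhaustive oracle up to ~8 taxa
all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3)
  trees <- list(utree_star3(1:3, n, labels))
  for (tip in seq(4L, length.out = max(0L, n - 3L))) {
    nxt <- list()
    for (tr in trees) {
      ed <- utree_edges(tr)
      for (e in seq_len(nrow(ed)))
        nxt[[length(nxt) + 1L]] <- utree_insert(tr, tip, ed[e, 1], ed[e, 2])
    }
    trees <- nxt
  }
  trees
}
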